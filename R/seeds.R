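#' Construct a seed set
#'
#' The only manual input of the mirror-image pipeline: one or more voxel
#' coordinates, each placed by a reader inside a high-uptake tumour lesion.
#' One seed per lesion handles multifocal disease. Coordinates are 1-based
#' voxel indices into the image array.
#'
#' @param coords Integer matrix with columns x, y, z (one row per seed), or
#'   a length-3 vector for a single seed.
#' @return An object of class `seed_set` (n x 3 integer matrix).
#' @export
seed_set <- function(coords) {
  if (is.numeric(coords) && is.null(dim(coords)) && length(coords) == 3L)
    coords <- matrix(coords, nrow = 1L)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) == 0L)
    stop("seeds must be a non-empty n x 3 matrix of (x, y, z) voxel indices")
  if (anyNA(coords) || any(coords != round(coords)) || any(coords < 1))
    stop("seed coordinates must be positive integers (1-based voxel indices)")
  storage.mode(coords) <- "integer"
  if (anyDuplicated(coords))
    stop("duplicate seed coordinates")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(coords, class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d seed(s)\n", nrow(x)))
  print(unclass(x))
  invisible(x)
}

#' Validate seeds against an image and brain mask
#'
#' Checks that every seed is inside the image bounds and the brain mask.
#' Called by both pipelines before any growing starts.
#'
#' @param seeds A [seed_set()].
#' @param image The `suv_image` the seeds index into.
#' @param brain Brain [voxel_mask()].
#' @return `seeds`, invisibly.
#' @export
validate_seeds <- function(seeds, image, brain) {
  stopifnot(inherits(seeds, "seed_set"))
  check_same_grid(image, brain)
  d <- dim(image)
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    if (any(s > d))
      stop("seed ", i, " (", paste(s, collapse = ","), ") outside image bounds")
    if (!brain[s[1], s[2], s[3]])
      stop("seed ", i, " (", paste(s, collapse = ","), ") outside brain mask")
  }
  invisible(seeds)
}

#' Read seeds from JSON or CSV
#'
#' JSON: an array of `[x, y, z]` integer triplets. CSV: a header line
#' `x,y,z` followed by one row per seed. Coordinates are 1-based voxel
#' indices in both formats.
#'
#' @param path Path to a `.json` or `.csv` seed file.
#' @return A [seed_set()].
#' @export
read_seeds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
    seed_set(as.matrix(x))
  } else {
    df <- read.csv(path)
    if (!all(c("x", "y", "z") %in% names(df)))
      stop("seed CSV must have columns x, y, z")
    seed_set(as.matrix(df[, c("x", "y", "z")]))
  }
}

#' Write seeds to JSON
#' @param seeds A [seed_set()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_seeds <- function(seeds, path) {
  stopifnot(inherits(seeds, "seed_set"))
  m <- unclass(seeds)
  dimnames(m) <- NULL
  jsonlite::write_json(m, path)
  invisible(path)
}
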