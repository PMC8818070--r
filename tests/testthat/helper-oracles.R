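# Independent oracles, deliberately naive: these re-derive expected results
# by brute force and must not share code with the implementation.

# queue-based breadth-first flood fill over an R array
flood_oracle <- function(vox, seeds, threshold, brain, connectivity = 26) {
  d <- dim(vox)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6)
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  out <- array(FALSE, d)
  q <- lapply(seq_len(nrow(seeds)), function(i) as.integer(seeds[i, ]))
  for (p in q) out[p[1], p[2], p[3]] <- TRUE
  while (length(q)) {
    p <- q[[1]]
    q <- q[-1]
    for (i in seq_len(nrow(offs))) {
      np <- p + offs[i, ]
      if (any(np < 1) || any(np > d)) next
      if (out[np[1], np[2], np[3]]) next
      if (!brain[np[1], np[2], np[3]]) next
      if (vox[np[1], np[2], np[3]] < threshold) next
      out[np[1], np[2], np[3]] <- TRUE
      q <- c(q, list(np))
    }
  }
  out
}

# ICC(2,1) from stats::aov mean squares (rows = targets, cols = raters)
icc_oracle <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   target = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ target + rater, data = df))[[1]]
  ms <- tab[["Mean Sq"]]  # order: target, rater, residuals
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# compact phantom for fast pipeline tests: 24x20x16 grid at 2 mm,
# 5 mm lesion 9 mm off-midline
small_phantom <- function(noise_sd = 0, seed = 42L, rim = FALSE) {
  generate_phantom(phantom_spec(
    shape = c(24L, 20L, 16L), spacing = c(2, 2, 2),
    brain_semi_axes_mm = c(21, 17, 13),
    noise_sd = noise_sd, seed = seed,
    lesions = list(lesion_spec(c(17, 10, 8), radius_mm = 5, suv = 3,
                               rim_width_mm = if (rim) 3 else 0,
                               rim_suv = if (rim) 2.0 else NULL))))
}

uniform_image <- function(value, dims = c(6L, 6L, 6L), spacing = c(2, 2, 2)) {
  suv_image(array(value, dim = dims), spacing)
}

full_mask <- function(dims = c(6L, 6L, 6L), spacing = c(2, 2, 2)) {
  voxel_mask(array(TRUE, dim = dims), spacing)
}
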