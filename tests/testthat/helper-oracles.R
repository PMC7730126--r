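# independent co-occurrence oracle: naive double loop over pixel pairs
oracle_glcm_stats <- function(pixels, mask, d, n_levels = 8) {
  v <- pixels[mask]
  rng <- range(v)
  g <- if (diff(rng) > 0) {
    pmin(pmax(floor((pixels - rng[1]) / diff(rng) * n_levels) + 1, 1), n_levels)
  } else matrix(1, nrow(pixels), ncol(pixels))
  offsets <- list(c(0, d), c(d, d), c(d, 0), c(d, -d))
  per_dir <- sapply(offsets, function(o) {
    P <- matrix(0, n_levels, n_levels)
    for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
      i2 <- i + o[1]; j2 <- j + o[2]
      if (i2 >= 1 && i2 <= nrow(g) && j2 >= 1 && j2 <= ncol(g) &&
          mask[i, j] && mask[i2, j2]) {
        P[g[i, j], g[i2, j2]] <- P[g[i, j], g[i2, j2]] + 1
        P[g[i2, j2], g[i, j]] <- P[g[i2, j2], g[i, j]] + 1
      }
    }
    stopifnot(abs(sum(P / sum(P)) - 1) < 1e-12)  # normalized before statistics
    P <- P / sum(P)
    ii <- matrix(seq_len(n_levels), n_levels, n_levels)
    jj <- t(ii)
    c(asm = sum(P^2),
      contrast = sum((ii - jj)^2 * P),
      entropy = -sum(ifelse(P > 0, P * log(P), 0)),
      idm = sum(P / (1 + (ii - jj)^2)))
  })
  rowMeans(per_dir)
}
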