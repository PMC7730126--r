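# geometric fixtures used across morphometry and segmentation tests

mk_disk <- function(r, n = 2 * r + 5) {
  cc <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) sqrt((i - cc)^2 + (j - cc)^2)) <= r
}

mk_ellipse <- function(a, b, n = 2 * max(a, b) + 5) {
  cc <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) ((j - cc) / a)^2 + ((i - cc) / b)^2) <= 1
}

# irregular blob: union of seeded random disks
mk_blob <- function(seed, n = 80) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  pts <- cbind(sample(25:(n - 25), 12, TRUE), sample(25:(n - 25), 12, TRUE))
  for (i in seq_len(nrow(pts))) {
    d <- outer(1:n, 1:n, function(a, b)
      sqrt((a - pts[i, 1])^2 + (b - pts[i, 2])^2))
    m <- m | (d <= sample(6:12, 1))
  }
  m
}

# a small factorial design for fast statistical tests
small_levels <- function(replicates = 2) {
  factor_levels(stiffness_kPa = c(0.5, 2, 8), polymer_pct = c(1, 1.5, 3),
                ecm_base = c("L", "F"), replicates = replicates)
}

# labelled feature tibble with planted class structure in feature space
# (three informative measurements, the rest standard-normal noise)
synthetic_feature_set <- function(n_per_class = 50, seed = 1, sep = 6) {
  set.seed(seed)
  ph <- phenotypes()
  n <- n_per_class * length(ph)
  centers <- matrix(c(0, 0, 0,
                      sep, 0, 0,
                      0, sep, 0,
                      0, 0, sep), 4, 3, byrow = TRUE)
  lab <- rep(ph, each = n_per_class)
  m <- matrix(rnorm(n * 102), n, 102)
  colnames(m) <- feature_columns()
  for (k in 1:4) {
    rows <- lab == ph[k]
    m[rows, 1:3] <- m[rows, 1:3] + matrix(centers[k, ], sum(rows), 3, byrow = TRUE)
  }
  dplyr::bind_cols(
    tibble::tibble(well_id = paste0("W", rep(1:8, length.out = n)),
                   colony_id = seq_len(n), phenotype = lab),
    tibble::as_tibble(m))
}
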