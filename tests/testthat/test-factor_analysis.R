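test_that("feature scaling gives z-scores and drops constants", {
  set.seed(1)
  f <- synthetic_feature_set(n_per_class = 20, seed = 1)
  sc <- scale_features(f)
  expect_true(all(abs(colMeans(sc$matrix)) < 1e-10))
  expect_true(all(abs(apply(sc$matrix, 2, sd) - 1) < 1e-10))
  # scaling an already scaled matrix changes nothing
  sc2 <- scale_features(sc$matrix)
  expect_equal(sc2$matrix, sc$matrix, ignore_attr = TRUE)

  f$area <- 5  # constant measurement
  expect_warning(scd <- scale_features(f), "constant")
  expect_false("area" %in% colnames(scd$matrix))
  expect_equal(scd$dropped, "area")
  expect_error(scale_features(matrix(1, 5, 3)), "constant")
})

test_that("SVD matches a brute-force covariance eigen-oracle", {
  set.seed(2)
  m <- scale(matrix(rnorm(50 * 20), 50, 20))
  attr(m, "scaled:center") <- attr(m, "scaled:scale") <- NULL
  colnames(m) <- paste0("v", 1:20)
  sv <- svd_decompose(m)
  # eigenvalues of X'X are squared singular values
  ev <- eigen(crossprod(m), symmetric = TRUE)$values
  expect_equal(sv$d^2, ev, tolerance = 1e-8)
  # loadings match eigenvectors up to sign
  V <- eigen(crossprod(m), symmetric = TRUE)$vectors
  for (j in 1:5) {
    expect_equal(abs(sum(sv$loadings[, j] * V[, j])), 1, tolerance = 1e-8)
  }
  # full reconstruction
  rec <- sv$scores %*% diag(sv$d) %*% t(sv$loadings)
  expect_lt(max(abs(rec - m)), 1e-8)
  # variance shares: non-increasing, sum to one, orthonormal loadings
  expect_equal(sum(sv$variance_explained), 1)
  expect_true(all(diff(sv$variance_explained) <= 1e-12))
  expect_equal(colSums(sv$loadings^2), rep(1, 20), ignore_attr = TRUE,
               tolerance = 1e-10)
  # sign convention: dominant loading of every component is positive
  dom <- apply(sv$loadings, 2, function(v) v[which.max(abs(v))])
  expect_true(all(dom > 0))
})

test_that("a rank-1 matrix concentrates all variance in one component", {
  u <- rnorm(30); v <- rnorm(6)
  m <- outer(u, v)
  colnames(m) <- paste0("v", 1:6)
  sv <- svd_decompose(m)
  expect_equal(sv$variance_explained[1], 1, tolerance = 1e-12)
  expect_lt(sv$variance_explained[2], 1e-12)
})

test_that("component selection follows the cumulative-variance rule", {
  fake <- function(ve) structure(list(variance_explained = ve,
                                      d = sqrt(ve)), class = "morphoscreen_svd")
  expect_equal(select_components(fake(c(0.8, 0.2)))$components, 1L)
  # engineered so ten components just pass the 73% target
  ve <- c(0.15, 0.10, 0.09, 0.08, 0.07, 0.065, 0.06, 0.055, 0.05, 0.06,
          rep(0.22 / 20, 20))
  sel <- select_components(fake(ve), threshold = 0.73, max_k = 10)
  expect_equal(length(sel$components), 10)
  expect_gte(sel$cumulative_variance, 0.73)
  expect_equal(select_components(fake(c(0.6, 0.4)), threshold = 0)$components, 1L)
})

test_that("component-phenotype correlation recovers a planted association", {
  set.seed(4)
  n_wells <- 40
  wells <- sprintf("W%02d", 1:n_wells)
  freq <- runif(n_wells)
  per_well <- 25
  well_of <- rep(wells, each = per_well)
  n <- n_wells * per_well
  m <- matrix(rnorm(n * 20, sd = 0.05), n, 20)
  # one dominating block of measurements carries the well frequency
  m[, 1:10] <- m[, 1:10] + freq[match(well_of, wells)] * 5
  colnames(m) <- paste0("v", 1:20)
  sc <- scale_features(m)
  sc$ids <- tibble::tibble(well_id = well_of)
  sv <- svd_decompose(sc)
  profiles <- tibble::tibble(well_id = wells,
                             f_polarized = freq, f_nonpolarized = 0.5,
                             f_spread = runif(n_wells),
                             f_inverted = runif(n_wells))
  assoc <- pc_phenotype_correlation(sv, profiles, components = 1:3)
  pol1 <- dplyr::filter(assoc, component == 1, phenotype == "polarized")
  expect_gte(abs(pol1$pcc), 0.95)
  # constant frequency is flagged undefined, not zero
  np <- dplyr::filter(assoc, phenotype == "nonpolarized")
  expect_true(all(np$undefined))
  expect_true(all(is.na(np$pcc)))
  # permutation null: association vanishes
  set.seed(5)
  prof_perm <- profiles
  prof_perm$f_polarized <- sample(profiles$f_polarized)
  ap <- pc_phenotype_correlation(sv, prof_perm, components = 1)
  expect_lte(abs(ap$pcc[ap$phenotype == "polarized"]), 3 / sqrt(n))
  # well-aggregated variant agrees in sign and strength
  aw <- pc_phenotype_correlation(sv, profiles, components = 1,
                                 aggregate = "well")
  expect_gte(abs(aw$pcc[aw$phenotype == "polarized"]), 0.95)
})

test_that("measurement contributions decompose by family", {
  mf <- feature_manifest()
  set.seed(6)
  n <- 150
  m <- matrix(rnorm(n * 102, sd = 1e-4), n, 102)
  colnames(m) <- mf$name
  shared <- rnorm(n)
  is_int <- mf$family == "intensity"
  m[, is_int] <- m[, is_int] + shared * 3
  sv <- svd_decompose(m)
  contrib <- measurement_contributions(sv, 1)
  int_share <- contrib$family$share[contrib$family$family == "intensity"]
  expect_gte(int_share, 0.99)
  expect_equal(sum(contrib$family$share), 1)
  pos <- contrib$top$name[contrib$top$sign == "positive"]
  neg <- contrib$top$name[contrib$top$sign == "negative"]
  expect_equal(length(intersect(pos, neg)), 0)
  expect_error(measurement_contributions(sv, 1, manifest = mf[1:50, ]),
               "missing from manifest")
})

test_that("phenotype co-occurrence clustering joins correlated phenotypes first", {
  set.seed(7)
  n <- 60
  z <- rnorm(n)
  pol <- plogis(z + rnorm(n, sd = 0.5)) * 0.4
  nonpol <- plogis(z + rnorm(n, sd = 0.5)) * 0.4     # correlated with pol
  inv <- pmax(0, 0.8 - pol - nonpol)                 # anti-correlated
  spread <- pmax(0, 1 - pol - nonpol - inv)
  profiles <- tibble::tibble(well_id = sprintf("W%02d", 1:n),
                             f_polarized = pol, f_nonpolarized = nonpol,
                             f_spread = spread, f_inverted = inv)
  cl <- phenotype_cooccurrence_clustering(profiles)
  expect_setequal(cl$hclust$labels, phenotypes())
  first <- cl$hclust$merge[1, ]
  expect_setequal(cl$hclust$labels[-first],
                  c("polarized", "nonpolarized"))

  # identical frequency vectors merge at distance zero
  prof2 <- profiles
  prof2$f_nonpolarized <- prof2$f_polarized
  cl2 <- phenotype_cooccurrence_clustering(prof2)
  expect_equal(min(cl2$hclust$height), 0, tolerance = 1e-12)
})
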