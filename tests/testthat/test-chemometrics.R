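test_that("PCA recovers rank-1 structure and matches an eigen oracle", {
  set.seed(1)
  dir <- rnorm(10)
  X <- outer(rnorm(8), dir)
  s <- make_set(X, axis = 1:10)
  p <- spectra_pca(s, 2)
  expect_equal(p$explained_variance_ratio[1], 1, tolerance = 1e-10)

  X2 <- matrix(rnorm(20), 5, 4)
  s2 <- make_set(X2, axis = 1:4)
  p2 <- spectra_pca(s2, 3)
  ev <- eigen(cov(scale(X2, scale = FALSE)), symmetric = TRUE)
  for (k in 1:3) {
    v <- ev$vectors[, k]
    j <- which.max(abs(v))
    if (v[j] < 0) v <- -v
    expect_equal(unname(p2$loadings[k, ]), v, tolerance = 1e-8)
  }
  # explained variance ratio against eigenvalues of the covariance
  expect_equal(p2$explained_variance_ratio,
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-8)
})

test_that("PCA satisfies its structural invariants", {
  set.seed(2)
  X <- matrix(rnorm(80), 8, 10)
  X <- rbind(X, X[1, ])  # duplicated cell
  s <- make_set(X, axis = 1:10)
  p <- spectra_pca(s, 4)
  G <- p$loadings %*% t(p$loadings)
  expect_equal(G, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(p$explained_variance_ratio), 1 + 1e-12)
  cv <- cov(p$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8 * max(diag(cv)))
  expect_equal(p$scores[1, ], p$scores[9, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(spectra_pca(s, 11), "n_components")
  prof <- pc_loading_profile(p, 2)
  expect_equal(sqrt(sum(prof$loading^2)), 1, tolerance = 1e-10)
  expect_error(pc_loading_profile(p, 5), "range")
})

test_that("spectral contrast angle behaves like an angle", {
  x <- c(1, 2, 3)
  expect_equal(spectral_contrast_angle(x, x), 0)
  expect_equal(spectral_contrast_angle(c(1, 0), c(0, 1)), pi / 2)
  y <- c(3, 1, 0.5)
  expect_equal(spectral_contrast_angle(x, 7 * y),
               spectral_contrast_angle(x, y), tolerance = 1e-12)
  expect_error(spectral_contrast_angle(x, c(0, 0, 0)), "zero-norm")
  expect_error(spectral_contrast_angle(x, c(1, 2)), "length")
})

test_that("distance matrices are metric-correct and well-formed", {
  s <- make_set(rbind(c(0, 0), c(3, 0), c(4, 0)), axis = 1:2)
  d <- distance_matrix(s, "euclidean")
  expect_equal(sort(d$values[upper.tri(d$values)]), c(1, 3, 4))
  expect_equal(d$values, t(d$values))
  expect_equal(diag(d$values), rep(0, 3), ignore_attr = TRUE)

  set.seed(3)
  X <- matrix(rexp(40), 4, 10)
  s2 <- make_set(X, axis = 1:10)
  s3 <- make_set(X * runif(4, 0.5, 5), axis = 1:10)
  expect_equal(distance_matrix(s2, "contrast_angle")$values,
               distance_matrix(s3, "contrast_angle")$values,
               tolerance = 1e-10)
  same <- make_set(rbind(c(1, 2), c(1, 2)), axis = 1:2)
  expect_equal(max(distance_matrix(same)$values), 0)
})

test_that("PCoA reproduces Euclidean configurations and PCA scores", {
  set.seed(4)
  pts <- cbind(rnorm(7), rnorm(7))
  s <- make_set(pts, axis = 1:2)
  d <- distance_matrix(s, "euclidean")
  ord <- spectra_pcoa(d, 2)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(rec, d$values, tolerance = 1e-8, ignore_attr = TRUE)

  X <- matrix(rnorm(60), 10, 6)
  s2 <- make_set(X, axis = 1:6)
  ord2 <- spectra_pcoa(distance_matrix(s2), 2)
  p2 <- spectra_pca(s2, 2)
  expect_equal(abs(ord2$coordinates), abs(p2$scores[, 1:2]),
               tolerance = 1e-6, ignore_attr = TRUE)

  pair <- make_set(rbind(c(0, 0), c(3, 4)), axis = 1:2)
  opair <- spectra_pcoa(distance_matrix(pair), 1)
  expect_equal(unname(abs(diff(opair$coordinates[, 1]))), 5,
               tolerance = 1e-10)
})

test_that("Ward D2 clustering matches a brute-force Lance-Williams oracle", {
  s <- make_set(matrix(c(0, 1, 10), ncol = 1,
                       dimnames = NULL) %x% t(rep(1, 2)), axis = 1:2)
  d <- distance_matrix(s)
  h <- ward_dendrogram(d)
  expect_equal(sort(h$merge[1, ]), c(-2, -1))  # first merge = {0, 1}

  set.seed(5)
  X <- matrix(rnorm(12), 6, 2)
  d6 <- distance_matrix(make_set(X, axis = 1:2))
  h6 <- ward_dendrogram(d6)
  expect_equal(h6$height, oracle_ward_heights(d6$values),
               tolerance = 1e-10)

  # two well-separated blobs: the first cut recovers them exactly
  blobs <- rbind(matrix(rnorm(10, 0, 0.05), 5, 2),
                 matrix(rnorm(10, 100, 0.05), 5, 2))
  db <- distance_matrix(make_set(blobs, axis = 1:2))
  hb <- ward_dendrogram(db)
  cl <- cutree(hb, k = 2)
  expect_equal(length(unique(cl[1:5])), 1L)
  expect_equal(length(unique(cl[6:10])), 1L)
  expect_true(cl[1] != cl[6])
  expect_error(ward_dendrogram(distance_matrix(make_set(
    matrix(rexp(20), 4, 5), axis = 1:5), "contrast_angle")), "euclidean")
})

test_that("class means and contrast profiles obey linearity and sign", {
  s <- make_set(rbind(rep(0, 4), rep(2, 4), rep(5, 4)), axis = 1:4,
                groups = c("a", "a", "b"))
  expect_equal(class_mean_spectrum(s, "a"), rep(1, 4),
               ignore_attr = TRUE)
  expect_equal(class_mean_spectrum(s, "b"), rep(5, 4),
               ignore_attr = TRUE)
  expect_error(class_mean_spectrum(s, "zz"), "unknown")
  # mean of all cells equals the size-weighted mean of group means
  all_mean <- colMeans(s$intensities)
  expect_equal(all_mean,
               (2 * class_mean_spectrum(s, "a") +
                  1 * class_mean_spectrum(s, "b")) / 3)
  ab <- contrast_profile(s, "a", "b")
  ba <- contrast_profile(s, "b", "a")
  expect_equal(ab$density, -ba$density)
  same <- contrast_profile(make_set(rbind(1:4, 1:4), axis = 1:4,
                                    groups = c("a", "b")), "a", "b")
  expect_equal(same$density, rep(0, 4))
})

test_that("contrast profile of a phi6-like population has the planted signs", {
  pop <- small_population("phi6_like", n = 40, seed = 21)
  ctr <- contrast_profile(pop$set, "infected", "control")
  expect_gt(ctr$density[ctr$wavenumber == 1576], 0)
  expect_lt(ctr$density[ctr$wavenumber == 1004], 0)
  expect_lt(ctr$density[ctr$wavenumber == 1671], 0)
})

test_that("MRPP handles perfect separation and matches exhaustive enumeration", {
  # coincident groups: delta = 0, A = 1; with 10+10 points the chance
  # that a random relabelling reproduces the split is ~1e-5, so the
  # add-one permutation p sits at its floor
  X <- rbind(matrix(0, 10, 2), matrix(100, 10, 2))
  d <- distance_matrix(make_set(X, axis = 1:2))
  g <- rep(c("a", "b"), each = 10)
  r <- mrpp(d, g, n_permutations = 199, seed = 1)
  expect_equal(r$delta_observed, 0)
  expect_equal(r$A, 1)
  expect_equal(r$p_value, 1 / 200)

  set.seed(6)
  for (rep in 1:3) {
    X6 <- matrix(rnorm(12), 6, 2)
    d6 <- distance_matrix(make_set(X6, axis = 1:2))
    g6 <- rep(c("a", "b"), each = 3)
    p_exact <- oracle_mrpp_exhaustive_p(d6$values, g6)
    r6 <- mrpp(d6, g6, n_permutations = 999, seed = rep)
    expect_lt(abs(r6$p_value - p_exact), 2 / sqrt(999))
    expect_equal(r6$delta_observed, oracle_mrpp_delta(d6$values, g6),
                 tolerance = 1e-12)
  }
  expect_error(mrpp(d, rep("a", 20), seed = 1), "2 groups")
  expect_error(mrpp(d, c("a", rep("b", 19)), seed = 1), ">= 2 cells")
})

test_that("MRPP agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(7)
  X <- matrix(rnorm(60), 20, 3)
  X[11:20, ] <- X[11:20, ] + 1
  g <- rep(c("a", "b"), each = 10)
  d <- distance_matrix(make_set(X, axis = 1:3))
  mine <- mrpp(d, g, n_permutations = 999, seed = 2)
  ref <- vegan::mrpp(dist(X), g, permutations = 999)
  expect_equal(mine$delta_observed, ref$delta, tolerance = 1e-10)
  expect_equal(mine$A, ref$A, tolerance = 0.02)
  expect_lt(abs(mine$p_value - ref$Pvalue), 0.02)
})

test_that("MRPP A is centered at zero under exchangeable labels", {
  set.seed(8)
  As <- replicate(200, {
    X <- matrix(rnorm(24 * 4), 24, 4)
    d <- distance_matrix(make_set(X, axis = 1:4))
    mrpp(d, rep(c("a", "b"), each = 12), n_permutations = 99,
         seed = sample.int(1e6, 1))$A
  })
  expect_lt(abs(mean(As)), 0.01)
})
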