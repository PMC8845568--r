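test_that("band intensity extraction: window max and nearest point", {
  axis <- seq(1560, 1590, by = 1)
  y <- 0.01 * exp(-4 * log(2) * (axis - 1576)^2 / 14^2)
  expect_equal(peak_intensity(axis, y, 1576, 5), 0.01)
  # w = 0: nearest grid point
  expect_equal(peak_intensity(axis, y, 1576.4, 0), y[axis == 1576])
  # apex shifted +3 from the query: wide window reaches it, narrow does not
  y3 <- 0.01 * exp(-4 * log(2) * (axis - 1579)^2 / 14^2)
  expect_equal(peak_intensity(axis, y3, 1576, 5), 0.01)
  shoulder <- peak_intensity(axis, y3, 1576, 1)
  expect_lt(shoulder, 0.01)
  expect_equal(shoulder, y3[axis == 1577])
  expect_error(peak_intensity(axis, y, 2000, 5), "outside")
})

test_that("the virocell ratio reproduces hand-computed values", {
  expect_equal(virocell_ratio(1, c(1, 2)), 1)
  expect_equal(virocell_ratio(2, c(1, 1)), 4)
  expect_equal(virocell_ratio(c(`1576` = 1.2), c(`1003` = 0.8,
                                                 `1671` = 1.5)),
               1.2 * 2 / (0.8 * 1.5))
  # homogeneity
  expect_equal(virocell_ratio(2 * 1.2, c(0.8, 1.5)),
               2 * virocell_ratio(1.2, c(0.8, 1.5)))
  expect_equal(virocell_ratio(1.2, c(2 * 0.8, 1.5)),
               virocell_ratio(1.2, c(0.8, 1.5)) / 2)
  # whole-spectrum rescaling by c changes the ratio by 1/c
  expect_equal(virocell_ratio(3 * 1.2, 3 * c(0.8, 1.5)),
               virocell_ratio(1.2, c(0.8, 1.5)) / 3)
  expect_error(virocell_ratio(c(`1576` = 0), c(1, 2)), "1576")
})

test_that("ratio tables recover the planted effect direction", {
  p6 <- small_population("phi6_like", n = 40, seed = 41)
  r6 <- ratio_table(p6$set)
  expect_gt(mean(r6$ratio[r6$group == "infected"]),
            mean(r6$ratio[r6$group == "control"]))
  p29 <- small_population("phi29_like", n = 40, seed = 41)
  r29 <- ratio_table(p29$set)
  expect_lt(mean(r29$ratio[r29$group == "infected"]),
            mean(r29$ratio[r29$group == "control"]))
  # identical cells give identical ratios; ratio is recomputable
  s <- make_set(rbind(rep(1, 1201), rep(1, 1201)),
                axis = seq(600, 1800, 1), groups = c("a", "b"))
  rr <- ratio_table(s)
  expect_equal(rr$ratio[1], rr$ratio[2])
  expect_equal(rr$ratio,
               rr$I_1576 * 2 / (rr$I_1003 * rr$I_1671))
})

test_that("cells with non-positive band intensity are skipped and logged", {
  axis <- seq(600, 1800, 1)
  good <- rep(1, 1201)
  bad <- rep(1, 1201)
  bad[axis >= 999 & axis <= 1007] <- 0
  s <- make_set(rbind(good, bad), axis = axis, groups = c("a", "a"))
  rt <- ratio_table(s)
  expect_equal(nrow(rt), 1L)
  expect_equal(attr(rt, "skipped")$cell_id, "cell_02")
})

test_that("Shapiro wrapper is calibrated and detects mixtures", {
  set.seed(1)
  ps <- replicate(100, normality_test(rnorm(500))$p)
  # nominal pass rate 0.99; allow 3 binomial sd at 100 replicates
  expect_gte(mean(ps > 0.01), 0.99 - 3 * sqrt(0.99 * 0.01 / 100))
  set.seed(2)
  mix <- c(rnorm(250, 0), rnorm(250, 4))
  expect_lt(normality_test(mix)$p, 0.01)
  expect_true(normality_test(rep(1, 10))$degenerate)
  expect_error(normality_test(c(1, 2)), "3 <= n")
})

test_that("rank-sum test handles separation, identity and matches enumeration", {
  sep <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_lt(sep$p, 0.1)
  same <- rank_sum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p, 0.95)
  set.seed(3)
  for (rep in 1:5) {
    a <- rnorm(4)
    b <- rnorm(4, mean = runif(1, 0, 2))
    # worst-case gap of the continuity-corrected normal approximation to
    # the exact two-sided enumeration at n = 4 + 4 is ~0.031
    expect_lt(abs(rank_sum_test(a, b)$p - oracle_ranksum_exact_p(a, b)),
              0.035)
  }
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("Dunn's test separates shifted groups and is null-calibrated", {
  d <- dunn_test(c(1, 2, 3, 11, 12, 13, 21, 22, 23),
                 rep(c("a", "b", "c"), each = 3), adjustment = "none")
  # z by the formula, no ties: mean ranks 2, 5, 8; se = sqrt(N(N+1)/12 *
  # (1/3 + 1/3))
  N <- 9
  se <- sqrt((N * (N + 1) / 12) * (2 / 3))
  expect_equal(abs(d$z[d$group_i == "a" & d$group_j == "c"]),
               6 / se, tolerance = 1e-12)
  expect_equal(abs(d$z[d$group_i == "a" & d$group_j == "b"]),
               3 / se, tolerance = 1e-12)
  expect_lt(d$p_raw[d$group_i == "a" & d$group_j == "c"], 0.05)
  two <- dunn_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(two$z, 0)
  expect_equal(two$p_raw, 1)
  set.seed(4)
  hits <- replicate(200, {
    v <- rnorm(30)
    g <- rep(c("a", "b", "c"), each = 10)
    any(dunn_test(v, g, adjustment = "none")$p_raw <= 0.05)
  })
  # per-pair level 0.05, 3 correlated pairs: family-wise rate well below 0.3
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.25)
  expect_error(dunn_test(1:5, rep("a", 5)), "2 non-empty")
})

test_that("cutoff calibration matches the normal-quantile closed form", {
  set.seed(5)
  x <- rnorm(100, mean = 1, sd = 0.02)
  x <- 1 + 0.02 * scale(x)[, 1]  # force exact mean 1, sd 0.02
  cal <- calibrate_cutoff(x, 0.99)
  expect_equal(cal$cutoff, 1 + qnorm(0.99) * 0.02, tolerance = 1e-12)
  expect_false(cal$degenerate)
  deg <- calibrate_cutoff(rep(1, 10), 0.99)
  expect_true(deg$degenerate)
  expect_equal(deg$cutoff, 1)
  expect_error(calibrate_cutoff(x, 0.5), "confidence_level")
  expect_error(calibrate_cutoff(x, 1), "confidence_level")
  expect_error(calibrate_cutoff(c(1, 2), 0.99), ">= 3")
})

test_that("classification summarizes calls and false positives", {
  rt <- structure(data.frame(cell_id = paste0("c", 1:6),
                             group = rep(c("control", "infected"),
                                         each = 3),
                             ratio = c(0.9, 1.0, 0.95, 2, 2, 0.9)),
                  class = c("ratio_table", "data.frame"))
  cal <- structure(list(cutoff = 1.06, confidence_level = 0.99),
                   class = "cutoff_calibration")
  cls <- classify_virocells(rt, cal)
  expect_equal(cls$cells$is_virocell, c(F, F, F, T, T, F))
  expect_equal(cls$n_virocells, 2L)
  expect_equal(cls$virocell_fraction, 2 / 3)
  expect_equal(cls$n_false_positive, 0L)
  # all below cutoff -> zero calls
  cal2 <- structure(list(cutoff = 10), class = "cutoff_calibration")
  expect_equal(classify_virocells(rt, cal2)$n_virocells, 0L)
})

test_that("planted virocell fractions are recovered across settings", {
  for (frac in c(0.2, 0.45, 0.8)) {
    sc <- scenario_config("phi6_like", n_control = 80,
                          n_infected_sample = 100,
                          virocell_fraction = frac, seed = 50 + frac * 100)
    pp <- preprocess(generate_population(sc)$set)$set
    rt <- ratio_table(pp)
    cal <- calibrate_cutoff(rt$ratio[rt$group == "control"])
    cls <- classify_virocells(rt, cal)
    expect_lt(abs(cls$virocell_fraction - frac), 0.1)
  }
})

test_that("marker selection recovers the planted bands and rejects null data", {
  pop <- small_population("phi6_like", n = 40, seed = 61)
  ctr <- contrast_profile(pop$set, "infected", "control")
  pca <- spectra_pca(pop$set, 2)
  sel <- select_marker_wavenumbers(ctr, pca, pop$set, alpha = 0.01)
  num <- sel$wavenumber[sel$role == "numerator"]
  den <- sel$wavenumber[sel$role == "denominator"]
  expect_true(any(abs(num - 1576) <= 6))
  expect_true(any(abs(den - 1003) <= 6))
  expect_true(any(abs(den - 1671) <= 6))
  expect_true(all(!is.na(sel$assignment[abs(sel$wavenumber - 1576) <= 6])))
  # determinism
  sel2 <- select_marker_wavenumbers(ctr, pca, pop$set, alpha = 0.01)
  expect_identical(sel, sel2)
  # zero density -> empty with a warning
  flat <- make_set(rbind(rep(1, 50), rep(1, 50)), axis = 1:50,
                   groups = c("infected", "control"))
  ctr0 <- contrast_profile(flat, "infected", "control")
  expect_warning(s0 <- select_marker_wavenumbers(ctr0,
                                                 spectra_pca(flat, 1),
                                                 flat),
                 "no contrast extrema")
  expect_equal(nrow(s0), 0L)
})

test_that("null populations rarely yield surviving marker candidates", {
  survivors <- vapply(1:40, function(seed) {
    pop <- small_population("null", n = 25, seed = 1000 + seed)
    ctr <- contrast_profile(pop$set, "infected", "control")
    pca <- spectra_pca(pop$set, 2)
    sel <- suppressWarnings(
      select_marker_wavenumbers(ctr, pca, pop$set, alpha = 0.01))
    nrow(sel) > 0
  }, logical(1))
  expect_lte(sum(survivors), 4)
})
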