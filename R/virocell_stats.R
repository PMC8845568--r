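#' Marker band set for the virocell ratio
#'
#' The default reproduces the published differentiator: the nucleic-acid
#' band at 1,576 1/cm (doubled) in the numerator and the protein bands at
#' 1,003 and 1,671 1/cm in the denominator,
#' `ratio = (I_1576 * 2) / (I_1003 * I_1671)`.
#'
#' @param numerator_wavenumbers numerator band positions (1/cm).
#' @param denominator_wavenumbers denominator band positions (1/cm),
#'   non-empty.
#' @param numerator_multiplier scalar multiplier applied to the numerator
#'   product (default 2, as published).
#' @param window_halfwidth half-width (1/cm) of the max-in-window band
#'   extraction; 0 degenerates to nearest-grid-point lookup. The default
#'   4 1/cm captures peak shoulders, which carry part of the infection
#'   signal.
#' @return a list of class `marker_set`.
#' @export
marker_set <- function(numerator_wavenumbers = 1576,
                       denominator_wavenumbers = c(1003, 1671),
                       numerator_multiplier = 2,
                       window_halfwidth = 4) {
  if (length(denominator_wavenumbers) == 0L) {
    stop("denominator band list must be non-empty", call. = FALSE)
  }
  structure(list(numerator_wavenumbers = as.numeric(numerator_wavenumbers),
                 denominator_wavenumbers =
                   as.numeric(denominator_wavenumbers),
                 numerator_multiplier = numerator_multiplier,
                 window_halfwidth = window_halfwidth),
            class = "marker_set")
}

#' Band intensity of one cell at one wavenumber
#'
#' Maximum intensity within the closed window
#' `[wavenumber - w, wavenumber + w]`; with `w = 0` the intensity at the
#' nearest grid point.
#'
#' @param axis wavenumber grid.
#' @param intensities matching intensity vector.
#' @param wavenumber query position (1/cm).
#' @param window_halfwidth window half-width `w` (1/cm).
#' @return scalar intensity.
#' @export
peak_intensity <- function(axis, intensities, wavenumber,
                           window_halfwidth = 4) {
  w <- window_halfwidth
  if (w == 0) {
    if (wavenumber < min(axis) || wavenumber > max(axis)) {
      stop(sprintf("wavenumber %g outside axis", wavenumber), call. = FALSE)
    }
    return(intensities[which.min(abs(axis - wavenumber))])
  }
  keep <- axis >= wavenumber - w & axis <= wavenumber + w
  if (!any(keep)) {
    stop(sprintf("window [%g, %g] outside axis", wavenumber - w,
                 wavenumber + w), call. = FALSE)
  }
  max(intensities[keep])
}

#' The virocell ratio (nucleic acids over proteins)
#'
#' `ratio = (prod(I_num) * multiplier) / prod(I_den)`. With the default
#' markers this is `(I_1576 * 2) / (I_1003 * I_1671)`. All band
#' intensities must be positive. Note the ratio is not invariant to
#' rescaling the whole spectrum (one numerator band against two
#' denominator bands), which is why TIC normalization must precede it.
#'
#' @param I_num numerator band intensities (named or not).
#' @param I_den denominator band intensities.
#' @param multiplier numerator multiplier (default 2).
#' @return scalar ratio.
#' @export
virocell_ratio <- function(I_num, I_den, multiplier = 2) {
  check_pos <- function(v, side) {
    bad <- which(v <= 0)
    if (length(bad) > 0L) {
      nm <- names(v)[bad]
      if (is.null(nm) || any(nm == "")) nm <- paste0(side, "[", bad, "]")
      stop("non-positive band intensity at: ", paste(nm, collapse = ", "),
           call. = FALSE)
    }
  }
  check_pos(I_num, "numerator")
  check_pos(I_den, "denominator")
  prod(I_num) * multiplier / prod(I_den)
}

#' Per-cell band intensities and virocell ratios
#'
#' Cells whose extracted band intensity is non-positive at any marker are
#' excluded (their ratio would be infinite or undefined) and recorded in
#' the `skipped` attribute with the offending band.
#'
#' @param set a preprocessed [spectrum_set()].
#' @param markers a [marker_set()].
#' @return data.frame (class `ratio_table`) with `cell_id`, `group`, one
#'   `I_<band>` column per marker band, and `ratio`; attribute `skipped`
#'   lists excluded cells.
#' @export
ratio_table <- function(set, markers = marker_set()) {
  stopifnot(inherits(set, "spectrum_set"), inherits(markers, "marker_set"))
  bands <- c(markers$numerator_wavenumbers,
             markers$denominator_wavenumbers)
  n_num <- length(markers$numerator_wavenumbers)
  inten <- sapply(bands, function(b) {
    apply(set$intensities, 1L, function(y)
      peak_intensity(set$axis, y, b, markers$window_halfwidth))
  })
  inten <- matrix(inten, nrow = n_cells(set))
  colnames(inten) <- paste0("I_", bands)
  ok <- apply(inten > 0, 1L, all)
  ratio <- rep(NA_real_, n_cells(set))
  for (i in which(ok)) {
    ratio[i] <- virocell_ratio(inten[i, seq_len(n_num)],
                               inten[i, -seq_len(n_num)],
                               markers$numerator_multiplier)
  }
  out <- data.frame(cell_id = set$meta$cell_id, group = set$meta$group,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(inten), ratio = ratio)
  skipped <- out[!ok, c("cell_id", "group"), drop = FALSE]
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "markers") <- markers
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric sample, 3 <= n <= 5000.
#' @return list `W`, `p`, `degenerate` (TRUE when the sample is constant,
#'   in which case `W` and `p` are `NA`).
#' @export
normality_test <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    return(list(W = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, degenerate = FALSE)
}

#' Two-sided Wilcoxon/Mann-Whitney rank-sum test
#'
#' Unpaired rank-sum test with the tie-corrected normal approximation
#' (samples are distinct cells).
#'
#' @param a,b numeric samples, each non-empty.
#' @return list `U` (number of (a, b) pairs with a > b), `p` (two-sided).
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Dunn's post-hoc test of pairwise group differences in joint ranks
#'
#' Groups are ranked jointly (Kruskal-Wallis style, mid-ranks for ties);
#' for each pair `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i +
#' 1/n_j))` with tie correction `T = sum(t^3 - t) / (12 (N - 1))`.
#' Two-sided normal p-values, multiplicity-adjusted per `adjustment`.
#'
#' @param values numeric observations.
#' @param groups matching labels; >= 2 non-empty groups.
#' @param adjustment p-adjustment: `"bh"` (default), `"holm"`,
#'   `"bonferroni"`, `"none"`.
#' @return data.frame `group_i`, `group_j`, `z`, `p_raw`, `p_adjusted`;
#'   attribute `kruskal` holds the omnibus Kruskal-Wallis result.
#' @export
dunn_test <- function(values, groups,
                      adjustment = c("bh", "holm", "bonferroni", "none")) {
  adjustment <- match.arg(adjustment)
  groups <- as.character(groups)
  keep <- !is.na(values)
  values <- values[keep]; groups <- groups[keep]
  lev <- sort(unique(groups))
  sizes <- table(factor(groups, levels = lev))
  if (length(lev) < 2L || any(sizes == 0L)) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, factor(groups, levels = lev), mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(lev, 2L)
  res <- data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ],
                    z = NA_real_, p_raw = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / sizes[[i]] + 1 / sizes[[j]]))
    z <- if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
    res$z[k] <- z
    res$p_raw[k] <- 2 * stats::pnorm(-abs(z))
  }
  method <- switch(adjustment, bh = "BH", holm = "holm",
                   bonferroni = "bonferroni", none = "none")
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = method)
  attr(res, "kruskal") <- stats::kruskal.test(values,
                                              factor(groups, levels = lev))
  res
}

#' Calibrate the virocell cutoff from control-group ratios
#'
#' One-sided normal tolerance bound on individual cells:
#' `cutoff = mean + z(confidence_level) * sd` (sample sd, n - 1
#' denominator), so a fresh uninfected cell exceeds the cutoff with
#' probability `1 - confidence_level` when the control ratios are normal.
#' Shapiro-Wilk results for the control (and optionally the infected
#' sample) are stored as a validity note: control ratios are expected
#' normal, infected-sample ratios are expected non-normal because that
#' sample is a mixture of virocells and uninfected cells.
#'
#' @param control_ratios numeric ratios of control cells, n >= 3.
#' @param confidence_level in (0.5, 1); default 0.99.
#' @param infected_ratios optional infected-sample ratios for the
#'   validity note.
#' @return object of class `cutoff_calibration`: `control_mean`,
#'   `control_sd`, `confidence_level`, `cutoff`, `degenerate`,
#'   `shapiro_control`, `shapiro_infected` (or NULL).
#' @export
calibrate_cutoff <- function(control_ratios, confidence_level = 0.99,
                             infected_ratios = NULL) {
  control_ratios <- control_ratios[!is.na(control_ratios)]
  if (length(control_ratios) < 3L) {
    stop("need >= 3 control ratios", call. = FALSE)
  }
  if (confidence_level <= 0.5 || confidence_level >= 1) {
    stop("confidence_level must be in (0.5, 1)", call. = FALSE)
  }
  m <- mean(control_ratios)
  s <- stats::sd(control_ratios)
  degenerate <- s == 0
  cutoff <- if (degenerate) m else
    m + stats::qnorm(confidence_level) * s
  sh_c <- normality_test(control_ratios)
  sh_i <- if (!is.null(infected_ratios) &&
              sum(!is.na(infected_ratios)) >= 3L) {
    normality_test(infected_ratios)
  } else NULL
  structure(list(control_mean = m, control_sd = s,
                 confidence_level = confidence_level, cutoff = cutoff,
                 degenerate = degenerate,
                 shapiro_control = sh_c, shapiro_infected = sh_i),
            class = "cutoff_calibration")
}

#' Classify cells as virocells by the calibrated cutoff
#'
#' A cell is called a virocell when its ratio strictly exceeds the
#' cutoff. The summary counts calls per group; calls inside the control
#' group are false positives by construction.
#'
#' @param ratios a [ratio_table()].
#' @param calibration a [calibrate_cutoff()] result from the control
#'   group of the same experiment.
#' @param control_group label of the control group (default "control").
#' @return object of class `classification_result`: `cells` (per-cell
#'   data.frame with `is_virocell`), `summary` (per-group n and calls),
#'   plus `n_infected_sample`, `n_virocells`, `virocell_fraction`,
#'   `n_control`, `n_false_positive`, `cutoff`.
#' @export
classify_virocells <- function(ratios, calibration,
                               control_group = "control") {
  stopifnot(inherits(calibration, "cutoff_calibration"))
  cells <- as.data.frame(ratios)
  cells$is_virocell <- cells$ratio > calibration$cutoff
  groups <- unique(cells$group)
  summary <- data.frame(
    group = groups,
    n = vapply(groups, function(g) sum(cells$group == g), integer(1)),
    n_called = vapply(groups, function(g)
      sum(cells$is_virocell[cells$group == g]), integer(1)),
    stringsAsFactors = FALSE)
  infected <- cells$group != control_group
  n_inf <- sum(infected)
  n_vc <- sum(cells$is_virocell[infected])
  structure(list(cells = cells, summary = summary,
                 n_infected_sample = n_inf, n_virocells = n_vc,
                 virocell_fraction = if (n_inf > 0) n_vc / n_inf else
                   NA_real_,
                 n_control = sum(!infected),
                 n_false_positive = sum(cells$is_virocell[!infected]),
                 cutoff = calibration$cutoff),
            class = "classification_result")
}

#' Screen contrast and PCA profiles for candidate marker wavenumbers
#'
#' Candidate bands are local extrema of the absolute contrast density with
#' prominence at least `min_prominence` (default: 20% of the maximum
#' absolute density). Each candidate is annotated with its PC1/PC2
#' loading and its per-cell band-intensity rank-sum p-value. Because
#' candidates are data-driven extrema — under the null they sit exactly
#' where noise made the groups differ most — retention is decided by a
#' Westfall-Young maxT permutation test: a candidate is kept when its
#' absolute density exceeds the permutation distribution of the maximum
#' absolute density over the whole axis at level `alpha`. This controls
#' the family-wise rate of spurious candidates without sacrificing power
#' at the planted bands. Positive density assigns the band to the ratio
#' numerator, negative to the denominator. When a candidate lies within
#' +/- 6 1/cm of a packaged assignment-table entry, the assignment is
#' reported.
#'
#' @param contrast a [contrast_profile()] (infected minus control).
#' @param pca a [spectra_pca()] on the same preprocessed set (>= 2
#'   components).
#' @param set the preprocessed [spectrum_set()].
#' @param alpha family-wise retention level for the maxT permutation
#'   test.
#' @param min_prominence absolute-density prominence threshold; `NULL`
#'   for the default.
#' @param window_halfwidth band-extraction half-width for the per-cell
#'   test.
#' @param n_permutations label permutations for the maxT null
#'   distribution.
#' @param perm_seed seed of the (local, state-restoring) permutation
#'   stream, so selection is deterministic given its inputs.
#' @param assignments assignment lookup table (default
#'   [band_assignments()]).
#' @return data.frame of candidates: `wavenumber`, `density`,
#'   `pc1_loading`, `pc2_loading`, `p_value` (raw rank-sum),
#'   `p_maxt` (family-wise permutation p), `role`
#'   (`"numerator"`/`"denominator"`), `assignment`; ordered by decreasing
#'   `|density|`. Zero rows (with a warning) when no extremum is found.
#' @export
select_marker_wavenumbers <- function(contrast, pca, set, alpha = 0.01,
                                      min_prominence = NULL,
                                      window_halfwidth = 4,
                                      n_permutations = 499L,
                                      perm_seed = 1L,
                                      assignments = band_assignments()) {
  stopifnot(inherits(contrast, "contrast_profile"),
            inherits(pca, "spectra_pca"),
            inherits(set, "spectrum_set"))
  dens <- contrast$density
  absd <- abs(dens)
  if (is.null(min_prominence)) min_prominence <- 0.2 * max(absd)
  pk <- find_peaks(absd, min_prominence)
  empty <- data.frame(wavenumber = numeric(0), density = numeric(0),
                      pc1_loading = numeric(0), pc2_loading = numeric(0),
                      p_value = numeric(0), p_maxt = numeric(0),
                      role = character(0), assignment = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(pk) == 0L || max(absd) == 0) {
    warning("no contrast extrema found")
    return(empty)
  }
  groups <- unique(set$meta$group)
  if (length(groups) != 2L) stop("need exactly 2 groups", call. = FALSE)

  # permutation null of the maximum |density| over the axis, with a
  # local RNG stream so the caller's random state is untouched
  max_null <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(perm_seed)
    X <- set$intensities
    n <- nrow(X)
    is_a <- set$meta$group == groups[1L]
    n1 <- sum(is_a); n2 <- n - n1
    W <- matrix(0, n_permutations, n)
    for (b in seq_len(n_permutations)) {
      idx <- sample.int(n, n1)
      W[b, idx] <- 1 / n1
      W[b, -idx] <- -1 / n2
    }
    apply(abs(W %*% X), 1L, max)
  })

  out <- empty
  for (r in order(pk$height, decreasing = TRUE)) {
    i <- pk$index[r]
    wn <- contrast$wavenumber[i]
    p_maxt <- (sum(max_null >= absd[i]) + 1) / (n_permutations + 1)
    if (p_maxt >= alpha) next
    band <- apply(set$intensities, 1L, function(y)
      peak_intensity(set$axis, y, wn, window_halfwidth))
    p <- rank_sum_test(band[set$meta$group == groups[1L]],
                       band[set$meta$group == groups[2L]])$p
    near <- which(abs(assignments$wavenumber - wn) <= 6)
    out <- rbind(out, data.frame(
      wavenumber = wn, density = dens[i],
      pc1_loading = pca$loadings[1L, i],
      pc2_loading = if (nrow(pca$loadings) >= 2L) pca$loadings[2L, i]
        else NA_real_,
      p_value = p, p_maxt = p_maxt,
      role = if (dens[i] > 0) "numerator" else "denominator",
      assignment = if (length(near) > 0L)
        assignments$assignment[near[which.min(
          abs(assignments$wavenumber[near] - wn))]] else NA_character_,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
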