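#' Reference Raman band templates for microbial single cells
#'
#' Gaussian band templates at the packaged assignment-table wavenumbers
#' (phenylalanine 1,004; adenine/guanine 1,573-1,576; amide I 1,671; ...),
#' with widths typical for biological Raman bands (FWHM 10-16 1/cm) and
#' default amplitudes in arbitrary detector counts chosen to give a
#' realistic single-cell spectrum once a smooth fluorescence baseline and
#' shot noise are added. The `class` column drives the infection presets:
#' nucleic-acid bands rise and protein bands fall in phi6-like virocells,
#' and vice versa for phi29-like ones.
#'
#' @return data.frame `center` (1/cm), `fwhm` (1/cm), `base_amplitude`,
#'   `assignment`, `class`.
#' @export
reference_templates <- function() {
  data.frame(
    center = c(623, 645, 668, 724, 740, 785, 848, 960, 1004, 1035,
               1101, 1174, 1240, 1337, 1448, 1482, 1576, 1671),
    fwhm = c(10, 10, 12, 12, 10, 12, 12, 12, 10, 12,
             14, 12, 16, 14, 16, 14, 14, 16),
    base_amplitude = c(150, 120, 200, 220, 160, 450, 200, 180, 1000, 300,
                       250, 170, 350, 400, 450, 500, 900, 700),
    assignment = c("adenine", "cytosine, adenine", "guanine", "adenine",
                   "thymine", "cytosine/uracil", "ribose/O-P-O stretch",
                   "valine/leucine", "phenylalanine",
                   "proteins/phosphoenolpyruvate", "PO2-", "L-histidine",
                   "amide III", "adenine", "lipids CH2",
                   "guanine/adenine", "adenine, guanine",
                   "amide I"),
    class = c("nucleic_acid", "nucleic_acid", "nucleic_acid",
              "nucleic_acid", "nucleic_acid", "nucleic_acid",
              "nucleic_acid", "protein", "protein", "protein",
              "nucleic_acid", "protein", "protein", "nucleic_acid",
              "lipid", "nucleic_acid", "nucleic_acid", "protein"),
    stringsAsFactors = FALSE)
}

#' Scenario configuration for the synthetic population generator
#'
#' Presets mirror the study's population structure: the "infected" sample
#' is a mixture in which only `virocell_fraction` of cells are virocells;
#' the control contains none. `phi6_like` virocells gain nucleic-acid
#' signal and lose protein signal (1,576 x1.5; 1,003 and 1,671 x0.7), with
#' a late-stage sub-fraction additionally gaining lipid signal (1,448
#' x1.3); `phi29_like` inverts those fold-changes;
#' `archaeal_autofluorescence` adds a broad fluorescence hump far larger
#' than any Raman band, which inflates shot noise and degrades group
#' separability; `null` plants no effect.
#'
#' @param preset one of `"phi6_like"`, `"phi29_like"`,
#'   `"archaeal_autofluorescence"`, `"null"`.
#' @param n_control,n_infected_sample cell counts per sample.
#' @param virocell_fraction fraction of infected-sample cells that are
#'   virocells (default 0.45).
#' @param late_fraction fraction of virocells in the late (lipid-shifted)
#'   state (default 0.5).
#' @param effect named numeric vector of per-band multiplicative
#'   fold-changes for virocells, names = wavenumbers (matched to the
#'   nearest template center within 6 1/cm); `NULL` uses the preset
#'   default.
#' @param late_effect additional fold-changes applied only to late-state
#'   virocells.
#' @param baseline polynomial coefficients (intercept, linear, quadratic)
#'   of the smooth fluorescence baseline in `u = (wn - 600)/1200`.
#' @param hump_amplitude amplitude of a broad Gaussian fluorescence hump
#'   (center 1,300 1/cm, FWHM 700); the archaeal preset defaults to 8000,
#'   roughly an order of magnitude above the strongest Raman band.
#' @param noise_sd noise scale: additive Gaussian noise with
#'   `sd = noise_sd * sqrt(signal + 1)`, approximating shot noise.
#' @param cell_amplitude_cv lognormal coefficient of variation of
#'   cell-to-cell Raman brightness (default 0.15).
#' @param band_cv lognormal coefficient of variation of per-band,
#'   per-cell biological composition variation (default 0.015); this is
#'   the roughly symmetric cell-to-cell variability that makes control
#'   band ratios approximately normal, as observed for real uninfected
#'   cells. The default gives a control-group virocell-ratio cv of ~3%,
#'   close to the spread implied by a published 99% control bound of
#'   1.06 around a mean ratio of ~1 (cv ~2.6%).
#' @param spike_rate expected cosmic-ray spikes per cell (Poisson;
#'   default 0).
#' @param seed integer seed (mandatory).
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(preset = c("phi6_like", "phi29_like",
                                       "archaeal_autofluorescence",
                                       "null"),
                            n_control = 200L, n_infected_sample = 198L,
                            virocell_fraction = 0.45,
                            late_fraction = 0.5,
                            effect = NULL, late_effect = NULL,
                            baseline = c(420, -180, 90),
                            hump_amplitude = NULL,
                            noise_sd = 0.2,
                            cell_amplitude_cv = 0.15,
                            band_cv = 0.015,
                            spike_rate = 0,
                            seed) {
  preset <- match.arg(preset)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  phi6 <- c("1576" = 1.5, "1003" = 0.7, "1671" = 0.7)
  phi6_late <- c("1448" = 1.3)
  if (is.null(effect)) {
    effect <- switch(preset,
                     phi6_like = phi6,
                     archaeal_autofluorescence = phi6,
                     phi29_like = 1 / phi6,
                     null = c("1576" = 1))
  }
  if (is.null(late_effect)) {
    late_effect <- switch(preset,
                          phi6_like = phi6_late,
                          archaeal_autofluorescence = phi6_late,
                          phi29_like = 1 / phi6_late,
                          null = c("1448" = 1))
  }
  if (any(c(effect, late_effect) <= 0)) {
    stop("fold-changes must be > 0", call. = FALSE)
  }
  if (is.null(hump_amplitude)) {
    hump_amplitude <- if (preset == "archaeal_autofluorescence") 8000 else 0
  }
  if (virocell_fraction < 0 || virocell_fraction > 1) {
    stop("virocell_fraction must be in [0, 1]", call. = FALSE)
  }
  if (n_control < 0 || n_infected_sample < 0) {
    stop("cell counts must be >= 0", call. = FALSE)
  }
  structure(list(preset = preset, n_control = as.integer(n_control),
                 n_infected_sample = as.integer(n_infected_sample),
                 virocell_fraction = virocell_fraction,
                 late_fraction = late_fraction,
                 effect = effect, late_effect = late_effect,
                 baseline = baseline, hump_amplitude = hump_amplitude,
                 noise_sd = noise_sd,
                 cell_amplitude_cv = cell_amplitude_cv,
                 band_cv = band_cv,
                 spike_rate = spike_rate, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate a seeded synthetic single-cell Raman population
#'
#' Per cell: `spectrum = brightness * sum(Gaussian bands, virocell bands
#' scaled by their fold-changes) + polynomial baseline (+ fluorescence
#' hump) + Gaussian noise with sd proportional to sqrt(signal) (+
#' Poisson-thinned cosmic-ray spikes)`, clipped at 0. Fully reproducible
#' from the config seed. The control sample contains no virocells.
#'
#' @param config a [scenario_config()].
#' @param axis wavenumber grid (default 600:1800, step 1).
#' @return list: `set` (a [spectrum_set()], control cells first),
#'   `truth` (data.frame `cell_id`, `group`, `true_state` in
#'   ribocell/virocell_early/virocell_late; attribute `effect` records
#'   the planted fold-changes).
#' @export
generate_population <- function(config, axis = seq(600, 1800, by = 1)) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  tmpl <- reference_templates()
  n_pts <- length(axis)
  # band profile matrix: templates x wavenumbers
  P <- t(vapply(seq_len(nrow(tmpl)), function(i) {
    tmpl$base_amplitude[i] *
      exp(-4 * log(2) * (axis - tmpl$center[i])^2 / tmpl$fwhm[i]^2)
  }, numeric(n_pts)))

  fold_vector <- function(effects) {
    f <- rep(1, nrow(tmpl))
    for (nm in names(effects)) {
      wn <- as.numeric(nm)
      j <- which.min(abs(tmpl$center - wn))
      if (abs(tmpl$center[j] - wn) > 6) {
        stop("effect wavenumber ", nm,
             " matches no template band within 6 1/cm", call. = FALSE)
      }
      f[j] <- f[j] * effects[[nm]]
    }
    f
  }
  u <- (axis - 600) / 1200
  base <- config$baseline[1] + config$baseline[2] * u +
    config$baseline[3] * u^2
  if (config$hump_amplitude > 0) {
    base <- base + config$hump_amplitude *
      exp(-4 * log(2) * (axis - 1300)^2 / 700^2)
  }

  n_c <- config$n_control
  n_i <- config$n_infected_sample
  n_vc <- round(config$virocell_fraction * n_i)
  n_late <- round(config$late_fraction * n_vc)
  states <- c(rep("ribocell", n_c),
              rep("ribocell", n_i - n_vc),
              rep("virocell_early", n_vc - n_late),
              rep("virocell_late", n_late))
  group <- c(rep("control", n_c), rep("infected", n_i))
  n_tot <- n_c + n_i
  if (n_tot == 0L) stop("no cells requested", call. = FALSE)

  s <- config$cell_amplitude_cv
  brightness <- if (s > 0) {
    stats::rlnorm(n_tot, meanlog = -log(1 + s^2) / 2,
                  sdlog = sqrt(log(1 + s^2)))
  } else rep(1, n_tot)

  # per-cell, per-band biological composition jitter (lognormal, cv
  # band_cv); folds applied on top of the state-specific fold-changes
  state_folds <- rbind(
    ribocell = rep(1, nrow(tmpl)),
    virocell_early = fold_vector(config$effect),
    virocell_late = fold_vector(c(config$effect, config$late_effect)))
  b <- config$band_cv
  bio <- if (b > 0) {
    matrix(stats::rlnorm(n_tot * nrow(tmpl),
                         meanlog = -log(1 + b^2) / 2,
                         sdlog = sqrt(log(1 + b^2))),
           nrow = n_tot)
  } else matrix(1, n_tot, nrow(tmpl))
  signal <- brightness *
    ((state_folds[states, , drop = FALSE] * bio) %*% P)
  signal <- sweep(signal, 2L, base, "+")
  noise <- matrix(stats::rnorm(n_tot * n_pts,
                               sd = config$noise_sd *
                                 sqrt(pmax(signal, 0) + 1)),
                  nrow = n_tot)
  mat <- signal + noise
  if (config$spike_rate > 0) {
    n_spk <- stats::rpois(n_tot, config$spike_rate)
    for (i in which(n_spk > 0)) {
      pos <- sample.int(n_pts, n_spk[i])
      mat[i, pos] <- mat[i, pos] +
        stats::runif(n_spk[i], 5, 15) * max(signal[i, ])
    }
  }
  mat <- pmax(mat, 0)

  cell_id <- c(sprintf("ctrl_%04d", seq_len(n_c)),
               sprintf("inf_%04d", seq_len(n_i)))
  meta <- data.frame(cell_id = cell_id,
                     sample_id = paste(config$preset, group, sep = "_"),
                     group = group, stringsAsFactors = FALSE)
  truth <- data.frame(cell_id = cell_id, group = group,
                      true_state = states, stringsAsFactors = FALSE)
  attr(truth, "effect") <- config$effect
  attr(truth, "late_effect") <- config$late_effect
  list(set = spectrum_set(axis, mat, meta), truth = truth)
}
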