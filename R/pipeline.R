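#' Configuration for an end-to-end analysis run
#'
#' Input is either a simulation preset (see [scenario_config()]) or a
#' pair of spectra/metadata files. All stochastic stages draw their seeds
#' deterministically from the single top-level `seed` (generator uses
#' `seed`, MRPP uses `seed + 1`).
#'
#' @param preset simulation preset name, or `NULL` when reading files.
#' @param input_path,metadata_path spectra (wide format) and metadata
#'   files, used when `preset` is `NULL`.
#' @param scenario optional full [scenario_config()] overriding `preset`.
#' @param preprocess a [preprocess_config()].
#' @param metric distance metric for ordination/MRPP.
#' @param n_permutations MRPP permutations (default 999).
#' @param n_ortho OPLS orthogonal components.
#' @param markers a [marker_set()]; `NULL` selects markers from the data
#'   via [select_marker_wavenumbers()] (falling back to the published
#'   bands when selection is empty).
#' @param confidence_level cutoff confidence level (default 0.99).
#' @param control_group control group label.
#' @param outdir output directory (created if absent).
#' @param seed top-level integer seed (mandatory).
#' @return a list of class `run_config`.
#' @export
run_config <- function(preset = "phi6_like", input_path = NULL,
                       metadata_path = NULL, scenario = NULL,
                       preprocess = preprocess_config(),
                       metric = "euclidean", n_permutations = 999L,
                       n_ortho = 1L, markers = marker_set(),
                       confidence_level = 0.99,
                       control_group = "control", outdir, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (missing(outdir)) stop("outdir is required", call. = FALSE)
  structure(list(preset = preset, input_path = input_path,
                 metadata_path = metadata_path, scenario = scenario,
                 preprocess = preprocess, metric = metric,
                 n_permutations = as.integer(n_permutations),
                 n_ortho = as.integer(n_ortho), markers = markers,
                 confidence_level = confidence_level,
                 control_group = control_group, outdir = outdir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full virocell analysis and write all intermediate tables
#'
#' Executes read/simulate -> trim -> quality filter -> SNIP baseline
#' subtraction -> TIC normalization -> PCA + contrast profile + MRPP +
#' OPLS/VIP -> band ratios -> Shapiro + rank-sum tests -> cutoff
#' calibration on the control group -> per-cell classification (-> Dunn's
#' test when the metadata has more than two sample groups). Every number
#' in the returned report is also written as a CSV under `outdir`; two
#' runs with the same config produce byte-identical numeric tables.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results (`set`, `qc`,
#'   `pca`, `mrpp`, `contrast`, `opls`, `ratios`, `calibration`,
#'   `classification`, `dunn`, `paths`).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$outdir, name)
  log_lines <- c(sprintf("ramanvirocell %s",
                         as.character(utils::packageVersion(
                           "ramanvirocell"))),
                 sprintf("seed: %d", config$seed),
                 "config:",
                 utils::capture.output(utils::str(
                   config[setdiff(names(config), "scenario")])))

  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$scenario) || !is.null(config$preset)) {
      sc <- if (!is.null(config$scenario)) config$scenario else
        scenario_config(preset = config$preset, seed = config$seed)
      gen <- generate_population(sc)
      raw <- gen$set
      utils::write.csv(gen$truth, out("ground_truth.csv"),
                       row.names = FALSE)
    } else {
      raw <- read_spectra(config$input_path, format = "wide",
                          metadata_path = config$metadata_path)
    }

    stage <- "preprocess"
    pp <- preprocess(raw, config$preprocess)
    set <- pp$set
    utils::write.csv(pp$qc_report, out("qc_report.csv"),
                     row.names = FALSE)
    write_spectra(set, out("spectra_preprocessed.csv"), format = "wide")

    stage <- "chemometrics"
    pca <- spectra_pca(set, n_components = 2L)
    scores <- data.frame(cell_id = set$meta$cell_id,
                         group = set$meta$group, pca$scores)
    utils::write.csv(scores, out("pca_scores.csv"), row.names = FALSE)
    d <- distance_matrix(set, config$metric)
    groups <- set$meta$group
    glev <- unique(groups)
    mr <- mrpp(d, groups, n_permutations = config$n_permutations,
               seed = config$seed + 1L)
    utils::write.csv(data.frame(delta_observed = mr$delta_observed,
                                delta_expected = mr$delta_expected,
                                A = mr$A, p = mr$p_value,
                                n_permutations = mr$n_permutations,
                                seed = mr$seed),
                     out("mrpp.csv"), row.names = FALSE)
    infected_label <- setdiff(glev, config$control_group)[1L]
    ctr <- contrast_profile(set, infected_label, config$control_group)
    utils::write.csv(as.data.frame(ctr), out("contrast_profile.csv"),
                     row.names = FALSE)

    stage <- "opls"
    op <- fit_opls(set, n_ortho = config$n_ortho)
    utils::write.csv(vip_scores(op), out("vip_profile.csv"),
                     row.names = FALSE)

    stage <- "markers"
    markers <- config$markers
    selection <- NULL
    if (is.null(markers)) {
      selection <- select_marker_wavenumbers(ctr, pca, set)
      utils::write.csv(selection, out("marker_candidates.csv"),
                       row.names = FALSE)
      markers <- if (nrow(selection) >= 2L &&
                     any(selection$role == "numerator") &&
                     any(selection$role == "denominator")) {
        marker_set(
          numerator_wavenumbers =
            selection$wavenumber[selection$role == "numerator"][1L],
          denominator_wavenumbers =
            utils::head(
              selection$wavenumber[selection$role == "denominator"], 2L))
      } else marker_set()
    }

    stage <- "ratios"
    rt <- ratio_table(set, markers)
    utils::write.csv(as.data.frame(rt), out("ratio_table.csv"),
                     row.names = FALSE)
    is_ctrl <- rt$group == config$control_group
    wt <- rank_sum_test(rt$ratio[!is_ctrl], rt$ratio[is_ctrl])

    stage <- "calibration"
    cal <- calibrate_cutoff(rt$ratio[is_ctrl],
                            confidence_level = config$confidence_level,
                            infected_ratios = rt$ratio[!is_ctrl])
    cal_lines <- c(
      sprintf("control_mean: %.15g", cal$control_mean),
      sprintf("control_sd: %.15g", cal$control_sd),
      sprintf("confidence_level: %g", cal$confidence_level),
      sprintf("cutoff: %.15g", cal$cutoff),
      sprintf("degenerate: %s", cal$degenerate),
      sprintf("shapiro_control_W: %.6g", cal$shapiro_control$W),
      sprintf("shapiro_control_p: %.6g", cal$shapiro_control$p),
      if (!is.null(cal$shapiro_infected)) c(
        sprintf("shapiro_infected_W: %.6g", cal$shapiro_infected$W),
        sprintf("shapiro_infected_p: %.6g", cal$shapiro_infected$p)),
      sprintf("ranksum_U: %.15g", wt$U),
      sprintf("ranksum_p: %.6g", wt$p))
    writeLines(cal_lines, out("calibration.txt"))

    stage <- "classification"
    cls <- classify_virocells(rt, cal, config$control_group)
    utils::write.csv(cls$cells, out("classification.csv"),
                     row.names = FALSE)
    utils::write.csv(cls$summary, out("classification_summary.csv"),
                     row.names = FALSE)

    stage <- "dunn"
    dunn <- NULL
    if (length(unique(rt$group)) > 2L ||
        length(unique(set$meta$sample_id)) > 2L) {
      dunn <- dunn_test(rt$ratio, rt$group)
      utils::write.csv(dunn, out("dunn.csv"), row.names = FALSE)
    }

    list(set = set, qc = pp$qc_report, pca = pca, mrpp = mr,
         contrast = ctr, opls = op, markers = markers,
         marker_selection = selection, ratios = rt, calibration = cal,
         rank_sum = wt, classification = cls, dunn = dunn,
         paths = config$outdir)
  }, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  log_lines <- c(log_lines,
                 sprintf("mrpp_p: %.6g", result$mrpp$p_value),
                 sprintf("mrpp_A: %.6g", result$mrpp$A),
                 sprintf("significant_group_difference: %s",
                         result$mrpp$p_value <= 0.05),
                 sprintf("n_virocells: %d",
                         result$classification$n_virocells),
                 sprintf("virocell_fraction: %.6g",
                         result$classification$virocell_fraction))
  writeLines(log_lines, out("run_log.txt"))
  invisible(result)
}
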