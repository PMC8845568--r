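#!/usr/bin/env Rscript
# The headline computation: select marker wavenumbers on the phi6-like
# system, build the nucleic-acid/protein ratio per cell, calibrate the
# 99% control cutoff, classify virocells in every scenario, compare with
# the planted ground truth, and run Dunn's test across all
# scenario-by-infection groups. Writes results/classification/.

library(ramanvirocell)

pp_dir <- function(name) file.path("results", "preprocessed", name)
if (!dir.exists(pp_dir("phi6_like"))) {
  stop("run analysis/02_preprocess.R first")
}
outdir <- file.path("results", "classification")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

load_set <- function(name) {
  read_spectra(file.path(pp_dir(name), "spectra.csv"), format = "wide",
               metadata_path = file.path(pp_dir(name), "metadata.tsv"))
}

# -- marker selection on the reference (phi6-like) system ---------------
phi6 <- load_set("phi6_like")
sel <- select_marker_wavenumbers(
  contrast_profile(phi6, "infected", "control"),
  spectra_pca(phi6, 2), phi6)
write.csv(sel, file.path(outdir, "marker_candidates.csv"),
          row.names = FALSE)
cat("marker candidates (phi6-like system):\n")
print(sel[, c("wavenumber", "density", "p_value", "role", "assignment")])

markers <- marker_set()  # the published bands: (I_1576 * 2)/(I_1003 * I_1671)

# -- per-scenario ratios, cutoff, classification ------------------------
all_ratios <- NULL
for (name in basename(list.dirs("results/preprocessed",
                                recursive = FALSE))) {
  set <- load_set(name)
  rt <- ratio_table(set, markers)
  is_ctrl <- rt$group == "control"
  cal <- calibrate_cutoff(rt$ratio[is_ctrl], confidence_level = 0.99,
                          infected_ratios = rt$ratio[!is_ctrl])
  cls <- classify_virocells(rt, cal)
  wt <- rank_sum_test(rt$ratio[!is_ctrl], rt$ratio[is_ctrl])
  truth <- read.csv(file.path("results", "data", name,
                              "ground_truth.csv"))
  planted <- sum(truth$true_state != "ribocell")
  cat(sprintf(
    paste0("%-26s cutoff %8.2f | shapiro p (ctrl) %.3f | rank-sum p %8.2e |",
           " called %3d vs planted %3d virocells | false pos %d/%d\n"),
    name, cal$cutoff, cal$shapiro_control$p, wt$p, cls$n_virocells,
    planted, cls$n_false_positive, cls$n_control))
  write.csv(cls$cells, file.path(outdir, paste0(name, "_classification.csv")),
            row.names = FALSE)
  rt$scenario <- name
  all_ratios <- rbind(all_ratios, as.data.frame(rt))
}
write.csv(all_ratios, file.path(outdir, "ratio_table_all.csv"),
          row.names = FALSE)

# -- Dunn's test across scenario-by-infection groups --------------------
dg <- paste(all_ratios$scenario, all_ratios$group, sep = ":")
dunn <- dunn_test(all_ratios$ratio, dg, adjustment = "bh")
write.csv(dunn, file.path(outdir, "dunn.csv"), row.names = FALSE)
kw <- attr(dunn, "kruskal")
cat(sprintf("Kruskal-Wallis over %d groups: chi2 = %.1f, p = %.3g\n",
            length(unique(dg)), unname(kw$statistic), kw$p.value))
sig <- dunn[dunn$p_adjusted < 0.05, c("group_i", "group_j", "z",
                                      "p_adjusted")]
cat(sprintf("%d of %d pairwise contrasts significant after BH adjustment\n",
            nrow(sig), nrow(dunn)))
cat("wrote results/classification/\n")
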