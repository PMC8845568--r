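#!/usr/bin/env Rscript
# Multivariate comparison of infected vs control populations on the
# preprocessed spectra: PCA, MRPP significance (999 Monte Carlo
# permutations), contrast profiles, and OPLS-DA variable importance.
# Writes per-scenario tables under results/chemometrics/ and prints a
# short narrative.

library(ramanvirocell)

scenarios <- list.dirs("results/preprocessed", recursive = FALSE)
if (length(scenarios) == 0) stop("run analysis/02_preprocess.R first")

for (dir in scenarios) {
  name <- basename(dir)
  set <- read_spectra(file.path(dir, "spectra.csv"), format = "wide",
                      metadata_path = file.path(dir, "metadata.tsv"))
  outdir <- file.path("results", "chemometrics", name)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  pca <- spectra_pca(set, 2)
  write.csv(data.frame(cell_id = set$meta$cell_id,
                       group = set$meta$group, pca$scores),
            file.path(outdir, "pca_scores.csv"), row.names = FALSE)

  d <- distance_matrix(set, "euclidean")
  mr <- mrpp(d, cell_groups(set), n_permutations = 999, seed = 201)
  write.csv(data.frame(delta_observed = mr$delta_observed,
                       delta_expected = mr$delta_expected, A = mr$A,
                       p = mr$p_value,
                       n_permutations = mr$n_permutations,
                       seed = mr$seed),
            file.path(outdir, "mrpp.csv"), row.names = FALSE)

  ctr <- contrast_profile(set, "infected", "control")
  write.csv(as.data.frame(ctr), file.path(outdir, "contrast_profile.csv"),
            row.names = FALSE)

  op <- fit_opls(set, n_ortho = 1)
  write.csv(vip_scores(op), file.path(outdir, "vip_profile.csv"),
            row.names = FALSE)
  vp <- vip_peak_positions(op$vip, set$axis,
                           min_prominence = 0.3 * max(op$vip))

  cat(sprintf(
    "%-26s PC1 %4.1f%% PC2 %4.1f%% | MRPP A = %7.4f, p = %.3f | top VIP bands: %s\n",
    name, 100 * pca$explained_variance_ratio[1],
    100 * pca$explained_variance_ratio[2], mr$A, mr$p_value,
    paste(head(vp, 3), collapse = ", ")))
}
cat("wrote results/chemometrics/<scenario>/{pca_scores, mrpp, contrast_profile, vip_profile}.csv\n")
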