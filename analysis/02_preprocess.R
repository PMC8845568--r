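#!/usr/bin/env Rscript
# Read the simulated populations back from disk and run the fixed
# preprocessing chain: trim to 600-1800 1/cm -> quality filter (low
# intensity, cosmic rays, saturation) -> SNIP baseline subtraction ->
# TIC normalization. Writes preprocessed spectra and QC reports under
# results/preprocessed/.

library(ramanvirocell)

scenarios <- list.dirs("results/data", recursive = FALSE)
if (length(scenarios) == 0) stop("run analysis/01_simulate.R first")

for (dir in scenarios) {
  name <- basename(dir)
  raw <- read_spectra(file.path(dir, "spectra.csv"), format = "wide",
                      metadata_path = file.path(dir, "metadata.tsv"))
  pp <- preprocess(raw, preprocess_config())
  outdir <- file.path("results", "preprocessed", name)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_spectra(pp$set, file.path(outdir, "spectra.csv"), format = "wide",
                metadata_path = file.path(outdir, "metadata.tsv"))
  write.csv(pp$qc_report, file.path(outdir, "qc_report.csv"),
            row.names = FALSE)
  cat(sprintf("%-26s kept %d / %d cells (flagged: %s)\n", name,
              sum(pp$qc_report$kept), nrow(pp$qc_report),
              if (all(pp$qc_report$kept)) "none" else
                paste(pp$qc_report$cell_id[!pp$qc_report$kept],
                      collapse = ", ")))
}
cat("wrote results/preprocessed/<scenario>/{spectra.csv, metadata.tsv, qc_report.csv}\n")
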