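#!/usr/bin/env Rscript
# Generate the four synthetic study populations and write them as
# plain-text spectra + metadata + ground truth under results/data/.
#
#   phi6_like  — nucleic acids up, proteins down in virocells (45% of the
#                infected sample, 198 cells, as in the reference system)
#   phi29_like — the inverted system: proteins up, nucleic acids down
#   archaeal_autofluorescence — same planted effect drowned by a large
#                fluorescence background (the methanogen failure mode)
#   null       — no effect; used for calibration and type-I checks

library(ramanvirocell)

scenarios <- list(
  phi6_like = scenario_config("phi6_like", n_control = 200,
                              n_infected_sample = 198,
                              virocell_fraction = 0.45, seed = 101),
  phi29_like = scenario_config("phi29_like", n_control = 100,
                               n_infected_sample = 100, seed = 102),
  archaeal_autofluorescence =
    scenario_config("archaeal_autofluorescence", n_control = 60,
                    n_infected_sample = 60, seed = 103),
  null = scenario_config("null", n_control = 60, n_infected_sample = 60,
                         virocell_fraction = 0, seed = 104)
)

for (name in names(scenarios)) {
  dir <- file.path("results", "data", name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_population(scenarios[[name]])
  write_spectra(gen$set, file.path(dir, "spectra.csv"), format = "wide",
                metadata_path = file.path(dir, "metadata.tsv"))
  write.csv(gen$truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  n_vc <- sum(gen$truth$true_state != "ribocell")
  cat(sprintf("%-26s %3d control + %3d infected cells (%d virocells)\n",
              name, sum(gen$truth$group == "control"),
              sum(gen$truth$group == "infected"), n_vc))
}
cat("wrote results/data/<scenario>/{spectra.csv, metadata.tsv, ground_truth.csv}\n")
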