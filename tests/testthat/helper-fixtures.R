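# In-code fixtures shared across test files.

# Minimal spectrum_set from a cells x wavenumbers matrix.
make_set <- function(mat, axis = seq_len(ncol(mat)), groups = "g",
                     ids = NULL) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (length(groups) == 1L) groups <- rep(groups, n)
  if (is.null(ids)) ids <- sprintf("cell_%02d", seq_len(n))
  spectrum_set(axis, mat,
               data.frame(cell_id = ids, sample_id = rep("s", n),
                          group = groups, stringsAsFactors = FALSE))
}

# Small synthetic population, preprocessed, for pipeline-level tests.
small_population <- function(preset = "phi6_like", n = 30L, seed = 1L,
                             ...) {
  sc <- scenario_config(preset, n_control = n, n_infected_sample = n,
                        seed = seed, ...)
  gen <- generate_population(sc)
  pp <- preprocess(gen$set)
  list(set = pp$set, truth = gen$truth, qc = pp$qc_report, raw = gen$set)
}
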