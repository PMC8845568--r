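#' Preprocessing configuration
#'
#' Bundles the knobs for the fixed preprocessing order
#' trim -> quality filter -> SNIP baseline subtraction -> TIC
#' normalization.
#'
#' @param trim_low,trim_high analysis window in 1/cm (defaults 600, 1800).
#' @param snip_iterations SNIP clipping-window iterations; on a ~1 1/cm
#'   grid the default 100 removes fluorescence-scale structure while
#'   leaving Raman bands (FWHM 10-16 1/cm) intact.
#' @param snip_use_lls apply the log-log-sqrt compression before clipping.
#' @param qc_min_tic cells whose raw summed intensity (total ion current)
#'   falls below this are flagged `low_intensity`.
#' @param qc_spike_zscore robust (median/MAD) z-score above which a point
#'   is a cosmic-ray candidate.
#' @param qc_spike_max_width maximum width (grid points) of the contiguous
#'   run above half `qc_spike_zscore` for a candidate to count as a spike;
#'   genuine Raman bands are much wider.
#' @param qc_max_intensity optional saturation ceiling; any point at or
#'   above it flags the cell `saturated`.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(trim_low = 600, trim_high = 1800,
                              snip_iterations = 100L, snip_use_lls = FALSE,
                              qc_min_tic = 1e4, qc_spike_zscore = 8,
                              qc_spike_max_width = 3L,
                              qc_max_intensity = NULL) {
  if (trim_low >= trim_high) stop("trim_low must be < trim_high",
                                  call. = FALSE)
  if (snip_iterations < 1L) stop("snip_iterations must be >= 1",
                                 call. = FALSE)
  structure(list(trim_low = trim_low, trim_high = trim_high,
                 snip_iterations = as.integer(snip_iterations),
                 snip_use_lls = isTRUE(snip_use_lls),
                 qc_min_tic = qc_min_tic,
                 qc_spike_zscore = qc_spike_zscore,
                 qc_spike_max_width = as.integer(qc_spike_max_width),
                 qc_max_intensity = qc_max_intensity),
            class = "preprocess_config")
}

#' Trim spectra to a wavenumber window
#'
#' @param set a [spectrum_set()].
#' @param low,high closed window bounds in 1/cm.
#' @return a `spectrum_set` restricted to axis points `p` with
#'   `low <= p <= high`.
#' @export
trim <- function(set, low = 600, high = 1800) {
  stopifnot(inherits(set, "spectrum_set"))
  keep <- set$axis >= low & set$axis <= high
  if (sum(keep) == 0L) {
    stop(sprintf("trim window [%g, %g] contains no axis points", low, high),
         call. = FALSE)
  }
  if (sum(keep) < 2L) {
    # a one-point spectrum is useless downstream but the subset itself is
    # well defined; return it via the raw list to bypass the >=2 invariant
    out <- set
    out$axis <- set$axis[keep]
    out$intensities <- set$intensities[, keep, drop = FALSE]
    return(out)
  }
  spectrum_set(set$axis[keep], set$intensities[, keep, drop = FALSE],
               set$meta)
}

#' SNIP baseline estimate for a single spectrum
#'
#' Statistics-sensitive nonlinear iterative peak clipping: for clipping
#' half-window m = 1..iterations, each point is replaced by the minimum of
#' itself and the mean of its two neighbours at offset m; points whose
#' offset-m neighbours fall outside the spectrum are left unchanged.
#' Optionally the log-log-sqrt (LLS) compression
#' `v = ln(ln(sqrt(y + 1) + 1) + 1)` is applied first and inverted
#' afterwards. Without LLS the estimate never exceeds the input.
#'
#' @param intensities numeric vector of finite intensities.
#' @param iterations number of clipping passes, `1 <= iterations <=
#'   (length - 1) / 2`.
#' @param use_lls apply the LLS compression.
#' @return numeric baseline vector, same length as the input.
#' @export
snip_baseline <- function(intensities, iterations = 100L,
                          use_lls = FALSE) {
  y <- as.numeric(intensities)
  if (any(!is.finite(y))) stop("intensities must be finite", call. = FALSE)
  drop(snip_baseline_matrix(matrix(y, nrow = 1L), iterations, use_lls))
}

# Row-wise SNIP over a cells x wavenumbers matrix; vectorized across cells
# so the same clipping pass costs one pmin per iteration.
snip_baseline_matrix <- function(mat, iterations, use_lls = FALSE) {
  n <- ncol(mat)
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  if (iterations > (n - 1L) / 2) {
    stop(sprintf("iterations (%d) must be <= (length - 1)/2 = %g",
                 iterations, (n - 1L) / 2), call. = FALSE)
  }
  if (use_lls) mat <- log(log(sqrt(mat + 1) + 1) + 1)
  for (m in seq_len(iterations)) {
    idx <- (m + 1L):(n - m)
    mat[, idx] <- pmin(mat[, idx, drop = FALSE],
                       (mat[, idx - m, drop = FALSE] +
                        mat[, idx + m, drop = FALSE]) / 2)
  }
  if (use_lls) mat <- (exp(exp(mat) - 1) - 1)^2 - 1
  mat
}

#' Subtract the SNIP baseline from every cell
#'
#' Negatives produced by the subtraction are clipped to 0 so that TIC
#' normalization and the band-ratio statistics downstream operate on
#' non-negative intensities.
#'
#' @param set a trimmed [spectrum_set()].
#' @param config a [preprocess_config()].
#' @return the baseline-subtracted `spectrum_set`.
#' @export
subtract_baseline <- function(set, config = preprocess_config()) {
  stopifnot(inherits(set, "spectrum_set"))
  bl <- snip_baseline_matrix(set$intensities, config$snip_iterations,
                             config$snip_use_lls)
  out <- pmax(set$intensities - bl, 0)
  spectrum_set(set$axis, out, set$meta)
}

#' Total ion current normalization
#'
#' Divides each cell's intensities by their sum, so every cell integrates
#' to 1 and cell-to-cell brightness differences cancel.
#'
#' @param set a [spectrum_set()].
#' @return the normalized `spectrum_set`.
#' @export
tic_normalize <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  tic <- rowSums(set$intensities)
  bad <- which(tic <= 0)
  if (length(bad) > 0L) {
    stop("non-positive total ion current in cell(s): ",
         paste(set$meta$cell_id[bad], collapse = ", "), call. = FALSE)
  }
  spectrum_set(set$axis, set$intensities / tic, set$meta)
}

#' Quality filter: low-intensity, cosmic-ray and saturated spectra
#'
#' Operates on raw (pre-normalization) intensities. A cell is flagged
#' `low_intensity` when its total ion current falls below
#' `qc_min_tic`; `cosmic_ray` when some point's robust z-score (median/MAD
#' within the cell) exceeds `qc_spike_zscore` while sitting in a contiguous
#' run of points above half that z-score no wider than
#' `qc_spike_max_width` (genuine Raman bands form much wider runs);
#' `saturated` when any intensity reaches `qc_max_intensity`.
#'
#' @param set a [spectrum_set()].
#' @param config a [preprocess_config()].
#' @return list with `set` (kept cells, input order) and `report`
#'   (data.frame `cell_id`, `kept`, `reasons`; reasons semicolon-joined).
#' @export
quality_filter <- function(set, config = preprocess_config()) {
  stopifnot(inherits(set, "spectrum_set"))
  n <- n_cells(set)
  reasons <- character(n)
  zthr <- config$qc_spike_zscore
  for (i in seq_len(n)) {
    y <- set$intensities[i, ]
    flags <- character(0)
    if (sum(y) < config$qc_min_tic) flags <- c(flags, "low_intensity")
    med <- stats::median(y)
    scale <- stats::mad(y)
    if (scale <= 0) scale <- max(stats::sd(y), .Machine$double.eps)
    z <- (y - med) / scale
    if (any(z > zthr)) {
      runs <- rle(z > zthr / 2)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (r in which(runs$values)) {
        seg <- starts[r]:ends[r]
        if (any(z[seg] > zthr) &&
            runs$lengths[r] <= config$qc_spike_max_width) {
          flags <- c(flags, "cosmic_ray")
          break
        }
      }
    }
    if (!is.null(config$qc_max_intensity) &&
        any(y >= config$qc_max_intensity)) {
      flags <- c(flags, "saturated")
    }
    reasons[i] <- paste(flags, collapse = ";")
  }
  kept <- reasons == ""
  report <- data.frame(cell_id = set$meta$cell_id, kept = kept,
                       reasons = reasons, stringsAsFactors = FALSE)
  out <- if (any(kept)) subset_cells(set, which(kept)) else NULL
  list(set = out, report = report)
}

#' Full preprocessing: trim, QC, SNIP subtraction, TIC normalization
#'
#' @param set a raw [spectrum_set()].
#' @param config a [preprocess_config()].
#' @return list with `set` (preprocessed kept cells) and `qc_report`.
#' @export
preprocess <- function(set, config = preprocess_config()) {
  trimmed <- trim(set, config$trim_low, config$trim_high)
  qc <- quality_filter(trimmed, config)
  if (is.null(qc$set)) {
    stop("quality filter removed every cell", call. = FALSE)
  }
  out <- tic_normalize(subtract_baseline(qc$set, config))
  list(set = out, qc_report = qc$report)
}
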