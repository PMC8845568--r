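#' Construct a set of single-cell Raman spectra on a shared wavenumber axis
#'
#' A `spectrum_set` is the pipeline's universal currency: a shared,
#' strictly increasing wavenumber axis (1/cm), one intensity row per cell,
#' and per-cell metadata (`cell_id`, `sample_id`, `group`).
#'
#' @param axis numeric vector of wavenumbers (1/cm), strictly increasing,
#'   length >= 2, all finite.
#' @param intensities numeric matrix, one row per cell, `length(axis)`
#'   columns, all finite.
#' @param meta data.frame with columns `cell_id`, `sample_id`, `group`;
#'   one row per cell, `cell_id` unique and matching the row order of
#'   `intensities`.
#' @return An object of class `spectrum_set` with elements `axis`,
#'   `intensities` (rownames = cell ids) and `meta`.
#' @export
spectrum_set <- function(axis, intensities, meta) {
  axis <- as.numeric(axis)
  if (length(axis) < 2L) {
    stop("axis must contain at least 2 wavenumbers", call. = FALSE)
  }
  if (any(!is.finite(axis))) {
    stop("axis contains non-finite wavenumbers", call. = FALSE)
  }
  if (any(diff(axis) <= 0)) {
    stop("axis must be strictly increasing", call. = FALSE)
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (ncol(intensities) != length(axis)) {
    stop(sprintf("intensity matrix has %d columns but axis has %d points",
                 ncol(intensities), length(axis)), call. = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("cell_id", "sample_id", "group")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  meta <- meta[, required, drop = FALSE]
  meta$cell_id <- as.character(meta$cell_id)
  meta$sample_id <- as.character(meta$sample_id)
  meta$group <- as.character(meta$group)
  if (nrow(meta) != nrow(intensities)) {
    stop(sprintf("metadata has %d rows but intensity matrix has %d cells",
                 nrow(meta), nrow(intensities)), call. = FALSE)
  }
  dup <- meta$cell_id[duplicated(meta$cell_id)]
  if (length(dup) > 0L) {
    stop("duplicate cell_id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!apply(is.finite(intensities), 1L, all))
  if (length(bad) > 0L) {
    stop("non-finite intensities in cell(s): ",
         paste(meta$cell_id[bad], collapse = ", "), call. = FALSE)
  }
  if (anyNA(meta$group) || any(meta$group == "")) {
    stop("every cell must carry exactly one non-empty group label",
         call. = FALSE)
  }
  rownames(intensities) <- meta$cell_id
  rownames(meta) <- NULL
  structure(list(axis = axis, intensities = intensities, meta = meta),
            class = "spectrum_set")
}

#' Number of cells in a spectrum set
#' @param set a `spectrum_set`.
#' @return integer cell count.
#' @export
n_cells <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  nrow(set$intensities)
}

#' Subset cells of a spectrum set, preserving order
#' @param set a `spectrum_set`.
#' @param idx integer, logical or character (cell id) index.
#' @return a `spectrum_set` with the selected cells.
#' @export
subset_cells <- function(set, idx) {
  stopifnot(inherits(set, "spectrum_set"))
  if (is.character(idx)) idx <- match(idx, set$meta$cell_id)
  spectrum_set(set$axis,
               set$intensities[idx, , drop = FALSE],
               set$meta[idx, , drop = FALSE])
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d cells x %d wavenumbers [%g, %g] 1/cm\n",
              nrow(x$intensities), length(x$axis),
              min(x$axis), max(x$axis)))
  tab <- table(x$meta$group)
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-cell group labels
#' @param set a `spectrum_set`.
#' @return character vector of group labels, one per cell.
#' @export
cell_groups <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  set$meta$group
}
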