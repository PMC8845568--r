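#' Read single-cell Raman spectra from a plain-text table
#'
#' Two interchange layouts are supported. Wide: header
#' `wavenumber,<cell_1>,<cell_2>,...`, one row per wavenumber. Long: header
#' `cell_id,wavenumber,intensity`. The delimiter is auto-detected between
#' comma and tab. In long format every cell must be sampled on the same
#' grid as the first cell (within `axis_tol` 1/cm); matching grids are
#' snapped to the first cell's axis, anything further off is an error —
#' no interpolation is ever performed.
#'
#' @param path path to the spectra table.
#' @param format `"wide"` or `"long"`.
#' @param metadata_path optional path to a tab- or comma-separated table
#'   with columns `cell_id`, `sample_id`, `group`. When absent, cells get
#'   `sample_id = "sample"` and `group = "unassigned"`.
#' @param axis_tol maximum per-point wavenumber deviation (1/cm) tolerated
#'   between cells before the file is rejected. Default 0.01.
#' @return a [spectrum_set()].
#' @export
read_spectra <- function(path, format = c("wide", "long"),
                         metadata_path = NULL, axis_tol = 0.01) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_delimiter(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (format == "wide") {
    if (ncol(tab) < 2L || tolower(names(tab)[1L]) != "wavenumber") {
      stop("wide format requires a leading 'wavenumber' column plus ",
           "one column per cell", call. = FALSE)
    }
    axis <- as.numeric(tab[[1L]])
    cells <- names(tab)[-1L]
    mat <- t(as.matrix(tab[, -1L, drop = FALSE]))
    storage.mode(mat) <- "double"
    nan_rows <- which(apply(mat, 1L, anyNA))
    if (length(nan_rows) > 0L) {
      stop("missing/NaN intensities in cell(s): ",
           paste(cells[nan_rows], collapse = ", "), call. = FALSE)
    }
  } else {
    need <- c("cell_id", "wavenumber", "intensity")
    if (!all(need %in% names(tab))) {
      stop("long format requires columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    tab$cell_id <- as.character(tab$cell_id)
    cells <- unique(tab$cell_id)
    per_cell <- split(tab, factor(tab$cell_id, levels = cells))
    axis <- as.numeric(per_cell[[1L]]$wavenumber)
    mat <- matrix(NA_real_, nrow = length(cells), ncol = length(axis))
    for (i in seq_along(cells)) {
      block <- per_cell[[i]]
      wn <- as.numeric(block$wavenumber)
      if (anyDuplicated(wn)) {
        stop("duplicated wavenumber row(s) for cell ", cells[i],
             call. = FALSE)
      }
      o <- order(wn)
      wn <- wn[o]
      if (length(wn) != length(axis) || max(abs(wn - axis)) > axis_tol) {
        stop("cell ", cells[i], " is sampled on a different wavenumber ",
             "grid than cell ", cells[1L],
             " (tolerance ", axis_tol, " 1/cm)", call. = FALSE)
      }
      mat[i, ] <- as.numeric(block$intensity)[o]
    }
    if (anyNA(mat)) {
      bad <- cells[which(apply(mat, 1L, anyNA))]
      stop("missing/NaN intensities in cell(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (anyNA(axis)) stop("non-numeric wavenumber values", call. = FALSE)
  if (any(diff(axis) <= 0)) {
    stop("wavenumber axis is not strictly increasing", call. = FALSE)
  }
  meta <- if (is.null(metadata_path)) {
    data.frame(cell_id = cells, sample_id = "sample",
               group = "unassigned", stringsAsFactors = FALSE)
  } else {
    read_cell_metadata(metadata_path, cells)
  }
  spectrum_set(axis, mat, meta)
}

read_cell_metadata <- function(path, cells) {
  if (!file.exists(path)) stop("metadata file not found: ", path,
                               call. = FALSE)
  sep <- detect_delimiter(path)
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  need <- c("cell_id", "sample_id", "group")
  if (!all(need %in% names(meta))) {
    stop("metadata requires columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  meta$cell_id <- as.character(meta$cell_id)
  hit <- match(cells, meta$cell_id)
  if (anyNA(hit)) {
    stop("metadata is missing cell(s): ",
         paste(cells[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  meta[hit, need, drop = FALSE]
}

#' Write a spectrum set to a plain-text table
#'
#' Serializes with 15 significant digits so that
#' `read_spectra(write_spectra(x))` round-trips exactly at double
#' precision for all practical intensities.
#'
#' @param set a [spectrum_set()].
#' @param path output file path; delimiter follows the extension
#'   (`.tsv` tab, otherwise comma).
#' @param format `"wide"` or `"long"`.
#' @param metadata_path optional path; when given, the per-cell metadata
#'   is written there as a tab-separated table.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path, format = c("wide", "long"),
                          metadata_path = NULL) {
  stopifnot(inherits(set, "spectrum_set"))
  format <- match.arg(format)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  if (format == "wide") {
    out <- data.frame(wavenumber = fmt(set$axis), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(set$intensities))) {
      out[[set$meta$cell_id[i]]] <- fmt(set$intensities[i, ])
    }
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  } else {
    n <- length(set$axis)
    out <- data.frame(
      cell_id = rep(set$meta$cell_id, each = n),
      wavenumber = fmt(rep(set$axis, times = nrow(set$intensities))),
      intensity = fmt(as.vector(t(set$intensities))),
      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(metadata_path)) {
    utils::write.table(set$meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com && n_tab > 0L) "\t" else ","
}

#' Raman band assignments and contrast-plot densities
#'
#' The packaged lookup table of marker wavenumbers, their biomolecule
#' assignments, and the contrast-plot densities observed for the two
#' bacterial model systems (positive = more prominent in infected cells,
#' negative = more prominent in the control).
#'
#' @return data.frame with columns `wavenumber` (1/cm), `density_psyringae`,
#'   `density_bsubtilis`, `assignment`.
#' @export
band_assignments <- function() {
  path <- system.file("extdata", "band_assignments.tsv",
                      package = "ramanvirocell", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}
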