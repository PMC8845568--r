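#' Principal component analysis of a spectrum set
#'
#' Column-mean-centered singular value decomposition. Component signs are
#' fixed so that each loading vector's largest-magnitude element is
#' positive, making scores and loading profiles reproducible across runs.
#'
#' @param set a preprocessed [spectrum_set()] with >= 2 cells.
#' @param n_components number of components to keep,
#'   `<= min(n cells, n wavenumbers)`.
#' @return object of class `spectra_pca`: `scores` (cells x components),
#'   `loadings` (components x wavenumbers, orthonormal rows),
#'   `explained_variance_ratio`, `center`, `axis`.
#' @export
spectra_pca <- function(set, n_components = 2L) {
  stopifnot(inherits(set, "spectrum_set"))
  X <- set$intensities
  if (nrow(X) < 2L) stop("PCA needs at least 2 cells", call. = FALSE)
  k <- as.integer(n_components)
  if (k < 1L || k > min(dim(X))) {
    stop(sprintf("n_components must be in [1, %d]", min(dim(X))),
         call. = FALSE)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = k, nv = k)
  loadings <- t(sv$v)
  for (r in seq_len(k)) {
    j <- which.max(abs(loadings[r, ]))
    if (loadings[r, j] < 0) loadings[r, ] <- -loadings[r, ]
  }
  scores <- Xc %*% t(loadings)
  rownames(scores) <- set$meta$cell_id
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(loadings) <- paste0("PC", seq_len(k))
  evr <- sv$d[seq_len(k)]^2 / sum(svd(Xc, nu = 0, nv = 0)$d^2)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = evr, center = mu,
                 axis = set$axis, groups = set$meta$group),
            class = "spectra_pca")
}

#' Loading profile of one principal component
#'
#' @param pca a [spectra_pca()] result.
#' @param component 1-based component index.
#' @return data.frame `wavenumber`, `loading`.
#' @export
pc_loading_profile <- function(pca, component = 1L) {
  stopifnot(inherits(pca, "spectra_pca"))
  if (component < 1L || component > nrow(pca$loadings)) {
    stop("component out of range", call. = FALSE)
  }
  data.frame(wavenumber = pca$axis, loading = pca$loadings[component, ])
}

#' Spectral contrast angle between two spectra
#'
#' `acos(<x, y> / (|x| |y|))`, clamped into `[0, pi]`; a scale-invariant
#' dissimilarity (0 for proportional spectra, pi/2 for orthogonal ones).
#'
#' @param x,y numeric vectors of equal length with positive norm.
#' @return angle in radians.
#' @export
spectral_contrast_angle <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm spectrum", call. = FALSE)
  acos(min(1, max(-1, sum(x * y) / (nx * ny))))
}

#' Pairwise distance matrix over cells
#'
#' @param set a preprocessed [spectrum_set()].
#' @param metric `"euclidean"` (L2 on intensity vectors) or
#'   `"contrast_angle"` (see [spectral_contrast_angle()]).
#' @return object of class `distance_matrix`: `labels`, symmetric `values`
#'   with zero diagonal, `metric`.
#' @export
distance_matrix <- function(set, metric = c("euclidean",
                                            "contrast_angle")) {
  stopifnot(inherits(set, "spectrum_set"))
  metric <- match.arg(metric)
  X <- set$intensities
  if (metric == "euclidean") {
    D <- as.matrix(stats::dist(X))
  } else {
    nrm <- sqrt(rowSums(X^2))
    bad <- which(nrm == 0)
    if (length(bad) > 0L) {
      stop("zero-norm spectrum in cell(s): ",
           paste(set$meta$cell_id[bad], collapse = ", "), call. = FALSE)
    }
    G <- tcrossprod(X / nrm)
    G <- pmax(pmin(G, 1), -1)
    D <- acos(G)
    D <- (D + t(D)) / 2
  }
  diag(D) <- 0
  dimnames(D) <- list(set$meta$cell_id, set$meta$cell_id)
  structure(list(labels = set$meta$cell_id, values = D, metric = metric),
            class = "distance_matrix")
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' @param d a [distance_matrix()].
#' @param n_components number of coordinates requested; capped at the
#'   number of positive eigenvalues.
#' @return list: `coordinates` (cells x kept components), `eigenvalues`
#'   (all), `labels`.
#' @export
spectra_pcoa <- function(d, n_components = 2L) {
  stopifnot(inherits(d, "distance_matrix"))
  n <- nrow(d$values)
  k <- min(as.integer(n_components), n - 1L)
  cs <- stats::cmdscale(stats::as.dist(d$values), k = k, eig = TRUE)
  eig <- cs$eig
  if (all(eig <= 1e-12 * max(abs(eig), 1))) {
    stop("no positive eigenvalues: distances carry no metric structure",
         call. = FALSE)
  }
  coords <- as.matrix(cs$points)
  rownames(coords) <- d$labels
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig, labels = d$labels)
}

#' Ward D2 hierarchical clustering of a Euclidean distance matrix
#'
#' @param d a [distance_matrix()] with `metric = "euclidean"`.
#' @return an [stats::hclust] tree (method `ward.D2`).
#' @export
ward_dendrogram <- function(d) {
  stopifnot(inherits(d, "distance_matrix"))
  if (d$metric != "euclidean") {
    stop("Ward D2 clustering requires the euclidean metric", call. = FALSE)
  }
  if (nrow(d$values) < 2L) stop("need at least 2 cells", call. = FALSE)
  stats::hclust(stats::as.dist(d$values), method = "ward.D2")
}

#' Mean spectrum of one group
#'
#' @param set a [spectrum_set()].
#' @param group a group label present in the metadata.
#' @return numeric vector: per-wavenumber arithmetic mean over the group.
#' @export
class_mean_spectrum <- function(set, group) {
  stopifnot(inherits(set, "spectrum_set"))
  idx <- which(set$meta$group == group)
  if (length(idx) == 0L) stop("unknown or empty group: ", group,
                              call. = FALSE)
  colMeans(set$intensities[idx, , drop = FALSE])
}

#' Contrast profile between two groups
#'
#' Per-wavenumber difference of TIC-normalized class mean spectra
#' (`group_a` minus `group_b`). With `group_a` the infected sample,
#' positive density marks bands more prominent in infected cells and
#' negative density bands more prominent in the control.
#'
#' @param set a TIC-normalized [spectrum_set()].
#' @param group_a,group_b group labels (conventionally infected, control).
#' @return object of class `contrast_profile`: data.frame `wavenumber`,
#'   `density`.
#' @export
contrast_profile <- function(set, group_a, group_b) {
  density <- class_mean_spectrum(set, group_a) -
    class_mean_spectrum(set, group_b)
  structure(data.frame(wavenumber = set$axis, density = density,
                       row.names = NULL),
            class = c("contrast_profile", "data.frame"))
}

#' Multiresponse permutation procedure (MRPP)
#'
#' Tests whether within-group distances are smaller than expected under
#' random labelling. The observed statistic is
#' `delta = sum_g w_g * (mean pairwise distance within group g)`; the
#' expectation is the mean of `delta` over label permutations; the
#' chance-corrected within-group agreement is
#' `A = 1 - delta_observed / delta_expected`. The permutation p-value uses
#' the add-one estimator, so it is never 0 and never below
#' `1 / (n_permutations + 1)`.
#'
#' @param d a [distance_matrix()].
#' @param groups per-cell labels, >= 2 groups of size >= 2.
#' @param n_permutations Monte Carlo label shuffles (default 999).
#' @param seed integer seed; mandatory for reproducibility.
#' @param weight group weights: `"group_size"` (`n_g / N`, default) or
#'   `"group_size_minus_one"` (`(n_g - 1) / (N - K)`).
#' @return object of class `mrpp_result`: `delta_observed`,
#'   `delta_expected`, `A`, `p_value`, `n_permutations`, `seed`.
#' @export
mrpp <- function(d, groups, n_permutations = 999L, seed,
                 weight = c("group_size", "group_size_minus_one")) {
  stopifnot(inherits(d, "distance_matrix"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  weight <- match.arg(weight)
  groups <- as.character(groups)
  if (length(groups) != nrow(d$values)) {
    stop("groups length must match the distance matrix", call. = FALSE)
  }
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("every group needs >= 2 cells; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  D <- d$values
  N <- length(groups)
  lev <- names(sizes)
  w <- switch(weight,
              group_size = as.numeric(sizes) / N,
              group_size_minus_one =
                (as.numeric(sizes) - 1) / (N - length(sizes)))
  delta_of <- function(lab) {
    s <- 0
    for (g in seq_along(lev)) {
      idx <- which(lab == lev[g])
      ng <- length(idx)
      s <- s + w[g] * sum(D[idx, idx]) / (ng * (ng - 1))
    }
    s
  }
  delta_obs <- delta_of(groups)
  set.seed(seed)
  perm <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    perm[b] <- delta_of(sample(groups))
  }
  delta_exp <- mean(perm)
  structure(list(delta_observed = delta_obs,
                 delta_expected = delta_exp,
                 A = 1 - delta_obs / delta_exp,
                 p_value = (sum(perm <= delta_obs) + 1) /
                   (n_permutations + 1),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "mrpp_result")
}

#' @export
print.mrpp_result <- function(x, ...) {
  cat(sprintf(
    "MRPP: delta = %.6g (expected %.6g), A = %.4g, p = %.4g (%d perms)\n",
    x$delta_observed, x$delta_expected, x$A, x$p_value, x$n_permutations))
  invisible(x)
}
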