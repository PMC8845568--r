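#' Orthogonal projections to latent structures (O-PLS) discriminant model
#'
#' Two-class O-PLS after Trygg and Wold: response-orthogonal X-variation
#' is extracted and removed component by component, then a single
#' predictive PLS component is fitted on the deflated matrix. With
#' `n_ortho = 0` the predictive component coincides with the first
#' component of NIPALS PLS1. The class labels are encoded 0/1 in
#' alphabetical order and centered.
#'
#' @param set a preprocessed [spectrum_set()].
#' @param groups optional per-cell two-class labels; defaults to the
#'   set's metadata groups.
#' @param n_ortho number of orthogonal components (default 1).
#' @return object of class `opls_model`: `predictive_weights`,
#'   `predictive_loadings`, `predictive_scores`, `q` (y-loading),
#'   `orthogonal_weights`/`orthogonal_loadings`/`orthogonal_scores`
#'   (p x k / p x k / n x k matrices), `vip` (per wavenumber), `axis`,
#'   `y_encoding`, `n_ortho`.
#' @export
fit_opls <- function(set, groups = NULL, n_ortho = 1L) {
  stopifnot(inherits(set, "spectrum_set"))
  if (is.null(groups)) groups <- set$meta$group
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly 2 classes required", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("each class needs >= 2 cells", call. = FALSE)
  }
  X <- set$intensities
  dimnames(X) <- NULL
  n <- nrow(X); p <- ncol(X)
  n_ortho <- as.integer(n_ortho)
  if (n_ortho < 0L) stop("n_ortho must be >= 0", call. = FALSE)
  y <- as.numeric(groups == lev[2L])
  y <- y - mean(y)
  X <- sweep(X, 2L, colMeans(X))

  normalize <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < .Machine$double.eps) {
      stop("degenerate weight vector: n_ortho >= rank of X", call. = FALSE)
    }
    v / nv
  }

  W_o <- matrix(0, p, n_ortho); P_o <- matrix(0, p, n_ortho)
  T_o <- matrix(0, n, n_ortho)
  w <- normalize(drop(crossprod(X, y)))
  if (n_ortho > 0L) {
    for (k in seq_len(n_ortho)) {
      t_pred <- drop(X %*% w)
      p_load <- drop(crossprod(X, t_pred)) / sum(t_pred^2)
      w_o <- p_load - sum(w * p_load) * w
      w_o <- normalize(w_o)
      t_o <- drop(X %*% w_o)
      p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
      X <- X - tcrossprod(t_o, p_o)
      W_o[, k] <- w_o; P_o[, k] <- p_o; T_o[, k] <- t_o
      # X'y is invariant under orthogonal deflation in exact arithmetic;
      # recompute for numerical hygiene
      w <- normalize(drop(crossprod(X, y)))
    }
  }
  t_pred <- drop(X %*% w)
  p_pred <- drop(crossprod(X, t_pred)) / sum(t_pred^2)
  q <- sum(y * t_pred) / sum(t_pred^2)

  ssy <- q^2 * sum(t_pred^2)
  vip <- sqrt(p * w^2 * ssy / ssy)

  structure(list(predictive_weights = w,
                 predictive_loadings = p_pred,
                 predictive_scores = t_pred,
                 q = q,
                 orthogonal_weights = W_o,
                 orthogonal_loadings = P_o,
                 orthogonal_scores = T_o,
                 vip = vip,
                 axis = set$axis,
                 y_encoding = stats::setNames(c(0, 1), lev),
                 n_ortho = n_ortho),
            class = "opls_model")
}

#' Variable importance on projection (VIP)
#'
#' For predictive components a = 1..A with weights `w_ja` and explained
#' response sums of squares `SSY_a`:
#' `VIP_j = sqrt(p * sum_a(w_ja^2 SSY_a) / sum_a(SSY_a))`, so that the
#' mean of `VIP^2` over the `p` wavenumbers is exactly 1. This model has a
#' single predictive component, hence `VIP_j = sqrt(p) * |w_j|`.
#'
#' @param model a fitted [fit_opls()] model.
#' @return data.frame `wavenumber`, `vip`.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  data.frame(wavenumber = model$axis, vip = model$vip)
}

#' Peak maxima of a VIP (or any non-negative) profile
#'
#' Local maxima with topographic prominence at least `min_prominence`,
#' returned in descending profile-height order. The prominence of a peak
#' is its height minus the higher of the lowest points separating it from
#' higher terrain on either side (edges count as drops to the profile
#' minimum).
#'
#' @param vip numeric profile values on the trimmed axis.
#' @param axis matching wavenumbers; defaults to indices.
#' @param min_prominence minimum prominence to report.
#' @return numeric vector of wavenumbers (possibly empty).
#' @export
vip_peak_positions <- function(vip, axis = seq_along(vip),
                               min_prominence = 0) {
  pk <- find_peaks(vip, min_prominence)
  if (nrow(pk) == 0L) return(numeric(0))
  axis[pk$index[order(pk$height, decreasing = TRUE)]]
}

# Local maxima + topographic prominence of a numeric profile.
# Returns data.frame(index, height, prominence) of peaks passing
# min_prominence. Plateau maxima report their first index.
find_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3L) return(data.frame(index = integer(0), height = numeric(0),
                                prominence = numeric(0)))
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j < n && y[j + 1L] < y[j]) peaks <- c(peaks, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(peaks) == 0L) {
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  prom <- vapply(peaks, function(pidx) {
    h <- y[pidx]
    left_min <- h
    k <- pidx
    while (k > 1L) {
      k <- k - 1L
      if (y[k] > h) break
      left_min <- min(left_min, y[k])
      if (k == 1L) break
    }
    if (y[k] <= h) left_min <- min(left_min, min(y[1L:pidx]))
    right_min <- h
    k <- pidx
    while (k < n) {
      k <- k + 1L
      if (y[k] > h) break
      right_min <- min(right_min, y[k])
      if (k == n) break
    }
    if (y[k] <= h) right_min <- min(right_min, min(y[pidx:n]))
    h - max(left_min, right_min)
  }, numeric(1))
  keep <- prom >= min_prominence & prom > 0
  data.frame(index = peaks[keep], height = y[peaks[keep]],
             prominence = prom[keep])
}
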