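# Independent reference implementations used as oracles. Deliberately
# literal and loop-based; they share no code with the package internals.

# SNIP recurrence, transcribed point by point.
oracle_snip <- function(y, iterations, use_lls = FALSE) {
  n <- length(y)
  v <- y
  if (use_lls) {
    for (i in seq_len(n)) v[i] <- log(log(sqrt(v[i] + 1) + 1) + 1)
  }
  for (m in seq_len(iterations)) {
    w <- v
    for (i in seq_len(n)) {
      if (i - m >= 1 && i + m <= n) {
        a <- (v[i - m] + v[i + m]) / 2
        if (a < v[i]) w[i] <- a
      }
    }
    v <- w
  }
  if (use_lls) {
    for (i in seq_len(n)) v[i] <- (exp(exp(v[i]) - 1) - 1)^2 - 1
  }
  v
}

# First component of NIPALS PLS1 on column-centered X and centered y.
oracle_nipals_pls1_scores <- function(X, y) {
  X <- sweep(X, 2, colMeans(X))
  y <- y - mean(y)
  w <- drop(t(X) %*% y)
  w <- w / sqrt(sum(w^2))
  drop(X %*% w)
}

# VIP formula transcription for a one-predictive-component model.
oracle_vip <- function(weights, ssy) {
  p <- length(weights)
  out <- numeric(p)
  for (j in seq_len(p)) {
    out[j] <- sqrt(p * weights[j]^2 * ssy / ssy)
  }
  out
}

# MRPP delta for one labelling, group-size weights.
oracle_mrpp_delta <- function(D, labels) {
  lev <- unique(labels)
  N <- length(labels)
  delta <- 0
  for (g in lev) {
    idx <- which(labels == g)
    s <- 0
    np <- 0
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a < b) {
          s <- s + D[idx[a], idx[b]]
          np <- np + 1
        }
      }
    }
    delta <- delta + (length(idx) / N) * s / np
  }
  delta
}

# Exhaustive-permutation MRPP p-value for two groups.
oracle_mrpp_exhaustive_p <- function(D, labels) {
  lev <- unique(labels)
  stopifnot(length(lev) == 2)
  n <- length(labels)
  n1 <- sum(labels == lev[1])
  obs <- oracle_mrpp_delta(D, labels)
  sets <- utils::combn(n, n1)
  deltas <- apply(sets, 2, function(idx) {
    lab <- rep(lev[2], n)
    lab[idx] <- lev[1]
    oracle_mrpp_delta(D, lab)
  })
  mean(deltas <= obs + 1e-12)
}

# Brute-force Ward D2 agglomeration via the Lance-Williams update;
# returns merge heights in merge order.
oracle_ward_heights <- function(D) {
  n <- nrow(D)
  Dc <- D
  sizes <- rep(1, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(sizes)
    best <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (Dc[i, j] < best) { best <- Dc[i, j]; bi <- i; bj <- j }
      }
    }
    heights[step] <- best
    keep <- setdiff(seq_len(m), c(bi, bj))
    newd <- numeric(length(keep))
    for (kk in seq_along(keep)) {
      k <- keep[kk]
      ni <- sizes[bi]; nj <- sizes[bj]; nk <- sizes[k]
      newd[kk] <- sqrt(((ni + nk) * Dc[bi, k]^2 +
                        (nj + nk) * Dc[bj, k]^2 -
                        nk * Dc[bi, bj]^2) / (ni + nj + nk))
    }
    Dn <- matrix(0, length(keep) + 1, length(keep) + 1)
    if (length(keep) > 0) {
      Dn[seq_along(keep), seq_along(keep)] <- Dc[keep, keep, drop = FALSE]
      Dn[length(keep) + 1, seq_along(keep)] <- newd
      Dn[seq_along(keep), length(keep) + 1] <- newd
    }
    Dc <- Dn
    sizes <- c(sizes[keep], sizes[bi] + sizes[bj])
  }
  heights
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
oracle_ranksum_exact_p <- function(a, b) {
  n <- length(a) + length(b)
  vals <- c(a, b)
  r <- rank(vals)
  u_of <- function(idx) {
    ra <- sum(r[idx])
    ra - length(idx) * (length(idx) + 1) / 2
  }
  obs <- u_of(seq_along(a))
  mu <- length(a) * length(b) / 2
  sets <- utils::combn(n, length(a))
  us <- apply(sets, 2, u_of)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}
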