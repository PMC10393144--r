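#' Welch two-sample t statistic
#'
#' Unequal-variance (Welch) t statistic with Welch-Satterthwaite degrees of
#' freedom, the statistic underlying all pairwise group comparisons in the
#' pipeline. When both samples have zero variance and equal means the
#' statistic is defined as 0.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @return list with elements `t` and `df`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  welch_t_summary(mean(a), stats::sd(a), length(a),
                  mean(b), stats::sd(b), length(b))
}

#' Welch t statistic from summary statistics
#'
#' @param m1,s1,n1 mean, sd and size of the first sample.
#' @param m2,s2,n2 mean, sd and size of the second sample.
#' @return list with elements `t` and `df`.
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  va <- s1^2 / n1
  vb <- s2^2 / n2
  se2 <- va + vb
  d <- m1 - m2
  if (se2 == 0) {
    t <- if (d == 0) 0 else sign(d) * Inf
    df <- n1 + n2 - 2
  } else {
    t <- d / sqrt(se2)
    df <- se2^2 / (va^2 / (n1 - 1) + vb^2 / (n2 - 1))
  }
  list(t = t, df = df)
}

#' Hedges' g standardized mean difference
#'
#' Pooled-SD standardized mean difference with the exact small-sample bias
#' correction J(df) = Gamma(df/2) / (sqrt(df/2) * Gamma((df-1)/2)),
#' df = n1 + n2 - 2.
#'
#' @param a,b numeric samples.
#' @return the corrected effect size g (signed); `NA` with a warning when
#'   the pooled SD is zero.
#' @export
hedges_g <- function(a, b) {
  hedges_g_summary(mean(a), stats::sd(a), length(a),
                   mean(b), stats::sd(b), length(b))
}

#' @rdname hedges_g
#' @inheritParams welch_t_summary
#' @export
hedges_g_summary <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 == 0) {
    warning("zero pooled SD: Hedges' g undefined")
    return(NA_real_)
  }
  d <- (m1 - m2) / sqrt(sp2)
  d * hedges_correction(df)
}

# exact gamma-function small-sample correction factor J(df)
hedges_correction <- function(df) {
  exp(lgamma(df / 2) - 0.5 * log(df / 2) - lgamma((df - 1) / 2))
}

#' Permutation test based on the Welch t statistic
#'
#' Two-sided label-permutation test. When the number of distinct group
#' assignments `choose(n1 + n2, n1)` does not exceed `n_perm` the null
#' distribution is enumerated exactly (the p-value is then the exact
#' proportion of assignments with `|t| >=` the observed `|t|`, which
#' includes the observed assignment). Otherwise `n_perm` random assignments
#' are drawn and the add-one rule `p = (1 + #{|t*| >= |t|}) / (n_perm + 1)`
#' is used.
#'
#' @param a,b numeric samples.
#' @param n_perm maximum number of permutations.
#' @param seed optional integer seed for the random draw.
#' @return list with `t`, `df`, `p`, `n_perm` (permutations actually used)
#'   and `exact` (logical).
#' @export
perm_welch_test <- function(a, b, n_perm = 10000, seed = NULL) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  stopifnot(n >= 4)
  obs <- welch_t(a, b)
  z <- c(a, b)
  tol <- 1e-8 * (1 + abs(obs$t))
  n_arr <- choose(n, n1)
  if (is.finite(n_arr) && n_arr <= n_perm) {
    idx <- utils::combn(n, n1)
    tstar <- apply(idx, 2, function(i) welch_t(z[i], z[-i])$t)
    p <- mean(abs(tstar) >= abs(obs$t) - tol)
    return(list(t = obs$t, df = obs$df, p = p, n_perm = ncol(idx),
                exact = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  tstar <- perm_welch_stats(z, n1, n_perm)
  p <- (1 + sum(abs(tstar) >= abs(obs$t) - tol)) / (n_perm + 1)
  list(t = obs$t, df = obs$df, p = p, n_perm = n_perm, exact = FALSE)
}

# vectorized Welch t over n_perm random splits of pooled vector z
perm_welch_stats <- function(z, n1, n_perm) {
  n <- length(z)
  n2 <- n - n1
  S <- sum(z); Q <- sum(z^2)
  idx <- vapply(seq_len(n_perm), function(i) sample.int(n, n1),
                integer(n1))
  X <- matrix(z[idx], nrow = n1)
  s1 <- colSums(X); q1 <- colSums(X * X)
  s2 <- S - s1; q2 <- Q - q1
  v1 <- pmax(0, (q1 - s1^2 / n1) / (n1 - 1))
  v2 <- pmax(0, (q2 - s2^2 / n2) / (n2 - 1))
  se <- sqrt(v1 / n1 + v2 / n2)
  d <- s1 / n1 - s2 / n2
  t <- ifelse(se == 0, ifelse(d == 0, 0, sign(d) * Inf), d / pmax(se, 1e-300))
  t
}

#' Mann-Whitney U test
#'
#' Thin wrapper around [stats::wilcox.test()] returning the U statistic and
#' a two-sided p-value; the null distribution is exact for group sizes up to
#' 10 per group when there are no ties.
#'
#' @param a,b numeric samples.
#' @return list with `U` and `p`.
#' @export
mann_whitney_u <- function(a, b) {
  use_exact <- length(a) <= 10 && length(b) <= 10 &&
    !any(duplicated(c(a, b)))
  wt <- stats::wilcox.test(a, b, exact = use_exact, correct = !use_exact)
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Threshold-free cluster enhancement
#'
#' Enhances a statistic map by integrating cluster extent and height over
#' all thresholds: for each point p, TFCE(p) = sum over thresholds h (in
#' steps of `dh` up to the map maximum) of e(h)^E * h^H * dh, where e(h) is
#' the extent of the connected suprathreshold cluster containing p at
#' height h. Negative values are enhanced on the negated map and re-negated,
#' so the output carries the sign of the input.
#'
#' One kernel serves all domains: 1-D time courses (numeric vectors), 2-D
#' frequency-time maps (matrices, 4-connectivity) and channel maps (with an
#' explicit `adjacency` matrix from [channel_adjacency()]).
#'
#' @param map numeric vector or matrix of statistic values.
#' @param adjacency optional logical adjacency matrix; when `NULL` a lattice
#'   adjacency is derived from the shape of `map`.
#' @param E,H extent and height exponents (defaults 0.5 and 2).
#' @param dh threshold step; default `max(abs(map)) / 100`.
#' @return enhanced map with the same shape as `map`.
#' @export
tfce <- function(map, adjacency = NULL, E = 0.5, H = 2, dh = NULL) {
  stopifnot(all(is.finite(map)))
  v <- as.numeric(map)
  adj <- if (is.null(adjacency)) {
    if (is.matrix(map)) lattice_adjacency(dim(map)) else
      lattice_adjacency(length(v))
  } else if (is.matrix(adjacency)) {
    stopifnot(nrow(adjacency) == length(v))
    matrix_adjacency(adjacency)
  } else {
    adjacency  # already compressed
  }
  if (is.null(dh)) dh <- max(abs(v)) / 100
  if (!is.finite(dh) || dh <= 0) {
    out <- rep(0, length(v))
  } else {
    pos <- .tfce_graph(pmax(v, 0), adj$neighbors, adj$offsets, E, H, dh)
    neg <- .tfce_graph(pmax(-v, 0), adj$neighbors, adj$offsets, E, H, dh)
    out <- pos - neg
  }
  if (is.matrix(map)) dim(out) <- dim(map)
  out
}

# vectorized per-node Welch t between two subject-by-node matrices;
# var_floor is an additive variance regularizer (pseudo-t): without it,
# map points with near-degenerate variance (e.g. rarely-hit spectrogram
# bins) produce arbitrarily large t values that dominate the TFCE
# enhancement and its permutation null
welch_t_map <- function(A, B, var_floor = 0) {
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- (colSums(A * A) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(B * B) - n2 * m2^2) / (n2 - 1)
  se2 <- pmax(v1, 0) / n1 + pmax(v2, 0) / n2 + var_floor
  d <- m1 - m2
  ifelse(se2 == 0, 0, d / sqrt(pmax(se2, 1e-300)))
}

#' TFCE permutation test between two groups of maps
#'
#' Computes the pointwise Welch t map between two groups of per-subject maps,
#' enhances it with [tfce()], and derives family-wise-corrected permutation
#' p-values from the maximum enhanced statistic under random relabeling of
#' subjects. The threshold step `dh` is fixed from the observed map and
#' reused for all permutations.
#'
#' @param A,B numeric matrices, subjects in rows, map points in columns
#'   (flatten 2-D maps with `dim` supplied via `map_dim`).
#' @param adjacency `NULL` for a 1-D lattice over columns, a length-2
#'   integer vector interpreted as 2-D lattice dims, or an adjacency matrix.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @param alpha significance level for the reported mask.
#' @param E,H TFCE exponents.
#' @return An object of class `stat_result`: list with `statistic` (t map),
#'   `enhanced`, `p`, `mask`, `alpha`, `n_perm`, `mean_diff`.
#' @export
tfce_perm_test <- function(A, B, adjacency = NULL, n_perm = 1000,
                           seed = NULL, alpha = 0.05, E = 0.5, H = 2,
                           var_floor_frac = 1e-3) {
  stopifnot(ncol(A) == ncol(B), nrow(A) >= 2, nrow(B) >= 2)
  npt <- ncol(A)
  # pseudo-t regularization: a small fraction of the map-average pooled
  # variance, fixed across permutations
  vbar <- mean(apply(rbind(A, B), 2, stats::var))
  var_floor <- var_floor_frac * (vbar / (nrow(A) + nrow(B)) * 2)
  adj <- if (is.null(adjacency)) {
    lattice_adjacency(npt)
  } else if (is.list(adjacency)) {
    adjacency  # already compressed
  } else if (is.matrix(adjacency)) {
    matrix_adjacency(adjacency)
  } else {
    lattice_adjacency(as.integer(adjacency))  # lattice dims
  }
  if (length(adj$offsets) != npt + 1L)
    stop("adjacency does not cover all map points")
  tobs <- welch_t_map(A, B, var_floor)
  dh <- max(abs(tobs)) / 100
  enh <- if (dh > 0) {
    pos <- .tfce_graph(pmax(tobs, 0), adj$neighbors, adj$offsets, E, H, dh)
    neg <- .tfce_graph(pmax(-tobs, 0), adj$neighbors, adj$offsets, E, H, dh)
    pos - neg
  } else {
    rep(0, npt)
  }
  if (!is.null(seed)) set.seed(seed)
  n1 <- nrow(A)
  Z <- rbind(A, B)
  n <- nrow(Z)
  maxstat <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    pi <- sample.int(n, n1)
    tp <- welch_t_map(Z[pi, , drop = FALSE], Z[-pi, , drop = FALSE], var_floor)
    if (dh > 0) {
      ep <- .tfce_graph(pmax(tp, 0), adj$neighbors, adj$offsets, E, H, dh)
      en <- .tfce_graph(pmax(-tp, 0), adj$neighbors, adj$offsets, E, H, dh)
      maxstat[i] <- max(ep, en)
    } else {
      maxstat[i] <- 0
    }
  }
  p <- vapply(abs(enh), function(e) (1 + sum(maxstat >= e)) / (n_perm + 1),
              numeric(1))
  structure(list(statistic = tobs, enhanced = enh, p = p,
                 mask = p < alpha, alpha = alpha, n_perm = n_perm,
                 mean_diff = colMeans(A) - colMeans(B)),
            class = "stat_result")
}

#' Spearman correlation map with TFCE permutation significance
#'
#' Correlates one per-subject scalar with a per-subject, per-channel feature
#' matrix (Spearman rank correlation with mid-rank ties), enhances the
#' channel rho map over the channel adjacency graph with [tfce()], and
#' derives family-wise permutation p-values by shuffling the scalar across
#' subjects.
#'
#' @param x numeric per-subject scalar (length >= 5).
#' @param Y numeric matrix, subjects in rows, channels in columns.
#' @param adjacency logical channel adjacency matrix
#'   (default from [channel_adjacency()] when Y has 32 columns).
#' @param n_perm,seed,alpha,E,H as in [tfce_perm_test()].
#' @return `stat_result` with `statistic` = rho per channel.
#' @export
spearman_tfce_map <- function(x, Y, adjacency = NULL, n_perm = 2000,
                              seed = NULL, alpha = 0.05, E = 0.5, H = 2) {
  stopifnot(length(x) == nrow(Y), length(x) >= 5)
  if (stats::sd(x) == 0) stop("constant x: Spearman correlation undefined")
  adj <- if (is.null(adjacency)) {
    if (ncol(Y) == 32) matrix_adjacency(channel_adjacency())
    else lattice_adjacency(ncol(Y))
  } else if (is.matrix(adjacency)) {
    matrix_adjacency(adjacency)
  } else {
    adjacency
  }
  rx <- rank(x)
  RY <- apply(Y, 2, rank)
  const_col <- apply(Y, 2, function(col) stats::sd(col) == 0)
  rho_of <- function(rxv) {
    r <- suppressWarnings(stats::cor(rxv, RY))
    r[!is.finite(r)] <- 0
    as.numeric(r)
  }
  rho <- rho_of(rx)
  dh <- max(abs(rho)) / 100
  enhance <- function(v) {
    if (dh <= 0) return(rep(0, length(v)))
    .tfce_graph(pmax(v, 0), adj$neighbors, adj$offsets, E, H, dh) -
      .tfce_graph(pmax(-v, 0), adj$neighbors, adj$offsets, E, H, dh)
  }
  enh <- enhance(rho)
  if (!is.null(seed)) set.seed(seed)
  maxstat <- vapply(seq_len(n_perm), function(i) {
    max(abs(enhance(rho_of(sample(rx)))))
  }, numeric(1))
  p <- vapply(abs(enh), function(e) (1 + sum(maxstat >= e)) / (n_perm + 1),
              numeric(1))
  p[const_col] <- NA_real_
  structure(list(statistic = rho, enhanced = enh, p = p,
                 mask = !is.na(p) & p < alpha, alpha = alpha,
                 n_perm = n_perm, degenerate = const_col),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", length(x$statistic), " points; ",
      sum(x$mask, na.rm = TRUE), " significant at alpha = ", x$alpha,
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Contiguous significant intervals of a 1-D mask
#'
#' @param mask logical vector.
#' @param times numeric axis values (same length).
#' @return data.frame with `start`, `end` (axis units) per contiguous run.
#' @export
significant_spans <- function(mask, times) {
  stopifnot(length(mask) == length(times))
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = times[starts[keep]], end = times[ends[keep]])
}
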