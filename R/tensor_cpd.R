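#' Build the order-3 space x time x trial tensor
#'
#' Pools the retained target epochs of both groups, subtracts a per-trial,
#' per-channel offset estimated from the first 80 ms of the epoch, and
#' crops the time axis to -100..+900 ms (251 samples at 250 Hz for the
#' game paradigms).
#'
#' @param e `epoch_set` (epochs must cover the crop span).
#' @param crop_ms time range retained.
#' @param offset_ms duration of the leading offset-estimation window.
#' @param target_only pool only target trials (default TRUE).
#' @return list of class `trial_tensor`: `data` (channels x time x trials),
#'   `times`, `channels`, `labels`.
#' @export
build_order3 <- function(e, crop_ms = c(-100, 900), offset_ms = 80,
                         target_only = TRUE) {
  if (e$times[1] > crop_ms[1] || e$times[length(e$times)] < crop_ms[2]) {
    stop("epochs do not cover the requested crop span")
  }
  keep <- which(!e$rejected & (!target_only | e$labels$target))
  off_idx <- which(e$times < e$times[1] + offset_ms)
  t_idx <- which(e$times >= crop_ms[1] & e$times <= crop_ms[2])
  X <- e$data[, , keep, drop = FALSE]
  off <- apply(X[, off_idx, , drop = FALSE], c(1, 3), mean)
  d <- dim(X)
  X <- X - aperm(array(off, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  structure(list(data = X[, t_idx, , drop = FALSE], times = e$times[t_idx],
                 channels = e$channels,
                 labels = e$labels[keep, , drop = FALSE]),
            class = "trial_tensor")
}

#' Build the order-4 space x frequency x time x trial tensor
#'
#' Concatenates per-trial Hilbert spectrograms of one or more channels into
#' a 4-way array; optionally restricted to a high-frequency band (3-30 Hz)
#' to suppress the dominant low-frequency ERP energy.
#'
#' @param spect_list named list (one element per channel) of
#'   [epochs_to_spectrograms()] outputs on a shared grid.
#' @param band frequency band to retain, Hz (default `c(0, 30)`; use
#'   `c(3, 30)` for the high-band variant).
#' @return `trial_tensor` with `data` (channels x freq x time x trials),
#'   `freqs`, `times`, `channels`, `labels`.
#' @export
build_order4 <- function(spect_list, band = c(0, 30)) {
  ref <- spect_list[[1]]
  for (s in spect_list) {
    if (!identical(dim(s$power), dim(ref$power)) ||
        !isTRUE(all.equal(s$freqs, ref$freqs))) {
      stop("spectrogram grids do not match across channels")
    }
  }
  f_idx <- which(ref$freqs >= band[1] & ref$freqs <= band[2])
  d <- dim(ref$power)
  X <- array(0, dim = c(length(spect_list), length(f_idx), d[2], d[3]))
  for (c in seq_along(spect_list)) {
    X[c, , , ] <- spect_list[[c]]$power[f_idx, , ]
  }
  structure(list(data = X, freqs = ref$freqs[f_idx], times = ref$times,
                 channels = names(spect_list), labels = ref$labels),
            class = "trial_tensor")
}

# mode-n unfolding (rows = mode n, columns = remaining modes in order)
unfold <- function(X, mode) {
  d <- dim(X)
  perm <- c(mode, setdiff(seq_along(d), mode))
  matrix(aperm(X, perm), nrow = d[mode])
}

# column-wise Khatri-Rao product
khatri_rao <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  out <- matrix(0, nrow(A) * nrow(B), ncol(A))
  for (r in seq_len(ncol(A))) {
    out[, r] <- kronecker(A[, r], B[, r])
  }
  out
}

# Khatri-Rao of a list of factor matrices, *reversed* order (the convention
# matching the unfolding above: for mode n, KR of modes D, ..., n+1, n-1,
# ..., 1 reversed = KR over the remaining modes with the last mode varying
# slowest)
khatri_rao_list <- function(mats) {
  out <- mats[[1]]
  if (length(mats) > 1) {
    for (k in 2:length(mats)) out <- khatri_rao(mats[[k]], out)
  }
  out
}

#' Canonical polyadic decomposition by alternating least squares
#'
#' Fits a rank-R CP model to an order-3 or order-4 tensor with an optional
#' orthonormality constraint on the spatial (first-mode) factor: at each
#' sweep the unconstrained spatial update is projected onto the nearest
#' orthonormal matrix (polar projection via SVD), which prevents the
#' degeneracy of unconstrained CPD on EEG data. Component scale is
#' absorbed into the trial (last-mode) factor; components are reordered by
#' descending explained energy and sign-aligned so each temporal factor's
#' extremum is positive. Multiple random restarts keep the best fit.
#'
#' @param X `trial_tensor` or plain numeric array.
#' @param rank number of components R.
#' @param orthogonal_spatial constrain the spatial factor (default TRUE).
#' @param tol relative fit-change convergence tolerance.
#' @param max_iter maximum ALS sweeps per restart.
#' @param restarts number of random restarts.
#' @param seed integer seed for the random initializations.
#' @param ridge Tikhonov regularization added to rank-deficient
#'   least-squares solves (with a warning).
#' @return list of class `factor_model`: `factors` (named list: spatial,
#'   [spectral,] temporal, trial), `rank`, `fit` (1 - relative residual),
#'   `residual` (relative), `iterations`, `converged`, `labels` (carried
#'   from the tensor when present).
#' @export
fit_cpd <- function(X, rank, orthogonal_spatial = TRUE, tol = 1e-8,
                    max_iter = 200, restarts = 5, seed = 1,
                    ridge = 1e-10) {
  labels <- NULL
  if (inherits(X, "trial_tensor")) {
    labels <- X$labels
    X <- X$data
  }
  d <- dim(X)
  D <- length(d)
  stopifnot(D %in% c(3, 4), rank >= 1, all(rank <= d))
  unf <- lapply(seq_len(D), function(m) unfold(X, m))
  normX2 <- sum(unf[[1]]^2)
  set.seed(seed)
  best <- NULL
  for (rs in seq_len(restarts)) {
    F <- lapply(d, function(n) matrix(stats::rnorm(n * rank), n, rank))
    if (orthogonal_spatial) F[[1]] <- qr.Q(qr(F[[1]]))[, seq_len(rank)]
    grams <- lapply(F, crossprod)
    res_prev <- Inf
    it_used <- max_iter
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      for (m in seq_len(D)) {
        others <- setdiff(seq_len(D), m)
        KR <- khatri_rao_list(F[others])
        MTT <- unf[[m]] %*% KR
        if (m == 1 && orthogonal_spatial) {
          sv <- svd(MTT)
          F[[1]] <- sv$u %*% t(sv$v)
        } else {
          G <- Reduce("*", grams[others])
          sol <- tryCatch(solve(G, t(MTT)), error = function(e) NULL)
          if (is.null(sol)) {
            warning("rank-deficient ALS update; ridge-regularized solve")
            sol <- solve(G + diag(ridge * max(diag(G)), rank), t(MTT))
          }
          F[[m]] <- t(sol)
        }
        if (m < D) {  # unit-normalize non-trial factors, absorb into trial
          nrm <- sqrt(colSums(F[[m]]^2))
          nrm[nrm == 0] <- 1
          F[[m]] <- sweep(F[[m]], 2, nrm, "/")
          F[[D]] <- sweep(F[[D]], 2, nrm, "*")
        }
        grams[[m]] <- crossprod(F[[m]])
        grams[[D]] <- crossprod(F[[D]])
      }
      # exact residual via inner products
      KR <- khatri_rao_list(F[seq_len(D - 1)])
      inner <- sum((unf[[D]] %*% KR) * F[[D]])
      model2 <- sum(Reduce("*", grams))
      res2 <- max(0, normX2 - 2 * inner + model2)
      res <- sqrt(res2 / normX2)
      if (is.finite(res_prev) && abs(res_prev - res) < tol) {
        conv <- TRUE
        it_used <- it
        break
      }
      res_prev <- res
    }
    if (is.null(best) || res < best$residual) {
      best <- list(F = F, residual = res, iterations = it_used,
                   converged = conv)
    }
  }
  F <- best$F
  # order components by explained energy (trial-factor column norms, other
  # factors are unit norm) and make each temporal extremum positive
  energy <- colSums(F[[D]]^2)
  ord <- order(energy, decreasing = TRUE)
  F <- lapply(F, function(M) M[, ord, drop = FALSE])
  t_mode <- D - 1  # temporal factor (order-3: mode 2; order-4: mode 3)
  for (r in seq_len(rank)) {
    v <- F[[t_mode]][, r]
    if (v[which.max(abs(v))] < 0) {
      F[[t_mode]][, r] <- -v
      F[[D]][, r] <- -F[[D]][, r]
    }
  }
  names(F) <- if (D == 3) c("spatial", "temporal", "trial") else
    c("spatial", "spectral", "temporal", "trial")
  structure(list(factors = F, rank = rank, residual = best$residual,
                 fit = 1 - best$residual, iterations = best$iterations,
                 converged = best$converged, labels = labels),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("<factor_model> rank ", x$rank, "; fit ",
      sprintf("%.4f", x$fit), " (", x$iterations, " sweeps)\n", sep = "")
  invisible(x)
}

#' Per-subject component power from the trial factor
#'
#' The power a component carries for a subject is the signed sum of that
#' subject's trial-factor coefficients (after the energy-based sign
#' alignment performed by [fit_cpd()]).
#'
#' @param model `factor_model` whose `labels` carry a `subject` column
#'   aligned with the trial factor rows (or supply `labels`).
#' @param labels optional data.frame with `subject` and `group`.
#' @param absolute sum absolute coefficients instead (off by default).
#' @return list: `scores` (subject x component matrix), `subject`,
#'   `group`.
#' @export
subject_power <- function(model, labels = model$labels,
                          absolute = FALSE) {
  stopifnot(!is.null(labels), nrow(labels) == nrow(model$factors$trial))
  Tr <- model$factors$trial
  if (absolute) Tr <- abs(Tr)
  subs <- unique(labels$subject)
  S <- t(vapply(subs, function(s) {
    idx <- labels$subject == s
    if (!any(idx)) stop("subject with zero trials: ", s)
    colSums(Tr[idx, , drop = FALSE])
  }, numeric(model$rank)))
  grp <- labels$group[match(subs, labels$subject)]
  list(scores = S, subject = subs, group = grp)
}

#' Group test of per-subject component power
#'
#' Two-sided Mann-Whitney U test between the PRO and NOVICE per-subject
#' power scores of every CP component (exact null for <= 10 subjects per
#' group, untied).
#'
#' @param model `factor_model` with trial labels.
#' @param groups length-2 character, default `c("PRO", "NOVICE")`.
#' @param absolute passed to [subject_power()].
#' @return data.frame: component, U, p, median difference; plus attribute
#'   `"scores"` (the subject x component matrix).
#' @export
subject_power_test <- function(model, groups = c("PRO", "NOVICE"),
                               absolute = FALSE) {
  sp <- subject_power(model, absolute = absolute)
  a <- sp$group == groups[1]
  b <- sp$group == groups[2]
  out <- do.call(rbind, lapply(seq_len(model$rank), function(r) {
    mw <- mann_whitney_u(sp$scores[a, r], sp$scores[b, r])
    data.frame(component = r, U = mw$U, p = mw$p,
               median_diff = stats::median(sp$scores[a, r]) -
                 stats::median(sp$scores[b, r]))
  }))
  attr(out, "scores") <- sp
  out
}
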