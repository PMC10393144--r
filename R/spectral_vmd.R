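#' Variational mode decomposition configuration
#'
#' @param K number of modes.
#' @param alpha bandwidth penalty (larger = narrower modes).
#' @param tau dual-ascent step (0 = no exact-reconstruction enforcement,
#'   tolerant to noise).
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @param init_fmax_hz center frequencies are initialized uniformly over
#'   (0, `init_fmax_hz`].
#' @return list of class `vmd_config`.
#' @export
vmd_config <- function(K = 6, alpha = 2000, tau = 0, tol = 1e-7,
                       max_iter = 500, init_fmax_hz = 30) {
  stopifnot(K >= 1, alpha > 0, tau >= 0, tol > 0, max_iter >= 1)
  structure(list(K = as.integer(K), alpha = alpha, tau = tau, tol = tol,
                 max_iter = max_iter, init_fmax_hz = init_fmax_hz),
            class = "vmd_config")
}

fftshift_idx <- function(n) c((n / 2 + 1):n, 1:(n / 2))

#' Variational mode decomposition
#'
#' Decomposes a real signal into K band-limited intrinsic mode functions by
#' the frequency-domain ADMM scheme: Wiener-filter mode updates
#' `u_k = (f - sum(u_i, i != k) + lambda/2) / (1 + 2 alpha (w - w_k)^2)`,
#' center-frequency updates as power-weighted mean frequencies, and dual
#' ascent with step `tau`. The signal is mirror-extended to twice its
#' length to reduce boundary effects and the middle section is returned.
#'
#' @param x real signal.
#' @param srate sampling rate, Hz.
#' @param cfg [vmd_config()].
#' @return list of class `imf_set`: `modes` (K x length(x), ordered by
#'   ascending center frequency), `omega_hz`, `n_iter`, `converged`.
#' @export
vmd <- function(x, srate, cfg = vmd_config()) {
  stopifnot(all(is.finite(x)), length(x) >= 2 * cfg$K)
  T_ <- length(x)
  lp <- T_ %/% 2
  rp <- T_ - lp
  xm <- c(rev(x[seq_len(lp)]), x, rev(x[seq(T_ - rp + 1, T_)]))
  N <- length(xm)                     # = 2 * T_, even
  sh <- fftshift_idx(N)
  freqs <- ((seq_len(N) - 1) / N)[sh] # not used; explicit below
  freqs <- (seq_len(N) - 1) / N - 0.5 # shifted axis: -0.5 ... 0.5 - 1/N
  f_hat <- stats::fft(xm)[sh]
  f_hat_plus <- f_hat
  f_hat_plus[seq_len(N / 2)] <- 0     # zero negative frequencies
  K <- cfg$K
  omega <- (seq_len(K) - 0.5) / K * min(cfg$init_fmax_hz / srate, 0.49)
  u_hat <- matrix(0 + 0i, N, K)
  lambda <- rep(0 + 0i, N)
  pos <- seq(N / 2 + 1, N)
  converged <- FALSE
  n_iter <- cfg$max_iter
  for (it in seq_len(cfg$max_iter)) {
    u_prev <- u_hat
    for (k in seq_len(K)) {
      others <- rowSums(u_hat) - u_hat[, k]
      u_hat[, k] <- (f_hat_plus - others + lambda / 2) /
        (1 + 2 * cfg$alpha * (freqs - omega[k])^2)
      pw <- Mod(u_hat[pos, k])^2
      tp <- sum(pw)
      if (tp > 0) omega[k] <- sum(freqs[pos] * pw) / tp
      omega[k] <- min(max(omega[k], 0), 0.5 - 1 / N)
    }
    if (cfg$tau > 0) {
      lambda <- lambda + cfg$tau * (f_hat_plus - rowSums(u_hat))
    }
    num <- sum(Mod(u_hat - u_prev)^2)
    den <- sum(Mod(u_prev)^2)
    if (it > 1 && den > 0 && num / den < cfg$tol) {
      converged <- TRUE
      n_iter <- it
      break
    }
  }
  if (!converged) warning("VMD did not converge in ", cfg$max_iter,
                          " iterations")
  ord <- order(omega)
  modes <- matrix(0, K, T_)
  mid <- seq(lp + 1, lp + T_)
  for (j in seq_along(ord)) {
    k <- ord[j]
    spec <- u_hat[, k]
    spec[N / 2 + 1] <- Re(spec[N / 2 + 1]) + 0i   # DC real
    spec[1] <- Re(spec[1]) + 0i                   # Nyquist real
    full <- spec
    ii <- 2:(N / 2)
    full[ii] <- Conj(spec[N + 2 - ii])
    u <- Re(stats::fft(full[sh], inverse = TRUE)) / N
    modes[j, ] <- u[mid]
  }
  structure(list(modes = modes, omega_hz = sort(omega) * srate,
                 n_iter = n_iter, converged = converged),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat("<imf_set> ", nrow(x$modes), " modes, center frequencies (Hz): ",
      paste(sprintf("%.2f", x$omega_hz), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x real signal.
#' @return complex analytic signal (same length).
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# instantaneous frequency (Hz) from an analytic signal: derivative of the
# unwrapped phase, median-smoothed over `smooth` samples
instantaneous_frequency <- function(a, srate, smooth = 5) {
  phi <- Arg(a)
  dphi <- diff(phi)
  dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
  f <- c(dphi[1], dphi) * srate / (2 * pi)
  if (smooth > 1 && length(f) > smooth) {
    f <- stats::runmed(f, smooth)
  }
  f
}

#' Hilbert-Huang spectrogram of an IMF set
#'
#' For every mode the instantaneous amplitude and frequency are obtained
#' from the analytic signal; the squared amplitude is deposited in the
#' nearest of 101 frequency bins spanning 0-30 Hz at each (cropped) time
#' point, and modes are summed. Instantaneous frequencies outside
#' [0, Nyquist] are clipped (the count is reported); energy above the band
#' maximum is discarded.
#'
#' @param imfs `imf_set` from [vmd()].
#' @param srate sampling rate, Hz.
#' @param times time axis of the underlying epoch, ms.
#' @param crop_ms time range retained (default -100..500 ms, dropping
#'   boundary-distorted sections).
#' @param n_bins number of frequency bins (default 101).
#' @param fmax_hz top of the frequency band (default 30).
#' @return list of class `hh_spectrogram`: `power` (n_bins x time, uV^2),
#'   `freqs` (bin centers, Hz), `times` (cropped, ms), `n_clipped`.
#' @export
hilbert_spectrogram <- function(imfs, srate, times,
                                crop_ms = c(-100, 500), n_bins = 101,
                                fmax_hz = 30) {
  tidx <- which(times >= crop_ms[1] & times <= crop_ms[2])
  nt <- length(tidx)
  P <- matrix(0, n_bins, nt)
  df <- fmax_hz / (n_bins - 1)
  nyq <- srate / 2
  n_clipped <- 0L
  for (k in seq_len(nrow(imfs$modes))) {
    a <- analytic_signal(imfs$modes[k, ])
    amp2 <- Mod(a)^2
    f <- instantaneous_frequency(a, srate)
    bad <- f < 0 | f > nyq
    n_clipped <- n_clipped + sum(bad[tidx])
    f <- pmin(pmax(f, 0), nyq)
    bin <- as.integer(round(f / df)) + 1L
    for (j in seq_len(nt)) {
      b <- bin[tidx[j]]
      if (b >= 1 && b <= n_bins) P[b, j] <- P[b, j] + amp2[tidx[j]]
    }
  }
  structure(list(power = P, freqs = seq(0, fmax_hz, length.out = n_bins),
                 times = times[tidx], n_clipped = n_clipped),
            class = "hh_spectrogram")
}

#' Per-trial Hilbert spectrograms of one channel of an epoch set
#'
#' Runs [vmd()] and [hilbert_spectrogram()] on every retained trial.
#'
#' @param e `epoch_set`.
#' @param channel channel name (default `"Cz"`, the channel used for the
#'   group spectrogram comparison).
#' @param cfg [vmd_config()].
#' @param crop_ms,n_bins,fmax_hz passed to [hilbert_spectrogram()].
#' @param target_only keep only target trials.
#' @return list: `power` (n_bins x time x trials array), `freqs`, `times`,
#'   `labels` (rows of the retained trials).
#' @export
epochs_to_spectrograms <- function(e, channel = "Cz", cfg = vmd_config(),
                                   crop_ms = c(-100, 500), n_bins = 101,
                                   fmax_hz = 30, target_only = TRUE) {
  ch <- match(channel, e$channels)
  if (is.na(ch)) stop("unknown channel: ", channel)
  keep <- which(!e$rejected & (!target_only | e$labels$target))
  first <- NULL
  P <- NULL
  for (j in seq_along(keep)) {
    imfs <- suppressWarnings(vmd(e$data[ch, , keep[j]], e$srate, cfg))
    sp <- hilbert_spectrogram(imfs, e$srate, e$times, crop_ms, n_bins,
                              fmax_hz)
    if (is.null(P)) {
      first <- sp
      P <- array(0, dim = c(n_bins, length(sp$times), length(keep)))
    }
    P[, , j] <- sp$power
  }
  list(power = P, freqs = first$freqs, times = first$times,
       labels = e$labels[keep, , drop = FALSE])
}

#' Group comparison of Hilbert spectrograms
#'
#' Computes the pointwise Welch t map between groups of spectrograms and
#' applies 2-D TFCE with family-wise permutation p-values; the
#' mean-difference map is masked at the significance level.
#'
#' With `units = "subjects"` (the default) per-trial spectrograms are
#' averaged within subject first and subjects are the exchangeable units:
#' conservative, respecting between-subject variability. With
#' `units = "trials"` the single-trial spectrograms themselves are pooled
#' and permuted, matching the common practice of comparing mean
#' spectrograms over all trials; far more sensitive, but its p-values
#' ignore the subject level.
#'
#' @param spect output of [epochs_to_spectrograms()].
#' @param groups length-2 character, default `c("PRO", "NOVICE")`.
#' @param units `"subjects"` or `"trials"` (exchangeable units).
#' @param n_perm,seed,alpha passed to [tfce_perm_test()].
#' @return `stat_result` with matrices `statistic`, `enhanced`, `p`,
#'   `mask`, `masked_diff` (n_bins x time) plus `freqs`, `times`.
#' @export
compare_group_spectrograms <- function(spect, groups = c("PRO", "NOVICE"),
                                       units = c("subjects", "trials"),
                                       n_perm = 500, seed = NULL,
                                       alpha = 0.05) {
  units <- match.arg(units)
  lab <- spect$labels
  d <- dim(spect$power)
  if (units == "subjects") {
    subs <- unique(lab$subject)
    M <- matrix(0, length(subs), d[1] * d[2])
    grp <- character(length(subs))
    for (i in seq_along(subs)) {
      idx <- which(lab$subject == subs[i])
      M[i, ] <- as.numeric(apply(spect$power[, , idx, drop = FALSE],
                                 c(1, 2), mean))
      grp[i] <- lab$group[idx[1]]
    }
  } else {
    M <- t(matrix(spect$power, d[1] * d[2], d[3]))
    grp <- lab$group
  }
  A <- M[grp == groups[1], , drop = FALSE]
  B <- M[grp == groups[2], , drop = FALSE]
  if (nrow(A) < 2 || nrow(B) < 2) stop("need >= 2 units per group")
  res <- tfce_perm_test(A, B, adjacency = c(d[1], d[2]), n_perm = n_perm,
                        seed = seed, alpha = alpha)
  for (nm in c("statistic", "enhanced", "p", "mask", "mean_diff")) {
    dim(res[[nm]]) <- c(d[1], d[2])
  }
  res$masked_diff <- ifelse(res$mask, res$mean_diff, NA_real_)
  res$freqs <- spect$freqs
  res$times <- spect$times
  res
}
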