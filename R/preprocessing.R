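#' Design a Kaiser-windowed sinc FIR filter
#'
#' Linear-phase FIR design matching the study's preprocessing chain:
#' Kaiser-windowed sinc kernels (default beta 5.65), e.g. a 0.5 Hz
#' high-pass and a 30 Hz low-pass (order 184) at 250 Hz.
#'
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff cutoff frequency, Hz (must lie in (0, Nyquist)).
#' @param srate sampling rate, Hz.
#' @param order filter order (number of taps minus one; must be even so the
#'   group delay is an integer number of samples).
#' @param beta Kaiser window shape parameter.
#' @return numeric vector of `order + 1` coefficients. DC gain is 1 for
#'   low-pass and 0 for high-pass designs.
#' @export
design_fir <- function(kind = c("lowpass", "highpass"), cutoff, srate,
                       order = 184, beta = 5.65) {
  kind <- match.arg(kind)
  nyq <- srate / 2
  if (cutoff <= 0 || cutoff >= nyq) stop("cutoff must lie in (0, Nyquist)")
  if (order < 1) stop("order must be >= 1")
  if (order %% 2 != 0) stop("order must be even for zero-phase application")
  h <- as.numeric(signal::fir1(order, cutoff / nyq, type = "low",
                               window = signal::kaiser(order + 1, beta)))
  h <- h / sum(h)  # exact unit DC gain
  if (kind == "highpass") {
    # spectral inversion of the unit-DC-gain low-pass: exactly zero DC gain
    h <- -h
    h[order / 2 + 1] <- h[order / 2 + 1] + 1
  }
  h
}

#' Frequency response of FIR taps
#'
#' @param taps FIR coefficients.
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param srate sampling rate, Hz.
#' @return complex response at each frequency.
#' @export
fir_response <- function(taps, freqs, srate) {
  k <- seq_along(taps) - 1
  vapply(freqs, function(f) {
    sum(taps * exp(-2i * pi * f / srate * k))
  }, complex(1))
}

# zero-phase FIR application to the columns of a matrix, with odd
# reflection padding (up to 3x the filter order) and group-delay removal
fir_filtfilt_cols <- function(X, taps) {
  n <- nrow(X)
  np <- length(taps)
  gd <- (np - 1) %/% 2
  pad <- min(3 * (np - 1), n - 1)
  top <- 2 * matrix(X[1, ], pad, ncol(X), byrow = TRUE) -
    X[seq(pad + 1, 2), , drop = FALSE]
  bot <- 2 * matrix(X[n, ], pad, ncol(X), byrow = TRUE) -
    X[seq(n - 1, n - pad), , drop = FALSE]
  XP <- rbind(top, X, bot)
  Y <- stats::filter(XP, taps, method = "convolution", sides = 1)
  Y <- as.matrix(Y)
  Y[seq(pad + gd + 1, pad + gd + n), , drop = FALSE]
}

#' Zero-phase FIR filtering of an epoch set
#'
#' Applies a linear-phase FIR filter forward with group-delay compensation
#' (equivalent to zero-phase for symmetric kernels), using odd reflection
#' padding of up to three filter orders at each epoch edge to suppress edge
#' transients on finite epochs.
#'
#' @param e `epoch_set`.
#' @param taps FIR coefficients from [design_fir()].
#' @return filtered `epoch_set`.
#' @export
filter_epochs <- function(e, taps) {
  d <- dim(e$data)
  X <- matrix(aperm(e$data, c(2, 1, 3)), nrow = d[2])  # time x (ch*trial)
  Y <- fir_filtfilt_cols(X, taps)
  e$data <- aperm(array(Y, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  e
}

#' Epoch continuous EEG around events and subtract baseline
#'
#' Cuts epochs from a continuous recording at event samples, excludes the
#' first two trials of every block (initial orientation responses), drops
#' events whose epoch would cross the recording edge (with a message), and
#' subtracts the mean of the 100 ms pre-stimulus window per channel and
#' epoch.
#'
#' @param cont numeric matrix channels x samples (uV).
#' @param events data.frame with columns `sample` (1-based stimulus onset),
#'   `is_target`, and optionally `block` (defaults to one block).
#' @param paradigm paradigm name (sets the epoch span via
#'   [paradigm_specs()]).
#' @param srate sampling rate, Hz.
#' @param montage montage for the rows of `cont`.
#' @param subject,group labels attached to all epochs.
#' @return `epoch_set`.
#' @export
epoch_and_baseline <- function(cont, events, paradigm, srate,
                               montage = standard_montage(),
                               subject = "S01", group = "NA") {
  spec <- paradigm_specs()
  row <- spec[spec$paradigm == paradigm, ]
  if (nrow(row) != 1) stop("unknown paradigm: ", paradigm)
  if (is.null(events$block)) events$block <- 1L
  keep <- unlist(lapply(split(seq_len(nrow(events)), events$block),
                        function(i) i[-seq_len(min(2, length(i)))]),
                 use.names = FALSE)
  events <- events[sort(keep), , drop = FALSE]
  n_pre <- round(row$pre_ms / 1000 * srate)
  n_post <- round(row$post_ms / 1000 * srate)
  times <- seq(-n_pre, n_post) * 1000 / srate
  ok <- events$sample - n_pre >= 1 &
    events$sample + n_post <= ncol(cont)
  if (any(!ok)) {
    message(sum(!ok), " event(s) too close to the recording edge; dropped")
  }
  events <- events[ok, , drop = FALSE]
  ntr <- nrow(events)
  data <- array(0, dim = c(nrow(cont), length(times), ntr))
  for (i in seq_len(ntr)) {
    data[, , i] <- cont[, (events$sample[i] - n_pre):(events$sample[i] + n_post)]
  }
  e <- epoch_set(data, srate, times, montage,
                 data.frame(subject = subject, group = group,
                            target = as.logical(events$is_target),
                            trial = seq_len(ntr), stringsAsFactors = FALSE))
  baseline_epochs(e)
}

#' Subtract the pre-stimulus baseline
#'
#' Removes the per-epoch, per-channel mean of the baseline window (default
#' the last 100 ms before stimulus onset). Idempotent.
#'
#' @param e `epoch_set`.
#' @param window_ms baseline window (ms), default `c(-100, 0)`.
#' @return baselined `epoch_set`.
#' @export
baseline_epochs <- function(e, window_ms = c(-100, 0)) {
  idx <- which(e$times >= window_ms[1] & e$times < window_ms[2])
  if (length(idx) == 0) stop("baseline window contains no samples")
  d <- dim(e$data)
  bl <- apply(e$data[, idx, , drop = FALSE], c(1, 3), mean)  # ch x trial
  e$data <- e$data - aperm(array(bl, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  e
}

#' Reject epochs with excessive amplitude range
#'
#' Marks epochs rejected when any channel's peak-to-peak amplitude within
#' the epoch exceeds `threshold` uV (default 500 uV, excluding
#' non-stereotypical artifacts). Errors if every epoch of some subject
#' would be rejected.
#'
#' @param e `epoch_set`.
#' @param threshold peak-to-peak rejection threshold, uV.
#' @return list with `epochs` (the `epoch_set` with an updated rejection
#'   mask) and `report` (data.frame subject, n_total, n_rejected,
#'   fraction).
#' @export
reject_epochs <- function(e, threshold = 500) {
  stopifnot(threshold > 0)
  d <- dim(e$data)
  M <- matrix(aperm(e$data, c(2, 1, 3)), nrow = d[2])
  ptp <- matrix(colMax_minus_min(M), nrow = d[1])  # channels x trials
  bad <- apply(ptp > threshold, 2, any)
  rejected <- e$rejected | bad
  rep_df <- do.call(rbind, lapply(split(seq_len(d[3]), e$labels$subject),
                                  function(i) {
    data.frame(subject = e$labels$subject[i[1]], n_total = length(i),
               n_rejected = sum(rejected[i]),
               fraction = mean(rejected[i]), stringsAsFactors = FALSE)
  }))
  rownames(rep_df) <- NULL
  all_gone <- rep_df$subject[rep_df$n_rejected == rep_df$n_total]
  if (length(all_gone) > 0) {
    stop("all epochs rejected for subject(s): ",
         paste(all_gone, collapse = ", "))
  }
  e$rejected <- rejected
  list(epochs = e, report = rep_df)
}

colMax_minus_min <- function(M) {
  apply(M, 2, function(col) max(col) - min(col))
}

#' Flag and interpolate outlier channels
#'
#' Scores each channel by its standard deviation over all samples of all
#' retained epochs, converts scores to robust z-values
#' `(score - median) / (0.7413 * IQR)`, flags channels with z > 3, and
#' replaces flagged channels by an inverse-distance-weighted average of
#' their unflagged montage neighbors. At most two channels are
#' interpolated (the worst two, with a warning if more were flagged).
#'
#' @param e `epoch_set`.
#' @param z_threshold robust z threshold (default 3).
#' @param neighbor_dist_mm neighbor radius for interpolation, mm.
#' @param max_interp maximum number of channels to interpolate.
#' @return list with `epochs` (interpolated `epoch_set`) and `flagged`
#'   (character vector of interpolated channel names).
#' @export
flag_and_interpolate_channels <- function(e, z_threshold = 3,
                                          neighbor_dist_mm = 75,
                                          max_interp = 2) {
  d <- dim(e$data)
  stopifnot(d[1] >= 4)
  keep <- !e$rejected
  # score residual activity (data minus the per-subject evoked mean), so
  # genuinely strong posterior ERP topographies do not look like artifacts
  score <- numeric(d[1])
  for (s in unique(e$labels$subject)) {
    idx <- which(keep & e$labels$subject == s)
    if (length(idx) == 0) next
    blk <- e$data[, , idx, drop = FALSE]
    mu <- apply(blk, c(1, 2), mean)
    score <- score + rowSums((blk - array(mu, dim(blk)))^2)
  }
  score <- sqrt(score / (sum(keep) * d[2]))
  iqr <- stats::IQR(score)
  z <- if (iqr == 0) rep(0, d[1]) else
    (score - stats::median(score)) / (0.7413 * iqr)
  # robust z plus a minimum-excess guard: smooth spatial activity
  # gradients (e.g. posterior alpha) give tight IQRs where z alone
  # over-flags; a real artifact channel exceeds the median by far more
  flagged <- which(z > z_threshold & score > 1.3 * stats::median(score))
  if (length(flagged) > max_interp) {
    warning(length(flagged), " channels flagged; interpolating the worst ",
            max_interp)
    flagged <- flagged[order(z[flagged], decreasing = TRUE)][seq_len(max_interp)]
  }
  for (ch in flagged) {
    dx <- e$montage$x - e$montage$x[ch]
    dy <- e$montage$y - e$montage$y[ch]
    dist <- sqrt(dx^2 + dy^2)
    nb <- setdiff(which(dist > 0 & dist <= neighbor_dist_mm), flagged)
    if (length(nb) < 2) {
      nb <- setdiff(order(dist), c(ch, flagged))[1:3]
    }
    wts <- 1 / dist[nb]^2
    wts <- wts / sum(wts)
    acc <- array(0, dim = d[2:3])
    for (k in seq_along(nb)) acc <- acc + wts[k] * e$data[nb[k], , ]
    e$data[ch, , ] <- acc
  }
  list(epochs = e, flagged = e$channels[flagged])
}
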