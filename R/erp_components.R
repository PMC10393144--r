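#' Per-subject ERPs from an epoch set
#'
#' Averages the retained (unrejected) target epochs of every subject into a
#' per-subject ERP waveform.
#'
#' @param e `epoch_set`.
#' @param target_only average only target epochs (default TRUE).
#' @return list with `waveforms` (subjects x channels x time array),
#'   `subject`, `group`, `n_trials`, `times`, `channels`, `montage`.
#' @export
subject_erps <- function(e, target_only = TRUE) {
  keep <- !e$rejected
  if (target_only) keep <- keep & e$labels$target
  subs <- unique(e$labels$subject)
  d <- dim(e$data)
  W <- array(0, dim = c(length(subs), d[1], d[2]))
  grp <- character(length(subs))
  ntr <- integer(length(subs))
  for (i in seq_along(subs)) {
    idx <- which(keep & e$labels$subject == subs[i])
    if (length(idx) == 0) stop("no retained target trials for ", subs[i])
    W[i, , ] <- apply(e$data[, , idx, drop = FALSE], c(1, 2), mean)
    grp[i] <- e$labels$group[idx[1]]
    ntr[i] <- length(idx)
  }
  list(waveforms = W, subject = subs, group = grp, n_trials = ntr,
       times = e$times, channels = e$channels, montage = e$montage)
}

#' Grand-average ROI time course per group
#'
#' Averages per-subject waveforms over a channel region of interest
#' (default the posterior set P3, Pz, P4, PO3, PO4) and then over the
#' subjects of each group, returning the between-subject SD envelope as
#' well.
#'
#' @param waves output of [subject_erps()].
#' @param roi character vector of ROI channel names.
#' @return list keyed by group: each with `mean`, `sd` (time series) and
#'   `subject_tc` (subjects x time matrix); plus `times`.
#' @export
grand_average <- function(waves, roi = c("P3", "Pz", "P4", "PO3", "PO4")) {
  ch_idx <- match(roi, waves$channels)
  if (length(ch_idx) == 0 || anyNA(ch_idx)) stop("ROI channels not found")
  out <- list(times = waves$times)
  nt <- length(waves$times)
  roi_tc <- function(i) {
    m <- waves$waveforms[i, ch_idx, , drop = FALSE]
    dim(m) <- c(length(ch_idx), nt)
    colMeans(m)
  }
  for (g in unique(waves$group)) {
    rows <- which(waves$group == g)
    tc <- t(vapply(rows, roi_tc, numeric(nt)))
    out[[g]] <- list(mean = colMeans(tc),
                     sd = apply(tc, 2, stats::sd),
                     subject_tc = tc)
  }
  out
}

# middle index of the run of samples tied (within tol) with the extremum
peak_index <- function(y, tol = 1e-9) {
  m <- max(y)
  runs <- rle(y >= m - tol)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  k <- which(runs$values)[1]
  as.integer(round((starts[k] + ends[k]) / 2))
}

# earliest time where the cumulative trapezoid area of the non-negative,
# piecewise-linear signal r(t) reaches half the total area
half_area_time <- function(t, r) {
  seg <- diff(t) * (r[-length(r)] + r[-1]) / 2
  total <- sum(seg)
  if (total <= 0) return(NA_real_)
  target <- total / 2
  cs <- c(0, cumsum(seg))
  i <- which(cs >= target)[1] - 1L   # crossing inside segment i -> i+1
  if (i < 1) return(t[1])
  a <- target - cs[i]                # area still needed inside the segment
  dt <- t[i + 1] - t[i]
  r0 <- r[i]; s <- (r[i + 1] - r[i]) / dt
  if (abs(s) < 1e-12) {
    tau <- if (r0 > 0) a / r0 else dt
  } else {
    disc <- max(0, r0^2 + 2 * s * a)
    tau <- (-r0 + sqrt(disc)) / s
    if (!is.finite(tau) || tau < 0 || tau > dt) tau <- min(dt, max(0, a / max(r0, 1e-12)))
  }
  t[i] + tau
}

#' Fractional-area latency of a component peak
#'
#' Implements the 50 percent fractional-area latency: the earliest time at
#' which the cumulative area under the (polarity-rectified) peak reaches
#' half of the total peak area, computed on the piecewise-linear signal so
#' the estimate has sub-sample resolution.
#'
#' Integration bounds are the nearest flanking local extrema around the
#' detected peak (or the window edges), which separates overlapping
#' neighboring components inside wide windows. The rectification reference
#' is the higher of the two flanking saddle levels, so only the area the
#' peak rises above its surroundings is counted; for positive components
#' the reference is never below zero, hence an isolated bump on a zero
#' baseline reduces to the plain clip-at-zero rule. For negative
#' components (a trough that may ride on surrounding positivity, as the
#' N200 does between P200 and P300) this integrates the dip area below
#' the flanking ridge level.
#'
#' @param x waveform (uV).
#' @param times time axis, ms.
#' @param window numeric `c(start, end)` search window, ms.
#' @param polarity +1 or -1.
#' @return latency in ms (NA when no area of the correct polarity exists).
#' @export
fractional_area_latency <- function(x, times, window, polarity = 1) {
  win <- which(times >= window[1] & times <= window[2])
  if (length(win) < 3) stop("window too small")
  xv <- x[win]; tv <- times[win]
  y <- polarity * xv
  pk <- peak_index(y)
  # flanking bounds: nearest local minima of y on each side of the peak
  left <- pk
  while (left > 1 && y[left - 1] <= y[left]) left <- left - 1
  right <- pk
  n <- length(y)
  while (right < n && y[right + 1] <= y[right]) right <- right + 1
  idx <- left:right
  # reference level: the higher flanking saddle (for positive components
  # never below zero, so an isolated bump on a zero baseline reduces to
  # the plain clip-at-zero rule)
  ref <- max(y[left], y[right])
  if (polarity >= 0) ref <- max(ref, 0)
  r <- pmax(y[idx] - ref, 0)
  half_area_time(tv[idx], r)
}

#' Measure an ERP component on one waveform
#'
#' Automatic replacement for manual peak inspection: the component peak is
#' the windowed extremum of the stated polarity, the amplitude is the mean
#' of the signal within +/- 10 ms of the peak, and the latency is the
#' 50 percent fractional-area latency ([fractional_area_latency()]). A
#' validity flag marks measures whose extremum sits on the window boundary
#' or whose peak has no area of the correct polarity.
#'
#' @param x waveform (uV), e.g. an ROI-averaged subject ERP.
#' @param times time axis, ms.
#' @param window numeric `c(start, end)` search window, ms.
#' @param polarity +1 (positive peak) or -1 (trough).
#' @param smooth_ms half-width of the amplitude smoothing window (ms).
#' @return list with `amplitude` (uV, signed signal value), `latency`
#'   (ms), `peak_time` (ms) and `valid`.
#' @export
measure_component <- function(x, times, window, polarity = 1,
                              smooth_ms = 10) {
  win <- which(times >= window[1] & times <= window[2])
  if (length(win) < 3) stop("search window lies outside the epoch")
  y <- polarity * x[win]
  pk <- peak_index(y)
  peak_time <- times[win][pk]
  sm <- which(abs(times - peak_time) <= smooth_ms + 1e-9)
  amplitude <- mean(x[sm])
  lat <- fractional_area_latency(x, times, window, polarity)
  valid <- pk > 1 && pk < length(win) && !is.na(lat)
  if (polarity > 0 && max(x[win]) <= 0) valid <- FALSE
  if (is.na(lat)) lat <- peak_time
  list(amplitude = amplitude, latency = lat, peak_time = peak_time,
       valid = valid)
}

#' Component table for all subjects of an epoch set
#'
#' Measures P200, N200 and P300 amplitude and fractional-area latency on
#' each subject's ROI-averaged ERP (the posterior ROI by default;
#' per-channel measures via `channels`).
#'
#' @param waves output of [subject_erps()].
#' @param paradigm paradigm name (selects the component windows, including
#'   the extended ST P300 window).
#' @param roi ROI channel names averaged before measurement; ignored when
#'   `channels` is given.
#' @param channels optional character vector: measure per channel instead
#'   of on the ROI average (rows gain a `channel` column).
#' @param windows component window table, default [component_windows()].
#' @return tidy data.frame: subject, group, paradigm, component,
#'   (channel,) amplitude_uV, latency_ms, valid.
#' @export
measure_components_table <- function(waves, paradigm,
                                     roi = c("P3", "Pz", "P4", "PO3", "PO4"),
                                     channels = NULL,
                                     windows = component_windows(paradigm)) {
  rows <- list()
  sel <- if (is.null(channels)) list(ROI = match(roi, waves$channels)) else
    stats::setNames(as.list(match(channels, waves$channels)), channels)
  for (i in seq_along(waves$subject)) {
    for (chn in names(sel)) {
      ch_idx <- sel[[chn]]
      x <- if (length(ch_idx) > 1) {
        colMeans(waves$waveforms[i, ch_idx, , drop = FALSE][1, , ,
                                                            drop = TRUE])
      } else {
        waves$waveforms[i, ch_idx, ]
      }
      for (k in seq_len(nrow(windows))) {
        m <- measure_component(x, waves$times,
                               c(windows$start_ms[k], windows$end_ms[k]),
                               windows$polarity[k])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = waves$subject[i], group = waves$group[i],
          paradigm = paradigm, component = windows$component[k],
          channel = chn, amplitude_uV = m$amplitude,
          latency_ms = m$latency, valid = m$valid,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pointwise group comparison of ERP time courses
#'
#' Welch t statistic at every time point between the per-subject ROI time
#' courses of two groups, enhanced by 1-D TFCE with family-wise permutation
#' p-values; significant spans are reported as time intervals.
#'
#' @param waves output of [subject_erps()] containing both groups.
#' @param roi ROI channel names.
#' @param groups character vector of length 2, default `c("PRO",
#'   "NOVICE")` (the t map is group 1 minus group 2).
#' @param n_perm,seed,alpha passed to [tfce_perm_test()].
#' @return `stat_result` with an extra `spans` data.frame (ms intervals)
#'   and `times`.
#' @export
compare_groups_pointwise <- function(waves, roi = c("P3", "Pz", "P4",
                                                    "PO3", "PO4"),
                                     groups = c("PRO", "NOVICE"),
                                     n_perm = 1000, seed = NULL,
                                     alpha = 0.05) {
  ga <- grand_average(waves, roi)
  if (!all(groups %in% names(ga))) stop("need >= 2 subjects per group")
  A <- ga[[groups[1]]]$subject_tc
  B <- ga[[groups[2]]]$subject_tc
  res <- tfce_perm_test(A, B, n_perm = n_perm, seed = seed, alpha = alpha)
  res$times <- waves$times
  res$spans <- significant_spans(res$mask, waves$times)
  res
}
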