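#' Simulation configuration
#'
#' Collects the knobs of the synthetic EEG / cognitive-log generator. The
#' defaults are the study conditions this pipeline models: 10 subjects per
#' group, a 32-channel 10-20 montage sampled at 250 Hz, pink (1/f)
#' background noise and a posterior ~10 Hz alpha oscillation. The seed fully
#' determines the generator output.
#'
#' @param n_subjects_per_group subjects per group (default 10).
#' @param srate sampling rate in Hz (default 250).
#' @param noise_exponent spectral exponent of the 1/f background.
#' @param noise_amplitude RMS amplitude of the background, uV.
#' @param alpha_freq,alpha_bw alpha center frequency and bandwidth, Hz.
#' @param alpha_amplitude alpha oscillation amplitude, uV (scaled per group
#'   by the profile's `alpha_power_scale`, on the power scale).
#' @param outlier_frac fraction of cognitive-test trials replaced by
#'   out-of-threshold reaction times (exercises the filtering stage).
#' @param attrition fraction of epochs pre-marked rejected (emulates
#'   artifact attrition; default 0).
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects_per_group = 10, srate = 250,
                       noise_exponent = 1, noise_amplitude = 5,
                       alpha_freq = 10, alpha_bw = 2, alpha_amplitude = 4,
                       outlier_frac = 0.02, attrition = 0, seed = 1) {
  stopifnot(n_subjects_per_group >= 1, srate > 0, noise_amplitude >= 0,
            alpha_amplitude >= 0, outlier_frac >= 0, outlier_frac <= 1,
            attrition >= 0, attrition < 1)
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 srate = srate, noise_exponent = noise_exponent,
                 noise_amplitude = noise_amplitude, alpha_freq = alpha_freq,
                 alpha_bw = alpha_bw, alpha_amplitude = alpha_amplitude,
                 outlier_frac = outlier_frac, attrition = attrition,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default group profiles calibrated to the reference statistics
#'
#' Returns PRO and NOVICE generator profiles whose ERP component
#' means/SDs equal [erp_reference_stats()] and whose cognitive-test
#' parameters equal [cognitive_reference_stats()]. The PRO profile carries
#' a 2x alpha power scale (professionals exhibit stronger stimulus-locked
#' alpha power) and the hours-in-game feature (five players with
#' 1800-5000 h, five with 5000-8000 h).
#'
#' @return named list with elements `PRO` and `NOVICE`; each a list with
#'   `group`, `erp` (data.frame paradigm/component/amp_mean/amp_sd/
#'   lat_mean/lat_sd), `alpha_power_scale`, `cognitive` (named list) and,
#'   for PRO, `hours_in_game`.
#' @export
default_group_profiles <- function() {
  ref <- erp_reference_stats()
  cog <- cognitive_reference_stats()
  pull <- function(test, metric, col) {
    cog[cog$test == test & cog$metric == metric, col]
  }
  mk_cog <- function(side) {
    m <- paste0(side, "_mean"); s <- paste0(side, "_sd")
    list(
      rtm = c(mean = pull("RTM", "reaction_time", m),
              sd = pull("RTM", "reaction_time", s)),
      rtk = c(mean = pull("RTK", "reaction_time", m),
              sd = pull("RTK", "reaction_time", s)),
      rtd = c(mean = pull("RTD", "reaction_time_correct", m),
              sd = pull("RTD", "reaction_time_correct", s)),
      rtd_correct_rate = pull("RTD", "correct_rate", m),
      vs_correct_rate = pull("VS", "correct_rate", m),
      vs_search_L = c(mean = pull("VS", "search_time_L", m),
                      sd = pull("VS", "search_time_L", s)),
      vs_search_noL = c(mean = pull("VS", "search_time_noL", m),
                        sd = pull("VS", "search_time_noL", s)),
      mt_count_error = c(mean = pull("MT", "count_error", m),
                         sd = pull("MT", "count_error", s)),
      st_count_error = c(mean = pull("ST", "count_error", m),
                         sd = pull("ST", "count_error", s))
    )
  }
  mk_erp <- function(side) {
    data.frame(paradigm = ref$paradigm, component = ref$component,
               amp_mean = ref[[paste0("amp_", side, "_mean")]],
               amp_sd = ref[[paste0("amp_", side, "_sd")]],
               lat_mean = ref[[paste0("lat_", side, "_mean")]],
               lat_sd = ref[[paste0("lat_", side, "_sd")]],
               stringsAsFactors = FALSE)
  }
  list(
    PRO = list(group = "PRO", erp = mk_erp("pro"), alpha_power_scale = 2,
               cognitive = mk_cog("pro"),
               hours_in_game = seq(1800, 8000, length.out = 10)),
    NOVICE = list(group = "NOVICE", erp = mk_erp("novice"),
                  alpha_power_scale = 1, cognitive = mk_cog("novice"))
  )
}

#' Shrink the between-subject SDs of a profile pair
#'
#' Convenience for parameter-recovery experiments: multiplies all ERP
#' amplitude/latency SDs (and optionally cognitive SDs) by `factor`.
#'
#' @param profiles profile pair as from [default_group_profiles()].
#' @param factor multiplicative factor (e.g. 0.1).
#' @return modified profile pair.
#' @export
scale_profile_sds <- function(profiles, factor) {
  for (g in names(profiles)) {
    profiles[[g]]$erp$amp_sd <- profiles[[g]]$erp$amp_sd * factor
    profiles[[g]]$erp$lat_sd <- profiles[[g]]$erp$lat_sd * factor
    for (nm in c("rtm", "rtk", "rtd", "vs_search_L", "vs_search_noL",
                 "mt_count_error", "st_count_error")) {
      profiles[[g]]$cognitive[[nm]]["sd"] <-
        profiles[[g]]$cognitive[[nm]]["sd"] * factor
    }
  }
  profiles
}

# order the three component latencies and keep them physiologically apart
clamp_latencies <- function(L) {
  L[1] <- max(L[1], 110)
  L[2] <- max(L[2], L[1] + 20)
  L[3] <- max(L[3], L[2] + 30)
  L
}

# Monotone (Fritsch-Carlson) cubic Hermite interpolation. Guaranteed
# monotone on every knot interval -- stats::splinefun's "monoH.FC" can
# over/undershoot between knots with strongly asymmetric flanking slopes,
# which would plant spurious extrema in the ERP waveform.
mono_hermite <- function(xk, yk, xout) {
  n <- length(xk)
  h <- diff(xk)
  d <- diff(yk) / h
  m <- numeric(n)
  for (i in 2:(n - 1)) {
    m[i] <- if (d[i - 1] * d[i] <= 0) 0 else (d[i - 1] + d[i]) / 2
  }
  m[1] <- d[1]
  m[n] <- d[n - 1]
  for (i in seq_len(n - 1)) {
    if (d[i] == 0) {
      m[i] <- 0
      m[i + 1] <- 0
    } else {
      a <- m[i] / d[i]
      b <- m[i + 1] / d[i]
      s <- a^2 + b^2
      if (s > 9) {
        f <- 3 / sqrt(s)
        m[i] <- f * a * d[i]
        m[i + 1] <- f * b * d[i]
      }
    }
  }
  j <- findInterval(xout, xk, rightmost.closed = TRUE, all.inside = TRUE)
  t <- (xout - xk[j]) / h[j]
  yk[j] * (1 + 2 * t) * (1 - t)^2 + h[j] * m[j] * t * (1 - t)^2 +
    yk[j + 1] * t^2 * (3 - 2 * t) + h[j] * m[j + 1] * t^2 * (t - 1)
}

# ERP waveform through extremum knots: zero baseline, a 60 ms rise into
# the P200 peak, the N200 trough, the P300 peak and a 100 ms decay,
# interpolated with a monotone Hermite spline so every knot is an exact
# local extremum with the planted value. When the N200-P300 gap is wide
# (late P300, as in the ST paradigm) a small recovery hump and valley are
# inserted between them, which localizes the late positive deflection the
# way real visual-search ERPs do.
erp_waveform <- function(times_ms, L, A, vfrac = 0.15, use_hump = NULL) {
  k_t <- c(min(times_ms) - 10, 0, max(4, L[1] - 60), L[1], L[2], L[3],
           L[3] + 100, max(times_ms) + 10)
  k_v <- c(0, 0, 0, A[1], A[2], A[3], 0, 0)
  if (is.null(use_hump)) {
    use_hump <- L[3] - L[2] > 90 && A[3] > A[2] && A[1] - A[2] > 2.5
  }
  if (use_hump) {
    # recovery hump below the P200 peak (so it can never become the
    # windowed P200 extremum), well below the P300 (so trial-jitter
    # smoothing of the P300 can never let the hump win its windowed
    # extremum), and valley safely above the N200 trough
    hump <- min(A[2] + 0.45 * (A[3] - A[2]), A[2] + 0.7 * (A[1] - A[2]),
                A[3] - 1.5)
    hump <- max(hump, A[2] + 0.25)  # keep the knot sequence valid under
                                    # per-trial jitter of a fixed geometry
    # valley sits shortly before the late positivity so the P300 rises
    # over a compact flank comparable to its decay
    t_valley <- max(L[2] + 0.45 * (L[3] - L[2]), L[3] - 80)
    t_hump <- min(L[2] + 0.27 * (L[3] - L[2]), t_valley - 15)
    if (t_valley > 330) {
      # valley outside the N200 search window: it may dip below the
      # trough, giving even a weak late P300 a well-defined prominence
      valley <- max(0, min(A[2], A[3]) * 0.55)
    } else {
      valley <- min(A[2] + vfrac * (A[3] - A[2]), A[2] + 0.8 * (hump - A[2]))
      valley <- max(valley, A[2] + 0.3)
    }
    valley <- min(valley, hump - 0.05)
    k_t <- c(k_t, t_hump, t_valley)
    k_v <- c(k_v, hump, valley)
  }
  o <- order(k_t)
  k_t <- k_t[o]; k_v <- k_v[o]
  keep <- !duplicated(k_t)
  mono_hermite(k_t[keep], k_v[keep], times_ms)
}

# Self-calibration: shift the knots until the *measured* smoothed
# amplitude and fractional-area latency of each component equal the
# targets (decaying-step fixed point; the reference statistics are
# themselves measured quantities, so planting them requires inverting the
# measurement).
calibrate_erp_knots <- function(times_ms, lat_target, amp_target, windows,
                                iters = 40) {
  L <- clamp_latencies(lat_target)
  A <- amp_target
  vfrac <- 0.15
  best <- list(L = L, A = A, vfrac = vfrac, err = Inf)
  for (i in seq_len(iters)) {
    step <- 0.7 / i^0.55
    wf <- erp_waveform(times_ms, L, A, vfrac)
    err <- 0
    dL <- numeric(3); dA <- numeric(3)
    for (k in 1:3) {
      m <- measure_component(wf, times_ms,
                             c(windows$start_ms[k], windows$end_ms[k]),
                             windows$polarity[k])
      if (is.finite(m$latency) && m$valid) {
        dL[k] <- lat_target[k] - m$latency
        err <- err + abs(dL[k])
      } else {
        err <- err + 30  # collapsed/edge extremum: heavily penalized
      }
      dA[k] <- amp_target[k] - m$amplitude
      err <- err + 4 * abs(dA[k])
    }
    if (err < best$err) best <- list(L = L, A = A, vfrac = vfrac, err = err)
    L <- clamp_latencies(L + step * dL)
    A <- A + step * dA
    # valley depth is a second control for the late-P300 area balance;
    # the valley must stay above the N200 value so the windowed N200
    # extremum is never displaced
    vfrac <- min(0.45, max(0.12, vfrac + 0.01 * step / 0.7 * dL[3]))
  }
  list(L = best$L, A = best$A, vfrac = best$vfrac)
}

# m columns of length-n 1/f noise, each normalized to RMS `amp`
one_over_f_noise <- function(n, m, exponent, amp) {
  if (amp == 0 || m == 0) return(matrix(0, n, m))
  nf <- n %/% 2
  freqs <- seq_len(nf)
  scale <- freqs^(-exponent / 2)
  re <- matrix(stats::rnorm(nf * m), nf, m) * scale
  im <- matrix(stats::rnorm(nf * m), nf, m) * scale
  spec <- matrix(0 + 0i, n, m)
  spec[1 + freqs, ] <- complex(real = re, imaginary = im)
  # hermitian symmetry for a real series
  spec[n + 1 - freqs[freqs < n - nf + 1], ] <- Conj(spec[1 + freqs[freqs < n - nf + 1], ])
  if (n %% 2 == 0) spec[nf + 1, ] <- complex(real = re[nf, ], imaginary = 0)
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  sds <- sqrt(pmax(colMeans(x^2) - colMeans(x)^2, 1e-300))
  sweep(x, 2, amp / sds, "*")
}

#' Simulate an epoched oddball EEG data set
#'
#' Generates a two-group epoched EEG set for one paradigm. Target epochs
#' carry the P200/N200/P300 component structure: per subject, component
#' amplitudes and latencies are drawn once from the group profile
#' (between-subject variability) and turned into extremum knots of a
#' monotone-spline ERP waveform (the N200 forms a trough between the
#' positive P200/P300 peaks, as in real ERPs where the N200 value rides on
#' neighboring positivity); the knots are self-calibrated so the measured
#' smoothed amplitude and fractional-area latency of the noiseless
#' waveform equal the drawn values. Each trial adds Gaussian jitter with
#' 1/3 of the between-subject SD to the knots. The component topography is
#' a posterior-weighted spatial pattern normalized so the mean over the
#' P3/Pz/P4/PO3/PO4 ROI equals 1. All epochs carry 1/f background noise
#' and a posterior alpha oscillation whose power is scaled by the group's
#' `alpha_power_scale`.
#'
#' @param config [sim_config()].
#' @param paradigm one of `"B/RB"`, `"BT"`, `"MT"`, `"ST"`.
#' @param profiles profile pair as from [default_group_profiles()].
#' @param targets_only generate only target epochs (saves time and memory
#'   for ERP-only analyses).
#' @return An `epoch_set`: list with `data` (channels x time x trials, uV),
#'   `srate`, `times` (ms, stimulus at 0), `channels`, `montage`, `labels`
#'   (data.frame subject, group, target, trial) and `rejected`.
#' @export
simulate_epochs <- function(config = sim_config(), paradigm = "ST",
                            profiles = default_group_profiles(),
                            targets_only = FALSE) {
  spec <- paradigm_specs()
  row <- spec[spec$paradigm == paradigm, ]
  if (nrow(row) != 1) stop("unknown paradigm: ", paradigm)
  validate_profiles(profiles, paradigm)
  srate <- config$srate
  n_samp_pre <- row$pre_ms / 1000 * srate
  n_samp_post <- row$post_ms / 1000 * srate
  if (abs(n_samp_pre - round(n_samp_pre)) > 1e-9 ||
      abs(n_samp_post - round(n_samp_post)) > 1e-9) {
    stop("sampling rate and epoch span yield non-integer sample counts")
  }
  times <- seq(-row$pre_ms, row$post_ms, by = 1000 / srate)
  nt <- length(times)
  mont <- standard_montage()
  nch <- nrow(mont)
  roi <- c("P3", "Pz", "P4", "PO3", "PO4")
  cen <- colMeans(mont[mont$channel %in% roi, c("x", "y")])
  d2 <- (mont$x - cen[1])^2 + (mont$y - cen[2])^2
  w <- exp(-d2 / (2 * 45^2))
  w_comp <- w / mean(w[mont$channel %in% roi])  # ROI mean of pattern = 1
  # occipital alpha spreads more broadly than the evoked components and
  # remains clearly visible at the vertex
  w_alpha <- exp(-d2 / (2 * 80^2))
  w_alpha <- w_alpha / max(w_alpha)

  nsub <- config$n_subjects_per_group
  ntar <- row$n_targets
  nnon <- if (targets_only) 0L else row$n_nontargets
  ntr_sub <- ntar + nnon
  ntr <- 2L * nsub * ntr_sub
  set.seed(config$seed)
  data <- array(0, dim = c(nch, nt, ntr))
  subject <- character(ntr); group <- character(ntr)
  target <- logical(ntr)
  wins <- component_windows(paradigm)
  truth <- list()
  tr0 <- 0L
  for (g in c("PRO", "NOVICE")) {
    prof <- profiles[[g]]
    erp <- prof$erp[prof$erp$paradigm == paradigm, ]
    erp <- erp[match(c("P200", "N200", "P300"), erp$component), ]
    alpha_amp_g <- config$alpha_amplitude * sqrt(prof$alpha_power_scale)
    for (s in seq_len(nsub)) {
      sid <- sprintf("%s%02d", ifelse(g == "PRO", "PRO", "NOV"), s)
      lat_s <- sort(stats::rnorm(3, erp$lat_mean, erp$lat_sd))
      amp_s <- stats::rnorm(3, erp$amp_mean, erp$amp_sd)
      # physiological shape: the P200/P300 peaks stay positive and the
      # N200 remains a genuine trough between them (the reference
      # amplitudes are measured trough values, always below both peaks)
      amp_s[c(1, 3)] <- pmax(amp_s[c(1, 3)], 0.5)
      amp_s[2] <- min(amp_s[2], min(amp_s[1], amp_s[3]) - 1)
      knots <- calibrate_erp_knots(times, lat_s, amp_s, wins)
      # geometry decided once per subject; per-trial jitter must not flip
      # the hump/valley branch or the averaged ERP smears into a plateau
      use_hump <- knots$L[3] - knots$L[2] > 90 && knots$A[3] > knots$A[2] &&
        knots$A[1] - knots$A[2] > 2.5
      alpha_amp_s <- alpha_amp_g * stats::rlnorm(1, 0, 0.15)
      truth[[length(truth) + 1L]] <- data.frame(
        subject = sid, group = g, component = c("P200", "N200", "P300"),
        latency_ms = clamp_latencies(lat_s), amplitude_uV = amp_s,
        alpha_amp = alpha_amp_s, stringsAsFactors = FALSE)
      idx <- tr0 + seq_len(ntr_sub)
      subject[idx] <- sid; group[idx] <- g
      target[idx] <- c(rep(TRUE, ntar), rep(FALSE, nnon))
      noise <- one_over_f_noise(nt, ntr_sub * nch, config$noise_exponent,
                                config$noise_amplitude)
      blk <- array(noise, dim = c(nt, nch, ntr_sub))
      # posterior alpha oscillation, coherent across channels within a trial
      if (alpha_amp_s > 0) {
        f_tr <- stats::rnorm(ntr_sub, config$alpha_freq, config$alpha_bw / 2)
        ph_tr <- stats::runif(ntr_sub, 0, 2 * pi)
        for (tr in seq_len(ntr_sub)) {
          a <- alpha_amp_s * cos(2 * pi * f_tr[tr] * times / 1000 + ph_tr[tr])
          blk[, , tr] <- blk[, , tr] + outer(a, w_alpha)
        }
      }
      for (tr in seq_len(ntar)) {
        lat_tr <- clamp_latencies(knots$L + stats::rnorm(3, 0, erp$lat_sd / 3))
        amp_tr <- knots$A + stats::rnorm(3, 0, erp$amp_sd / 3)
        amp_tr[c(1, 3)] <- pmax(amp_tr[c(1, 3)], 0.3)
        amp_tr[2] <- min(amp_tr[2], min(amp_tr[1], amp_tr[3]) - 0.8)
        wf <- erp_waveform(times, lat_tr, amp_tr, knots$vfrac, use_hump)
        blk[, , tr] <- blk[, , tr] + outer(wf, w_comp)
      }
      data[, , idx] <- aperm(blk, c(2, 1, 3))
      tr0 <- tr0 + ntr_sub
    }
  }
  rejected <- if (config$attrition > 0) {
    stats::runif(ntr) < config$attrition
  } else {
    rep(FALSE, ntr)
  }
  e <- epoch_set(data, srate, times, mont,
                 data.frame(subject = subject, group = group,
                            target = target, trial = seq_len(ntr),
                            stringsAsFactors = FALSE),
                 rejected)
  e$truth <- do.call(rbind, truth)
  e
}

validate_profiles <- function(profiles, paradigm) {
  for (g in c("PRO", "NOVICE")) {
    erp <- profiles[[g]]$erp
    erp <- erp[erp$paradigm == paradigm, ]
    if (nrow(erp) != 3) stop("profile for ", g, " does not cover ", paradigm)
    if (any(erp$amp_sd < 0) || any(erp$lat_sd < 0)) stop("negative SD")
    lm <- erp$lat_mean[match(c("P200", "N200", "P300"), erp$component)]
    if (is.unsorted(lm, strictly = TRUE)) {
      stop("component mean latencies must be ordered P200 < N200 < P300")
    }
  }
  invisible(TRUE)
}

#' Construct an epoch set container
#'
#' @param data numeric array channels x time x trials (uV).
#' @param srate sampling rate, Hz.
#' @param times time axis in ms relative to stimulus onset.
#' @param montage montage data.frame ([standard_montage()] layout).
#' @param labels data.frame with one row per trial (columns `subject`,
#'   `group`, `target`, `trial`).
#' @param rejected logical rejection mask, one per trial.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, srate, times, montage, labels,
                      rejected = rep(FALSE, dim(data)[3])) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == nrow(montage),
            dim(data)[2] == length(times), dim(data)[3] == nrow(labels),
            length(rejected) == nrow(labels))
  structure(list(data = data, srate = srate, times = times,
                 channels = montage$channel, montage = montage,
                 labels = labels, rejected = rejected),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1], " channels x ", d[2], " samples x ", d[3],
      " trials @ ", x$srate, " Hz; ", sum(x$rejected), " rejected\n",
      sep = "")
  invisible(x)
}

#' Keep a subset of trials of an epoch set
#'
#' @param e epoch_set.
#' @param keep logical or integer trial index.
#' @return epoch_set restricted to the selected trials.
#' @export
subset_epochs <- function(e, keep) {
  epoch_set(e$data[, , keep, drop = FALSE], e$srate, e$times, e$montage,
            e$labels[keep, , drop = FALSE], e$rejected[keep])
}

# shifted-lognormal parameters matched to mean/sd of the shifted part
shifted_lognorm_draw <- function(n, mean, sd, shift = 100) {
  m <- mean - shift
  if (sd <= 0 || m <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + sd^2 / m^2))
  meanlog <- log(m) - sdlog^2 / 2
  shift + stats::rlnorm(n, meanlog, sdlog)
}

#' Simulate cognitive-test trial logs
#'
#' Produces one row per trial for the reaction-time tests (RTM, RTK, RTD:
#' 30 trials each) and the visual-search test (VS: 20 trials, half with the
#' target letter present), plus one counted-targets row per subject for the
#' MT and ST oddball blocks. Reaction times follow a shifted lognormal
#' (100 ms shift) matched to the profile mean/SD; correctness is Bernoulli
#' with the profile correct rate; a configurable fraction of RT trials is
#' replaced by out-of-threshold values to exercise filtering.
#'
#' @param config [sim_config()].
#' @param profiles profile pair as from [default_group_profiles()].
#' @param n_rt_trials trials per reaction-time test (default 30).
#' @param n_vs_trials trials in the visual-search test (default 20).
#' @return data.frame with columns `subject_id`, `group`, `test`, `trial`,
#'   `rt_ms`, `stimulus`, `response`, `correct`, `counted`, `true_count`,
#'   `hours_in_game`.
#' @export
simulate_cognitive_log <- function(config = sim_config(),
                                   profiles = default_group_profiles(),
                                   n_rt_trials = 30, n_vs_trials = 20) {
  set.seed(config$seed + 10007L)
  spec <- paradigm_specs()
  true_counts <- c(MT = spec$n_targets[spec$paradigm == "MT"],
                   ST = spec$n_targets[spec$paradigm == "ST"])
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  for (g in c("PRO", "NOVICE")) {
    prof <- profiles[[g]]
    cg <- prof$cognitive
    for (p in c(cg$rtd_correct_rate, cg$vs_correct_rate)) {
      if (p < 0 || p > 100) stop("correct-rate probability outside [0, 100]")
    }
    for (s in seq_len(config$n_subjects_per_group)) {
      sid <- sprintf("%s%02d", ifelse(g == "PRO", "PRO", "NOV"), s)
      hours <- if (g == "PRO") prof$hours_in_game[s] else NA_real_
      outlier <- function(rt) {
        bad <- stats::runif(length(rt)) < config$outlier_frac
        rt[bad] <- sample(c(stats::runif(sum(bad), 40, 110),
                            stats::runif(sum(bad), 900, 2500)),
                          sum(bad))
        rt
      }
      for (test in c("RTM", "RTK")) {
        par <- if (test == "RTM") cg$rtm else cg$rtk
        rt <- outlier(shifted_lognorm_draw(n_rt_trials, par["mean"],
                                           par["sd"]))
        add(data.frame(subject_id = sid, group = g, test = test,
                       trial = seq_len(n_rt_trials), rt_ms = rt,
                       stimulus = "go",
                       response = ifelse(test == "RTM", "click", "key"),
                       correct = TRUE, counted = NA_integer_,
                       true_count = NA_integer_, hours_in_game = hours,
                       stringsAsFactors = FALSE))
      }
      stim <- sample(c("red", "blue"), n_rt_trials, replace = TRUE)
      ok <- stats::runif(n_rt_trials) < cg$rtd_correct_rate / 100
      resp <- ifelse(ok, ifelse(stim == "red", "left", "right"),
                     ifelse(stim == "red", "right", "left"))
      rt <- outlier(shifted_lognorm_draw(n_rt_trials, cg$rtd["mean"],
                                         cg$rtd["sd"]))
      add(data.frame(subject_id = sid, group = g, test = "RTD",
                     trial = seq_len(n_rt_trials), rt_ms = rt,
                     stimulus = stim, response = resp, correct = ok,
                     counted = NA_integer_, true_count = NA_integer_,
                     hours_in_game = hours, stringsAsFactors = FALSE))
      half <- n_vs_trials %/% 2
      cond <- sample(rep(c("L", "no L"), c(half, n_vs_trials - half)))
      ok <- stats::runif(n_vs_trials) < cg$vs_correct_rate / 100
      st <- ifelse(cond == "L",
                   shifted_lognorm_draw(n_vs_trials, cg$vs_search_L["mean"] *
                                          1000, cg$vs_search_L["sd"] * 1000,
                                        shift = 0),
                   shifted_lognorm_draw(n_vs_trials,
                                        cg$vs_search_noL["mean"] * 1000,
                                        cg$vs_search_noL["sd"] * 1000,
                                        shift = 0))
      add(data.frame(subject_id = sid, group = g, test = "VS",
                     trial = seq_len(n_vs_trials), rt_ms = st,
                     stimulus = cond,
                     response = ifelse(ok, cond,
                                       ifelse(cond == "L", "no L", "L")),
                     correct = ok, counted = NA_integer_,
                     true_count = NA_integer_, hours_in_game = hours,
                     stringsAsFactors = FALSE))
      for (par in c("MT", "ST")) {
        ce <- cg[[paste0(tolower(par), "_count_error")]]
        err <- stats::rnorm(1, ce["mean"], ce["sd"])
        counted <- as.integer(round(true_counts[[par]] * (1 + err / 100)))
        add(data.frame(subject_id = sid, group = g, test = par, trial = 1L,
                       rt_ms = NA_real_, stimulus = "count",
                       response = "count", correct = NA,
                       counted = counted, true_count = true_counts[[par]],
                       hours_in_game = hours, stringsAsFactors = FALSE))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
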