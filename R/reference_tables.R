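#' Oddball paradigm specifications
#'
#' The four stimulus paradigms of the expertise study design: a non-specific
#' blue/red-ball oddball (B/RB) and three game-screenshot paradigms with an
#' enemy character of decreasing size (BT, MT, ST: big, medium and small
#' "terrors"). Timing and trial counts are the study defaults; epoch spans
#' are 800 ms (200 ms pre-stimulus) for B/RB and 1400 ms (500 ms
#' pre-stimulus) for the game paradigms.
#'
#' @return data.frame with columns `paradigm`, `stimulus_duration_s`,
#'   `blank_duration_s`, `n_targets`, `n_nontargets`, `pre_ms`, `post_ms`.
#' @export
paradigm_specs <- function() {
  data.frame(
    paradigm = c("B/RB", "BT", "MT", "ST"),
    stimulus_duration_s = c(0.25, 0.4, 0.4, 0.8),
    blank_duration_s = c(0.5, 1, 1, 1),
    n_targets = c(60L, 40L, 40L, 56L),
    n_nontargets = c(240L, 260L, 260L, 168L),
    pre_ms = c(200, 500, 500, 500),
    post_ms = c(600, 900, 900, 900),
    stringsAsFactors = FALSE
  )
}

#' Reaction-time validity thresholds
#'
#' Physiologically motivated lower/upper reaction-time bounds applied before
#' the interquartile-range outlier fence: 120-500 ms for the simple
#' reaction-time tests (mouse and keyboard) and 140-700 ms for the choice
#' reaction-time test.
#'
#' @return data.frame with columns `test`, `min_ms`, `max_ms`.
#' @export
rt_thresholds <- function() {
  data.frame(
    test = c("RTM", "RTK", "RTD"),
    min_ms = c(120, 120, 140),
    max_ms = c(500, 500, 700),
    stringsAsFactors = FALSE
  )
}

#' Reference cognitive-test group statistics
#'
#' Published group-level summaries (mean, SD, group metric size) of the
#' cognitive tests for professional (PRO) and novice (NOVICE) CS:GO
#' players. These values calibrate the synthetic cognitive-log generator
#' and support worked-example recomputation of the group statistics
#' (Welch t, permutation p, Hedges' g) from summaries alone.
#'
#' `level` distinguishes trial-level metrics (pooled across subjects after
#' filtering) from per-subject "complex" metrics that contribute one value
#' per subject (n = 10 per group).
#'
#' @return data.frame with columns `test`, `metric`, `level`,
#'   `pro_mean`, `pro_sd`, `novice_mean`, `novice_sd`, `unit`.
#' @export
cognitive_reference_stats <- function() {
  data.frame(
    test = c("RTM", "RTK", "RTD", "RTD", "VS", "VS", "VS", "VS", "MT", "ST"),
    metric = c("reaction_time", "reaction_time", "reaction_time_correct",
               "correct_rate", "final_score", "search_time_L",
               "search_time_noL", "correct_rate", "count_error",
               "count_error"),
    level = c("trial", "trial", "trial", "subject", "subject", "trial",
              "trial", "subject", "subject", "subject"),
    pro_mean = c(219, 242, 332, 88.3, 16.90, 2.53, 5.16, 87.2, -0.3, 0.4),
    pro_sd = c(32, 35, 74, 3.2, 6.05, 1.73, 2.52, 6.7, 0.8, 4.8),
    novice_mean = c(271, 267, 396, 89.7, 19.10, 2.33, 5.22, 92.0, 0, -7.3),
    novice_sd = c(61, 33, 92, 7.8, 6.37, 1.26, 3.74, 6.0, 1.7, 5.7),
    unit = c("ms", "ms", "ms", "%", "score", "s", "s", "%", "%", "%"),
    stringsAsFactors = FALSE
  )
}

#' Reference ERP component group statistics
#'
#' Published per-group means and SDs of P200/N200/P300 amplitude (uV) and
#' fractional-area latency (ms) over the posterior ROI, per paradigm, for
#' professional and novice players. These values calibrate the synthetic
#' EEG generator's component profiles. The ST P300 is the maximal positive
#' deflection during the (long) stimulus presentation rather than a
#' classical 300 ms component, hence its late latency.
#'
#' @return data.frame with columns `paradigm`, `component`, `lat_pro_mean`,
#'   `lat_pro_sd`, `lat_novice_mean`, `lat_novice_sd`, `amp_pro_mean`,
#'   `amp_pro_sd`, `amp_novice_mean`, `amp_novice_sd`.
#' @export
erp_reference_stats <- function() {
  df <- data.frame(
    paradigm = rep(c("B/RB", "BT", "MT", "ST"), each = 3),
    component = rep(c("P200", "N200", "P300"), times = 4),
    lat_pro_mean = c(177, 221, 335, 187, 228, 324, 195, 245, 347,
                     209, 273, 493),
    lat_pro_sd = c(22, 19, 29, 15, 27, 25, 12, 34, 25, 22, 31, 52),
    lat_novice_mean = c(208, 250, 361, 209, 261, 362, 217, 278, 389,
                        222, 289, 568),
    lat_novice_sd = c(20, 20, 13, 14, 20, 22, 14, 24, 17, 15, 20, 32),
    amp_pro_mean = c(6.78, 1.35, 10.66, 13.64, 11.22, 21.44,
                     14.29, 10.04, 21.84, 17.30, 10.90, 15.87),
    amp_pro_sd = c(4.08, 4.57, 2.83, 4.84, 5.41, 6.78,
                   2.97, 4.05, 6.11, 3.78, 3.82, 5.40),
    amp_novice_mean = c(4.84, 1.42, 9.28, 10.42, 6.65, 14.68,
                        8.41, 5.22, 13.48, 9.91, 4.69, 7.75),
    amp_novice_sd = c(2.63, 2.79, 3.38, 5.19, 5.78, 5.49,
                      3.24, 3.21, 3.54, 4.44, 4.23, 3.16),
    stringsAsFactors = FALSE
  )
  df
}

#' Default ERP component search windows
#'
#' Search windows (ms post-stimulus) for the automatic windowed-extremum
#' component measurement: P200 150-250 ms, N200 200-320 ms, P300
#' 280-450 ms. For the ST paradigm the P300 window extends from 350 ms to
#' the end of the stimulus (800 ms), because with a demanding visual-search
#' stimulus the maximal positive deflection occurs well after 300 ms.
#'
#' @param paradigm paradigm name (ST gets the extended P300 window).
#' @return data.frame with columns `component`, `polarity` (+1/-1),
#'   `start_ms`, `end_ms`.
#' @export
component_windows <- function(paradigm = "B/RB") {
  w <- data.frame(
    component = c("P200", "N200", "P300"),
    polarity = c(1, -1, 1),
    start_ms = c(150, 200, 280),
    end_ms = c(250, 320, 450),
    stringsAsFactors = FALSE
  )
  if (identical(paradigm, "ST")) {
    w$start_ms[w$component == "P300"] <- 350
    w$end_ms[w$component == "P300"] <- 800
  }
  w
}
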