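#' Filter one subject's reaction times
#'
#' Two-stage per-subject filtering: first the physiological validity
#' thresholds (test-specific min/max RT), then a 1.5-IQR outlier fence
#' (Q1 - 1.5 IQR, Q3 + 1.5 IQR) computed on the threshold-surviving
#' values. The order matters: gross out-of-range values never enter the
#' quartile estimates.
#'
#' @param rt_ms numeric reaction times, ms.
#' @param min_ms,max_ms validity thresholds, ms.
#' @param iqr_fence apply the IQR fence (TRUE for RT metrics).
#' @return list: `kept` (surviving values), `n_threshold_removed`,
#'   `n_iqr_removed`.
#' @export
filter_rts <- function(rt_ms, min_ms, max_ms, iqr_fence = TRUE) {
  ok <- rt_ms >= min_ms & rt_ms <= max_ms
  kept <- rt_ms[ok]
  n_iqr <- 0L
  if (iqr_fence && length(kept) >= 4) {
    q <- stats::quantile(kept, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    inside <- kept >= q[1] - 1.5 * iqr & kept <= q[2] + 1.5 * iqr
    n_iqr <- sum(!inside)
    kept <- kept[inside]
  }
  list(kept = kept, n_threshold_removed = sum(!ok), n_iqr_removed = n_iqr)
}

#' Percentage of correct responses
#'
#' @param correct logical vector of per-trial correctness.
#' @return percentage in [0, 100].
#' @export
correct_rate <- function(correct) {
  if (length(correct) == 0) stop("zero responses")
  100 * mean(correct)
}

#' Visual-search test metrics
#'
#' Final score (+1 per right answer, -1 per wrong answer), correct rate,
#' and search times restricted to correct answers, split by target-present
#' ("L") and target-absent ("no L") condition.
#'
#' @param trials data.frame with columns `stimulus` ("L"/"no L"),
#'   `correct`, `rt_ms` (search time in ms).
#' @return list: `final_score`, `correct_rate`, `search_L_s`,
#'   `search_noL_s` (seconds, correct trials only).
#' @export
vs_metrics <- function(trials) {
  list(final_score = sum(trials$correct) - sum(!trials$correct),
       correct_rate = correct_rate(trials$correct),
       search_L_s = trials$rt_ms[trials$correct &
                                   trials$stimulus == "L"] / 1000,
       search_noL_s = trials$rt_ms[trials$correct &
                                     trials$stimulus == "no L"] / 1000)
}

#' Signed target-count error
#'
#' Percentage deviation of the counted number of target stimuli from the
#' true target count: `100 * (counted - true_count) / true_count`.
#'
#' @param counted,true_count integer scalars or vectors.
#' @return signed percentage.
#' @export
count_error <- function(counted, true_count) {
  if (any(true_count <= 0)) stop("true_count must be positive")
  100 * (counted - true_count) / true_count
}

#' Group metrics from a cognitive log
#'
#' Computes every assessment metric per group: pooled trial-level reaction
#' times (RTM, RTK; RTD correct trials only) after per-subject
#' threshold + IQR filtering; per-subject RTD correct rate; visual-search
#' final score, correct rate and pooled correct-trial search times; and
#' per-subject MT/ST count errors. Trial-level metrics pool the surviving
#' trials of all subjects; "complex" per-subject metrics contribute one
#' value per subject. Subjects whose trials are all filtered out are
#' flagged and excluded from pooled metrics.
#'
#' @param log cognitive log data.frame ([simulate_cognitive_log()] schema).
#' @param thresholds RT threshold table, default [rt_thresholds()].
#' @return data.frame with one row per (metric, group): columns `metric`,
#'   `group`, `level`, `n`, and a list-column `values`; plus attribute
#'   `"flagged_subjects"`.
#' @export
cognitive_group_metrics <- function(log, thresholds = rt_thresholds()) {
  out <- list()
  flagged <- character(0)
  add <- function(metric, group, level, values) {
    out[[length(out) + 1L]] <<- data.frame(
      metric = metric, group = group, level = level,
      n = length(values), values = I(list(values)),
      stringsAsFactors = FALSE)
  }
  for (g in unique(log$group)) {
    lg <- log[log$group == g, ]
    for (test in c("RTM", "RTK", "RTD")) {
      th <- thresholds[thresholds$test == test, ]
      pooled <- numeric(0)
      for (s in unique(lg$subject_id)) {
        tr <- lg[lg$subject_id == s & lg$test == test, ]
        rt <- if (test == "RTD") tr$rt_ms[tr$correct] else tr$rt_ms
        f <- filter_rts(rt, th$min_ms, th$max_ms)
        if (length(f$kept) == 0) {
          flagged <- c(flagged, paste0(s, ":", test))
        } else {
          pooled <- c(pooled, f$kept)
        }
      }
      nm <- if (test == "RTD") "reaction_time_correct" else "reaction_time"
      add(paste0(test, ".", nm), g, "trial", pooled)
    }
    rtd_cr <- vapply(unique(lg$subject_id), function(s) {
      correct_rate(lg$correct[lg$subject_id == s & lg$test == "RTD"])
    }, numeric(1))
    add("RTD.correct_rate", g, "subject", unname(rtd_cr))
    vs_fs <- numeric(0); vs_cr <- numeric(0)
    vs_L <- numeric(0); vs_noL <- numeric(0)
    for (s in unique(lg$subject_id)) {
      vm <- vs_metrics(lg[lg$subject_id == s & lg$test == "VS", ])
      vs_fs <- c(vs_fs, vm$final_score)
      vs_cr <- c(vs_cr, vm$correct_rate)
      vs_L <- c(vs_L, vm$search_L_s)
      vs_noL <- c(vs_noL, vm$search_noL_s)
    }
    add("VS.final_score", g, "subject", vs_fs)
    add("VS.correct_rate", g, "subject", vs_cr)
    add("VS.search_time_L", g, "trial", vs_L)
    add("VS.search_time_noL", g, "trial", vs_noL)
    for (par in c("MT", "ST")) {
      cnt <- lg[lg$test == par, ]
      add(paste0(par, ".count_error"), g, "subject",
          count_error(cnt$counted, cnt$true_count))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "flagged_subjects") <- unique(flagged)
  res
}

#' Compare one group metric between groups
#'
#' Mean and SD per group, Welch t with Welch-Satterthwaite df, two-sided
#' permutation p-value (Welch-statistic label permutation) and Hedges' g.
#'
#' @param pro,novice numeric metric values of the two groups.
#' @param n_perm permutations for the p-value.
#' @param seed optional integer seed.
#' @return one-row data.frame: pro_mean, pro_sd, novice_mean, novice_sd,
#'   t, df, p, g.
#' @export
compare_group_metrics <- function(pro, novice, n_perm = 10000,
                                  seed = NULL) {
  stopifnot(length(pro) >= 2, length(novice) >= 2)
  wt <- welch_t(pro, novice)
  pt <- perm_welch_test(pro, novice, n_perm = n_perm, seed = seed)
  data.frame(pro_mean = mean(pro), pro_sd = stats::sd(pro),
             novice_mean = mean(novice), novice_sd = stats::sd(novice),
             t = wt$t, df = wt$df, p = pt$p,
             g = hedges_g(pro, novice))
}

#' Group comparison from summary statistics alone
#'
#' Welch t (with df) and Hedges' g recomputed from published mean/SD/n
#' summaries, for worked-example verification when raw data are not
#' available. The permutation p cannot be recomputed from summaries.
#'
#' @inheritParams welch_t_summary
#' @return one-row data.frame: t, df, g.
#' @export
compare_group_summary <- function(m1, s1, n1, m2, s2, n2) {
  wt <- welch_t_summary(m1, s1, n1, m2, s2, n2)
  data.frame(t = wt$t, df = wt$df,
             g = hedges_g_summary(m1, s1, n1, m2, s2, n2))
}

#' Full cognitive-test comparison report
#'
#' Runs [cognitive_group_metrics()] and compares every metric between the
#' groups, in the printed-report rounding convention (t to one decimal, g
#' to two decimals).
#'
#' @param log cognitive log data.frame.
#' @param n_perm permutations per metric.
#' @param seed integer seed.
#' @param groups length-2 character, default `c("PRO", "NOVICE")`.
#' @return data.frame with one row per metric.
#' @export
cognitive_report <- function(log, n_perm = 10000, seed = 1,
                             groups = c("PRO", "NOVICE")) {
  gm <- cognitive_group_metrics(log)
  metrics <- unique(gm$metric)
  out <- do.call(rbind, lapply(seq_along(metrics), function(i) {
    m <- metrics[i]
    a <- gm$values[[which(gm$metric == m & gm$group == groups[1])]]
    b <- gm$values[[which(gm$metric == m & gm$group == groups[2])]]
    cmp <- compare_group_metrics(a, b, n_perm = n_perm, seed = seed + i)
    cbind(data.frame(metric = m, n_pro = length(a), n_novice = length(b)),
          cmp)
  }))
  out$t_rounded <- round(out$t, 1)
  out$g_rounded <- round(out$g, 2)
  out
}
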