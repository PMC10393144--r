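#' Per-subject cognitive features
#'
#' Condenses a cognitive log into one row per subject: mean filtered
#' reaction times (RTM, RTK), mean correct RTD reaction time and correct
#' rate, visual-search final score / correct rate / mean correct search
#' times, and hours in game where present.
#'
#' @param log cognitive log data.frame.
#' @param thresholds RT threshold table.
#' @return data.frame keyed by `subject`, `group`.
#' @export
cognitive_features <- function(log, thresholds = rt_thresholds()) {
  subs <- unique(log$subject_id)
  rows <- lapply(subs, function(s) {
    ls <- log[log$subject_id == s, ]
    rt_mean <- function(test) {
      th <- thresholds[thresholds$test == test, ]
      tr <- ls[ls$test == test, ]
      rt <- if (test == "RTD") tr$rt_ms[tr$correct] else tr$rt_ms
      mean(filter_rts(rt, th$min_ms, th$max_ms)$kept)
    }
    vm <- vs_metrics(ls[ls$test == "VS", ])
    data.frame(
      subject = s, group = ls$group[1],
      rtm_mean = rt_mean("RTM"), rtk_mean = rt_mean("RTK"),
      rtd_mean_correct = rt_mean("RTD"),
      rtd_correct_rate = correct_rate(ls$correct[ls$test == "RTD"]),
      vs_final_score = vm$final_score, vs_correct_rate = vm$correct_rate,
      vs_search_L = mean(vm$search_L_s), vs_search_noL = mean(vm$search_noL_s),
      hours_in_game = ls$hours_in_game[1],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

paradigm_code <- function(p) {
  c("B/RB" = "BRB", "BT" = "BT", "MT" = "MT", "ST" = "ST")[[p]]
}

#' Assemble the per-subject feature table of one group
#'
#' Joins the combined ERP features (the mean over Fz, Cz and Pz of each
#' component's amplitude and latency, per paradigm: 24 columns named
#' `{amp|lat}_{P200|N200|P300}_{BRB|BT|MT|ST}`), the cognitive-test
#' features and, for the PRO group, hours in game. Rows with missing
#' constituents are flagged via the `complete` column.
#'
#' @param measures component-measure table ([measure_components_table()]
#'   rows, concatenated over paradigms) measured per channel, containing
#'   at least the Fz, Cz, Pz channels.
#' @param cog per-subject cognitive features ([cognitive_features()]).
#' @param group group to assemble (intragroup analyses never mix groups).
#' @return data.frame, one row per subject of `group`.
#' @export
build_feature_table <- function(measures, cog, group) {
  m <- measures[measures$group == group &
                  measures$channel %in% c("Fz", "Cz", "Pz"), ]
  cg <- cog[cog$group == group, ]
  subs <- sort(unique(cg$subject))
  paradigms <- intersect(c("B/RB", "BT", "MT", "ST"), unique(m$paradigm))
  rows <- lapply(subs, function(s) {
    row <- cg[cg$subject == s, , drop = FALSE]
    names(row)[names(row) == "subject"] <- "subject"
    complete <- TRUE
    for (p in paradigms) {
      for (comp in c("P200", "N200", "P300")) {
        sel <- m$subject == s & m$paradigm == p & m$component == comp
        code <- paradigm_code(p)
        if (sum(sel) == 0) {
          row[[paste0("amp_", comp, "_", code)]] <- NA_real_
          row[[paste0("lat_", comp, "_", code)]] <- NA_real_
          complete <- FALSE
        } else {
          row[[paste0("amp_", comp, "_", code)]] <- mean(m$amplitude_uV[sel])
          row[[paste0("lat_", comp, "_", code)]] <- mean(m$latency_ms[sel])
        }
      }
    }
    row$complete <- complete
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Spearman correlation heatmap with permutation p-values
#'
#' Spearman rank correlation between all numeric feature columns, with a
#' per-cell two-sided permutation p-value obtained by permuting subject
#' order (one common set of permutations serves all cells). Constant
#' columns yield `NA` cells.
#'
#' @param tbl feature table ([build_feature_table()]); non-numeric and
#'   all-NA columns are dropped.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list: `rho` (correlation matrix), `p` (permutation p matrix,
#'   `NA` diagonal), `n`.
#' @export
heatmap_correlations <- function(tbl, n_perm = 2000, seed = 1) {
  num <- tbl[vapply(tbl, is.numeric, logical(1))]
  num <- num[, colSums(!is.na(num)) > 0, drop = FALSE]
  n <- nrow(num)
  stopifnot(n >= 5)
  R <- apply(num, 2, rank)
  constant <- apply(num, 2, function(x) stats::sd(x, na.rm = TRUE) == 0)
  rho <- suppressWarnings(stats::cor(R, method = "pearson"))
  set.seed(seed)
  exceed <- matrix(0, ncol(R), ncol(R))
  for (i in seq_len(n_perm)) {
    Rp <- R[sample.int(n), , drop = FALSE]
    rp <- suppressWarnings(stats::cor(Rp, R))
    exceed <- exceed + (abs(rp) >= abs(rho) - 1e-12)
  }
  p <- (1 + exceed) / (n_perm + 1)
  rho[constant, ] <- NA; rho[, constant] <- NA
  p[constant, ] <- NA; p[, constant] <- NA
  diag(rho) <- ifelse(constant, NA, 1)
  diag(p) <- NA
  dimnames(rho) <- dimnames(p) <- list(colnames(R), colnames(R))
  list(rho = rho, p = p, n = n)
}

#' Channel-wise correlation of a scalar feature with an ERP feature
#'
#' Correlates a per-subject scalar (for example hours in game, or the RTD
#' correct rate) with a per-subject, per-channel ERP feature inside one
#' group, using [spearman_tfce_map()] over the channel graph.
#'
#' @param x per-subject scalar (one group's subjects).
#' @param Y subjects x channels feature matrix (same order).
#' @param adjacency channel adjacency matrix.
#' @param n_perm,seed,alpha passed through.
#' @return `stat_result` over channels.
#' @export
channelwise_feature_correlation <- function(x, Y,
                                            adjacency = channel_adjacency(),
                                            n_perm = 2000, seed = NULL,
                                            alpha = 0.05) {
  if (length(x) < 5) stop("group too small for correlation mapping")
  spearman_tfce_map(x, Y, adjacency = adjacency, n_perm = n_perm,
                    seed = seed, alpha = alpha)
}

#' Evaluate the two-part significance criteria on correlation maps
#'
#' Small-sample topographic correlations are only trusted when (1) the
#' correlation pattern is consistent across closely related paradigms and
#' (2) several significant channels form a contiguous area. Criterion 1 is
#' operationalized as sign concordance: for each paradigm pair both maps
#' must have at least one significant channel and the summed rho over the
#' union of their significant channels must agree in sign. Criterion 2
#' requires at least `min_cluster` significant channels sharing an
#' adjacency edge in at least one considered paradigm.
#'
#' @param results named list of `stat_result`s keyed by paradigm.
#' @param adjacency channel adjacency matrix.
#' @param pairs list of length-2 character vectors of paradigm names to
#'   check for concordance (default `list(c("MT", "ST"))`).
#' @param min_cluster minimum size of the connected significant set.
#' @return list: `criterion1`, `criterion2`, `overall`, `detail`.
#' @export
evaluate_criteria <- function(results, adjacency = channel_adjacency(),
                              pairs = list(c("MT", "ST")),
                              min_cluster = 2) {
  has_cluster <- function(res) {
    sig <- which(res$mask)
    if (length(sig) < min_cluster) return(FALSE)
    any(adjacency[sig, sig, drop = FALSE])
  }
  crit2 <- any(vapply(results, has_cluster, logical(1)))
  concord <- vapply(pairs, function(pr) {
    if (!all(pr %in% names(results))) return(FALSE)
    a <- results[[pr[1]]]; b <- results[[pr[2]]]
    sa <- which(a$mask); sb <- which(b$mask)
    if (length(sa) == 0 || length(sb) == 0) return(FALSE)
    u <- union(sa, sb)
    sign(sum(a$statistic[u])) == sign(sum(b$statistic[u]))
  }, logical(1))
  crit1 <- all(concord)
  list(criterion1 = crit1, criterion2 = crit2,
       overall = crit1 && crit2,
       detail = list(pair_concordance = concord))
}
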