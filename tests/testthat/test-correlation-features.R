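make_measures <- function(paradigms = c("B/RB", "BT", "MT", "ST"),
                          n = 10, group = "PRO", seed = 1) {
  set.seed(seed)
  rows <- expand.grid(subject = sprintf("%s%02d", substr(group, 1, 3), 1:n),
                      paradigm = paradigms,
                      component = c("P200", "N200", "P300"),
                      channel = c("Fz", "Cz", "Pz"),
                      stringsAsFactors = FALSE)
  rows$group <- group
  rows$amplitude_uV <- rnorm(nrow(rows), 10, 3)
  rows$latency_ms <- rnorm(nrow(rows), 300, 30)
  rows$valid <- TRUE
  rows
}

make_cog <- function(n = 10, group = "PRO", seed = 2) {
  set.seed(seed)
  data.frame(subject = sprintf("%s%02d", substr(group, 1, 3), 1:n),
             group = group, rtm_mean = rnorm(n, 220, 20),
             rtk_mean = rnorm(n, 240, 20),
             rtd_mean_correct = rnorm(n, 330, 40),
             rtd_correct_rate = rnorm(n, 88, 3),
             vs_final_score = rnorm(n, 17, 5),
             vs_correct_rate = rnorm(n, 87, 5),
             vs_search_L = rnorm(n, 2.5, 0.8),
             vs_search_noL = rnorm(n, 5, 1.5),
             hours_in_game = if (group == "PRO") seq(2000, 8000,
                                                     length.out = n)
             else NA_real_,
             stringsAsFactors = FALSE)
}

test_that("feature table carries the 24 combined ERP features per subject", {
  tbl <- build_feature_table(make_measures(), make_cog(), "PRO")
  comb <- grep("^(amp|lat)_(P200|N200|P300)_(BRB|BT|MT|ST)$", names(tbl))
  expect_length(comb, 24)
  expect_equal(nrow(tbl), 10)
  expect_true(all(tbl$complete))
  # identical Fz/Cz/Pz values -> combined feature equals that value
  m <- make_measures(n = 5)
  m$amplitude_uV[m$subject == "PRO01" & m$paradigm == "MT" &
                   m$component == "P300"] <- 7.7
  t2 <- build_feature_table(m, make_cog(n = 5), "PRO")
  expect_equal(t2$amp_P300_MT[t2$subject == "PRO01"], 7.7)
  # permuting input rows leaves content invariant
  m3 <- make_measures()
  t3a <- build_feature_table(m3, make_cog(), "PRO")
  t3b <- build_feature_table(m3[sample(nrow(m3)), ], make_cog(), "PRO")
  expect_equal(t3a, t3b)
  # a subject missing a paradigm is flagged incomplete
  m4 <- make_measures()
  m4 <- m4[!(m4$subject == "PRO02" & m4$paradigm == "ST"), ]
  t4 <- build_feature_table(m4, make_cog(), "PRO")
  expect_false(t4$complete[t4$subject == "PRO02"])
})

test_that("correlation heatmap is symmetric with unit diagonal and exact rho", {
  tbl <- build_feature_table(make_measures(), make_cog(), "PRO")
  hm <- heatmap_correlations(tbl, n_perm = 300, seed = 4)
  expect_equal(hm$rho, t(hm$rho))
  expect_true(all(diag(hm$rho) == 1, na.rm = TRUE))
  expect_true(all(hm$p >= 0 & hm$p <= 1, na.rm = TRUE))
  # 6-subject toy table equals brute-force pairwise rank correlation
  toy <- data.frame(a = c(3, 1, 4, 1.5, 5, 9), b = c(2, 7, 1, 8, 2.8, 1.9),
                    c = c(1, 2, 3, 4, 5, 6))
  hm2 <- heatmap_correlations(toy, n_perm = 200, seed = 1)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(hm2$rho[i, j],
                 cor(rank(toy[[i]]), rank(toy[[j]])), tolerance = 1e-12)
  }
  # constant column flagged NA
  toy$d <- 5
  hm3 <- heatmap_correlations(toy, n_perm = 100, seed = 1)
  expect_true(all(is.na(hm3$rho[, "d"])))
})

test_that("planted monotone links are detected with small n", {
  set.seed(9)
  hits <- 0L
  for (i in 1:20) {
    x <- rnorm(10)
    y <- x + rnorm(10, sd = sqrt(1 / 0.9^2 - 1))  # rho_true ~ 0.9
    tbl <- data.frame(f1 = x, f2 = y, f3 = rnorm(10))
    hm <- heatmap_correlations(tbl, n_perm = 200, seed = i)
    if (hm$rho["f1", "f2"] > 0.6) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("channel-wise correlation criteria distinguish planted from null links", {
  adj <- channel_adjacency()
  mont <- standard_montage()
  left_parietal <- which(mont$channel %in% c("P3", "CP1", "CP5", "P7"))
  set.seed(12)
  x <- rnorm(10)
  planted <- list()
  for (p in c("MT", "ST")) {
    Y <- matrix(rnorm(10 * 32), 10)
    Y[, left_parietal] <- Y[, left_parietal] +
      2.2 * matrix(x, 10, length(left_parietal))
    planted[[p]] <- channelwise_feature_correlation(x, Y, adj,
                                                    n_perm = 400,
                                                    seed = 3)
  }
  crit <- evaluate_criteria(planted, adj)
  expect_true(crit$criterion1)
  expect_true(crit$criterion2)
  expect_true(crit$overall)
  # independent noise: overall flag almost always false
  false_hits <- 0L
  for (i in 1:15) {
    set.seed(100 + i)
    xn <- rnorm(10)
    nulls <- lapply(c(MT = "MT", ST = "ST"), function(p) {
      channelwise_feature_correlation(xn, matrix(rnorm(320), 10), adj,
                                      n_perm = 200, seed = i)
    })
    if (evaluate_criteria(nulls, adj)$overall) false_hits <- false_hits + 1L
  }
  expect_lte(false_hits, 1L)
  # degenerate constant feature: flagged, no crash
  expect_error(channelwise_feature_correlation(rep(1, 10),
                                               matrix(rnorm(320), 10),
                                               adj),
               "constant")
})
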