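test_that("Welch t reproduces the published cognitive-test statistics", {
  # visual-search final score, n = 10 per group
  vs <- welch_t_summary(16.90, 6.05, 10, 19.10, 6.37, 10)
  expect_equal(round(vs$t, 1), -0.8)
  expect_true(vs$df > 17 && vs$df <= 18)
  # RTD correct rate
  expect_equal(round(welch_t_summary(88.3, 3.2, 10, 89.7, 7.8, 10)$t, 1),
               -0.5)
  # VS correct rate
  expect_equal(round(welch_t_summary(87.2, 6.7, 10, 92.0, 6.0, 10)$t, 1),
               -1.7)
})

test_that("Welch t basic properties hold", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  b <- c(0.4, 2.2, 1.1)
  expect_equal(welch_t(a, a)$t, 0)
  expect_equal(welch_t(3 * a, 3 * b)$t, welch_t(a, b)$t)
  expect_equal(welch_t(a, b)$t, -welch_t(b, a)$t)
  # agrees with the base implementation
  tt <- t.test(a, b, var.equal = FALSE)
  expect_equal(welch_t(a, b)$t, unname(tt$statistic))
  expect_equal(welch_t(a, b)$df, unname(tt$parameter))
  # zero variance, equal means
  expect_equal(welch_t(c(2, 2), c(2, 2))$t, 0)
})

test_that("Hedges g matches published effect sizes and the df approximation", {
  expect_lt(abs(abs(hedges_g_summary(16.90, 6.05, 10, 19.10, 6.37, 10)) -
                  0.34), 0.015)
  expect_lt(abs(abs(hedges_g_summary(88.3, 3.2, 10, 89.7, 7.8, 10)) -
                  0.21), 0.015)
  expect_lt(abs(abs(hedges_g_summary(87.2, 6.7, 10, 92.0, 6.0, 10)) -
                  0.73), 0.015)
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3)), 0)
  # exact gamma correction vs the classic 1 - 3/(4 df - 1) approximation
  for (df in c(10, 18, 30, 100)) {
    expect_lt(abs(esporterp:::hedges_correction(df) -
                    (1 - 3 / (4 * df - 1))), 1e-3)
  }
  expect_warning(g0 <- hedges_g(c(1, 1), c(1, 1)), "zero pooled SD")
  expect_true(is.na(g0))
})

test_that("permutation Welch test enumerates exactly and is seed-stable", {
  a <- c(0.2, 1.5, 2.9)
  b <- c(2.1, 3.3, 4.0)
  res <- perm_welch_test(a, b, n_perm = 1000)
  expect_true(res$exact)
  expect_equal(res$p, perm_welch_oracle(a, b))
  # identical samples -> p = 1
  expect_equal(perm_welch_test(c(1, 2, 3), c(1, 2, 3), n_perm = 50)$p, 1)
  # seed determinism for the sampled branch
  set.seed(1)
  x <- rnorm(12); y <- rnorm(12) + 1
  p1 <- perm_welch_test(x, y, n_perm = 500, seed = 9)$p
  p2 <- perm_welch_test(x, y, n_perm = 500, seed = 9)$p
  expect_identical(p1, p2)
  # swapping groups preserves the two-sided p exactly on the exact branch
  expect_equal(perm_welch_test(a, b, n_perm = 1000)$p,
               perm_welch_test(b, a, n_perm = 1000)$p)
})

test_that("Mann-Whitney wrapper agrees with brute-force enumeration", {
  set.seed(4)
  for (i in 1:5) {
    a <- round(rnorm(4), 3)
    b <- round(rnorm(5) + 0.8, 3)
    mw <- mann_whitney_u(a, b)
    expect_equal(mw$p, mw_oracle(a, b), tolerance = 1e-12)
  }
  # mirrored samples are distributionally identical -> p = 1 under the
  # exact null
  a <- c(-2, -1, 1, 2)
  b <- c(-1.5, -0.5, 0.5, 1.5)
  expect_equal(mann_whitney_u(a, b)$p, 1)
})

test_that("TFCE kernel matches the cluster-integral oracle on lattices and graphs", {
  set.seed(11)
  # 1-D
  for (i in 1:5) {
    v <- sample(-3:5, 12, replace = TRUE)
    expect_equal(tfce(as.numeric(v), dh = 0.1),
                 tfce_oracle_signed(v, lattice_adj_matrix(12), dh = 0.1),
                 tolerance = 1e-10)
  }
  # 2-D integer maps, 3x3 and 5x5
  for (n in c(3, 5)) {
    for (i in 1:10) {
      m <- matrix(sample(0:5, n * n, replace = TRUE), n, n)
      got <- tfce(m * 1.0, dh = 0.1)
      want <- tfce_oracle_signed(as.numeric(m), lattice_adj_matrix(c(n, n)),
                                 dh = 0.1)
      expect_equal(as.numeric(got), want, tolerance = 1e-10)
    }
  }
  # channel graph
  adj <- channel_adjacency()
  v <- rnorm(32)
  expect_equal(tfce(v, adjacency = adj, dh = 0.05),
               tfce_oracle_signed(v, adj, dh = 0.05), tolerance = 1e-10)
})

test_that("TFCE closed form and elementary properties", {
  expect_equal(tfce(rep(0, 10)), rep(0, 10))
  # rectangular plateau: extent e0 constant across thresholds
  h0 <- 2; e0 <- 4; dh <- 0.01
  v <- c(0, rep(h0, e0), 0, 0)
  enh <- tfce(v, E = 0.5, H = 2, dh = dh)
  hs <- seq(dh, h0, by = dh)
  closed <- sqrt(e0) * sum(hs^2) * dh
  expect_equal(max(enh), closed, tolerance = 1e-8)
  # raising a single point never decreases its enhancement
  set.seed(2)
  v <- abs(rnorm(15))
  for (i in c(3, 9)) {
    v2 <- v; v2[i] <- v2[i] + 0.5
    expect_gte(tfce(v2, dh = 0.02)[i], tfce(v, dh = 0.02)[i] - 1e-12)
  }
})

test_that("TFCE permutation test is exchangeable and detects planted effects", {
  set.seed(3)
  npt <- 40
  A <- matrix(rnorm(8 * npt), 8)
  B <- matrix(rnorm(8 * npt), 8)
  res0 <- tfce_perm_test(A, A + 0, n_perm = 200, seed = 1)
  expect_true(all(res0$p >= 0.9))  # identical groups: nothing significant
  # label swap negates the t map
  r1 <- tfce_perm_test(A, B, n_perm = 100, seed = 5)
  r2 <- tfce_perm_test(B, A, n_perm = 100, seed = 5)
  expect_equal(r1$statistic, -r2$statistic)
  # planted cluster is found
  Bp <- B; Bp[, 15:25] <- Bp[, 15:25] + 3
  rp <- tfce_perm_test(Bp, A, n_perm = 300, seed = 7)
  expect_true(any(rp$mask[15:25]))
  expect_false(any(rp$mask[c(1:5, 35:40)]))
})

test_that("Spearman TFCE map: exact rho, enumeration p, degenerate input", {
  set.seed(8)
  n <- 6
  x <- rnorm(n)
  Y <- matrix(rnorm(n * 4), n)
  Y[, 2] <- exp(x)  # monotone transform -> rho 1
  res <- spearman_tfce_map(x, Y, adjacency = lattice_adj_matrix(4),
                           n_perm = 300, seed = 2)
  expect_equal(res$statistic[2], 1)
  # rho equals the classical rank formula without ties
  for (j in 1:4) {
    expect_equal(res$statistic[j],
                 suppressWarnings(cor(x, Y[, j], method = "spearman")))
  }
  expect_error(spearman_tfce_map(rep(1, n), Y), "constant")
  Yc <- Y; Yc[, 3] <- 5
  resc <- spearman_tfce_map(x, Yc, adjacency = lattice_adj_matrix(4),
                            n_perm = 100, seed = 2)
  expect_true(is.na(resc$p[3]))
  expect_equal(resc$statistic[3], 0)
})

test_that("significant_spans extracts contiguous intervals", {
  mask <- c(FALSE, TRUE, TRUE, FALSE, TRUE)
  sp <- significant_spans(mask, c(0, 10, 20, 30, 40))
  expect_equal(sp$start, c(10, 40))
  expect_equal(sp$end, c(20, 40))
  expect_equal(nrow(significant_spans(rep(FALSE, 4), 1:4)), 0)
})
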