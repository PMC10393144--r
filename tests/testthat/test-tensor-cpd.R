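make_cp_tensor <- function(dims, rank, seed = 1, noise = 0,
                           orth_spatial = TRUE) {
  set.seed(seed)
  A <- matrix(rnorm(dims[1] * rank), dims[1])
  if (orth_spatial) A <- qr.Q(qr(A))[, seq_len(rank), drop = FALSE]
  B <- matrix(rnorm(dims[2] * rank), dims[2])
  C <- matrix(rnorm(dims[3] * rank), dims[3])
  X <- array(0, dims)
  for (r in seq_len(rank)) {
    X <- X + outer(outer(A[, r], B[, r]), C[, r])
  }
  if (noise > 0) {
    X <- X + array(rnorm(prod(dims), sd = noise * sd(X)), dims)
  }
  list(X = X, A = A, B = B, C = C)
}

congruence <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))

test_that("order-3 tensor construction: offset, crop, pooling", {
  e <- tiny_epochs("MT", n = 2, seed = 41)
  tt <- build_order3(e)
  expect_equal(dim(tt$data)[2], 251L)          # -100..900 ms at 250 Hz
  expect_equal(range(tt$times), c(-100, 900))
  expect_equal(dim(tt$data)[3], sum(e$labels$target))  # pooled targets
  # constant epochs -> all-zero tensor after offset subtraction
  ec <- e
  ec$data[] <- 3
  expect_lt(max(abs(build_order3(ec)$data)), 1e-12)
  # too-short epochs error
  eb <- tiny_epochs("B/RB", n = 1, seed = 41)
  expect_error(build_order3(eb), "crop span")
})

test_that("order-4 tensor construction: band crop and energy conservation", {
  e <- tiny_epochs("B/RB", n = 1, seed = 43, noise = 3)
  e <- subset_epochs(e, 1:6)
  sp <- lapply(c(Cz = "Cz", Pz = "Pz"), function(ch) {
    epochs_to_spectrograms(e, ch, vmd_config(K = 3, max_iter = 100))
  })
  t4 <- build_order4(sp)
  expect_equal(dim(t4$data)[1:2], c(2L, 101L))
  expect_equal(sum(t4$data), sum(sp$Cz$power) + sum(sp$Pz$power))
  hb <- build_order4(sp, band = c(3, 30))
  expect_equal(dim(hb$data)[2], sum(sp$Cz$freqs >= 3))
  # all-zero spectrograms -> zero tensor
  sp0 <- sp
  sp0$Cz$power[] <- 0; sp0$Pz$power[] <- 0
  expect_equal(sum(build_order4(sp0)$data), 0)
})

test_that("CP-ALS recovers planted factors", {
  # rank-1: exact recovery
  tz <- make_cp_tensor(c(12, 20, 15), 1, seed = 3)
  m1 <- fit_cpd(tz$X, 1, restarts = 2, seed = 5)
  expect_gt(m1$fit, 0.999)
  expect_gt(congruence(m1$factors$spatial[, 1], tz$A[, 1]), 0.999)
  expect_gt(congruence(m1$factors$temporal[, 1], tz$B[, 1]), 0.999)
  # rank-3 with orthogonal spatial factors and 1% noise
  tz3 <- make_cp_tensor(c(16, 40, 60), 3, seed = 7, noise = 0.01)
  m3 <- fit_cpd(tz3$X, 3, restarts = 3, seed = 6)
  expect_lt(m3$residual, 0.05)
  perm <- apply(abs(crossprod(m3$factors$spatial, tz3$A)), 2, which.max)
  expect_setequal(perm, 1:3)
  for (r in 1:3) {
    expect_gt(congruence(m3$factors$spatial[, perm[r]], tz3$A[, r]), 0.95)
    expect_gt(congruence(m3$factors$temporal[, perm[r]], tz3$B[, r]), 0.95)
  }
  # spatial orthonormality at convergence
  G <- crossprod(m3$factors$spatial)
  expect_lt(max(abs(G - diag(3))), 1e-8)
})

test_that("explained energy grows with rank and components are energy-ordered", {
  tz <- make_cp_tensor(c(10, 18, 25), 3, seed = 11, noise = 0.05)
  f1 <- fit_cpd(tz$X, 1, restarts = 2, seed = 2)
  f2 <- fit_cpd(tz$X, 2, restarts = 2, seed = 2)
  f3 <- fit_cpd(tz$X, 3, restarts = 2, seed = 2)
  expect_gte(f2$fit, f1$fit - 1e-8)
  expect_gte(f3$fit, f2$fit - 1e-8)
  en <- colSums(f3$factors$trial^2)
  expect_true(all(diff(en) <= 1e-8))
  # sign convention: temporal extrema are positive
  for (r in 1:3) {
    v <- f3$factors$temporal[, r]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("per-subject power scoring and Mann-Whitney group test", {
  tz <- make_cp_tensor(c(8, 15, 40), 2, seed = 13)
  labels <- data.frame(
    subject = rep(sprintf("S%02d", 1:8), each = 5),
    group = rep(c("PRO", "NOVICE"), each = 20),
    stringsAsFactors = FALSE)
  m <- fit_cpd(tz$X, 2, restarts = 2, seed = 3)
  m$labels <- labels
  # trial factor all ones -> per-subject power equals the trial count
  m1 <- m
  m1$factors$trial <- matrix(1, 40, 2)
  sp <- subject_power(m1)
  expect_true(all(sp$scores == 5))
  # planted 2x PRO trial-coefficient scale flags the component: build a
  # rank-2 tensor whose component-1 trial coefficients are positive
  # (a component present in every trial) and doubled for the PRO half
  detected <- 0L
  for (rep_i in 1:10) {
    set.seed(100 + rep_i)
    A <- qr.Q(qr(matrix(rnorm(8 * 2), 8)))
    B <- matrix(rnorm(15 * 2), 15)
    C <- matrix(abs(rnorm(40 * 2)) + 0.5, 40)
    C[1:20, 1] <- 2 * C[1:20, 1]
    Xp <- array(0, c(8, 15, 40))
    for (r in 1:2) Xp <- Xp + outer(outer(A[, r], B[, r]), C[, r])
    Xp <- Xp + array(rnorm(prod(dim(Xp)), sd = 0.02 * sd(Xp)), dim(Xp))
    mp <- fit_cpd(Xp, 2, restarts = 2, seed = 4)
    mp$labels <- labels
    res <- subject_power_test(mp)
    if (any(res$p < 0.05)) detected <- detected + 1L
  }
  expect_gte(detected, 9L)
  # subject with zero trials errors
  m$labels$subject[m$labels$subject == "S01"] <- "S02"
  sp2 <- subject_power(m, labels = data.frame(
    subject = c("S01", rep("S02", 39)), group = labels$group))
  expect_equal(nrow(sp2$scores), 2)
})
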