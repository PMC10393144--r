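test_that("Kaiser FIR designs meet their frequency-response contract", {
  lp <- design_fir("lowpass", 30, 250, 184, 5.65)
  expect_length(lp, 185)
  # stopband: >= 50 dB down at 60 Hz
  expect_lt(20 * log10(Mod(fir_response(lp, 60, 250))), -50)
  # passband: 10 Hz sinusoid within 1%
  expect_lt(abs(Mod(fir_response(lp, 10, 250)) - 1), 0.01)
  expect_equal(Mod(fir_response(lp, 0, 250)), 1, tolerance = 1e-12)
  hp <- design_fir("highpass", 0.5, 250, 1000, 5.65)
  expect_lt(Mod(fir_response(hp, 0, 250)), 1e-12)
  expect_error(design_fir("lowpass", 130, 250), "Nyquist")
  expect_error(design_fir("lowpass", 30, 250, order = 185), "even")
})

test_that("high-pass filtering removes a DC offset from epochs", {
  e <- tiny_epochs("B/RB", n = 1, noise = 1, alpha = 0)
  e$data <- e$data + 40  # constant offset
  hp <- design_fir("highpass", 0.5, 250, 150, 5.65)
  ef <- filter_epochs(e, hp)
  # after the transient the offset is gone (interior samples)
  mid <- 60:140
  expect_lt(abs(mean(ef$data[1, mid, 1])), 1.5)
})

test_that("zero-phase application leaves a symmetric pulse center unchanged", {
  lp <- design_fir("lowpass", 30, 250, 184)
  x <- exp(-((1:300) - 150)^2 / 80)
  y <- esporterp:::fir_filtfilt_cols(matrix(x, ncol = 1), lp)[, 1]
  com <- function(v) sum(seq_along(v) * abs(v)) / sum(abs(v))
  expect_lt(abs(com(y) - com(x)), 1)
})

test_that("epoching excludes the first two trials per block and respects bounds", {
  set.seed(1)
  cont <- matrix(rnorm(8 * 20000), 8)
  mont <- standard_montage()[1:8, ]
  ns <- 40
  ev <- data.frame(sample = seq(500, 19000, length.out = ns),
                   is_target = rep_len(c(TRUE, FALSE), ns),
                   block = rep(1:2, each = ns / 2))
  e <- epoch_and_baseline(cont, ev, "B/RB", 250, montage = mont)
  expect_equal(dim(e$data)[3], ns - 4L)  # two per block dropped
  expect_equal(dim(e$data)[2], 201L)     # 800 ms + endpoint at 250 Hz
  # event at the very edge is dropped with a message
  ev2 <- rbind(ev, data.frame(sample = 19995, is_target = TRUE, block = 2))
  expect_message(e2 <- epoch_and_baseline(cont, ev2, "B/RB", 250,
                                          montage = mont), "edge")
  expect_equal(dim(e2$data)[3], ns - 4L)
})

test_that("baseline subtraction zeroes constant epochs and is idempotent", {
  e <- tiny_epochs("B/RB", n = 1, noise = 1)
  ec <- e
  ec$data[] <- 7.5
  expect_lt(max(abs(baseline_epochs(ec)$data)), 1e-12)
  b1 <- baseline_epochs(e)
  b2 <- baseline_epochs(b1)
  expect_equal(b1$data, b2$data, tolerance = 1e-12)
})

test_that("amplitude rejection flags exactly the planted epochs, monotonically", {
  e <- tiny_epochs("B/RB", n = 1, noise = 3)
  # all epochs within +-10 uV of their mean would pass a 500 uV threshold
  expect_equal(sum(reject_epochs(e)$epochs$rejected), 0L)
  planted <- c(2, 9, 17, 25, 33)
  e$data[4, 50, planted] <- e$data[4, 50, planted] + 80
  r80 <- reject_epochs(e, threshold = 70)
  expect_equal(which(r80$epochs$rejected), planted)
  expect_equal(sum(r80$report$n_rejected), 5L)
  # lowering the threshold never un-rejects
  r40 <- reject_epochs(e, threshold = 35)
  expect_true(all(r80$epochs$rejected <= r40$epochs$rejected))
  # a single 600 uV span epoch is rejected at the default threshold
  e$data[1, 30, 1] <- e$data[1, 30, 1] + 600
  expect_true(reject_epochs(e)$epochs$rejected[1])
  expect_error(reject_epochs(e, threshold = 1e-6), "all epochs rejected")
})

test_that("outlier channels are flagged, capped at two, and interpolated", {
  e <- tiny_epochs("B/RB", n = 2, noise = 5, alpha = 4, sd_scale = 1)
  expect_length(flag_and_interpolate_channels(e)$flagged, 0)
  e$data[7, , ] <- e$data[7, , ] * 10
  fl <- flag_and_interpolate_channels(e)
  expect_equal(fl$flagged, e$channels[7])
  # more than two planted -> worst two interpolated with a warning
  e2 <- tiny_epochs("B/RB", n = 2, noise = 5, alpha = 4, sd_scale = 1)
  e2$data[3, , ] <- e2$data[3, , ] * 8
  e2$data[9, , ] <- e2$data[9, , ] * 10
  e2$data[15, , ] <- e2$data[15, , ] * 12
  expect_warning(fl2 <- flag_and_interpolate_channels(e2), "worst 2")
  expect_length(fl2$flagged, 2)
  # interpolation reconstructs a flagged channel from neighbors on
  # noiseless data (all channels share the scaled component waveform)
  e3 <- simulate_epochs(sim_config(n_subjects_per_group = 1,
                                   noise_amplitude = 0,
                                   alpha_amplitude = 0, seed = 6),
                        "MT", scale_profile_sds(default_group_profiles(),
                                                0.05),
                        targets_only = TRUE)
  ch <- match("CP1", e3$channels)
  clean <- e3$data[ch, , 1]
  e3$data[ch, , ] <- e3$data[ch, , ] * 20
  fl3 <- flag_and_interpolate_channels(e3)
  expect_true("CP1" %in% fl3$flagged)
  expect_gt(cor(fl3$epochs$data[ch, , 1], clean), 0.99)
})
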