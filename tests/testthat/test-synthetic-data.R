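test_that("paradigm table drives trial counts and epoch spans", {
  spec <- paradigm_specs()
  expect_equal(spec$n_targets[spec$paradigm == "B/RB"], 60L)
  expect_equal(spec$n_nontargets[spec$paradigm == "B/RB"], 240L)
  e <- simulate_epochs(sim_config(n_subjects_per_group = 1, seed = 1),
                       "B/RB", targets_only = FALSE)
  # 60 targets + 240 non-targets per subject, two groups of one subject
  expect_equal(dim(e$data)[3], 600L)
  pro1 <- e$labels$subject == "PRO01"
  expect_equal(sum(pro1), 300L)
  expect_equal(sum(e$labels$target[pro1]), 60L)
  expect_equal(range(e$times), c(-200, 600))  # 800 ms epoch incl. 200 pre
  e2 <- tiny_epochs("ST", n = 1)
  expect_equal(range(e2$times), c(-500, 900)) # 1400 ms epoch incl. 500 pre
  expect_error(simulate_epochs(sim_config(seed = 1), "XX"),
               "unknown paradigm")
})

test_that("the generator is seed-deterministic", {
  cfg <- sim_config(n_subjects_per_group = 1, seed = 33)
  a <- simulate_epochs(cfg, "B/RB", targets_only = TRUE)
  b <- simulate_epochs(cfg, "B/RB", targets_only = TRUE)
  expect_identical(a$data, b$data)
  expect_identical(a$labels, b$labels)
  d <- simulate_epochs(sim_config(n_subjects_per_group = 1, seed = 34),
                       "B/RB", targets_only = TRUE)
  expect_false(identical(a$data, d$data))
  la <- simulate_cognitive_log(cfg)
  lb <- simulate_cognitive_log(cfg)
  expect_identical(la, lb)
})

test_that("noiseless zero-variance target epochs are identical with the peak at the planted P300", {
  prof <- scale_profile_sds(default_group_profiles(), 0)
  cfg <- sim_config(n_subjects_per_group = 1, noise_amplitude = 0,
                    alpha_amplitude = 0, seed = 5)
  e <- simulate_epochs(cfg, "MT", prof, targets_only = TRUE)
  pro <- which(e$labels$group == "PRO")
  expect_lt(max(abs(e$data[, , pro[1]] - e$data[, , pro[2]])), 1e-9)
  # overall extremum of the Pz trace sits at the (calibrated) P300 knot,
  # within a few samples of the configured latency
  pz <- match("Pz", e$channels)
  pk_t <- e$times[which.max(e$data[pz, , pro[1]])]
  lat_cfg <- erp_reference_stats()
  lat_cfg <- lat_cfg$lat_pro_mean[lat_cfg$paradigm == "MT" &
                                    lat_cfg$component == "P300"]
  expect_lt(abs(pk_t - lat_cfg), 20)
  # and the measured fractional-area latency equals the configured value
  w <- subject_erps(e)
  tb <- measure_components_table(w, "MT")
  expect_lt(abs(tb$latency_ms[tb$component == "P300" &
                                tb$group == "PRO"][1] - lat_cfg), 4)
})

test_that("component parameters are recovered per subject from low-noise data", {
  prof <- scale_profile_sds(default_group_profiles(), 0.1)
  for (par in c("MT", "ST")) {
    cfg <- sim_config(n_subjects_per_group = 3, noise_amplitude = 0.25,
                      alpha_amplitude = 0.25, seed = 7)
    e <- simulate_epochs(cfg, par, prof, targets_only = TRUE)
    w <- subject_erps(e)
    tb <- measure_components_table(w, par)
    mg <- merge(tb, e$truth, by = c("subject", "group", "component"),
                suffixes = c("", ".true"))
    expect_lt(max(abs(mg$latency_ms - mg$latency_ms.true)), 8)
    expect_lt(max(abs(mg$amplitude_uV - mg$amplitude_uV.true)), 0.5)
    expect_true(all(mg$valid))
  }
})

test_that("cognitive log has the documented structure and plug-in behavior", {
  cfg <- sim_config(n_subjects_per_group = 10, outlier_frac = 0, seed = 2)
  log <- simulate_cognitive_log(cfg)
  # 30 RTD trials x 10 members -> the pooled group metric is built from
  # 300 values before filtering
  expect_equal(sum(log$test == "RTD" & log$group == "PRO"), 300L)
  f <- filter_rts(log$rt_ms[log$test == "RTD" & log$group == "PRO"],
                  -Inf, Inf, iqr_fence = FALSE)
  expect_length(f$kept, 300L)
  expect_setequal(unique(log$test), c("RTM", "RTK", "RTD", "VS", "MT", "ST"))
  # counted-target rows carry true counts from the paradigm table
  expect_equal(unique(log$true_count[log$test == "ST"]), 56L)

  # degenerate correctness probability -> correct rate exactly 100%
  prof <- default_group_profiles()
  prof$PRO$cognitive$rtd_correct_rate <- 100
  log2 <- simulate_cognitive_log(cfg, prof)
  rtd <- log2[log2$test == "RTD" & log2$group == "PRO", ]
  expect_equal(correct_rate(rtd$correct), 100)

  # sd -> 0, no outliers: pooled RTM group difference equals the
  # configured difference
  prof0 <- scale_profile_sds(default_group_profiles(), 0)
  log3 <- simulate_cognitive_log(sim_config(outlier_frac = 0, seed = 3),
                                 prof0)
  gm <- cognitive_group_metrics(log3)
  pro <- gm$values[[which(gm$metric == "RTM.reaction_time" &
                            gm$group == "PRO")]]
  nov <- gm$values[[which(gm$metric == "RTM.reaction_time" &
                            gm$group == "NOVICE")]]
  expect_equal(mean(nov) - mean(pro), 271 - 219, tolerance = 1e-6)
})

test_that("profile validation catches bad inputs", {
  prof <- default_group_profiles()
  prof$PRO$erp$lat_mean[prof$PRO$erp$paradigm == "MT"] <- c(300, 250, 400)
  expect_error(simulate_epochs(sim_config(seed = 1), "MT", prof),
               "ordered")
  prof2 <- default_group_profiles()
  prof2$NOVICE$erp$amp_sd[1] <- -1
  expect_error(simulate_epochs(sim_config(seed = 1), "B/RB", prof2),
               "negative SD")
  prof3 <- default_group_profiles()
  prof3$PRO$cognitive$rtd_correct_rate <- 140
  expect_error(simulate_cognitive_log(sim_config(seed = 1), prof3),
               "probability")
})
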