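test_that("eeg simulator places tents exactly and is seed-deterministic", {
  times <- c(10, 30, 50)
  cfg <- eeg_sim_config(blink_times = times, noise_sd = 0, seed = 4,
                        duration = 60)
  sim <- simulate_eeg(cfg)
  # noiseless: local maxima of the blink channel sit at the given times
  x <- sim$recording$signal[, "Fpz"]
  peaks <- which(diff(sign(diff(x))) == -2) + 1
  peaks <- peaks[x[peaks] > max(x) / 2]
  expect_equal(length(peaks), length(times))
  expect_equal((peaks - 1) / cfg$fs, times, tolerance = 2 / cfg$fs)
  expect_equal(max(x), cfg$blink_amplitude)
  # ground-truth conservation
  expect_equal(nrow(sim$truth), length(times))
  # empty blink list, no noise -> flat zeros
  flat <- simulate_eeg(eeg_sim_config(blink_times = numeric(0),
                                      noise_sd = 0, duration = 10))
  expect_true(all(flat$recording$signal == 0))
  # seed determinism, bit-identical
  cfg_n <- eeg_sim_config(blink_times = times, noise_sd = 10, seed = 8,
                          duration = 60, saccade_times = 20)
  expect_identical(simulate_eeg(cfg_n), simulate_eeg(cfg_n))
})

test_that("eeg config rejects invalid geometry", {
  expect_error(eeg_sim_config(fs = 50), "100 Hz")
  expect_error(eeg_sim_config(blink_times = c(10, 10.2), duration = 60),
               "overlap")
  expect_error(eeg_sim_config(blink_times = c(-1, 10), duration = 60),
               "within")
})

test_that("participant simulator reproduces its generating model", {
  # no mediator noise: the X -> M equation is recovered exactly
  cfg0 <- population_sim_config(n_participants = 100, sigma_m = 0,
                                sigma_y = 0, seed = 2)
  p0 <- simulate_participants(cfg0)
  fm <- lm(flexibility ~ sebr + I(sebr^2), data = p0)
  expect_equal(unname(coef(fm)), c(cfg0$i_m, cfg0$a1, cfg0$a2),
               tolerance = 1e-8)
  # no outcome noise (mediator noise retained for identifiability):
  # the Y equation is recovered exactly
  cfgy <- population_sim_config(n_participants = 100, sigma_m = 0.3,
                                sigma_y = 0, seed = 2)
  py <- simulate_participants(cfgy)
  fy <- lm(originality ~ flexibility + sebr + I(sebr^2), data = py)
  expect_equal(unname(coef(fy)),
               c(cfgy$i_y, cfgy$b, cfgy$c1, cfgy$c2), tolerance = 1e-8)
  # large-sample recovery within 3 SEs under noise
  cfg <- population_sim_config(n_participants = 10000, a1 = 0.08,
                               a2 = -0.004, b = 1.5, sigma_m = 0.3,
                               sigma_y = 0.3, seed = 1)
  p <- simulate_participants(cfg)
  sm <- summary(lm(flexibility ~ sebr + I(sebr^2), data = p))$coefficients
  sy <- summary(lm(originality ~ flexibility + sebr + I(sebr^2),
                   data = p))$coefficients
  expect_lt(abs(sm["sebr", 1] - cfg$a1) / sm["sebr", 2], 3)
  expect_lt(abs(sm["I(sebr^2)", 1] - cfg$a2) / sm["I(sebr^2)", 2], 3)
  expect_lt(abs(sy["flexibility", 1] - cfg$b) / sy["flexibility", 2], 3)
  expect_true(all(p$sebr > 0))
  expect_identical(simulate_participants(cfg0), simulate_participants(cfg0))
})

test_that("an inverted U centred on the mean hides the linear correlation", {
  # apex of the X->M curve at the predictor mean: X and M nearly
  # uncorrelated even though the quadratic fit explains real variance
  cfg <- population_sim_config(n_participants = 5000, ebr_mean = 10,
                               ebr_sd = 4, a1 = 0.08, a2 = -0.004,
                               sigma_m = 0.05, seed = 6)
  p <- simulate_participants(cfg)
  expect_lt(abs(cor(p$sebr, p$flexibility)), 0.15)
  r2 <- summary(lm(flexibility ~ sebr + I(sebr^2), data = p))$r.squared
  expect_gt(r2, 0.5)
})

test_that("quadratic-term significance rates match the generating model", {
  # a2 != 0: significant at n = 1000 in at least 95% of 200 replicates
  hits <- vapply(seq_len(200), function(i) {
    p <- simulate_participants(population_sim_config(
      n_participants = 1000, seed = 1000 + i))
    s <- summary(lm(flexibility ~ sebr + I(sebr^2), data = p))
    s$coefficients["I(sebr^2)", 4] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # a2 = 0: significant in about 5% (+- 3 points) of 500 replicates
  null_hits <- vapply(seq_len(500), function(i) {
    p <- simulate_participants(population_sim_config(
      n_participants = 1000, a2 = 0, seed = 5000 + i))
    s <- summary(lm(flexibility ~ sebr + I(sebr^2), data = p))
    s$coefficients["I(sebr^2)", 4] < 0.05
  }, logical(1))
  expect_lt(abs(mean(null_hits) - 0.05), 0.03)
})

test_that("response simulator honours its degenerate contracts", {
  p <- simulate_participants(population_sim_config(n_participants = 12,
                                                   seed = 3))
  # zero rater noise -> perfect agreement -> ICC exactly 1
  r0 <- simulate_aut_responses(p, response_sim_config(rater_noise_sd = 0,
                                                      seed = 2))
  icc <- compute_icc(as.matrix(r0[, c("rater1_score", "rater2_score")]))
  expect_equal(icc$icc, 1.0)
  # single-category codebook -> flexibility 1.0 for everyone
  cb <- list(brick = "weight", hat = "container")
  r1 <- simulate_aut_responses(p, response_sim_config(
    n_objects = 2, category_codebook = cb, seed = 2))
  ff <- score_flexibility_fluency(r1)
  expect_true(all(ff$flexibility == 1.0))
  expect_true(all(r1$category_label %in% unlist(cb)))
  # empty codebook rejected
  expect_error(simulate_aut_responses(p, response_sim_config(
    n_objects = 2, category_codebook = list(brick = "a", hat = character(0)),
    seed = 2)), "empty category codebook")
  # rater scores clipped to the 1-5 scale; determinism
  cfg <- response_sim_config(seed = 7)
  r2 <- simulate_aut_responses(p, cfg)
  expect_true(all(r2$rater1_score >= 1 & r2$rater1_score <= 5))
  expect_identical(r2, simulate_aut_responses(p, cfg))
})

test_that("rater-noise calibration reaches the target ICC at scale", {
  p <- simulate_participants(population_sim_config(n_participants = 80,
                                                   seed = 5))
  r <- simulate_aut_responses(p, response_sim_config(target_icc = 0.88,
                                                     seed = 9))
  expect_gt(nrow(r), 1200)  # of the order of the full idea set
  icc <- compute_icc(as.matrix(r[, c("rater1_score", "rater2_score")]))
  expect_lt(abs(icc$icc - 0.88), 0.05)
})
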