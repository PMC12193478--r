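test_that("invalid walk configs name the offending field", {
  expect_error(walkSimConfig(n_frames = 1), "n_frames")
  expect_error(walkSimConfig(step_sd = -1), "step_sd")
  expect_error(walkSimConfig(dropout_rate = 1), "dropout_rate")
  expect_error(walkSimConfig(lr_asymmetry = -0.5), "lr_asymmetry")
})

test_that("zero-noise trials give exactly zero variance through the pipeline", {
  seq <- simulateWalkTrial(walkSimConfig(n_frames = 80, step_sd = 0,
                                         trend = 0, dropout_rate = 0,
                                         seed = 5))
  tracks <- extractFootTracks(seq, 0.3)
  expect_identical(displacementVariance(frameDisplacements(tracks$left))@variance, 0)
  expect_identical(displacementVariance(frameDisplacements(tracks$right))@variance, 0)
})

test_that("identical config and seed reproduce the trial exactly", {
  cfg <- walkSimConfig(n_frames = 40, step_sd = 2, trend = 0.02,
                       dropout_rate = 0.2, seed = 77)
  s1 <- simulateWalkTrial(cfg)
  s2 <- simulateWalkTrial(cfg)
  expect_identical(s1@keypoints, s2@keypoints)
})

test_that("pipeline variance agrees with a Monte-Carlo oracle of the step model", {
  cfg <- walkSimConfig(n_frames = 5000, step_mean = 10, step_sd = 2, seed = 19)
  seq <- simulateWalkTrial(cfg, foot_phase_offset = 0.5)
  got <- displacementVariance(frameDisplacements(
    extractFootTracks(seq, 0)$left))@variance
  # direct re-simulation of the stated generative rule: steps are
  # mean + sd * (1 + amp*sin(2*pi*k/period)) * z, feet advance along x only
  set.seed(4242)
  reps <- replicate(40, {
    ks <- seq_len(cfg@n_frames - 1L)
    m <- 1 + cfg@phase_amplitude * sin(2 * pi * ks / cfg@gait_period)
    steps <- cfg@step_mean + cfg@step_sd * m * rnorm(length(ks))
    twoPassVariance(abs(steps))
  })
  expect_lt(abs(got - mean(reps)) / mean(reps), 0.10)
})

test_that("dropout lowers detection confidence at the configured rate", {
  cfg <- walkSimConfig(n_frames = 4000, dropout_rate = 0.25, seed = 23)
  seq <- simulateWalkTrial(cfg)
  feet_conf <- seq@keypoints[, 16:17, 3]
  frac_low <- mean(apply(feet_conf < 0.3, 1, any))
  expect_lt(abs(frac_low - 0.25), 0.03)
  # dropped frames removed by extraction, both tracks stay aligned
  tracks <- extractFootTracks(seq, 0.3)
  expect_equal(nFrames(tracks$left), nFrames(tracks$right))
  expect_equal(nDropped(tracks$left), 4000L - nFrames(tracks$left))
})

test_that("lr_asymmetry scales right-foot step statistics multiplicatively", {
  cfg <- walkSimConfig(n_frames = 3000, step_mean = 6, step_sd = 1.5,
                       lr_asymmetry = 1.6, seed = 29)
  seq <- simulateWalkTrial(cfg)
  tracks <- extractFootTracks(seq, 0)
  dl <- displacements(frameDisplacements(tracks$left))
  dr <- displacements(frameDisplacements(tracks$right))
  expect_equal(mean(dr) / mean(dl), 1.6, tolerance = 0.05)
  expect_equal(sd(dr) / sd(dl), 1.6, tolerance = 0.10)
})

test_that("cohort simulation is reproducible and structurally complete", {
  cfg <- cohortSimConfig(n_subjects = 6, seed = 12)
  s1 <- simulateCohort(cfg)
  s2 <- simulateCohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$features, s2$features)
  expect_equal(names(s1$cohort),
               c("subject_id", "age", "gender", "height_cm", "weight_kg",
                 "score2_1", "score2_2", "score2",
                 "duration1", "duration2", "duration"))
  expect_equal(s1$cohort$duration,
               s1$cohort$duration1 + s1$cohort$duration2)
  expect_true(all(s1$cohort$score2 ==
                    pmax(s1$cohort$score2_1, s1$cohort$score2_2)))
  expect_error(cohortSimConfig(n_subjects = 1), "n_subjects")
})

test_that("noiseless coupling gives a perfectly linear duration link", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 12, noise_sd = 0,
                                        coupling_beta = -0.4, seed = 3))
  expect_equal(cor(sim$features$var_mean, sim$cohort$duration), -1,
               tolerance = 1e-12)
  # per-trial durations reconstruct exactly from the linear rule
  expect_equal(sim$cohort$duration1,
               12 - 0.4 * sim$features$var_mean_2_1, tolerance = 1e-12)
})

test_that("zero coupling leaves var_mean and duration uncorrelated", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 150, coupling_beta = 0,
                                        noise_sd = 1, seed = 8))
  r <- cor(sim$features$var_mean, sim$cohort$duration)
  expect_lt(abs(r), 2 / sqrt(150))
})

test_that("calibrated noise recovers the analytic correlation (n=200)", {
  # pilot: measure the var_mean spread of the generator at these settings
  beta <- -0.4
  pilot <- simulateCohort(cohortSimConfig(n_subjects = 200, noise_sd = 0,
                                          coupling_beta = beta, seed = 500))
  sigma_vm <- sd(pilot$features$var_mean)
  noise <- calibrateNoiseSD(beta, sigma_vm, 0.9)
  expect_equal(analyticDurationCorrelation(beta, sigma_vm, noise), -0.9,
               tolerance = 1e-12)
  rs <- vapply(1:5, function(i) {
    sim <- simulateCohort(cohortSimConfig(n_subjects = 200, noise_sd = noise,
                                          coupling_beta = beta,
                                          seed = 1000 + i))
    cor(sim$features$var_mean, sim$cohort$duration)
  }, numeric(1))
  expect_lt(abs(mean(rs) - (-0.9)), 0.05)
})

test_that("exact-correlation feature matrices hit the target to machine precision", {
  R <- blockExchangeableCorrelation(0.6, 0.2)
  X <- simulateFeatureMatrix(40, correlation = R, seed = 6)
  expect_equal(unname(cor(X)), unname(R), tolerance = 1e-12)
  expect_equal(colnames(X),
               c("var15_test2_1", "var16_test2_1",
                 "var15_test2_2", "var16_test2_2"))
  # rank-2 route
  Y <- simulateFeatureMatrix(20, n_factors = 2, seed = 6)
  expect_equal(qr(scale(Y, scale = FALSE))$rank, 2L)
})
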