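## Synthetic-data generator: walking-trial keypoint streams and cohort
## tables with the statistical structure the downstream analysis assumes.
##
## Walk model: the foot advances along x with per-frame step
##   step_k = step_mean + trend * (k - 1) + step_sd * m_k * z_k,  z_k ~ N(0,1)
## where m_k = 1 + phase_amplitude * sin(2*pi*(k / gait_period + phase))
## modulates the noise envelope over the gait cycle, and the two feet carry
## a configurable phase offset (alternating-foot pattern in the stochastic
## gait adjustments). With step_sd = 0 and trend = 0 the walk is exactly
## constant-step, so the pipeline's displacement variance is exactly zero.
## The right foot's step mean, trend and noise SD are multiplied by
## lr_asymmetry.

#' Build a validated WalkSimConfig
#'
#' @param n_frames number of frames (>= 2)
#' @param step_mean mean per-frame foot displacement (pixels)
#' @param step_sd per-frame displacement noise SD (pixels, >= 0)
#' @param trend linear stride-length drift (pixels/frame; may be negative)
#' @param lr_asymmetry multiplier on right-foot step statistics (>= 0)
#' @param dropout_rate probability in `[0, 1)` that a frame has a
#'   low-confidence foot keypoint
#' @param gait_period gait-cycle length in frames
#' @param phase_amplitude amplitude in `[0, 1]` of the gait-phase modulation
#'   of the noise SD
#' @param seed integer RNG seed
#' @return a [WalkSimConfig-class]
#' @seealso [simulateWalkTrial()]
#' @export
walkSimConfig <- function(n_frames = 150L, step_mean = 8, step_sd = 2,
                          trend = 0, lr_asymmetry = 1, dropout_rate = 0,
                          gait_period = 30, phase_amplitude = 0.5,
                          seed = 1L) {
  assertField(is.numeric(n_frames) && length(n_frames) == 1L && n_frames >= 2,
              "n_frames", "must be a count >= 2")
  assertField(is.numeric(step_sd) && step_sd >= 0, "step_sd", "must be >= 0")
  assertField(is.numeric(dropout_rate) && dropout_rate >= 0 && dropout_rate < 1,
              "dropout_rate", "must lie in [0, 1)")
  assertField(is.numeric(lr_asymmetry) && lr_asymmetry >= 0,
              "lr_asymmetry", "must be >= 0")
  assertField(is.numeric(phase_amplitude) && phase_amplitude >= 0 &&
                phase_amplitude <= 1,
              "phase_amplitude", "must lie in [0, 1]")
  new("WalkSimConfig",
      n_frames = as.integer(n_frames), step_mean = step_mean,
      step_sd = step_sd, trend = trend, lr_asymmetry = lr_asymmetry,
      dropout_rate = dropout_rate, gait_period = gait_period,
      phase_amplitude = phase_amplitude, seed = as.integer(seed))
}

## Fixed skeleton geometry for the 15 non-foot keypoints (0-based indices
## 0..14): lateral x offset from the body midline and y (image rows; feet
## sit near y = 400).
.SKELETON_OFFSETS <- data.frame(
  dx = c(0, -4, 4, -9, 9, -16, 16, -20, 20, -22, 22, -11, 11, -11, 11),
  y  = c(96, 90, 90, 98, 98, 150, 150, 210, 210, 268, 268, 255, 255, 330, 330)
)

#' Simulate one walking trial of skeletal keypoints
#'
#' Generates a forward walk: keypoints 15 (left foot) and 16 (right foot)
#' advance along x with per-frame steps drawn from the configured step
#' model; the two feet differ by `foot_phase_offset` gait-cycle fractions in
#' the phase of the noise-envelope modulation. The 15 non-foot keypoints are
#' filled by rigid torso interpolation above the feet midline. Dropout
#' frames receive one foot keypoint with confidence below 0.3. Output is
#' deterministic given the config seed.
#'
#' @param config a [WalkSimConfig-class]
#' @param foot_phase_offset right-foot phase lag as a fraction of the gait
#'   cycle (default 0.5: anti-phase feet)
#' @param subject_id,trial_id identifiers stamped on the sequence
#' @return a [PoseSequence-class] of `n_frames` frames
#' @examples
#' seq <- simulateWalkTrial(walkSimConfig(n_frames = 50, seed = 7))
#' tracks <- extractFootTracks(seq)
#' displacementVariance(frameDisplacements(tracks$left))
#' @export
simulateWalkTrial <- function(config, foot_phase_offset = 0.5,
                              subject_id = "sim", trial_id = "test2_1") {
  stopifnot(is(config, "WalkSimConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@n_frames
  ks <- seq_len(n - 1L)
  modulation <- function(phase)
    1 + config@phase_amplitude * sin(2 * pi * (ks / config@gait_period + phase))
  stepFor <- function(mean_f, sd_f, trend_f, phase)
    mean_f + trend_f * (ks - 1L) + sd_f * modulation(phase) * stats::rnorm(n - 1L)
  a <- config@lr_asymmetry
  steps_l <- stepFor(config@step_mean, config@step_sd, config@trend, 0)
  steps_r <- stepFor(a * config@step_mean, a * config@step_sd, a * config@trend,
                     foot_phase_offset)
  x_l <- 100 + c(0, cumsum(steps_l))
  x_r <- 100 + c(0, cumsum(steps_r))
  y_l <- rep(392, n)
  y_r <- rep(408, n)

  kp <- array(0, dim = c(n, N_KEYPOINTS, 3L),
              dimnames = list(NULL, NULL, c("x", "y", "confidence")))
  mid_x <- (x_l + x_r) / 2
  for (i in seq_len(nrow(.SKELETON_OFFSETS))) {
    kp[, i, 1L] <- mid_x + .SKELETON_OFFSETS$dx[i]
    kp[, i, 2L] <- .SKELETON_OFFSETS$y[i]
  }
  li <- FOOT_LEFT + 1L
  ri <- FOOT_RIGHT + 1L
  kp[, li, 1L] <- x_l; kp[, li, 2L] <- y_l
  kp[, ri, 1L] <- x_r; kp[, ri, 2L] <- y_r
  kp[, , 3L] <- stats::runif(n * N_KEYPOINTS, 0.9, 1)

  if (config@dropout_rate > 0) {
    drop <- which(stats::runif(n) < config@dropout_rate)
    if (length(drop)) {
      foot <- sample(c(li, ri), length(drop), replace = TRUE)
      kp[cbind(drop, foot, 3L)] <- stats::runif(length(drop), 0, 0.25)
    }
  }
  PoseSequence(kp, subject_id = subject_id, trial_id = trial_id)
}

#' Build a validated CohortSimConfig
#'
#' Defaults emulate a small community-dwelling elderly cohort performing a
#' twice-repeated 4-m walking test: ages 60-90, predominantly male (as in
#' the motivating cohort), per-trial baseline duration around 12 s reduced
#' by the gait-variability coupling, and SPPB-style per-trial scoring from
#' standard 4-m gait-speed cutpoints (4.82 / 6.21 / 8.70 s).
#'
#' @param n_subjects number of subjects (>= 2)
#' @param age_range,height_range,weight_range length-2 sampling bounds
#'   (years, cm, kg)
#' @param male_fraction fraction of male subjects in `[0, 1]`
#' @param step_mean mean per-frame step (pixels)
#' @param step_sd_range per-subject step-noise SD bounds (pixels); the
#'   across-subject heterogeneity that spreads var_mean
#' @param trend_range per-subject stride-trend bounds (pixels/frame),
#'   emulating gradually increasing or decreasing stride length
#' @param n_frames frames per trial
#' @param duration_intercept baseline per-trial duration (seconds)
#' @param coupling_beta slope (s per px^2) linking per-trial mean variance to
#'   duration; negative reproduces the negative variability-duration
#'   association
#' @param noise_sd duration residual SD (seconds, >= 0)
#' @param score_breaks increasing duration cutpoints (s) for ordinal scoring
#' @param score_max top ordinal score
#' @param seed integer RNG seed
#' @return a [CohortSimConfig-class]
#' @seealso [simulateCohort()]
#' @export
cohortSimConfig <- function(n_subjects = 19L,
                            age_range = c(60, 90),
                            height_range = c(145, 180),
                            weight_range = c(40, 90),
                            male_fraction = 0.79,
                            step_mean = 8,
                            step_sd_range = c(1, 4),
                            trend_range = c(-0.01, 0.01),
                            n_frames = 150L,
                            duration_intercept = 12,
                            coupling_beta = -0.4,
                            noise_sd = 0.5,
                            score_breaks = c(4.82, 6.21, 8.70),
                            score_max = 4L,
                            seed = 1L) {
  assertField(is.numeric(n_subjects) && n_subjects >= 2,
              "n_subjects", "must be >= 2")
  assertField(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  assertField(is.numeric(male_fraction) && male_fraction >= 0 &&
                male_fraction <= 1, "male_fraction", "must lie in [0, 1]")
  new("CohortSimConfig",
      n_subjects = as.integer(n_subjects),
      age_range = age_range, height_range = height_range,
      weight_range = weight_range, male_fraction = male_fraction,
      step_mean = step_mean, step_sd_range = step_sd_range,
      trend_range = trend_range, n_frames = as.integer(n_frames),
      duration_intercept = duration_intercept,
      coupling_beta = coupling_beta, noise_sd = noise_sd,
      score_breaks = score_breaks, score_max = as.integer(score_max),
      seed = as.integer(seed))
}

## Derive a stream of per-trial seeds from the master seed, kept < 2^31.
.deriveSeeds <- function(seed, n) {
  (as.double(seed) * 48271 + 1e4 * seq_len(n)) %% 2147483647
}

#' Simulate a study cohort with coupled gait variability and test duration
#'
#' For each subject: draws demographics and per-subject walk parameters,
#' generates the two walking-trial pose sequences, runs the feature pipeline
#' (confidence filtering, displacements, variances, composite index), and
#' generates per-trial durations as
#' `duration_j = duration_intercept + coupling_beta * var_mean_2_j + noise`
#' with Gaussian residuals. Per-trial ordinal scores follow the configured
#' duration cutpoints; the overall Test-2 score is the better (maximum) of
#' the two trials and the overall duration is the sum of the two. The whole
#' cohort is reproducible under the config seed.
#'
#' @param config a [CohortSimConfig-class]
#' @param keep_trials logical; also return the simulated pose sequences
#' @param min_confidence confidence threshold used by the feature pipeline
#' @return list with components `cohort` (data.frame with columns
#'   `subject_id, age, gender, height_cm, weight_kg, score2_1, score2_2,
#'   score2, duration1, duration2, duration`), `features` (the
#'   [gaitFeatures()] data.frame), and `trials` (if `keep_trials`, a named
#'   list of per-subject `list(test2_1 =, test2_2 =)` pose sequences)
#' @examples
#' sim <- simulateCohort(cohortSimConfig(n_subjects = 5, seed = 3))
#' head(sim$cohort)
#' @export
simulateCohort <- function(config, keep_trials = FALSE, min_confidence = 0.3) {
  stopifnot(is(config, "CohortSimConfig"))
  validObject(config)
  n <- config@n_subjects
  set.seed(config@seed)
  ## draw all cohort-level randomness before trial simulation touches the RNG
  age <- round(stats::runif(n, config@age_range[1L], config@age_range[2L]))
  gender <- ifelse(stats::runif(n) < config@male_fraction, "male", "female")
  height <- round(stats::runif(n, config@height_range[1L],
                               config@height_range[2L]), 1)
  weight <- round(stats::runif(n, config@weight_range[1L],
                               config@weight_range[2L]), 1)
  step_sd <- stats::runif(n, config@step_sd_range[1L], config@step_sd_range[2L])
  trend <- stats::runif(n, config@trend_range[1L], config@trend_range[2L])
  lr_asym <- stats::runif(n, 0.9, 1.1)
  dur_noise <- matrix(stats::rnorm(2L * n, 0, config@noise_sd), ncol = 2L)
  trial_seeds <- .deriveSeeds(config@seed, 2L * n)

  ids <- sprintf("S%03d", seq_len(n))
  trials <- vector("list", n)
  names(trials) <- ids
  for (i in seq_len(n)) {
    trials[[i]] <- lapply(stats::setNames(1:2, c("test2_1", "test2_2")),
      function(j) {
        cfg <- walkSimConfig(
          n_frames = config@n_frames, step_mean = config@step_mean,
          step_sd = step_sd[i], trend = trend[i],
          lr_asymmetry = lr_asym[i], dropout_rate = 0,
          seed = trial_seeds[2L * (i - 1L) + j])
        simulateWalkTrial(cfg, subject_id = ids[i],
                          trial_id = paste0("test2_", j))
      })
  }

  features <- gaitFeatures(trials, min_confidence = min_confidence)
  dur1 <- config@duration_intercept +
    config@coupling_beta * features$var_mean_2_1 + dur_noise[, 1L]
  dur2 <- config@duration_intercept +
    config@coupling_beta * features$var_mean_2_2 + dur_noise[, 2L]
  scoreOf <- function(d)
    pmax(config@score_max - findInterval(d, config@score_breaks), 0L)
  cohort <- data.frame(
    subject_id = ids, age = age, gender = gender,
    height_cm = height, weight_kg = weight,
    score2_1 = scoreOf(dur1), score2_2 = scoreOf(dur2),
    score2 = pmax(scoreOf(dur1), scoreOf(dur2)),
    duration1 = dur1, duration2 = dur2, duration = dur1 + dur2)
  out <- list(cohort = cohort, features = features)
  if (keep_trials) out$trials <- trials
  out
}

#' Analytic var_mean-duration correlation of the cohort generator
#'
#' Under the generator's linear link the total duration is
#' `2 * intercept + 2 * beta * var_mean + e1 + e2` with independent
#' `N(0, noise_sd^2)` residuals per trial, so the population Pearson
#' correlation between var_mean and total duration is
#' \deqn{\rho = \frac{2\beta\sigma_{vm}}
#'   {\sqrt{4\beta^2\sigma_{vm}^2 + 2\sigma_{noise}^2}}.}
#'
#' @param beta duration-coupling slope (s per px^2)
#' @param sigma_vm across-subject SD of var_mean (px^2)
#' @param noise_sd per-trial duration residual SD (s)
#' @return the signed population correlation
#' @seealso [calibrateNoiseSD()] for the inverse
#' @export
analyticDurationCorrelation <- function(beta, sigma_vm, noise_sd) {
  2 * beta * sigma_vm / sqrt(4 * beta^2 * sigma_vm^2 + 2 * noise_sd^2)
}

#' Duration noise SD that yields a target var_mean-duration correlation
#'
#' Inverts [analyticDurationCorrelation()]: given the coupling slope and the
#' across-subject spread of var_mean, returns the per-trial residual SD for
#' which the population correlation between var_mean and total duration
#' equals `rho` in magnitude.
#'
#' @param beta duration-coupling slope
#' @param sigma_vm across-subject SD of var_mean
#' @param rho target correlation magnitude in `(0, 1]`
#' @return per-trial duration residual SD (seconds)
#' @export
calibrateNoiseSD <- function(beta, sigma_vm, rho) {
  stopifnot(abs(rho) > 0, abs(rho) <= 1)
  abs(beta) * sigma_vm * sqrt(2 * (1 / rho^2 - 1))
}

#' Simulate a four-feature matrix with prescribed structure
#'
#' Generates an `n x 4` matrix of gait-variance features (columns ordered
#' `var15_test2_1, var16_test2_1, var15_test2_2, var16_test2_2`) either
#' (a) with an exactly prescribed sample correlation matrix — the draws are
#' empirically whitened and recolored by the Cholesky factor of `correlation`,
#' so `cor(result)` equals it to machine precision — or (b) as linear
#' combinations of `n_factors` independent latent factors (a rank-deficient
#' feature set).
#'
#' @param n_subjects number of rows (must exceed 4 for the exact-correlation
#'   route)
#' @param correlation optional 4 x 4 positive-definite target sample
#'   correlation matrix
#' @param n_factors optional latent-factor count in `1..3` (ignored when
#'   `correlation` is given)
#' @param seed integer RNG seed
#' @return numeric `n_subjects x 4` matrix with feature column names
#' @seealso [fitPCAIndex()]
#' @export
simulateFeatureMatrix <- function(n_subjects, correlation = NULL,
                                  n_factors = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  if (!is.null(correlation)) {
    stopifnot(all(dim(correlation) == c(4L, 4L)), n_subjects > 4L)
    X <- matrix(stats::rnorm(n_subjects * 4L), ncol = 4L)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    Y <- Xc %*% solve(chol(crossprod(Xc) / (n_subjects - 1))) %*%
      chol(correlation)
  } else if (!is.null(n_factors)) {
    stopifnot(n_factors >= 1L, n_factors <= 3L)
    F <- matrix(stats::rnorm(n_subjects * n_factors), ncol = n_factors)
    A <- matrix(stats::rnorm(n_factors * 4L, sd = 1) + 1, nrow = n_factors)
    Y <- F %*% A
  } else {
    stop("supply either 'correlation' or 'n_factors'")
  }
  Y <- Y + 10  # variances live on a positive scale
  colnames(Y) <- FEATURE_COLS
  Y
}

#' Block-exchangeable correlation matrix of the four variance features
#'
#' The 4 x 4 correlation matrix that is invariant under swapping feet and
#' under swapping trials: within-trial left-right correlation `a`, all four
#' cross-trial correlations `b`. Its eigenvectors are forced by the two swap
#' symmetries to `(1,1,1,1)/2` and `(1,1,-1,-1)/2` (plus two within-trial
#' contrasts), so correlation-matrix PCA of data with this structure yields
#' loadings of exactly 0.5 in magnitude.
#'
#' @param within within-trial (left-right) correlation
#' @param between cross-trial correlation
#' @return 4 x 4 correlation matrix in feature column order
#' @export
blockExchangeableCorrelation <- function(within = 0.6, between = 0.2) {
  R <- matrix(between, 4L, 4L)
  R[1L, 2L] <- R[2L, 1L] <- within
  R[3L, 4L] <- R[4L, 3L] <- within
  diag(R) <- 1
  dimnames(R) <- list(FEATURE_COLS, FEATURE_COLS)
  R
}
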