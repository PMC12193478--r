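test_that("auto-classification follows the kind rules", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 15, seed = 4))
  specs <- classifyVariables(merge(sim$cohort, sim$features))
  kinds <- vapply(specs, function(s) s@kind, character(1))
  expect_equal(unname(kinds["gender"]), "binary")
  expect_equal(unname(kinds["score2_1"]), "ordinal")
  expect_equal(unname(kinds["score2"]), "ordinal")
  expect_equal(unname(kinds["height_cm"]), "continuous")
  expect_equal(unname(kinds["duration2"]), "continuous")
  expect_equal(unname(kinds["var_mean"]), "continuous")
  expect_false("subject_id" %in% names(specs))
})

test_that("overrides win and constant columns are excluded with a warning", {
  df <- data.frame(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2),
                   s = c(0, 1, 1, 2))
  expect_warning(specs <- classifyVariables(df), "constant column 'b'")
  expect_false("b" %in% names(specs))
  specs2 <- suppressWarnings(
    classifyVariables(df, overrides = c(s = "continuous")))
  expect_equal(specs2$s@kind, "continuous")
})

test_that("ordinal preprocessing midranks ties then z-scores", {
  sp <- varSpec("o", "ordinal", c(1, 2, 2, 4))
  z <- preprocessVariable(sp)
  r <- c(1, 2.5, 2.5, 4)
  expect_equal(z, (r - mean(r)) / sd(r))
  expect_equal(sum(z), 0)
  expect_error(preprocessVariable(varSpec("t", "ordinal", c(2, 2, 2))),
               "zero-variance ordinal")
})

test_that("LOWESS smoothing reproduces constants and can be disabled", {
  sp <- varSpec("c", "continuous", rep(3.3, 12))
  expect_equal(preprocessVariable(sp, smooth = TRUE), rep(3.3, 12))
  sp2 <- varSpec("c", "continuous", sin(1:20))
  expect_identical(preprocessVariable(sp2, smooth = FALSE), sp2@values)
  expect_false(identical(preprocessVariable(sp2, smooth = TRUE), sp2@values))
})

test_that("method dispatch matches the kind lookup table for all six pairs", {
  n <- 30
  set.seed(55)
  specs <- list(
    binary = varSpec("b", "binary", rep(0:1, 15)),
    ordinal = varSpec("o", "ordinal", sample(0:4, n, TRUE)),
    continuous = varSpec("c", "continuous", rnorm(n)))
  want <- rbind(
    c("binary", "binary", "undefined_default"),
    c("binary", "ordinal", "point_biserial"),
    c("binary", "continuous", "point_biserial"),
    c("ordinal", "ordinal", "kendall_tau"),
    c("ordinal", "continuous", "spearman"),
    c("continuous", "continuous", "pearson"))
  for (i in seq_len(nrow(want))) {
    a <- specs[[want[i, 1]]]
    b <- specs[[want[i, 2]]]
    expect_equal(pairwiseCorrelation(a, b)$method, want[i, 3])
    expect_equal(pairwiseCorrelation(b, a)$method, want[i, 3])
  }
})

test_that("binary-binary pairs return the undefined default", {
  r <- pairwiseCorrelation(varSpec("b1", "binary", c(0, 1, 0, 1)),
                           varSpec("b2", "binary", c(1, 1, 0, 0)))
  expect_true(is.na(r$coefficient))
  expect_true(is.na(r$p_raw))
  expect_match(r$note, "binary-binary")
})

test_that("point-biserial equals Pearson on the 0/1 coding", {
  b <- varSpec("b", "binary", c(0, 0, 1, 1))
  x <- varSpec("x", "continuous", c(1, 2, 3, 4))
  r <- pairwiseCorrelation(b, x)
  expect_equal(r$coefficient, 0.8944272, tolerance = 1e-6)
  expect_equal(r$coefficient, cor(c(0, 0, 1, 1), 1:4), tolerance = 1e-12)
})

test_that("rank coefficients hit their exact extremes", {
  o1 <- varSpec("o1", "ordinal", 1:6)
  o2 <- varSpec("o2", "ordinal", 6:1)
  expect_equal(pairwiseCorrelation(o1, o2)$coefficient, -1)
  x <- varSpec("x", "continuous", c(2.2, 5.1, 7.9, 8, 11, 30))
  expect_equal(pairwiseCorrelation(o1, x)$method, "spearman")
  expect_equal(pairwiseCorrelation(o1, x)$coefficient, 1)
  # continuous self-correlation, smoothing off
  expect_equal(pairwiseCorrelation(x, x)$coefficient, 1)
})

test_that("degenerate pairs are handled explicitly", {
  short_a <- varSpec("a", "continuous", c(1, 2, NA, NA))
  short_b <- varSpec("b", "continuous", c(2, 1, NA, NA))
  expect_error(pairwiseCorrelation(short_a, short_b), ">= 3 paired")
  flat <- varSpec("f", "continuous", c(1, 1, 1, 1))
  x <- varSpec("x", "continuous", c(1, 2, 3, 4))
  r <- pairwiseCorrelation(flat, x)
  expect_true(is.na(r$coefficient))
  expect_match(r$note, "zero variance")
})

test_that("BH adjustment matches the hand step-up on toy vectors", {
  expect_equal(fdrAdjust(0.03), 0.03)
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(rep(0.02, 5)), rep(0.02, 5))
  set.seed(66)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    got <- fdrAdjust(p)
    want <- bhStepUp(p)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got >= p - 1e-15))
    expect_true(all(got <= 1))
    expect_true(all(diff(got[order(p)]) >= -1e-15))
  }
  # NA entries stay NA and do not enter the family
  p <- c(0.01, NA, 0.04)
  expect_equal(fdrAdjust(p), c(0.02, NA, 0.04))
})

test_that("the full matrix is symmetric with a unit diagonal and stars", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 25, seed = 10))
  cm <- correlationMatrix(merge(sim$cohort, sim$features))
  co <- corCoefficients(cm)
  expect_equal(co, t(co))
  nb <- cm@kinds != "binary"
  expect_equal(unname(diag(co)[nb]), rep(1, sum(nb)))
  pr <- rawPvalues(cm); pa <- adjustedPvalues(cm)
  ok <- !is.na(pr)
  expect_true(all(pa[ok] >= pr[ok]))
  expect_true(all(abs(co[!is.na(co)]) <= 1 + 1e-12))
  st <- starMatrix(cm)
  expect_true(all(st[!is.na(pa) & pa < 0.001] == "***"))
  expect_true(all(st[is.na(pa)] == ""))
})

test_that("star thresholds and coefficient rendering follow convention", {
  expect_equal(significanceStars(c(0.0005, 0.005, 0.04, 0.2)),
               c("***", "**", "*", ""))
  expect_equal(gaitvar:::formatCoef(c(-0.955, 0.871, NA)),
               c("-0.96", "0.87", ""))
})

test_that("export yields one row per off-diagonal pair with blanks where undefined", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 12, seed = 14))
  df <- merge(sim$cohort, sim$features)
  df$frail <- rep(c("yes", "no"), 6)  # second binary variable
  cm <- correlationMatrix(df)
  out <- exportCorrelations(cm)
  p <- length(cm@variables)
  expect_equal(nrow(out), p * (p - 1) / 2)
  bb <- out$method == "undefined_default"
  expect_true(any(bb))
  expect_true(all(out$label[bb] == ""))
  expect_true(all(out$stars[bb] == ""))
  path <- withr::local_tempfile(fileext = ".csv")
  exportCorrelations(cm, path)
  expect_equal(nrow(utils::read.csv(path)), nrow(out))
})

test_that("noiseless coupled cohorts show Mean x duration = -1.00***", {
  sim <- simulateCohort(cohortSimConfig(n_subjects = 20, noise_sd = 0,
                                        coupling_beta = -0.4, seed = 17))
  cm <- correlationMatrix(merge(sim$cohort, sim$features))
  expect_equal(corCoefficients(cm)["var_mean", "duration"], -1,
               tolerance = 1e-10)
  expect_equal(starMatrix(cm)["var_mean", "duration"], "***")
  expect_equal(gaitvar:::formatCoef(
    corCoefficients(cm)["var_mean", "duration"]), "-1.00")
})
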