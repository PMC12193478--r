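test_that("canonical JSON round-trips a simulated trial exactly", {
  seq <- simulateWalkTrial(walkSimConfig(n_frames = 12, seed = 42),
                           subject_id = "S1", trial_id = "test2_1")
  path <- withr::local_tempfile(fileext = ".json")
  writeKeypointJSON(seq, path)
  back <- readKeypointJSON(path)
  expect_equal(back@subject_id, "S1")
  expect_equal(back@trial_id, "test2_1")
  expect_equal(back@keypoints, seq@keypoints, tolerance = 1e-9,
               ignore_attr = TRUE)
  # well beyond the 6-decimal contract
  expect_lt(max(abs(back@keypoints - seq@keypoints)), 1e-6)
})

test_that("writer output is byte-identical for identical config and seed", {
  cfg <- walkSimConfig(n_frames = 20, step_sd = 1.5, dropout_rate = 0.1,
                       seed = 7)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeKeypointJSON(simulateWalkTrial(cfg), p1)
  writeKeypointJSON(simulateWalkTrial(cfg), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("empty-frame files parse to a zero-length sequence with a warning", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"subject_id":"e","trial_id":"t","frames":[]}', path)
  expect_warning(seq <- readKeypointJSON(path), "empty")
  expect_equal(nFrames(seq), 0L)
})

test_that("reader enforces the 17-keypoint schema and reports the frame", {
  path <- withr::local_tempfile(fileext = ".json")
  bad <- jsonlite::toJSON(list(frames = list(
    list(keypoints = rep(list(c(0, 0, 1)), 16)))), auto_unbox = TRUE)
  writeLines(bad, path)
  expect_error(readKeypointJSON(path), "frame 0.*16")
})

test_that("null keypoint entries become confidence-0 placeholders", {
  path <- withr::local_tempfile(fileext = ".json")
  pts <- rep(list(c(1, 2, 0.9)), 17)
  pts[5] <- list(NULL)  # a missing detection
  json <- jsonlite::toJSON(list(frames = list(list(keypoints = pts))),
                           auto_unbox = TRUE, null = "null")
  writeLines(json, path)
  seq <- readKeypointJSON(path)
  expect_equal(nFrames(seq), 1L)
  expect_equal(unname(seq@keypoints[1, 5, ]), c(0, 0, 0))
  expect_equal(unname(seq@keypoints[1, 6, ]), c(1, 2, 0.9))
})

test_that("the flat 51-float frame layout is accepted", {
  path <- withr::local_tempfile(fileext = ".json")
  flat <- as.numeric(t(cbind(matrix(seq_len(34), ncol = 2), 1)))
  writeLines(jsonlite::toJSON(list(frames = list(flat))), path)
  seq <- readKeypointJSON(path)
  expect_equal(unname(seq@keypoints[1, 1, ]), c(1, 18, 1))
  expect_equal(unname(seq@keypoints[1, 17, ]), c(17, 34, 1))
})

test_that("feet are read by keypoint index, never by geometry", {
  # left foot (index 15) placed to the RIGHT of the right foot in space
  left <- rbind(c(100, 400), c(103, 404))
  right <- rbind(c(0, 400), c(0, 400))
  seq <- poseFromFeet(left, right)
  path <- withr::local_tempfile(fileext = ".json")
  writeKeypointJSON(seq, path)
  tracks <- extractFootTracks(readKeypointJSON(path), min_confidence = 0)
  expect_equal(tracks$left@foot_index, 15L)
  expect_equal(unname(footCoords(tracks$left)), unname(left))
  expect_equal(unname(footCoords(tracks$right)), unname(right))
})

test_that("hand-built 2-frame fixture yields the expected foot coords", {
  seq <- poseFromFeet(rbind(c(0, 0), c(3, 4)))
  tracks <- extractFootTracks(seq, min_confidence = 0.3)
  expect_equal(unname(footCoords(tracks$left)),
               rbind(c(0, 0), c(3, 4)))
  expect_equal(nDropped(tracks$left), 0L)
})

test_that("confidence filtering drops frames from both tracks in lockstep", {
  n <- 10
  left <- cbind(seq_len(n), rep(400, n))
  conf_left <- rep(1, n)
  conf_left[c(4, 7)] <- 0.1  # below threshold on the left foot only
  seq <- poseFromFeet(left, left + 5, conf_left = conf_left)
  tracks <- extractFootTracks(seq, min_confidence = 0.3)
  expect_equal(nFrames(tracks$left), 8L)
  expect_equal(nFrames(tracks$right), 8L)
  expect_equal(nDropped(tracks$left), 2L)
  expect_equal(tracks$left@frame_index, setdiff(0:9, c(3, 6)))
})

test_that("min_confidence = 0 is the identity filter", {
  seq <- simulateWalkTrial(walkSimConfig(n_frames = 30, dropout_rate = 0.3,
                                         seed = 9))
  tracks <- extractFootTracks(seq, min_confidence = 0)
  expect_equal(nFrames(tracks$left), 30L)
  expect_equal(nDropped(tracks$left), 0L)
})

test_that("filtering is monotone in the threshold", {
  seq <- simulateWalkTrial(walkSimConfig(n_frames = 60, dropout_rate = 0.4,
                                         seed = 11))
  kept <- vapply(c(0, 0.1, 0.3, 0.6, 0.9),
                 function(th) nFrames(extractFootTracks(seq, th)$left),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("fewer than 2 surviving frames is an explicit error", {
  seq <- poseFromFeet(rbind(c(0, 0), c(1, 1), c(2, 2)),
                      conf_left = c(1, 0.1, 0.1))
  expect_error(extractFootTracks(seq, min_confidence = 0.5),
               "insufficient frames")
})

test_that("the shipped schema file exists and matches the dialect", {
  sch <- jsonlite::fromJSON(keypointSchemaPath(), simplifyVector = FALSE)
  expect_equal(sch$required[[1]], "frames")
  kp <- sch$properties$frames$items$oneOf[[1]]$properties$keypoints
  expect_equal(kp$minItems, 17)
  expect_equal(kp$maxItems, 17)
})
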