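## Reading and writing the canonical keypoint JSON dialect, and extraction of
## clean left/right foot coordinate tracks.
##
## Canonical dialect (one file per trial):
##   {"subject_id": "...", "trial_id": "...",
##    "frames": [{"keypoints": [[x, y, confidence] x 17]}, ...]}
## A tolerant reader also accepts a flat 51-float layout per frame
## (x1, y1, c1, x2, y2, c2, ...), as emitted by common pose estimators.
## The schema is shipped at inst/extdata/keypoint-schema.json.

#' Construct a PoseSequence
#'
#' @param keypoints numeric array `n_frames x 17 x 3` of `(x, y, confidence)`
#' @param subject_id,trial_id identifier strings
#' @return a [PoseSequence-class]
#' @export
PoseSequence <- function(keypoints, subject_id = "subject", trial_id = "trial") {
  new("PoseSequence",
      subject_id = as.character(subject_id),
      trial_id = as.character(trial_id),
      keypoints = keypoints)
}

#' @describeIn PoseSequence number of frames
#' @param x a PoseSequence
#' @export
setMethod("nFrames", "PoseSequence", function(x) dim(x@keypoints)[1L])

setMethod("show", "PoseSequence", function(object) {
  cat(sprintf("PoseSequence: subject '%s', trial '%s', %d frames x %d keypoints\n",
              object@subject_id, object@trial_id,
              nFrames(object), N_KEYPOINTS))
})

#' Read a keypoint JSON trial file
#'
#' Parses one trial of 17-keypoint pose detections into a
#' [PoseSequence-class]. Frames are kept in file order; a frame entry listing
#' `null` in place of a keypoint becomes a confidence-0 placeholder at
#' `(0, 0)`. A frame whose keypoint count differs from 17 raises a schema
#' error naming the frame. No frame is ever silently dropped.
#'
#' @param path path to a JSON file in the canonical dialect (nested
#'   `[[x, y, c] x 17]` frames or the flat 51-float layout)
#' @return a [PoseSequence-class]
#' @seealso [writeKeypointJSON()], [extractFootTracks()]
#' @export
readKeypointJSON <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$frames)) stop("schema error: missing 'frames' field", call. = FALSE)
  n <- length(doc$frames)
  if (n == 0L) warning("empty trial: 'frames' has no entries", call. = FALSE)
  kp <- array(0, dim = c(n, N_KEYPOINTS, 3L),
              dimnames = list(NULL, NULL, c("x", "y", "confidence")))
  for (k in seq_len(n)) {
    fr <- doc$frames[[k]]
    pts <- if (!is.null(fr$keypoints)) fr$keypoints else fr
    # flat 51-float layout
    if (length(pts) == 3L * N_KEYPOINTS &&
        all(vapply(pts, function(p) is.numeric(p) && length(p) == 1L, logical(1L)))) {
      kp[k, , ] <- matrix(unlist(pts), ncol = 3L, byrow = TRUE)
      next
    }
    if (length(pts) != N_KEYPOINTS)
      stop(sprintf("schema error in frame %d: expected %d keypoints, found %d",
                   k - 1L, N_KEYPOINTS, length(pts)), call. = FALSE)
    for (i in seq_len(N_KEYPOINTS)) {
      p <- pts[[i]]
      if (is.null(p) || length(p) == 0L) next  # confidence-0 placeholder
      if (length(p) < 2L)
        stop(sprintf("schema error in frame %d: keypoint %d is not an [x, y, confidence] triple",
                     k - 1L, i - 1L), call. = FALSE)
      kp[k, i, 1L] <- as.numeric(p[[1L]])
      kp[k, i, 2L] <- as.numeric(p[[2L]])
      kp[k, i, 3L] <- if (length(p) >= 3L) as.numeric(p[[3L]]) else 1
    }
  }
  PoseSequence(kp,
               subject_id = if (is.null(doc$subject_id)) "unknown" else doc$subject_id,
               trial_id   = if (is.null(doc$trial_id)) "unknown" else doc$trial_id)
}

#' Write a PoseSequence as canonical keypoint JSON
#'
#' Serializes a trial to the canonical nested dialect. Coordinates are
#' written with enough digits that a read/write round trip reproduces them
#' beyond 6-decimal precision; output is byte-deterministic for a given
#' sequence.
#'
#' @param seq a [PoseSequence-class]
#' @param path output file path
#' @return `path`, invisibly
#' @seealso [readKeypointJSON()]
#' @export
writeKeypointJSON <- function(seq, path) {
  stopifnot(is(seq, "PoseSequence"))
  n <- nFrames(seq)
  frames <- vector("list", n)
  for (k in seq_len(n)) {
    m <- seq@keypoints[k, , , drop = TRUE]
    frames[[k]] <- list(keypoints = lapply(seq_len(N_KEYPOINTS),
                                           function(i) unname(m[i, ])))
  }
  doc <- list(subject_id = seq@subject_id,
              trial_id = seq@trial_id,
              frames = frames)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  con <- file(path, open = "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Extract confidence-filtered left and right foot tracks
#'
#' Pulls the coordinates of keypoints 15 (left foot) and 16 (right foot) out
#' of a pose sequence, dropping every frame in which either foot's detection
#' confidence falls below `min_confidence`. Frames are dropped from both
#' tracks, keeping left and right aligned in time; the count of removed
#' frames is recorded on each track. Feet are identified by keypoint index
#' only, never by geometry.
#'
#' @param seq a [PoseSequence-class]
#' @param min_confidence confidence threshold in `[0, 1]`; frames with either
#'   foot confidence strictly below it are removed. `0` disables filtering.
#' @return list with elements `left` and `right`, each a [FootTrack-class]
#'   of equal length
#' @seealso [frameDisplacements()]
#' @export
extractFootTracks <- function(seq, min_confidence = 0.3) {
  stopifnot(is(seq, "PoseSequence"))
  if (min_confidence < 0 || min_confidence > 1)
    stop("min_confidence must lie in [0, 1]", call. = FALSE)
  li <- FOOT_LEFT + 1L   # 0-based keypoint index -> 1-based row
  ri <- FOOT_RIGHT + 1L
  kp <- seq@keypoints
  n <- dim(kp)[1L]
  keep <- kp[, li, 3L] >= min_confidence & kp[, ri, 3L] >= min_confidence
  if (sum(keep) < 2L)
    stop(sprintf("insufficient frames: %d of %d survive confidence filtering (need >= 2)",
                 sum(keep), n), call. = FALSE)
  idx <- which(keep)
  n_dropped <- n - length(idx)
  mk <- function(foot, col) {
    new("FootTrack",
        foot_index = foot,
        trial_id = seq@trial_id,
        coords = matrix(c(kp[idx, col, 1L], kp[idx, col, 2L]),
                        ncol = 2L, dimnames = list(NULL, c("x", "y"))),
        frame_index = idx - 1L,
        n_dropped = n_dropped)
  }
  list(left = mk(FOOT_LEFT, li), right = mk(FOOT_RIGHT, ri))
}

#' @describeIn extractFootTracks accessors for [FootTrack-class]
#' @param x a FootTrack
#' @export
setMethod("nFrames", "FootTrack", function(x) nrow(x@coords))

#' @rdname extractFootTracks
#' @export
setMethod("footCoords", "FootTrack", function(x) x@coords)

#' @rdname extractFootTracks
#' @export
setMethod("nDropped", "FootTrack", function(x) x@n_dropped)

setMethod("show", "FootTrack", function(object) {
  cat(sprintf("FootTrack: %s foot (index %d), trial '%s', %d frames kept, %d dropped\n",
              if (object@foot_index == FOOT_LEFT) "left" else "right",
              object@foot_index, object@trial_id,
              nFrames(object), object@n_dropped))
})

#' Path to the shipped keypoint JSON schema
#'
#' Returns the location of the JSON-Schema document describing the canonical
#' keypoint dialect, for interoperability with external tooling.
#'
#' @return file path of `keypoint-schema.json`
#' @export
keypointSchemaPath <- function() {
  system.file("extdata", "keypoint-schema.json", package = "gaitvar",
              mustWork = TRUE)
}
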