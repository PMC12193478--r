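# Independent oracles and small fixture builders used across the suite.

# Textbook two-pass unbiased sample variance (independent of stats::var and
# of the package implementation).
twoPassVariance <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sum((x - m)^2) / (n - 1)
}

# Brute-force leading eigenpairs by power iteration with deflation.
# Independent of eigen(); used to cross-check the PCA stage.
powerIterationEigen <- function(S, k = 2L, iters = 5000L, tol = 1e-13) {
  p <- nrow(S)
  vals <- numeric(k)
  vecs <- matrix(0, p, k)
  A <- S
  for (j in seq_len(k)) {
    v <- rep(1 / sqrt(p), p)
    for (it in seq_len(iters)) {
      w <- A %*% v
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- as.numeric(w / nw)
      if (max(abs(w - v)) < tol || max(abs(w + v)) < tol) { v <- w; break }
      v <- w
    }
    lam <- as.numeric(t(v) %*% A %*% v)
    vals[j] <- lam
    vecs[, j] <- v
    A <- A - lam * tcrossprod(v)
  }
  list(values = vals, vectors = vecs)
}

# Hand-rolled Benjamini-Hochberg step-up, written straight from the
# definition: p_(i) * m / i, cumulative minimum from the largest rank down.
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Build a PoseSequence with both feet following the given coordinate rows.
# All other keypoints sit at the origin with full confidence.
poseFromFeet <- function(left, right = left, conf_left = NULL,
                         conf_right = NULL, trial_id = "test2_1",
                         subject_id = "fixture") {
  n <- nrow(left)
  kp <- array(0, dim = c(n, 17L, 3L))
  kp[, , 3L] <- 1
  kp[, 16L, 1:2] <- as.matrix(left)   # keypoint index 15 (left foot)
  kp[, 17L, 1:2] <- as.matrix(right)  # keypoint index 16 (right foot)
  if (!is.null(conf_left)) kp[, 16L, 3L] <- conf_left
  if (!is.null(conf_right)) kp[, 17L, 3L] <- conf_right
  PoseSequence(kp, subject_id = subject_id, trial_id = trial_id)
}

# A displacement series object wrapping raw values (for variance tests).
seriesFromValues <- function(d, foot = 15L, trial = "test2_1") {
  new("DisplacementSeries", foot_index = foot, trial_id = trial,
      values = d, gap_spanning = rep(FALSE, length(d)))
}

# Variable specs from raw vectors, bypassing auto-classification.
varSpec <- function(name, kind, values, levels = character()) {
  new("VariableSpec", name = name, kind = kind,
      values = as.numeric(values), levels = levels)
}
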