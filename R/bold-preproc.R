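#' Drop initial volumes
#'
#' Removes the first `k` volumes (scanner stabilization and adaptation
#' period); 205 volumes become 195 in the default configuration.
#'
#' @param ts a [ts_matrix()].
#' @param k number of initial time points to drop (default 10).
#' @return The shortened [ts_matrix()].
#' @export
drop_initial_volumes <- function(ts, k = 10L) {
  assert_that(inherits(ts, "ts_matrix"), "ts must be a ts_matrix")
  k <- as.integer(k)
  assert_that(k >= 0L, "k must be non-negative")
  assert_that(k < n_timepoints(ts) - 1L, "k must leave at least 2 time points")
  if (k == 0L) return(ts)
  ts_matrix(ts$values[, -(seq_len(k)), drop = FALSE], ts$sampling_interval,
            ts$node_labels)
}

#' Remove per-node linear trends
#'
#' Removes the least-squares fit of intercept plus linear time trend from
#' each node's series; output rows have zero mean and zero correlation with
#' the time index.
#'
#' @param ts a [ts_matrix()].
#' @return The detrended [ts_matrix()].
#' @export
detrend_ts <- function(ts) {
  assert_that(inherits(ts, "ts_matrix"), "ts must be a ts_matrix")
  Tn <- n_timepoints(ts)
  assert_that(Tn >= 3L, "at least 3 time points required to detrend")
  X <- cbind(1, seq_len(Tn))
  resid <- t(ts$values) - X %*% qr.coef(qr(X), t(ts$values))
  ts_matrix(t(resid), ts$sampling_interval, ts$node_labels)
}

#' Regress nuisance confounds out of every node series
#'
#' Projects each node's series onto the orthogonal complement of the span of
#' the confound columns plus an intercept (white matter, cerebrospinal fluid
#' and motion regressors in the intended use). Rank-deficient confound sets
#' are reduced by dropping linearly dependent columns with a warning.
#'
#' @param ts a [ts_matrix()].
#' @param confounds time x p numeric matrix; rows must match the number of
#'   time points.
#' @return The residual [ts_matrix()]; the retained confound rank is
#'   attached as attribute `"confound_rank"`.
#' @export
regress_confounds <- function(ts, confounds) {
  assert_that(inherits(ts, "ts_matrix"), "ts must be a ts_matrix")
  confounds <- as.matrix(confounds)
  Tn <- n_timepoints(ts)
  assert_that(nrow(confounds) == Tn, "confound rows must match time points")
  assert_that(ncol(confounds) < Tn - 1L, "more confounds than time points")
  X <- cbind(intercept = 1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    warning(sprintf("dropping %d linearly dependent confound column(s)",
                    ncol(X) - qx$rank))
    X <- X[, sort(keep), drop = FALSE]
    qx <- qr(X)
  }
  resid <- qr.resid(qx, t(ts$values))
  out <- ts_matrix(t(resid), ts$sampling_interval, ts$node_labels)
  attr(out, "confound_rank") <- qx$rank - 1L  # excluding the intercept
  out
}

#' Ideal band-pass filter
#'
#' Rectangular filter in the discrete Fourier domain: components whose
#' frequency magnitude lies in `[low, high]` are retained, all others —
#' including the zero-frequency (mean) term — are zeroed. The filter is
#' zero-phase by construction and idempotent. The default 0.04–0.07 Hz band
#' is the range used for slow BOLD synchronization analysis.
#'
#' @param ts a [ts_matrix()].
#' @param low,high band edges in Hz; `high` must not exceed the Nyquist
#'   frequency `1 / (2 TR)` (0.25 Hz at TR = 2 s).
#' @return The filtered [ts_matrix()].
#' @export
bandpass_ts <- function(ts, low = 0.04, high = 0.07) {
  assert_that(inherits(ts, "ts_matrix"), "ts must be a ts_matrix")
  nyq <- 1 / (2 * ts$sampling_interval)
  assert_that(low >= 0 && low < high, "need 0 <= low < high")
  assert_that(high <= nyq + 1e-12,
              sprintf("high edge exceeds the Nyquist frequency (%.4g Hz)", nyq))
  Tn <- n_timepoints(ts)
  freqs <- seq_len(Tn) - 1
  freqs <- pmin(freqs, Tn - freqs) / (Tn * ts$sampling_interval)
  mask <- as.numeric(freqs >= low & freqs <= high)
  spec <- t(apply(ts$values, 1, fft)) * rep(mask, each = n_nodes(ts))
  filtered <- Re(t(apply(spec, 1, fft, inverse = TRUE))) / Tn
  ts_matrix(filtered, ts$sampling_interval, ts$node_labels)
}

#' Friston 24-parameter motion expansion
#'
#' Expands a 6-parameter rigid-body motion trace to the 24-regressor set:
#' the parameters, their one-volume lags (zero for the first volume), and
#' the squares of both.
#'
#' @param motion time x 6 matrix (3 translations in mm, 3 rotations in
#'   radians).
#' @return time x 24 numeric matrix.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  assert_that(ncol(motion) == 6L, "motion must have 6 columns")
  lagged <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lagged, motion^2, lagged^2)
  colnames(out) <- c(paste0("mp", 1:6), paste0("mp", 1:6, "_lag"),
                     paste0("mp", 1:6, "_sq"), paste0("mp", 1:6, "_lagsq"))
  out
}

# Rotation matrix from Euler angles (radians), applied as Rx %*% Ry %*% Rz.
.rigid_transform <- function(p) {
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Tm <- diag(4)
  Tm[1:3, 1:3] <- Rx %*% Ry %*% Rz
  Tm[1:3, 4] <- p[1:3]
  Tm
}

#' Jenkinson framewise displacement
#'
#' Root-mean-square displacement between successive volumes' rigid-body
#' transforms, averaged over a solid sphere of the given radius centred at
#' the origin: for the relative transform with rotation residual
#' \eqn{A = R - I} and translation \eqn{b},
#' \deqn{FD = \sqrt{\tfrac{1}{5} r^2\, \mathrm{tr}(A^\top A) + b^\top b}.}
#' The first volume is assigned 0.
#'
#' @param motion time x 6 matrix: 3 translations (mm) then 3 rotations
#'   (radians) per volume.
#' @param radius sphere radius in mm (default 80, the standard value).
#' @param summary `"mean"` (default) or `"max"`: the per-subject summary
#'   used for exclusion decisions.
#' @return A list with `fd` (per-volume trace in mm), `summary_fd` (the
#'   chosen subject-level summary) and `summary` (its name).
#' @export
jenkinson_fd <- function(motion, radius = 80, summary = c("mean", "max")) {
  summary <- match.arg(summary)
  motion <- as.matrix(motion)
  assert_that(ncol(motion) == 6L, "motion must be a time x 6 matrix")
  assert_that(nrow(motion) >= 2L, "at least 2 volumes required")
  assert_that(all(is.finite(motion)), "motion parameters must be finite")
  Tn <- nrow(motion)
  fd <- numeric(Tn)
  prev <- .rigid_transform(motion[1, ])
  for (t in 2:Tn) {
    cur <- .rigid_transform(motion[t, ])
    M <- cur %*% solve(prev)
    A <- M[1:3, 1:3] - diag(3)
    b <- M[1:3, 4]
    fd[t] <- sqrt(radius^2 / 5 * sum(A * A) + sum(b * b))
    prev <- cur
  }
  list(fd = fd,
       summary_fd = if (summary == "mean") mean(fd) else max(fd),
       summary = summary)
}

#' Exclude subjects by framewise displacement
#'
#' Subjects whose summary FD strictly exceeds the threshold are excluded;
#' a value exactly equal to the threshold is kept.
#'
#' @param fd_summaries named numeric vector of per-subject summary FDs (mm).
#' @param threshold exclusion threshold in mm (default 0.2).
#' @return A list with `kept` and `excluded` (names, or indices when
#'   unnamed).
#' @export
exclude_by_fd <- function(fd_summaries, threshold = 0.2) {
  assert_that(all(is.finite(fd_summaries)), "FD summaries must be finite")
  ids <- names(fd_summaries) %||% seq_along(fd_summaries)
  drop <- fd_summaries > threshold
  list(kept = ids[!drop], excluded = ids[drop])
}

#' Run the full BOLD conditioning chain
#'
#' Applies, in this fixed order: initial-volume dropping, per-node linear
#' detrend, confound regression (tissue regressors plus the Friston-24
#' expansion of the motion trace, both optional), and the ideal band-pass.
#' Motion-based confounds are truncated to the kept volumes. When a motion
#' trace is supplied the Jenkinson FD summary and the exclusion decision are
#' reported alongside.
#'
#' @param ts a [ts_matrix()] of raw parcellated BOLD.
#' @param confounds optional time x p matrix of tissue/nuisance regressors
#'   (full acquisition length).
#' @param motion optional time x 6 motion trace (full acquisition length).
#' @param drop number of initial volumes to drop (default 10).
#' @param band band-pass edges in Hz (default `c(0.04, 0.07)`).
#' @param fd_threshold exclusion threshold in mm (default 0.2).
#' @return A list with `ts` (the conditioned [ts_matrix()]) and `log`
#'   (volumes dropped, confound rank, FD summary and exclusion decision).
#' @export
preprocess_bold <- function(ts, confounds = NULL, motion = NULL, drop = 10L,
                            band = c(0.04, 0.07), fd_threshold = 0.2) {
  log <- list(volumes_dropped = as.integer(drop), confound_rank = 0L,
              fd_summary = NA_real_, excluded = FALSE)
  if (!is.null(motion)) {
    fd <- jenkinson_fd(motion)
    log$fd_summary <- fd$summary_fd
    log$excluded <- fd$summary_fd > fd_threshold
  }
  out <- drop_initial_volumes(ts, drop)
  out <- detrend_ts(out)
  keep_rows <- function(m) {
    if (drop > 0L) m[-seq_len(drop), , drop = FALSE] else m
  }
  conf <- NULL
  if (!is.null(confounds)) {
    conf <- keep_rows(as.matrix(confounds))
  }
  if (!is.null(motion)) {
    conf <- cbind(conf, keep_rows(friston24(motion)))
  }
  if (!is.null(conf)) {
    out <- regress_confounds(out, conf)
    log$confound_rank <- attr(out, "confound_rank")
  }
  out <- bandpass_ts(out, band[1], band[2])
  list(ts = out, log = log)
}
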