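# Independent reference implementations used to cross-check the package.
# Each oracle deliberately takes a different computational route from the
# code under test.

# ROI statistics by brute force: loop over every pixel of the slice and test
# the disc inequality directly.
oracle_roi_stats <- function(volume, roi) {
  d <- dim(volume$intensities)
  vx <- volume$voxel_size[1]
  r_mm <- sqrt(roi$area_mm2 / pi)
  vals <- c()
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      dist_mm <- sqrt(((i - roi$cx) * vx)^2 + ((j - roi$cy) * vx)^2)
      if (dist_mm < r_mm) {
        vals <- c(vals, volume$intensities[i, j, roi$slice])
      }
    }
  }
  list(mean_si = mean(vals), sd_si = sd(vals), n_pixels = length(vals))
}

# Analytic signal through an explicit DFT matrix (no fft call): forward
# transform by direct matrix product, zero the negative frequencies, double
# the interior positive ones, invert with the conjugate matrix.
oracle_analytic <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  X <- drop(W %*% x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[c(1, n / 2 + 1)] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  drop(Conj(W) %*% (X * w)) / n
}

# Full phase-synchronization pipeline coded directly: per-node oracle
# analytic signal, explicit border trim, explicit complex sums per time
# point, plain mean.
oracle_sync <- function(values, trim = 10L) {
  phases <- t(apply(values, 1, function(r) Arg(oracle_analytic(r))))
  Tn <- ncol(phases)
  phases <- phases[, (trim + 1):(Tn - trim), drop = FALSE]
  r <- numeric(ncol(phases))
  for (t in seq_len(ncol(phases))) {
    z <- 0
    for (j in seq_len(nrow(phases))) z <- z + exp(1i * phases[j, t])
    r[t] <- Mod(z) / nrow(phases)
  }
  list(r_trace = r, mean_sync = mean(r))
}

# Jenkinson FD for a single relative rigid transform by Monte-Carlo
# integration over a solid sphere: RMS displacement of points drawn
# uniformly in the ball of the given radius.
oracle_fd_mc <- function(rotation, translation, radius = 80, n = 2e5) {
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * radius * runif(n)^(1 / 3)
  disp <- pts %*% t(rotation) +
    matrix(translation, n, 3, byrow = TRUE) - pts
  sqrt(mean(rowSums(disp^2)))
}

# ICC mean squares via base aov(), an independent ANOVA decomposition.
oracle_icc <- function(s1, s2) {
  n <- length(s1)
  d <- data.frame(y = c(s1, s2),
                  subj = factor(rep(seq_len(n), 2)),
                  sess = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + sess, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# Partial correlation for a single covariate via the recursion on pairwise
# Pearson correlations.
oracle_pcorr_1cov <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# A band-limited random series: sum of sinusoids on DFT bins inside the band.
band_limited_series <- function(Tn, tr = 2, low = 0.04, high = 0.07) {
  bins <- which((0:(Tn - 1)) / (Tn * tr) >= low &
                  (0:(Tn - 1)) / (Tn * tr) <= high) - 1
  t <- 0:(Tn - 1)
  rowSums(sapply(bins, function(b) {
    a <- rnorm(1); ph <- runif(1, 0, 2 * pi)
    a * cos(2 * pi * b * t / Tn + ph)
  }))
}
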