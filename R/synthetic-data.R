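#' Ground-truth description of a neuromelanin phantom
#'
#' Describes the planted geometry and intensities of a synthetic NM-MRI
#' volume: bright locus coeruleus (LC) discs adjacent to a pontine tegmentum
#' (PT) reference on three contiguous slices, and substantia nigra (SN)
#' subregion discs with a cerebral peduncle (CP) reference on one slice.
#' The planted contrast-to-noise ratio of a structure is exactly
#' `(SI_structure - SI_reference) / noise_sd`.
#'
#' Default geometry assumes the acquisition this emulates: 220 mm in-plane
#' field of view at a 512 matrix (0.4297 mm pixels), 3 mm slices, scaled to a
#' small grid centred on the brainstem.
#'
#' @param shape integer length-3 vector of voxel counts (x, y, slices).
#' @param voxel_size mm per axis; in-plane pixels must be square.
#' @param lc_slices three contiguous slice indices carrying the LC/PT discs.
#' @param sn_slice slice index carrying the SN/CP discs.
#' @param lc_centers,pt_center,sn_centers,cp_center in-plane centres in pixel
#'   units. `lc_centers` is a named list (`left`, `right`); `sn_centers` a
#'   named list with entries `lateral_left`, `central_left`, `medial_left`,
#'   `medial_right`, `central_right`, `lateral_right`. Defaults place all
#'   structures centrally with no disc overlap.
#' @param si_map named numeric vector of planted mean intensities for
#'   `background`, `LC`, `PT`, `SN`, `CP` (arbitrary MR units).
#' @param noise_sd standard deviation of additive Gaussian noise (intensity
#'   units); 0 gives a noise-free phantom.
#' @return An object of class `phantom_truth`; its `true_cnr` element holds
#'   the planted dimensionless contrasts for LC and SN (NA when
#'   `noise_sd = 0`).
#' @export
phantom_truth <- function(shape = c(96L, 96L, 7L),
                          voxel_size = c(0.4297, 0.4297, 3),
                          lc_slices = 2:4,
                          sn_slice = 6L,
                          lc_centers = NULL,
                          pt_center = NULL,
                          sn_centers = NULL,
                          cp_center = NULL,
                          si_map = c(background = 70, LC = 120, PT = 100,
                                     SN = 110, CP = 90),
                          noise_sd = 10) {
  shape <- as.integer(shape)
  assert_that(length(shape) == 3L && all(shape[1:2] >= 8L) && shape[3] >= 1L,
              "shape must be 3 voxel counts (in-plane >= 8)")
  voxel_size <- as.numeric(voxel_size)
  assert_that(length(voxel_size) == 3L && all(voxel_size > 0),
              "voxel_size must be 3 positive values (mm)")
  assert_that(abs(voxel_size[1] - voxel_size[2]) < 1e-12,
              "in-plane pixels must be square")
  assert_that(length(lc_slices) == 3L && all(diff(sort(lc_slices)) == 1L),
              "lc_slices must be 3 contiguous slice indices")
  assert_that(all(c(lc_slices, sn_slice) >= 1L) &&
                all(c(lc_slices, sn_slice) <= shape[3]),
              "slice indices must lie inside the volume")
  assert_that(all(c("background", "LC", "PT", "SN", "CP") %in% names(si_map)),
              "si_map must name background, LC, PT, SN, CP")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")

  c0 <- (shape[1:2] + 1) / 2
  if (is.null(lc_centers)) {
    lc_centers <- list(left  = c(c0[1] - 9, c0[2] - 10),
                       right = c(c0[1] + 9, c0[2] - 10))
  }
  if (is.null(pt_center)) pt_center <- c(c0[1], c0[2] + 12)
  if (is.null(sn_centers)) {
    off <- c(lateral = 24, central = 15, medial = 6)
    sn_centers <- list(
      lateral_left  = c(c0[1] - off["lateral"], c0[2]),
      central_left  = c(c0[1] - off["central"], c0[2]),
      medial_left   = c(c0[1] - off["medial"],  c0[2]),
      medial_right  = c(c0[1] + off["medial"],  c0[2]),
      central_right = c(c0[1] + off["central"], c0[2]),
      lateral_right = c(c0[1] + off["lateral"], c0[2]))
    sn_centers <- lapply(sn_centers, unname)
  }
  if (is.null(cp_center)) cp_center <- c(c0[1], c0[2] - 18)

  true_cnr <- if (noise_sd > 0) {
    c(LC = unname((si_map[["LC"]] - si_map[["PT"]]) / noise_sd),
      SN = unname((si_map[["SN"]] - si_map[["CP"]]) / noise_sd))
  } else {
    c(LC = NA_real_, SN = NA_real_)
  }

  truth <- structure(list(shape = shape, voxel_size = voxel_size,
                          lc_slices = sort(as.integer(lc_slices)),
                          sn_slice = as.integer(sn_slice),
                          lc_centers = lc_centers, pt_center = pt_center,
                          sn_centers = sn_centers, cp_center = cp_center,
                          si_map = si_map, noise_sd = noise_sd,
                          true_cnr = true_cnr),
                     class = "phantom_truth")
  .validate_phantom_geometry(truth)
  truth
}

# Area (mm^2) of each ROI type, the protocol constants of the quantification.
.roi_areas <- c(LC = 2, PT = 20, SN = 10, CP = 30)

# Table of all planted ROIs for a truth object.
phantom_roi_table <- function(truth) {
  rows <- list()
  for (s in truth$lc_slices) {
    for (side in c("left", "right")) {
      ctr <- truth$lc_centers[[side]]
      rows[[length(rows) + 1L]] <- data.frame(
        label = paste0("LC_", side), structure = "LC", side = side,
        subregion = "", slice = s, cx = ctr[1], cy = ctr[2],
        area_mm2 = .roi_areas[["LC"]])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      label = "PT", structure = "PT", side = "", subregion = "",
      slice = s, cx = truth$pt_center[1], cy = truth$pt_center[2],
      area_mm2 = .roi_areas[["PT"]])
  }
  for (nm in names(truth$sn_centers)) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    ctr <- truth$sn_centers[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      label = paste0("SN_", nm), structure = "SN", side = parts[2],
      subregion = parts[1], slice = truth$sn_slice, cx = ctr[1], cy = ctr[2],
      area_mm2 = .roi_areas[["SN"]])
  }
  rows[[length(rows) + 1L]] <- data.frame(
    label = "CP", structure = "CP", side = "", subregion = "",
    slice = truth$sn_slice, cx = truth$cp_center[1], cy = truth$cp_center[2],
    area_mm2 = .roi_areas[["CP"]])
  do.call(rbind, rows)
}

.validate_phantom_geometry <- function(truth) {
  rois <- phantom_roi_table(truth)
  vx <- truth$voxel_size[1]
  r_px <- sqrt(rois$area_mm2 / pi) / vx
  inside <- rois$cx - r_px >= 1 & rois$cx + r_px <= truth$shape[1] &
    rois$cy - r_px >= 1 & rois$cy + r_px <= truth$shape[2]
  assert_that(all(inside), "all ROI discs must lie fully inside the volume")
  # pairwise non-overlap of discs sharing a slice (centre distance in mm)
  for (i in seq_len(nrow(rois) - 1L)) {
    for (j in (i + 1L):nrow(rois)) {
      if (rois$slice[i] != rois$slice[j]) next
      d <- sqrt((rois$cx[i] - rois$cx[j])^2 + (rois$cy[i] - rois$cy[j])^2) * vx
      rmin <- sqrt(rois$area_mm2[i] / pi) + sqrt(rois$area_mm2[j] / pi)
      assert_that(d > rmin,
                  sprintf("ROI discs %s and %s overlap on slice %d",
                          rois$label[i], rois$label[j], rois$slice[i]))
    }
  }
  invisible(truth)
}

#' Generate a synthetic NM-MRI phantom volume
#'
#' Renders the geometry described by a [phantom_truth()] object into an
#' intensity volume: each structure's disc is painted at its planted mean
#' intensity over a uniform background, then i.i.d. Gaussian noise of the
#' truth's `noise_sd` is added everywhere. A pixel belongs to a disc iff its
#' centre lies strictly inside the circle of radius `sqrt(area / pi)` (mm)
#' around the structure centre.
#'
#' @param truth a [phantom_truth()] object.
#' @param seed integer seed; the same seed yields a bit-identical volume.
#' @return A list with elements `volume` (an [image_volume()]) and `rois`
#'   (data frame of the planted ROI specifications: label, structure, side,
#'   subregion, slice, centre `cx`/`cy` in pixels, `area_mm2`).
#' @export
gen_nm_phantom <- function(truth, seed = 1L) {
  assert_that(inherits(truth, "phantom_truth"), "truth must be a phantom_truth")
  rois <- phantom_roi_table(truth)
  vol <- array(truth$si_map[["background"]], dim = truth$shape)
  for (k in seq_len(nrow(rois))) {
    idx <- disc_pixels(truth$shape[1:2], c(rois$cx[k], rois$cy[k]),
                       rois$area_mm2[k], truth$voxel_size[1])
    si <- truth$si_map[[rois$structure[k]]]
    vol[cbind(idx, rois$slice[k])] <- si
  }
  if (truth$noise_sd > 0) {
    vol <- vol + with_seed(seed, array(rnorm(length(vol), sd = truth$noise_sd),
                                       dim = truth$shape))
  }
  list(volume = image_volume(vol, truth$voxel_size), rois = rois)
}

# Integer pixel (i, j) pairs whose centres fall strictly inside the disc of
# the given area (mm^2) centred at `center` (pixel units), on a slice of the
# given in-plane dimensions with square pixels of side `vx` mm.
disc_pixels <- function(dim2, center, area_mm2, vx) {
  r_px <- sqrt(area_mm2 / pi) / vx
  is <- max(1L, ceiling(center[1] - r_px)):min(dim2[1], floor(center[1] + r_px))
  js <- max(1L, ceiling(center[2] - r_px)):min(dim2[2], floor(center[2] + r_px))
  grid <- expand.grid(i = is, j = js)
  keep <- (grid$i - center[1])^2 + (grid$j - center[2])^2 < r_px^2
  if (!any(keep)) {
    stop("ROI disc contains no pixel centres at this resolution", call. = FALSE)
  }
  as.matrix(grid[keep, , drop = FALSE])
}

#' Parameters of the coupled phase-oscillator BOLD simulator
#'
#' @param n_nodes number of network nodes (33 for the somatomotor network).
#' @param coupling global coupling strength K >= 0 (dimensionless);
#'   0 gives independent oscillators, large values drive full synchrony.
#' @param natural_freqs optional per-node natural frequencies in Hz; when
#'   `NULL` they are drawn uniformly in [0.04, 0.07] Hz, the band the
#'   downstream filter passes.
#' @param n_timepoints number of volumes (default 205).
#' @param sampling_interval TR in seconds (default 2).
#' @param obs_noise_sd standard deviation of additive observation noise on
#'   the unit-amplitude signal.
#' @param init_phases optional initial phases (radians); drawn uniformly on
#'   the circle when `NULL`.
#' @param seed integer seed.
#' @return An object of class `oscillator_params`.
#' @export
oscillator_params <- function(n_nodes = 33L, coupling = 0,
                              natural_freqs = NULL,
                              n_timepoints = 205L, sampling_interval = 2,
                              obs_noise_sd = 0.1, init_phases = NULL,
                              seed = 1L) {
  assert_that(n_nodes >= 2L, "n_nodes must be >= 2")
  assert_that(coupling >= 0, "coupling must be >= 0")
  assert_that(sampling_interval > 0, "sampling_interval must be positive")
  assert_that(n_timepoints >= 2L, "n_timepoints must be >= 2")
  assert_that(obs_noise_sd >= 0, "obs_noise_sd must be non-negative")
  if (!is.null(natural_freqs)) {
    assert_that(length(natural_freqs) == n_nodes && all(natural_freqs > 0),
                "natural_freqs must be n_nodes positive frequencies (Hz)")
  }
  if (!is.null(init_phases)) {
    assert_that(length(init_phases) == n_nodes,
                "init_phases must have length n_nodes")
  }
  structure(list(n_nodes = as.integer(n_nodes), coupling = coupling,
                 natural_freqs = natural_freqs,
                 n_timepoints = as.integer(n_timepoints),
                 sampling_interval = sampling_interval,
                 obs_noise_sd = obs_noise_sd, init_phases = init_phases,
                 seed = as.integer(seed)),
            class = "oscillator_params")
}

#' Simulate somatomotor-like BOLD from coupled phase oscillators
#'
#' Integrates the mean-field phase-oscillator system
#' \deqn{d\theta_j/dt = \omega_j + (K/n) \sum_k \sin(\theta_k - \theta_j)}
#' with a fixed-step explicit Euler scheme at a substep of
#' `sampling_interval / 20`, and observes
#' \eqn{s_j(t) = \sin\theta_j(t) + \epsilon} at each TR. The observation is a
#' real narrowband signal so the downstream Hilbert-phase step is exercised
#' end to end; the model's own order parameter is exactly the synchronization
#' statistic the pipeline estimates.
#'
#' @param params an [oscillator_params()] object.
#' @return A [ts_matrix()] of `n_nodes` x `n_timepoints`, with the latent
#'   phase matrix attached as attribute `"phases"`.
#' @export
gen_oscillator_bold <- function(params) {
  assert_that(inherits(params, "oscillator_params"),
              "params must be an oscillator_params object")
  n <- params$n_nodes
  Tn <- params$n_timepoints
  with_seed(params$seed, {
    theta <- params$init_phases %||% runif(n, -pi, pi)
    freqs <- params$natural_freqs %||% runif(n, 0.04, 0.07)
    omega <- 2 * pi * freqs
    dt <- params$sampling_interval / 20
    K <- params$coupling
    phases <- matrix(0, n, Tn)
    phases[, 1] <- theta
    for (t in 2:Tn) {
      for (s in 1:20) {
        z <- mean(exp(1i * theta))
        theta <- theta + dt * (omega + K * Mod(z) * sin(Arg(z) - theta))
      }
      phases[, t] <- theta
    }
    values <- sin(phases)
    if (params$obs_noise_sd > 0) {
      values <- values + matrix(rnorm(n * Tn, sd = params$obs_noise_sd), n, Tn)
    }
    out <- ts_matrix(values, params$sampling_interval)
    attr(out, "phases") <- wrap_phase(phases)
    out
  })
}

#' Parameters of the synthetic patient cohort generator
#'
#' @param n_subjects number of patients (default 57).
#' @param target_r planted partial correlation between CNR_LC and the
#'   UPDRS-III rate of change, after removing the covariates; |target_r| < 1.
#' @param target_r_sync planted partial correlation between CNR_LC and the
#'   synchronization rate of change (negative: responders' synchronization
#'   rises ON, making the rate negative).
#' @param covariate_effects named list of length-3 coefficient vectors
#'   (`age`, `duration`, `ledd`, applied to standardized covariates) for
#'   `cnr_lc`, `cnr_sn`, `rate_updrs`, `rate_sync`.
#' @param noise_sds named residual standard deviations for the same four
#'   variables.
#' @param rate_mean,rate_sync_mean mean planted rates of change.
#' @param seed integer seed.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 57L, target_r = 0.42,
                          target_r_sync = -0.32,
                          covariate_effects = NULL, noise_sds = NULL,
                          rate_mean = 0.35, rate_sync_mean = -0.12,
                          seed = 1L) {
  assert_that(abs(target_r) < 1, "|target_r| must be < 1")
  assert_that(abs(target_r_sync) < 1, "|target_r_sync| must be < 1")
  assert_that(n_subjects >= 7L, "n_subjects must be at least 4 + 3 covariates")
  assert_that(rate_mean < 1, "a mean UPDRS rate of change >= 1 is infeasible")
  covariate_effects <- covariate_effects %||% list(
    cnr_lc     = c(age = -0.12, duration = -0.05, ledd = 0.00),
    cnr_sn     = c(age = -0.20, duration = -0.10, ledd = 0.00),
    rate_updrs = c(age = -0.03, duration = -0.02, ledd = 0.01),
    rate_sync  = c(age = 0.010, duration = 0.000, ledd = 0.00))
  noise_sds <- noise_sds %||% c(cnr_lc = 0.55, cnr_sn = 0.50,
                                rate_updrs = 0.12, rate_sync = 0.07)
  need <- c("cnr_lc", "cnr_sn", "rate_updrs", "rate_sync")
  assert_that(all(need %in% names(covariate_effects)) &&
                all(need %in% names(noise_sds)),
              "covariate_effects and noise_sds must cover cnr_lc, cnr_sn, rate_updrs, rate_sync")
  assert_that(all(noise_sds > 0), "noise_sds must be positive")
  structure(list(n_subjects = as.integer(n_subjects), target_r = target_r,
                 target_r_sync = target_r_sync,
                 covariate_effects = covariate_effects, noise_sds = noise_sds,
                 rate_mean = rate_mean, rate_sync_mean = rate_sync_mean,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Generate a synthetic patient cohort table
#'
#' Draws age, duration of dopaminergic drug administration and levodopa
#' equivalent daily dose (LEDD), then builds CNR_LC and the two rates of
#' change from shared latent factors so that, after residualizing both
#' variables on the covariates, the correlation between CNR_LC and the
#' UPDRS-III rate of change converges to `target_r` (and to `target_r_sync`
#' for the synchronization rate). UPDRS-III ON is derived from OFF and the
#' planted rate so that `(OFF - ON) / OFF` reproduces the rate exactly;
#' likewise for the ON-state synchronization. CNR_SN carries covariate
#' effects but no relation to either rate.
#'
#' @param params a [cohort_params()] object.
#' @return A data frame with one row per subject and columns `id`, `age`
#'   (years), `duration_med` (years), `ledd` (mg), `sex` (0/1), `cnr_lc`,
#'   `cnr_sn`, `updrs3_off`, `updrs3_on`, `sync_off`, `sync_on`.
#' @export
gen_cohort <- function(params) {
  assert_that(inherits(params, "cohort_params"),
              "params must be a cohort_params object")
  n <- params$n_subjects
  eff <- params$covariate_effects
  sds <- params$noise_sds
  with_seed(params$seed, {
    age <- rnorm(n, 62, 8)
    duration <- pmax(0.5, rnorm(n, 4, 2))
    ledd <- pmax(50, rnorm(n, 450, 150))
    sex <- rbinom(n, 1, 0.55)
    Z <- scale(cbind(age = age, duration = duration, ledd = ledd))

    z_lc <- rnorm(n)
    z_updrs <- params$target_r * z_lc +
      sqrt(1 - params$target_r^2) * rnorm(n)
    z_sync <- params$target_r_sync * z_lc +
      sqrt(1 - params$target_r_sync^2) * rnorm(n)

    cnr_lc <- 1.5 + drop(Z %*% eff$cnr_lc) + sds[["cnr_lc"]] * z_lc
    cnr_sn <- 2.3 + drop(Z %*% eff$cnr_sn) + sds[["cnr_sn"]] * rnorm(n)
    rate_updrs <- params$rate_mean + drop(Z %*% eff$rate_updrs) +
      sds[["rate_updrs"]] * z_updrs
    rate_sync <- params$rate_sync_mean + drop(Z %*% eff$rate_sync) +
      sds[["rate_sync"]] * z_sync

    if (any(rate_updrs >= 1)) {
      stop("infeasible draw: a planted UPDRS rate of change reached 1 ",
           "(ON score would be negative); reduce rate_mean or its noise",
           call. = FALSE)
    }
    updrs3_off <- pmax(5, rnorm(n, 35, 8))
    updrs3_on <- updrs3_off * (1 - rate_updrs)
    sync_off <- pmin(0.6, pmax(0.1, rnorm(n, 0.32, 0.04)))
    sync_on <- sync_off * (1 - rate_sync)
    if (any(sync_on < 0 | sync_on > 1)) {
      stop("infeasible draw: an ON-state synchronization left [0, 1]; ",
           "reduce the magnitude of rate_sync_mean or its noise", call. = FALSE)
    }
    data.frame(id = sprintf("sub%03d", seq_len(n)), age = age,
               duration_med = duration, ledd = ledd, sex = sex,
               cnr_lc = cnr_lc, cnr_sn = cnr_sn,
               updrs3_off = updrs3_off, updrs3_on = updrs3_on,
               sync_off = sync_off, sync_on = sync_on)
  })
}
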