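#' ROI statistics on one slice of an image volume
#'
#' Mean and standard deviation of the signal intensity over all pixels whose
#' centres fall strictly inside the circular ROI. The radius is derived from
#' the ROI area in mm^2 (`r = sqrt(area / pi)`) and tested per pixel in mm,
#' so the protocol's areas (2 mm^2 LC, 20 mm^2 PT, 10 mm^2 SN subregion,
#' 30 mm^2 CP) translate across resolutions. The SD uses the n-1 denominator.
#'
#' @param volume an [image_volume()].
#' @param roi a one-row data frame or list with `slice`, `cx`, `cy`
#'   (pixel units) and `area_mm2`.
#' @return A list with `mean_si`, `sd_si` and `n_pixels`.
#' @export
roi_stats <- function(volume, roi) {
  assert_that(inherits(volume, "image_volume"), "volume must be an image_volume")
  slice <- as.integer(roi$slice)
  assert_that(slice >= 1L && slice <= dim(volume$intensities)[3],
              "ROI slice outside the volume")
  idx <- disc_pixels(dim(volume$intensities)[1:2], c(roi$cx, roi$cy),
                     roi$area_mm2, volume$voxel_size[1])
  vals <- volume$intensities[cbind(idx, slice)]
  list(mean_si = mean(vals),
       sd_si = if (length(vals) > 1L) sd(vals) else 0,
       n_pixels = nrow(idx))
}

#' Locate the locus coeruleus by maximal mean intensity
#'
#' Implements the placement rule of the quantification protocol: on each of
#' three contiguous slices, the 2 mm^2 disc is placed, independently per
#' side, at the position inside that side's search region whose mean
#' intensity is highest. The search is an exhaustive scan over integer
#' pixel-centre placements whose disc lies fully inside the search box; ties
#' are broken by the lexicographically smallest (row, column) centre.
#'
#' @param volume an [image_volume()].
#' @param search_region named list with elements `left` and `right`, each an
#'   in-plane bounding box `c(xmin, xmax, ymin, ymax)` in pixel units.
#' @param slice_range exactly 3 contiguous slice indices.
#' @param area_mm2 disc area (default the protocol's 2 mm^2).
#' @return Data frame of located ROIs (`label`, `side`, `slice`, `cx`, `cy`,
#'   `area_mm2`, `mean_si`), one row per slice and side.
#' @export
locate_lc <- function(volume, search_region, slice_range, area_mm2 = 2) {
  assert_that(inherits(volume, "image_volume"), "volume must be an image_volume")
  assert_that(length(slice_range) == 3L && all(diff(sort(slice_range)) == 1L),
              "slice_range must be exactly 3 contiguous slices")
  d <- dim(volume$intensities)
  assert_that(all(slice_range >= 1L & slice_range <= d[3]),
              "slice_range outside the volume")
  assert_that(is.list(search_region) &&
                all(c("left", "right") %in% names(search_region)),
              "search_region must be a list with boxes 'left' and 'right'")
  vx <- volume$voxel_size[1]
  r_px <- sqrt(area_mm2 / pi) / vx
  # disc offsets relative to an integer centre
  span <- ceiling(r_px)
  offs <- expand.grid(dx = -span:span, dy = -span:span)
  offs <- offs[offs$dx^2 + offs$dy^2 < r_px^2, , drop = FALSE]
  assert_that(nrow(offs) > 0, "disc smaller than one pixel at this resolution")

  out <- list()
  for (s in sort(slice_range)) {
    sl <- volume$intensities[, , s]
    for (side in c("left", "right")) {
      box <- search_region[[side]]
      assert_that(length(box) == 4L, "each search box must be c(xmin, xmax, ymin, ymax)")
      assert_that(box[1] >= 1 && box[2] <= d[1] && box[3] >= 1 && box[4] <= d[2],
                  "search region must lie inside the volume")
      cx_rng <- ceiling(box[1] + span):floor(box[2] - span)
      cy_rng <- ceiling(box[3] + span):floor(box[4] - span)
      assert_that(length(cx_rng) > 0 && box[1] + span <= box[2] - span &&
                    length(cy_rng) > 0 && box[3] + span <= box[4] - span,
                  "search region smaller than the ROI disc")
      # accumulate disc sums for every candidate centre with shifted reads
      acc <- matrix(0, length(cx_rng), length(cy_rng))
      for (k in seq_len(nrow(offs))) {
        acc <- acc + sl[cx_rng + offs$dx[k], cy_rng + offs$dy[k], drop = FALSE]
      }
      best <- which(acc == max(acc), arr.ind = TRUE)
      # lexicographically smallest (row, column) centre on ties
      best <- best[order(best[, 1], best[, 2])[1], , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        label = paste0("LC_", side), side = side, slice = s,
        cx = cx_rng[best[1, 1]], cy = cy_rng[best[1, 2]],
        area_mm2 = area_mm2,
        mean_si = max(acc) / nrow(offs))
    }
  }
  do.call(rbind, out)
}

#' Contrast-to-noise ratio
#'
#' `CNR = (SI_target - SI_reference) / SD_reference`, the imaging proxy for
#' neuronal integrity of neuromelanin-rich nuclei: for the locus coeruleus
#' the reference is the pontine tegmentum, for the substantia nigra the
#' cerebral peduncle.
#'
#' @param si_target mean signal intensity of the target ROI.
#' @param si_ref mean signal intensity of the reference ROI.
#' @param sd_ref standard deviation of the reference ROI; must be positive.
#' @return Dimensionless contrast-to-noise ratio (vectorized).
#' @export
cnr <- function(si_target, si_ref, sd_ref) {
  assert_that(all(sd_ref > 0), "sd_ref must be positive (degenerate reference region)")
  (si_target - si_ref) / sd_ref
}

#' Aggregate locus coeruleus CNR over slices, sides and sessions
#'
#' One CNR is computed per (session, side, slice) against that slice's
#' pontine reference, and the aggregate is the arithmetic mean of all
#' 3 slices x 2 sides x S sessions values, the averaging scheme of the
#' quantification protocol (two assessments in the original design).
#'
#' @param lc_stats data frame with columns `session`, `side`
#'   (left/right), `slice`, `mean_si`: LC ROI means.
#' @param pt_stats data frame with columns `session`, `slice`, `mean_si`,
#'   `sd_si`: one pontine reference per (session, slice).
#' @return An object of class `cnr_result`: `per_measurement` (data frame
#'   with the per-cell CNRs) and `aggregate` (their mean).
#' @export
aggregate_cnr_lc <- function(lc_stats, pt_stats) {
  sessions <- sort(unique(lc_stats$session))
  slices <- sort(unique(c(lc_stats$slice, pt_stats$slice)))
  assert_that(length(slices) == 3L, "exactly 3 slices expected")
  need <- expand.grid(session = sessions, side = c("left", "right"),
                      slice = slices, stringsAsFactors = FALSE)
  have <- paste(lc_stats$session, lc_stats$side, lc_stats$slice)
  missing <- need[!paste(need$session, need$side, need$slice) %in% have, ]
  if (nrow(missing) > 0) {
    stop("missing LC cells: ",
         paste(sprintf("(%s, %s, slice %s)", missing$session, missing$side,
                       missing$slice), collapse = ", "), call. = FALSE)
  }
  ref_key <- paste(pt_stats$session, pt_stats$slice)
  need_ref <- unique(paste(lc_stats$session, lc_stats$slice))
  if (!all(need_ref %in% ref_key)) {
    stop("missing PT reference for (session, slice): ",
         paste(setdiff(need_ref, ref_key), collapse = ", "), call. = FALSE)
  }
  m <- match(paste(lc_stats$session, lc_stats$slice), ref_key)
  per <- data.frame(session = lc_stats$session, side = lc_stats$side,
                    slice = lc_stats$slice,
                    cnr = cnr(lc_stats$mean_si, pt_stats$mean_si[m],
                              pt_stats$sd_si[m]))
  structure(list(per_measurement = per, aggregate = mean(per$cnr)),
            class = "cnr_result")
}

#' Aggregate substantia nigra CNR over subregions, sides and sessions
#'
#' One CNR per (session, side, subregion) against that session and side's
#' cerebral-peduncle reference; the aggregate is the mean over all six
#' divisions (bilateral lateral, central, medial) per session. Bilateral
#' averaging is unconditional.
#'
#' @param sn_stats data frame with columns `session`, `side`, `subregion`
#'   (lateral/central/medial), `mean_si`.
#' @param cp_stats data frame with columns `session`, `side`, `mean_si`,
#'   `sd_si`; duplicated values across sides are accepted.
#' @return A `cnr_result` as in [aggregate_cnr_lc()].
#' @export
aggregate_cnr_sn <- function(sn_stats, cp_stats) {
  sessions <- sort(unique(sn_stats$session))
  need <- expand.grid(session = sessions, side = c("left", "right"),
                      subregion = c("lateral", "central", "medial"),
                      stringsAsFactors = FALSE)
  have <- paste(sn_stats$session, sn_stats$side, sn_stats$subregion)
  missing <- need[!paste(need$session, need$side, need$subregion) %in% have, ]
  if (nrow(missing) > 0) {
    stop("missing SN cells: ",
         paste(sprintf("(%s, %s, %s)", missing$session, missing$side,
                       missing$subregion), collapse = ", "), call. = FALSE)
  }
  ref_key <- paste(cp_stats$session, cp_stats$side)
  need_ref <- unique(paste(sn_stats$session, sn_stats$side))
  if (!all(need_ref %in% ref_key)) {
    stop("missing CP reference for (session, side): ",
         paste(setdiff(need_ref, ref_key), collapse = ", "), call. = FALSE)
  }
  m <- match(paste(sn_stats$session, sn_stats$side), ref_key)
  per <- data.frame(session = sn_stats$session, side = sn_stats$side,
                    subregion = sn_stats$subregion,
                    cnr = cnr(sn_stats$mean_si, cp_stats$mean_si[m],
                              cp_stats$sd_si[m]))
  structure(list(per_measurement = per, aggregate = mean(per$cnr)),
            class = "cnr_result")
}

#' @export
print.cnr_result <- function(x, ...) {
  cat(sprintf("<cnr_result> %d measurements, aggregate CNR = %.4f\n",
              nrow(x$per_measurement), x$aggregate))
  invisible(x)
}

#' Intra-rater intraclass correlation coefficient
#'
#' Two-way mixed-effects, absolute-agreement, single-measure ICC (the
#' ICC(2,1) form) between two assessment sessions of the same subjects,
#' computed from the ANOVA mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with k = 2 sessions, subject (row) mean square \eqn{MS_R}, session
#' (column) mean square \eqn{MS_C} and residual \eqn{MS_E}.
#'
#' @param session1,session2 numeric vectors of per-subject aggregates from
#'   the two assessments; equal lengths >= 3.
#' @return The ICC, a dimensionless value in [-1, 1].
#' @export
icc_intra_rater <- function(session1, session2) {
  assert_that(length(session1) == length(session2), "sessions must have equal length")
  n <- length(session1)
  assert_that(n >= 3L, "at least 3 subjects required")
  x <- cbind(session1, session2)
  k <- 2L
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps * max(1, grand^2)) {
    stop("zero between-subject variance: ICC undefined", call. = FALSE)
  }
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}
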