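# File interfaces: NIfTI volumes, TSV matrices, CSV tables, JSON summaries.

#' Write / read an image volume as NIfTI
#'
#' @param volume an [image_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_volume_nifti` returns `path` invisibly;
#'   `read_volume_nifti` returns an [image_volume()].
#' @export
write_volume_nifti <- function(volume, path) {
  assert_that(inherits(volume, "image_volume"), "volume must be an image_volume")
  img <- RNifti::asNifti(volume$intensities)
  RNifti::pixdim(img) <- volume$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim = dim(img)),
               RNifti::pixdim(img)[1:3])
}

#' Write / read a node-by-time matrix as TSV
#'
#' Nodes as rows (first column the node label), one column per volume.
#'
#' @param ts a [ts_matrix()].
#' @param path output TSV path.
#' @param sampling_interval TR in seconds used when reading back.
#' @return `write_ts_tsv` returns `path` invisibly; `read_ts_tsv` a
#'   [ts_matrix()].
#' @export
write_ts_tsv <- function(ts, path) {
  assert_that(inherits(ts, "ts_matrix"), "ts must be a ts_matrix")
  df <- data.frame(node = ts$node_labels, ts$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ts_tsv
#' @export
read_ts_tsv <- function(path, sampling_interval = 2) {
  df <- read.delim(path, check.names = FALSE)
  ts_matrix(as.matrix(df[, -1, drop = FALSE]), sampling_interval, df[[1]])
}

#' Write / read ROI specifications as CSV
#'
#' Columns: label, structure, side, subregion, slice, cx, cy, area_mm2.
#'
#' @param rois ROI data frame (as produced by [gen_nm_phantom()] or
#'   [locate_lc()]).
#' @param path CSV path.
#' @return `write_rois_csv` returns `path` invisibly; `read_rois_csv` the
#'   data frame.
#' @export
write_rois_csv <- function(rois, path) {
  write.csv(rois, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois_csv
#' @export
read_rois_csv <- function(path) read.csv(path)

#' Write / read a cohort table as CSV
#'
#' Column header documented in [gen_cohort()].
#'
#' @param cohort cohort data frame.
#' @param path CSV path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   the data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) read.csv(path)

#' Write a synchronization result as JSON
#'
#' Records `mean_sync`, `n_nodes` and `L` (time points used).
#'
#' @param sync a `sync_result` from [somatomotor_sync()].
#' @param path JSON path.
#' @param r_trace_path optional CSV path for the per-time r(t) trace.
#' @return `path`, invisibly.
#' @export
write_sync_json <- function(sync, path, r_trace_path = NULL) {
  assert_that(inherits(sync, "sync_result"), "sync must be a sync_result")
  jsonlite::write_json(list(mean_sync = sync$mean_sync,
                            n_nodes = sync$n_nodes,
                            L = sync$n_timepoints_used),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(r_trace_path)) {
    write.csv(data.frame(t = seq_along(sync$r_trace), r = sync$r_trace),
              r_trace_path, row.names = FALSE)
  }
  invisible(path)
}
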