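#' Image volume container
#'
#' A light wrapper around a 3D intensity array with voxel dimensions, the
#' carrier of the neuromelanin-sensitive MRI signal. Slices are indexed along
#' the third array axis.
#'
#' @param intensities numeric 3D array of scalar intensities (arbitrary MR
#'   units).
#' @param voxel_size numeric length-3 vector, mm per axis (in-plane x, y and
#'   slice thickness), all strictly positive.
#' @return An object of class `image_volume` with elements `intensities` and
#'   `voxel_size`.
#' @export
image_volume <- function(intensities, voxel_size) {
  assert_that(is.array(intensities) && length(dim(intensities)) == 3L,
              "intensities must be a 3D array")
  assert_that(all(dim(intensities) >= 1L), "all dimensions must be >= 1")
  voxel_size <- as.numeric(voxel_size)
  assert_that(length(voxel_size) == 3L && all(voxel_size > 0),
              "voxel_size must be 3 strictly positive values (mm)")
  structure(list(intensities = intensities, voxel_size = voxel_size),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_volume> %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Node-by-time BOLD matrix
#'
#' Container for a parcellated BOLD data set: one row per network node, one
#' column per volume, plus the sampling interval (TR).
#'
#' @param values numeric matrix, nodes x time; no missing values.
#' @param sampling_interval repetition time in seconds.
#' @param node_labels optional character vector of unique node names; defaults
#'   to `node01`, `node02`, ...
#' @return An object of class `ts_matrix`.
#' @export
ts_matrix <- function(values, sampling_interval, node_labels = NULL) {
  values <- as.matrix(values)
  assert_that(is.numeric(values), "values must be numeric")
  assert_that(!anyNA(values) && all(is.finite(values)),
              "values must contain no missing or non-finite entries")
  assert_that(ncol(values) >= 2L, "at least 2 time points required")
  if (is.null(node_labels)) {
    node_labels <- sprintf("node%02d", seq_len(nrow(values)))
  }
  assert_that(length(node_labels) == nrow(values) && !anyDuplicated(node_labels),
              "node_labels must be unique and match the number of rows")
  assert_that(is.numeric(sampling_interval) && length(sampling_interval) == 1L &&
                sampling_interval > 0,
              "sampling_interval must be a single positive number (seconds)")
  rownames(values) <- node_labels
  structure(list(values = values, node_labels = node_labels,
                 sampling_interval = sampling_interval),
            class = "ts_matrix")
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("<ts_matrix> %d nodes x %d time points, TR = %g s\n",
              nrow(x$values), ncol(x$values), x$sampling_interval))
  invisible(x)
}

n_timepoints <- function(ts) ncol(ts$values)
n_nodes <- function(ts) nrow(ts$values)
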