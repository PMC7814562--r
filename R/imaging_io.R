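#' Dynamic image container
#'
#' A `dynamic_image` bundles a 4D array of per-voxel activity (MBq per voxel,
#' one volume per frame) with its [voxel_grid()] geometry and
#' [frame_schedule()]. Storing activity per voxel (rather than concentration)
#' means an ROI sum is directly the ROI activity in MBq.
#'
#' @param values 4D numeric array, dims `c(grid$dims, n_frames(frames))`;
#'   all values >= 0.
#' @param grid a [voxel_grid()].
#' @param frames a [frame_schedule()]; length must equal `dim(values)[4]`.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(values, grid, frames) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stop_("dynamic_image: values must be a 4D array")
  if (!identical(as.integer(dim(values)[1:3]), grid$dims))
    stop_("dynamic_image: value dims (%s) do not match grid dims (%s)",
          paste(dim(values)[1:3], collapse = "x"),
          paste(grid$dims, collapse = "x"))
  if (dim(values)[4] != n_frames(frames))
    stop_("dynamic_image: frame-count mismatch: %d volumes vs %d scheduled frames",
          dim(values)[4], n_frames(frames))
  if (min(values) < 0)
    stop_("dynamic_image: negative voxel values")
  structure(list(values = values, grid = grid, frames = frames),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  cat(sprintf("<dynamic_image> %s voxels x %d frames, total activity %.4g MBq (frame 1)\n",
              paste(x$grid$dims, collapse = " x "), n_frames(x$frames),
              sum(x$values[, , , 1])))
  invisible(x)
}

#' Per-frame total activity
#' @param image a [dynamic_image()].
#' @return Numeric vector, sum over all voxels per frame (MBq).
#' @export
frame_totals <- function(image) {
  colSums(image$values, dims = 3L)
}

# Build an RNifti image carrying grid geometry in the sform.
as_nifti_with_grid <- function(arr, grid) {
  ni <- RNifti::asNifti(arr)
  m <- rbind(cbind(diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
  RNifti::`sform<-`(ni, structure(m, code = 2L))
}

grid_from_nifti <- function(ni) {
  x <- RNifti::xform(ni)
  spacing <- sqrt(colSums(x[1:3, 1:3]^2))
  origin <- x[1:3, 4]
  d <- dim(ni)
  voxel_grid(d[1:3], spacing, origin)
}

#' Save a dynamic image as a NIfTI-1 file
#'
#' Writes the 4D activity array with the voxel spacing and origin recorded in
#' the NIfTI sform; values are stored as float64 so a save/load cycle is
#' bit-exact. The frame schedule is not stored in the NIfTI header; keep it
#' in a JSON sidecar via [write_frame_schedule()].
#'
#' @param image a [dynamic_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_dynamic_image <- function(image, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_("save_dynamic_image: directory does not exist: %s", dir)
  ni <- as_nifti_with_grid(image$values, image$grid)
  RNifti::writeNifti(ni, path, datatype = "double")
  invisible(path)
}

#' Load a dynamic image from a NIfTI-1 file
#'
#' @param path path to a 4D NIfTI-1 file.
#' @param schedule a [frame_schedule()] whose length must equal the file's
#'   4th dimension.
#' @return A [dynamic_image()] with grid geometry read from the file header.
#' @export
load_dynamic_image <- function(path, schedule) {
  if (!file.exists(path)) stop_("load_dynamic_image: file not found: %s", path)
  ni <- RNifti::readNifti(path)
  d <- dim(ni)
  # NIfTI writers drop trailing singleton dimensions; a single-frame series
  # read back as 3D is reinstated, anything else 3D is rejected.
  if (length(d) == 3L && n_frames(schedule) == 1L) {
    d <- c(d, 1L)
  } else if (length(d) != 4L) {
    stop_("load_dynamic_image: non-4D image (found %d dimensions)", length(d))
  }
  if (d[4] != n_frames(schedule))
    stop_("load_dynamic_image: frame-count mismatch: file has %d volumes, schedule has %d frames",
          d[4], n_frames(schedule))
  grid <- grid_from_nifti(ni)
  vals <- as.array(ni)
  attributes(vals) <- list(dim = d)
  dynamic_image(vals, grid, schedule)
}

#' Label volume
#'
#' A per-voxel integer label map on a [voxel_grid()], with a legend mapping
#' each code to a plant identifier and an anatomical/scene region. Region
#' names used by the phantom are `"root"` (the merged solution + root pool
#' inside the beaker), `"stem"`, `"leaf"`, `"reference"` and `"background"`.
#'
#' @param labels 3D integer array of label codes.
#' @param grid a [voxel_grid()] matching `dim(labels)`.
#' @param legend data.frame with columns `code`, `plant_id`, `region`; every
#'   code present in `labels` must appear exactly once.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, grid, legend) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop_("label_volume: labels must be a 3D array")
  if (!identical(as.integer(dim(labels)), grid$dims))
    stop_("label_volume: label dims do not match grid dims")
  req <- c("code", "plant_id", "region")
  if (!all(req %in% names(legend)))
    stop_("label_volume: legend must have columns code, plant_id, region")
  if (anyDuplicated(legend$code))
    stop_("label_volume: duplicated codes in legend")
  present <- sort(unique(as.vector(labels)))
  missing <- setdiff(present, legend$code)
  if (length(missing) > 0)
    stop_("label_volume: codes present in labels but absent from legend: %s",
          paste(missing, collapse = ", "))
  structure(list(labels = labels, grid = grid,
                 legend = as.data.frame(legend, stringsAsFactors = FALSE)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d labelled regions\n",
              paste(x$grid$dims, collapse = " x "), nrow(x$legend)))
  invisible(x)
}

#' Save / load a label volume (NIfTI-1 + JSON legend sidecar)
#'
#' The integer label array is written as NIfTI-1; the legend is written next
#' to it as `<path>.legend.json`.
#'
#' @param volume a [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `save_label_volume` returns `path` invisibly; `load_label_volume`
#'   returns a [label_volume()].
#' @export
save_label_volume <- function(volume, path) {
  ni <- as_nifti_with_grid(volume$labels, volume$grid)
  RNifti::writeNifti(ni, path, datatype = "int32")
  jsonlite::write_json(volume$legend, paste0(path, ".legend.json"), digits = NA)
  invisible(path)
}

#' @rdname save_label_volume
#' @export
load_label_volume <- function(path) {
  if (!file.exists(path)) stop_("load_label_volume: file not found: %s", path)
  legend_path <- paste0(path, ".legend.json")
  if (!file.exists(legend_path))
    stop_("load_label_volume: legend sidecar not found: %s", legend_path)
  ni <- RNifti::readNifti(path)
  d <- dim(ni)
  if (length(d) != 3L) stop_("load_label_volume: expected a 3D label image")
  grid <- grid_from_nifti(ni)
  labels <- array(as.integer(as.array(ni)), dim = d)
  legend <- jsonlite::read_json(legend_path, simplifyVector = TRUE)
  label_volume(labels, grid, legend)
}
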