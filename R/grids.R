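#' Voxel grid geometry
#'
#' A `voxel_grid` describes a regular 3D sampling lattice: the number of
#' voxels along each axis, the voxel spacing in millimetres, and the physical
#' position (mm) of the *center* of voxel `(0, 0, 0)`. Voxel indices
#' throughout the package are zero-based, following the NIfTI voxel
#' coordinate convention; the vertical plant-height axis is z.
#'
#' @param dims integer triple, number of voxels along (x, y, z); all >= 1.
#' @param spacing numeric triple, voxel size in mm along (x, y, z); all > 0.
#' @param origin numeric triple, physical mm position of the center of voxel
#'   `(0, 0, 0)`. Defaults to `c(0, 0, 0)`.
#' @return An object of class `voxel_grid`.
#' @examples
#' pet <- voxel_grid(c(64, 64, 48), c(1.59, 1.59, 2.027))
#' mm_to_voxel_index(c(0, 0, 20.27), pet)  # z index 10
#' @export
voxel_grid <- function(dims, spacing, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3L || anyNA(dims) || any(dims < 1L))
    stop_("voxel_grid: dims must be 3 integers >= 1")
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop_("voxel_grid: spacing must be 3 positive numbers (mm)")
  if (length(origin) != 3L || anyNA(origin))
    stop_("voxel_grid: origin must be 3 numbers (mm)")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %g x %g x %g mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$dims)

same_grid <- function(a, b) {
  identical(a$dims, b$dims) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-9))
}

# Zero-based index along one axis, half-open voxel model: voxel i covers
# [origin + i*s - s/2, origin + i*s + s/2); a position exactly on a boundary
# belongs to the higher index. Vectorised over `pos_mm`; no extent check.
axis_index_raw <- function(pos_mm, origin, spacing) {
  as.integer(floor((pos_mm - origin) / spacing + 0.5))
}

#' Convert a physical position (mm) to a zero-based voxel index
#'
#' Each voxel index `i` along an axis covers the half-open physical interval
#' `[origin + i*s - s/2, origin + i*s + s/2)` (s = spacing); a position that
#' falls exactly on the shared boundary of two voxels maps to the higher
#' index. This makes the mm-to-index mapping total over the grid extent and
#' guarantees that abutting regions convert to non-overlapping index ranges.
#'
#' @param position_mm numeric triple, physical (x, y, z) position in mm.
#' @param grid a [voxel_grid()].
#' @return Integer triple of zero-based voxel indices.
#' @export
mm_to_voxel_index <- function(position_mm, grid) {
  position_mm <- as.numeric(position_mm)
  if (length(position_mm) != 3L || anyNA(position_mm))
    stop_("mm_to_voxel_index: position must be 3 numbers (mm)")
  idx <- axis_index_raw(position_mm, grid$origin, grid$spacing)
  if (any(idx < 0L) || any(idx > grid$dims - 1L))
    stop_("mm_to_voxel_index: position (%g, %g, %g) mm lies outside the grid extent",
          position_mm[1], position_mm[2], position_mm[3])
  idx
}

#' Convert a zero-based voxel index to the physical position of its center
#'
#' @param index integer triple of zero-based voxel indices.
#' @param grid a [voxel_grid()].
#' @return Numeric triple, mm position of the voxel center.
#' @export
voxel_index_to_mm <- function(index, grid) {
  grid$origin + as.numeric(index) * grid$spacing
}

#' Frame schedule of a dynamic acquisition
#'
#' Describes the temporal binning of a dynamic PET series: contiguous frames
#' of uniform duration. Frame timestamps used in analysis are the frame
#' midpoints.
#'
#' @param frame_starts_h numeric, start of each frame in hours since tracer
#'   administration; strictly increasing and contiguous.
#' @param frame_duration_h single positive number, frame length in hours.
#' @return An object of class `frame_schedule`.
#' @examples
#' frame_schedule(0:71, 1)  # 72 one-hour frames
#' @export
frame_schedule <- function(frame_starts_h, frame_duration_h) {
  frame_starts_h <- as.numeric(frame_starts_h)
  frame_duration_h <- as.numeric(frame_duration_h)
  if (length(frame_duration_h) != 1L || is.na(frame_duration_h) || frame_duration_h <= 0)
    stop_("frame_schedule: frame_duration_h must be a single positive number")
  if (length(frame_starts_h) < 1L || anyNA(frame_starts_h))
    stop_("frame_schedule: frame_starts_h must be non-empty and finite")
  if (length(frame_starts_h) > 1L) {
    gaps <- diff(frame_starts_h)
    if (any(gaps <= 0))
      stop_("frame_schedule: frame starts must be strictly increasing")
    if (any(abs(gaps - frame_duration_h) > 1e-9))
      stop_("frame_schedule: frames must be contiguous (start[i+1] = start[i] + duration)")
  }
  structure(list(frame_starts_h = frame_starts_h,
                 frame_duration_h = frame_duration_h),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames of %g h, t = %g .. %g h\n",
              n_frames(x), x$frame_duration_h, x$frame_starts_h[1],
              x$frame_starts_h[length(x$frame_starts_h)] + x$frame_duration_h))
  invisible(x)
}

#' Number of frames in a schedule
#' @param frames a [frame_schedule()].
#' @return Integer frame count.
#' @export
n_frames <- function(frames) length(frames$frame_starts_h)

#' Frame midpoint times
#' @param frames a [frame_schedule()].
#' @return Numeric vector of frame midpoints, hours since administration.
#' @export
frame_midpoints <- function(frames) {
  frames$frame_starts_h + frames$frame_duration_h / 2
}

#' Write / read a frame schedule as a JSON sidecar
#'
#' The sidecar holds `{"frame_starts_h": [...], "frame_duration_h": x}`.
#'
#' @param frames a [frame_schedule()].
#' @param path file path for the JSON sidecar.
#' @return `read_frame_schedule` returns a [frame_schedule()];
#'   `write_frame_schedule` returns `path` invisibly.
#' @export
write_frame_schedule <- function(frames, path) {
  jsonlite::write_json(list(frame_starts_h = frames$frame_starts_h,
                            frame_duration_h = frames$frame_duration_h),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frame_schedule
#' @export
read_frame_schedule <- function(path) {
  if (!file.exists(path)) stop_("read_frame_schedule: file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  frame_schedule(x$frame_starts_h, x$frame_duration_h)
}
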