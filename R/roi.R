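# CT-guided prism ROIs. Region boundaries are identified as heights (mm
# above the beaker bottom) in the CT image; the lateral extent of each plant
# is the bounding box of its isolation cylinder. Both are converted to
# inclusive zero-based PET voxel index bounds with the shared half-open
# boundary convention, so abutting regions partition the plant column with
# no double-counted voxel.

#' Prism region of interest
#'
#' An axis-aligned 3D rectangular prism in PET voxel space, identified by
#' plant and region. Bounds are inclusive, zero-based voxel indices.
#'
#' @param plant_id plant/grouping identifier.
#' @param region region name (e.g. `"root"`, `"leaf"`, `"reference"`).
#' @param x,y,z integer pairs `c(lo, hi)`, inclusive zero-based bounds.
#' @param grid optional [voxel_grid()] to validate the bounds against.
#' @return An object of class `plant_roi`.
#' @export
plant_roi <- function(plant_id, region, x, y, z, grid = NULL) {
  b <- rbind(x = as.integer(x), y = as.integer(y), z = as.integer(z))
  if (ncol(b) != 2L || anyNA(b)) stop_("plant_roi: bounds must be integer pairs")
  if (any(b[, 2] < b[, 1])) stop_("plant_roi: empty prism (hi < lo)")
  if (any(b[, 1] < 0L)) stop_("plant_roi: negative voxel index")
  if (!is.null(grid) && any(b[, 2] > grid$dims - 1L))
    stop_("plant_roi: bounds exceed grid extent")
  structure(list(plant_id = plant_id, region = region,
                 x = b["x", ], y = b["y", ], z = b["z", ]),
            class = "plant_roi")
}

#' @export
print.plant_roi <- function(x, ...) {
  cat(sprintf("<plant_roi> %s/%s x %d..%d y %d..%d z %d..%d (%d voxels)\n",
              x$plant_id, x$region, x$x[1], x$x[2], x$y[1], x$y[2],
              x$z[1], x$z[2], roi_n_voxels(x)))
  invisible(x)
}

#' Number of voxels in a prism ROI
#' @param roi a [plant_roi()].
#' @return Integer voxel count.
#' @export
roi_n_voxels <- function(roi) {
  prod(roi$x[2] - roi$x[1] + 1L, roi$y[2] - roi$y[1] + 1L,
       roi$z[2] - roi$z[1] + 1L)
}

# Convert a half-open mm interval [lo, hi) on one axis to an inclusive
# zero-based index range, erroring if empty or out of extent.
interval_to_index_range <- function(lo_mm, hi_mm, origin, spacing, n, what) {
  if (hi_mm <= lo_mm) stop_("%s: empty interval [%g, %g) mm", what, lo_mm, hi_mm)
  i0 <- axis_index_raw(lo_mm, origin, spacing)
  i1 <- axis_index_raw(hi_mm, origin, spacing) - 1L
  if (i0 < 0L || i1 > n - 1L)
    stop_("%s: interval [%g, %g) mm lies outside the grid extent", what, lo_mm, hi_mm)
  if (i1 < i0)
    stop_("%s: interval [%g, %g) mm converts to an empty prism", what, lo_mm, hi_mm)
  c(i0, i1)
}

#' Build prism ROIs from CT-measured region heights
#'
#' One prism per (plant, region): the z bounds come from converting the
#' region's height interval (mm above the beaker bottom) to PET slice
#' indices; the x/y bounds come from converting the plant's lateral cylinder
#' bounding box. All prisms of one plant share the lateral bounds exactly,
#' and abutting height intervals convert to disjoint slice ranges (the
#' boundary slice belongs to the upper region).
#'
#' @param heights data.frame with columns `plant_id`, `region`,
#'   `z_bottom_mm`, `z_top_mm`; region intervals of one plant must not
#'   overlap.
#' @param lateral_bounds data.frame with columns `plant_id`, `x_min_mm`,
#'   `x_max_mm`, `y_min_mm`, `y_max_mm`.
#' @param pet_grid the PET [voxel_grid()].
#' @param ct_grid optional CT [voxel_grid()]; when given, heights and
#'   lateral bounds are checked against its extent (heights are measured on
#'   the CT image).
#' @return List of [plant_roi()] objects.
#' @export
rois_from_heights <- function(heights, lateral_bounds, pet_grid,
                              ct_grid = NULL) {
  req_h <- c("plant_id", "region", "z_bottom_mm", "z_top_mm")
  req_l <- c("plant_id", "x_min_mm", "x_max_mm", "y_min_mm", "y_max_mm")
  if (!all(req_h %in% names(heights)))
    stop_("rois_from_heights: heights needs columns %s", paste(req_h, collapse = ", "))
  if (!all(req_l %in% names(lateral_bounds)))
    stop_("rois_from_heights: lateral_bounds needs columns %s", paste(req_l, collapse = ", "))
  if (any(heights$z_top_mm <= heights$z_bottom_mm))
    stop_("rois_from_heights: z_top_mm must exceed z_bottom_mm")
  for (pid in unique(heights$plant_id)) {
    h <- heights[heights$plant_id == pid, ]
    if (nrow(h) > 1L) {
      o <- order(h$z_bottom_mm)
      if (any(h$z_bottom_mm[o][-1] < h$z_top_mm[o][-nrow(h)]))
        stop_("rois_from_heights: overlapping region heights for plant '%s'", pid)
    }
  }
  if (!is.null(ct_grid)) {
    zext <- ct_grid$origin[3] + c(-0.5, ct_grid$dims[3] - 0.5) * ct_grid$spacing[3]
    if (any(heights$z_bottom_mm < zext[1]) || any(heights$z_top_mm > zext[2]))
      stop_("rois_from_heights: heights exceed the CT grid extent")
  }

  out <- vector("list", nrow(heights))
  for (i in seq_len(nrow(heights))) {
    pid <- heights$plant_id[i]
    lb <- lateral_bounds[lateral_bounds$plant_id == pid, ]
    if (nrow(lb) != 1L)
      stop_("rois_from_heights: no unique lateral bounds for plant '%s'", pid)
    xr <- interval_to_index_range(lb$x_min_mm, lb$x_max_mm, pet_grid$origin[1],
                                  pet_grid$spacing[1], pet_grid$dims[1],
                                  "rois_from_heights (x)")
    yr <- interval_to_index_range(lb$y_min_mm, lb$y_max_mm, pet_grid$origin[2],
                                  pet_grid$spacing[2], pet_grid$dims[2],
                                  "rois_from_heights (y)")
    zr <- interval_to_index_range(heights$z_bottom_mm[i], heights$z_top_mm[i],
                                  pet_grid$origin[3], pet_grid$spacing[3],
                                  pet_grid$dims[3], "rois_from_heights (z)")
    out[[i]] <- plant_roi(pid, heights$region[i], xr, yr, zr, grid = pet_grid)
  }
  out
}

#' Per-voxel membership mask of a prism ROI
#'
#' @param roi a [plant_roi()].
#' @param grid the [voxel_grid()] the mask is defined on.
#' @return Logical 3D array; `TRUE` exactly inside the inclusive bounds.
#' @export
roi_mask <- function(roi, grid) {
  if (any(c(roi$x[2], roi$y[2], roi$z[2]) > grid$dims - 1L))
    stop_("roi_mask: ROI exceeds grid extent")
  m <- array(FALSE, dim = grid$dims)
  m[(roi$x[1]:roi$x[2]) + 1L, (roi$y[1]:roi$y[2]) + 1L,
    (roi$z[1]:roi$z[2]) + 1L] <- TRUE
  m
}

#' Write / read prism ROIs as JSON
#'
#' The JSON is a list of objects with `plant_id`, `region` and inclusive
#' zero-based voxel bounds `x`, `y`, `z`, suitable for audit.
#'
#' @param rois list of [plant_roi()].
#' @param path JSON file path.
#' @return `write_rois` returns `path` invisibly; `read_rois` returns a list
#'   of [plant_roi()].
#' @export
write_rois <- function(rois, path) {
  x <- lapply(rois, function(r)
    list(plant_id = r$plant_id, region = r$region,
         x = r$x, y = r$y, z = r$z))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop_("read_rois: file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(x, function(r)
    plant_roi(r$plant_id, r$region, unlist(r$x), unlist(r$y), unlist(r$z)))
}
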