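# Synthetic 4D phantom: four simultaneously scanned plant groupings
# (high/low nutrient x with/without inhibitor) plus a constant reference
# source, rendered into corrected/uncorrected dynamic PET image pairs with
# full ground-truth bookkeeping.

#' Phantom specification
#'
#' Describes the synthetic scene and simulation parameters: voxel grid and
#' frame schedule, light schedule, per-grouping kinetics, scene geometry,
#' attenuation, detector sensitivity and RNG seed.
#'
#' Geometry: each grouping is a vertical stack of a solution/root cylinder
#' (the beaker), a thin stem column and a leaf-canopy cylinder, placed at
#' laterally disjoint (x, y) centers; a small constant-activity reference
#' source sits apart from all groupings. Region z-bands are specified in mm
#' from the beaker bottom (the z origin) and voxelized with the same
#' half-open boundary convention as [mm_to_voxel_index()].
#'
#' @param grid a [voxel_grid()].
#' @param frames a [frame_schedule()].
#' @param light a [light_schedule()].
#' @param groupings named list of four [kinetic_params()], in scanner order
#'   `high_noBa`, `high_Ba`, `low_noBa`, `low_Ba`.
#' @param geometry list of scene parameters; see [default_phantom_spec()]
#'   for the fields and defaults.
#' @param mu_per_mm water-equivalent linear attenuation coefficient, per mm
#'   (0.0096/mm for 511 keV photons in water).
#' @param sensitivity expected detected counts per MBq.h in one voxel;
#'   `Inf` disables counting noise.
#' @param reference_activity_MBq activity of the reference source.
#' @param seed integer RNG seed for the counting noise.
#' @return An object of class `phantom_spec`.
#' @seealso [default_phantom_spec()], [generate_dataset()]
#' @export
phantom_spec <- function(grid, frames, light, groupings, geometry,
                         mu_per_mm = 0.0096, sensitivity = 1e4,
                         reference_activity_MBq = 1.0, seed = 1L) {
  if (length(groupings) != 4L || is.null(names(groupings)))
    stop_("phantom_spec: groupings must be a named list of four kinetic_params")
  if (!all(vapply(groupings, inherits, logical(1), "kinetic_params")))
    stop_("phantom_spec: each grouping must be a kinetic_params object")
  if (mu_per_mm < 0) stop_("phantom_spec: mu_per_mm must be >= 0")
  if (sensitivity <= 0) stop_("phantom_spec: sensitivity must be > 0")
  if (reference_activity_MBq <= 0)
    stop_("phantom_spec: reference_activity_MBq must be > 0")
  structure(list(grid = grid, frames = frames, light = light,
                 groupings = groupings, geometry = geometry,
                 mu_per_mm = mu_per_mm, sensitivity = sensitivity,
                 reference_activity_MBq = reference_activity_MBq,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom specification
#'
#' Builds a [phantom_spec()] emulating the study conditions of a multi-day
#' continuous scan: four plant groupings imaged simultaneously over 72
#' one-hour frames under a 12 h light / 8 h dark cycle, with administered
#' doses 2.25, 2.09, 2.00 and 2.03 MBq (high-nutrient without inhibitor,
#' high with, low without, low with). Low-nutrient groupings take up sodium
#' 1.6x faster; inhibitor-treated groupings at 0.5x; the diurnal modulation
#' amplitude is 0.4 about a base rate of 0.01/h.
#'
#' Scene geometry scales with the grid extent so that reduced grids remain
#' valid scenes; on the default 64 x 64 x 48 grid at PET voxel size
#' (1.59 x 1.59 x 2.027 mm) the beakers have ~9 mm radius.
#'
#' @param dims grid size in voxels; default `c(64, 64, 48)`.
#' @param spacing voxel size in mm; default PET `c(1.59, 1.59, 2.027)`.
#' @param n_frames number of 1-h frames; default 72.
#' @param doses_MBq administered activity per grouping, MBq.
#' @param k_base base uptake rate, per hour.
#' @param f_nutrient_low nutrient multiplier for low-nutrient groupings.
#' @param f_inhibitor inhibitor multiplier for treated groupings.
#' @param a_diurnal diurnal modulation amplitude in `[0, 1)`.
#' @param phase_advance hours of rate anticipation of light transitions.
#' @param light a [light_schedule()].
#' @param mu_per_mm attenuation coefficient, per mm.
#' @param sensitivity detected counts per MBq.h per voxel; `Inf` = noiseless.
#' @param reference_activity_MBq reference-source activity, MBq.
#' @param stem_fraction fraction of shoot activity rendered in the stem
#'   column (taken out of the leaf region so totals are conserved).
#' @param seed RNG seed for counting noise.
#' @return A [phantom_spec()].
#' @examples
#' spec <- default_phantom_spec(dims = c(24, 24, 24), n_frames = 24)
#' ds <- generate_dataset(spec)
#' @export
default_phantom_spec <- function(dims = c(64, 64, 48),
                                 spacing = c(1.59, 1.59, 2.027),
                                 n_frames = 72,
                                 doses_MBq = c(high_noBa = 2.25, high_Ba = 2.09,
                                               low_noBa = 2.00, low_Ba = 2.03),
                                 k_base = 0.01,
                                 f_nutrient_low = 1.6,
                                 f_inhibitor = 0.5,
                                 a_diurnal = 0.4,
                                 phase_advance = 0,
                                 light = light_schedule(12, 8, 0),
                                 mu_per_mm = 0.0096,
                                 sensitivity = 1e4,
                                 reference_activity_MBq = 1.0,
                                 stem_fraction = 0,
                                 seed = 1L) {
  grid <- voxel_grid(dims, spacing)
  frames <- frame_schedule(seq(0, n_frames - 1), 1)
  ext <- (grid$dims - 1) * grid$spacing  # span of voxel centers, mm
  geometry <- list(
    centers_x_mm = (c(1, 3, 5, 7) / 8) * ext[1],
    center_y_mm = 0.3 * ext[2],
    beaker_radius_mm = 0.09 * ext[1],
    stem_radius_mm = max(0.02 * ext[1], 1.05 * max(spacing[1:2])),
    leaf_radius_mm = 0.09 * ext[1],
    beaker_top_mm = 0.22 * ext[3],
    stem_top_mm = 0.5 * ext[3],
    leaf_top_mm = 0.92 * ext[3],
    reference_center_mm = c(0.5 * ext[1], 0.8 * ext[2], 0.3 * ext[3]),
    reference_halfsize_mm = pmax(1.05 * spacing, 0.03 * ext),
    stem_fraction = stem_fraction
  )
  nm <- c("high_noBa", "high_Ba", "low_noBa", "low_Ba")
  doses <- unname(doses_MBq)
  f_nut <- c(1, 1, f_nutrient_low, f_nutrient_low)
  f_inh <- c(1, f_inhibitor, 1, f_inhibitor)
  groupings <- stats::setNames(lapply(1:4, function(i) {
    kinetic_params(k_base = k_base, f_nutrient = f_nut[i],
                   f_inhibitor = f_inh[i], a_diurnal = a_diurnal,
                   phase_advance = phase_advance, A_total = doses[i])
  }), nm)
  phantom_spec(grid, frames, light, groupings, geometry,
               mu_per_mm = mu_per_mm, sensitivity = sensitivity,
               reference_activity_MBq = reference_activity_MBq, seed = seed)
}

# Region codes: background 0; grouping g in 1..4 gets 3*(g-1) + {1,2,3} for
# root/stem/leaf; reference is 13.
REGIONS_PER_PLANT <- c("root", "stem", "leaf")
REFERENCE_CODE <- 13L

#' Voxelize the phantom scene into a label volume
#'
#' Builds the per-voxel label map: for each grouping a solution/root
#' cylinder (z from 0 to `beaker_top_mm`), a stem column above it and a leaf
#' cylinder above that; plus the reference-source box; background elsewhere.
#' Labels are disjoint by construction and validated to be so.
#'
#' @param spec a [phantom_spec()].
#' @return A [label_volume()] with legend of 4 x 3 plant regions plus
#'   `reference` and `background`.
#' @export
build_geometry <- function(spec) {
  grid <- spec$grid
  g <- spec$geometry
  ext <- (grid$dims - 1) * grid$spacing
  if (g$leaf_top_mm > ext[3] + grid$spacing[3] / 2 ||
      any(g$centers_x_mm + g$beaker_radius_mm > ext[1] + grid$spacing[1] / 2) ||
      any(g$centers_x_mm - g$beaker_radius_mm < -grid$spacing[1] / 2))
    stop_("build_geometry: geometry exceeds grid extent")
  d <- dist(g$centers_x_mm)
  if (any(d <= 2 * g$beaker_radius_mm))
    stop_("build_geometry: overlapping groupings (centers closer than one beaker diameter)")

  cx <- grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$spacing[1]
  cy <- grid$origin[2] + (seq_len(grid$dims[2]) - 1) * grid$spacing[2]
  labels <- array(0L, dim = grid$dims)

  # z index band [lo_mm, hi_mm): same half-open rule as mm_to_voxel_index
  zband <- function(lo_mm, hi_mm) {
    z0 <- axis_index_raw(lo_mm, grid$origin[3], grid$spacing[3])
    z1 <- axis_index_raw(hi_mm, grid$origin[3], grid$spacing[3]) - 1L
    z0 <- max(z0, 0L); z1 <- min(z1, grid$dims[3] - 1L)
    if (z1 < z0) stop_("build_geometry: empty z band [%g, %g) mm", lo_mm, hi_mm)
    (z0:z1) + 1L  # 1-based for array indexing
  }
  bands <- list(root = zband(0, g$beaker_top_mm),
                stem = zband(g$beaker_top_mm, g$stem_top_mm),
                leaf = zband(g$stem_top_mm, g$leaf_top_mm))
  radii <- c(root = g$beaker_radius_mm, stem = g$stem_radius_mm,
             leaf = g$leaf_radius_mm)

  for (gi in 1:4) {
    lat2 <- outer((cx - g$centers_x_mm[gi])^2, (cy - g$center_y_mm)^2, `+`)
    for (ri in 1:3) {
      region <- REGIONS_PER_PLANT[ri]
      disk <- lat2 <= radii[[region]]^2
      if (!any(disk))
        stop_("build_geometry: %s cylinder of grouping %d contains no voxels", region, gi)
      code <- 3L * (gi - 1L) + ri
      for (z in bands[[region]]) {
        sl <- labels[, , z]
        if (any(sl[disk] != 0L))
          stop_("build_geometry: region overlap at grouping %d, region %s", gi, region)
        sl[disk] <- code
        labels[, , z] <- sl
      }
    }
  }

  rc <- g$reference_center_mm
  rh <- g$reference_halfsize_mm
  ix <- which(abs(cx - rc[1]) <= rh[1])
  iy <- which(abs(cy - rc[2]) <= rh[2])
  czv <- grid$origin[3] + (seq_len(grid$dims[3]) - 1) * grid$spacing[3]
  iz <- which(abs(czv - rc[3]) <= rh[3])
  if (!length(ix) || !length(iy) || !length(iz))
    stop_("build_geometry: reference source contains no voxels")
  if (any(labels[ix, iy, iz] != 0L))
    stop_("build_geometry: reference source overlaps a plant grouping")
  labels[ix, iy, iz] <- REFERENCE_CODE

  legend <- data.frame(
    code = c(vapply(1:4, function(gi) 3L * (gi - 1L) + 1:3, integer(3)),
             REFERENCE_CODE, 0L),
    plant_id = c(rep(names(spec$groupings), each = 3), "reference", "background"),
    region = c(rep(REGIONS_PER_PLANT, 4), "reference", "background"),
    stringsAsFactors = FALSE
  )
  label_volume(labels, grid, legend)
}

region_code <- function(labels, plant_id, region) {
  leg <- labels$legend
  code <- leg$code[leg$plant_id == plant_id & leg$region == region]
  if (length(code) != 1L)
    stop_("no unique label code for plant '%s' region '%s'", plant_id, region)
  code
}

#' Render compartment series into a noiseless dynamic image
#'
#' Forward model from compartments to voxels: at each frame, each
#' compartment's activity — physically decayed to the frame midpoint — is
#' spread uniformly over that compartment's voxels. The root-side pool fills
#' the solution/root cylinder; shoot activity fills the leaf region (with an
#' optional `stem_fraction` of it diverted to the stem column); the
#' reference source is rendered at its constant decayed activity; background
#' is zero, so each noiseless frame total equals the decayed administered
#' total plus the decayed reference activity.
#'
#' @param labels a [label_volume()] from [build_geometry()].
#' @param series named list of [simulate_kinetics()] results, one per
#'   grouping, names matching `spec$groupings`.
#' @param spec the [phantom_spec()].
#' @return A [dynamic_image()] (noiseless, unattenuated ground truth).
#' @export
render_frames <- function(labels, series, spec) {
  nf <- n_frames(spec$frames)
  t_mid <- frame_midpoints(spec$frames)
  if (!identical(sort(names(series)), sort(names(spec$groupings))))
    stop_("render_frames: series names do not match spec groupings")
  for (s in series)
    if (length(s$t) != nf || max(abs(s$t - t_mid)) > 1e-9)
      stop_("render_frames: series frames do not match spec frames")

  nvox <- n_voxels(labels$grid)
  vals <- matrix(0, nrow = nvox, ncol = nf)
  dec <- decay_factor(t_mid)
  sf <- spec$geometry$stem_fraction %||% 0

  put <- function(code, activity_per_frame) {
    idx <- which(as.vector(labels$labels) == code)
    if (!length(idx)) stop_("render_frames: label code %d has no voxels", code)
    vals[idx, ] <<- vals[idx, ] + rep(activity_per_frame / length(idx),
                                      each = length(idx))
  }

  for (nm in names(spec$groupings)) {
    s <- series[[nm]]
    put(region_code(labels, nm, "root"), s$A_pool * dec)
    put(region_code(labels, nm, "leaf"), (1 - sf) * s$A_leaf * dec)
    if (sf > 0) put(region_code(labels, nm, "stem"), sf * s$A_leaf * dec)
  }
  put(REFERENCE_CODE, spec$reference_activity_MBq * dec)

  dim(vals) <- c(labels$grid$dims, nf)
  dynamic_image(vals, labels$grid, spec$frames)
}

#' Build a per-voxel attenuation map by lateral ray casting
#'
#' For each voxel, photons are assumed to escape laterally along the x axis;
#' the survival factor is `exp(-mu * path_mm)` where `path_mm` is the
#' water-equivalent thickness of attenuating material (by default the
#' solution/root regions) crossed between the voxel center and the nearer of
#' the two lateral grid faces. An attenuating voxel contributes its full
#' x-spacing when crossed and half of it when it is the source voxel itself.
#' This validates the correction arithmetic, not scanner physics: a full
#' line-of-response model is out of scope.
#'
#' @param labels a [label_volume()].
#' @param mu_per_mm linear attenuation coefficient, per mm; >= 0.
#' @param attenuating_regions region names that attenuate; default the
#'   water-filled solution/root compartment.
#' @return An object of class `attenuation_map` with fields `grid` and
#'   `factor` (3D array in (0, 1]).
#' @export
build_attenuation_map <- function(labels, mu_per_mm,
                                  attenuating_regions = "root") {
  if (mu_per_mm < 0) stop_("build_attenuation_map: mu must be >= 0")
  codes <- labels$legend$code[labels$legend$region %in% attenuating_regions]
  m <- array(as.numeric(labels$labels %in% codes), dim = dim(labels$labels))
  sx <- labels$grid$spacing[1]
  nx <- dim(m)[1]
  mm <- matrix(m, nrow = nx)            # x fastest: columns are (y, z) rows
  cs <- apply(mm, 2, cumsum)
  tot <- cs[nx, ]
  right <- sx * (rep(tot, each = nx) - cs) + mm * sx / 2
  left <- sx * (cs - mm) + mm * sx / 2
  path <- pmin(right, left)
  factor <- array(exp(-mu_per_mm * path), dim = dim(m))
  structure(list(grid = labels$grid, factor = factor),
            class = "attenuation_map")
}

#' Apply or undo attenuation
#'
#' `apply_attenuation` multiplies every frame voxelwise by the survival
#' factors; `correct_attenuation` divides by them (exact correction with the
#' true map), so the two are inverse operations.
#'
#' @param image a [dynamic_image()].
#' @param attn an `attenuation_map` on the same grid.
#' @return A [dynamic_image()].
#' @export
apply_attenuation <- function(image, attn) {
  if (!same_grid(image$grid, attn$grid))
    stop_("apply_attenuation: image and attenuation map grids differ")
  out <- image
  out$values <- image$values * as.vector(attn$factor)
  out
}

#' @rdname apply_attenuation
#' @export
correct_attenuation <- function(image, attn) {
  if (!same_grid(image$grid, attn$grid))
    stop_("correct_attenuation: image and attenuation map grids differ")
  out <- image
  out$values <- image$values / as.vector(attn$factor)
  out
}

#' Add Poisson counting noise
#'
#' Each voxel-frame activity `v` is replaced by
#' `Poisson(v * sensitivity * frame_duration) / (sensitivity * frame_duration)`,
#' an unbiased counts-derived estimate. Deterministic given `seed`; the
#' caller's RNG state is left untouched. Infinite sensitivity returns the
#' input unchanged (noiseless mode).
#'
#' @param image a [dynamic_image()].
#' @param sensitivity expected counts per MBq.h in one voxel; > 0.
#' @param frames the [frame_schedule()] supplying the frame duration.
#' @param seed integer RNG seed.
#' @return A [dynamic_image()] with Poisson-resampled values.
#' @export
add_counting_noise <- function(image, sensitivity, frames = image$frames,
                               seed = 1L) {
  if (sensitivity <= 0) stop_("add_counting_noise: sensitivity must be > 0")
  if (!is.finite(sensitivity)) return(image)
  scale <- sensitivity * frames$frame_duration_h
  out <- image
  out$values <- with_seed(seed, {
    counts <- stats::rpois(length(image$values), as.vector(image$values) * scale)
    array(counts / scale, dim = dim(image$values))
  })
  out
}

#' Generate a complete synthetic dataset
#'
#' Composes the phantom pipeline: voxelize the scene, simulate per-grouping
#' kinetics, render noiseless frames, attenuate, add counting noise, and
#' reconstruct the attenuation-corrected variant by exact division with the
#' true map. Both image variants share one noise realization (one simulated
#' scan, two reconstructions). With `sensitivity = Inf` both variants are
#' noiseless and the corrected image equals the rendered ground truth
#' bit-exactly.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `synthetic_dataset`: list with
#'   `pet_corrected`, `pet_uncorrected` ([dynamic_image()]s), `labels`
#'   ([label_volume()]), `attenuation` (attenuation map), `truth` (named
#'   list per grouping of `compartment_series`), `doses_MBq`, and `spec`.
#' @export
generate_dataset <- function(spec) {
  labels <- build_geometry(spec)
  series <- lapply(spec$groupings, simulate_kinetics,
                   frames = spec$frames, light = spec$light)
  truth_img <- render_frames(labels, series, spec)
  attn <- build_attenuation_map(labels, spec$mu_per_mm)
  attenuated <- apply_attenuation(truth_img, attn)
  if (is.finite(spec$sensitivity)) {
    noisy <- add_counting_noise(attenuated, spec$sensitivity, spec$frames,
                                seed = spec$seed)
    pet_uncorrected <- noisy
    pet_corrected <- correct_attenuation(noisy, attn)
  } else {
    pet_uncorrected <- attenuated
    pet_corrected <- truth_img
  }
  structure(list(pet_corrected = pet_corrected,
                 pet_uncorrected = pet_uncorrected,
                 labels = labels,
                 attenuation = attn,
                 truth = series,
                 doses_MBq = vapply(spec$groupings, `[[`, numeric(1), "A_total"),
                 spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %s voxels x %d frames, %d groupings, doses %s MBq\n",
              paste(x$spec$grid$dims, collapse = " x "),
              n_frames(x$spec$frames), length(x$truth),
              paste(signif(x$doses_MBq, 3), collapse = "/")))
  invisible(x)
}

#' Read a phantom specification from JSON or YAML
#'
#' The file mirrors the arguments of [default_phantom_spec()]; any field not
#' present keeps its default. YAML files require the `yaml` package.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) stop_("read_phantom_spec: file not found: %s", path)
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_("read_phantom_spec: the 'yaml' package is required for YAML specs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- x[intersect(names(x), names(formals(default_phantom_spec)))]
  if (!is.null(args$light))
    args$light <- do.call(light_schedule, as.list(args$light))
  if (!is.null(args$doses_MBq)) args$doses_MBq <- unlist(args$doses_MBq)
  do.call(default_phantom_spec, args)
}
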