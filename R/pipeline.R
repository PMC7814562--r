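# End-to-end orchestration: phantom or file input -> ROIs -> TACs -> ratios
# -> rates -> uptake-rate estimates -> diurnal test -> attenuation-correction
# validation -> reference drift QC -> CSV/JSON/PNG outputs.

#' ROIs implied by a phantom specification
#'
#' Derives the same inputs an analyst would take from the CT image — region
#' height intervals and lateral cylinder bounding boxes — from the phantom
#' geometry, and converts them with [rois_from_heights()]. Lateral bounds
#' are padded by one voxel so each prism fully covers its cylinder. Also
#' returns the reference-source ROI and, per grouping, a whole-grouping
#' prism (full z column) used for total-activity estimation.
#'
#' @param spec a [phantom_spec()].
#' @return List with elements `plant` (list of [plant_roi()], root and leaf
#'   per grouping, plus stem when `stem_fraction > 0`), `reference` (one
#'   [plant_roi()]) and `whole` (named list of whole-grouping prisms).
#' @export
phantom_rois <- function(spec) {
  g <- spec$geometry
  grid <- spec$grid
  pad <- grid$spacing[1:2]
  lo_lim <- grid$origin[1:2] - grid$spacing[1:2] / 2 + 1e-9
  hi_lim <- grid$origin[1:2] + (grid$dims[1:2] - 0.5) * grid$spacing[1:2] - 1e-9
  r <- max(g$beaker_radius_mm, g$leaf_radius_mm)

  nm <- names(spec$groupings)
  regions <- c("root", "leaf", if ((g$stem_fraction %||% 0) > 0) "stem")
  zb <- list(root = c(0, g$beaker_top_mm),
             stem = c(g$beaker_top_mm, g$stem_top_mm),
             leaf = c(g$stem_top_mm, g$leaf_top_mm))
  heights <- do.call(rbind, lapply(nm, function(p)
    data.frame(plant_id = p, region = regions,
               z_bottom_mm = vapply(zb[regions], `[`, numeric(1), 1),
               z_top_mm = vapply(zb[regions], `[`, numeric(1), 2),
               stringsAsFactors = FALSE)))
  lateral <- data.frame(
    plant_id = nm,
    x_min_mm = pmax(g$centers_x_mm - r - pad[1], lo_lim[1]),
    x_max_mm = pmin(g$centers_x_mm + r + pad[1], hi_lim[1]),
    y_min_mm = pmax(g$center_y_mm - r - pad[2], lo_lim[2]),
    y_max_mm = pmin(g$center_y_mm + r + pad[2], hi_lim[2]),
    stringsAsFactors = FALSE)
  plant <- rois_from_heights(heights, lateral, grid)

  whole <- stats::setNames(lapply(nm, function(p) {
    lb <- lateral[lateral$plant_id == p, ]
    xr <- interval_to_index_range(lb$x_min_mm, lb$x_max_mm, grid$origin[1],
                                  grid$spacing[1], grid$dims[1], "phantom_rois")
    yr <- interval_to_index_range(lb$y_min_mm, lb$y_max_mm, grid$origin[2],
                                  grid$spacing[2], grid$dims[2], "phantom_rois")
    plant_roi(p, "whole", xr, yr, c(0L, grid$dims[3] - 1L), grid = grid)
  }), nm)

  rc <- g$reference_center_mm
  rh <- g$reference_halfsize_mm + grid$spacing
  ref <- plant_roi("reference", "reference",
                   interval_to_index_range(max(rc[1] - rh[1], grid$origin[1] - grid$spacing[1] / 2 + 1e-9),
                                           min(rc[1] + rh[1], grid$origin[1] + (grid$dims[1] - 0.5) * grid$spacing[1] - 1e-9),
                                           grid$origin[1], grid$spacing[1], grid$dims[1], "phantom_rois"),
                   interval_to_index_range(max(rc[2] - rh[2], grid$origin[2] - grid$spacing[2] / 2 + 1e-9),
                                           min(rc[2] + rh[2], grid$origin[2] + (grid$dims[2] - 0.5) * grid$spacing[2] - 1e-9),
                                           grid$origin[2], grid$spacing[2], grid$dims[2], "phantom_rois"),
                   interval_to_index_range(max(rc[3] - rh[3], grid$origin[3] - grid$spacing[3] / 2 + 1e-9),
                                           min(rc[3] + rh[3], grid$origin[3] + (grid$dims[3] - 0.5) * grid$spacing[3] - 1e-9),
                                           grid$origin[3], grid$spacing[3], grid$dims[3], "phantom_rois"),
                   grid = grid)
  list(plant = plant, reference = ref, whole = whole)
}

#' Estimate total activity in a prism at one frame
#'
#' Sums the prism at the requested frame and decay-corrects the sum to
#' t = 0, so the estimate is directly comparable with the administered dose.
#'
#' @param image a [dynamic_image()].
#' @param roi a [plant_roi()].
#' @param frame 1-based frame index.
#' @param half_life_y half-life in years; default sodium-22.
#' @return Estimated activity at administration time, MBq.
#' @export
estimate_total_activity <- function(image, roi, frame,
                                    half_life_y = NA22_HALF_LIFE_Y) {
  nf <- n_frames(image$frames)
  if (frame < 1 || frame > nf)
    stop_("estimate_total_activity: frame %d outside 1..%d", frame, nf)
  x <- extract_tac(image, roi)
  x <- decay_correct(x, half_life_y = half_life_y, t_ref_h = 0)
  x$A_MBq[frame]
}

#' Validate attenuation correction against administered doses
#'
#' For each grouping, the whole-grouping prism total (beaker, solution and
#' plant together) at the chosen frame is decay-corrected to t = 0 and
#' compared with the administered dose, for both the attenuation-corrected
#' and the uncorrected reconstruction. With any nontrivial attenuation the
#' uncorrected totals must underestimate the truth for every grouping; this
#' is asserted and reported.
#'
#' @param dataset a [generate_dataset()] result.
#' @param frame 1-based frame index; defaults to the final frame.
#' @return An object of class `ac_validation_result`: data.frame with one
#'   row per grouping and columns `plant_id`, `ground_truth_MBq`,
#'   `est_with_AC_MBq`, `est_without_AC_MBq`, `rel_err_with_AC`,
#'   `rel_err_without_AC`.
#' @export
validate_attenuation_correction <- function(dataset,
                                            frame = n_frames(dataset$spec$frames)) {
  if (is.null(dataset$pet_corrected) || is.null(dataset$pet_uncorrected))
    stop_("validate_attenuation_correction: dataset is missing an image variant")
  whole <- phantom_rois(dataset$spec)$whole
  nm <- names(dataset$spec$groupings)
  truth <- unname(dataset$doses_MBq[nm])
  with_ac <- vapply(nm, function(p)
    estimate_total_activity(dataset$pet_corrected, whole[[p]], frame), numeric(1))
  without_ac <- vapply(nm, function(p)
    estimate_total_activity(dataset$pet_uncorrected, whole[[p]], frame), numeric(1))
  out <- data.frame(plant_id = nm,
                    ground_truth_MBq = truth,
                    est_with_AC_MBq = unname(with_ac),
                    est_without_AC_MBq = unname(without_ac),
                    rel_err_with_AC = unname(with_ac / truth - 1),
                    rel_err_without_AC = unname(without_ac / truth - 1),
                    stringsAsFactors = FALSE)
  if (dataset$spec$mu_per_mm > 0 && any(out$est_without_AC_MBq >= truth))
    warning("uncorrected totals do not all underestimate the administered dose")
  class(out) <- c("ac_validation_result", class(out))
  out
}

#' Reference-source drift check
#'
#' The decay-corrected TAC of a constant-activity reference source should be
#' flat; scanner drift shows up as deviation from its mean. Reports the
#' maximum relative deviation `max |A(t) - mean| / mean` and a pass/fail
#' verdict at the threshold.
#'
#' @param image a [dynamic_image()].
#' @param ref_roi the reference-source [plant_roi()].
#' @param threshold maximum tolerated relative deviation; default 0.05.
#' @return An object of class `drift_report`: fields `tac` (decay-corrected
#'   [tac()]), `max_rel_deviation`, `threshold`, `pass`.
#' @export
check_reference_drift <- function(image, ref_roi, threshold = 0.05) {
  x <- decay_correct(extract_tac(image, ref_roi))
  m <- mean(x$A_MBq)
  if (m <= 0) stop_("check_reference_drift: empty reference TAC")
  dev <- max(abs(x$A_MBq - m)) / m
  structure(list(tac = x, max_rel_deviation = dev, threshold = threshold,
                 pass = dev < threshold),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("<drift_report> max relative deviation %.4g (threshold %g): %s\n",
              x$max_rel_deviation, x$threshold,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Run configuration
#'
#' Exactly one of `spec` (phantom mode) or `pet_path` (file mode) must be
#' given. File mode additionally needs the frame-schedule sidecar, an ROI
#' JSON and a light schedule.
#'
#' @param out_dir output directory (created if absent).
#' @param spec a [phantom_spec()] for phantom mode.
#' @param pet_path path to a 4D NIfTI for file mode.
#' @param schedule_path frame-schedule JSON sidecar (file mode).
#' @param rois_path ROI JSON as written by [write_rois()] (file mode).
#' @param light a [light_schedule()]; defaults to the spec's in phantom mode.
#' @param eps root-ratio floor for [estimate_uptake_rate()].
#' @param drift_threshold relative threshold for [check_reference_drift()].
#' @param p_cutoff significance cutoff reported alongside the diurnal test.
#' @param seed integer seed; in phantom mode it overrides the spec's seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, spec = NULL, pet_path = NULL,
                       schedule_path = NULL, rois_path = NULL, light = NULL,
                       eps = 0.05, drift_threshold = 0.05, p_cutoff = 0.05,
                       seed = 1L) {
  if (is.null(spec) == is.null(pet_path))
    stop_("run_config: exactly one of 'spec' (phantom mode) or 'pet_path' (file mode) must be given")
  if (!is.null(pet_path)) {
    if (is.null(schedule_path) || is.null(rois_path) || is.null(light))
      stop_("run_config: file mode needs schedule_path, rois_path and light")
  } else {
    light <- light %||% spec$light
    spec$seed <- as.integer(seed)
  }
  structure(list(out_dir = out_dir, spec = spec, pet_path = pet_path,
                 schedule_path = schedule_path, rois_path = rois_path,
                 light = light, eps = eps, drift_threshold = drift_threshold,
                 p_cutoff = p_cutoff, seed = as.integer(seed)),
            class = "run_config")
}

write_curves_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, tac_to_df))
  utils::write.csv(df, path, row.names = FALSE)
  df
}

plot_plant_panel <- function(rel_list, rate_list, mask, t_h, path, plant_id) {
  grDevices::png(path, width = 1200, height = 500, res = 110)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  shade_dark <- function(ylim) {
    r <- rle(!mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values))
      graphics::rect(t_h[starts[i]] - 0.5, ylim[1], t_h[ends[i]] + 0.5,
                     ylim[2], col = "grey85", border = NA)
  }
  cols <- c(root = "firebrick", leaf = "forestgreen", stem = "goldenrod")
  ylim <- c(0, 1)
  graphics::plot(NA, xlim = range(t_h), ylim = ylim, xlab = "time (h)",
                 ylab = "radioactivity ratio", main = plant_id)
  shade_dark(ylim)
  for (r in rel_list)
    graphics::lines(r$t_h, r$R, col = cols[[r$region]] %||% "black", lwd = 2)
  graphics::legend("right", legend = vapply(rel_list, `[[`, character(1), "region"),
                   col = vapply(rel_list, function(r) cols[[r$region]] %||% "black",
                                character(1)), lwd = 2, bty = "n")
  yr <- range(unlist(lapply(rate_list, `[[`, "dRdt")))
  graphics::plot(NA, xlim = range(t_h), ylim = yr, xlab = "time (h)",
                 ylab = "d(ratio)/dt (per h)", main = "rate of change")
  shade_dark(yr)
  graphics::abline(h = 0, col = "grey50")
  for (r in rate_list)
    graphics::lines(r$t_h, r$dRdt, col = cols[[r$region]] %||% "black", lwd = 2)
}

#' Run the full analysis pipeline
#'
#' Phantom mode simulates a dataset from the config's [phantom_spec()] and
#' analyses it; file mode loads a saved 4D PET series, frame schedule and
#' ROI definitions. Either way the pipeline extracts per-region TACs,
#' decay-corrects them, normalizes per plant, differentiates, estimates the
#' uptake-rate time course, runs the circular-shift diurnal test on each
#' leaf rate curve, checks reference drift (when a reference ROI exists) and
#' — in phantom mode — validates the attenuation correction against the
#' administered doses. All tabular outputs are CSV/JSON under `out_dir`,
#' panel figures are PNG, and a manifest records the configuration; reruns
#' with the same seed are identical.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `tacs`, `ratios`, `rates`, `uptake`,
#'   `diurnal`, `anticipation`, `drift`, `ac_validation` (phantom mode) and
#'   `paths` of everything written.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop_("run_pipeline: not a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  if (!is.null(config$spec)) {
    dataset <- generate_dataset(config$spec)
    image <- dataset$pet_corrected
    rois <- phantom_rois(config$spec)
    plant_rois <- rois$plant
    ref_roi <- rois$reference
  } else {
    schedule <- read_frame_schedule(config$schedule_path)
    image <- load_dynamic_image(config$pet_path, schedule)
    dataset <- NULL
    all_rois <- read_rois(config$rois_path)
    is_ref <- vapply(all_rois, function(r) r$region == "reference", logical(1))
    plant_rois <- all_rois[!is_ref]
    ref_roi <- if (any(is_ref)) all_rois[is_ref][[1]] else NULL
  }

  mask <- light_mask(image$frames, config$light)
  tacs <- lapply(plant_rois, function(r) decay_correct(extract_tac(image, r)))
  plants <- unique(vapply(tacs, `[[`, character(1), "plant_id"))

  ratios <- list(); rates <- list(); uptake <- list()
  diurnal <- list(); anticipation <- list()
  for (p in plants) {
    mine <- tacs[vapply(tacs, function(x) x$plant_id == p, logical(1))]
    rel <- normalize_tacs(mine)
    names(rel) <- vapply(rel, `[[`, character(1), "region")
    rc <- lapply(rel, rate_of_change)
    ratios[[p]] <- rel
    rates[[p]] <- rc
    if (all(c("root", "leaf") %in% names(rel))) {
      uptake[[p]] <- estimate_uptake_rate(rc$leaf, rel$root, eps = config$eps)
      dr <- circular_shift_test(rc$leaf, mask)
      dr$significant <- dr$p <= config$p_cutoff
      diurnal[[p]] <- dr
      anticipation[[p]] <- anticipation_scan(rc$leaf, image$frames, config$light)
    }
  }

  paths <- list(tacs = out("tacs.csv"), ratios = out("ratios.csv"),
                rates = out("rates.csv"), uptake = out("uptake_rates.csv"),
                diurnal = out("diurnal.json"),
                anticipation = out("anticipation_scan.csv"),
                manifest = out("manifest.json"))
  write_curves_csv(tacs, paths$tacs)
  write_curves_csv(do.call(c, unname(ratios)), paths$ratios)
  write_curves_csv(do.call(c, unname(rates)), paths$rates)
  if (length(uptake)) write_curves_csv(uptake, paths$uptake)
  jsonlite::write_json(lapply(diurnal, unclass), paths$diurnal,
                       auto_unbox = TRUE, digits = NA)
  if (length(anticipation)) {
    ant <- do.call(rbind, lapply(names(anticipation), function(p)
      cbind(plant_id = p, anticipation[[p]])))
    utils::write.csv(ant, paths$anticipation, row.names = FALSE)
  }

  drift <- NULL
  if (!is.null(ref_roi)) {
    drift <- check_reference_drift(image, ref_roi, config$drift_threshold)
    paths$drift <- out("drift.json")
    jsonlite::write_json(list(max_rel_deviation = drift$max_rel_deviation,
                              threshold = drift$threshold, pass = drift$pass),
                         paths$drift, auto_unbox = TRUE, digits = NA)
  }

  ac <- NULL
  if (!is.null(dataset)) {
    ac <- validate_attenuation_correction(dataset)
    paths$ac_validation <- out("ac_validation.csv")
    utils::write.csv(as.data.frame(ac), paths$ac_validation, row.names = FALSE)
  }

  for (p in plants) {
    paths[[paste0("panel_", p)]] <- out(paste0("panel_", p, ".png"))
    plot_plant_panel(ratios[[p]], rates[[p]], mask,
                     frame_midpoints(image$frames),
                     paths[[paste0("panel_", p)]], p)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("phytopet")),
                   mode = if (is.null(config$spec)) "file" else "phantom",
                   seed = config$seed, eps = config$eps,
                   drift_threshold = config$drift_threshold,
                   p_cutoff = config$p_cutoff,
                   n_frames = n_frames(image$frames),
                   grid_dims = image$grid$dims,
                   plants = plants)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(tacs = tacs, ratios = ratios, rates = rates, uptake = uptake,
                 diurnal = diurnal, anticipation = anticipation, drift = drift,
                 ac_validation = ac, dataset = dataset, paths = paths))
}
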