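# Time-activity curves: ROI summation, decay correction, per-plant
# normalization, rate-of-change by first central differences, and the
# per-frame uptake-rate estimator.

#' Time-activity curve
#'
#' ROI-summed activity per frame. Constructed by [extract_tac()]; held as a
#' light S3 list so curve arithmetic stays simple; use [tac_to_df()] for a
#' tidy data.frame.
#'
#' @param plant_id,region identifiers.
#' @param t_h frame midpoints, hours.
#' @param A_MBq activity per frame, MBq; >= 0.
#' @param decay_corrected logical flag.
#' @return An object of class `tac`.
#' @export
tac <- function(plant_id, region, t_h, A_MBq, decay_corrected = FALSE) {
  if (length(t_h) != length(A_MBq))
    stop_("tac: t_h and A_MBq lengths differ")
  if (min(A_MBq) < 0) stop_("tac: negative activity")
  structure(list(plant_id = plant_id, region = region,
                 t_h = as.numeric(t_h), A_MBq = as.numeric(A_MBq),
                 decay_corrected = isTRUE(decay_corrected)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s/%s, %d frames, A = %.4g .. %.4g MBq%s\n",
              x$plant_id, x$region, length(x$t_h), min(x$A_MBq), max(x$A_MBq),
              if (x$decay_corrected) " (decay-corrected)" else ""))
  invisible(x)
}

#' Extract a TAC by summing a prism ROI over each frame
#'
#' @param image a [dynamic_image()].
#' @param roi a [plant_roi()] within the image grid.
#' @return A [tac()] with `decay_corrected = FALSE`.
#' @export
extract_tac <- function(image, roi) {
  g <- image$grid
  if (any(c(roi$x[2], roi$y[2], roi$z[2]) > g$dims - 1L))
    stop_("extract_tac: ROI exceeds the image grid")
  sub <- image$values[(roi$x[1]:roi$x[2]) + 1L, (roi$y[1]:roi$y[2]) + 1L,
                      (roi$z[1]:roi$z[2]) + 1L, , drop = FALSE]
  tac(roi$plant_id, roi$region, frame_midpoints(image$frames),
      colSums(sub, dims = 3L))
}

#' Decay-correct a TAC
#'
#' Refers measured activities to a common reference time:
#' `A_corr(t) = A(t) * 2^((t - t_ref) / T_half)` with the half-life in hours
#' (1 y = 8766 h). For sodium-22 over a 72-h scan this is a <= 0.22% effect,
#' applied for correctness and for the reference-source drift check.
#'
#' @param x a [tac()].
#' @param half_life_y half-life in years; > 0. Default sodium-22.
#' @param t_ref_h reference time, hours; default 0 (tracer administration).
#' @return A [tac()] with `decay_corrected = TRUE`.
#' @export
decay_correct <- function(x, half_life_y = NA22_HALF_LIFE_Y, t_ref_h = 0) {
  if (half_life_y <= 0) stop_("decay_correct: half-life must be positive")
  half_life_h <- half_life_y * HOURS_PER_YEAR
  out <- x
  out$A_MBq <- x$A_MBq * 2^((x$t_h - t_ref_h) / half_life_h)
  out$decay_corrected <- TRUE
  out
}

#' Normalize a plant's TACs to relative radioactivity
#'
#' At each frame, each region's activity is divided by the plant's total
#' over all supplied regions, yielding dimensionless ratios that sum to 1
#' per frame. The ratio cancels physical decay, so decay correction of the
#' inputs does not change the result (as long as all regions are treated
#' alike).
#'
#' @param tacs list of [tac()] objects for one plant on one frame schedule.
#' @return List of objects of class `relative_tac` (fields `plant_id`,
#'   `region`, `t_h`, `R`, and `denominator_regions` recording what the
#'   plant total comprised), in the input order.
#' @export
normalize_tacs <- function(tacs) {
  if (!length(tacs)) stop_("normalize_tacs: no TACs supplied")
  pid <- unique(vapply(tacs, `[[`, character(1), "plant_id"))
  if (length(pid) != 1L)
    stop_("normalize_tacs: TACs belong to different plants: %s",
          paste(pid, collapse = ", "))
  t0 <- tacs[[1]]$t_h
  for (x in tacs)
    if (length(x$t_h) != length(t0) || max(abs(x$t_h - t0)) > 1e-9)
      stop_("normalize_tacs: TACs are on different frame schedules")
  total <- Reduce(`+`, lapply(tacs, `[[`, "A_MBq"))
  bad <- which(total <= 0)
  if (length(bad))
    stop_("normalize_tacs: zero plant total at frame(s) %s",
          paste(utils::head(bad, 5), collapse = ", "))
  regions <- vapply(tacs, `[[`, character(1), "region")
  lapply(tacs, function(x)
    structure(list(plant_id = x$plant_id, region = x$region,
                   t_h = x$t_h, R = x$A_MBq / total,
                   denominator_regions = regions),
              class = "relative_tac"))
}

#' Rate of change of a relative TAC by first central differences
#'
#' Interior frames use `(R[i+1] - R[i-1]) / (2h)`; the two endpoints use
#' one-sided first differences and are tagged as such. Frame spacing must be
#' uniform.
#'
#' @param rel a `relative_tac` from [normalize_tacs()] (or any list with
#'   `t_h` and `R`).
#' @return An object of class `rate_curve`: fields `plant_id`, `region`,
#'   `t_h`, `dRdt` (per hour), `interior` (logical; `FALSE` at the two
#'   endpoints) and `endpoint_method = "one_sided"`.
#' @export
rate_of_change <- function(rel) {
  t <- rel$t_h; R <- rel$R
  n <- length(t)
  if (n < 3L) stop_("rate_of_change: need at least 3 frames")
  h <- diff(t)
  if (max(abs(h - h[1])) > 1e-9)
    stop_("rate_of_change: non-uniform frame spacing")
  h <- h[1]
  dRdt <- numeric(n)
  dRdt[2:(n - 1)] <- (R[3:n] - R[1:(n - 2)]) / (2 * h)
  dRdt[1] <- (R[2] - R[1]) / h
  dRdt[n] <- (R[n] - R[n - 1]) / h
  structure(list(plant_id = rel$plant_id, region = rel$region,
                 t_h = t, dRdt = dRdt,
                 interior = c(FALSE, rep(TRUE, n - 2), FALSE),
                 endpoint_method = "one_sided"),
            class = "rate_curve")
}

#' Estimate the uptake rate time course
#'
#' For the two-pool transport model `dA_leaf/dt = k(t) * A_pool`, dividing
#' the leaf ratio's rate of change by the root-side ratio recovers the rate
#' constant frame by frame: `k_hat(t) = dR_leaf/dt / R_root(t)`. Only
#' interior frames (central differences) are evaluated; frames where the
#' root ratio has fallen to `eps` or below are flagged and excluded to avoid
#' division blow-up as the pool empties.
#'
#' @param rate_leaf a [rate_of_change()] result for the leaf region.
#' @param rel_root the root `relative_tac` on the same frames.
#' @param eps exclusion floor for the root ratio; default 0.05.
#' @return An object of class `uptake_rate_estimate`: fields `t_h`, `k_hat`
#'   (per hour, `NA` where excluded), `used` (logical), `eps`.
#' @export
estimate_uptake_rate <- function(rate_leaf, rel_root, eps = 0.05) {
  if (length(rate_leaf$t_h) != length(rel_root$t_h) ||
      max(abs(rate_leaf$t_h - rel_root$t_h)) > 1e-9)
    stop_("estimate_uptake_rate: curves are on different frame schedules")
  used <- rate_leaf$interior & rel_root$R > eps
  if (!any(used)) stop_("estimate_uptake_rate: no evaluable frames")
  k_hat <- ifelse(used, rate_leaf$dRdt / rel_root$R, NA_real_)
  structure(list(plant_id = rate_leaf$plant_id, t_h = rate_leaf$t_h,
                 k_hat = k_hat, used = used, eps = eps),
            class = "uptake_rate_estimate")
}

#' Tidy data.frame view of curve objects
#'
#' @param x a `tac`, `relative_tac`, `rate_curve` or `uptake_rate_estimate`.
#' @return data.frame with columns `plant_id`, `region` (where applicable),
#'   `frame`, `t_h`, `value`.
#' @export
tac_to_df <- function(x) {
  val <- x$A_MBq %||% x$R %||% x$dRdt %||% x$k_hat
  data.frame(plant_id = x$plant_id,
             region = x$region %||% NA_character_,
             frame = seq_along(x$t_h),
             t_h = x$t_h,
             value = val,
             stringsAsFactors = FALSE)
}
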