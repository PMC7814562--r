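# Shared fixtures and independent oracles for the test suite.

# A reduced phantom that keeps the full 72-frame temporal structure but a
# small spatial grid; counting statistics per ROI depend only on activity
# (ROI counts ~ Poisson(A * sensitivity * duration)), not on voxel count,
# so the reduced grid does not change the noise regime.
small_spec <- function(n_frames = 72, ...) {
  default_phantom_spec(dims = c(24, 24, 24), n_frames = n_frames, ...)
}

# Independent numerical oracle for the two-pool kinetics: integrate
# dA_leaf/dt = k(t) (A_total - A_leaf) with a high-order adaptive solver,
# evaluating k(t) directly from the rate definition.
ode_leaf_oracle <- function(params, times, light) {
  rhs <- function(t, y, parms) {
    list(uptake_rate_at(t, params, light) * (params$A_total - y[1]))
  }
  # hmax bounds the step so the solver cannot leap across a light/dark
  # discontinuity of k(t)
  out <- deSolve::ode(y = c(A = 0), times = c(0, times), func = rhs,
                      parms = NULL, method = "lsoda", hmax = 0.05,
                      rtol = 1e-11, atol = 1e-13)
  out[-1, "A"]
}

# Brute-force triple-loop ROI sum (zero-based inclusive bounds).
loop_roi_sum <- function(values4d, roi) {
  nf <- dim(values4d)[4]
  sums <- numeric(nf)
  for (f in seq_len(nf))
    for (x in roi$x[1]:roi$x[2])
      for (y in roi$y[1]:roi$y[2])
        for (z in roi$z[1]:roi$z[2])
          sums[f] <- sums[f] + values4d[x + 1, y + 1, z + 1, f]
  sums
}

# A random in-extent point of a grid.
random_point_in_grid <- function(grid) {
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$dims - 1) * grid$spacing + grid$spacing / 2
  stats::runif(3, lo + 1e-6, hi - 1e-6)
}

# A random non-empty prism ROI inside a grid.
random_roi <- function(grid, plant_id = "p", region = "r") {
  b <- function(n) sort(sample(0:(n - 1), 2, replace = TRUE))
  plant_roi(plant_id, region, b(grid$dims[1]), b(grid$dims[2]),
            b(grid$dims[3]), grid = grid)
}

# Full analysis path for one grouping of a generated dataset: TACs from the
# corrected image, decay correction, normalization, rates and the
# uptake-rate estimate.
analyse_grouping <- function(ds, plant_id, eps = 0.05) {
  rois <- phantom_rois(ds$spec)
  mine <- Filter(function(r) r$plant_id == plant_id, rois$plant)
  tacs <- lapply(mine, function(r) decay_correct(extract_tac(ds$pet_corrected, r)))
  rel <- normalize_tacs(tacs)
  names(rel) <- vapply(rel, `[[`, character(1), "region")
  rates <- lapply(rel, rate_of_change)
  list(rel = rel, rates = rates,
       est = estimate_uptake_rate(rates$leaf, rel$root, eps = eps))
}

# Analytic relative TACs of the two-pool model at frame midpoints, for
# estimator tests that need noiseless curves without rendering a volume.
analytic_ratios <- function(params, frames, light) {
  s <- simulate_kinetics(params, frames, light)
  rel_root <- structure(list(plant_id = "p", region = "root", t_h = s$t,
                             R = s$A_pool / s$A_total), class = "relative_tac")
  rel_leaf <- structure(list(plant_id = "p", region = "leaf", t_h = s$t,
                             R = s$A_leaf / s$A_total), class = "relative_tac")
  list(root = rel_root, leaf = rel_leaf, series = s)
}
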