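make_random_image <- function(grid, nf = 5, seed = 1) {
  set.seed(seed)
  vals <- array(stats::runif(prod(grid$dims) * nf), c(grid$dims, nf))
  dynamic_image(vals, grid, frame_schedule(seq(0, nf - 1), 1))
}

test_that("prism sums equal triple-loop accumulation and frame totals", {
  grid <- voxel_grid(c(8, 7, 6), c(1, 1, 1))
  img <- make_random_image(grid, nf = 4, seed = 2)
  whole <- plant_roi("p", "all", c(0, 7), c(0, 6), c(0, 5), grid = grid)
  expect_equal(extract_tac(img, whole)$A_MBq, frame_totals(img))
  set.seed(21)
  for (i in 1:20) {
    roi <- random_roi(grid)
    expect_equal(extract_tac(img, roi)$A_MBq, loop_roi_sum(img$values, roi))
  }
  # all-zero image -> zero TAC
  z <- dynamic_image(array(0, c(grid$dims, 2)), grid, frame_schedule(0:1, 1))
  expect_equal(extract_tac(z, whole)$A_MBq, c(0, 0))
})

test_that("extract_tac is additive over disjoint prisms", {
  grid <- voxel_grid(c(8, 7, 6), c(1, 1, 1))
  img <- make_random_image(grid, nf = 3, seed = 4)
  lower <- plant_roi("p", "a", c(0, 7), c(0, 6), c(0, 2), grid = grid)
  upper <- plant_roi("p", "b", c(0, 7), c(0, 6), c(3, 5), grid = grid)
  expect_equal(extract_tac(img, lower)$A_MBq + extract_tac(img, upper)$A_MBq,
               frame_totals(img))
})

test_that("decay correction matches the independent factor and inverts", {
  x <- tac("p", "root", t_h = 72, A_MBq = 1)
  corr <- decay_correct(x)
  # independent evaluation of 2^(72 / (2.605 * 8766)) at full precision
  expect_equal(corr$A_MBq, 2^(72 / (2.605 * 8766)), tolerance = 1e-12)
  expect_equal(corr$A_MBq, 1.00219, tolerance = 1e-5)
  expect_true(corr$decay_corrected)
  # t = t_ref leaves the value unchanged
  expect_equal(decay_correct(tac("p", "r", 10, 1), t_ref_h = 10)$A_MBq, 1)
  # correcting forward then referencing back restores the input
  y <- tac("p", "r", t_h = c(1, 30, 72), A_MBq = c(0.5, 1, 2))
  fwd <- decay_correct(y, t_ref_h = 0)
  back <- fwd
  back$A_MBq <- fwd$A_MBq * 2^(-(fwd$t_h - 0) / (2.605 * 8766))
  expect_equal(back$A_MBq, y$A_MBq, tolerance = 1e-14)
  expect_error(decay_correct(y, half_life_y = -1), "positive")
})

test_that("per-plant normalization yields ratios summing to one", {
  t_h <- c(0.5, 1.5)
  root <- tac("p", "root", t_h, c(1.2, 1.0))
  leaf <- tac("p", "leaf", t_h, c(0.3, 0.5))
  rel <- normalize_tacs(list(root, leaf))
  expect_equal(rel[[1]]$R, c(1.2, 1.0) / c(1.5, 1.5))
  expect_equal(rel[[1]]$R[1], 0.8)
  expect_equal(rel[[2]]$R[1], 0.2)
  expect_equal(rel[[1]]$R + rel[[2]]$R, c(1, 1))
  expect_equal(rel[[1]]$denominator_regions, c("root", "leaf"))
  # single-region plant: ratio identically 1
  expect_equal(normalize_tacs(list(root))[[1]]$R, c(1, 1))
  # invariant to uniform rescaling
  c_ <- 3.7
  root2 <- root; root2$A_MBq <- root$A_MBq * c_
  leaf2 <- leaf; leaf2$A_MBq <- leaf$A_MBq * c_
  rel2 <- normalize_tacs(list(root2, leaf2))
  expect_equal(rel2[[1]]$R, rel[[1]]$R, tolerance = 1e-14)
  # zero plant total is reported with the frame index
  zero <- tac("p", "leaf", t_h, c(0, 0.5))
  root0 <- tac("p", "root", t_h, c(0, 1))
  expect_error(normalize_tacs(list(root0, zero)), "frame")
})

test_that("central-difference rates are exact for quadratics", {
  rel <- structure(list(plant_id = "p", region = "leaf",
                        t_h = 0:10, R = (0:10)^2 / 200), class = "relative_tac")
  rc <- rate_of_change(rel)
  expect_equal(rc$dRdt[2:10], 2 * (1:9) / 200, tolerance = 1e-14)
  expect_equal(rc$endpoint_method, "one_sided")
  expect_false(rc$interior[1])
  expect_false(rc$interior[11])
  # constant curve -> zero rate
  cst <- structure(list(plant_id = "p", region = "r", t_h = 0:5,
                        R = rep(0.4, 6)), class = "relative_tac")
  expect_equal(rate_of_change(cst)$dRdt, rep(0, 6))
  # worked example: R = [0, 0.1, 0.4] on t = [0, 1, 2]
  ex <- structure(list(plant_id = "p", region = "r", t_h = 0:2,
                       R = c(0, 0.1, 0.4)), class = "relative_tac")
  expect_equal(rate_of_change(ex)$dRdt[2], 0.2)
  # guard rails
  expect_error(rate_of_change(list(t_h = 0:1, R = c(0, 1))), "3 frames")
  expect_error(rate_of_change(list(t_h = c(0, 1, 3), R = c(0, 1, 2))),
               "non-uniform")
})

test_that("region rates of one plant sum to zero at interior frames", {
  light <- light_schedule(12, 8, 0)
  frames <- frame_schedule(0:47, 1)
  an <- analytic_ratios(kinetic_params(k_base = 0.02, a_diurnal = 0.4),
                        frames, light)
  r_root <- rate_of_change(an$root)
  r_leaf <- rate_of_change(an$leaf)
  s <- r_root$dRdt + r_leaf$dRdt
  expect_lt(max(abs(s[r_root$interior])), 1e-14)
})

test_that("uptake-rate estimator recovers a constant rate from noiseless curves", {
  light <- light_schedule(12, 8, 0)
  frames <- frame_schedule(0:71, 1)
  an <- analytic_ratios(kinetic_params(k_base = 0.01), frames, light)
  est <- estimate_uptake_rate(rate_of_change(an$leaf), an$root)
  k_hat <- stats::median(est$k_hat[est$used])
  expect_lt(abs(k_hat - 0.01) / 0.01, 0.01)
  # constant leaf ratio -> zero estimated rate
  flat <- structure(list(plant_id = "p", region = "leaf", t_h = an$leaf$t_h,
                         R = rep(0.2, 72)), class = "relative_tac")
  est0 <- estimate_uptake_rate(rate_of_change(flat), an$root)
  expect_true(all(est0$k_hat[est0$used] == 0))
  # frames with a depleted root pool are flagged out
  tiny_root <- an$root; tiny_root$R <- rep(0.01, 72)
  expect_error(estimate_uptake_rate(rate_of_change(an$leaf), tiny_root),
               "no evaluable")
})

test_that("light/dark uptake-rate ratio matches (1+a)/(1-a) on noiseless data", {
  light <- light_schedule(12, 8, 0)
  frames <- frame_schedule(0:71, 1)
  a <- 0.4
  an <- analytic_ratios(kinetic_params(k_base = 0.01, a_diurnal = a),
                        frames, light)
  est <- estimate_uptake_rate(rate_of_change(an$leaf), an$root)
  mask <- light_mask(frames, light)
  ok <- est$used
  # drop transition frames whose central difference straddles the boundary
  core <- ok & c(FALSE, mask[-length(mask)]) == mask & c(mask[-1], FALSE) == mask
  ratio <- mean(est$k_hat[core & mask]) / mean(est$k_hat[core & !mask])
  expect_lt(abs(ratio - (1 + a) / (1 - a)) / ((1 + a) / (1 - a)), 0.10)
})

test_that("noiseless phantom ratios are monotone and total TAC is constant", {
  spec <- small_spec(sensitivity = Inf)
  ds <- generate_dataset(spec)
  rois <- phantom_rois(spec)
  for (nm in c("high_noBa", "low_Ba")) {
    mine <- Filter(function(r) r$plant_id == nm, rois$plant)
    tacs <- lapply(mine, function(r) decay_correct(extract_tac(ds$pet_corrected, r)))
    total <- Reduce(`+`, lapply(tacs, `[[`, "A_MBq"))
    expect_lt(max(abs(total / mean(total) - 1)), 1e-10)
    rel <- normalize_tacs(tacs)
    names(rel) <- vapply(rel, `[[`, character(1), "region")
    expect_true(all(diff(rel$root$R) <= 1e-12))
    expect_true(all(diff(rel$leaf$R) >= -1e-12))
    expect_equal(rel$root$R + rel$leaf$R, rep(1, 72), tolerance = 1e-12)
  }
})
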