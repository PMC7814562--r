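test_that("scene voxelization produces a disjoint labelled partition", {
  spec <- small_spec(sensitivity = Inf)
  lv <- build_geometry(spec)
  # 4 groupings x 3 regions + reference + background
  expect_equal(nrow(lv$legend), 14L)
  expect_setequal(unique(lv$legend$region),
                  c("root", "stem", "leaf", "reference", "background"))
  # every code in the array is in the legend (constructor enforces), and
  # the array is single-valued per voxel by construction
  expect_true(all(as.vector(lv$labels) %in% lv$legend$code))
  # all 13 non-background regions are non-empty
  counts <- table(factor(as.vector(lv$labels), levels = lv$legend$code))
  expect_true(all(counts[as.character(setdiff(lv$legend$code, 0L))] > 0))
})

test_that("cylinder voxel volume approximates pi r^2 h for r >= 5 voxels", {
  spec <- default_phantom_spec()  # 64 x 64 x 48, beaker radius ~9 mm (>5 vox)
  lv <- build_geometry(spec)
  g <- spec$geometry
  code <- lv$legend$code[lv$legend$plant_id == "high_noBa" &
                           lv$legend$region == "root"]
  n <- sum(lv$labels == code)
  voxvol <- prod(spec$grid$spacing)
  # z band [0, beaker_top) resolves to whole slices; use the realised height
  nz <- length(unique(which(lv$labels == code, arr.ind = TRUE)[, 3]))
  analytic <- pi * g$beaker_radius_mm^2 * nz * spec$grid$spacing[3]
  expect_lt(abs(n * voxvol - analytic) / analytic, 0.05)
})

test_that("geometry errors on overlap or out-of-grid placement", {
  spec <- small_spec()
  spec$geometry$centers_x_mm <- rep(10, 4)  # all four on top of each other
  expect_error(build_geometry(spec), "overlapping")
  spec2 <- small_spec()
  spec2$geometry$leaf_top_mm <- 1e4
  expect_error(build_geometry(spec2), "exceeds")
})

test_that("rendered frames conserve decayed totals, scale linearly, zero empty", {
  spec <- small_spec(sensitivity = Inf)
  lv <- build_geometry(spec)
  series <- lapply(spec$groupings, simulate_kinetics,
                   frames = spec$frames, light = spec$light)
  img <- render_frames(lv, series, spec)
  dec <- decay_factor(frame_midpoints(spec$frames))
  expected <- (sum(vapply(series, `[[`, numeric(1), "A_total")) +
                 spec$reference_activity_MBq) * dec
  expect_equal(frame_totals(img), expected, tolerance = 1e-12)

  # stem compartments carry zero activity with stem_fraction = 0
  stem_codes <- lv$legend$code[lv$legend$region == "stem"]
  stem_mask <- lv$labels %in% stem_codes
  expect_true(all(img$values[array(stem_mask, dim(img$values)[1:3])] == 0))

  # doubling every administered dose doubles every voxel value
  spec2 <- spec
  for (nm in names(spec2$groupings))
    spec2$groupings[[nm]]$A_total <- 2 * spec2$groupings[[nm]]$A_total
  series2 <- lapply(spec2$groupings, simulate_kinetics,
                    frames = spec2$frames, light = spec2$light)
  img2 <- render_frames(lv, series2, spec2)
  # compare only plant voxels (reference activity was not doubled)
  plant_mask <- as.vector(lv$labels %in% setdiff(lv$legend$code, c(0L, 13L)))
  v1 <- matrix(img$values, ncol = dim(img$values)[4])[plant_mask, ]
  v2 <- matrix(img2$values, ncol = dim(img2$values)[4])[plant_mask, ]
  expect_equal(v2, 2 * v1, tolerance = 1e-14)
})

test_that("attenuation map matches hand-computed factors on a 5x1x1 line", {
  # attenuating material in voxels 2..4 (zero-based 1..3); spacing 2 mm
  grid <- voxel_grid(c(5, 1, 1), c(2, 1, 1))
  labels <- array(0L, c(5, 1, 1)); labels[2:4, 1, 1] <- 1L
  legend <- data.frame(code = c(0L, 1L), plant_id = c("background", "p"),
                       region = c("background", "root"))
  lv <- label_volume(labels, grid, legend)
  mu <- 0.05
  m <- build_attenuation_map(lv, mu)
  # voxel 1 (empty, at edge): nothing between it and the -x face
  expect_equal(m$factor[1, 1, 1], 1)
  # voxel 2 (attenuating): half its own width each way; left is shorter: 1 mm
  expect_equal(m$factor[2, 1, 1], exp(-mu * 1))
  # voxel 3 (center): half self + one full neighbour = 3 mm either way
  expect_equal(m$factor[3, 1, 1], exp(-mu * 3))
  # voxel 5 (empty edge): factor 1
  expect_equal(m$factor[5, 1, 1], 1)
  # mu = 0: all factors 1
  expect_true(all(build_attenuation_map(lv, 0)$factor == 1))
})

test_that("attenuate and correct are inverse; uniform factor scales totals", {
  spec <- small_spec(sensitivity = Inf)
  ds <- generate_dataset(spec)
  img <- ds$pet_corrected
  attn <- ds$attenuation
  expect_true(all(attn$factor > 0 & attn$factor <= 1))
  back <- correct_attenuation(apply_attenuation(img, attn), attn)
  expect_equal(back$values, img$values, tolerance = 1e-14)
  # identity map is the identity
  id <- attn; id$factor[] <- 1
  expect_identical(apply_attenuation(img, id)$values, img$values)
  # uniform factor 0.5 halves every frame total
  half <- attn; half$factor[] <- 0.5
  expect_equal(frame_totals(apply_attenuation(img, half)), frame_totals(img) / 2)
})

test_that("counting noise is seed-deterministic, unbiased, and fixes zero", {
  grid <- voxel_grid(c(2, 2, 2), c(1, 1, 1))
  fs <- frame_schedule(0, 1)
  img <- dynamic_image(array(c(1, 0, 2, 0.5, 1, 0, 2, 0.5), c(2, 2, 2, 1)),
                       grid, fs)
  a <- add_counting_noise(img, 100, fs, seed = 9)
  b <- add_counting_noise(img, 100, fs, seed = 9)
  expect_identical(a$values, b$values)
  d <- add_counting_noise(img, 100, fs, seed = 10)
  expect_false(identical(a$values, d$values))
  # zero activity stays exactly zero
  expect_true(all(a$values[img$values == 0] == 0))

  # Monte-Carlo unbiasedness: voxel with v = 1, sensitivity*duration = 100
  means <- vapply(1:200, function(s)
    add_counting_noise(img, 100, fs, seed = s)$values[1, 1, 1, 1], numeric(1))
  expect_lt(abs(mean(means) - 1), 3 / sqrt(200 * 100))

  # infinite sensitivity = noiseless passthrough
  expect_identical(add_counting_noise(img, Inf, fs, seed = 1)$values, img$values)
})

test_that("counting noise leaves the caller's RNG state untouched", {
  grid <- voxel_grid(c(2, 2, 2), c(1, 1, 1))
  fs <- frame_schedule(0, 1)
  img <- dynamic_image(array(1, c(2, 2, 2, 1)), grid, fs)
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(add_counting_noise(img, 100, fs, seed = 77))
  expect_identical(stats::runif(1), before)
})

test_that("noiseless end-to-end dataset matches the kinetics ground truth", {
  spec <- small_spec(sensitivity = Inf, a_diurnal = 0)
  ds <- generate_dataset(spec)
  rois <- phantom_rois(spec)
  dec <- decay_factor(frame_midpoints(spec$frames))
  for (nm in names(spec$groupings)) {
    leaf_roi <- Filter(function(r) r$plant_id == nm && r$region == "leaf",
                       rois$plant)[[1]]
    leaf_tac <- extract_tac(ds$pet_corrected, leaf_roi)
    truth <- ds$truth[[nm]]$A_leaf * dec
    expect_lt(max(abs(leaf_tac$A_MBq - truth)) / max(truth), 1e-10)
  }
})

test_that("changing the seed alters noisy voxels but not the truth series", {
  s1 <- small_spec(seed = 1)
  s2 <- small_spec(seed = 2)
  d1 <- generate_dataset(s1)
  d2 <- generate_dataset(s2)
  expect_false(identical(d1$pet_uncorrected$values, d2$pet_uncorrected$values))
  expect_identical(d1$truth$low_noBa$A_leaf, d2$truth$low_noBa$A_leaf)
  # same seed reproduces the noisy data exactly
  expect_identical(generate_dataset(s1)$pet_uncorrected$values,
                   d1$pet_uncorrected$values)
})

test_that("phantom specs load from JSON and YAML files", {
  cfg <- list(dims = c(16, 16, 16), n_frames = 12, k_base = 0.02,
              light = list(period_light = 10, period_dark = 6, t0 = 1),
              sensitivity = 500)
  pj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, pj, auto_unbox = TRUE)
  sp <- read_phantom_spec(pj)
  expect_identical(sp$grid$dims, c(16L, 16L, 16L))
  expect_equal(sp$groupings$high_noBa$k_base, 0.02)
  expect_equal(sp$light$period_dark, 6)
  skip_if_not_installed("yaml")
  py <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, py)
  sp2 <- read_phantom_spec(py)
  expect_equal(sp2$sensitivity, 500)
})
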