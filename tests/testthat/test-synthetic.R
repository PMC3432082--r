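test_that("confinement mask placement: full-frame, counted regions, empty", {
  full <- generate_confinement_mask(c(64, 64), n_regions = 1,
                                    region_width_px = 64)
  expect_true(all(full))

  m <- generate_confinement_mask(c(128, 128), n_regions = 4,
                                 region_width_px = 12, seed = 1)
  expect_length(oracle_components(m, 8), 4)
  expect_length(oracle_components(m, 4), 4)

  empty <- generate_confinement_mask(c(16, 16), n_regions = 0)
  expect_false(any(empty))

  # impossible packing errors out naming the failing region
  expect_error(
    generate_confinement_mask(c(32, 32), n_regions = 10,
                              region_width_px = 10, seed = 1),
    "cannot place confinement region")
})

test_that("confinement mask is deterministic in the seed", {
  a <- generate_confinement_mask(c(96, 96), 3, 10, seed = 42)
  b <- generate_confinement_mask(c(96, 96), 3, 10, seed = 42)
  c <- generate_confinement_mask(c(96, 96), 3, 10, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("coloc scene honors the colocalized-fraction rounding rule", {
  for (frac in c(0, 0.25, 0.5, 1)) {
    spec <- coloc_scene_spec(shape = c(1, 96, 96), n_puncta_ch1 = 18,
                             n_puncta_ch2 = 20, coloc_fraction = frac,
                             confinement_params = list(n_regions = 2,
                                                       region_width_px = 30),
                             seed = 5)
    sc <- generate_coloc_scene(spec)
    expect_identical(sum(sc$truth$ch1_coloc), as.integer(round(frac * 18)))
    expect_identical(nrow(sc$truth$ch1_centers), 18L)
    expect_identical(nrow(sc$truth$ch2_centers), 20L)
  }
})

test_that("coloc scene center-set identities at the fraction extremes", {
  key <- function(m) paste(m[, 1], m[, 2])
  sc1 <- generate_coloc_scene(coloc_scene_spec(
    shape = c(1, 96, 96), n_puncta_ch1 = 15, n_puncta_ch2 = 15,
    coloc_fraction = 1, jitter_px = 0,
    confinement_params = list(n_regions = 2, region_width_px = 30),
    seed = 2))
  expect_true(all(key(sc1$truth$ch1_centers) %in% key(sc1$truth$ch2_centers)))

  sc0 <- generate_coloc_scene(coloc_scene_spec(
    shape = c(1, 96, 96), n_puncta_ch1 = 15, n_puncta_ch2 = 15,
    coloc_fraction = 0,
    confinement_params = list(n_regions = 2, region_width_px = 30),
    seed = 2))
  expect_length(intersect(key(sc0$truth$ch1_centers),
                          key(sc0$truth$ch2_centers)), 0)
})

test_that("noise-free scene equals the analytic spot model", {
  spec <- coloc_scene_spec(shape = c(3, 48, 48), n_puncta_ch1 = 4,
                           n_puncta_ch2 = 4, coloc_fraction = 0.5,
                           spot_sigma_px = 1.5, background_level = 7,
                           poisson_noise = FALSE, read_noise_sd = 0,
                           confinement = matrix(TRUE, 48, 48), seed = 9)
  sc <- generate_coloc_scene(spec)
  # independent render: direct evaluation of the documented model
  # (Gaussian spots on a 4-sigma patch, shared z-envelope, background)
  env <- exp(-((1:3 - 2)^2) / (2 * max(1, 3 / 4)^2))
  rad <- ceiling(4 * 1.5)
  expected <- array(0, c(3, 48, 48))
  base <- matrix(0, 48, 48)
  ctr <- sc$truth$ch1_centers
  for (k in seq_len(nrow(ctr))) {
    for (i in seq_len(48)) for (j in seq_len(48)) {
      if (abs(i - ctr[k, 1]) <= rad && abs(j - ctr[k, 2]) <= rad &&
          i >= floor(ctr[k, 1] - rad) && i <= ceiling(ctr[k, 1] + rad) &&
          j >= floor(ctr[k, 2] - rad) && j <= ceiling(ctr[k, 2] + rad)) {
        d2 <- (i - ctr[k, 1])^2 + (j - ctr[k, 2])^2
        base[i, j] <- base[i, j] +
          sc$truth$amp_ch1[k] * exp(-d2 / (2 * 1.5^2))
      }
    }
  }
  for (z in 1:3) expected[z, , ] <- 7 + env[z] * base
  expect_equal(sc$ch1$data, expected, tolerance = 1e-12)
})

test_that("scene generation is bit-reproducible from the seed", {
  spec <- coloc_scene_spec(shape = c(2, 64, 64), seed = 31,
                           n_puncta_ch1 = 10, n_puncta_ch2 = 10,
                           confinement_params = list(n_regions = 1,
                                                     region_width_px = 40))
  a <- generate_coloc_scene(spec)
  b <- generate_coloc_scene(spec)
  expect_identical(a$ch1$data, b$ch1$data)
  expect_identical(a$ch2$data, b$ch2$data)
  expect_identical(a$truth, b$truth)
})

test_that("scene capacity errors are raised", {
  tiny <- matrix(FALSE, 32, 32); tiny[1:3, 1:3] <- TRUE
  expect_error(generate_coloc_scene(coloc_scene_spec(
    shape = c(1, 32, 32), n_puncta_ch1 = 20, n_puncta_ch2 = 20,
    confinement = tiny, seed = 1)), "capacity")
})

test_that("bouton field ground truth: count, areas in window, separation", {
  spec <- bouton_field_spec(shape = c(1, 384, 384), n_boutons = 30,
                            poisson_noise = FALSE, seed = 4)
  fld <- generate_bouton_field(spec)
  expect_identical(nrow(fld$truth), 30L)
  expect_true(all(fld$truth$area_um2 >= 0.5 & fld$truth$area_um2 <= 1.1))
  d <- as.matrix(dist(fld$truth[, c("y", "x")]))
  diag(d) <- Inf
  r_max <- sqrt((1.1 / pixel_area_um2(spec$cal)) / pi) + spec$rim_width_px
  expect_true(min(d) >= 2 * r_max + spec$min_separation_px - 1e-9)

  empty <- generate_bouton_field(bouton_field_spec(
    shape = c(1, 64, 64), n_boutons = 0, poisson_noise = FALSE, seed = 1))
  expect_equal(empty$stack$data[1, , ],
               matrix(20, 64, 64), tolerance = 1e-12)
  expect_identical(nrow(empty$truth), 0L)

  expect_error(generate_bouton_field(bouton_field_spec(
    shape = c(1, 64, 64), n_boutons = 50, seed = 1)), "capacity")
})

test_that("noise-free bouton areas equal half-amplitude thresholding", {
  spec <- bouton_field_spec(shape = c(1, 256, 256), n_boutons = 8,
                            poisson_noise = FALSE, seed = 12)
  fld <- generate_bouton_field(spec)
  img <- fld$stack$data[1, , ] - spec$background_level
  # objects are isolated: threshold the whole clean image at each object's
  # half amplitude and count pixels near its center
  px_area <- pixel_area_um2(spec$cal)
  for (k in seq_len(nrow(fld$truth))) {
    above <- which(img > fld$truth$amplitude[k] / 2, arr.ind = TRUE)
    near <- sqrt((above[, 1] - fld$truth$y[k])^2 +
                 (above[, 2] - fld$truth$x[k])^2) < 15
    expect_equal(sum(near) * px_area, fld$truth$area_um2[k],
                 tolerance = 1e-12)
  }
})

test_that("ground-truth consistency holds across many random specs", {
  set.seed(99)
  for (i in 1:100) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    frac <- runif(1)
    if (round(frac * n1) > n2) frac <- 0
    sc <- generate_coloc_scene(coloc_scene_spec(
      shape = c(1, 64, 64), n_puncta_ch1 = n1, n_puncta_ch2 = n2,
      coloc_fraction = frac,
      confinement_params = list(n_regions = 1, region_width_px = 48),
      poisson_noise = FALSE, read_noise_sd = 0,
      seed = sample.int(1e6, 1)))
    expect_identical(sum(sc$truth$ch1_coloc), as.integer(round(frac * n1)))
    expect_identical(nrow(sc$truth$ch1_centers), as.integer(n1))
    conf <- sc$confinement
    on_conf <- conf[cbind(round(sc$truth$ch1_centers[, 1]),
                          round(sc$truth$ch1_centers[, 2]))]
    expect_true(all(on_conf))
  }
})

test_that("time-series generator closed forms", {
  flat <- generate_timeseries(timeseries_spec(
    n_rois = 1, step_amplitude = 0, bleach_rate_per_s = 0, noise_sd = 0))
  expect_equal(flat$traces[[1]]$F, rep(100, 120), tolerance = 1e-12)

  dec <- generate_timeseries(timeseries_spec(
    n_rois = 1, decay_tau_s = 20, event_time_s = 30, noise_sd = 0))
  tr <- dec$traces[[1]]
  f30 <- tr$F[tr$t_s == 30]; f50 <- tr$F[tr$t_s == 50]
  expect_equal(f50 / f30, exp(-1), tolerance = 1e-12)

  stp <- generate_timeseries(timeseries_spec(
    n_rois = 1, step_amplitude = 0.68, noise_sd = 0))
  tr <- stp$traces[[1]]
  expect_equal(mean(tr$F[tr$t_s >= 30]) / mean(tr$F[tr$t_s < 30]), 1.68,
               tolerance = 1e-12)

  expect_error(timeseries_spec(event_time_s = 500), "window")
  a <- generate_timeseries(timeseries_spec(noise_sd = 0.1, seed = 8))
  b <- generate_timeseries(timeseries_spec(noise_sd = 0.1, seed = 8))
  expect_identical(a$traces[[1]]$F, b$traces[[1]]$F)
})
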