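test_that("Manders M1 identities and the 3x3 toy case", {
  conf <- matrix(TRUE, 3, 3)
  m <- matrix(FALSE, 3, 3); m[1:2, 1:2] <- TRUE
  int1 <- matrix(1, 3, 3)
  expect_equal(manders_m1(coloc_input(int1, m, m, conf)), 1)

  m2 <- matrix(FALSE, 3, 3); m2[3, 3] <- TRUE
  expect_equal(manders_m1(coloc_input(int1, m, m2, conf)), 0)

  # ch1 carries 4 units on the overlap pixel and 6 on a non-overlap pixel
  int1 <- matrix(0, 3, 3); int1[1, 1] <- 4; int1[2, 2] <- 6
  m1m <- int1 > 0
  m2m <- matrix(FALSE, 3, 3); m2m[1, 1] <- TRUE
  expect_equal(manders_m1(coloc_input(int1, m1m, m2m, conf)), 0.4)
  # binary mode ignores the weights
  expect_equal(manders_m1(coloc_input(int1, m1m, m2m, conf),
                          weighted = FALSE), 0.5)

  expect_error(manders_m1(coloc_input(int1, matrix(FALSE, 3, 3), m2m, conf)),
               "undefined|no channel-1")
})

test_that("M1 stays in [0, 1] over many random instances", {
  set.seed(41)
  for (i in 1:200) {
    conf <- matrix(runif(100) < 0.9, 10, 10)
    m1 <- conf & matrix(runif(100) < 0.4, 10, 10)
    m2 <- conf & matrix(runif(100) < 0.4, 10, 10)
    if (!any(m1)) next
    v <- manders_m1(coloc_input(matrix(runif(100, 0.1, 5), 10, 10),
                                m1, m2, conf))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("coloc input validates mask confinement", {
  conf <- matrix(FALSE, 4, 4); conf[1:2, 1:2] <- TRUE
  m <- matrix(TRUE, 4, 4)
  expect_error(coloc_input(matrix(1, 4, 4), m, m, conf), "confinement")
  inp <- coloc_input(matrix(1, 4, 4), m, m, conf, intersect = TRUE)
  expect_identical(inp$ch1_mask, conf)
})

test_that("displacement enumeration matches the integer-pair oracle", {
  conf <- matrix(TRUE, 21, 21)
  m <- matrix(FALSE, 21, 21); m[9:13, 9:13] <- TRUE
  d1 <- enumerate_confined_displacements(m, conf, max_radius = 1,
                                         min_retained_fraction = 0)
  expect_identical(nrow(d1), 4L)   # (+-1,0),(0,+-1); sqrt(2) excluded
  expect_identical(d1$dy, c(-1L, 0L, 0L, 1L))
  expect_identical(d1$dx, c(0L, -1L, 1L, 0L))

  d2 <- enumerate_confined_displacements(m, conf, max_radius = 2,
                                         min_retained_fraction = 0)
  expect_identical(nrow(d2), 12L)

  # oracle count for a larger radius
  r <- 5
  cnt <- 0
  for (dy in -r:r) for (dx in -r:r) {
    if (dy^2 + dx^2 > 0 && dy^2 + dx^2 <= r^2) cnt <- cnt + 1
  }
  d5 <- enumerate_confined_displacements(m, conf, max_radius = r,
                                         min_retained_fraction = 0)
  expect_identical(nrow(d5), as.integer(cnt))

  # retention filtering against explicit shifting
  conf2 <- matrix(FALSE, 21, 21); conf2[5:17, 5:17] <- TRUE
  m2 <- conf2
  d <- enumerate_confined_displacements(m2, conf2, max_radius = 3,
                                        min_retained_fraction = 0.9)
  for (i in seq_len(nrow(d))) {
    shifted <- oracle_shift(m2 * 1, d$dy[i], d$dx[i])
    expect_equal(d$retention[i], sum(shifted * conf2) / sum(m2),
                 tolerance = 1e-12)
    expect_gte(d$retention[i], 0.9)
  }

  # mask equal to confinement at full retention: every shift loses pixels
  expect_error(
    enumerate_confined_displacements(conf2, conf2, max_radius = 3,
                                     min_retained_fraction = 1),
    "no valid displacement")
})

test_that("CDA is shift-invariant on a uniform full-overlap scene", {
  conf <- matrix(TRUE, 12, 12)
  inp <- coloc_input(matrix(3, 12, 12), conf, conf, conf)
  res <- cda_effective_colocalization(inp, max_radius = 2,
                                      min_retained_fraction = 0.5)
  expect_equal(res$m1_d0, 1)
  expect_true(all(res$null_values == 1))
  expect_equal(res$m1_effective, 0)
  expect_equal(res$percent_effective, 0)
})

test_that("CDA equals brute-force enumeration on small instances", {
  for (s in 1:25) {
    inst <- random_cda_instance(s)
    res <- cda_effective_colocalization(
      coloc_input(inst$int1, inst$m1, inst$m2, inst$conf),
      max_radius = inst$max_radius, min_retained_fraction = 0.5)
    orc <- oracle_cda(inst$int1, inst$m1, inst$m2, inst$conf,
                      inst$max_radius, 0.5)
    expect_equal(res$m1_d0, orc$m1_d0, tolerance = 1e-12)
    expect_identical(res$n_displacements, length(orc$null_values))
    expect_equal(sort(res$null_values), sort(orc$null_values),
                 tolerance = 1e-12)
    expect_equal(res$m1_random, orc$m1_random, tolerance = 1e-12)
    expect_equal(res$m1_effective, orc$m1_effective, tolerance = 1e-12)
    # result invariants
    expect_identical(res$m1_effective, res$m1_d0 - res$m1_random)
    expect_identical(res$percent_effective, 100 * res$m1_effective)
    expect_gt(res$p_null, 0); expect_lte(res$p_null, 1)
    expect_true(all(res$null_values >= 0 & res$null_values <= 1))
  }
})

test_that("null exchangeability: the inverse displacement recovers M1(d=0)", {
  set.seed(61)
  conf <- matrix(TRUE, 24, 24)
  m1 <- matrix(FALSE, 24, 24); m1[9:15, 9:15] <- runif(49) < 0.6
  m2 <- matrix(FALSE, 24, 24); m2[8:16, 8:16] <- runif(81) < 0.4
  int1 <- matrix(runif(576, 1, 5), 24, 24)
  base <- cda_effective_colocalization(coloc_input(int1, m1, m2, conf),
                                       max_radius = 3,
                                       min_retained_fraction = 0.5)
  dy <- 2L; dx <- 1L
  m1s <- oracle_shift(m1 * 1, dy, dx) > 0
  ints <- oracle_shift(int1 * m1, dy, dx)
  shifted <- cda_effective_colocalization(coloc_input(ints, m1s, m2, conf),
                                          max_radius = 3,
                                          min_retained_fraction = 0.5)
  inv <- which(shifted$displacements$dy == -dy &
               shifted$displacements$dx == -dx)
  expect_equal(shifted$null_values[inv], base$m1_d0, tolerance = 1e-12)
})

test_that("effective colocalization recovers the coloc fraction ordering", {
  mean_pct <- vapply(c(0, 0.5, 1), function(frac) {
    vals <- vapply(1:6, function(s) {
      sc <- generate_coloc_scene(coloc_scene_spec(
        shape = c(1, 160, 160), n_puncta_ch1 = 25, n_puncta_ch2 = 25,
        coloc_fraction = frac,
        confinement_params = list(n_regions = 2, region_width_px = 50),
        seed = 100 + s))
      inp <- segment_coloc_channels(sc$ch1, sc$ch2, sc$confinement)
      cda_effective_colocalization(inp, max_radius = 8)$percent_effective
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_pct) > 0))
  expect_lt(abs(mean_pct[1]), 6)
  expect_gt(mean_pct[3], 30)
})

test_that("coloc_report summarizes groups with SEM conventions", {
  r <- function(p) structure(list(percent_effective = p),
                             class = "cda_result")
  one <- coloc_report(list(r(31)), "tr")
  expect_equal(one$mean_percent, 31)
  expect_equal(one$sem_percent, 0)
  expect_true(one$single_observation)

  two <- coloc_report(list(r(25), r(25)), c("a", "a"))
  expect_equal(two$sem_percent, 0)
  expect_false(two$single_observation)

  set.seed(13)
  vals <- rnorm(12, 30, 5)
  g <- rep(c("x", "y", "z"), each = 4)
  rep_tab <- coloc_report(lapply(vals, r), g)
  for (lv in c("x", "y", "z")) {
    v <- vals[g == lv]
    row <- rep_tab[rep_tab$group == lv, ]
    expect_equal(row$mean_percent, mean(v), tolerance = 1e-12)
    expect_equal(row$sem_percent, sd(v) / 2, tolerance = 1e-12)
  }
})
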