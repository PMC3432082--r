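make_stack <- function(arr, px = 0.1) {
  image_stack(arr, calibration(pixel_size_um = px))
}

test_that("z-projection reductions match per-pixel oracles", {
  const <- make_stack(array(3.5, c(4, 6, 5)))
  expect_equal(z_project(const, method = "max")$pixels,
               matrix(3.5, 6, 5))
  expect_equal(z_project(const, method = "mean")$pixels,
               matrix(3.5, 6, 5))

  a <- array(0, c(3, 8, 8)); a[2, 5, 6] <- 9
  expect_equal(z_project(make_stack(a), method = "max")$pixels[5, 6], 9)

  set.seed(1)
  r <- array(runif(5 * 7 * 6), c(5, 7, 6))
  st <- make_stack(r)
  mean_oracle <- matrix(0, 7, 6)
  sum_oracle <- matrix(0, 7, 6)
  max_oracle <- matrix(-Inf, 7, 6)
  for (i in 1:7) for (j in 1:6) {
    mean_oracle[i, j] <- mean(r[, i, j])
    sum_oracle[i, j] <- sum(r[, i, j])
    max_oracle[i, j] <- max(r[, i, j])
  }
  expect_equal(z_project(st, method = "mean")$pixels, mean_oracle,
               tolerance = 1e-12)
  expect_equal(z_project(st, method = "sum")$pixels, sum_oracle,
               tolerance = 1e-12)
  expect_equal(z_project(st, method = "max")$pixels, max_oracle)

  # window selection and bounds
  expect_equal(z_project(st, z_start = 2, n_slices = 2,
                         method = "mean")$pixels[1, 1],
               mean(r[2:3, 1, 1]), tolerance = 1e-12)
  expect_error(z_project(st, z_start = 4, n_slices = 3), "outside")
})

test_that("max projection dominates mean projection pointwise", {
  set.seed(7)
  st <- make_stack(array(rexp(4 * 10 * 10), c(4, 10, 10)))
  expect_true(all(z_project(st, method = "max")$pixels >=
                  z_project(st, method = "mean")$pixels))
})

test_that("gradient magnitude matches the direct convolution oracle", {
  expect_equal(gradient_magnitude(matrix(5, 6, 6)), matrix(0, 6, 6))

  # vertical step edge: maximal response on the edge columns, zero far away
  step <- cbind(matrix(0, 8, 4), matrix(2, 8, 4))
  g <- gradient_magnitude(step)
  expect_true(all(g[, 4] > 0) && all(g[, 5] > 0))
  expect_equal(g[, c(1, 2, 7, 8)], matrix(0, 8, 4))

  set.seed(3)
  m <- matrix(runif(64, 0, 10), 8, 8)
  expect_equal(gradient_magnitude(m), oracle_sobel_magnitude(m),
               tolerance = 1e-10)
})

test_that("otsu threshold equals the exhaustive between-class maximizer", {
  expect_error(otsu_threshold(matrix(1, 4, 4)), "degenerate")

  two <- matrix(c(rep(10, 40), rep(100, 12)), 4, 13)
  mask <- binarize(two, "otsu")
  expect_identical(as.vector(mask), as.vector(two == 100))

  set.seed(11)
  for (i in 1:5) {
    v <- c(rnorm(300, 10, 2), rnorm(80, 30, 4))
    expect_equal(otsu_threshold(v), oracle_otsu(v), tolerance = 1e-12)
  }
})

test_that("manual binarization records its threshold", {
  m <- matrix(runif(16, 1, 2), 4, 4)
  b <- binarize(m, "manual", manual_threshold = 0)
  expect_true(all(b))
  expect_identical(attr(b, "threshold"), 0)
  expect_identical(attr(b, "method"), "manual")
  expect_error(binarize(m, "manual"), "manual_threshold")
})

test_that("connected-component labeling matches flood fill and EBImage", {
  empty <- label_components(matrix(FALSE, 5, 5))
  expect_identical(n_labels(empty), 0L)

  diagpair <- matrix(FALSE, 4, 4)
  diagpair[2, 2] <- diagpair[3, 3] <- TRUE
  expect_identical(n_labels(label_components(diagpair, 4)), 2L)
  expect_identical(n_labels(label_components(diagpair, 8)), 1L)

  set.seed(21)
  for (i in 1:10) {
    mask <- matrix(runif(30 * 30) < 0.35, 30, 30)
    for (conn in c(4L, 8L)) {
      lm <- label_components(mask, conn)
      comps <- oracle_components(mask, conn)
      expect_identical(n_labels(lm), length(comps))
      # identical partition of pixels into components
      got <- lapply(seq_len(n_labels(lm)),
                    function(k) sort(which(lm$labels == k)))
      expect_setequal(vapply(got, paste, "", collapse = ","),
                      vapply(comps, paste, "", collapse = ","))
    }
    # cross-check against an independent implementation (bwlabel is
    # 4-connectivity)
    expect_identical(n_labels(label_components(mask, 4L)),
                     as.integer(max(EBImage::bwlabel(mask * 1))))
  }
})

test_that("labels are assigned in raster order of first pixels", {
  mask <- matrix(FALSE, 6, 6)
  mask[5, 1] <- TRUE                       # later row, first column
  mask[1, 4] <- TRUE                       # first row
  mask[3, 2] <- TRUE
  lm <- label_components(mask, 8)
  expect_identical(lm$labels[1, 4], 1L)
  expect_identical(lm$labels[3, 2], 2L)
  expect_identical(lm$labels[5, 1], 3L)
})

test_that("size filter keeps the inclusive window and compacts labels", {
  # three objects of 40, 80 and 150 px at 0.1 um/px: 0.40 / 0.80 / 1.50 um2
  lab <- matrix(0L, 40, 40)
  lab[1:4, 1:10] <- 1L       # 40 px
  lab[10:17, 1:10] <- 2L     # 80 px
  lab[25:34, 1:15] <- 3L     # 150 px
  lm <- label_map(lab, calibration(pixel_size_um = 0.1))
  f <- size_filter(lm, 0.5, 1.1)
  expect_identical(n_labels(f), 1L)
  expect_identical(sort(unique(as.vector(f$labels))), c(0L, 1L))
  expect_identical(which(f$labels == 1L), which(lab == 2L))

  empty <- size_filter(label_map(matrix(0L, 5, 5), calibration()), 0.5, 1.1)
  expect_identical(n_labels(empty), 0L)

  expect_error(size_filter(label_map(matrix(0L, 5, 5)), 0.5, 1.1),
               "calibrat")
})

test_that("size filter equals brute-force per-object area check and is monotone", {
  set.seed(5)
  px <- 0.12
  cal <- calibration(pixel_size_um = px)
  for (i in 1:10) {
    mask <- matrix(runif(50 * 50) < 0.3, 50, 50)
    lm <- label_components(mask, 8, cal)
    k <- n_labels(lm)
    areas <- vapply(seq_len(k), function(j) sum(lm$labels == j) * px^2,
                    numeric(1))
    lo <- runif(1, 0.01, 0.1); hi <- lo + runif(1, 0.05, 0.5)
    f <- size_filter(lm, lo, hi)
    expect_identical(n_labels(f), sum(areas >= lo & areas <= hi))
    # survivors are exactly the in-window objects
    surv_px <- sort(which(f$labels > 0))
    expected_px <- sort(which(matrix(lm$labels %in% which(areas >= lo & areas <= hi),
                                     50, 50)))
    expect_identical(surv_px, expected_px)
    # widening never decreases the count
    wide <- size_filter(lm, lo / 2, hi * 2)
    expect_gte(n_labels(wide), n_labels(f))
    # compaction: labels are exactly 1..K
    if (n_labels(f) > 0) {
      expect_identical(sort(unique(as.vector(f$labels[f$labels > 0]))),
                       seq_len(n_labels(f)))
    }
  }
})

test_that("bouton quantification matches per-label accumulation", {
  cal <- calibration(pixel_size_um = 0.1)
  lab <- matrix(0L, 10, 10); lab[2:3, 2:6] <- 1L   # 10 px
  img <- matrix(1, 10, 10)
  tab <- quantify_boutons(label_map(lab, cal), img)
  expect_equal(tab$area_um2, 0.1, tolerance = 1e-12)
  expect_equal(tab$centroid_y, 2.5, tolerance = 1e-12)  # uniform = geometric
  expect_equal(tab$centroid_x, 4, tolerance = 1e-12)

  set.seed(9)
  mask <- matrix(runif(30 * 30) < 0.25, 30, 30)
  lm <- label_components(mask, 8, cal)
  img <- matrix(runif(900, 1, 5), 30, 30)
  tab <- quantify_boutons(lm, img)
  expect_identical(attr(tab, "count"), n_labels(lm))
  for (k in seq_len(n_labels(lm))) {
    px <- which(lm$labels == k)
    yy <- (px - 1) %% 30 + 1; xx <- (px - 1) %/% 30 + 1
    w <- img[px]
    expect_equal(tab$area_um2[k], length(px) * 0.01, tolerance = 1e-12)
    expect_equal(tab$mean_intensity[k], mean(w), tolerance = 1e-12)
    expect_equal(tab$centroid_y[k], sum(w * yy) / sum(w), tolerance = 1e-12)
    expect_equal(tab$centroid_x[k], sum(w * xx) / sum(w), tolerance = 1e-12)
  }

  expect_error(quantify_boutons(lm, matrix(0, 5, 5)), "dimensions")
})

test_that("area histogram bins left-closed and conserves counts", {
  cal <- calibration(pixel_size_um = 0.1)
  empty <- quantify_boutons(label_map(matrix(0L, 5, 5), cal),
                            matrix(0, 5, 5))
  h0 <- area_histogram(empty, 0.1)
  expect_identical(sum(h0$counts), 0L)
  expect_identical(h0$edges[1], 0)

  tab <- data.frame(area_um2 = c(0.55, 0.56, 1.05))
  h <- area_histogram(tab, 0.1)
  expect_identical(h$counts[6], 2L)    # [0.5, 0.6)
  expect_identical(h$counts[11], 1L)   # [1.0, 1.1)
  expect_identical(sum(h$counts), 3L)

  set.seed(2)
  tab <- data.frame(area_um2 = runif(200, 0.05, 3))
  bw <- 0.17
  h <- area_histogram(tab, bw)
  oracle_counts <- as.vector(table(factor(floor(tab$area_um2 / bw),
                                          levels = 0:(length(h$counts) - 1))))
  expect_identical(h$counts, as.integer(oracle_counts))
  expect_identical(sum(h$counts), 200L)
})

test_that("end-to-end pipeline recovers exact counts on clean fields", {
  fld <- generate_bouton_field(bouton_field_spec(
    shape = c(6, 384, 384), n_boutons = 25, poisson_noise = FALSE, seed = 17))
  seg <- segment_boutons(fld$stack)
  expect_identical(seg$count, 25L)
  m <- match_boutons(seg$table, fld$truth, max_dist_px = 3)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  # measured half-amplitude areas agree with ground truth
  ord_meas <- seg$table$area_um2[order(seg$table$centroid_y)]
  ord_true <- fld$truth$area_um2[order(fld$truth$y)]
  expect_equal(ord_meas, ord_true, tolerance = 1e-9)
  # every decision is recorded for audit
  expect_true(is.numeric(seg$settings$threshold))
  expect_identical(seg$settings$threshold_method, "otsu")
})
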