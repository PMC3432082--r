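#' Z-projection of an image stack
#'
#' Reduces `n_slices` optical sections starting at `z_start` to a single
#' 2-D image. The default analysis projects 10 sections 0.3 um apart, the
#' acquisition geometry the pipeline's counting is calibrated for.
#'
#' @param stack An [image_stack()] with 3-D `(z, y, x)` data.
#' @param z_start First slice (1-based).
#' @param n_slices Number of slices; `NULL` means all remaining.
#' @param method One of `"max"`, `"mean"`, `"sum"`.
#' @return An [image2d()] carrying the stack's calibration.
#' @export
z_project <- function(stack, z_start = 1L, n_slices = NULL,
                      method = c("max", "mean", "sum")) {
  stopifnot(inherits(stack, "image_stack"), length(dim(stack$data)) == 3L)
  method <- match.arg(method)
  nz <- dim(stack$data)[1]
  if (is.null(n_slices)) n_slices <- nz - z_start + 1L
  if (z_start < 1L || n_slices < 1L || z_start + n_slices - 1L > nz) {
    stop(sprintf("z window [%d, %d] outside stack depth %d",
                 z_start, z_start + n_slices - 1L, nz), call. = FALSE)
  }
  slices <- lapply(seq.int(z_start, length.out = n_slices),
                   function(z) stack$data[z, , ])
  out <- switch(method,
                max  = Reduce(pmax, slices),
                mean = Reduce(`+`, slices) / n_slices,
                sum  = Reduce(`+`, slices))
  image2d(out, stack$calibration)
}

# 3x3 correlation with replicate-edge padding, via shifted submatrices.
conv3 <- function(m, k) {
  ny <- nrow(m); nx <- ncol(m)
  p <- matrix(0, ny + 2L, nx + 2L)
  p[2:(ny + 1L), 2:(nx + 1L)] <- m
  p[1, ] <- p[2, ]; p[ny + 2L, ] <- p[ny + 1L, ]
  p[, 1] <- p[, 2]; p[, nx + 2L] <- p[, nx + 1L]
  out <- matrix(0, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    kk <- k[dy + 2L, dx + 2L]
    if (kk != 0) {
      out <- out + kk * p[(2L + dy):(ny + 1L + dy), (2L + dx):(nx + 1L + dx)]
    }
  }
  out
}

#' Gradient magnitude (Sobel)
#'
#' Per-pixel magnitude of the 3x3 separable Sobel first-derivative
#' operator, with replicate-edge padding so a constant image (and image
#' borders) yield exactly zero response.
#'
#' @param img An [image2d()] or numeric matrix, at least 2x2.
#' @return Same type as the input, nonnegative everywhere.
#' @export
gradient_magnitude <- function(img) {
  m <- if (inherits(img, "image2d")) img$pixels else img
  stopifnot(is.matrix(m), nrow(m) >= 2L, ncol(m) >= 2L)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  g <- sqrt(conv3(m, kx)^2 + conv3(m, t(kx))^2)
  if (inherits(img, "image2d")) image2d(g, img$calibration) else g
}

#' Otsu threshold
#'
#' Exhaustive scan of the between-class-variance criterion over a
#' `levels`-bin histogram of the data range. Ties resolve to the lowest
#' threshold. The returned value is on the image's own intensity scale;
#' pixels strictly above it form the foreground.
#'
#' @param x Numeric vector or matrix.
#' @param levels Number of histogram bins (default 256).
#' @return The threshold value.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.vector(x)
  stopifnot(all(is.finite(v)), length(v) >= 2L)
  rng <- range(v)
  if (diff(rng) == 0) {
    stop("degenerate histogram: constant image has no Otsu threshold",
         call. = FALSE)
  }
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE)
  counts <- as.numeric(tabulate(bin, nbins = levels))
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(counts)[-levels]
  w1 <- length(v) - w0
  s0 <- cumsum(counts * mids)[-levels]
  mu0 <- s0 / w0
  mu1 <- (sum(counts * mids) - s0) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  breaks[which.max(bcv) + 1L]
}

#' Binarize an image
#'
#' Thresholds an image into a binary mask, either automatically (Otsu) or
#' at a supplied manual threshold. The threshold actually used is recorded
#' in the mask's attributes for audit.
#'
#' @param img An [image2d()] or numeric matrix.
#' @param method `"otsu"` or `"manual"`.
#' @param manual_threshold Threshold for `method = "manual"`.
#' @return Logical matrix with attributes `threshold` and `method`;
#'   foreground pixels are strictly above the threshold.
#' @export
binarize <- function(img, method = c("otsu", "manual"),
                     manual_threshold = NULL) {
  method <- match.arg(method)
  m <- if (inherits(img, "image2d")) img$pixels else img
  stopifnot(is.matrix(m))
  thr <- switch(method,
                otsu = otsu_threshold(m),
                manual = {
                  if (is.null(manual_threshold)) {
                    stop("manual binarization requires `manual_threshold`",
                         call. = FALSE)
                  }
                  manual_threshold
                })
  structure(m > thr, threshold = thr, method = method)
}

#' Label connected components
#'
#' Labels maximal connected foreground components `1..K` under 4- or
#' 8-connectivity. Labels are assigned in raster-scan order of each
#' component's first pixel (ascending row, then column), so the labeling is
#' deterministic.
#'
#' @param mask Binary matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param cal Optional [calibration()] propagated into the result (needed
#'   later by [size_filter()]).
#' @return A [label_map()].
#' @export
label_components <- function(mask, connectivity = 8L, cal = NULL) {
  mask <- as_mask(mask)
  labels <- .cc_label_cpp(mask, as.integer(connectivity))
  label_map(labels, cal)
}

# Pixel counts per label 1..K (K = max label).
label_areas_px <- function(labels) {
  k <- max(labels, 0L)
  if (k == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = k)
}

#' Filter labeled objects by physical area
#'
#' Retains components whose area in um^2 lies inside
#' `[min_um2, max_um2]` (both bounds inclusive) and compacts the surviving
#' labels to `1..K`, preserving raster order. The default window selects
#' the representative synaptic-bouton population of 0.5-1.1 um^2.
#'
#' @param lm A [label_map()] with a calibration.
#' @param min_um2,max_um2 Inclusive area bounds in um^2.
#' @return A filtered, compacted [label_map()].
#' @export
size_filter <- function(lm, min_um2 = 0.5, max_um2 = 1.1) {
  stopifnot(inherits(lm, "label_map"), min_um2 < max_um2)
  if (is.null(lm$calibration)) {
    stop("size_filter requires a calibrated label map (um^2 bounds)",
         call. = FALSE)
  }
  areas <- label_areas_px(lm$labels) * pixel_area_um2(lm$calibration)
  keep <- which(areas >= min_um2 & areas <= max_um2)
  remap <- integer(length(areas) + 1L)            # index 1 = background 0
  remap[keep + 1L] <- seq_along(keep)
  new_labels <- matrix(remap[lm$labels + 1L],
                       nrow(lm$labels), ncol(lm$labels))
  label_map(new_labels, lm$calibration)
}

#' Quantify labeled objects
#'
#' One row per label: exact pixel-count area converted to um^2,
#' intensity-weighted centroid (1-based `(y, x)`; geometric centroid if the
#' object's total intensity is zero), and mean intensity.
#'
#' @param lm A calibrated [label_map()].
#' @param img An [image2d()] or matrix of the same shape.
#' @return A `bouton_table` data frame with attribute `count = K`.
#' @export
quantify_boutons <- function(lm, img) {
  stopifnot(inherits(lm, "label_map"))
  m <- if (inherits(img, "image2d")) img$pixels else img
  if (!all(dim(lm$labels) == dim(m))) {
    stop("label map and image dimensions differ", call. = FALSE)
  }
  if (is.null(lm$calibration)) {
    stop("quantify_boutons requires a calibrated label map", call. = FALSE)
  }
  px_area <- pixel_area_um2(lm$calibration)
  idx <- which(lm$labels > 0L)
  lab <- lm$labels[idx]
  k <- max(lm$labels, 0L)
  if (k == 0L) {
    tab <- data.frame(label = integer(0), area_um2 = numeric(0),
                      centroid_y = numeric(0), centroid_x = numeric(0),
                      mean_intensity = numeric(0))
    attr(tab, "count") <- 0L
    class(tab) <- c("bouton_table", "data.frame")
    return(tab)
  }
  yy <- (idx - 1L) %% nrow(m) + 1L
  xx <- (idx - 1L) %/% nrow(m) + 1L
  w <- m[idx]
  npx <- tabulate(lab, k)
  sw <- as.vector(rowsum(w, lab))
  swy <- as.vector(rowsum(w * yy, lab))
  swx <- as.vector(rowsum(w * xx, lab))
  sy <- as.vector(rowsum(as.numeric(yy), lab))
  sx <- as.vector(rowsum(as.numeric(xx), lab))
  cy <- ifelse(sw > 0, swy / sw, sy / npx)
  cx <- ifelse(sw > 0, swx / sw, sx / npx)
  tab <- data.frame(label = seq_len(k), area_um2 = npx * px_area,
                    centroid_y = cy, centroid_x = cx,
                    mean_intensity = sw / npx)
  attr(tab, "count") <- k
  class(tab) <- c("bouton_table", "data.frame")
  tab
}

#' Histogram of object areas
#'
#' Left-closed, right-open bins of width `bin_width_um2` starting at 0;
#' counts always sum to the table's object count.
#'
#' @param table A `bouton_table` from [quantify_boutons()].
#' @param bin_width_um2 Bin width in um^2 (> 0).
#' @return A list with `edges` (length `n_bins + 1`, starting at 0),
#'   `counts`, and `bin_width_um2`.
#' @export
area_histogram <- function(table, bin_width_um2 = 0.1) {
  stopifnot(bin_width_um2 > 0)
  areas <- table$area_um2
  n_bins <- if (length(areas) == 0L) 1L else
    floor(max(areas) / bin_width_um2) + 1L
  edges <- seq(0, by = bin_width_um2, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(areas, edges), nbins = n_bins)
  list(edges = edges, counts = counts, bin_width_um2 = bin_width_um2)
}

#' Full bouton-segmentation pipeline
#'
#' Z-projection, optional Gaussian smoothing, Sobel gradient magnitude,
#' thresholding (Otsu by default), 3x3 morphological closing and hole
#' filling, connected-component labeling, a half-amplitude (FWHM) area
#' refinement of each filled component, size filtering in um^2, and
#' quantification. The FWHM refinement re-thresholds each component of the
#' filled gradient mask at `background + (peak - background) / 2` (peak =
#' upper `peak_quantile` of the raw projection inside the component,
#' background = median outside the mask), because a filled gradient ring
#' overestimates the object by about one rim width; the refined area is the
#' standard half-maximum area.
#'
#' @param x An [image_stack()] (projected internally) or an [image2d()].
#' @param z_start,n_slices,method Passed to [z_project()] when `x` is a
#'   stack (defaults: all slices, maximum-intensity projection).
#' @param smooth_sigma Gaussian pre-smoothing s.d. in px before the
#'   gradient (0 disables; default 1).
#' @param threshold_method,manual_threshold Passed to [binarize()].
#' @param close_size Box size of the morphological closing (default 3).
#' @param fill_holes Fill holes in the closed mask (default `TRUE`).
#' @param refine_halfmax Apply the FWHM refinement (default `TRUE`).
#' @param peak_quantile Quantile of within-component projection intensity
#'   used as the object peak (default 0.95, robust to noise maxima).
#' @param connectivity Labeling connectivity (default 8).
#' @param min_um2,max_um2 Inclusive size-filter window (defaults 0.5, 1.1).
#' @return A list: `table` (final `bouton_table`), `count`, `labels`
#'   (filtered [label_map()]), `labels_all` (pre-filter), `mask` (binary,
#'   post-fill), `projection` ([image2d()]), and `settings` (every
#'   threshold and option actually used, for the audit sidecar).
#' @export
segment_boutons <- function(x, z_start = 1L, n_slices = NULL,
                            method = "max", smooth_sigma = 1,
                            threshold_method = "otsu",
                            manual_threshold = NULL,
                            close_size = 3L, fill_holes = TRUE,
                            refine_halfmax = TRUE, peak_quantile = 0.95,
                            connectivity = 8L,
                            min_um2 = 0.5, max_um2 = 1.1) {
  proj <- if (inherits(x, "image_stack")) {
    z_project(x, z_start = z_start, n_slices = n_slices, method = method)
  } else if (inherits(x, "image2d")) {
    x
  } else {
    stop("`x` must be an image_stack or image2d", call. = FALSE)
  }
  p <- proj$pixels
  sm <- if (smooth_sigma > 0) {
    EBImage::gblur(p, sigma = smooth_sigma, boundary = "replicate")
  } else p
  g <- gradient_magnitude(sm)
  mask <- binarize(g, method = threshold_method,
                   manual_threshold = manual_threshold)
  thr <- attr(mask, "threshold")
  m <- mask * 1
  if (close_size > 1L) {
    m <- EBImage::closing(m, EBImage::makeBrush(as.integer(close_size),
                                                shape = "box"))
  }
  if (fill_holes) m <- EBImage::fillHull(m)
  m <- matrix(as.numeric(m) > 0, nrow(p), ncol(p))
  lm_all <- label_components(m, connectivity = connectivity,
                             cal = proj$calibration)
  if (refine_halfmax && n_labels(lm_all) > 0L) {
    bg <- median(p[!m])
    refined <- matrix(FALSE, nrow(p), ncol(p))
    for (k in seq_len(max(lm_all$labels))) {
      comp <- lm_all$labels == k
      peak <- quantile(p[comp], peak_quantile, names = FALSE)
      refined <- refined | (comp & p > bg + 0.5 * (peak - bg))
    }
    lm_all <- label_components(refined, connectivity = connectivity,
                               cal = proj$calibration)
  }
  lm_f <- size_filter(lm_all, min_um2 = min_um2, max_um2 = max_um2)
  tab <- quantify_boutons(lm_f, proj)
  list(table = tab, count = attr(tab, "count"), labels = lm_f,
       labels_all = lm_all, mask = m, projection = proj,
       settings = list(projection_method = method, z_start = z_start,
                       n_slices = n_slices, smooth_sigma = smooth_sigma,
                       threshold_method = threshold_method,
                       threshold = thr, close_size = close_size,
                       fill_holes = fill_holes,
                       refine_halfmax = refine_halfmax,
                       peak_quantile = peak_quantile,
                       connectivity = connectivity,
                       min_um2 = min_um2, max_um2 = max_um2))
}

#' Match detected objects to ground-truth centers
#'
#' Greedy one-to-one matching by centroid distance (closest pairs first),
#' for validating counting on synthetic fields.
#'
#' @param table A `bouton_table`.
#' @param truth Data frame with `y`, `x` true centers.
#' @param max_dist_px Maximum match distance in pixels.
#' @return List with `n_matched`, `recall`, `precision`.
#' @export
match_boutons <- function(table, truth, max_dist_px = 5) {
  nd <- nrow(table); nt <- nrow(truth)
  if (nd == 0L || nt == 0L) {
    return(list(n_matched = 0L,
                recall = if (nt == 0L) NA_real_ else 0,
                precision = if (nd == 0L) NA_real_ else 0))
  }
  d <- sqrt(outer(table$centroid_y, truth$y, `-`)^2 +
            outer(table$centroid_x, truth$x, `-`)^2)
  n_matched <- 0L
  repeat {
    i <- which.min(d)
    if (d[i] > max_dist_px) break
    ri <- (i - 1L) %% nd + 1L
    ci <- (i - 1L) %/% nd + 1L
    n_matched <- n_matched + 1L
    d[ri, ] <- Inf
    d[, ci] <- Inf
    if (!any(is.finite(d))) break
  }
  list(n_matched = n_matched, recall = n_matched / nt,
       precision = n_matched / nd)
}
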