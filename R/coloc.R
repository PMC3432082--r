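#' Input for confined colocalization analysis
#'
#' Bundles the channel-1 intensity image, the segmented channel-1 and
#' channel-2 masks, and the confinement region (e.g. segmented
#' photoreceptor-axon cartridges). Both signal masks must lie inside the
#' confinement; set `intersect = TRUE` to clip them instead of erroring.
#'
#' @param ch1_intensity An [image2d()] or numeric matrix (channel-1
#'   intensities).
#' @param ch1_mask,ch2_mask Binary matrices: segmented signal of each
#'   channel.
#' @param confinement Binary matrix: the confinement region.
#' @param intersect If `TRUE`, masks are intersected with the confinement
#'   rather than validated against it.
#' @return An object of class `coloc_input`.
#' @export
coloc_input <- function(ch1_intensity, ch1_mask, ch2_mask, confinement,
                        intersect = FALSE) {
  m <- if (inherits(ch1_intensity, "image2d")) ch1_intensity$pixels
       else ch1_intensity
  stopifnot(is.matrix(m), all(is.finite(m)), all(m >= 0))
  ch1_mask <- as_mask(ch1_mask, "ch1_mask")
  ch2_mask <- as_mask(ch2_mask, "ch2_mask")
  confinement <- as_mask(confinement, "confinement")
  if (!all(dim(m) == dim(ch1_mask)) || !all(dim(m) == dim(ch2_mask)) ||
      !all(dim(m) == dim(confinement))) {
    stop("all colocalization inputs must share one shape", call. = FALSE)
  }
  if (intersect) {
    ch1_mask <- ch1_mask & confinement
    ch2_mask <- ch2_mask & confinement
  } else if (any(ch1_mask & !confinement) || any(ch2_mask & !confinement)) {
    stop("signal masks must lie inside the confinement region ",
         "(use intersect = TRUE to clip)", call. = FALSE)
  }
  structure(list(ch1_intensity = m, ch1_mask = ch1_mask,
                 ch2_mask = ch2_mask, confinement = confinement),
            class = "coloc_input")
}

#' Manders M1 within the confined ROI
#'
#' Intensity-weighted fraction of channel-1 signal residing where
#' channel-2 signal is present:
#' `M1 = sum(ch1 over ch1_mask & ch2_mask & confinement) /
#'       sum(ch1 over ch1_mask & confinement)`.
#' With `weighted = FALSE` the numerator and denominator count pixels
#' instead (binary overlap).
#'
#' @param input A [coloc_input()].
#' @param weighted Intensity-weighted (default) or binary.
#' @return M1 in `[0, 1]`.
#' @export
manders_m1 <- function(input, weighted = TRUE) {
  stopifnot(inherits(input, "coloc_input"))
  w <- if (weighted) input$ch1_intensity else
    matrix(1, nrow(input$ch1_intensity), ncol(input$ch1_intensity))
  sel <- input$ch1_mask & input$confinement
  den <- sum(w[sel])
  if (den <= 0) {
    stop("undefined Manders coefficient: no channel-1 signal in the ROI",
         call. = FALSE)
  }
  sum(w[sel & input$ch2_mask]) / den
}

# All integer displacements with 0 < radius <= max_radius, in
# lexicographic (dy, dx) order.
candidate_displacements <- function(max_radius) {
  stopifnot(max_radius >= 1)
  r <- floor(max_radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)      # dy varies slowest
  g <- g[, c("dy", "dx")]
  rad <- sqrt(g$dy^2 + g$dx^2)
  keep <- rad > 0 & rad <= max_radius
  data.frame(dy = g$dy[keep], dx = g$dx[keep], radius = rad[keep])
}

#' Enumerate valid confined displacements
#'
#' All integer `(dy, dx)` shifts with radius in `(0, max_radius]` for which
#' the displaced channel-1 mask retains at least `min_retained_fraction` of
#' its pixels inside the confinement region (pixels shifted out of the
#' frame count as lost). Deterministic lexicographic order.
#'
#' @param ch1_mask Binary matrix (segmented channel-1 signal).
#' @param confinement Binary matrix.
#' @param max_radius Maximum displacement radius in pixels (default 20).
#' @param min_retained_fraction Minimum retained fraction (default 0.9).
#' @return Data frame `dy, dx, radius, retention`.
#' @export
enumerate_confined_displacements <- function(ch1_mask, confinement,
                                             max_radius = 20,
                                             min_retained_fraction = 0.9) {
  ch1_mask <- as_mask(ch1_mask, "ch1_mask")
  confinement <- as_mask(confinement, "confinement")
  n_mask <- sum(ch1_mask)
  if (n_mask == 0L) stop("empty channel-1 mask", call. = FALSE)
  cand <- candidate_displacements(max_radius)
  scan <- .cda_scan_cpp(ch1_mask * 1, ch1_mask, confinement, confinement,
                        as.integer(cand$dy), as.integer(cand$dx))
  cand$retention <- scan$retained / n_mask
  out <- cand[cand$retention >= min_retained_fraction, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop(sprintf(
      "no valid displacement within radius %g at retention >= %g; widen max_radius or relax min_retained_fraction",
      max_radius, min_retained_fraction), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Confined displacement algorithm (CDA): effective colocalization
#'
#' Estimates random colocalization by shifting the channel-1 intensity and
#' mask by every valid confined displacement (integer x/y shifts up to
#' `max_radius`, keeping at least `min_retained_fraction` of the mask
#' inside the confinement; displaced pixels leaving the confinement are
#' dropped) and recomputing M1 against the fixed channel-2 mask. The mean
#' of this null is subtracted from the zero-displacement coefficient:
#' `M1_effective = M1(d = 0) - M1(random)`, reported also as a percentage
#' (`Eff-Colocalization (%) = 100 * M1_effective`), together with the full
#' null distribution and an add-one-corrected empirical exceedance
#' p-value.
#'
#' @param input A [coloc_input()].
#' @param max_radius Maximum displacement radius in px (default 20).
#' @param min_retained_fraction Minimum retained mask fraction (default
#'   0.9).
#' @param weighted Intensity-weighted M1 (default) or binary.
#' @return An object of class `cda_result`: `m1_d0`, `m1_random`,
#'   `m1_effective`, `percent_effective`, `null_values`, `displacements`,
#'   `n_displacements`, `p_null`, and the parameters used.
#' @export
cda_effective_colocalization <- function(input, max_radius = 20,
                                         min_retained_fraction = 0.9,
                                         weighted = TRUE) {
  stopifnot(inherits(input, "coloc_input"))
  m1_d0 <- manders_m1(input, weighted = weighted)
  w <- if (weighted) input$ch1_intensity * input$ch1_mask else
    (input$ch1_mask * 1)
  n_mask <- sum(input$ch1_mask)
  cand <- candidate_displacements(max_radius)
  scan <- .cda_scan_cpp(w, input$ch1_mask, input$confinement,
                        input$ch2_mask,
                        as.integer(cand$dy), as.integer(cand$dx))
  cand$retention <- scan$retained / n_mask
  valid <- cand$retention >= min_retained_fraction & scan$den > 0
  if (!any(valid)) {
    stop(sprintf(
      "no valid displacement within radius %g at retention >= %g; widen max_radius or relax min_retained_fraction",
      max_radius, min_retained_fraction), call. = FALSE)
  }
  disp <- cand[valid, , drop = FALSE]
  disp$m1 <- scan$num[valid] / scan$den[valid]
  rownames(disp) <- NULL
  m1_random <- mean(disp$m1)
  n <- nrow(disp)
  structure(list(m1_d0 = m1_d0, m1_random = m1_random,
                 m1_effective = m1_d0 - m1_random,
                 percent_effective = 100 * (m1_d0 - m1_random),
                 null_values = disp$m1, displacements = disp,
                 n_displacements = n,
                 p_null = (1 + sum(disp$m1 >= m1_d0)) / (1 + n),
                 params = list(max_radius = max_radius,
                               min_retained_fraction = min_retained_fraction,
                               weighted = weighted)),
            class = "cda_result")
}

#' @export
print.cda_result <- function(x, ...) {
  cat(sprintf(
    "<cda_result> M1(d=0) = %.4f, M1(random) = %.4f over %d displacements\n",
    x$m1_d0, x$m1_random, x$n_displacements))
  cat(sprintf("  effective colocalization = %.4f (%.1f%%), p_null = %.4g\n",
              x$m1_effective, x$percent_effective, x$p_null))
  invisible(x)
}

#' Group summary of effective colocalization
#'
#' Per-group mean and SEM of the effective-colocalization percentage over a
#' list of CDA results.
#'
#' @param results List of `cda_result` objects (or numeric
#'   percent-effective values).
#' @param group_labels Character/factor of the same length.
#' @return Data frame `group, n, mean_percent, sem_percent,
#'   single_observation`; the SEM of a single observation is undefined and
#'   reported as 0 with the flag set.
#' @export
coloc_report <- function(results, group_labels) {
  vals <- vapply(results, function(r) {
    if (inherits(r, "cda_result")) r$percent_effective else as.numeric(r)
  }, numeric(1))
  if (length(vals) != length(group_labels) || length(vals) == 0L) {
    stop("results and group_labels must be non-empty and equal length",
         call. = FALSE)
  }
  g <- factor(group_labels)
  if (any(table(g) == 0L)) stop("empty group", call. = FALSE)
  out <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- vals[g == lv]
    data.frame(group = lv, n = length(v), mean_percent = mean(v),
               sem_percent = if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0,
               single_observation = length(v) == 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Segment both channels inside a confinement region for CDA
#'
#' Maximum-intensity projection of each channel followed by Otsu
#' thresholding computed over the confinement pixels only; the resulting
#' masks are clipped to the confinement. This supplies the segmented
#' signals the CDA operates on when only raw stacks are available.
#'
#' @param ch1,ch2 [image_stack()] or [image2d()] objects.
#' @param confinement Binary matrix.
#' @param method Projection method (default `"max"`).
#' @return A [coloc_input()] plus a `thresholds` attribute.
#' @export
segment_coloc_channels <- function(ch1, ch2, confinement, method = "max") {
  confinement <- as_mask(confinement, "confinement")
  proj <- function(x) {
    if (inherits(x, "image_stack")) z_project(x, method = method) else x
  }
  p1 <- proj(ch1); p2 <- proj(ch2)
  thr1 <- otsu_threshold(p1$pixels[confinement])
  thr2 <- otsu_threshold(p2$pixels[confinement])
  inp <- coloc_input(p1, (p1$pixels > thr1) & confinement,
                     (p2$pixels > thr2) & confinement, confinement)
  attr(inp, "thresholds") <- c(ch1 = thr1, ch2 = thr2)
  inp
}
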