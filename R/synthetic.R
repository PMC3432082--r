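#' Generate an elongated confinement mask
#'
#' Builds a binary confinement region emulating segmented photoreceptor-axon
#' cartridges: `n_regions` parallel full-height bands of width
#' `region_width_px`, placed at random non-overlapping x positions (at least
#' `gap_px` empty columns between bands, so bands stay distinct connected
#' components under 4- or 8-connectivity). With `n_regions = 1` and width
#' equal to the field, the mask degenerates to the full frame.
#'
#' @param shape Integer `(n_y, n_x)` image shape.
#' @param n_regions Number of bands (0 gives an all-`FALSE` mask).
#' @param region_width_px Band width in pixels, at least 3.
#' @param seed Optional integer seed; the mask is a deterministic function
#'   of `shape`, the parameters and the seed.
#' @param gap_px Minimum empty columns between bands (default 1).
#' @return Logical `(n_y, n_x)` matrix.
#' @examples
#' m <- generate_confinement_mask(c(128, 128), n_regions = 4,
#'                                region_width_px = 12, seed = 1)
#' sum(m) / length(m)
#' @export
generate_confinement_mask <- function(shape, n_regions, region_width_px = 12,
                                      seed = NULL, gap_px = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 1), n_regions >= 0)
  ny <- as.integer(shape[1]); nx <- as.integer(shape[2])
  mask <- matrix(FALSE, ny, nx)
  if (n_regions == 0L) return(mask)
  stopifnot(region_width_px >= 3, region_width_px <= nx)
  w <- as.integer(region_width_px); gap <- as.integer(gap_px)
  free <- nx - n_regions * w - (n_regions - 1L) * gap
  if (free < 0L) {
    fit <- (nx + gap) %/% (w + gap)
    stop(sprintf(
      "cannot place confinement region %d of %d without overlap (width %d px in %d columns)",
      fit + 1L, n_regions, w, nx), call. = FALSE)
  }
  with_seed(seed, {
    # uniform composition of the free columns into n_regions + 1 gaps:
    # always succeeds when the layout is feasible
    pad <- sort(sample.int(free + 1L, n_regions, replace = TRUE)) - 1L
    starts <- pad + (seq_len(n_regions) - 1L) * (w + gap) + 1L
    for (s in starts) mask[, s:(s + w - 1L)] <- TRUE
  })
  mask
}

#' Specification of a synthetic two-channel colocalization scene
#'
#' Parameters of a punctate two-channel stack inside a confinement region,
#' with a controlled fraction of channel-1 puncta placed on (jittered)
#' channel-2 punctum centers. Puncta are isotropic 2-D Gaussian spots of
#' s.d. `spot_sigma_px`, rendered on a finite patch of radius
#' `ceiling(4 * spot_sigma_px)` and replicated across z with a shared
#' Gaussian envelope peaking at the central slice. Noise is Poisson on the
#' clean signal plus additive Gaussian read noise, clipped at zero.
#'
#' @param shape Integer `(n_z, n_y, n_x)`.
#' @param n_puncta_ch1,n_puncta_ch2 Punctum counts per channel.
#' @param coloc_fraction Fraction in `[0, 1]` of channel-1 puncta whose
#'   centers coincide (up to `jitter_px`) with a channel-2 punctum; the
#'   realized count is `round(coloc_fraction * n_puncta_ch1)`.
#' @param spot_sigma_px Gaussian spot s.d. in pixels.
#' @param jitter_px Maximum per-axis integer jitter of a colocalized
#'   channel-1 punctum around its channel-2 partner (default 1; 0 forces
#'   exact coincidence).
#' @param amplitude_range `(low, high)` uniform range of spot amplitudes
#'   above background, in intensity units.
#' @param background_level Constant background intensity.
#' @param read_noise_sd Gaussian read-noise s.d. (0 disables).
#' @param poisson_noise Logical; apply Poisson noise to the clean signal.
#' @param confinement Optional logical `(n_y, n_x)` mask; if `NULL`, one is
#'   generated from `confinement_params`.
#' @param confinement_params List with `n_regions` and `region_width_px`
#'   used when `confinement` is `NULL`.
#' @param cal A [calibration()].
#' @param seed Integer seed; together with the spec it fully determines the
#'   scene.
#' @return An object of class `coloc_scene_spec`.
#' @export
coloc_scene_spec <- function(shape = c(1L, 256L, 256L),
                             n_puncta_ch1 = 40L, n_puncta_ch2 = 40L,
                             coloc_fraction = 0.5,
                             spot_sigma_px = 2,
                             jitter_px = 1L,
                             amplitude_range = c(120, 220),
                             background_level = 20,
                             read_noise_sd = 3,
                             poisson_noise = TRUE,
                             confinement = NULL,
                             confinement_params = list(n_regions = 4L,
                                                       region_width_px = 48L),
                             cal = calibration(),
                             seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1),
            coloc_fraction >= 0, coloc_fraction <= 1,
            spot_sigma_px > 0, jitter_px >= 0,
            length(amplitude_range) == 2L,
            amplitude_range[1] > 0, diff(amplitude_range) >= 0,
            background_level >= 0, read_noise_sd >= 0,
            n_puncta_ch1 >= 0, n_puncta_ch2 >= 0)
  if (!is.null(confinement)) confinement <- as_mask(confinement, "confinement")
  structure(list(shape = as.integer(shape),
                 n_puncta_ch1 = as.integer(n_puncta_ch1),
                 n_puncta_ch2 = as.integer(n_puncta_ch2),
                 coloc_fraction = coloc_fraction,
                 spot_sigma_px = spot_sigma_px,
                 jitter_px = as.integer(jitter_px),
                 amplitude_range = amplitude_range,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 poisson_noise = isTRUE(poisson_noise),
                 confinement = confinement,
                 confinement_params = confinement_params,
                 cal = cal, seed = as.integer(seed)),
            class = "coloc_scene_spec")
}

# Additive rendering of Gaussian spots onto 2-D `img` (modified copy
# returned). Finite support: patch of radius ceiling(4 sigma) per spot.
render_gaussian_spots <- function(img, centers, amplitudes, sigma) {
  if (nrow(centers) == 0L) return(img)
  ny <- nrow(img); nx <- ncol(img)
  rad <- ceiling(4 * sigma)
  for (k in seq_len(nrow(centers))) {
    cy <- centers[k, 1]; cx <- centers[k, 2]
    ys <- max(1L, floor(cy - rad)):min(ny, ceiling(cy + rad))
    xs <- max(1L, floor(cx - rad)):min(nx, ceiling(cx + rad))
    d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
    img[ys, xs] <- img[ys, xs] + amplitudes[k] * exp(-d2 / (2 * sigma^2))
  }
  img
}

# Poisson + Gaussian read noise on a clean nonnegative array, clipped at 0.
apply_noise <- function(clean, poisson, read_sd) {
  out <- clean
  if (poisson) out <- array(rpois(length(clean), lambda = clean), dim(clean))
  if (read_sd > 0) out <- out + rnorm(length(out), sd = read_sd)
  out[out < 0] <- 0
  out
}

# Shared z-envelope: Gaussian across slices, 1 at the central slice.
z_envelope <- function(n_z, sigma_z = max(1, n_z / 4)) {
  zc <- (n_z + 1) / 2
  exp(-((seq_len(n_z) - zc)^2) / (2 * sigma_z^2))
}

#' Generate a synthetic two-channel colocalization scene
#'
#' Draws channel-2 punctum centers uniformly over the confinement region,
#' places `round(coloc_fraction * n_puncta_ch1)` channel-1 puncta on
#' jittered channel-2 centers and the remainder on confinement pixels
#' disjoint from every channel-2 center, renders both channels, and applies
#' the configured noise. With all noise disabled each channel is exactly
#' `background + sum of Gaussian spots`.
#'
#' @param spec A [coloc_scene_spec()].
#' @return A list with elements `ch1`, `ch2` ([image_stack]s), `confinement`
#'   (logical matrix), and `truth` (punctum centers as `(y, x)` matrices,
#'   logical `ch1_coloc` flags summing to the rounded colocalized count,
#'   amplitudes).
#' @export
generate_coloc_scene <- function(spec) {
  stopifnot(inherits(spec, "coloc_scene_spec"))
  n_z <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  with_seed(spec$seed, {
    conf <- spec$confinement
    if (is.null(conf)) {
      conf <- generate_confinement_mask(
        c(ny, nx),
        n_regions = spec$confinement_params$n_regions,
        region_width_px = spec$confinement_params$region_width_px)
    }
    conf_idx <- which(conf)
    n1 <- spec$n_puncta_ch1; n2 <- spec$n_puncta_ch2
    n_coloc <- as.integer(round(spec$coloc_fraction * n1))
    if (n_coloc > n2) {
      stop("coloc_fraction * n_puncta_ch1 exceeds n_puncta_ch2", call. = FALSE)
    }
    if (n2 > length(conf_idx) || (n1 - n_coloc) > length(conf_idx) - n2) {
      stop(sprintf(
        "confinement capacity exceeded: %d pixels for %d + %d puncta",
        length(conf_idx), n2, n1), call. = FALSE)
    }
    idx2 <- sample(conf_idx, n2)
    ch2_centers <- cbind(y = (idx2 - 1L) %% ny + 1L,
                         x = (idx2 - 1L) %/% ny + 1L)
    # colocalized ch1 puncta: jitter around a unique ch2 partner, staying
    # inside the confinement (bounded retries, then exact coincidence)
    partners <- if (n_coloc > 0L) sample.int(n2, n_coloc) else integer(0)
    coloc_centers <- matrix(numeric(0), 0, 2)
    for (p in partners) {
      base <- ch2_centers[p, ]
      pos <- base
      if (spec$jitter_px > 0L) {
        for (try in 1:20) {
          cand <- base + sample(seq(-spec$jitter_px, spec$jitter_px),
                                2L, replace = TRUE)
          if (cand[1] >= 1 && cand[1] <= ny && cand[2] >= 1 &&
              cand[2] <= nx && conf[cand[1], cand[2]]) {
            pos <- cand
            break
          }
        }
      }
      coloc_centers <- rbind(coloc_centers, pos)
    }
    free_idx <- setdiff(conf_idx, idx2)
    idx1 <- if (n1 - n_coloc > 0L) sample(free_idx, n1 - n_coloc) else integer(0)
    rand_centers <- cbind(y = (idx1 - 1L) %% ny + 1L,
                          x = (idx1 - 1L) %/% ny + 1L)
    ch1_centers <- rbind(coloc_centers, rand_centers)
    dimnames(ch1_centers) <- list(NULL, c("y", "x"))
    ch1_coloc <- c(rep(TRUE, n_coloc), rep(FALSE, n1 - n_coloc))
    amp1 <- runif(n1, spec$amplitude_range[1], spec$amplitude_range[2])
    amp2 <- runif(n2, spec$amplitude_range[1], spec$amplitude_range[2])
    env <- z_envelope(n_z)
    render_channel <- function(centers, amps) {
      st <- array(0, c(n_z, ny, nx))
      base <- render_gaussian_spots(matrix(0, ny, nx), centers, amps,
                                    spec$spot_sigma_px)
      for (z in seq_len(n_z)) {
        st[z, , ] <- spec$background_level + env[z] * base
      }
      apply_noise(st, spec$poisson_noise, spec$read_noise_sd)
    }
    list(ch1 = image_stack(render_channel(ch1_centers, amp1), spec$cal),
         ch2 = image_stack(render_channel(ch2_centers, amp2), spec$cal),
         confinement = conf,
         truth = list(ch1_centers = ch1_centers, ch2_centers = ch2_centers,
                      ch1_coloc = ch1_coloc, n_coloc = n_coloc,
                      amp_ch1 = amp1, amp_ch2 = amp2),
         spec = spec)
  })
}

#' Specification of a synthetic bouton field
#'
#' Parameters of a field of non-overlapping synaptic-bouton-like objects.
#' Each object is a plateaued disc with a raised-cosine rim of half-width
#' `rim_width_px`: intensity `amp` inside radius `r0 - w`, 0 outside
#' `r0 + w`, crossing half-amplitude exactly at `r0`, so the half-amplitude
#' (FWHM) area `pi * r0^2` is well defined for generator and pipeline
#' alike. Target areas are drawn uniformly from `area_range_um2` shrunk by
#' 5% of its width at each end, so that discretized pixel areas stay
#' strictly inside the nominal range. Objects can extend across z with a
#' per-object Gaussian envelope that reaches exactly 1 at its peak slice,
#' so a maximum-intensity projection of the clean stack preserves every
#' amplitude.
#'
#' @param shape Integer `(n_z, n_y, n_x)`; the default maps a ~36 um field
#'   onto 512 px at 0.07 um/px over 10 optical sections.
#' @param n_boutons Number of objects.
#' @param area_range_um2 `(low, high)` half-amplitude area window in um^2.
#' @param min_separation_px Minimum gap between object supports, enforced
#'   by jittered-grid placement (guaranteed, not best-effort).
#' @param rim_width_px Rim half-width `w` in pixels.
#' @param amplitude_range,background_level,read_noise_sd,poisson_noise
#'   Intensity and noise parameters as in [coloc_scene_spec()].
#' @param cal A [calibration()].
#' @param seed Integer seed.
#' @return An object of class `bouton_field_spec`.
#' @export
bouton_field_spec <- function(shape = c(10L, 512L, 512L),
                              n_boutons = 50L,
                              area_range_um2 = c(0.5, 1.1),
                              min_separation_px = 6L,
                              rim_width_px = 1.5,
                              amplitude_range = c(120, 220),
                              background_level = 20,
                              read_noise_sd = 0,
                              poisson_noise = TRUE,
                              cal = calibration(),
                              seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1), n_boutons >= 0,
            length(area_range_um2) == 2L, area_range_um2[1] > 0,
            diff(area_range_um2) > 0, min_separation_px >= 1,
            rim_width_px > 0, background_level >= 0)
  structure(list(shape = as.integer(shape),
                 n_boutons = as.integer(n_boutons),
                 area_range_um2 = area_range_um2,
                 min_separation_px = as.integer(min_separation_px),
                 rim_width_px = rim_width_px,
                 amplitude_range = amplitude_range,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 poisson_noise = isTRUE(poisson_noise),
                 cal = cal, seed = as.integer(seed)),
            class = "bouton_field_spec")
}

# Plateaued-disc radial profile: 1 for r <= r0 - w, 0 for r >= r0 + w,
# raised-cosine in between; exactly 0.5 at r = r0.
disc_profile <- function(r, r0, w) {
  p <- numeric(length(r))
  p[r <= r0 - w] <- 1
  ramp <- r > r0 - w & r < r0 + w
  p[ramp] <- 0.5 * (1 + cos(pi * (r[ramp] - (r0 - w)) / (2 * w)))
  p
}

#' Generate a synthetic bouton field with ground truth
#'
#' Places `n_boutons` plateaued discs on a jittered grid (guaranteeing the
#' minimum separation), renders the stack, and records per-object ground
#' truth. The true area of an object is its count of pixels whose clean
#' intensity contribution exceeds half its amplitude, converted to um^2 —
#' the same half-amplitude definition the segmentation pipeline measures.
#'
#' @param spec A [bouton_field_spec()].
#' @return A list with `stack` ([image_stack]) and `truth` (data frame with
#'   one row per object: `y`, `x`, `amplitude`, `area_um2`, `z_peak`).
#' @export
generate_bouton_field <- function(spec) {
  stopifnot(inherits(spec, "bouton_field_spec"))
  n_z <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  px_area <- pixel_area_um2(spec$cal)
  lo <- spec$area_range_um2[1]; hi <- spec$area_range_um2[2]
  margin <- 0.05 * (hi - lo)
  r_max <- sqrt((hi / px_area) / pi) + spec$rim_width_px
  with_seed(spec$seed, {
    n <- spec$n_boutons
    truth <- data.frame(y = numeric(0), x = numeric(0),
                        amplitude = numeric(0), area_um2 = numeric(0),
                        z_peak = integer(0))
    clean2d <- matrix(0, ny, nx)
    areas_px <- integer(0)
    if (n > 0L) {
      target_um2 <- runif(n, lo + margin, hi - margin)
      r0 <- sqrt((target_um2 / px_area) / pi)
      amps <- runif(n, spec$amplitude_range[1], spec$amplitude_range[2])
      # jittered-grid placement: cells wide enough that any two objects in
      # different cells respect the separation
      cell <- ceiling(2 * r_max + spec$min_separation_px + 6)
      border <- ceiling(r_max) + 2L
      gy <- floor((ny - 2 * border) / cell)
      gx <- floor((nx - 2 * border) / cell)
      if (gy * gx < n) {
        stop(sprintf(
          "field capacity exceeded: %d grid cells for %d boutons (shape %dx%d, cell %d px)",
          gy * gx, n, ny, nx, cell), call. = FALSE)
      }
      cells <- sample.int(gy * gx, n)
      cy0 <- border + ((cells - 1L) %% gy) * cell
      cx0 <- border + ((cells - 1L) %/% gy) * cell
      jit_max <- cell - 2 * r_max - spec$min_separation_px
      yy <- cy0 + r_max + runif(n, 0, jit_max)
      xx <- cx0 + r_max + runif(n, 0, jit_max)
      z_peak <- sample.int(n_z, n, replace = TRUE)
      areas_px <- integer(n)
      for (k in seq_len(n)) {
        rad <- ceiling(r0[k] + spec$rim_width_px)
        ys <- max(1L, floor(yy[k] - rad)):min(ny, ceiling(yy[k] + rad))
        xs <- max(1L, floor(xx[k] - rad)):min(nx, ceiling(xx[k] + rad))
        r <- sqrt(outer((ys - yy[k])^2, (xs - xx[k])^2, `+`))
        prof <- matrix(disc_profile(as.vector(r), r0[k], spec$rim_width_px),
                       nrow = length(ys))
        clean2d[ys, xs] <- clean2d[ys, xs] + amps[k] * prof
        areas_px[k] <- sum(prof > 0.5)
      }
      truth <- data.frame(y = yy, x = xx, amplitude = amps,
                          area_um2 = areas_px * px_area, z_peak = z_peak)
      stopifnot(all(truth$area_um2 >= lo), all(truth$area_um2 <= hi))
    }
    st <- array(0, c(n_z, ny, nx))
    if (n_z == 1L || n == 0L) {
      for (z in seq_len(n_z)) st[z, , ] <- spec$background_level + clean2d
    } else {
      # per-object z-envelope, exactly 1 at the object's peak slice
      sigma_z <- max(1, n_z / 5)
      for (z in seq_len(n_z)) {
        sl <- matrix(0, ny, nx)
        for (k in seq_len(n)) {
          envk <- exp(-((z - truth$z_peak[k])^2) / (2 * sigma_z^2))
          if (envk < 1e-3) next
          rad <- ceiling(sqrt((hi / px_area) / pi) + spec$rim_width_px)
          ys <- max(1L, floor(truth$y[k] - rad)):min(ny, ceiling(truth$y[k] + rad))
          xs <- max(1L, floor(truth$x[k] - rad)):min(nx, ceiling(truth$x[k] + rad))
          sl[ys, xs] <- sl[ys, xs] + envk * clean2d[ys, xs]
        }
        st[z, , ] <- spec$background_level + sl
      }
    }
    st <- apply_noise(st, spec$poisson_noise, spec$read_noise_sd)
    list(stack = image_stack(st, spec$cal), truth = truth, spec = spec)
  })
}

#' Specification of synthetic ROI fluorescence time courses
#'
#' Parameters of per-ROI mean-fluorescence traces
#' `F(t) = baseline * exp(-bleach_rate * t) * response(t)`, where the
#' response is 1 before the event and, after it, a sustained step
#' `(1 + step_amplitude)`, an exponential unloading `exp(-(t - t0) / tau)`,
#' or their product when both are given. Noise is additive Gaussian with
#' s.d. `noise_sd * baseline_level` (i.e. `noise_sd` is in units of the
#' baseline), clipped at zero.
#'
#' @param n_rois Number of ROI traces (identical clean signal, independent
#'   noise).
#' @param n_timepoints,dt_s Sampling grid: `n_timepoints` samples `dt_s`
#'   seconds apart starting at `t = 0`.
#' @param baseline_level Pre-event fluorescence (strictly positive).
#' @param event_time_s Event (depolarization / light) time in seconds; must
#'   lie inside the sampled window.
#' @param step_amplitude Sustained fractional step (dF/F0), or `NULL`.
#' @param decay_tau_s Unloading time constant in seconds, or `NULL`.
#' @param bleach_rate_per_s Photobleaching rate (per second).
#' @param noise_sd Gaussian noise s.d. as a fraction of baseline.
#' @param seed Integer seed.
#' @return An object of class `timeseries_spec`.
#' @export
timeseries_spec <- function(n_rois = 4L, n_timepoints = 120L, dt_s = 1,
                            baseline_level = 100, event_time_s = 30,
                            step_amplitude = NULL, decay_tau_s = NULL,
                            bleach_rate_per_s = 0, noise_sd = 0,
                            seed = 1L) {
  stopifnot(n_rois >= 1, n_timepoints >= 2, dt_s > 0, baseline_level > 0,
            bleach_rate_per_s >= 0, noise_sd >= 0)
  if (!is.null(step_amplitude)) stopifnot(step_amplitude >= -1)
  if (!is.null(decay_tau_s)) stopifnot(decay_tau_s > 0)
  t_max <- (n_timepoints - 1) * dt_s
  if (event_time_s <= 0 || event_time_s >= t_max) {
    stop(sprintf("event_time_s = %g outside the sampled window (0, %g)",
                 event_time_s, t_max), call. = FALSE)
  }
  structure(list(n_rois = as.integer(n_rois),
                 n_timepoints = as.integer(n_timepoints), dt_s = dt_s,
                 baseline_level = baseline_level,
                 event_time_s = event_time_s,
                 step_amplitude = step_amplitude,
                 decay_tau_s = decay_tau_s,
                 bleach_rate_per_s = bleach_rate_per_s,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "timeseries_spec")
}

#' Generate synthetic ROI fluorescence traces
#'
#' @param spec A [timeseries_spec()].
#' @return A list with `traces` (list of [ts_trace()]) and `truth`
#'   (the generating parameters).
#' @export
generate_timeseries <- function(spec) {
  stopifnot(inherits(spec, "timeseries_spec"))
  t_s <- (seq_len(spec$n_timepoints) - 1) * spec$dt_s
  resp <- rep(1, spec$n_timepoints)
  post <- t_s >= spec$event_time_s
  if (!is.null(spec$step_amplitude)) {
    resp[post] <- resp[post] * (1 + spec$step_amplitude)
  }
  if (!is.null(spec$decay_tau_s)) {
    resp[post] <- resp[post] *
      exp(-(t_s[post] - spec$event_time_s) / spec$decay_tau_s)
  }
  clean <- spec$baseline_level * exp(-spec$bleach_rate_per_s * t_s) * resp
  with_seed(spec$seed, {
    traces <- lapply(seq_len(spec$n_rois), function(i) {
      f <- clean
      if (spec$noise_sd > 0) {
        f <- f + rnorm(length(f), sd = spec$noise_sd * spec$baseline_level)
        f[f < 0] <- 0
      }
      ts_trace(roi_id = i, t_s = t_s, F = f,
               meta = list(event_time_s = spec$event_time_s))
    })
    list(traces = traces,
         truth = list(clean = clean,
                      baseline_level = spec$baseline_level,
                      event_time_s = spec$event_time_s,
                      step_amplitude = spec$step_amplitude,
                      decay_tau_s = spec$decay_tau_s,
                      bleach_rate_per_s = spec$bleach_rate_per_s),
         spec = spec)
  })
}
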