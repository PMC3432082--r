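# TIFF, CSV, JSON and YAML readers/writers. Every writer has a reader and
# round-trips on supported dialects.

# Smallest power of two >= m (>= 1): a clean, exactly-representable
# intensity scale.
pow2_scale <- function(m) {
  if (!is.finite(m) || m <= 1) return(1)
  2^ceiling(log2(m))
}

stack_sidecar <- function(path) paste0(path, ".json")

#' Write / read calibrated image stacks as multi-page TIFF
#'
#' Stacks are stored as 32-bit TIFF pages (z fastest, then t for 4-D data)
#' of `data / scale`, where `scale` is the smallest power of two not below
#' the intensity maximum; the scale, axes, shape, calibration and whether
#' the voxels were integer-valued go to a JSON sidecar (`<path>.json`).
#' TIFF samples are 32-bit integers, so integer-valued stacks (photon
#' counts) round-trip bit-exactly (the quantization step `scale / 2^32` is
#' far below 0.5 and the reader restores the integers); general
#' real-valued stacks round-trip to one part in `2^32` of the scale.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `write_stack`: the path, invisibly. `read_stack`: an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  pages <- if (length(d) == 3L) {
    lapply(seq_len(d[1]), function(z) stack$data[z, , ])
  } else {
    unlist(lapply(seq_len(d[1]), function(t) {
      lapply(seq_len(d[2]), function(z) stack$data[t, z, , ])
    }), recursive = FALSE)
  }
  scale <- pow2_scale(max(stack$data))
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                  bits.per.sample = 32L)
  jsonlite::write_json(
    list(shape = d, axes = if (length(d) == 3L) "zyx" else "tzyx",
         scale = scale,
         integer_data = all(stack$data == round(stack$data)),
         pixel_size_um = stack$calibration$pixel_size_um,
         z_step_um = stack$calibration$z_step_um),
    stack_sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param cal Optional [calibration()] used when no sidecar is present.
#' @export
read_stack <- function(path, cal = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  side <- stack_sidecar(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    d <- as.integer(meta$shape)
    scale <- meta$scale
    cal <- calibration(meta$pixel_size_um, meta$z_step_um)
    arr <- array(0, d)
    if (length(d) == 3L) {
      for (z in seq_len(d[1])) arr[z, , ] <- pages[[z]] * scale
    } else {
      i <- 0L
      for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
        i <- i + 1L
        arr[t, z, , ] <- pages[[i]] * scale
      }
    }
    if (isTRUE(meta$integer_data)) arr <- round(arr)
    return(image_stack(arr, cal))
  }
  # bare TIFF: promote pages to a (z, y, x) stack
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  image_stack(arr, cal %||% calibration())
}

#' Write / read binary masks as TIFF
#'
#' 8-bit, foreground = 255.
#'
#' @param mask Logical matrix.
#' @param path TIFF path.
#' @return `write_mask`: the path, invisibly; `read_mask`: logical matrix.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  tiff::readTIFF(path) > 0.5
}

#' Write / read label maps as 16-bit TIFF
#'
#' Labels up to 65535; calibration goes to a JSON sidecar.
#'
#' @param lm A [label_map()].
#' @param path TIFF path.
#' @return `write_label_map`: the path, invisibly; `read_label_map`: a
#'   [label_map()].
#' @export
write_label_map <- function(lm, path) {
  stopifnot(inherits(lm, "label_map"))
  if (max(lm$labels, 0L) > 65535L) {
    stop("label values exceed 16-bit range", call. = FALSE)
  }
  tiff::writeTIFF(lm$labels / 65535, path, bits.per.sample = 16L)
  meta <- list(max_label = max(lm$labels, 0L))
  if (!is.null(lm$calibration)) {
    meta$pixel_size_um <- lm$calibration$pixel_size_um
    meta$z_step_um <- lm$calibration$z_step_um
  }
  jsonlite::write_json(meta, stack_sidecar(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  labels <- round(tiff::readTIFF(path) * 65535)
  cal <- NULL
  side <- stack_sidecar(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$pixel_size_um)) {
      cal <- calibration(meta$pixel_size_um, meta$z_step_um)
    }
  }
  label_map(labels, cal)
}

#' Write / read ROI time series as CSV
#'
#' Tidy table with columns `roi_id, t_s, F`.
#'
#' @param traces List of [ts_trace()] (or a single trace).
#' @param path CSV path.
#' @return `write_timeseries_csv`: the path, invisibly;
#'   `read_timeseries_csv`: a list of [ts_trace()].
#' @export
write_timeseries_csv <- function(traces, path) {
  if (inherits(traces, "ts_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, as.data.frame))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @export
read_timeseries_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("roi_id", "t_s", "F") %in% names(df)))
  lapply(split(df, df$roi_id), function(d) {
    d <- d[order(d$t_s), ]
    ts_trace(d$roi_id[1], d$t_s, d$F)
  })
}

#' Write / read ground truth and results as JSON
#'
#' Plain JSON serialization (full numeric precision) for generator ground
#' truth and analysis results.
#'
#' @param x A list (ground truth, CDA result, settings, ...).
#' @param path JSON path.
#' @return `write_json_result`: the path, invisibly; `read_json_result`:
#'   the parsed list.
#' @export
write_json_result <- function(x, path) {
  if (inherits(x, "cda_result")) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_json_result
#' @export
read_json_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
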