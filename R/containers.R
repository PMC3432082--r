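#' Calibrated image containers
#'
#' Light containers tying pixel data to a [calibration()]. An `image_stack`
#' holds a 3-D `(z, y, x)` or 4-D `(t, z, y, x)` nonnegative intensity
#' array; an `image2d` holds a single 2-D image (e.g. a z-projection); a
#' `label_map` holds an integer matrix of connected-component labels
#' (0 = background, labels compact `1..K`). Binary masks (confinement
#' regions, segmented signals) are plain logical matrices throughout.
#'
#' Coordinates are 1-based `(row, col) = (y, x)`, following the host
#' language's matrix convention.
#'
#' @param data Numeric array, 3-D `(z, y, x)` or 4-D `(t, z, y, x)`,
#'   finite and nonnegative.
#' @param pixels Numeric matrix `(y, x)`, finite and nonnegative.
#' @param labels Integer matrix, nonnegative; labels need not be compact on
#'   input (see [size_filter()] for compaction).
#' @param cal A [calibration()], or `NULL` for a `label_map` built before
#'   calibration is known.
#' @return An object of class `image_stack`, `image2d` or `label_map`.
#' @name containers
NULL

#' @rdname containers
#' @export
image_stack <- function(data, cal = calibration()) {
  stopifnot(is.array(data), length(dim(data)) %in% c(3L, 4L),
            inherits(cal, "calibration"))
  if (!all(is.finite(data)) || any(data < 0)) {
    stop("image_stack data must be finite and nonnegative", call. = FALSE)
  }
  structure(list(data = data, calibration = cal), class = "image_stack")
}

#' @rdname containers
#' @export
image2d <- function(pixels, cal = calibration()) {
  stopifnot(is.matrix(pixels), is.numeric(pixels),
            inherits(cal, "calibration"))
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop("image2d pixels must be finite and nonnegative", call. = FALSE)
  }
  structure(list(pixels = pixels, calibration = cal), class = "image2d")
}

#' @rdname containers
#' @export
label_map <- function(labels, cal = NULL) {
  stopifnot(is.matrix(labels))
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be nonnegative integers", call. = FALSE)
  }
  if (!is.null(cal)) stopifnot(inherits(cal, "calibration"))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, calibration = cal), class = "label_map")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> dims [%s], range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = " x "),
              min(x$data), max(x$data)))
  print(x$calibration)
  invisible(x)
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d px, %d object(s)\n",
              nrow(x$labels), ncol(x$labels), n_labels(x)))
  invisible(x)
}

#' Number of labeled objects in a label map
#' @param lm A [label_map()].
#' @return Integer count of distinct nonzero labels.
#' @export
n_labels <- function(lm) {
  stopifnot(inherits(lm, "label_map"))
  length(setdiff(unique(as.vector(lm$labels)), 0L))
}
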