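# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

is_binary_mask <- function(x) {
  is.matrix(x) && (is.logical(x) ||
    (is.numeric(x) && all(x %in% c(0, 1))))
}

as_mask <- function(x, what = "mask") {
  if (!is_binary_mask(x)) {
    stop(sprintf("`%s` must be a binary (logical or 0/1) matrix", what),
         call. = FALSE)
  }
  m <- x != 0
  storage.mode(m) <- "logical"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
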