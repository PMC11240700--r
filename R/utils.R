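## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Deterministic sub-seed derivation: one global seed fans out into named
## stage streams. Kept below 2^31 - 1 (R integers are 32 bit).
derive_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + index) %% 2147483629) + 1L
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

## Trapezoidal rule on a sorted grid.
trapz <- function(x, y) {
  if (length(x) < 2L) stop("need at least two grid points")
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

is_binary_mask <- function(mask) {
  is.array(mask) && length(dim(mask)) == 3L && all(mask %in% c(0, 1))
}
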