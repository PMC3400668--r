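#' @keywords internal
"_PACKAGE"

# Shared argument checks. All user-facing errors go through stop() with
# call. = FALSE so the message, not the internal call, reaches the user.

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("`%s` must be a single non-negative finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Seed the RNG only when the caller asks for reproducibility; leaves the
# global stream untouched otherwise.
maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number or NULL", call. = FALSE)
    }
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
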