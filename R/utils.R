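#' aepkit: auditory evoked-potential analysis for mouse ABR/AEP recordings
#'
#' @keywords internal
"_PACKAGE"

# Input validation helpers --------------------------------------------------

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Round a value to the nearest point on a regular grid
#'
#' @param x numeric vector.
#' @param step grid step (same units as `x`).
#' @return `x` rounded to the nearest multiple of `step`.
#' @keywords internal
round_to_grid <- function(x, step = 5) step * round(x / step)

# Deterministic sub-seed derivation: keeps derived seeds positive and
# below .Machine$integer.max so `set.seed()` accepts them anywhere.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic polynomial rolling hash of a string; used to stamp outputs
# with a config fingerprint without pulling in a digest dependency.
string_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
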