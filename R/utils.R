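# internal helpers shared across modules

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulators are pure functions of
#' `(config, seed)` without clobbering the caller's RNG stream.
#'
#' @param seed integer seed (< 2^31).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  force(code)
}

stop_input <- function(...) {
  stop(..., call. = FALSE)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L) {
    stop_input(name, " must be a numeric scalar")
  }
  if (finite && !is.finite(x)) stop_input(name, " must be finite")
  if (positive && !(x > 0)) stop_input(name, " must be > 0")
  if (nonneg && x < 0) stop_input(name, " must be >= 0")
  invisible(x)
}

# Boltzmann constant in pN nm / K
.kB_pN_nm_per_K <- 0.0138064852
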