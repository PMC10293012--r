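`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

#' Check a probability-like scalar
#' @noRd
check_prob <- function(x, name) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1,
          sprintf("'%s' must be a single probability in [0, 1]", name))
  invisible(x)
}

#' Check a positive integer-like scalar
#' @noRd
check_count <- function(x, name) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x != round(x),
          sprintf("'%s' must be a single positive integer", name))
  invisible(as.integer(x))
}

#' Run code under a local RNG state
#'
#' Saves and restores `.Random.seed` so substream draws do not perturb the
#' caller's RNG, giving each simulator modality an independent reproducible
#' stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
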