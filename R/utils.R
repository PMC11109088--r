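# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulation helpers do not
#' disturb the caller's RNG stream.
#' @param seed integer seed, or NULL to run without touching the RNG
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_qmri <- function(..., class = "qmripd_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_qmri(...)
  invisible(TRUE)
}

# degrees -> radians
deg2rad <- function(deg) deg * pi / 180

# trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
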