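#' Indeterminacy interval
#'
#' Constructs the neutrosophic indeterminacy interval \eqn{[I_L, I_N]}.
#' The lower endpoint corresponds to the classical (crisp) analysis; the
#' degenerate interval \eqn{[0, 0]} recovers classical statistics exactly.
#'
#' @param lower lower indeterminacy \eqn{I_L \ge 0} (dimensionless).
#' @param upper upper indeterminacy \eqn{I_N \ge I_L}.
#' @return An object of class `indet_interval`: numeric of length 2 with
#'   elements `lower` and `upper`.
#' @examples
#' indet_interval(0, 0.05)
#' @export
indet_interval <- function(lower = 0, upper = lower) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L)
  if (!is.finite(lower) || !is.finite(upper) || lower < 0 || upper < lower)
    stop("indeterminacy interval requires 0 <= lower <= upper", call. = FALSE)
  structure(c(lower = lower, upper = upper), class = "indet_interval")
}

#' @export
print.indet_interval <- function(x, ...) {
  cat(sprintf("I_Neu = [%g, %g]\n", x[["lower"]], x[["upper"]]))
  invisible(x)
}

## Coerce user input (scalar, length-2 numeric, or indet_interval) to a
## validated indet_interval.
as_indet <- function(I) {
  if (inherits(I, "indet_interval")) return(I)
  if (is.numeric(I) && length(I) == 1L) return(indet_interval(I, I))
  if (is.numeric(I) && length(I) == 2L) return(indet_interval(I[1L], I[2L]))
  stop("cannot interpret 'I' as an indeterminacy interval", call. = FALSE)
}

## Parameter validation shared by every distribution-facing function.
## lambda, theta: shape parameters (strictly positive); indet: I >= 0.
check_params <- function(lambda, theta, indet) {
  if (!is.numeric(lambda) || !is.numeric(theta) || !is.numeric(indet))
    stop("parameters must be numeric", call. = FALSE)
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("'lambda' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("'theta' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(indet)) || any(indet < 0))
    stop("'indet' must be finite and >= 0", call. = FALSE)
  invisible(TRUE)
}

check_x_positive <- function(x, what = "x") {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be finite and > 0", what), call. = FALSE)
  invisible(TRUE)
}
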