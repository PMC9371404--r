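#' Hill activation
#'
#' Dimensionless Hill activation `x^a / (1 + x^a)`: the occupancy of an
#' operator by an activating transcription factor at concentration `x`,
#' measured in units of its Hill constant (so the half-maximal point is
#' always at `x = 1`). `a` is the Hill coefficient (cooperativity).
#'
#' `hill_act(x, a) + hill_rep(x, a) == 1` for every `x >= 0`.
#'
#' @param x Non-negative numeric vector of (dimensionless) concentrations.
#' @param a Hill coefficient; a single integer `>= 1`. The circuits studied
#'   here only use integer cooperativities, so non-integer values are
#'   rejected rather than silently accepted.
#' @return Numeric vector in `[0, 1)`, strictly increasing in `x`.
#' @seealso [hill_rep()]
#' @examples
#' hill_act(0, 2)   # 0
#' hill_act(1, 3)   # 0.5 at the Hill constant, for every a
#' hill_act(3, 2)   # 9/10
#' @export
hill_act <- function(x, a) {
  check_hill_coef(a)
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop_config("`x` must be a non-negative numeric vector")
  }
  .hill_act(x, a)
}

#' Hill repression
#'
#' Dimensionless Hill repression `1 / (1 + x^a)`: the probability that an
#' operator is free of a repressor at concentration `x` (in units of its
#' Hill constant). Algebraically the complement of [hill_act()].
#'
#' @inheritParams hill_act
#' @return Numeric vector in `(0, 1]`, strictly decreasing in `x`.
#' @examples
#' hill_rep(0, 3)    # 1: no repressor present
#' hill_rep(1, 2)    # 0.5
#' hill_rep(10, 2)   # 1/101
#' @export
hill_rep <- function(x, a) {
  check_hill_coef(a)
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop_config("`x` must be a non-negative numeric vector")
  }
  .hill_rep(x, a)
}

# unchecked kernels used inside RHS evaluations (validation happens once,
# at parameter construction / integrator entry, not per step)
.hill_act <- function(x, a) {
  xa <- x^a
  xa / (1 + xa)
}

.hill_rep <- function(x, a) {
  1 / (1 + x^a)
}

check_hill_coef <- function(a, name = "a") {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) ||
      a < 1 || a != round(a)) {
    stop_config(sprintf(
      "Hill coefficient `%s` must be a single integer >= 1 (got %s)",
      name, deparse(a)
    ))
  }
  invisible(TRUE)
}
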