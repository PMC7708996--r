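#' Payoff constants of the Continuous Prisoner's Dilemma
#'
#' The four corner payoffs of the discrete game: mutual cooperation `C`,
#' temptation `T` (defect against a cooperator), mutual defection `D`, and
#' the sucker payoff `S`. Validity requires the classic ordering
#' `T > C > D > S` together with `2C > T + D` so that sustained mutual
#' cooperation beats alternating exploitation. The defaults (4, 5, 1, 0)
#' satisfy both; note the textbook (3, 5, 1, 0) violates `2C > T + D` and is
#' rejected.
#'
#' @param C,T,D,S Corner payoffs.
#' @return A list of class `payoff_constants`.
#' @export
payoff_constants <- function(C = 4, T = 5, D = 1, S = 0) {
  if (!(T > C && C > D && D > S)) {
    stop("payoff constants must satisfy T > C > D > S", call. = FALSE)
  }
  if (!(2 * C > T + D)) {
    stop("payoff constants must satisfy 2C > T + D", call. = FALSE)
  }
  structure(list(C = C, T = T, D = D, S = S), class = "payoff_constants")
}

#' @export
print.payoff_constants <- function(x, ...) {
  cat(sprintf(
    "<payoff_constants> C=%g T=%g D=%g S=%g\n", x$C, x$T, x$D, x$S
  ))
  invisible(x)
}

#' Expected cooperation of a counterpart
#'
#' The expectation is the arithmetic mean of the counterpart's cooperation
#' levels over the retrieved traces. When nothing was retrieved (first
#' encounter, or total forgetting) the cold-start value is used; `cold_start`
#' may be a fixed level or `"uniform"` for a fresh Uniform(0, 1) draw, the
#' package default (see the methods vignette for why a fixed homogeneous
#' cold start degenerates the dynamics).
#'
#' @param retrieved A trace tibble of retrieved traces (possibly zero rows).
#' @param cold_start Either a number in \[0, 1\] or `"uniform"`.
#' @return Expected cooperation in \[0, 1\].
#' @export
expected_cooperation <- function(retrieved, cold_start = "uniform") {
  if (nrow(retrieved) > 0) {
    return(mean(retrieved$cooperation))
  }
  if (identical(cold_start, "uniform")) {
    stats::runif(1)
  } else {
    check_range(cold_start, 0, 1, "cold_start")
    cold_start
  }
}

#' Cooperation rule
#'
#' An agent cooperates at the level it expects its counterpart to cooperate:
#' the identity map on the expectation. Isolated as its own operation so that
#' alternative strategies could be plugged in.
#'
#' @param expectation Expected counterpart cooperation in \[0, 1\].
#' @return The chosen cooperation level.
#' @export
choose_cooperation <- function(expectation) {
  check_range(expectation, 0, 1, "expectation")
  expectation
}

#' Continuous Prisoner's Dilemma payoff
#'
#' Bilinear interpolation of the discrete payoff matrix: with `cb := 1 - c`,
#' the payoff to self is
#' `c_self*c_other*C + c_self*cb_other*S + cb_self*c_other*T +
#' cb_self*cb_other*D`. The four corners reproduce C, S, T, D exactly.
#'
#' @param c_self,c_other Cooperation levels in \[0, 1\].
#' @param k A [payoff_constants()] object.
#' @return The payoff to self. Vectorised over the cooperation levels.
#' @export
cpd_payoff <- function(c_self, c_other, k = payoff_constants()) {
  check_range(c_self, 0, 1, "c_self")
  check_range(c_other, 0, 1, "c_other")
  c_self * c_other * k$C + c_self * (1 - c_other) * k$S +
    (1 - c_self) * c_other * k$T + (1 - c_self) * (1 - c_other) * k$D
}
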