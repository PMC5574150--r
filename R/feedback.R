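#' Michaelis-Menten feedback factors
#'
#' Cytokine-mediated regulation is modelled with saturating Michaelis-Menten
#' factors. Cytokine concentrations are assumed proportional to the
#' concentration `C` of the cell state that secretes them, so the factors are
#' written directly in terms of cell concentrations.
#'
#' `negative_feedback()` returns `k / (k + C)`, a dimensionless inhibition
#' factor in `(0, 1]`: no regulator means no inhibition, and the factor halves
#' when `C` equals the Michaelis constant `k`. `positive_feedback()` returns
#' the complementary activation factor `C / (k + C)` in `[0, 1)`. For equal
#' arguments the two factors sum to one.
#'
#' @param k Michaelis constant (cells/uL), strictly positive.
#' @param C Regulator cell concentration (cells/uL), non-negative.
#'   Both arguments are vectorised.
#' @return A dimensionless numeric factor (or vector of factors).
#' @examples
#' negative_feedback(10, 10) # half-maximal inhibition: 0.5
#' positive_feedback(2, 6)   # 0.75
#' @export
negative_feedback <- function(k, C) {
  check_feedback_args(k, C)
  k / (k + C)
}

#' @rdname negative_feedback
#' @export
positive_feedback <- function(k, C) {
  check_feedback_args(k, C)
  C / (k + C)
}

check_feedback_args <- function(k, C) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("Michaelis constant `k` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(C)) || any(C < 0)) {
    stop("regulator concentration `C` must be finite and >= 0", call. = FALSE)
  }
  invisible(NULL)
}

#' Asymmetric self-renewal fluxes of a dividing population
#'
#' Progenitor and stem-cell divisions either retain the parent identity
#' (self-renewal, probability `a`) or commit both daughters to the next
#' maturation stage. With mitosis rate `mr` (1/day) and population `X`
#' (cells/uL) the net self-renewal flux is `(2 * a_eff - 1) * mr * X` and the
#' differentiation outflux is `2 * (1 - a_eff) * mr * X`, where
#' `a_eff = a * inhibition` is the feedback-attenuated self-renewal
#' probability. The two fluxes always sum to the total division output
#' `mr * X`, so cell production is conserved.
#'
#' @param a Self-renewal probability in `[0, 1]`.
#' @param mr Mitosis rate (1/day), non-negative.
#' @param X Population concentration (cells/uL), non-negative.
#' @param inhibition Dimensionless feedback factor in `[0, 1]` (default 1).
#' @return A named list with `net` (net self-renewal flux, cells/uL/day; may
#'   be negative when `a_eff < 1/2`) and `out` (differentiation outflux,
#'   cells/uL/day, always non-negative).
#' @examples
#' self_renewal_fluxes(a = 0.5, mr = 1, X = 100)  # symmetric: net 0, out 100
#' self_renewal_fluxes(a = 0.8, mr = 1, X = 100, inhibition = 0.5)
#' @export
self_renewal_fluxes <- function(a, mr, X, inhibition = 1) {
  stopifnot(a >= 0, a <= 1, mr >= 0, X >= 0, inhibition >= 0, inhibition <= 1)
  a_eff <- a * inhibition
  list(
    net = (2 * a_eff - 1) * mr * X,
    out = 2 * (1 - a_eff) * mr * X
  )
}
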