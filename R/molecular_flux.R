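# The erfc-based "molecular flux" description of blood->CSF transfer.
# Kept for comparison and critique: its half-erfc boundary condition pins
# the CSF-side boundary concentration at half the blood concentration for
# all t > 0, which contradicts Fick's first law for this system.  All
# package inference uses the connected steady-state model instead.

#' erfc diffusion profile with a constant-concentration boundary
#'
#' Concentration ratio in a semi-infinite medium whose boundary is held at
#' the source concentration: \eqn{Q(z) = \mathrm{erfc}(z)} with
#' \eqn{z = x / (2\sqrt{Dt})}.  At the boundary (z = 0) the ratio is 1, as
#' a constant-concentration boundary condition requires.
#'
#' @param z Dimensionless similarity argument, >= 0 (CSF side, x > 0).
#' @return Quotient(s) in (0, 1\].
#' @export
mf_q_constant_boundary <- function(z) {
  if (any(!is.finite(z)) || any(z < 0))
    stop("'z' must be finite and non-negative", call. = FALSE)
  pracma::erfc(z)
}

#' Half-erfc diffusion profile (the molecular-flux model)
#'
#' The variant actually used by the molecular-flux theory:
#' \eqn{Q(z) = \frac{1}{2}\mathrm{erfc}(z)}.  Its pathology is visible at
#' z = 0: the boundary concentration is half the blood concentration for
#' all t > 0, so CSF could never equilibrate with blood.
#'
#' @inheritParams mf_q_constant_boundary
#' @return Quotient(s) in (0, 0.5\].
#' @export
#' @examples
#' mf_q_reiber(2.035)   # ~0.002
#' mf_q_reiber(1.45)    # ~0.02
#' mf_q_reiber(0)       # 0.5: the boundary-value pathology
mf_q_reiber <- function(z) {
  0.5 * mf_q_constant_boundary(z)
}

#' Invert the half-erfc profile
#'
#' Solves \eqn{\frac{1}{2}\mathrm{erfc}(z) = q} for z >= 0.  Round-trips
#' with [mf_q_reiber()] to better than 1e-12 on the quotient scale.
#'
#' @param q Quotient(s) in (0, 0.5\].
#' @return Dimensionless argument(s) z >= 0.
#' @export
mf_inverse <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0) || any(q > 0.5))
    stop("'q' must lie in (0, 0.5]: the half-erfc model cannot exceed 0.5",
         call. = FALSE)
  pracma::erfcinv(2 * q)
}

#' Flow-time multiplication factor under the half-erfc model
#'
#' At fixed position x and diffusion coefficient D the similarity argument
#' scales as \eqn{z \propto 1/\sqrt{t}}, so moving from quotient `q_from`
#' to `q_to` implies a flow-time change by \eqn{(z_{from}/z_{to})^2}.  The
#' model's steep erfc tail makes this factor far smaller than the quotient
#' change itself: a ~2x flow-time increase inflates a quotient of 2e-3
#' tenfold, in contrast to the near-proportional small-Q response of the
#' connected steady-state model (see [flow_time_for_q()]).
#'
#' @param q_from,q_to Quotients in (0, 0.5).
#' @return Dimensionless flow-time factor t_to/t_from.
#' @export
#' @examples
#' mf_flow_time_factor(0.002, 0.02)   # ~1.97
mf_flow_time_factor <- function(q_from, q_to) {
  (mf_inverse(q_from) / mf_inverse(q_to))^2
}
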