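#' Steady-state diffusional flux across a planar barrier
#'
#' Flux through a barrier of thickness `l` separating two well-mixed
#' compartments held at concentrations `c1` and `c2`:
#' \deqn{F = D (c_1 - c_2)/l.}
#' The concentration profile inside the barrier is linear at steady state;
#' the sign of the flux follows the gradient direction.
#'
#' @param d Free diffusion coefficient (cm^2/s, >= 0).
#' @param c1,c2 Compartment concentrations (any common unit).
#' @param l Barrier thickness (cm, > 0).
#' @return Flux in concentration-unit * cm/s.
#' @export
planar_flux <- function(d, c1, c2, l) {
  if (any(!is.finite(d)) || any(d < 0))
    stop("'d' must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(l)) || any(l <= 0))
    stop("'l' must be finite and positive", call. = FALSE)
  d * (c1 - c2) / l
}

.check_rate_args <- function(aleph, k_over_l) {
  if (any(!is.finite(aleph)) || any(aleph < 0))
    stop("'aleph' must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(k_over_l)) || any(k_over_l <= 0))
    stop("'k_over_l' must be finite and positive", call. = FALSE)
}

#' Connected steady-state saturation quotient
#'
#' The CSF/serum concentration quotient after flow time `t` under the
#' connected steady-state model:
#' \deqn{Q(t) = 1 - e^{-\aleph k t / L},}
#' where `aleph` = D*B is the exchange coefficient (free diffusion times
#' barrier factor), k a proportionality constant (1/length) and L the
#' barrier thickness.  Two conventions are supported: "fitted" mode with
#' dimensionless `aleph` and `k_over_l = 1` (the convention used when
#' fitting immunoglobulin curves), or physical units via `k_over_l = k/L`.
#'
#' @param t CSF flow time (>= 0; arbitrary units in fitted mode).
#' @param aleph Exchange coefficient (>= 0).
#' @param k_over_l Composite rate constant k/L (> 0, default 1).
#' @return Quotient in \[0, 1), vectorized over any argument.
#' @seealso [steady_state_flux()], [flow_time_for_q()], [cascade_q()]
#' @export
#' @examples
#' steady_state_q(t = 0.5, aleph = 2)      # 1 - exp(-1)
#' steady_state_q(t = 0.00251, aleph = 2)  # a physiological Q_Alb of ~5e-3
steady_state_q <- function(t, aleph, k_over_l = 1) {
  .check_rate_args(aleph, k_over_l)
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and non-negative", call. = FALSE)
  1 - exp(-aleph * k_over_l * t)
}

#' Relative net molecular flux under the connected steady-state model
#'
#' The net diffusional flux from blood into CSF relative to its initial
#' (empty-CSF) value: \eqn{F(t) = e^{-\aleph k t/L} = 1 - Q(t)}.  Back
#' diffusion grows as CSF fills, so the net flux decays toward zero.
#'
#' @inheritParams steady_state_q
#' @return Flux fraction in (0, 1\].
#' @export
steady_state_flux <- function(t, aleph, k_over_l = 1) {
  1 - steady_state_q(t, aleph, k_over_l)
}

#' CSF flow time implied by a quotient
#'
#' Inverse of [steady_state_q()]: \eqn{t = -\ln(1 - Q)/(\aleph k/L)}.
#' In the small-Q regime t is nearly proportional to Q, so a doubling of
#' flow time doubles the albumin quotient; reaching strongly elevated
#' quotients requires disproportionately long flow times.
#'
#' @param q Quotient(s) in \[0, 1).
#' @inheritParams steady_state_q
#' @return Flow time(s), same units as in [steady_state_q()].
#' @export
flow_time_for_q <- function(q, aleph, k_over_l = 1) {
  .check_rate_args(aleph, k_over_l)
  if (any(!is.finite(q)) || any(q < 0) || any(q >= 1))
    stop("'q' must lie in [0, 1): the model saturates at 1", call. = FALSE)
  -log(1 - q) / (aleph * k_over_l)
}

#' Discrete cascade of consecutive steady states
#'
#' Iterates the segment-by-segment recursion that motivates the closed-form
#' saturation law: starting from protein-free CSF, each downstream segment
#' gains concentration proportional to the remaining blood-CSF gradient,
#' \deqn{C(E_{i+1}) = C(E_i) + (\aleph/L)(C_{blood} - C(E_i))/v,}
#' with v the bulk-flow velocity.  The first segment reproduces
#' \eqn{C(E_1) = (\aleph/L) C_{blood}/v}; as the number of segments grows
#' (at fixed total flow time t, i.e. v = n/t) the cascade converges to
#' \eqn{Q(t) = 1 - e^{-\aleph t/L}}, providing a numerical check on the
#' closed form.
#'
#' @param aleph Exchange coefficient (>= 0).
#' @param v Bulk-flow velocity (> 0), in units such that aleph/(L v) is the
#'   per-segment transfer fraction.
#' @param c_blood Blood concentration (default 1).
#' @param n_segments Number of segments (>= 1).
#' @param l Barrier thickness (default 1, fitted mode).
#' @return Numeric vector `Q[i] = C(E_i)/c_blood`, length `n_segments`.
#' @export
#' @examples
#' # cascade at total flow time t = 0.5 with 1e4 segments vs closed form
#' q <- cascade_q(aleph = 2, v = 1e4 / 0.5, n_segments = 1e4)
#' c(tail(q, 1), steady_state_q(0.5, 2))
cascade_q <- function(aleph, v, c_blood = 1, n_segments, l = 1) {
  if (length(n_segments) != 1L || n_segments < 1 ||
      n_segments != as.integer(n_segments))
    stop("'n_segments' must be a positive integer", call. = FALSE)
  if (!is.finite(v) || v <= 0)
    stop("'v' must be finite and positive", call. = FALSE)
  if (!is.finite(aleph) || aleph < 0)
    stop("'aleph' must be finite and non-negative", call. = FALSE)
  if (!is.finite(l) || l <= 0)
    stop("'l' must be finite and positive", call. = FALSE)
  delta <- aleph / (l * v)   # per-segment transfer fraction
  # Q_i = 1 - (1 - delta)^i, computed in closed form for stability
  i <- seq_len(n_segments)
  q <- 1 - (1 - delta)^i
  if (delta > 1) q <- pmin(q, 1)  # coarse discretizations cannot overshoot
  q
}

#' Stokes-Einstein free diffusion coefficient
#'
#' \deqn{D = k_B T / (6\pi\eta R_H).}
#' Defaults describe water at body temperature (T = 310.15 K, viscosity
#' 6.9e-4 Pa s).  Only diffusion-coefficient *ratios* between molecules in
#' the same fluid are anchored quantities; absolute values depend on the
#' chosen temperature and viscosity.
#'
#' @param r_h Hydrodynamic radius in nm (> 0), vectorized.
#' @param temperature Absolute temperature in K.
#' @param viscosity Dynamic viscosity in Pa s.
#' @return Diffusion coefficient(s) in cm^2/s.
#' @export
#' @examples
#' stokes_einstein_d(3.51) / stokes_einstein_d(5.29)  # = 5.29/3.51
stokes_einstein_d <- function(r_h, temperature = 310.15,
                              viscosity = 6.9e-4) {
  if (any(!is.finite(r_h)) || any(r_h <= 0))
    stop("'r_h' must be finite and positive (nm)", call. = FALSE)
  if (!is.finite(temperature) || temperature <= 0 ||
      !is.finite(viscosity) || viscosity <= 0)
    stop("temperature and viscosity must be positive", call. = FALSE)
  k_b <- 1.380649e-23                       # J/K
  d_m2s <- k_b * temperature / (6 * pi * viscosity * r_h * 1e-9)
  d_m2s * 1e4                               # m^2/s -> cm^2/s
}

#' Barrier-factor quotient from exchange-coefficient and radius ratios
#'
#' Because aleph = D*B and D is inversely proportional to the hydrodynamic
#' radius, the exchange-coefficient quotient of a reference molecule to a
#' test molecule factorizes as
#' \deqn{\aleph_{ref}/\aleph_x = (R_H(x)/R_H(ref)) \cdot (B_{ref}/B_x).}
#' This function divides the radius ratio out, returning the barrier-factor
#' quotient B_ref/B_x.  A value of 1 means the barrier discriminates the
#' two molecules exactly in proportion to their free diffusion; values > 1
#' mean extra, size-selective attenuation of the larger molecule.
#'
#' @param aleph_ratio aleph_ref/aleph_x (> 0).
#' @param rh_ratio R_H(x)/R_H(ref) (> 0).
#' @return B_ref/B_x, dimensionless.
#' @export
#' @examples
#' barrier_quotient(2 / 1.23, 5.29 / 3.51)  # albumin vs IgG, ~1.08
barrier_quotient <- function(aleph_ratio, rh_ratio) {
  if (any(!is.finite(aleph_ratio)) || any(aleph_ratio <= 0) ||
      any(!is.finite(rh_ratio)) || any(rh_ratio <= 0))
    stop("ratios must be finite and positive", call. = FALSE)
  aleph_ratio / rh_ratio
}

#' Infer an in-vivo hydrodynamic radius from exchange-coefficient ratios
#'
#' Under the assumption of equal barrier factors, the exchange-coefficient
#' quotient against a reference protein of known radius gives the test
#' protein's effective in-vivo hydrodynamic radius:
#' \eqn{R_H(x) = R_H(ref) \cdot (\aleph_{ref}/\aleph_x)}.  If the barrier
#' ratio B_ref/B_x is known it is divided out instead of assumed to be 1.
#'
#' @param aleph_ratio aleph_ref/aleph_x (> 0).
#' @param reference_rh Reference hydrodynamic radius in nm.
#' @param assume_equal_b If `TRUE` (default) take B_ref/B_x = 1.
#' @param barrier_ratio B_ref/B_x; required when `assume_equal_b = FALSE`.
#' @return Inferred hydrodynamic radius in nm.
#' @export
#' @examples
#' infer_rh(5.29 / 3.51, 3.51)   # recovers 5.29 when B ratio is 1
infer_rh <- function(aleph_ratio, reference_rh, assume_equal_b = TRUE,
                     barrier_ratio = NULL) {
  if (any(!is.finite(aleph_ratio)) || any(aleph_ratio <= 0))
    stop("'aleph_ratio' must be finite and positive", call. = FALSE)
  if (!is.finite(reference_rh) || reference_rh <= 0)
    stop("'reference_rh' must be finite and positive", call. = FALSE)
  if (assume_equal_b) {
    if (!is.null(barrier_ratio))
      warning("'barrier_ratio' ignored because assume_equal_b = TRUE",
              call. = FALSE)
    barrier_ratio <- 1
  } else if (is.null(barrier_ratio)) {
    stop("'barrier_ratio' is required when assume_equal_b = FALSE",
         call. = FALSE)
  }
  reference_rh * aleph_ratio / barrier_ratio
}

#' Packaged reference molecule table
#'
#' The four reference molecules with measured hydrodynamic radii (IgA as
#' the monomeric variant) and the dimensionless exchange coefficients
#' obtained by fitting the saturation model to the mean hyperbolic curves
#' with anchors aleph(albumin) = 2 and k/L = 1.
#'
#' @return A data.frame with columns `name`, `r_h_nm`, `aleph_fitted`.
#' @export
csf_molecules <- function() {
  m <- .csfq_defaults("molecules")$molecules
  data.frame(name = vapply(m, `[[`, "", "name"),
             r_h_nm = vapply(m, `[[`, 0, "r_h_nm"),
             aleph_fitted = vapply(m, `[[`, 0, "aleph_fitted"),
             stringsAsFactors = FALSE)
}
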