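#' CSF flow-path geometry
#'
#' Geometry and rate defaults for order-of-magnitude transport estimates:
#' a 50 cm flow path from ventricle vault to lumbar sac, 100 ml of CSF
#' (cranial subarachnoid volume ignored), production at 0.3 ml/min, and a
#' representative protein diffusion coefficient of 1e-6 cm^2/s.
#'
#' @param l_fp Flow-path length in cm.
#' @param v_csf CSF volume in ml.
#' @param production_rate CSF production rate in ml/min.
#' @param d_protein Protein free diffusion coefficient in cm^2/s.
#' @return An object of class `flow_geometry`.
#' @export
flow_geometry <- function(l_fp = 50, v_csf = 100, production_rate = 0.3,
                          d_protein = 1e-6) {
  vals <- c(l_fp = l_fp, v_csf = v_csf, production_rate = production_rate,
            d_protein = d_protein)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all flow-geometry values must be finite and positive",
         call. = FALSE)
  structure(as.list(vals), class = "flow_geometry")
}

#' @export
print.flow_geometry <- function(x, ...) {
  cat(sprintf(
    "CSF flow geometry: L_FP = %g cm, V_CSF = %g ml, production = %g ml/min, D = %g cm^2/s\n",
    x$l_fp, x$v_csf, x$production_rate, x$d_protein))
  cat(sprintf("  bulk-flow velocity = %g cm/s, Peclet = %.3g\n",
              bulk_flow_velocity(x),
              peclet(bulk_flow_velocity(x), x$l_fp, x$d_protein)))
  invisible(x)
}

#' Bulk-flow velocity of CSF
#'
#' Treating the CSF space as a tube of constant cross-section carrying the
#' full production rate, the mean bulk-flow velocity is
#' `production_rate * l_fp / v_csf`, converted to cm/s.  With the default
#' geometry this is 0.15 cm/min = 0.0025 cm/s.
#'
#' @param g A [flow_geometry()].
#' @return Velocity in cm/s.
#' @export
bulk_flow_velocity <- function(g = flow_geometry()) {
  if (!inherits(g, "flow_geometry"))
    stop("'g' must be a flow_geometry", call. = FALSE)
  g$production_rate * g$l_fp / g$v_csf / 60
}

#' Peclet number
#'
#' Ratio of advective to diffusive transport, Pe = v*l/d.  For the default
#' CSF geometry Pe = 1.25e5 >> 1: bulk flow dominates and diffusional
#' fluxes inside the CSF space along the flow axis can be neglected.
#'
#' @param v Velocity in cm/s.
#' @param l Length scale in cm.
#' @param d Diffusion coefficient in cm^2/s.
#' @return Dimensionless Peclet number.
#' @export
#' @examples
#' peclet(bulk_flow_velocity(), 50, 1e-6)   # 1.25e5
peclet <- function(v, l, d) {
  if (any(!is.finite(c(v, l, d))) || any(c(v, l, d) <= 0))
    stop("'v', 'l' and 'd' must be finite and positive", call. = FALSE)
  v * l / d
}

#' Mean residence time of a CSF compartment
#'
#' Compartment volume divided by production (throughput) rate.  With ~25 ml
#' of ventricular CSF at 0.4 ml/min this is ~1 h; the ~125 ml subarachnoid
#' space gives ~5 h.
#'
#' @param volume Compartment volume in ml.
#' @param production_rate Throughput in ml/min.
#' @return Residence time in minutes.
#' @export
residence_time <- function(volume, production_rate) {
  if (any(!is.finite(c(volume, production_rate))) ||
      any(c(volume, production_rate) <= 0))
    stop("'volume' and 'production_rate' must be positive", call. = FALSE)
  volume / production_rate
}

#' Classify a rostrocaudal concentration gradient by protein source
#'
#' Blood-derived proteins accumulate along the CSF flow path, so their
#' upstream/downstream (ventricular/lumbar, or first/last serial fraction)
#' concentration ratio is well below 1 (~0.4-0.63 for albumin).
#' Brain-derived proteins enter mostly cranially and stay roughly constant
#' (ratio ~1).  Strongly elevated upstream ratios (e.g. intracellular
#' proteins released by surgical interference) are flagged separately.
#'
#' @param upstream_conc,downstream_conc Positive concentrations, or pass
#'   `ratio` directly.
#' @param ratio Upstream/downstream ratio; computed from the concentrations
#'   when omitted.
#' @param thresholds Named numeric with elements `blood_max` (default
#'   0.75), `brain_max` (1.3) and `elevated_min` (2): ratios below
#'   `blood_max` are `"blood_derived_pattern"`, in `[blood_max, brain_max]`
#'   `"brain_derived_pattern"`, above `elevated_min`
#'   `"elevated_upstream_flag"`, anything else `"indeterminate"`.
#' @return Character vector of source classes (a total, deterministic
#'   partition of the positive ratios).
#' @export
#' @examples
#' classify_gradient(ratio = c(0.56, 1.01, 6.83))
classify_gradient <- function(upstream_conc = NULL, downstream_conc = NULL,
                              ratio = NULL,
                              thresholds = c(blood_max = 0.75,
                                             brain_max = 1.3,
                                             elevated_min = 2)) {
  if (is.null(ratio)) {
    if (is.null(upstream_conc) || is.null(downstream_conc))
      stop("supply either 'ratio' or both concentrations", call. = FALSE)
    if (any(!is.finite(c(upstream_conc, downstream_conc))) ||
        any(c(upstream_conc, downstream_conc) <= 0))
      stop("concentrations must be finite and positive", call. = FALSE)
    ratio <- upstream_conc / downstream_conc
  }
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("'ratio' must be finite and positive", call. = FALSE)
  th <- thresholds
  if (!all(c("blood_max", "brain_max", "elevated_min") %in% names(th)) ||
      th[["blood_max"]] >= th[["brain_max"]] ||
      th[["brain_max"]] > th[["elevated_min"]])
    stop("thresholds must satisfy blood_max < brain_max <= elevated_min",
         call. = FALSE)
  ifelse(ratio < th[["blood_max"]], "blood_derived_pattern",
  ifelse(ratio <= th[["brain_max"]], "brain_derived_pattern",
  ifelse(ratio > th[["elevated_min"]], "elevated_upstream_flag",
         "indeterminate")))
}
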