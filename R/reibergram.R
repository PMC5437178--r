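#' Hyperbolic discrimination-curve parameters
#'
#' Constructs the parameter triplet of a hyperbolic quotient curve
#' \deqn{Q_{IgX}(Q_{Alb}) = (a/b)\sqrt{Q_{Alb}^2 + b^2} - c.}
#' All three parameters are dimensionless and expressed on the absolute
#' quotient scale (no 1e-3 / 1e-6 table scalings).
#'
#' @param a_over_b Asymptotic slope ratio a/b (> 0).
#' @param b_sq Squared quotient offset b^2 (> 0).
#' @param c Quotient intercept shift c (>= 0).
#' @return An object of class `hyperbolic_params`.
#' @seealso [hyperbolic_q()], [reibergram_family()]
#' @export
#' @examples
#' igg_mean <- hyperbolic_params(0.65, 8e-6, 1.4e-3)
#' hyperbolic_q(5e-3, igg_mean)
hyperbolic_params <- function(a_over_b, b_sq, c) {
  stopifnot(is.numeric(a_over_b), length(a_over_b) == 1L,
            is.numeric(b_sq), length(b_sq) == 1L,
            is.numeric(c), length(c) == 1L)
  if (!is.finite(a_over_b) || a_over_b <= 0)
    stop("'a_over_b' must be a positive finite number", call. = FALSE)
  if (!is.finite(b_sq) || b_sq <= 0)
    stop("'b_sq' must be a positive finite number", call. = FALSE)
  if (!is.finite(c) || c < 0)
    stop("'c' must be a non-negative finite number", call. = FALSE)
  structure(list(a_over_b = a_over_b, b_sq = b_sq, c = c),
            class = "hyperbolic_params")
}

#' @export
print.hyperbolic_params <- function(x, ...) {
  cat(sprintf("Hyperbolic curve: Q = %.3g * sqrt(Q_Alb^2 + %.3g) - %.3g\n",
              x$a_over_b, x$b_sq, x$c))
  invisible(x)
}

#' Evaluate a hyperbolic quotient curve
#'
#' Computes the expected immunoglobulin quotient Q_IgX at given albumin
#' quotients Q_Alb under the hyperbolic reference relation.  Lower-limit
#' parameter sets can yield slightly negative values at very small Q_Alb;
#' these are returned as-is (plotting code may clamp them for display).
#'
#' @param q_alb Numeric vector of albumin quotients (>= 0, dimensionless).
#' @param params A [hyperbolic_params()] object.
#' @return Numeric vector of quotients, same length as `q_alb`.
#' @export
hyperbolic_q <- function(q_alb, params) {
  if (!inherits(params, "hyperbolic_params"))
    stop("'params' must be a hyperbolic_params object", call. = FALSE)
  if (!is.numeric(q_alb) || any(!is.finite(q_alb)) || any(q_alb < 0))
    stop("'q_alb' must be finite and non-negative", call. = FALSE)
  params$a_over_b * sqrt(q_alb^2 + params$b_sq) - params$c
}

#' Reibergram curve family for one immunoglobulin
#'
#' Bundles the upper discrimination, mean, and lower discrimination
#' hyperbolic curves of one analyte, together with the albumin-quotient
#' window over which the curves were calibrated.  Validity requires
#' upper > mean > lower throughout the window.
#'
#' @param analyte Analyte name, one of `"IgG"`, `"IgA"`, `"IgM"` (other
#'   identifiers are allowed for user-supplied curve sets).
#' @param upper,mean,lower [hyperbolic_params()] objects for the three curves.
#' @param q_alb_range Length-2 numeric, calibrated Q_Alb window
#'   (default `c(2e-3, 0.15)`).
#' @return An object of class `reibergram_family`.
#' @export
#' @examples
#' fam <- reibergram_families()$IgG
#' variation_coefficient(fam, 2.2e-3)
reibergram_family <- function(analyte, upper, mean, lower,
                              q_alb_range = c(2e-3, 0.15)) {
  stopifnot(is.character(analyte), length(analyte) == 1L)
  for (p in list(upper, mean, lower))
    if (!inherits(p, "hyperbolic_params"))
      stop("curves must be hyperbolic_params objects", call. = FALSE)
  if (!is.numeric(q_alb_range) || length(q_alb_range) != 2L ||
      q_alb_range[1] <= 0 || q_alb_range[2] <= q_alb_range[1])
    stop("'q_alb_range' must be an increasing positive pair", call. = FALSE)
  fam <- structure(list(analyte = analyte, upper = upper, mean = mean,
                        lower = lower, q_alb_range = q_alb_range),
                   class = "reibergram_family")
  # ordering check on a dense grid across the calibrated window
  grid <- seq(q_alb_range[1], q_alb_range[2], length.out = 101L)
  up <- hyperbolic_q(grid, upper)
  mid <- hyperbolic_q(grid, mean)
  lo <- hyperbolic_q(grid, lower)
  if (any(up <= mid) || any(mid <= lo))
    stop("curve ordering upper > mean > lower violated inside q_alb_range",
         call. = FALSE)
  fam
}

#' @export
print.reibergram_family <- function(x, ...) {
  cat(sprintf("Reibergram family '%s' on Q_Alb in [%.3g, %.3g]\n",
              x$analyte, x$q_alb_range[1], x$q_alb_range[2]))
  for (nm in c("upper", "mean", "lower")) {
    p <- x[[nm]]
    cat(sprintf("  %-5s a/b = %.3g, b_sq = %.3g, c = %.3g\n",
                nm, p$a_over_b, p$b_sq, p$c))
  }
  invisible(x)
}

#' Packaged Reibergram curve families
#'
#' Returns the packaged hyperbolic curve families for IgG, IgA and IgM
#' (upper/mean/lower discrimination curves from the published 4254-patient
#' reference population), loaded from `reibergram_params.json`.
#'
#' @return Named list of [reibergram_family()] objects.
#' @export
reibergram_families <- function() {
  defs <- .csfq_defaults("reibergram")
  out <- lapply(names(defs$families), function(an) {
    f <- defs$families[[an]]
    reibergram_family(
      analyte = an,
      upper = hyperbolic_params(f$upper$a_over_b, f$upper$b_sq, f$upper$c),
      mean = hyperbolic_params(f$mean$a_over_b, f$mean$b_sq, f$mean$c),
      lower = hyperbolic_params(f$lower$a_over_b, f$lower$b_sq, f$lower$c),
      q_alb_range = as.numeric(defs$q_alb_range))
  })
  names(out) <- names(defs$families)
  out
}

#' Published population variation-coefficient grid
#'
#' The reference grid of population variation coefficients
#' (upper - lower)/mean at tabulated Q_Alb values, as published.  Used as
#' the regression anchor for the packaged curve parameters.
#'
#' @return A data.frame with columns `q_alb`, `IgG`, `IgA`, `IgM`.
#' @export
variation_grid <- function() {
  g <- .csfq_defaults("reibergram")$variation_grid
  data.frame(q_alb = as.numeric(g$q_alb), IgG = as.numeric(g$IgG),
             IgA = as.numeric(g$IgA), IgM = as.numeric(g$IgM))
}

#' Population variation coefficient of a curve family
#'
#' The spread of the reference population at a given albumin quotient,
#' defined as (upper(Q_Alb) - lower(Q_Alb)) / mean(Q_Alb).
#'
#' @param family A [reibergram_family()].
#' @param q_alb Numeric vector of albumin quotients.
#' @return Numeric vector of dimensionless variation coefficients.
#' @export
variation_coefficient <- function(family, q_alb) {
  if (!inherits(family, "reibergram_family"))
    stop("'family' must be a reibergram_family", call. = FALSE)
  m <- hyperbolic_q(q_alb, family$mean)
  if (any(m <= 0))
    stop("mean curve is non-positive at the requested q_alb; ",
         "variation coefficient undefined", call. = FALSE)
  (hyperbolic_q(q_alb, family$upper) - hyperbolic_q(q_alb, family$lower)) / m
}

#' Classify patient quotients against Reibergram discrimination limits
#'
#' Positions each patient's immunoglobulin quotient relative to the upper
#' and lower discrimination curves at that patient's Q_Alb.  Values above
#' the upper curve indicate an additional, typically intrathecal, source of
#' the immunoglobulin; values below the lower curve are outside the
#' reference population in the other direction.
#'
#' @param records A data.frame with columns `id`, `q_alb` and at least one
#'   of `q_igg`, `q_iga`, `q_igm` (absolute dimensionless fractions), e.g.
#'   from [read_quotient_table()] or [simulate_cohort()].
#' @param families Named list of [reibergram_family()] objects; defaults to
#'   the packaged curves.  Family names must match analyte column suffixes
#'   case-insensitively (`IgG` -> `q_igg`).
#' @param warn_outside_range Warn (once) when a record's Q_Alb lies outside
#'   the calibrated window; the record is still classified.
#' @return A data.frame of class `reibergram_classification` with one row
#'   per (record, analyte): `id`, `analyte`, `q_alb`, `observed_q`, `band`
#'   (`"above_upper"`, `"within_reference"`, `"below_lower"`, or
#'   `"missing"`), the three curve values `limit_q_lower`, `mean_q`,
#'   `limit_q_upper`, `ratio_to_mean`, and `in_calibrated_range`.
#' @export
#' @examples
#' rec <- data.frame(id = "p1", q_alb = 5e-3, q_igg = 4e-3)
#' classify_quotients(rec)
classify_quotients <- function(records, families = reibergram_families(),
                               warn_outside_range = TRUE) {
  records <- validate_quotient_records(records)
  rows <- list()
  n_outside <- 0L
  for (an in names(families)) {
    fam <- families[[an]]
    col <- paste0("q_", tolower(an))
    if (!col %in% names(records)) next
    qa <- records$q_alb
    obs <- records[[col]]
    up <- hyperbolic_q(qa, fam$upper)
    mid <- hyperbolic_q(qa, fam$mean)
    lo <- hyperbolic_q(qa, fam$lower)
    band <- ifelse(is.na(obs), "missing",
            ifelse(obs > up, "above_upper",
            ifelse(obs < lo, "below_lower", "within_reference")))
    in_range <- qa >= fam$q_alb_range[1] & qa <= fam$q_alb_range[2]
    n_outside <- n_outside + sum(!in_range)
    rows[[an]] <- data.frame(
      id = records$id, analyte = an, q_alb = qa, observed_q = obs,
      band = band, limit_q_lower = lo, mean_q = mid, limit_q_upper = up,
      ratio_to_mean = obs / mid, in_calibrated_range = in_range,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("no immunoglobulin quotient columns matching the supplied families",
         call. = FALSE)
  if (warn_outside_range && n_outside > 0L)
    warning(sprintf(
      "%d classification(s) at Q_Alb beyond the calibrated range; results extrapolate the hyperbolic curves",
      n_outside), call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("reibergram_classification", "data.frame")
  out
}

#' Plot a Reibergram
#'
#' Draws the log-log quotient diagram of one analyte: the three hyperbolic
#' curves over the calibrated window, optionally overlaid with patient
#' points.  Negative lower-curve values (possible at the smallest Q_Alb)
#' are clamped to the plotting floor for display only.
#'
#' @param family A [reibergram_family()].
#' @param records Optional data.frame of patient records (see
#'   [classify_quotients()]).
#' @param n Number of curve evaluation points.
#' @return A ggplot object.
#' @export
plot_reibergram <- function(family, records = NULL, n = 300L) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_reibergram requires the 'ggplot2' package", call. = FALSE)
  rng <- family$q_alb_range
  qa <- exp(seq(log(rng[1]), log(rng[2]), length.out = n))
  floor_q <- 1e-5
  curves <- do.call(rbind, lapply(c("upper", "mean", "lower"), function(nm) {
    data.frame(q_alb = qa, curve = nm,
               q_igx = pmax(hyperbolic_q(qa, family[[nm]]), floor_q))
  }))
  p <- ggplot2::ggplot(curves,
         ggplot2::aes(x = q_alb, y = q_igx, linetype = curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Q[Alb]),
                  y = bquote(Q[.(family$analyte)]),
                  title = paste("Reibergram:", family$analyte)) +
    ggplot2::theme_minimal()
  if (!is.null(records)) {
    col <- paste0("q_", tolower(family$analyte))
    if (col %in% names(records)) {
      pts <- data.frame(q_alb = records$q_alb, q_igx = records[[col]])
      pts <- pts[stats::complete.cases(pts), , drop = FALSE]
      p <- p + ggplot2::geom_point(
        data = pts, ggplot2::aes(x = q_alb, y = q_igx),
        inherit.aes = FALSE, alpha = 0.5, size = 0.8)
    }
  }
  p
}
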