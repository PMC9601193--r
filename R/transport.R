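#' Construct a transwell transport time series
#'
#' Receiver-compartment concentration measurements over time for one
#' transport direction, with the assay geometry needed to convert the
#' concentration slope into an apparent permeability.
#'
#' @param times sampling times (s), strictly increasing, first >= 0.
#' @param receiver_concentration receiver concentrations (umol/L), >= 0.
#' @param c0 initial donor concentration (umol/L), > 0.
#' @param vr receiver-chamber volume (mL), > 0.
#' @param area effective insert area (cm2), > 0; 0.11 cm2 for a 96-well
#'   Transwell insert.
#' @param direction `"AtoB"` (apical to basolateral) or `"BtoA"`.
#' @return List of class `"transport_series"`.
#' @export
transport_series <- function(times, receiver_concentration, c0, vr = 0.3,
                             area = 0.11, direction = c("AtoB", "BtoA")) {
  direction <- match.arg(direction)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(times) != length(receiver_concentration)) {
    stop("times and concentrations differ in length")
  }
  if (any(receiver_concentration < 0)) stop("receiver concentrations must be >= 0")
  if (c0 <= 0 || vr <= 0 || area <= 0) stop("assay geometry must be positive")
  structure(list(times = as.numeric(times),
                 receiver_concentration = as.numeric(receiver_concentration),
                 c0 = c0, vr = vr, area = area, direction = direction),
            class = "transport_series")
}

#' @export
print.transport_series <- function(x, ...) {
  cat(sprintf("transport series (%s): %d time points over %.0f s, C0 = %g uM, Vr = %g mL, A = %g cm2\n",
              x$direction, length(x$times), max(x$times), x$c0, x$vr, x$area))
  invisible(x)
}

#' Apparent permeability from a transport series
#'
#' `Papp = (dQ/dt x Vr) / (C0 x A)` in cm/s, with `dQ/dt` the
#' least-squares slope (umol/L/s) of receiver concentration versus time
#' over the linear window. The window is the set of points where the
#' receiver concentration stays below 10% of `C0` (sink conditions);
#' when fewer than 3 points qualify, all points are used. Since
#' 1 mL = 1 cm3, the units reduce to cm/s without further conversion.
#'
#' @param series a [transport_series()] with >= 3 time points.
#' @param sink_fraction sink-condition cut-off as a fraction of `c0`.
#' @param slope_tolerance negative slopes smaller in magnitude than this
#'   (umol/L/s) are clamped to zero; larger negative slopes return 0
#'   with a warning.
#' @return Apparent permeability (cm/s).
#' @export
papp <- function(series, sink_fraction = 0.1, slope_tolerance = 1e-12) {
  stopifnot(inherits(series, "transport_series"))
  if (length(series$times) < 3) stop("need at least 3 time points")
  in_window <- series$receiver_concentration < sink_fraction * series$c0
  use <- if (sum(in_window) >= 3) in_window else rep(TRUE, length(series$times))
  t <- series$times[use]
  conc <- series$receiver_concentration[use]
  if (length(unique(t)) < 2) stop("degenerate linear window: need >= 2 distinct times")
  slope <- unname(stats::coef(stats::lm(conc ~ t))[2])
  if (slope < 0) {
    if (abs(slope) > slope_tolerance) {
      warning(sprintf("negative fitted slope (%.3g); returning Papp = 0", slope))
    }
    return(0)
  }
  slope * series$vr / (series$c0 * series$area)
}

#' Efflux ratio
#'
#' `Papp(B to A) / Papp(A to B)`. A ratio well above 1 indicates active
#' apical efflux.
#'
#' @param papp_ab apical-to-basolateral permeability (cm/s), > 0.
#' @param papp_ba basolateral-to-apical permeability (cm/s), >= 0.
#' @return Dimensionless efflux ratio.
#' @export
efflux_ratio <- function(papp_ab, papp_ba) {
  if (papp_ab <= 0) stop("Papp(A to B) must be > 0; efflux ratio undefined")
  papp_ba / papp_ab
}

#' Percent reduction of the efflux ratio by an inhibitor
#'
#' `100 * (ER_control - ER_inhibited) / ER_control`; an increase in the
#' efflux ratio yields a negative percentage, returned as-is.
#'
#' @param er_control efflux ratio without inhibitor, > 0.
#' @param er_inhibited efflux ratio with inhibitor.
#' @return Percent reduction (signed).
#' @export
efflux_inhibition <- function(er_control, er_inhibited) {
  if (er_control <= 0) stop("control efflux ratio must be > 0")
  100 * (er_control - er_inhibited) / er_control
}
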