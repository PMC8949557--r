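#' Dryer geometry
#'
#' Section volumes of the six-section continuous mixed-flow dryer. For the
#' equivalent-accumulated-temperature model the grain bed is accounted in
#' four zones: upper drying; middle drying + tempering; lower drying +
#' tempering; cooling + discharge. Defaults are the reference test dryer.
#'
#' @param Vg1 Upper drying section volume, litres.
#' @param Vg2h1 Middle drying + tempering section volume, litres.
#' @param Vg3h2 Lower drying + tempering section volume, litres.
#' @param Vl Cooling section volume, litres.
#' @param Vpp Discharge section volume, litres.
#' @param Vp Grain volume discharged per discharge-wheel rotation, litres.
#' @return An object of class `dryer_geometry`.
#' @export
dryer_geometry <- function(Vg1 = 92.382, Vg2h1 = 107.971, Vg3h2 = 107.971,
                           Vl = 92.382, Vpp = 69.027, Vp = 8.0) {
  v <- c(Vg1 = Vg1, Vg2h1 = Vg2h1, Vg3h2 = Vg3h2, Vl = Vl, Vpp = Vpp, Vp = Vp)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop_eatdry("eatdry_config", "all dryer volumes must be positive and finite")
  }
  structure(as.list(v), class = "dryer_geometry")
}

#' @export
print.dryer_geometry <- function(x, ...) {
  cat(sprintf(
    "Dryer geometry (L): upper %.3f | middle %.3f | lower %.3f | cooling %.3f | discharge %.3f | per-discharge %.3f\n",
    x$Vg1, x$Vg2h1, x$Vg3h2, x$Vl, x$Vpp, x$Vp))
  cat(sprintf("  total bed volume %.3f L\n", total_bed_volume(x)))
  invisible(x)
}

#' Total grain bed volume of a dryer
#'
#' @param geom A [dryer_geometry()].
#' @return Total bed volume in litres (all sections, discharge wheel excluded).
#' @export
total_bed_volume <- function(geom) {
  stopifnot(inherits(geom, "dryer_geometry"))
  geom$Vg1 + geom$Vg2h1 + geom$Vg3h2 + geom$Vl + geom$Vpp
}

#' Accumulated temperature of a temperature trace
#'
#' Discretises the integral of the grain temperature excess over the
#' desorption equilibrium temperature, `integral (T - Te) dt`, with a
#' left-rectangle rule. Only heating above the equilibrium temperature
#' accumulates: negative increments are clipped to zero (cooling does not
#' erase drying history).
#'
#' @param t Sample times in minutes, strictly increasing, length >= 2.
#' @param T Grain temperature at each sample, degrees C.
#' @param Te Equilibrium temperature, degrees C; scalar or per-sample vector.
#' @return Accumulated temperature in degree-minutes.
#' @examples
#' accumulated_temperature(c(0, 100), c(60, 60), Te = 25)  # 3500
#' @export
accumulated_temperature <- function(t, T, Te) {
  if (length(t) < 2) stop_eatdry("eatdry_domain", "at least 2 samples required")
  if (length(T) != length(t)) stop_eatdry("eatdry_domain", "t and T lengths differ")
  if (any(diff(t) <= 0)) stop_eatdry("eatdry_domain", "sample times must be strictly increasing")
  Te <- rep_len(Te, length(t))
  inc <- pmax(T - Te, 0)
  sum(inc[-length(t)] * diff(t))
}

#' Theoretical accumulated temperature for a drying task
#'
#' Combines the thin-layer inverse model with the tempering-time correction:
#' the drying time to reach the target moisture (hours, tempering excluded)
#' is stretched by `60 (1 + gamma)` into total process minutes, and
#' multiplied by the driving temperature difference:
#' \deqn{AT_0 = (T_f - T_e)\; 60 (1+\gamma)\; t(M_t)}
#' This is the initial window area used by window selection.
#'
#' @param params [thinlayer_params()] describing the grain.
#' @param Tf Drying (hot-air) temperature, degrees C; must exceed `Te`.
#' @param Te Desorption equilibrium temperature, degrees C.
#' @param Mt Target moisture, percent dry basis.
#' @param M0 Initial moisture, percent dry basis.
#' @param Me Equilibrium moisture, percent dry basis.
#' @param gamma Tempering ratio (tempering time / drying time).
#' @return Theoretical accumulated temperature, degree-minutes.
#' @export
theoretical_at <- function(params, Tf, Te, Mt, M0, Me, gamma = 0) {
  if (Tf <= Te) stop_eatdry("eatdry_domain", "drying temperature Tf must exceed Te")
  if (gamma < 0) stop_eatdry("eatdry_domain", "tempering ratio gamma must be >= 0")
  t_h <- time_for_moisture(params, Mt = Mt, M0 = M0, Me = Me)
  (Tf - Te) * 60 * (1 + gamma) * t_h
}

#' Discharge counts needed to empty each accounting zone
#'
#' Number of discharge events for all grain in each of the four
#' accumulated-temperature zones to pass out, i.e. zone volume divided by the
#' per-discharge volume, reported to one decimal as in dryer commissioning
#' practice. With the default geometry this gives 11.5, 13.5, 13.5 and 20.2
#' (the last combining cooling + discharge sections).
#'
#' @param geom A [dryer_geometry()].
#' @return Named numeric vector `c(c1, c2, c3, c4)`, one decimal place.
#' @export
section_pass_counts <- function(geom) {
  stopifnot(inherits(geom, "dryer_geometry"))
  round(c(c1 = geom$Vg1, c2 = geom$Vg2h1, c3 = geom$Vg3h2,
          c4 = geom$Vl + geom$Vpp) / geom$Vp, 1)
}

# Reference-dryer zone weights as printed in the published closed-form EAT
# formula: 11.5 on the upper zone, 27 on EACH of the middle and lower zone
# excesses (the formula multiplies their SUM by the combined count
# 13.5 + 13.5 = 27), and 21.2 on the cooling + discharge zone. Both readings
# disagree with the per-zone passage-time equations, which give 13.5 per
# middle/lower zone and 20.2 for zone 4; the inconsistencies are exposed,
# not resolved.
.printed_eat_coefficients <- c(c1 = 11.5, c2 = 27, c3 = 27, c4 = 21.2)

#' Zone coefficients of the dryer EAT model
#'
#' @param geom A [dryer_geometry()].
#' @param source `"printed"` reproduces the published closed-form formula
#'   bit-exactly: weights (11.5, 27, 27, 21.2), where 27 is the combined
#'   middle + lower pass count applied to each of those zone excesses as
#'   printed. `"geometry"` derives the weights from the section volumes via
#'   [section_pass_counts()] (11.5, 13.5, 13.5, 20.2), which is the reading
#'   consistent with the per-zone passage times; the two paths therefore
#'   disagree on the middle/lower zones (27 vs 13.5) and on zone 4
#'   (21.2 vs 20.2). The printed set is only meaningful for the default
#'   geometry, and a warning is raised if it is requested for any other.
#' @return Named numeric vector of four zone weights.
#' @export
eat_coefficients <- function(geom, source = c("printed", "geometry")) {
  source <- match.arg(source)
  if (source == "geometry") return(section_pass_counts(geom))
  default <- dryer_geometry()
  same <- all(vapply(names(default), function(nm) {
    isTRUE(all.equal(geom[[nm]], default[[nm]]))
  }, logical(1)))
  if (!same) {
    warning("printed EAT coefficients correspond to the default geometry; ",
            "using them with a different geometry is inconsistent")
  }
  .printed_eat_coefficients
}

#' Equivalent accumulated temperature of the continuous dryer
#'
#' Sums, over the four accounting zones, the zone mean grain temperature
#' excess over the equilibrium temperature times the zone weight and the
#' event duration `(tx + 0.5)` minutes (each discharge takes a fixed 0.5 min
#' on top of the intermittent interval `tx`):
#' \deqn{AT_1 = \sum_i c_i (\bar T_i - T_e) \times (t_x + 0.5)}
#' With `coefficients = "printed"` the weights reproduce the published
#' closed-form formula exactly; with `"geometry"` they are the pass counts
#' derived from the section volumes (see [eat_coefficients()] for why the
#' two disagree).
#'
#' @param Tbar Numeric length-4 vector of zone mean grain temperatures,
#'   degrees C (upper drying; middle; lower; cooling + discharge).
#' @param Te Equilibrium temperature, degrees C.
#' @param tx Intermittent discharge interval, minutes; > 0.
#' @param geom A [dryer_geometry()].
#' @param coefficients `"printed"` or `"geometry"`, see [eat_coefficients()].
#' @return Equivalent accumulated temperature, degree-minutes.
#' @export
dryer_eat <- function(Tbar, Te, tx, geom = dryer_geometry(),
                      coefficients = c("printed", "geometry")) {
  if (length(Tbar) != 4) stop_eatdry("eatdry_domain", "Tbar must have 4 zone temperatures")
  if (tx <= 0) stop_eatdry("eatdry_domain", "discharge interval tx must be > 0")
  co <- eat_coefficients(geom, match.arg(coefficients))
  sum(co * (Tbar - Te)) * (tx + 0.5)
}

#' Discharge interval realising a target equivalent accumulated temperature
#'
#' Inverts [dryer_eat()] for the intermittent interval:
#' `tx = AT_set / sum(c_i (Tbar_i - Te)) - 0.5`, floored at `tx_min`. This is
#' the proportional window-adaptation step: holding the window area fixed
#' while the zone temperatures move reshapes the window by changing the
#' residence time.
#'
#' @inheritParams dryer_eat
#' @param AT_set Target equivalent accumulated temperature, degree-minutes.
#' @param tx_min Lower bound on the interval, minutes. When the unfloored
#'   solution falls below it, the result carries attribute `floored = TRUE`.
#' @return Discharge interval in minutes (attribute `floored` indicates
#'   whether the bound was hit).
#' @export
solve_discharge_interval <- function(Tbar, Te, AT_set, geom = dryer_geometry(),
                                     coefficients = c("printed", "geometry"),
                                     tx_min = 0.5) {
  if (length(Tbar) != 4) stop_eatdry("eatdry_domain", "Tbar must have 4 zone temperatures")
  if (AT_set <= 0) stop_eatdry("eatdry_domain", "AT_set must be > 0")
  co <- eat_coefficients(geom, match.arg(coefficients))
  denom <- sum(co * (Tbar - Te))
  if (denom <= 0) {
    stop_eatdry("eatdry_cannot_actuate",
                "grain at or below equilibrium temperature: no discharge interval can realise the window")
  }
  tx <- AT_set / denom - 0.5
  floored <- tx < tx_min
  tx <- max(tx, tx_min)
  attr(tx, "floored") <- floored
  tx
}
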