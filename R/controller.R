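# The EAT mutual-window controller: window selection picks the initial
# accumulated-temperature window from the thin-layer model; window
# adjustment (GA model correction) changes the window AREA when the
# predicted outlet moisture strays beyond delta1; window adaptation changes
# only the window ASPECT RATIO (discharge interval) otherwise.

#' Mutual-window control law
#'
#' Combines a window-width term (deviation of the current grain temperature
#' from the reference), a window-area term (running sum of the grain
#' temperature, the discrete accumulated temperature) and an aspect-ratio
#' term (temperature slope):
#' `u(k) = kH (Ti - T0) + kS sum(Ti) + kI dTi/dt`.
#'
#' @param gains List with elements `kH`, `kS`, `kI`.
#' @param Ti Grain temperature history, degrees C (latest last).
#' @param T0 Reference grain temperature, degrees C.
#' @param dt Sample spacing in minutes (scalar or per-interval vector).
#' @return The controller output `u(k)`. With a single sample the slope term
#'   is zero and the result carries attribute `slope_missing = TRUE`.
#' @export
control_law <- function(gains, Ti, T0, dt = 1) {
  n <- length(Ti)
  if (n == 0) stop_eatdry("eatdry_domain", "at least one temperature sample required")
  slope <- if (n >= 2) (Ti[n] - Ti[n - 1]) / dt[length(dt)] else 0
  u <- gains$kH * (Ti[n] - T0) + gains$kS * sum(Ti) + gains$kI * slope
  if (n < 2) attr(u, "slope_missing") <- TRUE
  u
}

#' Window selection: initial accumulated-temperature window
#'
#' Chooses the window area (EAT setpoint) from the theoretical
#' accumulated-temperature model for the configured drying task.
#'
#' @param map A [param_map()] (the controller's model).
#' @param cond [drying_conditions()] of the drying task.
#' @param target_wb Target outlet moisture, percent wet basis.
#' @param Tf Reference drying temperature, degrees C.
#' @param Te Equilibrium temperature, degrees C.
#' @param Me_db Equilibrium moisture, percent dry basis.
#' @return Window area `AT_set` in degree-minutes.
#' @export
select_window <- function(map, cond, target_wb, Tf, Te, Me_db = 5) {
  params <- params_for_conditions(map, cond)
  theoretical_at(params, Tf = Tf, Te = Te, Mt = wb_to_db(target_wb),
                 M0 = wb_to_db(cond$W0), Me = Me_db, gamma = cond$gamma)
}

#' Predict outlet moisture by least squares
#'
#' Fits an ordinary least-squares line to the last `W` outlet-moisture
#' readings against discharge index (the sampled moisture-loss curve) and
#' extrapolates `H` discharges ahead.
#'
#' @param m Outlet moisture series, percent wet basis (latest last).
#' @param W Number of trailing samples to fit (window length).
#' @param H Prediction horizon in discharges.
#' @return A list with `prediction`, `slope` (per discharge) and `ok`. With
#'   fewer than 3 samples `ok = FALSE` and no prediction is made (the
#'   controller holds).
#' @export
predict_outlet_moisture <- function(m, W = 10, H = 1) {
  n <- length(m)
  if (n < 3) return(list(prediction = NA_real_, slope = NA_real_, ok = FALSE))
  tail_i <- seq(max(1, n - W + 1), n)
  x <- seq_along(tail_i)
  y <- m[tail_i]
  fit <- stats::lm.fit(cbind(1, x), y)
  beta <- fit$coefficients
  list(prediction = unname(beta[1] + beta[2] * (length(x) + H)),
       slope = unname(beta[2]), ok = TRUE)
}

#' Classify the predicted deviation into a control mode
#'
#' Partition of the real line: beyond `delta1` in magnitude the window area
#' must change (`ADJUST`); between the dead band `epsilon` and `delta1` only
#' the aspect ratio is reshaped (`ADAPT`); inside the dead band the
#' controller holds (`HOLD`).
#'
#' @param predicted Predicted outlet moisture, percent wet basis.
#' @param target Target moisture, percent wet basis.
#' @param delta1 Tight threshold, percent wet basis.
#' @param epsilon Dead band, percent wet basis (default 0).
#' @return `"ADJUST"`, `"ADAPT"` or `"HOLD"`.
#' @export
classify_deviation <- function(predicted, target, delta1, epsilon = 0) {
  stopifnot(delta1 > 0, epsilon >= 0, epsilon <= delta1)
  dev <- abs(predicted - target)
  if (dev > delta1) "ADJUST" else if (dev > epsilon) "ADAPT" else "HOLD"
}

# Model-implied outlet moisture (percent wet basis) for slabs that realised
# the given accumulated temperatures, under drying constants (a, b, k, N).
# The realised EAT is converted to an equivalent thin-layer drying time via
# the tempering-time correction, then pushed through the Weibull curve.
implied_outlet_wb <- function(a, b, k, N, at, Tf, Te, gamma, M0_db, Me_db) {
  t_h <- pmax(at, 0) / (60 * (1 + gamma) * (Tf - Te))
  mr <- a + b * exp(-k * t_h^N)
  db_to_wb(Me_db + (M0_db - Me_db) * mr)
}

#' Window adjustment: GA correction of the drying-constant model
#'
#' Searches correction coefficients (da, db, dk, dN), bounded relative
#' perturbations of the controller's current drying constants, so that the
#' corrected model's implied outlet moistures best explain the recently
#' observed ones. Each recent discharge is replayed through the corrected
#' model at its realised slab accumulated temperature; the residuals e(k),
#' the logged control outputs u(k), the rise time and the overshoot enter
#' the control-performance objective ([ga_objective()]). The incumbent
#' (zero correction) is seeded into the population, so when the model
#' already explains the data the GA returns to it and the window is left
#' unchanged.
#'
#' @param params Current controller drying constants ([thinlayer_params()]).
#' @param obs Data frame of recent discharges with columns `m_wb` (observed
#'   outlet moisture), `at` (realised slab EAT, degree-minutes) and
#'   optionally `u` (control-law diagnostic) and `Tf` (per-slab reference
#'   drying temperature averaged over the slab's residence, degrees C —
#'   attributes observations correctly across setpoint changes).
#' @param target_wb Target moisture, percent wet basis.
#' @param Tf,Te Reference drying and equilibrium temperatures, degrees C.
#' @param gamma Tempering ratio.
#' @param M0_db,Me_db Inlet and equilibrium moisture, percent dry basis.
#' @param ga List of GA settings (`pop`, `generations`, `pc`, `pm`, `bound`,
#'   `w1`, `w2`, `w3`), e.g. `eatdry_config()$controller$ga`.
#' @param delta1 Band used for the rise-time term, percent wet basis.
#' @param seed GA seed.
#' @param init_corrections Optional matrix of correction vectors (rows)
#'   seeded into the initial population besides the zero (incumbent) row —
#'   typically the previous adjustment's result.
#' @return A list with `params` (corrected constants), `correction` (the
#'   four coefficients), `improved` (logical; `FALSE` flags GA
#'   non-improvement, in which case the incumbent is kept) and `value`
#'   (objective at the optimum).
#' @export
ga_window_adjustment <- function(params, obs, target_wb, Tf, Te, gamma,
                                 M0_db, Me_db, ga, delta1 = 0.5, seed = 1,
                                 init_corrections = NULL) {
  stopifnot(inherits(params, "thinlayer_params"), nrow(obs) >= 3)
  u <- obs$u %||% rep(0, nrow(obs))
  u[!is.finite(u)] <- 0
  Tf_obs <- obs$Tf %||% rep(Tf, nrow(obs))
  weights <- c(ga$w1, ga$w2, ga$w3)
  # Overshoot of the observed response in the window: the outlet crossing
  # the target beyond the initial deviation direction. A property of the
  # rollout initial conditions, not of the candidate corrections.
  e_obs <- obs$m_wb - target_wb
  over <- if (e_obs[1] > 0) max(-e_obs) else max(e_obs)
  sigma <- if (is.finite(over) && over > 0 && abs(e_obs[1]) > 1e-9) {
    100 * over / abs(e_obs[1])
  } else NULL
  fitness <- function(d) {
    a <- params$a * (1 + d[1]); b <- params$b * (1 + d[2])
    k <- params$k * (1 + d[3]); N <- params$N * (1 + d[4])
    if (b <= 0 || k <= 0 || N <= 0) return(Inf)
    pred <- implied_outlet_wb(a, b, k, N, obs$at, Tf_obs, Te, gamma, M0_db, Me_db)
    e <- obs$m_wb - pred
    tr <- which(abs(e) <= delta1)[1]
    if (is.na(tr)) tr <- length(e) + 1
    ga_objective(e, u, tr, weights, sigma)
  }
  bound <- rep_len(as.numeric(unlist(ga$bound)), 4)
  res <- ga_optimize(fitness, lower = -bound, upper = bound,
                     pop = ga$pop, generations = ga$generations,
                     pc = ga$pc, pm = ga$pm, seed = seed,
                     init = rbind(rep(0, 4), init_corrections))
  incumbent_value <- fitness(rep(0, 4))
  improved <- res$value < incumbent_value - 1e-12
  d <- if (improved) res$par else rep(0, 4)
  corrected <- suppressWarnings(thinlayer_params(
    params$a * (1 + d[1]), params$b * (1 + d[2]),
    params$k * (1 + d[3]), params$N * (1 + d[4])
  ))
  list(params = corrected, correction = d, improved = improved,
       value = res$value, history = res$history)
}

#' Window adaptation: reshape the window at constant area
#'
#' Keeps the accumulated-temperature window area (`AT_set`) fixed and
#' re-solves the discharge interval against the current zone temperatures —
#' the proportional adjustment of the dryer EAT model. Rising grain
#' temperatures therefore shorten the residence (smaller `tx`) and falling
#' ones stretch it.
#'
#' @inheritParams solve_discharge_interval
#' @return Discharge interval in minutes (see [solve_discharge_interval()]).
#' @export
window_adaptation <- function(Tbar, Te, AT_set, geom = dryer_geometry(),
                              coefficients = c("printed", "geometry"),
                              tx_min = 0.5) {
  solve_discharge_interval(Tbar, Te, AT_set, geom, coefficients, tx_min)
}
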