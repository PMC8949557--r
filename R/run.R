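# Run engine: advances the simulated bed on the time grid, discharges on
# the (controller-set or fixed) interval, and logs one row per discharge.

run_dryer <- function(scenario, cfg, closed = TRUE, tx_fixed = NULL) {
  stopifnot(inherits(scenario, "drying_scenario"), inherits(cfg, "eatdry_config"))
  state <- init_bed(cfg, scenario)
  geom <- cfg$geom
  ct <- cfg$controller
  dt <- scenario$dt_min %||% cfg$sim$dt_min
  dur_min <- scenario$duration_h * 60
  n_steps <- floor(dur_min / dt + 1e-9)
  turnover <- total_bed_volume(geom) / geom$Vp
  H <- ct$H %||% ceiling(turnover)
  cooldown <- ct$cooldown %||% ceiling(turnover)
  Me_db <- cfg$kinetics$Me_db

  base_setpoints <- scenario$setpoints
  ambient0 <- scenario$ambient_T %||% cfg$sim$ambient_T

  map0 <- cfg$controller_map   # pristine anchors: corrections re-anchor here
  ctrl_map <- map0
  d_prev <- rep(0, 4)
  # What the controller believes about the incoming grain: the inlet
  # sensor's (noisy) lot reading — never the true realised lot mean.
  inlet_assumed <- state$inlet_measured %||% cfg$calibration$inlet_wb
  cond_at <- function(setpoints) {
    drying_conditions(T = tf_reference(setpoints, geom, cfg$sim$gamma),
                      RH = cfg$kinetics$rh_hot, V = cfg$kinetics$V_air,
                      W0 = inlet_assumed, gamma = cfg$sim$gamma)
  }
  AT_set <- if (closed) {
    scenario$initial_at %||% {
      # Window selection anchored at the calibration point: the theoretical
      # model supplies the RATIO between the scenario's conditions and the
      # calibration conditions, scaled by the known-good calibrated window.
      # A multiplicative error on the model's rate constant cancels in the
      # ratio, so the initial window is unbiased under the anchor mismatch.
      at_now <- select_window(
        map0, cond_at(base_setpoints), ct$target_wb,
        Tf = tf_reference(base_setpoints, geom, cfg$sim$gamma),
        Te = state$Te, Me_db = Me_db)
      cond_cal <- drying_conditions(
        T = cfg$Tf_ref, RH = cfg$kinetics$rh_hot, V = cfg$kinetics$V_air,
        W0 = inlet_assumed, gamma = cfg$sim$gamma)
      at_cal <- select_window(map0, cond_cal, ct$target_wb,
                              Tf = cfg$Tf_ref, Te = cfg$Te_ref, Me_db = Me_db)
      cfg$calibration$AT0 * at_now / at_cal
    }
  } else NA_real_
  tx <- if (closed) {
    # Cold start: no usable zone temperatures yet, so solve the discharge
    # interval from the EAT model a priori, taking grain at hot-air
    # temperature in the drying zones and the cooling zone at Te.
    ct$tx0 %||% tryCatch(
      clamp(as.numeric(solve_discharge_interval(
        c(base_setpoints, state$Te), state$Te, AT_set, geom,
        coefficients = "geometry", tx_min = ct$tx_min)),
        ct$tx_min, ct$tx_max),
      eatdry_error = function(e) 5)
  } else tx_fixed
  if (is.null(tx)) stop_eatdry("eatdry_config", "open-loop runs need a fixed tx")

  nmax <- ceiling(dur_min / (ct$tx_min + 0.5)) + 2
  log <- list(
    clock_min = numeric(nmax), event = integer(nmax), tx_min = numeric(nmax),
    M_out_wb = numeric(nmax), T1 = numeric(nmax), T2 = numeric(nmax),
    T3 = numeric(nmax), T4 = numeric(nmax), Te = numeric(nmax),
    AT_set = numeric(nmax), AT_realized = numeric(nmax),
    mode = character(nmax), u = numeric(nmax), M_pred = numeric(nmax),
    AT_model = numeric(nmax)
  )
  ev <- 0L
  adjustments <- list()   # one record per GA window adjustment
  m_hist <- numeric(0)    # outlet readings, latest last
  Ti_hist <- numeric(0)   # mean drying-zone grain temperature per event
  Tf_hist <- numeric(0)   # reference drying temperature per event
  u_hist <- numeric(0)
  T0_ref <- NA_real_
  Tbar_f <- NULL          # smoothed zone temperatures for the adaptation
  last_adjust <- -Inf
  last_cond_change <- -Inf
  # Window memory per hot-air regime: returning to a previously operated
  # regime restores its settled window instead of re-deriving it.
  regime_memory <- list()
  regime_key <- function(sp) paste(round(sp, 1), collapse = "/")
  next_discharge <- tx + 0.5

  for (s in seq_len(n_steps)) {
    eff <- apply_disturbance(base_setpoints, ambient0, scenario$disturbances,
                             state$clock)
    state$sect_T <- eff$setpoints
    state$ambient_T <- eff$ambient_T
    state <- step_sim(state, dt)

    if (state$clock >= next_discharge - 1e-9) {
      res <- discharge_event(state)
      state <- res$state
      out <- res$outlet
      ev <- ev + 1L

      Tbar <- zone_mean_temps(state)
      zone <- .region_zone[state$region]
      drying_sel <- zone <= 3
      Ti <- sum(state$temp[drying_sel] * state$vol[drying_sel]) /
        sum(state$vol[drying_sel])
      if (is.na(T0_ref)) T0_ref <- Ti
      Ti_hist <- c(Ti_hist, Ti)
      Tf_hist <- c(Tf_hist, tf_reference(state$sect_T, geom, cfg$sim$gamma))
      m_hist <- c(m_hist, out$m_wb)

      mode <- "open"
      u <- NA_real_
      pred <- NA_real_
      if (closed) {
        u <- as.numeric(control_law(ct$gains, Ti_hist, T0_ref, dt = tx + 0.5))
        u_hist <- c(u_hist, u)
        # Feedforward on known setpoint changes: the window area is rescaled
        # by the model's theoretical ratio at the new vs the previous
        # reference temperature, so the window answers a hot-air change
        # immediately instead of waiting for it to surface at the outlet.
        Tf_ev <- Tf_hist[ev]
        if (ev > 1 && abs(Tf_ev - Tf_hist[ev - 1]) > 0.5) {
          key_new <- regime_key(state$sect_T)
          if (!is.null(regime_memory[[key_new]])) {
            # Known regime: restore its settled window.
            AT_set <- regime_memory[[key_new]]
          } else {
            # New regime: rescale by the pristine model's theoretical
            # ratio (multiplicative rate errors cancel in the ratio), but
            # only on the drying-zone share of the window — the cooling
            # zone's contribution rides on ambient, not hot air.
            at_ratio <- tryCatch({
              at_new_T <- select_window(map0, cond_at(state$sect_T),
                                        ct$target_wb, Tf = Tf_ev,
                                        Te = state$Te, Me_db = Me_db)
              p_old <- cond_at(state$sect_T)
              p_old$T <- p_old$T - (Tf_ev - Tf_hist[ev - 1])
              at_old_T <- select_window(map0, p_old, ct$target_wb,
                                        Tf = Tf_hist[ev - 1],
                                        Te = state$Te, Me_db = Me_db)
              at_new_T / at_old_T
            }, eatdry_error = function(e) 1)
            at_ratio <- clamp(at_ratio, 0.7, 1.4)
            co4 <- eat_coefficients(geom, "geometry")[4]
            z4 <- clamp(co4 * (Tbar[4] - state$Te) * (tx + 0.5),
                        0, 0.3 * AT_set)
            # Partial feedforward: the theoretical ratio carries
            # regime-dependent model error (the realisation offset does not
            # scale with hot-air temperature), so apply 70 % of it and let
            # the damped refits close the remainder.
            at_ff <- z4 + at_ratio * (AT_set - z4)
            AT_set <- AT_set + 0.7 * (at_ff - AT_set)
          }
          last_cond_change <- ev
        }
        pr <- predict_outlet_moisture(m_hist, W = ct$W, H = H)
        if (pr$ok) {
          pred <- clamp(pr$prediction, 5, 40)
          mode <- classify_deviation(pred, ct$target_wb, ct$delta1, ct$epsilon)
        } else {
          mode <- "HOLD"
        }
        warmup <- ct$warmup %||% ceiling(turnover)
        # Coarse regime: during window establishment (first two turnovers)
        # and whenever the predicted deviation exceeds the coarse threshold
        # delta2, adjustments run at a faster cadence and undamped (below).
        # Between delta1 and delta2 the fine regime applies damped updates.
        # A recent setpoint change forces the fine regime: discharged slabs
        # then carry mixed-regime histories, so refits resume damped after
        # half a transit and the feedforward owns the immediate response.
        in_transition <- ev - last_cond_change < turnover
        coarse <- !in_transition &&
          (ev < 2 * turnover ||
             (is.finite(pred) && abs(pred - ct$target_wb) > ct$delta2))
        cd_now <- if (coarse) max(4, cooldown %/% 2) else cooldown
        if (mode == "ADJUST" &&
            (ev - last_adjust < cd_now || ev < max(ct$W, warmup) ||
             ev - last_cond_change < turnover / 2)) {
          mode <- "ADAPT"
        }
        if (mode == "ADJUST") {
          # The model refit uses a longer tail than the predictor: one bed
          # turnover of discharges spans a wide realised-EAT range, which
          # pins the local slope of the EAT-moisture map and prevents the
          # refit from extrapolating a transient.
          W_fit <- ct$W_fit %||% ceiling(turnover)
          wi <- seq(max(1, ev - W_fit + 1), ev)
          tn <- ceiling(turnover)
          obs <- data.frame(m_wb = m_hist[wi],
                            at = log$AT_realized[wi],
                            u = u_hist[wi],
                            # reference temperature each slab actually saw,
                            # averaged over its residence
                            Tf = vapply(wi, function(k) {
                              mean(Tf_hist[seq(max(1, k - tn + 1), k)])
                            }, numeric(1)))
          obs$at[wi == ev] <- out$eat
          # Partial-residence slabs from the cold start carry less than the
          # commanded window and say nothing about steady operation; keep
          # them out of the refit once enough full-residence slabs exist.
          full <- obs$at >= 0.5 * AT_set
          if (sum(full) >= 10) { obs <- obs[full, ]; wi <- wi[full] }
          Tf_now <- tf_reference(state$sect_T, geom, cfg$sim$gamma)
          adj <- ga_window_adjustment(
            params_for_conditions(map0, cond_at(state$sect_T)),
            obs, target_wb = ct$target_wb, Tf = Tf_now, Te = state$Te,
            gamma = cfg$sim$gamma, M0_db = wb_to_db(inlet_assumed),
            Me_db = Me_db, ga = ct$ga, delta1 = ct$delta1,
            seed = child_seed(scenario$seed, ev),
            init_corrections = rbind(d_prev))
          d <- adj$correction
          d_prev <- d
          ctrl_map$a <- map0$a * (1 + d[1])
          ctrl_map$b <- map0$b * (1 + d[2])
          ctrl_map$k_ref <- map0$k_ref * (1 + d[3])
          ctrl_map$N <- map0$N * (1 + d[4])
          AT_new <- tryCatch(
            select_window(ctrl_map, cond_at(state$sect_T), ct$target_wb,
                          Tf = Tf_now, Te = state$Te, Me_db = Me_db),
            eatdry_error = function(e) AT_set)
          # The inversion yields the slab-realised EAT for the target; the
          # discharge loop realises slightly more than it is commanded
          # (model-vs-slab accounting differences), so convert to a command
          # by subtracting the recently observed realisation offset. Only
          # meaningful near steady state, hence the 10 % gate.
          # A slab's realised EAT answers the window commands over its whole
          # transit, so the realisation offset is measured against each
          # recent slab's life-average commanded window (valid during
          # descents as well as at steady state). Only slabs with a full
          # post-startup transit qualify.
          ri <- seq(max(1, ev - 19), ev)
          ri <- ri[ri > ceiling(turnover)]
          offset <- 0
          if (length(ri) >= 5) {
            at_real <- log$AT_realized[ri]; at_real[ri == ev] <- out$eat
            seth <- log$AT_set; seth[ev] <- AT_set
            tn <- ceiling(turnover)
            life_avg <- vapply(ri, function(k) {
              mean(seth[seq(max(1, k - tn + 1), k)])
            }, numeric(1))
            offset <- stats::median(at_real - life_avg)
            if (!is.finite(offset) || abs(offset) > 0.06 * AT_set) offset <- 0
          }
          AT_new <- AT_new - offset
          adjustments[[length(adjustments) + 1]] <- data.frame(
            event = ev, AT_before = AT_set, AT_indicated = AT_new,
            realisation_offset = offset,
            obs_mean = mean(obs$m_wb), da = d[1], db = d[2], dk = d[3],
            dN = d[4])
          # Damped update: the outlet answers an area change only after up
          # to one bed turnover, so applying the full indicated change at
          # every adjustment would double-count the in-flight correction.
          # During startup (first two turnovers) the window must instead be
          # established quickly, so the indicated change is applied in full
          # with a wider cap — matching the large early window changes and
          # small later ones of dryer commissioning practice.
          gain <- if (coarse) 1 else ct$at_gain
          cap <- if (coarse) 2 * ct$at_rate_limit else ct$at_rate_limit
          AT_new <- AT_set + gain * (AT_new - AT_set)
          AT_set <- clamp(AT_new, AT_set * (1 - cap), AT_set * (1 + cap))
          last_adjust <- ev
        }
        # Window adaptation against smoothed zone temperatures: the
        # proportional inversion is memoryless, so solving against
        # instantaneous readings after a hot-air change would retime the
        # discharge faster than the in-flight grain can follow, pushing
        # exiting slabs off the window. Smoothing the zone temperatures over
        # roughly half a bed transit spreads the interval change across the
        # cohort instead.
        # Startup warming is itself a bed-wide transient the interval must
        # track, so smoothing starts only once the bed has turned over twice.
        Tbar_f <- if (is.null(Tbar_f) || ev < 2 * turnover) Tbar else {
          Tbar_f + ct$temp_filter * (Tbar - Tbar_f)
        }
        tx_base <- if (mode == "HOLD") tx else {
          tryCatch(
            as.numeric(window_adaptation(Tbar_f, state$Te, AT_set, geom,
                                         coefficients = "geometry",
                                         tx_min = ct$tx_min)),
            eatdry_cannot_actuate = function(e) tx)
        }
        tx_cmd <- tx_base - ct$gains$trim * u
        tx <- clamp(tx_cmd, tx * (1 - ct$tx_rate_limit),
                    tx * (1 + ct$tx_rate_limit))
        tx <- clamp(tx, ct$tx_min, ct$tx_max)
        regime_memory[[regime_key(state$sect_T)]] <- AT_set
      }

      log$clock_min[ev] <- state$clock
      log$event[ev] <- ev
      log$tx_min[ev] <- tx
      log$M_out_wb[ev] <- out$m_wb
      log$T1[ev] <- Tbar[1]; log$T2[ev] <- Tbar[2]
      log$T3[ev] <- Tbar[3]; log$T4[ev] <- Tbar[4]
      log$Te[ev] <- state$Te
      log$AT_set[ev] <- AT_set
      log$AT_realized[ev] <- out$eat
      log$mode[ev] <- mode
      log$u[ev] <- u
      log$M_pred[ev] <- pred
      # The loop works on the geometry-consistent EAT model: the printed
      # closed-form weights double the middle/lower zones and would break
      # the slab-accounting identity the adaptation relies on.
      log$AT_model[ev] <- dryer_eat(Tbar, state$Te, tx, geom,
                                    coefficients = "geometry")

      next_discharge <- state$clock + tx + 0.5
    }
  }

  log <- as.data.frame(lapply(log, function(col) col[seq_len(ev)]))
  structure(
    list(log = log, scenario = scenario, config = cfg,
         mode = if (closed) "closed" else "open",
         controller_map = if (closed) ctrl_map else NULL,
         adjustments = if (closed) do.call(rbind, adjustments) else NULL,
         summary = run_summary(log, cfg)),
    class = "drying_run"
  )
}

#' Summarise a drying run log
#'
#' Recomputes the run summary from a discharge log: the maximum absolute
#' deviation of outlet moisture from the target after the settling period
#' (two full bed turnovers), the settling time (first instant from which the
#' outlet stays inside the target band), and the number of window
#' adjustments and adaptations.
#'
#' @param log A run log data frame (as in `drying_run$log` or read back via
#'   [read_run_log()]).
#' @param cfg The run's [eatdry_config()].
#' @return A list with `target_wb`, `settle_events`, `max_dev_post`,
#'   `settle_time_min`, `n_adjustments`, `n_adaptations`, `n_events`.
#' @export
run_summary <- function(log, cfg) {
  ct <- cfg$controller
  turnover <- total_bed_volume(cfg$geom) / cfg$geom$Vp
  settle_events <- ceiling(2 * turnover)
  dev <- log$M_out_wb - ct$target_wb
  post <- log$event > settle_events
  in_band <- abs(dev) <= ct$delta1
  settle_time <- NA_real_
  if (nrow(log) > 0 && any(in_band)) {
    ok_from <- rev(cumprod(rev(in_band))) == 1
    if (any(ok_from)) settle_time <- log$clock_min[which(ok_from)[1]]
  }
  list(
    target_wb = ct$target_wb,
    settle_events = settle_events,
    max_dev_post = if (any(post)) max(abs(dev[post])) else NA_real_,
    mean_out_post = if (any(post)) mean(log$M_out_wb[post]) else NA_real_,
    settle_time_min = settle_time,
    n_adjustments = sum(log$mode == "ADJUST"),
    n_adaptations = sum(log$mode == "ADAPT"),
    n_events = nrow(log)
  )
}

#' Open-loop dryer run at a fixed discharge interval
#'
#' @param scenario A [drying_scenario()].
#' @param cfg An [eatdry_config()].
#' @param tx Fixed intermittent discharge interval, minutes.
#' @return A `drying_run` object (log + summary).
#' @export
run_open_loop <- function(scenario, cfg = eatdry_config(), tx = 5) {
  run_dryer(scenario, cfg, closed = FALSE, tx_fixed = tx)
}

#' Closed-loop mutual-window control run
#'
#' Runs the simulated dryer under the EAT mutual-window controller: each
#' discharge reading feeds the least-squares outlet prediction; predicted
#' deviations beyond `delta1` trigger the GA window adjustment (new window
#' area from the corrected model), smaller ones the proportional window
#' adaptation (new discharge interval at constant area), and the control-law
#' trim is added to the interval.
#'
#' @param scenario A [drying_scenario()].
#' @param cfg An [eatdry_config()].
#' @return A `drying_run` object with elements `log` (one row per
#'   discharge), `summary` (see [run_summary()]), `scenario` and `config`.
#' @examples
#' \donttest{
#' run <- closed_loop_run(drying_scenario("continuous", duration_h = 6, seed = 1))
#' summary(run)
#' }
#' @export
closed_loop_run <- function(scenario, cfg = eatdry_config()) {
  run_dryer(scenario, cfg, closed = TRUE)
}

#' @export
print.drying_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s-loop drying run ('%s', %.1f h, seed %d): %d discharges\n",
              x$mode, x$scenario$preset, x$scenario$duration_h,
              x$scenario$seed, s$n_events))
  if (is.finite(s$max_dev_post %||% NA)) {
    cat(sprintf("  post-settling max |M_out - %.1f| = %.3f %% w.b.\n",
                s$target_wb, s$max_dev_post))
  }
  invisible(x)
}

#' @export
summary.drying_run <- function(object, ...) {
  s <- object$summary
  print(object)
  cat(sprintf("  settling: first in-band-and-staying at %s min (band +/- %.2f %%)\n",
              format(s$settle_time_min), object$config$controller$delta1))
  cat(sprintf("  window adjustments: %d, adaptations: %d\n",
              s$n_adjustments, s$n_adaptations))
  if (nrow(object$log) > 0) {
    cat(sprintf("  final tx = %.2f min, final AT_set = %s C*min\n",
                object$log$tx_min[nrow(object$log)],
                format(round(object$log$AT_set[nrow(object$log)], 1))))
  }
  invisible(s)
}

#' @export
plot.drying_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lg <- x$log
  tgt <- x$config$controller$target_wb
  d1 <- x$config$controller$delta1
  plot(lg$clock_min / 60, lg$M_out_wb, type = "l",
       xlab = "time (h)", ylab = "outlet moisture (% w.b.)",
       main = sprintf("outlet moisture ('%s')", x$scenario$preset), ...)
  graphics::abline(h = tgt, col = "red3")
  graphics::abline(h = c(tgt - d1, tgt + d1), col = "red3", lty = 2)
  plot(lg$clock_min / 60, lg$AT_set, type = "s", xlab = "time (h)",
       ylab = "window area (C*min)", main = "accumulated-temperature window")
  graphics::lines(lg$clock_min / 60, lg$AT_realized, col = "grey50")
  invisible(x)
}
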