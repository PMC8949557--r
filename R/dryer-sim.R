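# Discrete-event simulator of the six-section continuous mixed-flow dryer.
#
# The grain bed is an ordered queue of slabs (top = inlet, bottom = outlet),
# each nominally one discharge volume Vp. Slabs in drying regions advance
# along their Weibull thin-layer curve by the equivalent-time method: the
# current moisture ratio is inverted to an equivalent drying time, the step
# is added, and the curve is re-evaluated — exact under constant conditions,
# and consistent across condition changes. Tempering holds moisture and
# temperature; cooling and discharge sections hold moisture while the grain
# temperature relaxes to ambient. Every slab accumulates effective
# accumulated temperature max(T_grain - Te, 0) dt over its whole residence.

# Region ids: 1 upper drying, 2 middle drying, 3 middle tempering,
# 4 lower drying, 5 lower tempering, 6 cooling, 7 discharge.
.region_zone <- c(1L, 2L, 2L, 3L, 3L, 4L, 4L)
.region_air <- c(1L, 2L, NA, 3L, NA, NA, NA)

region_boundaries <- function(geom, gamma) {
  phi <- temper_fraction(gamma, geom)
  b1 <- geom$Vg1
  b2 <- b1 + (1 - phi) * geom$Vg2h1
  b3 <- b1 + geom$Vg2h1
  b4 <- b3 + (1 - phi) * geom$Vg3h2
  b5 <- b3 + geom$Vg3h2
  b6 <- b5 + geom$Vl
  c(b1, b2, b3, b4, b5, b6)
}

assign_regions <- function(state) {
  mid <- cumsum(state$vol) - state$vol / 2
  state$region <- findInterval(mid, state$bounds) + 1L
  state
}

# AR(1) inlet moisture stream (percent wet basis), clipped to the range.
inlet_stream <- function(n, mean, sd, rho, range) {
  z <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- mean + sd * z[1]
  if (n > 1) {
    innov_sd <- sd * sqrt(1 - rho^2)
    for (i in 2:n) x[i] <- mean + rho * (x[i - 1] - mean) + innov_sd * z[i]
  }
  clamp(x, range[1], range[2])
}

#' Initialise the dryer bed
#'
#' Fills the bed with slabs of the per-discharge volume at (seeded) inlet
#' moisture; the remainder of the bed volume that does not divide evenly
#' becomes one fractional slab at the bottom, which clears with the first
#' discharges. With the default geometry this yields 58 full slabs plus a
#' fractional one (467.733 L at 8 L per slab).
#'
#' @param cfg An [eatdry_config()].
#' @param scenario A [drying_scenario()]; supplies inlet statistics and seed.
#' @return An object of class `dryer_state`.
#' @export
init_bed <- function(cfg, scenario = drying_scenario("continuous")) {
  stopifnot(inherits(cfg, "eatdry_config"), inherits(scenario, "drying_scenario"))
  geom <- cfg$geom
  V <- total_bed_volume(geom)
  n_full <- floor(V / geom$Vp)
  frac <- V - n_full * geom$Vp
  vol <- c(rep(geom$Vp, n_full), if (frac > 1e-9) frac)
  n <- length(vol)

  dur_min <- scenario$duration_h * 60
  n_events_max <- ceiling(dur_min / (cfg$controller$tx_min + 0.5)) + n + 10
  drawn <- with_local_seed(scenario$seed, {
    lot_mean <- scenario$inlet_mean %||%
      stats::runif(1, scenario$inlet_range[1], scenario$inlet_range[2])
    list(
      stream = inlet_stream(n + n_events_max, lot_mean, scenario$inlet_sd,
                            scenario$inlet_rho, scenario$inlet_range),
      # What the rig's inlet moisture sensor reports for this lot: the true
      # mean plus measurement error. The controller sees only this reading.
      measured = lot_mean +
        stats::rnorm(1, 0, cfg$controller$inlet_sensor_sd %||% 0)
    )
  })
  stream <- drawn$stream
  # The bed was filled from the top: the bottom slab is the oldest draw.
  w0 <- rev(stream[seq_len(n)])
  ambient_T <- scenario$ambient_T %||% cfg$sim$ambient_T

  state <- structure(
    list(
      vol = vol,
      w0_wb = w0,
      m0_db = wb_to_db(w0),
      m_db = wb_to_db(w0),
      temp = rep(ambient_T, n),
      eat = rep(0, n),
      t_enter = rep(0, n),
      events = rep(0L, n),
      clock = 0,
      bounds = region_boundaries(geom, cfg$sim$gamma),
      sect_T = scenario$setpoints,
      ambient_T = ambient_T,
      ambient_RH = scenario$ambient_RH %||% cfg$sim$ambient_RH,
      Te = NA_real_,
      stream = stream,
      stream_ptr = n + 1L,
      inlet_measured = drawn$measured,
      geom = geom,
      cfg_sim = cfg$sim,
      cfg_kin = cfg$kinetics,
      truth_map = cfg$truth_map,
      target_db = wb_to_db(cfg$controller$target_wb),
      cae = cae_constants(cfg$equilibrium$A, cfg$equilibrium$B, cfg$equilibrium$C),
      te_form = cfg$equilibrium$form
    ),
    class = "dryer_state"
  )
  state$Te <- state_te(state)
  assign_regions(state)
}

# Equilibrium temperature seen by the rig: exhaust relative humidity
# (ambient plus evaporative pickup) with the drying target moisture.
state_te <- function(state) {
  erh <- clamp(state$ambient_RH + state$cfg_sim$rh_pickup, 1e-6, 1 - 1e-6)
  equilibrium_temperature(erh, state$target_db, state$cae, state$te_form)
}

# Fast unvalidated path of the condition map for the inner loop.
map_k_fast <- function(map, T, RH, V, W0) {
  exp(log(map$k_ref) + map$alpha_T * (T - map$T_ref) +
        map$beta_RH * (RH - map$RH_ref) + map$beta_V * (V - map$V_ref) +
        map$beta_W * (W0 - map$W_ref))
}

#' Advance the simulated bed by one time step
#'
#' @param state A `dryer_state`.
#' @param dt Step in minutes; must not exceed 1 (equivalent-time tracking
#'   stability bound).
#' @return The advanced `dryer_state`.
#' @export
step_sim <- function(state, dt) {
  if (dt <= 0 || dt > 1) stop_eatdry("eatdry_domain", "dt must lie in (0, 1] minutes")
  region <- state$region
  temp0 <- state$temp

  # Effective accumulated temperature: only heating above Te counts.
  state$eat <- state$eat + pmax(temp0 - state$Te, 0) * dt

  drying <- which(region %in% c(1L, 2L, 4L))
  if (length(drying) > 0) {
    map <- state$truth_map
    kin <- state$cfg_kin
    airT <- state$sect_T[.region_air[region[drying]]]
    k <- map_k_fast(map, airT, kin$rh_hot, kin$V_air, state$w0_wb[drying])
    a <- map$a; b <- map$b; N <- map$N
    Me <- kin$Me_db
    m0 <- state$m0_db[drying]
    mr <- (state$m_db[drying] - Me) / (m0 - Me)
    mr <- clamp(mr, a + 1e-12, a + b)
    t_eq <- ((log(b) - log(mr - a)) / k)^(1 / N)
    mr_new <- a + b * exp(-k * (t_eq + dt / 60)^N)
    state$m_db[drying] <- Me + (m0 - Me) * mr_new
  }

  # Grain temperature: first-order lag toward local air in drying regions,
  # adiabatic hold in tempering, relaxation to ambient in cooling/discharge.
  lag <- 1 - exp(-dt / state$cfg_sim$tau_g_min)
  tgt <- temp0
  if (length(drying) > 0) tgt[drying] <- state$sect_T[.region_air[region[drying]]]
  cooling <- which(region >= 6L)
  if (length(cooling) > 0) tgt[cooling] <- state$ambient_T
  state$temp <- temp0 + (tgt - temp0) * lag

  state$clock <- state$clock + dt
  state
}

#' Discharge one grain quantum from the bed
#'
#' Removes exactly the per-discharge volume `Vp` from the bottom of the bed
#' (splitting the boundary slab if the bed holds a fractional slab), reports
#' the outlet reading, and feeds one fresh slab of inlet grain at the top,
#' so the bed volume is conserved.
#'
#' @param state A `dryer_state`.
#' @return A list with the updated `state` and `outlet`, a list carrying the
#'   volume-weighted outlet moisture (`m_wb`, percent wet basis as the
#'   sensor reads it), realised slab accumulated temperature `eat`
#'   (degree-minutes), `residence` (minutes) and survived discharge `events`.
#' @export
discharge_event <- function(state) {
  n <- length(state$vol)
  if (n == 0) stop_eatdry("eatdry_invalid_state", "bed is empty")
  Vp <- state$geom$Vp
  take <- numeric(0); idx <- integer(0)
  remaining <- Vp
  i <- n
  while (remaining > 1e-9 && i >= 1) {
    amt <- min(state$vol[i], remaining)
    take <- c(take, amt); idx <- c(idx, i)
    remaining <- remaining - amt
    i <- i - 1
  }
  w <- take / sum(take)
  outlet <- list(
    m_wb = db_to_wb(sum(w * state$m_db[idx])),
    m_db = sum(w * state$m_db[idx]),
    eat = sum(w * state$eat[idx]),
    residence = sum(w * (state$clock - state$t_enter[idx])),
    events = max(state$events[idx]),
    temp = sum(w * state$temp[idx])
  )

  fully <- idx[take >= state$vol[idx] - 1e-9]
  partial <- setdiff(idx, fully)
  if (length(partial) > 0) {
    state$vol[partial] <- state$vol[partial] - take[idx %in% partial]
  }
  keep <- setdiff(seq_len(n), fully)
  for (f in c("vol", "w0_wb", "m0_db", "m_db", "temp", "eat", "t_enter")) {
    state[[f]] <- state[[f]][keep]
  }
  state$events <- state$events[keep] + 1L

  w_new <- state$stream[state$stream_ptr]
  state$stream_ptr <- state$stream_ptr + 1L
  state$vol <- c(Vp, state$vol)
  state$w0_wb <- c(w_new, state$w0_wb)
  state$m0_db <- c(wb_to_db(w_new), state$m0_db)
  state$m_db <- c(wb_to_db(w_new), state$m_db)
  state$temp <- c(state$ambient_T, state$temp)
  state$eat <- c(0, state$eat)
  state$t_enter <- c(state$clock, state$t_enter)
  state$events <- c(0L, state$events)

  list(state = assign_regions(state), outlet = outlet)
}

# Volume-weighted mean grain temperature of the four accounting zones.
zone_mean_temps <- function(state) {
  zone <- .region_zone[state$region]
  vapply(1:4, function(z) {
    sel <- zone == z
    if (!any(sel)) return(NA_real_)
    sum(state$temp[sel] * state$vol[sel]) / sum(state$vol[sel])
  }, numeric(1))
}

#' @export
print.dryer_state <- function(x, ...) {
  cat(sprintf(
    "Dryer bed: %d slabs, %.1f L, clock %.1f min\n  outlet %.2f %% w.b., zone temps %s C, Te %.2f C\n",
    length(x$vol), sum(x$vol), x$clock, db_to_wb(x$m_db[length(x$m_db)]),
    paste(sprintf("%.1f", zone_mean_temps(x)), collapse = "/"), x$Te))
  invisible(x)
}
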