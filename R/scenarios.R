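#' Disturbance on hot air or ambient conditions
#'
#' @param kind `"step"` (setpoint changes to `value` from `start` onward),
#'   `"pulse"` (setpoint is `value` during `[start, start + duration)` then
#'   reverts) or `"sinusoid"` (additive `delta * sin(2 pi (t - start) /
#'   period)`).
#' @param target `"section1"`, `"section2"`, `"section3"`, `"all"` (all
#'   drying sections) or `"ambient"`.
#' @param value Absolute setpoint, degrees C (step / pulse).
#' @param delta Amplitude, degrees C (sinusoid).
#' @param start Start time, minutes from run start.
#' @param duration Pulse duration, minutes.
#' @param period Sinusoid period, minutes.
#' @return An object of class `dryer_disturbance`.
#' @export
disturbance <- function(kind = c("step", "pulse", "sinusoid"),
                        target = c("all", "section1", "section2", "section3", "ambient"),
                        value = NULL, delta = NULL, start = 0,
                        duration = NULL, period = NULL) {
  kind <- tryCatch(match.arg(kind), error = function(e) {
    stop_eatdry("eatdry_config", sprintf("unknown disturbance kind '%s'", kind[1]))
  })
  target <- match.arg(target)
  if (kind %in% c("step", "pulse") && is.null(value)) {
    stop_eatdry("eatdry_config", sprintf("%s disturbance needs an absolute 'value'", kind))
  }
  if (kind == "pulse" && is.null(duration)) {
    stop_eatdry("eatdry_config", "pulse disturbance needs a 'duration'")
  }
  if (kind == "sinusoid" && (is.null(delta) || is.null(period))) {
    stop_eatdry("eatdry_config", "sinusoid disturbance needs 'delta' and 'period'")
  }
  structure(list(kind = kind, target = target, value = value, delta = delta,
                 start = start, duration = duration, period = period),
            class = "dryer_disturbance")
}

# Effective hot-air setpoints and ambient temperature at a given clock time.
apply_disturbance <- function(setpoints, ambient_T, disturbances, clock) {
  for (d in disturbances) {
    idx <- switch(d$target,
                  all = 1:3, section1 = 1L, section2 = 2L, section3 = 3L,
                  ambient = 0L)
    eff <- NULL
    if (d$kind == "step") {
      if (clock >= d$start) eff <- d$value
    } else if (d$kind == "pulse") {
      if (clock >= d$start && clock < d$start + d$duration) eff <- d$value
    } else { # sinusoid
      if (clock >= d$start) {
        add <- d$delta * sin(2 * pi * (clock - d$start) / d$period)
        if (identical(idx, 0L)) ambient_T <- ambient_T + add
        else setpoints[idx] <- setpoints[idx] + add
      }
    }
    if (!is.null(eff)) {
      if (identical(idx, 0L)) ambient_T <- eff else setpoints[idx] <- eff
    }
  }
  list(setpoints = setpoints, ambient_T = ambient_T)
}

#' Drying run scenario
#'
#' A scenario bundles run length, hot-air setpoints, inlet-moisture
#' statistics, the disturbance schedule and the seed. Four presets mirror
#' the reference test programme:
#'
#' * `"continuous"`: 110/100/110 degree hot air, initial window area 12,000
#'   degree-minutes, 36 h.
#' * `"step"`: all sections 90 degrees, stepped to 80 at 12 h and back to 90
#'   at 24 h; 33.5 h.
#' * `"pulse"`: all sections 90 degrees; upper section pulsed to 60 degrees
#'   for 10 min at 16 h, lower section to 50 degrees for 10 min at 18.5 h;
#'   26 h.
#' * `"sinusoid"`: continuous-operation setpoints with the ambient
#'   temperature oscillating +/- 2 degrees (4 h period); 24 h.
#'
#' Inlet moisture: each run draws a lot mean uniformly from `inlet_range`
#' (the grain delivered to one run comes from one lot of the campaign),
#' then adds slab-to-slab AR(1) noise of stationary standard deviation
#' `inlet_sd` and autocorrelation `inlet_rho`, clipped to `inlet_range`.
#' Passing `inlet_mean` pins the lot mean instead of drawing it. The
#' controller never sees the realised lot mean — only the inlet sensor's
#' noisy reading of it (config `controller$inlet_sensor_sd`).
#'
#' @param preset One of `"continuous"`, `"step"`, `"pulse"`, `"sinusoid"`.
#' @param duration_h Run length in hours (preset default if `NULL`).
#' @param seed Integer seed driving all randomness of the run.
#' @param setpoints Hot-air setpoints per drying section, degrees C.
#' @param inlet_mean,inlet_sd,inlet_rho,inlet_range Inlet moisture AR(1)
#'   parameters (percent wet basis) and clipping range.
#' @param ambient_T,ambient_RH Ambient conditions (defaults from config).
#' @param disturbances List of [disturbance()] objects (preset default).
#' @param initial_at Initial window area in degree-minutes; `NULL` selects
#'   it from the controller's model via window selection.
#' @param dt_min Integration step override, minutes.
#' @return An object of class `drying_scenario`.
#' @export
drying_scenario <- function(preset = c("continuous", "step", "pulse", "sinusoid"),
                            duration_h = NULL, seed = 1, setpoints = NULL,
                            inlet_mean = NULL, inlet_sd = 0.15,
                            inlet_rho = 0.9, inlet_range = c(24.7, 26.3),
                            ambient_T = NULL, ambient_RH = NULL,
                            disturbances = NULL, initial_at = NULL,
                            dt_min = NULL) {
  preset <- match.arg(preset)
  min_of <- function(h) h * 60
  def <- switch(preset,
    continuous = list(duration_h = 36, setpoints = c(110, 100, 110),
                      initial_at = 12000, disturbances = list()),
    step = list(duration_h = 33.5, setpoints = c(90, 90, 90), initial_at = NULL,
                disturbances = list(
                  disturbance("step", "all", value = 80, start = min_of(12)),
                  disturbance("step", "all", value = 90, start = min_of(24)))),
    pulse = list(duration_h = 26, setpoints = c(90, 90, 90), initial_at = NULL,
                 disturbances = list(
                   disturbance("pulse", "section1", value = 60,
                               start = min_of(16), duration = 10),
                   disturbance("pulse", "section3", value = 50,
                               start = min_of(18.5), duration = 10))),
    sinusoid = list(duration_h = 24, setpoints = c(110, 100, 110),
                    initial_at = 12000,
                    disturbances = list(
                      disturbance("sinusoid", "ambient", delta = 2,
                                  start = 0, period = min_of(4))))
  )
  sc <- list(
    preset = preset,
    duration_h = duration_h %||% def$duration_h,
    setpoints = setpoints %||% def$setpoints,
    inlet_mean = inlet_mean, inlet_sd = inlet_sd, inlet_rho = inlet_rho,
    inlet_range = inlet_range,
    ambient_T = ambient_T, ambient_RH = ambient_RH,
    disturbances = disturbances %||% def$disturbances,
    initial_at = if (is.null(initial_at)) def$initial_at else initial_at,
    dt_min = dt_min, seed = seed
  )
  if (sc$duration_h < 0) stop_eatdry("eatdry_config", "duration must be >= 0")
  if (length(sc$setpoints) != 3) {
    stop_eatdry("eatdry_config", "three hot-air setpoints are required")
  }
  structure(sc, class = "drying_scenario")
}

#' @export
print.drying_scenario <- function(x, ...) {
  cat(sprintf("Drying scenario '%s': %.1f h, hot air %s C, seed %d\n",
              x$preset, x$duration_h,
              paste(x$setpoints, collapse = "/"), x$seed))
  if (length(x$disturbances) > 0) {
    cat(sprintf("  %d disturbance(s): %s\n", length(x$disturbances),
                paste(vapply(x$disturbances, function(d) d$kind, ""),
                      collapse = ", ")))
  }
  invisible(x)
}
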