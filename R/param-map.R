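#' Drying conditions for a thin layer of grain
#'
#' @param T Hot-air temperature, degrees C.
#' @param RH Hot-air relative humidity, fraction in (0, 1).
#' @param V Hot-air velocity, m/s (non-negative).
#' @param W0 Initial grain moisture, percent wet basis, in (0, 100).
#' @param gamma Tempering ratio (tempering time / drying time), >= 0.
#' @return An object of class `drying_conditions` (a validated list).
#' @export
drying_conditions <- function(T, RH, V, W0, gamma = 0) {
  if (any(RH <= 0 | RH >= 1)) {
    stop_eatdry("eatdry_domain", "RH must be a fraction strictly inside (0, 1)")
  }
  if (any(V < 0)) stop_eatdry("eatdry_domain", "air velocity V must be >= 0")
  if (any(W0 <= 0 | W0 >= 100)) {
    stop_eatdry("eatdry_domain", "W0 (% w.b.) must lie in (0, 100)")
  }
  if (any(gamma < 0)) stop_eatdry("eatdry_domain", "tempering ratio gamma must be >= 0")
  structure(list(T = T, RH = RH, V = V, W0 = W0, gamma = gamma),
            class = "drying_conditions")
}

#' Parametric map from drying conditions to Weibull constants
#'
#' The multi-factor regression that would normally be fitted from a designed
#' thin-layer experiment is represented here by a declared smooth map: the
#' offset `a`, amplitude `b` and shape `N` are held at their anchor values,
#' while the rate constant follows a log-linear response surface
#' \deqn{\log k = \log k_{ref} + \alpha_T (T - T_{ref}) + \beta_{RH}(RH - RH_{ref})
#'  + \beta_V (V - V_{ref}) + \beta_W (W_0 - W_{ref})}
#' so that `k` increases with temperature (`alpha_T > 0`) and responds mildly
#' to humidity, airflow and initial moisture. The same map serves as the
#' simulator's ground truth, so a controller holding a perturbed copy has a
#' genuine model mismatch to correct.
#'
#' @param a,b,N Anchor Weibull constants (see [thinlayer_params()]).
#' @param k_ref Anchor rate constant at the reference conditions, per hour^N.
#' @param T_ref,RH_ref,V_ref,W_ref Reference conditions at which `k = k_ref`.
#' @param alpha_T Temperature sensitivity of `log k`, per degree C.
#' @param beta_RH,beta_V,beta_W Humidity, velocity and initial-moisture
#'   sensitivities of `log k`.
#' @param T_range Temperatures outside this range flag extrapolation.
#' @return An object of class `param_map`.
#' @seealso [params_for_conditions()], [calibrate_param_map()]
#' @export
param_map <- function(a = 0.02, b = 0.98, N = 1.1, k_ref = 0.5,
                      T_ref = 100, RH_ref = 0.10, V_ref = 0.6, W_ref = 25.5,
                      alpha_T = 0.010, beta_RH = -0.25, beta_V = 0.05,
                      beta_W = -0.005, T_range = c(40, 130)) {
  stopifnot(k_ref > 0, b > 0, N > 0, length(T_range) == 2, T_range[1] < T_range[2])
  structure(
    list(a = a, b = b, N = N, k_ref = k_ref,
         T_ref = T_ref, RH_ref = RH_ref, V_ref = V_ref, W_ref = W_ref,
         alpha_T = alpha_T, beta_RH = beta_RH, beta_V = beta_V,
         beta_W = beta_W, T_range = T_range),
    class = "param_map"
  )
}

#' @export
print.param_map <- function(x, ...) {
  cat(sprintf(
    "Condition map for Weibull constants: a=%.3g b=%.3g N=%.3g k_ref=%.4g at T=%.4g C\n",
    x$a, x$b, x$N, x$k_ref, x$T_ref))
  invisible(x)
}

#' Weibull constants at given drying conditions
#'
#' Evaluates a [param_map()] at a set of conditions. Deterministic: the same
#' input always yields the same constants. Temperatures outside the map's
#' declared range do not fail, but the result carries attribute
#' `extrapolated = TRUE`.
#'
#' @param map A [param_map()].
#' @param cond A [drying_conditions()] object (fields may be vectorised; all
#'   outputs are then vectors of the common length).
#' @return A [thinlayer_params()] object, with attribute `extrapolated`.
#' @export
params_for_conditions <- function(map, cond) {
  stopifnot(inherits(map, "param_map"), inherits(cond, "drying_conditions"))
  logk <- log(map$k_ref) +
    map$alpha_T * (cond$T - map$T_ref) +
    map$beta_RH * (cond$RH - map$RH_ref) +
    map$beta_V  * (cond$V - map$V_ref) +
    map$beta_W  * (cond$W0 - map$W_ref)
  n <- length(logk)
  out <- structure(
    list(a = rep_len(map$a, n), b = rep_len(map$b, n),
         k = exp(logk), N = rep_len(map$N, n)),
    class = "thinlayer_params"
  )
  extrap <- any(cond$T < map$T_range[1] | cond$T > map$T_range[2])
  if (extrap) {
    warning(sprintf("temperature outside map range [%g, %g]; extrapolating",
                    map$T_range[1], map$T_range[2]))
  }
  attr(out, "extrapolated") <- extrap
  out
}

#' Generate a synthetic thin-layer drying dataset
#'
#' Stands in for a designed thin-layer drying experiment: for each condition
#' in `design` the true Weibull constants come from `true_map`, the analytic
#' curve is sampled at `n_points` times, Gaussian noise of standard deviation
#' `noise_sd` is added in moisture-ratio space, and the result is returned as
#' a flat table ready for CSV export (columns
#' `condition_id, T_C, RH_frac, V_ms, W0_wb, gamma, t_h, Mt_db`).
#'
#' @param true_map A [param_map()] taken as ground truth.
#' @param design A list of [drying_conditions()] (one entry per curve).
#' @param noise_sd Standard deviation of the moisture-ratio noise; >= 0.
#' @param seed Integer seed; the same seed reproduces the same table.
#' @param n_points Samples per curve.
#' @param t_max_h Last sampling time in hours; defaults to the time at which
#'   the true curve reaches moisture ratio `a + 0.05 b` (deep into drying).
#' @param Me_db Equilibrium moisture, percent dry basis.
#' @return A `data.frame` in the thin-layer CSV dialect.
#' @export
generate_thinlayer_dataset <- function(true_map, design, noise_sd = 0.005,
                                       seed = 1, n_points = 40, t_max_h = NULL,
                                       Me_db = 5) {
  stopifnot(inherits(true_map, "param_map"))
  if (length(design) == 0) {
    stop_eatdry("eatdry_domain", "design must contain at least one condition")
  }
  if (noise_sd < 0) stop_eatdry("eatdry_domain", "noise_sd must be >= 0")
  with_local_seed(seed, {
    rows <- lapply(seq_along(design), function(i) {
      cond <- design[[i]]
      stopifnot(inherits(cond, "drying_conditions"))
      p <- params_for_conditions(true_map, cond)
      tm <- t_max_h %||% mr_inverse_kernel(p$a, p$b, p$k, p$N, p$a + 0.05 * p$b)
      t_h <- seq(tm / n_points, tm, length.out = n_points)
      mr <- mr_kernel(p$a, p$b, p$k, p$N, t_h) + stats::rnorm(n_points, 0, noise_sd)
      M0_db <- wb_to_db(cond$W0)
      data.frame(
        condition_id = i, T_C = cond$T, RH_frac = cond$RH, V_ms = cond$V,
        W0_wb = cond$W0, gamma = cond$gamma, t_h = t_h,
        Mt_db = Me_db + (M0_db - Me_db) * mr
      )
    })
    do.call(rbind, rows)
  })
}

#' Write / read the thin-layer CSV dialect
#'
#' Header row, UTF-8, '.' decimal separator, columns
#' `condition_id,T_C,RH_frac,V_ms,W0_wb,gamma,t_h,Mt_db`.
#'
#' @param x Data frame as produced by [generate_thinlayer_dataset()].
#' @param path File path.
#' @return `read_thinlayer_csv` returns the data frame; the writer returns
#'   `path` invisibly.
#' @export
write_thinlayer_csv <- function(x, path) {
  cols <- c("condition_id", "T_C", "RH_frac", "V_ms", "W0_wb", "gamma", "t_h", "Mt_db")
  stopifnot(all(cols %in% names(x)))
  utils::write.csv(x[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_thinlayer_csv
#' @export
read_thinlayer_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
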