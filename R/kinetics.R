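#' Thin-layer Weibull drying constants
#'
#' Container for the four drying constants of the Weibull I thin-layer model
#' \deqn{MR(t) = a + b\,\exp(-k t^N)}
#' where `MR` is the moisture ratio \eqn{(M_t - M_e)/(M_0 - M_e)} and `t` is
#' drying time in hours (tempering time excluded).
#'
#' @param a Dimensionless offset. `MR(t)` tends to `a` as `t` grows.
#' @param b Dimensionless amplitude; must be positive. `MR(0) = a + b`,
#'   which should be close to 1 for a physically meaningful curve.
#' @param k Drying rate constant (per hour^N); must be positive.
#' @param N Dimensionless shape parameter; must be positive.
#' @return An object of class `thinlayer_params`.
#' @examples
#' p <- thinlayer_params(a = 0.02, b = 0.98, k = 0.5, N = 1.1)
#' moisture_ratio(p, t = 1)
#' @export
thinlayer_params <- function(a, b, k, N) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(k), is.numeric(N))
  if (any(!is.finite(c(a, b, k, N)))) {
    stop_eatdry("eatdry_invalid_params", "drying constants must be finite")
  }
  if (any(b <= 0)) stop_eatdry("eatdry_invalid_params", "b must be > 0")
  if (any(k <= 0)) stop_eatdry("eatdry_invalid_params", "k must be > 0")
  if (any(N <= 0)) stop_eatdry("eatdry_invalid_params", "N must be > 0")
  if (any(a + b < 0.9 | a + b > 1.1)) {
    warning("a + b = MR(0) outside [0.9, 1.1]; curve is not physically meaningful")
  }
  structure(list(a = a, b = b, k = k, N = N), class = "thinlayer_params")
}

#' @export
print.thinlayer_params <- function(x, ...) {
  cat("Weibull thin-layer drying constants (t in hours):\n")
  cat(sprintf("  a = %.5g, b = %.5g, k = %.5g h^-N, N = %.5g\n",
              x$a[1], x$b[1], x$k[1], x$N[1]))
  invisible(x)
}

# Raw moisture-ratio kernel without class checks; vectorised over everything.
# Used in inner simulation/GA loops where constructing classed objects per
# step would dominate the cost.
mr_kernel <- function(a, b, k, N, t) a + b * exp(-k * t^N)

# Inverse kernel: time (hours) at which the curve reaches moisture ratio mr.
# Caller must guarantee a < mr < a + b.
mr_inverse_kernel <- function(a, b, k, N, mr) {
  ((log(b) - log(mr - a)) / k)^(1 / N)
}

#' Moisture ratio of the Weibull thin-layer model
#'
#' Evaluates \eqn{MR(t) = a + b\exp(-k t^N)}.
#'
#' @param params A [thinlayer_params()] object.
#' @param t Drying time in hours (tempering excluded); non-negative.
#' @return Dimensionless moisture ratio, same length as `t`.
#' @export
moisture_ratio <- function(params, t) {
  stopifnot(inherits(params, "thinlayer_params"))
  if (any(t < 0)) stop_eatdry("eatdry_domain", "drying time t must be >= 0")
  mr_kernel(params$a, params$b, params$k, params$N, t)
}

#' Moisture content after a given drying time
#'
#' Maps the Weibull moisture ratio back to dry-basis moisture:
#' `Mt = Me + (M0 - Me) * MR(t)`.
#'
#' @inheritParams moisture_ratio
#' @param M0 Initial moisture, percent dry basis; must exceed `Me`.
#' @param Me Equilibrium moisture, percent dry basis.
#' @return Moisture at time `t`, percent dry basis.
#' @export
moisture_at_time <- function(params, t, M0, Me) {
  if (any(M0 <= Me)) {
    stop_eatdry("eatdry_invalid_state", "initial moisture M0 must exceed equilibrium Me")
  }
  Me + (M0 - Me) * moisture_ratio(params, t)
}

#' Drying time required to reach a target moisture
#'
#' Inverts the Weibull I model:
#' \deqn{t = \left[\frac{1}{k}\left(\ln b - \ln\left(\frac{M_t - M_e}{M_0 - M_e} - a\right)\right)\right]^{1/N}}
#' The returned time excludes tempering; multiply by `60 * (1 + gamma)` to
#' obtain total process minutes including tempering holds.
#'
#' @inheritParams moisture_at_time
#' @param Mt Target moisture, percent dry basis; must satisfy `Me < Mt < M0`
#'   and correspond to a moisture ratio inside `(a, a + b)`.
#' @return Drying time in hours.
#' @export
time_for_moisture <- function(params, Mt, M0, Me) {
  stopifnot(inherits(params, "thinlayer_params"))
  if (any(M0 <= Me)) {
    stop_eatdry("eatdry_invalid_state", "initial moisture M0 must exceed equilibrium Me")
  }
  mr <- (Mt - Me) / (M0 - Me)
  if (any(mr - params$a <= 0) || any(mr >= params$a + params$b)) {
    stop_eatdry(
      "eatdry_unreachable_moisture",
      sprintf(
        "target moisture ratio %.4g outside reachable range (%.4g, %.4g)",
        mr[1], params$a[1], params$a[1] + params$b[1]
      )
    )
  }
  mr_inverse_kernel(params$a, params$b, params$k, params$N, mr)
}

#' Convert between wet-basis and dry-basis moisture
#'
#' Wet basis expresses water as a percentage of total mass, dry basis as a
#' percentage of dry matter: `db = 100 wb / (100 - wb)` and
#' `wb = 100 db / (100 + db)`.
#'
#' @param m Moisture percentage (vectorised).
#' @param from Basis of `m`: `"wb"` (wet) or `"db"` (dry).
#' @return Moisture percentage on the other basis.
#' @examples
#' convert_basis(14.5, "wb")   # ~16.96 % d.b.
#' wb_to_db(50)                # 100
#' @export
convert_basis <- function(m, from = c("wb", "db")) {
  from <- match.arg(from)
  if (from == "wb") wb_to_db(m) else db_to_wb(m)
}

#' @rdname convert_basis
#' @export
wb_to_db <- function(m) {
  if (any(m < 0 | m >= 100)) {
    stop_eatdry("eatdry_domain", "wet-basis moisture must lie in [0, 100)")
  }
  100 * m / (100 - m)
}

#' @rdname convert_basis
#' @export
db_to_wb <- function(m) {
  if (any(m < 0)) stop_eatdry("eatdry_domain", "dry-basis moisture must be >= 0")
  100 * m / (100 + m)
}
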