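#' Fit the Weibull I thin-layer model to a drying curve
#'
#' Nonlinear least squares in moisture-ratio space using bounded
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]) with a small seeded
#' multi-start to avoid local minima. Goodness of fit is reported as the
#' determination coefficient R^2, the reduced chi-square statistic
#' `sum((obs - pred)^2) / (n - p)` and the root-mean-square error, all on the
#' moisture-ratio scale.
#'
#' Non-convergence (including degenerate inputs such as a flat curve) does
#' not raise an error: the returned object has `converged = FALSE` and
#' carries the failure message as a diagnostic.
#'
#' @param t Drying times in hours, strictly increasing, at least 6 points.
#' @param Mt Observed moisture, percent dry basis, same length as `t`.
#' @param M0 Initial moisture, percent dry basis. Defaults to the first
#'   observation extrapolated to `MR(0) = 1`.
#' @param Me Equilibrium moisture, percent dry basis; must be below all `Mt`.
#' @param bounds Named list with `lower` and `upper` vectors over
#'   `(a, b, k, N)`. Defaults to a in \[-0.2, 0.3\], b in \[0.5, 1.5\],
#'   k in (0, 10\], N in (0.3, 3\].
#' @param n_starts Number of multi-start attempts (>= 1).
#' @param seed Seed for the start-point jitter.
#' @return An object of class `weibull_fit` with elements `params`
#'   ([thinlayer_params()] when converged), `r2`, `chi2`, `rmse`, `n_points`,
#'   `converged`, `message`, plus the data used.
#' @examples
#' p <- thinlayer_params(0, 1, 0.5, 1.1)
#' t <- seq(0.1, 4, length.out = 20)
#' Mt <- moisture_at_time(p, t, M0 = 30, Me = 10)
#' fit <- fit_weibull(t, Mt, M0 = 30, Me = 10)
#' coef(fit)
#' @export
fit_weibull <- function(t, Mt, M0 = NULL, Me, bounds = NULL, n_starts = 3,
                        seed = 1) {
  if (length(t) < 6) {
    stop_eatdry("eatdry_domain", "at least 6 points are required to fit 4 constants")
  }
  if (length(Mt) != length(t)) stop_eatdry("eatdry_domain", "t and Mt lengths differ")
  if (any(diff(t) <= 0)) stop_eatdry("eatdry_domain", "t must be strictly increasing")
  if (is.null(M0)) M0 <- max(Mt)
  if (M0 <= Me) {
    stop_eatdry("eatdry_invalid_state", "initial moisture M0 must exceed equilibrium Me")
  }
  mr <- (Mt - Me) / (M0 - Me)

  lower <- (bounds$lower %||% c(a = -0.2, b = 0.5, k = 1e-6, N = 0.3))
  upper <- (bounds$upper %||% c(a = 0.3, b = 1.5, k = 10, N = 3))

  failed <- function(msg) {
    structure(
      list(params = NULL, r2 = NA_real_, chi2 = NA_real_, rmse = NA_real_,
           n_points = length(t), converged = FALSE, message = msg,
           data = data.frame(t = t, MR = mr, Mt = Mt),
           boundaries = c(M0 = M0, Me = Me)),
      class = "weibull_fit"
    )
  }
  if (stats::sd(mr) < 1e-10) {
    return(failed("degenerate curve: moisture ratio is constant (no drying)"))
  }

  # Heuristic rate scale from the half-drying time of the observed curve.
  half_idx <- which(mr <= (max(mr) + min(mr)) / 2)[1]
  k0 <- if (is.na(half_idx)) 1 else log(2) / max(t[half_idx], min(diff(t)))
  k0 <- clamp(k0, lower["k"] * 2, upper["k"] / 2)

  df <- data.frame(t = t, mr = mr)
  best <- NULL
  with_local_seed(seed, {
    for (s in seq_len(n_starts)) {
      start <- list(
        a = clamp(0.02 + (s - 1) * stats::runif(1, -0.05, 0.05), lower["a"], upper["a"]),
        b = clamp(1.0 + (s - 1) * stats::runif(1, -0.1, 0.1), lower["b"], upper["b"]),
        k = clamp(k0 * c(1, 0.3, 3, 0.1, 10)[(s - 1) %% 5 + 1], lower["k"], upper["k"]),
        N = clamp(1 + (s - 1) * stats::runif(1, -0.3, 0.3), lower["N"], upper["N"])
      )
      fit <- tryCatch(
        minpack.lm::nlsLM(
          mr ~ a + b * exp(-k * t^N), data = df, start = start,
          lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) e
      )
      if (inherits(fit, "nls")) {
        sse <- sum(stats::residuals(fit)^2)
        if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
      }
    }
  })
  if (is.null(best)) {
    return(failed("nonlinear least squares failed to converge from all starts"))
  }

  cf <- stats::coef(best$fit)
  sse <- best$sse
  sst <- sum((mr - mean(mr))^2)
  n <- length(t)
  params <- suppressWarnings(thinlayer_params(
    unname(cf["a"]), unname(cf["b"]), unname(cf["k"]), unname(cf["N"])))
  structure(
    list(params = params,
         r2 = 1 - sse / sst,
         chi2 = sse / (n - 4),
         rmse = sqrt(sse / n),
         n_points = n, converged = TRUE, message = "converged",
         data = data.frame(t = t, MR = mr, Mt = Mt),
         boundaries = c(M0 = M0, Me = Me),
         fit = best$fit),
    class = "weibull_fit"
  )
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("Weibull I thin-layer drying fit\n")
  if (!x$converged) {
    cat("  did not converge:", x$message, "\n")
    return(invisible(x))
  }
  p <- x$params
  cat(sprintf("  a = %.5g  b = %.5g  k = %.5g h^-N  N = %.5g\n", p$a, p$b, p$k, p$N))
  cat(sprintf("  n = %d   R2 = %.6f   chi2 = %.3e   RMSE = %.3e (MR scale)\n",
              x$n_points, x$r2, x$chi2, x$rmse))
  invisible(x)
}

#' @export
summary.weibull_fit <- function(object, ...) {
  print(object)
  if (object$converged) {
    cat(sprintf("  boundaries: M0 = %.3f, Me = %.3f %% d.b.\n",
                object$boundaries["M0"], object$boundaries["Me"]))
  }
  invisible(object)
}

#' @export
coef.weibull_fit <- function(object, ...) {
  if (!object$converged) return(c(a = NA_real_, b = NA_real_, k = NA_real_, N = NA_real_))
  with(object$params, c(a = a, b = b, k = k, N = N))
}

#' Predict moisture from a fitted thin-layer model
#'
#' @param object A `weibull_fit`.
#' @param newdata Optional data frame with column `t` (hours); defaults to
#'   the fitted times.
#' @param type `"Mt"` for percent dry basis, `"MR"` for moisture ratio.
#' @param ... Unused.
#' @export
predict.weibull_fit <- function(object, newdata = NULL,
                                type = c("Mt", "MR"), ...) {
  type <- match.arg(type)
  if (!object$converged) stop_eatdry("eatdry_fit_failure", "fit did not converge")
  t <- if (is.null(newdata)) object$data$t else newdata$t
  mr <- moisture_ratio(object$params, t)
  if (type == "MR") mr
  else object$boundaries["Me"] + diff(object$boundaries[c("Me", "M0")]) * mr
}

#' @export
residuals.weibull_fit <- function(object, ...) {
  if (!object$converged) stop_eatdry("eatdry_fit_failure", "fit did not converge")
  object$data$MR - moisture_ratio(object$params, object$data$t)
}

#' @export
fitted.weibull_fit <- function(object, ...) {
  predict.weibull_fit(object, type = "MR")
}

#' Simulate replicate drying curves from a fitted model
#'
#' @param object A converged `weibull_fit`.
#' @param nsim Number of replicate curves.
#' @param seed Seed for the Gaussian moisture-ratio noise.
#' @param noise_sd Noise standard deviation; defaults to the fit RMSE.
#' @param ... Unused.
#' @return A data frame with columns `sim`, `t`, `MR`.
#' @export
simulate.weibull_fit <- function(object, nsim = 1, seed = NULL,
                                 noise_sd = NULL, ...) {
  if (!object$converged) stop_eatdry("eatdry_fit_failure", "fit did not converge")
  noise_sd <- noise_sd %||% object$rmse
  t <- object$data$t
  mu <- moisture_ratio(object$params, t)
  with_local_seed(seed, {
    do.call(rbind, lapply(seq_len(nsim), function(i) {
      data.frame(sim = i, t = t, MR = mu + stats::rnorm(length(t), 0, noise_sd))
    }))
  })
}

#' @export
plot.weibull_fit <- function(x, ...) {
  plot(x$data$t, x$data$MR, xlab = "drying time (h)", ylab = "moisture ratio",
       main = "Weibull I thin-layer fit", ...)
  if (x$converged) {
    tt <- seq(min(x$data$t), max(x$data$t), length.out = 200)
    graphics::lines(tt, moisture_ratio(x$params, tt), col = "red3", lwd = 2)
  }
  invisible(x)
}
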