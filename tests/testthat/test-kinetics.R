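test_that("moisture ratio follows the Weibull I curve", {
  p1 <- thinlayer_params(a = 0, b = 1, k = 0.01, N = 1)
  expect_equal(moisture_ratio(p1, 0), 1.0)
  expect_equal(moisture_ratio(p1, 100), exp(-1))
  # direct evaluation of the formula, written out independently
  p2 <- thinlayer_params(a = 0.02, b = 0.98, k = 0.05, N = 1.2)
  expect_equal(moisture_ratio(p2, 30), 0.02 + 0.98 * exp(-0.05 * 30^1.2),
               tolerance = 1e-12)
  expect_error(moisture_ratio(p1, -1), class = "eatdry_domain")
})

test_that("parameter validation enforces the physical invariants", {
  expect_error(thinlayer_params(0, -1, 0.5, 1), class = "eatdry_invalid_params")
  expect_error(thinlayer_params(0, 1, 0, 1), class = "eatdry_invalid_params")
  expect_error(thinlayer_params(0, 1, 0.5, -1), class = "eatdry_invalid_params")
  expect_warning(thinlayer_params(0.5, 1, 0.5, 1), "outside")
})

test_that("moisture at time maps the ratio onto the dry-basis scale", {
  p <- thinlayer_params(0, 1, 0.01, 1)
  expect_equal(moisture_at_time(p, 0, M0 = 30, Me = 10), 30)
  expect_equal(moisture_at_time(p, 100, M0 = 30, Me = 10), 10 + 20 * exp(-1))
  expect_error(moisture_at_time(p, 1, M0 = 10, Me = 30),
               class = "eatdry_invalid_state")
})

test_that("the time inverse reproduces the forward curve", {
  p <- thinlayer_params(0, 1, 0.01, 1)
  # inverse at the start and at the closed-form point
  expect_equal(time_for_moisture(p, Mt = 10 + 20 * exp(-1), M0 = 30, Me = 10), 100)
  # unreachable targets
  expect_error(time_for_moisture(p, Mt = 30, M0 = 30, Me = 10),
               class = "eatdry_unreachable_moisture")
  expect_error(time_for_moisture(p, Mt = 9, M0 = 30, Me = 10),
               class = "eatdry_unreachable_moisture")
})

test_that("forward/inverse roundtrip holds across the parameter space", {
  set.seed(42)
  for (i in 1:25) {
    p <- suppressWarnings(thinlayer_params(
      a = runif(1, -0.1, 0.1), b = runif(1, 0.9, 1.05),
      k = runif(1, 0.05, 2), N = runif(1, 0.5, 2)))
    M0 <- runif(1, 28, 36); Me <- runif(1, 3, 8)
    mr <- runif(1, p$a + 1e-6, p$a + p$b - 1e-6)
    Mt <- Me + (M0 - Me) * mr
    t <- time_for_moisture(p, Mt, M0, Me)
    expect_lt(abs(moisture_at_time(p, t, M0, Me) - Mt), 1e-9 * (M0 - Me))
  }
})

test_that("moisture ratio decreases strictly in time", {
  p <- thinlayer_params(0.02, 0.98, 0.5, 1.1)
  t <- seq(0.01, 10, length.out = 200)
  expect_true(all(diff(moisture_ratio(p, t)) < 0))
})

test_that("basis conversion is exact and involutive", {
  expect_equal(wb_to_db(0), 0)
  expect_equal(wb_to_db(50), 100)
  expect_equal(wb_to_db(14.5), 100 * 14.5 / 85.5, tolerance = 1e-12)
  expect_equal(convert_basis(convert_basis(14.5, "wb"), "db"), 14.5,
               tolerance = 1e-12)
  m <- seq(0.5, 95, by = 0.5)
  expect_equal(db_to_wb(wb_to_db(m)), m, tolerance = 1e-12)
  expect_error(wb_to_db(100), class = "eatdry_domain")
})

test_that("fitting recovers known constants from a clean curve", {
  truth <- thinlayer_params(0, 1, 0.5, 1.1)
  t <- seq(0.1, 6, length.out = 30)
  Mt <- moisture_at_time(truth, t, M0 = 30, Me = 5)
  fit <- fit_weibull(t, Mt, M0 = 30, Me = 5)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(0, 1, 0.5, 1.1), tolerance = 1e-5)
  expect_gt(fit$r2, 1 - 1e-10)
  expect_lt(fit$rmse, 1e-6)
  expect_equal(fit$n_points, 30)
})

test_that("fitting survives noise and degenerate input", {
  truth <- thinlayer_params(0.02, 0.98, 0.5, 1.1)
  t <- seq(0.1, 6, length.out = 40)
  mr <- moisture_ratio(truth, t)
  set.seed(7)
  Mt <- 5 + 25 * (mr + rnorm(40, 0, 0.005))
  fit <- fit_weibull(t, Mt, M0 = 30, Me = 5, seed = 7)
  expect_true(fit$converged)
  rel <- abs(coef(fit) - unlist(truth)) / abs(unlist(truth))
  expect_true(all(rel[c("b", "k", "N")] < 0.10))
  # flat curve: a diagnostic failure object, never an error
  flat <- fit_weibull(t, rep(20, 40), M0 = 30, Me = 5)
  expect_false(flat$converged)
  expect_match(flat$message, "degenerate")
  expect_true(all(is.na(coef(flat))))
  expect_error(fit_weibull(t[1:4], Mt[1:4], M0 = 30, Me = 5),
               class = "eatdry_domain")
})

test_that("parameter recovery holds over replicated synthetic curves", {
  map <- param_map(k_ref = 0.5)
  design <- lapply(seq(80, 120, length.out = 20), function(T) {
    drying_conditions(T = T, RH = 0.1, V = 0.6, W0 = 25.5, gamma = 0.5)
  })
  tab <- generate_thinlayer_dataset(map, design, noise_sd = 0.005, seed = 11)
  rel_err <- sapply(unique(tab$condition_id), function(id) {
    cur <- tab[tab$condition_id == id, ]
    truth <- params_for_conditions(map, design[[id]])
    fit <- fit_weibull(cur$t_h, cur$Mt_db, M0 = wb_to_db(cur$W0_wb[1]),
                       Me = 5, seed = id)
    if (!fit$converged) return(rep(NA_real_, 4))
    abs(coef(fit) - c(truth$a, truth$b, truth$k, truth$N)) /
      pmax(abs(c(truth$a, truth$b, truth$k, truth$N)), 1e-6)
  })
  # median relative error of b, k, N within 10 % (a ~ 0 is scale-free)
  med <- apply(rel_err, 1, stats::median, na.rm = TRUE)
  expect_true(all(med[2:4] <= 0.10))
})

test_that("the condition map is deterministic, anchored and monotone in T", {
  map <- param_map(k_ref = 0.5)
  anchor <- drying_conditions(T = 100, RH = 0.10, V = 0.6, W0 = 25.5, gamma = 0.5)
  p <- params_for_conditions(map, anchor)
  expect_equal(p$k, 0.5)           # identity at the calibration point
  expect_equal(p$a, map$a)
  hot <- params_for_conditions(map, drying_conditions(110, 0.10, 0.6, 25.5, 0.5))
  expect_gt(hot$k, p$k)            # k strictly increases with temperature
  expect_identical(p, params_for_conditions(map, anchor))
  expect_warning(
    out <- params_for_conditions(map, drying_conditions(200, 0.1, 0.6, 25.5, 0.5)),
    "extrapolating")
  expect_true(attr(out, "extrapolated"))
})

test_that("the simulator and the generator share one truth map", {
  cfg <- test_cfg()
  temps <- c(70, 85, 100, 115, 125)
  for (T in temps) {
    cond <- drying_conditions(T, cfg$kinetics$rh_hot, cfg$kinetics$V_air,
                              25.5, cfg$sim$gamma)
    p <- params_for_conditions(cfg$truth_map, cond)
    k_sim <- eatdry:::map_k_fast(cfg$truth_map, T, cfg$kinetics$rh_hot,
                                 cfg$kinetics$V_air, 25.5)
    expect_equal(p$k, k_sim, tolerance = 1e-12)
  }
})

test_that("the thin-layer dataset generator is reproducible", {
  map <- param_map(k_ref = 0.5)
  design <- list(drying_conditions(100, 0.1, 0.6, 25.5, 0.5))
  t1 <- generate_thinlayer_dataset(map, design, noise_sd = 0.005, seed = 3)
  t2 <- generate_thinlayer_dataset(map, design, noise_sd = 0.005, seed = 3)
  expect_identical(t1, t2)
  expect_named(t1, c("condition_id", "T_C", "RH_frac", "V_ms", "W0_wb",
                     "gamma", "t_h", "Mt_db"))
  clean <- generate_thinlayer_dataset(map, design, noise_sd = 0, seed = 3)
  fit <- fit_weibull(clean$t_h, clean$Mt_db, M0 = wb_to_db(25.5), Me = 5)
  truth <- params_for_conditions(map, design[[1]])
  expect_equal(unname(coef(fit)), c(truth$a, truth$b, truth$k, truth$N),
               tolerance = 1e-4)
  expect_error(generate_thinlayer_dataset(map, list(), seed = 1),
               class = "eatdry_domain")
})

test_that("thin-layer CSV writer and reader roundtrip", {
  map <- param_map(k_ref = 0.5)
  design <- list(drying_conditions(100, 0.1, 0.6, 25.5, 0.5))
  tab <- generate_thinlayer_dataset(map, design, noise_sd = 0.002, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_thinlayer_csv(tab, path)
  back <- read_thinlayer_csv(path)
  expect_equal(back$Mt_db, tab$Mt_db, tolerance = 1e-10)
  expect_identical(names(back), names(tab))
})

test_that("weibull_fit methods behave like a model object", {
  truth <- thinlayer_params(0.02, 0.98, 0.6, 1.2)
  t <- seq(0.1, 5, length.out = 25)
  Mt <- moisture_at_time(truth, t, M0 = 32, Me = 6)
  fit <- fit_weibull(t, Mt, M0 = 32, Me = 6)
  expect_s3_class(fit, "weibull_fit")
  expect_length(residuals(fit), 25)
  expect_lt(max(abs(residuals(fit))), 1e-7)
  expect_equal(predict(fit, newdata = data.frame(t = 0), type = "MR"),
               1.0, tolerance = 1e-5, ignore_attr = TRUE)
  sims <- simulate(fit, nsim = 2, seed = 1, noise_sd = 0.01)
  expect_identical(sims, simulate(fit, nsim = 2, seed = 1, noise_sd = 0.01))
  expect_output(print(fit), "Weibull I")
})
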