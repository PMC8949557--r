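test_that("accumulated temperature integrates the clipped excess", {
  # constant trace: left-rectangle sum is exact at any spacing
  expect_equal(accumulated_temperature(c(0, 100), c(60, 60), Te = 25), 3500)
  expect_equal(accumulated_temperature(seq(0, 100, by = 0.1),
                                       rep(60, 1001), Te = 25), 3500)
  expect_equal(accumulated_temperature(c(0, 50, 100), c(25, 25, 25), Te = 25), 0)
  expect_error(accumulated_temperature(c(0, 10, 5), c(1, 2, 3), 0),
               class = "eatdry_domain")
  expect_error(accumulated_temperature(0, 60, 25), class = "eatdry_domain")
})

test_that("sub-equilibrium segments are clipped, matching brute force", {
  set.seed(5)
  for (i in 1:10) {
    t <- cumsum(runif(50, 0.1, 2))
    T <- runif(50, 15, 80)
    Te <- runif(1, 20, 30)
    brute <- 0
    for (j in 1:49) brute <- brute + max(T[j] - Te, 0) * (t[j + 1] - t[j])
    expect_equal(accumulated_temperature(t, T, Te), brute, tolerance = 1e-12)
  }
})

test_that("theoretical accumulated temperature combines drive, tempering and time", {
  # params chosen so the drying time is exactly 2 h
  p <- thinlayer_params(0, 1, 0.5, 1)
  Mt <- 10 + 20 * exp(-1)  # MR = e^-1 at t = 2 h when k = 0.5
  expect_equal(theoretical_at(p, Tf = 90, Te = 25, Mt = Mt, M0 = 30, Me = 10,
                              gamma = 0.5),
               65 * 60 * 1.5 * 2, tolerance = 1e-9)
  expect_equal(theoretical_at(p, Tf = 90, Te = 25, Mt = Mt, M0 = 30, Me = 10,
                              gamma = 0),
               65 * 60 * 2, tolerance = 1e-9)
  expect_error(theoretical_at(p, Tf = 20, Te = 25, Mt = Mt, M0 = 30, Me = 10),
               class = "eatdry_domain")
  expect_error(theoretical_at(p, Tf = 90, Te = 25, Mt = 30, M0 = 30, Me = 10),
               class = "eatdry_unreachable_moisture")
})

test_that("the default drying task lands in the expected window band", {
  cfg <- test_cfg()
  p <- params_for_conditions(
    cfg$truth_map,
    drying_conditions(cfg$Tf_ref, cfg$kinetics$rh_hot, cfg$kinetics$V_air,
                      25.5, cfg$sim$gamma))
  at0 <- theoretical_at(p, Tf = cfg$Tf_ref, Te = cfg$Te_ref,
                        Mt = wb_to_db(14.5), M0 = wb_to_db(25.5),
                        Me = cfg$kinetics$Me_db, gamma = cfg$sim$gamma)
  expect_gt(at0, 8000)
  expect_lt(at0, 20000)
})

test_that("discharge counts derive from the section volumes", {
  counts <- section_pass_counts(dryer_geometry())
  expect_equal(unname(counts), c(11.5, 13.5, 13.5, 20.2))
  # per-discharge volume doubled: counts derive from the same arithmetic
  halved <- section_pass_counts(dryer_geometry(Vp = 16))
  g <- dryer_geometry(Vp = 16)
  expect_equal(unname(halved),
               round(c(g$Vg1, g$Vg2h1, g$Vg3h2, g$Vl + g$Vpp) / 16, 1))
})

test_that("printed and geometry-derived weights expose the published inconsistencies", {
  printed <- eat_coefficients(dryer_geometry(), "printed")
  derived <- eat_coefficients(dryer_geometry(), "geometry")
  # upper zone agrees
  expect_equal(unname(printed[1]), unname(derived[1]))
  # the published closed form applies the COMBINED middle+lower pass count
  # (13.5 + 13.5 = 27) to each of those zone excesses, where the per-zone
  # passage times give 13.5 each
  expect_equal(unname(printed[2]), unname(derived[2] + derived[3]))
  expect_equal(unname(printed[2:3]), c(27, 27))
  expect_equal(unname(derived[2:3]), c(13.5, 13.5))
  # the published zone-4 weight is 21.2 while the volumes imply 20.2
  expect_equal(unname(printed[4]), 21.2)
  expect_equal(unname(derived[4]), 20.2)
  expect_warning(eat_coefficients(dryer_geometry(Vp = 16), "printed"),
                 "default geometry")
})

test_that("the dryer EAT model reproduces the published arithmetic", {
  Tbar <- c(60, 55, 50, 30)
  expect_equal(dryer_eat(Tbar, Te = 25, tx = 10),
               (11.5 * 35 + 27 * 55 + 21.2 * 5) * 10.5)
  expect_equal(dryer_eat(rep(25, 4), Te = 25, tx = 10), 0)
  # the geometry path evaluates the same zone sum with the derived counts
  co_g <- eat_coefficients(dryer_geometry(), "geometry")
  expect_equal(dryer_eat(Tbar, 25, 10, coefficients = "geometry"),
               sum(co_g * (Tbar - 25)) * 10.5, tolerance = 1e-12)
  # upper-zone terms of the two paths agree; the rest differ as published
  expect_equal(11.5 * 35 * 10.5,
               unname(co_g[1] * (Tbar[1] - 25) * 10.5))
})

test_that("dryer EAT is linear in the interval and each zone excess", {
  Tbar <- c(80, 95, 100, 35); Te <- 25
  base <- dryer_eat(Tbar, Te, tx = 5)
  # linear in (tx + 0.5)
  expect_equal(dryer_eat(Tbar, Te, tx = 10.5) / base, 11 / 5.5, tolerance = 1e-12)
  # superposition over zone excesses
  co <- eat_coefficients(dryer_geometry(), "printed")
  for (z in 1:4) {
    bump <- Tbar; bump[z] <- bump[z] + 7
    expect_equal(dryer_eat(bump, Te, tx = 5) - base, co[z] * 7 * 5.5,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("the discharge interval solve inverts the EAT model exactly", {
  Tbar <- c(60, 55, 50, 30); Te <- 25
  tx <- solve_discharge_interval(Tbar, Te, AT_set = 12000)
  expect_equal(as.numeric(tx), 12000 / 1993.5 - 0.5, tolerance = 1e-9)
  expect_false(attr(tx, "floored"))
  set.seed(31)
  for (i in 1:15) {
    Tb <- c(runif(3, 40, 110), runif(1, 26, 45))
    at <- runif(1, 6000, 18000)
    tx_i <- solve_discharge_interval(Tb, Te, at, tx_min = 1e-6)
    expect_equal(dryer_eat(Tb, Te, as.numeric(tx_i)), at, tolerance = 1e-9)
  }
  expect_error(solve_discharge_interval(rep(25, 4), 25, 12000),
               class = "eatdry_cannot_actuate")
  floored <- solve_discharge_interval(c(60, 55, 50, 30), 25, 500, tx_min = 0.5)
  expect_true(attr(floored, "floored"))
  expect_equal(as.numeric(floored), 0.5)
})

test_that("geometry validation and totals", {
  expect_error(dryer_geometry(Vp = 0), class = "eatdry_config")
  expect_equal(total_bed_volume(dryer_geometry()),
               92.382 + 107.971 + 107.971 + 92.382 + 69.027)
})
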