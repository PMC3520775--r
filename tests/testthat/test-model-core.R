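test_that("tariquidar effect schedule D follows the covariate algebra", {
  effs <- covariate_effects(Eff_tariquidar = c("3" = 0.161, "15" = 0.135),
                            Eff_scan = 1.33)
  ev <- data.frame(dose_group = 3, start = 60, duration = 1)
  # untreated: D = 1 at any time in either scan
  expect_equal(effect_D(NULL, 1, c(0, 50, 139), effs), rep(1, 3))
  expect_equal(effect_D(ev[0, ], 2, 30, effs), 1)
  # baseline scan: 1 before administration, Eff_tariquidar afterwards
  expect_equal(effect_D(ev, 1, c(30, 59.9, 60, 90, 139), effs),
               c(1, 1, 0.161, 0.161, 0.161))
  # post-inhibition scan: Eff_tariquidar * Eff_scan throughout
  expect_equal(effect_D(ev, 2, c(0, 30, 59), effs), rep(0.21413, 3))
  ev15 <- data.frame(dose_group = 15, start = 60, duration = 1)
  expect_equal(effect_D(ev15, 1, 90, effs), 0.135)
  # unknown dose group is a configuration error
  ev9 <- data.frame(dose_group = 9, start = 60, duration = 1)
  expect_error(effect_D(ev9, 1, 90, effs), "dose group")
})

test_that("lognormal individual-parameter model", {
  expect_equal(individual_from_population(16.4, 0), 16.4)
  expect_equal(individual_from_population(16.4, log(2)), 32.8)
  expect_error(individual_from_population(-1, 0), "positive")
  # median over many draws equals the typical value (lognormal median)
  withr::with_seed(401, {
    draws <- individual_from_population(16.4, rnorm(1e5, 0, 0.162))
    expect_equal(median(draws), 16.4, tolerance = 0.005)
    # between-subject CV matches sqrt(exp(omega^2) - 1)
    expect_equal(sd(draws) / mean(draws), sqrt(exp(0.162^2) - 1),
                 tolerance = 0.02)
  })
})

test_that("status-epilepticus covariate on Vbr1", {
  expect_equal(apply_se_covariate(0.132, 1.84, "control"), 0.132)
  expect_equal(apply_se_covariate(0.132, 1.84, "post_SE"), 0.24288)
  expect_equal(apply_se_covariate(0.132, 1, "post_SE"), 0.132)
})

test_that("plasma simulation: linearity, AUC identity, mass balance", {
  p <- plasma_params(38.8, 141, 1580, 16.4, 29.1, 22.3)
  times <- sort(unique(c(seq(0.1, 20, 0.1), seq(21, 300, 1),
                         seq(305, 20000, 5))))
  zero <- simulate_plasma(p, data.frame(amount = 0, start = 0, duration = 0.4),
                          times = 1:10)
  expect_true(all(zero$value == 0))
  one <- simulate_plasma(p, data.frame(amount = 91000, start = 0,
                                       duration = 0.4), times)
  two <- simulate_plasma(p, data.frame(amount = 182000, start = 0,
                                       duration = 0.4), times)
  expect_equal(two$value, 2 * one$value, tolerance = 1e-12)
  # linear-PK identity AUC(0, inf) = dose / CL
  auc <- sum(diff(c(0, times)) * (c(0, head(one$value, -1)) + one$value) / 2)
  expect_equal(auc, 91000 / 16.4, tolerance = 1e-3)
  # with CL = 0 the total amount is conserved after the infusion ends
  p0 <- plasma_params(38.8, 141, 1580, 1e-12, 29.1, 22.3)
  M <- petnlme:::.plasma_matrix(p0)
  M[1, 1] <- -(29.1 + 22.3) / 38.8  # exactly zero elimination
  seg <- petnlme:::.dose_segments(
    data.frame(amount = 91000, start = 0, duration = 0.4), 500)
  A <- petnlme:::.lin_const_solve(M, seg$breaks, seg$rates,
                                  c(0.5, 5, 50, 500))
  totals <- colSums(A)
  expect_equal(max(abs(totals - 91000)) / 91000, 0, tolerance = 1e-9)
})

test_that("plasma simulation matches the adaptive ODE oracle", {
  p <- plasma_params(38.8, 141, 1580, 16.4, 29.1, 22.3)
  times <- c(0.25, 0.5, 1, 2, 5, 10, 30, 60, 100, 139)
  sim <- simulate_plasma(p, data.frame(amount = 91000, start = 0,
                                       duration = 0.4), times)
  orc <- ode_plasma_oracle(p, 91000, 0.4, times)
  expect_lt(max(abs(sim$value - orc) / orc), 1e-6)
})

test_that("brain simulation: influx shutoff, steady state, ODE oracle", {
  bp <- brain_params(0.132, 2, 5.62, 3.60, 0.115)
  effs <- covariate_effects(Eff_tariquidar = c("3" = 0.161), Eff_scan = 1.33)
  flat <- tac("plasma", seq(0, 3000, 5), rep(8, 601))
  # no influx, no signal
  bp0 <- brain_params(0.132, 2, 1e-300, 3.60, 0.115)
  z <- simulate_brain(bp0, effs, flat, NULL, 1, times = c(10, 100))
  expect_equal(z$value, c(0, 0))
  # steady state without inhibitor: brain/plasma -> Qin/Qout
  ss <- simulate_brain(bp, effs, flat, NULL, 1, times = 3000)
  expect_equal(ss$value / 8, 5.62 / 3.60, tolerance = 1e-3)
  # with inhibitor on the efflux clearance: Qin/(D * Qout); the slowest
  # equilibration time constant is minutes, 3000 min is > 20 half-lives
  ev <- data.frame(dose_group = 3, start = 0.01, duration = 1)
  ssd <- simulate_brain(bp, effs, flat, ev, 1, times = 3000)
  expect_equal(ssd$value / 8, 5.62 / (0.161 * 3.60), tolerance = 1e-3)
  # against the RK45 oracle driven by the same interpolated forcing
  p <- plasma_params(38.8, 141, 1580, 16.4, 29.1, 22.3)
  ft <- sort(unique(c(seq(0, 5, 0.1), seq(5.25, 20, 0.25), seq(21, 139, 1),
                      60)))
  fc <- c(0, simulate_plasma(p, data.frame(amount = 91000, start = 0,
                                           duration = 0.4), ft[-1])$value)
  forcing <- tac("plasma", ft, fc)
  ev60 <- data.frame(dose_group = 3, start = 60, duration = 1)
  times <- c(1, 5, 20, 59, 61, 80, 120, 139)
  sim <- simulate_brain(bp, effs, forcing, ev60, 1, times = times)
  orc <- ode_brain_oracle(bp, "on_Qout", ft, fc,
                          function(t) ifelse(t >= 60, 0.161, 1), times)
  expect_lt(max(abs(sim$value - orc) / orc), 1e-6)
})

test_that("matrix-exponential and ODE-oracle solutions agree across random models", {
  withr::with_seed(402, {
    for (i in 1:10) {
      p <- plasma_params(runif(1, 5, 100), runif(1, 50, 500),
                         runif(1, 200, 3000), runif(1, 2, 40),
                         runif(1, 5, 60), runif(1, 5, 60))
      times <- c(0.5, 2, 10, 45, 120)
      sim <- simulate_plasma(p, data.frame(amount = 5e4, start = 0,
                                           duration = 0.5), times)
      orc <- ode_plasma_oracle(p, 5e4, 0.5, times)
      expect_lt(max(abs(sim$value - orc) / pmax(orc, 1e-12)), 1e-6)
    }
  })
})

test_that("decreasing D strictly increases brain exposure for efflux placement", {
  p <- plasma_params(38.8, 141, 1580, 16.4, 29.1, 22.3)
  ft <- sort(unique(c(seq(0, 5, 0.1), seq(5.5, 140, 0.5))))
  fc <- c(0, simulate_plasma(p, data.frame(amount = 91000, start = 0,
                                           duration = 0.4), ft[-1])$value)
  forcing <- tac("plasma", ft, fc)
  ev <- data.frame(dose_group = 3, start = 60, duration = 1)
  times <- seq(2, 140, 2)
  for (qin in c(2, 5.62)) {
    for (qout in c(1.5, 3.6)) {
      bp <- brain_params(0.132, 2, qin, qout, 0.115)
      aucs <- vapply(c(1, 0.5, 0.25, 0.1), function(D) {
        effs <- covariate_effects(Eff_tariquidar = c("3" = D))
        cur <- simulate_brain(bp, effs, forcing, ev, 1, times = times)
        sum(diff(c(0, times)) * cur$value)
      }, numeric(1))
      expect_true(all(diff(aucs) > 0))
    }
  }
})

test_that("SUV normalization", {
  x <- tac("brain", c(1, 2, 3), c(500, 350, 100))
  suv <- suv_normalize(x, injected = 91000, body_weight = 260)
  expect_equal(suv$value[1], 500 * 260 / 91000)
  expect_equal(suv$value[1], 1.4286, tolerance = 1e-4)
  expect_equal(suv$unit, rep("SUV", 3))
  flat <- tac("brain", 1:3, c(91000 / 260, 91000 / 260, 91000 / 260))
  expect_equal(suv_normalize(flat, 91000, 260)$value, rep(1, 3))
  zero <- tac("brain", 1:3, c(0, 0, 0))
  expect_equal(suv_normalize(zero, 91000, 260)$value, rep(0, 3))
  expect_error(suv_normalize(suv, 91000, 260), "kBq_per_ml")
})
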