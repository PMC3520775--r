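test_that("rat study roster reproduces the published design", {
  st <- make_rat_study(seed = 5)
  expect_equal(nrow(st$subjects), 21L)
  expect_equal(table(st$subjects$group, st$subjects$dose_group),
               table(rep(c("control", "control", "post_SE", "post_SE"),
                         c(7, 4, 5, 5)),
                     rep(c(3, 15, 3, 15), c(7, 4, 5, 5))))
  expect_equal(st$scans$duration, c(140, 60))
  expect_equal(st$tq$start, 60)
  # deterministic under a fixed seed
  expect_identical(make_rat_study(seed = 5), st)
  expect_false(identical(make_rat_study(seed = 6)$subjects$body_weight_g,
                         st$subjects$body_weight_g))
  # body weights draw from the published group distribution
  big <- make_rat_study(n_per_group = c(1e4, 1, 1, 1), seed = 7)
  w <- big$subjects$body_weight_g[big$subjects$group == "control" &
                                    big$subjects$dose_group == 3]
  expect_equal(mean(w), 260, tolerance = 0.002)
  expect_equal(sd(w), 5, tolerance = 0.05)
})

test_that("human study roster reproduces the published design", {
  st <- make_human_study(seed = 5)
  expect_equal(nrow(st$subjects), 5L)
  expect_equal(st$scans$duration, c(120, 40))
  expect_equal(st$tq$start, 40)
  expect_equal(st$tq$duration, 30)
  expect_identical(make_human_study(seed = 5), st)
  big <- make_human_study(n = 1e4, seed = 8)
  expect_equal(mean(big$subjects$injected_1), 379e3, tolerance = 0.002)
  expect_equal(mean(big$subjects$body_weight_g), 74e3, tolerance = 0.002)
})

test_that("degenerate noise reproduces model predictions exactly", {
  tm <- default_true_model("rat")
  tm0 <- true_model(tm$plasma, tm$brain, tm$effs,
                    plasma_iiv = list(), brain_iiv = list(),
                    sigma_plasma = 0, sigma_brain = 0)
  st <- make_rat_study(n_per_group = c(1, 1, 1, 1), seed = 9)
  ds <- simulate_dataset(st, tm0, seed = 9)
  # brain values equal a direct noise-free simulation of the same subject
  s <- st$subjects[1, ]
  mids <- st$frames[[1]]$mid
  grid <- petnlme:::.forcing_grid(140, extra = c(mids, 60))
  pl <- simulate_plasma(tm$plasma,
                        data.frame(amount = s$injected_1, start = 0,
                                   duration = s$inj_dur_1),
                        grid[grid > 0])
  pl <- rbind(tac("plasma", 0, 0)[0, ],
              tac("plasma", c(0, pl$time_min), c(0, pl$value)))
  ev <- data.frame(dose_group = s$dose_group, start = 60, duration = 1)
  br <- simulate_brain(tm$brain, tm$effs, pl, ev, 1, mids)
  got <- ds[ds$subject_id == s$subject_id & ds$scan == 1 &
              ds$obs_type == "brain", ]
  expect_equal(got$value, br$value, tolerance = 1e-12)
})

test_that("proportional residual noise has the configured magnitude and sign behaviour", {
  base <- default_true_model("rat")
  # no IIV so that the noise-free predictions are deterministic and the
  # same-seed sigma = 0 run yields f record by record
  tm <- true_model(base$plasma, base$brain, base$effs,
                   sigma_plasma = base$sigma_plasma,
                   sigma_brain = base$sigma_brain)
  st <- make_rat_study(n_per_group = c(4, 2, 3, 3), seed = 21)
  ds <- simulate_dataset(st, tm, seed = 21)
  expect_true(all(ds$value >= 0))
  tm0 <- true_model(base$plasma, base$brain, base$effs,
                    sigma_plasma = 0, sigma_brain = 0)
  ds0 <- simulate_dataset(st, tm0, seed = 21)
  br <- ds$obs_type == "brain"
  rel <- (ds$value[br] - ds0$value[br]) / ds0$value[br]
  # truncation at zero clips the left tail, so compare against the
  # truncated-normal SD of the same draw
  raw <- rnorm(1e6, 0, tm$sigma_brain)
  sd_trunc <- sd(pmax(raw, -1))
  expect_equal(sd(rel), sd_trunc, tolerance = 0.05)
  # two calls with the same seed are identical
  expect_identical(simulate_dataset(st, tm, seed = 21), ds)
})

test_that("shared-eta blocks give identical realized etas within a block", {
  iiv <- list(eta1 = list(params = c("Vc", "CL", "Q2"), omega = 0.162),
              eta2 = list(params = c("Vp1", "Q1"), omega = 0.169))
  withr::with_seed(30, {
    etas <- petnlme:::.draw_etas(iiv)
    expect_length(etas, 2L)
    expect_identical(petnlme:::.eta_for_param("Vc", iiv, etas),
                     petnlme:::.eta_for_param("CL", iiv, etas))
    expect_identical(petnlme:::.eta_for_param("Vc", iiv, etas),
                     petnlme:::.eta_for_param("Q2", iiv, etas))
    expect_identical(petnlme:::.eta_for_param("Vp1", iiv, etas),
                     petnlme:::.eta_for_param("Q1", iiv, etas))
    expect_identical(petnlme:::.eta_for_param("Vp2", iiv, etas), 0)
  })
})

test_that("frame schedule covers the scan with increasing frame widths", {
  fr <- frame_schedule(140)
  expect_equal(fr$start[1], 0)
  expect_equal(max(fr$end), 140)
  expect_true(all(diff(fr$mid) > 0))
  expect_true(all(abs(fr$end[-nrow(fr)] - fr$start[-1]) < 1e-12))
  widths <- fr$end - fr$start
  expect_true(all(diff(widths) >= -1e-12))
})

test_that("human paired-scan design simulates and supports model evaluation", {
  st <- make_human_study(seed = 81)
  tm <- default_true_model("human")
  ds <- simulate_dataset(st, tm, seed = 81)
  expect_equal(length(unique(ds$subject_id)), 5L)
  expect_true(all(ds$dose_group == 2))
  expect_equal(unique(ds$tq_dur_min[ds$scan == 1]), 30)
  m <- default_brain_model("human")
  expect_false(m$fixed[["Vbr2"]])  # Vbr2 is only fixed in rats
  o <- ofv(ds, m, plasma_fit = fixed_plasma(tm$plasma))
  expect_true(is.finite(o))
})
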