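# shared input function: rich plasma curve from the published rat model
.classic_input <- function(t_end = 90) {
  p <- plasma_params(38.8, 141, 1580, 16.4, 29.1, 22.3)
  ft <- sort(unique(c(seq(0.05, 5, 0.05), seq(5.1, t_end, 0.1))))
  out <- simulate_plasma(p, data.frame(amount = 91000, start = 0,
                                       duration = 0.4), ft)
  tac("plasma", c(0, ft), c(0, out$value))
}

test_that("blood-to-plasma conversion is a labelled pointwise scaling", {
  b <- tac("blood", c(1, 2, 3), c(100, 50, 25))
  p1 <- plasma_from_blood(b, ratio = 1)
  expect_equal(p1$value, b$value)
  expect_equal(unique(p1$label), "plasma")
  p <- plasma_from_blood(b)  # default published ratio 1.29
  expect_equal(p$value[1], 129)
  back <- plasma_from_blood(p, ratio = 1 / 1.29)
  expect_equal(back$value, b$value, tolerance = 1e-12)
})

test_that("2T4K fit recovers parameters from noise-free self-simulated data", {
  input <- .classic_input()
  times <- c(seq(0.25, 5, 0.25), seq(6, 90, 2))
  truth <- c(K1 = 0.1, k2 = 0.2, k3 = 0.05, k4 = 0.05)
  y <- petnlme:::.sim_2t4k(truth["K1"], truth["k2"], truth["k3"],
                           truth["k4"], input$time_min, input$value, times)
  reg <- tac("WB", times, y)
  fit <- fit_2t4k(reg, input, start = truth * 1.5)
  # VT identity: K1/k2 * (1 + k3/k4) = 1.0 for this parameter set
  expect_equal(fit$VT_2T4K, 1.0, tolerance = 0.01)
  est <- unlist(fit[c("K1", "k2", "k3", "k4")])
  expect_lt(max(abs(est - truth) / truth), 0.01)
  # residuals on self-simulated data are numerically zero
  refit_pred <- petnlme:::.sim_2t4k(fit$K1, fit$k2, fit$k3, fit$k4,
                                    input$time_min, input$value, times)
  expect_lt(max(abs(refit_pred - y) / pmax(y, 1e-9)), 1e-6)
})

test_that("2T4K reduces to one-tissue behaviour when k3 = k4 = 0", {
  input <- .classic_input()
  times <- c(seq(0.25, 5, 0.25), seq(6, 90, 2))
  y <- petnlme:::.sim_2t4k(0.15, 0.1, 0, 0, input$time_min, input$value,
                           times)
  fit <- fit_2t4k(tac("WB", times, y), input)
  expect_equal(fit$VT_2T4K, 1.5, tolerance = 0.01)
})

test_that("2T4K honours the exclusion window and the frame minimum", {
  input <- .classic_input()
  times <- c(seq(0.25, 5, 0.25), seq(6, 90, 2))
  y <- petnlme:::.sim_2t4k(0.1, 0.2, 0.05, 0.05, input$time_min,
                           input$value, times)
  reg <- tac("WB", times, y)
  fit <- fit_2t4k(reg, input, exclusion_window = c(60, 90))
  expect_equal(fit$n_frames, sum(times < 60))
  expect_error(fit_2t4k(reg[1:5, ], input), "8 frames")
})

test_that("Logan slope equals the equilibrium ratio for proportional curves", {
  input <- .classic_input()
  idx <- seq(20, nrow(input), by = 10)
  ct <- tac("WB", input$time_min[idx], 1.5 * input$value[idx])
  fit <- logan_vt(ct, input, t_star = 10)
  expect_equal(fit$VT_Logan, 1.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # invariance under common rescaling of both curves
  input2 <- dplyr::mutate(input, value = value * 7.3)
  ct2 <- dplyr::mutate(ct, value = value * 7.3)
  fit2 <- logan_vt(ct2, input2, t_star = 10)
  expect_equal(fit2$VT_Logan, fit$VT_Logan, tolerance = 1e-12)
})

test_that("Logan analysis estimates VT from compartmental simulations", {
  input <- .classic_input()
  # fine early frames: the frame-grid trapezoid of the input must resolve
  # the injection peak for the late-time slope to be unbiased
  times <- c(seq(0.1, 5, 0.1), seq(5.5, 90, 0.5))
  # one-tissue: K1/k2 = 1.5
  y1 <- petnlme:::.sim_2t4k(0.3, 0.2, 0, 0, input$time_min, input$value,
                            times)
  f1 <- logan_vt(tac("WB", times, y1), input, t_star = 30)
  expect_equal(f1$VT_Logan, 1.5, tolerance = 0.02 * 1.5)
  # 2T4K: VT = K1/k2 (1 + k3/k4) = 1.0, late linear segment
  y2 <- petnlme:::.sim_2t4k(0.1, 0.2, 0.05, 0.05, input$time_min,
                            input$value, times)
  f2 <- logan_vt(tac("WB", times, y2), input, t_star = 50)
  expect_equal(f2$VT_Logan, 1.0, tolerance = 0.05)
  # automatic t_star lands on a well-fitting late segment
  f3 <- logan_vt(tac("WB", times, y2), input)
  expect_gte(f3$r_squared, 0.99)
  expect_equal(f3$VT_Logan, 1.0, tolerance = 0.05)
  expect_error(logan_vt(tac("WB", times[1:2], y2[1:2]), input, t_star = 0),
               "3 frames")
})

test_that("batch reference analysis runs per subject and scan with exclusion", {
  ds <- small_rat_dataset(seed = 71, n_per_group = c(2, 1, 1, 1))
  res <- pet_reference_analysis(ds)
  expect_equal(nrow(res), length(unique(ds$subject_id)) * 2L)
  expect_true(all(c("VT_2T4K", "VT_Logan", "t_star") %in% names(res)))
  # most fits succeed and produce positive volumes
  ok <- is.finite(res$VT_2T4K)
  expect_gt(mean(ok), 0.7)
  expect_true(all(res$VT_2T4K[ok] > 0))
})
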