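# Shared fixture builders for the estimation tests. All data are generated
# in code under fixed seeds; reduced designs (fewer subjects, scan-1-only or
# baseline-only windows) keep the fitting tests inside the suite's time
# budget while preserving the identifiability structure they exercise.

# small complete rat study (both scans, all four groups)
small_rat_dataset <- function(seed = 11, n_per_group = c(2, 1, 2, 1),
                              model = default_true_model("rat")) {
  simulate_dataset(make_rat_study(n_per_group = n_per_group, seed = seed),
                   model, seed = seed)
}

# scan-1-only control-rat design: tariquidar step at 60 min inside the
# baseline scan identifies the transport effect without the second scan
scan1_dataset <- function(seed, n = 6, model = default_true_model("rat"),
                          t_end = 100) {
  st <- make_rat_study(n_per_group = c(n, 1, 1, 1), seed = seed)
  st$subjects <- st$subjects[st$subjects$group == "control" &
                               st$subjects$dose_group == 3, ][seq_len(n), ]
  st$scans <- st$scans[1, ]
  st$scans$duration <- t_end
  st$frames <- list(frame_schedule(t_end))
  simulate_dataset(st, model, seed = seed)
}

# baseline-only design (no tariquidar observations): frames truncated to
# the pre-inhibitor window; used for the SE-covariate selection studies
baseline_dataset <- function(seed, n_control = 6, n_se = 6,
                             model = default_true_model("rat"),
                             t_end = 55) {
  st <- make_rat_study(n_per_group = c(n_control, 1, n_se, 1), seed = seed)
  st$subjects <- st$subjects[st$subjects$dose_group == 3, ]
  st$scans <- st$scans[1, ]
  st$scans$duration <- t_end
  st$frames <- list(frame_schedule(t_end))
  ds <- simulate_dataset(st, model, seed = seed)
  # no tariquidar is observed in this window
  ds$tq_start_min <- NA_real_
  ds$tq_dur_min <- NA_real_
  ds
}

# brain-stage model for reduced designs, free transport parameters only
reduced_brain_model <- function(tq_doses = 3, scan_effect = FALSE,
                                se_covariate = FALSE, init = NULL) {
  default_brain_model("rat", tq_doses = tq_doses, scan_effect = scan_effect,
                      se_covariate = se_covariate, init = init)
}

true_plasma_forcing <- function(model = default_true_model("rat")) {
  fixed_plasma(model$plasma)
}

# memoized small brain-stage fit reused by several estimation tests
.fixture_env <- new.env(parent = emptyenv())

fixture_scan1_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    ds <- scan1_dataset(seed = 41, n = 6)
    m <- reduced_brain_model(tq_doses = 3)
    .fixture_env$data <- ds
    .fixture_env$fit <- fit_population(ds, m,
                                       plasma_fit = true_plasma_forcing(),
                                       control = list(se = FALSE))
  }
  .fixture_env$fit
}

# full paired-scan design restricted to control 3 mg/kg rats: the richest
# per-subject information for the mechanism (placement) comparison
full_scan_dataset <- function(seed, n = 6,
                              model = default_true_model("rat")) {
  st <- make_rat_study(n_per_group = c(n, 1, 1, 1), seed = seed)
  st$subjects <- st$subjects[st$subjects$group == "control" &
                               st$subjects$dose_group == 3, ][seq_len(n), ]
  simulate_dataset(st, model, seed = seed)
}
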