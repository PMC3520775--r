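#' Default PET frame schedule
#'
#' Frame midpoint schedule used by the synthetic-study generator: 12 x 10 s,
#' 6 x 30 s, 5 x 60 s, then 5-min frames to the end of the scan. The original
#' studies' exact framing is not public; this is a conventional dynamic PET
#' schedule and is configurable wherever it is consumed.
#'
#' @param t_end scan duration, min.
#' @return A tibble with columns `start`, `end`, `mid` (min).
#' @export
frame_schedule <- function(t_end) {
  check_positive_scalar(t_end, "t_end")
  starts <- c(seq(0, 2 - 1 / 6, by = 1 / 6),
              seq(2, 4.5, by = 0.5),
              seq(5, 9, by = 1))
  ends <- c(starts[-1], 10)
  if (t_end > 10) {
    s5 <- seq(10, t_end - 5, by = 5)
    starts <- c(starts, s5)
    ends <- c(ends, s5 + 5)
  }
  keep <- ends <= t_end + 1e-9
  tibble::tibble(start = starts[keep], end = ends[keep],
                 mid = (starts[keep] + ends[keep]) / 2)
}

.draw_trunc_norm <- function(n, mean, sd, lower = 0) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x <= lower)
  }
  x
}

.roster_from_design <- function(design, species, prefix) {
  rows <- purrr::pmap(design, function(group, dose_group, n, bw_mean, bw_sd,
                                       act1_mean, act1_sd, dur1_mean, dur1_sd,
                                       act2_mean, act2_sd, dur2_mean, dur2_sd) {
    tibble::tibble(
      species = species, group = group, dose_group = dose_group,
      body_weight_g = .draw_trunc_norm(n, bw_mean, bw_sd),
      injected_1 = .draw_trunc_norm(n, act1_mean, act1_sd),
      inj_dur_1 = .draw_trunc_norm(n, dur1_mean, dur1_sd),
      injected_2 = .draw_trunc_norm(n, act2_mean, act2_sd),
      inj_dur_2 = .draw_trunc_norm(n, dur2_mean, dur2_sd)
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out,
                subject_id = sprintf("%s%02d", prefix, dplyr::row_number()),
                .before = 1)
}

#' Generate a paired-scan rat study design
#'
#' Builds a synthetic roster emulating the preclinical paired-scan design:
#' a 140-min baseline scan with tariquidar (3 or 15 mg/kg) given as a 1-min
#' I.V. bolus at 60 min, and a 60-min post-inhibition scan started 2 h after
#' tariquidar, in naive (control) and 48-h post status epilepticus (post_SE)
#' rats. Body weights, injected activities, and injection durations are drawn
#' from the published group means and SDs (truncated at zero).
#'
#' @param n_per_group subjects per group, in the order control/3 mg/kg,
#'   control/15 mg/kg, post_SE/3 mg/kg, post_SE/15 mg/kg. Defaults to the
#'   published sizes (7, 4, 5, 5; 21 rats in total).
#' @param seed integer seed for the roster draws.
#' @return A `study_design` list: `$species`, `$subjects` roster tibble,
#'   `$scans` (scan windows, min), `$tq` (administration start/duration within
#'   scan 1 and gap to scan 2), `$frames` (per-scan frame schedule tibbles).
#' @examples
#' st <- make_rat_study(seed = 1)
#' nrow(st$subjects) # 21
#' @export
make_rat_study <- function(n_per_group = c(7, 4, 5, 5), seed = 1) {
  if (length(n_per_group) != 4L || any(n_per_group < 1)) {
    abort("`n_per_group` must give >= 1 subject for each of the four groups.")
  }
  design <- study_design_table("rat")
  design$n <- as.integer(n_per_group)
  subjects <- withr::with_seed(seed, .roster_from_design(design, "rat", "R"))
  structure(list(
    species = "rat",
    subjects = subjects,
    scans = tibble::tibble(scan = c(1L, 2L), duration = c(140, 60)),
    tq = list(start = 60, duration = 1, gap_to_scan2 = 120),
    frames = list(frame_schedule(140), frame_schedule(60))
  ), class = "study_design")
}

#' Generate a paired-scan human study design
#'
#' Healthy-volunteer analogue of [make_rat_study()]: a 120-min baseline scan
#' with tariquidar 2 mg/kg infused over 30 min starting at 40 min, and a
#' 40-min post-inhibition scan started 2 h 50 min after the end of the
#' infusion. Body weights (kg, stored in g) and injected activities are drawn
#' from the published means and SDs.
#'
#' @param n number of volunteers (published study: 5).
#' @param seed integer seed.
#' @return A `study_design` list as in [make_rat_study()].
#' @export
make_human_study <- function(n = 5, seed = 1) {
  if (n < 1) abort("`n` must be >= 1.")
  design <- study_design_table("human")
  design$n <- as.integer(n)
  subjects <- withr::with_seed(seed, .roster_from_design(design, "human", "H"))
  structure(list(
    species = "human",
    subjects = subjects,
    scans = tibble::tibble(scan = c(1L, 2L), duration = c(120, 40)),
    tq = list(start = 40, duration = 30, gap_to_scan2 = 170),
    frames = list(frame_schedule(120), frame_schedule(40))
  ), class = "study_design")
}

#' Ground-truth population model for simulation
#'
#' Bundles the structural parameters, covariate effects, inter-individual
#' variability (IIV), and residual error used by [simulate_dataset()].
#' `default_true_model()` populates it with the published population
#' estimates for a region. Published tables report no brain-stage IIV, so the
#' default assigns a lognormal SD of 0.2 to `Qin` and `Qout` (independent
#' etas), a realistic preclinical level.
#'
#' @param plasma a [plasma_params()] object.
#' @param brain a [brain_params()] object.
#' @param effs a [covariate_effects()] object.
#' @param plasma_iiv named list of eta blocks, each
#'   `list(params = <chr>, omega = <sd>)`; parameters in one block share a
#'   realized eta.
#' @param brain_iiv same structure for brain-stage parameters.
#' @param sigma_plasma,sigma_brain proportional residual error SDs (> 0).
#' @return A list with class `"true_model"`.
#' @export
true_model <- function(plasma, brain, effs,
                       plasma_iiv = list(), brain_iiv = list(),
                       sigma_plasma = 0.482, sigma_brain = 0.404) {
  stopifnot(inherits(plasma, "plasma_params"), inherits(brain, "brain_params"),
            inherits(effs, "covariate_effects"))
  check_nonneg_scalar(sigma_plasma, "sigma_plasma")
  check_nonneg_scalar(sigma_brain, "sigma_brain")
  for (b in c(plasma_iiv, brain_iiv)) {
    if (!is.numeric(b$omega) || b$omega < 0) abort("IIV omegas must be >= 0.")
  }
  structure(list(plasma = plasma, brain = brain, effs = effs,
                 plasma_iiv = plasma_iiv, brain_iiv = brain_iiv,
                 sigma_plasma = sigma_plasma, sigma_brain = sigma_brain),
            class = "true_model")
}

#' @rdname true_model
#' @param species `"rat"` or `"human"`.
#' @param region brain region label (rat only; human fits are whole-brain).
#' @param placement which transport clearance tariquidar acts on.
#' @export
default_true_model <- function(species = c("rat", "human"), region = "WB",
                               placement = "on_Qout") {
  species <- match.arg(species)
  pl <- plasma_param_estimates(species)
  pp <- do.call(plasma_params, as.list(setNames(pl$estimate[1:6], pl$parameter[1:6])))
  br <- brain_param_estimates(species)
  br <- br[br$region == region, ]
  if (nrow(br) != 1L) abort(sprintf("Unknown region '%s'.", region))
  bp <- brain_params(br$Vbr1, br$Vbr2, br$Qin, br$Qout, br$Qbr,
                     Vbr2_fixed = species == "rat")
  if (species == "rat") {
    effs <- covariate_effects(
      Eff_tariquidar = c("3" = br$Eff_tq_3, "15" = br$Eff_tq_15),
      Eff_scan = br$Eff_scan, Eff_SE = br$Eff_SE, placement = placement)
    plasma_iiv <- list(
      eta1 = list(params = c("Vc", "CL", "Q2"), omega = 0.162),
      eta2 = list(params = c("Vp1", "Q1"), omega = 0.169))
  } else {
    effs <- covariate_effects(
      Eff_tariquidar = c("2" = br$Eff_tq_2),
      Eff_scan = br$Eff_scan, Eff_SE = 1, placement = placement)
    plasma_iiv <- list()
  }
  true_model(
    plasma = pp, brain = bp, effs = effs,
    plasma_iiv = plasma_iiv,
    brain_iiv = list(etaQin = list(params = "Qin", omega = 0.2),
                     etaQout = list(params = "Qout", omega = 0.2)),
    sigma_plasma = pl$estimate[pl$parameter == "sigma_plasma"],
    sigma_brain = br$sigma_brain
  )
}

# internal fine grid used as plasma forcing support for brain simulation
.forcing_grid <- function(t_end, extra = numeric()) {
  g <- c(seq(0, min(5, t_end), by = 0.1),
         if (t_end > 5) seq(5.25, min(20, t_end), by = 0.25),
         if (t_end > 20) seq(21, t_end, by = 1))
  sort(unique(c(g, t_end, extra[extra >= 0 & extra <= t_end])))
}

.draw_etas <- function(iiv) {
  if (!length(iiv)) return(numeric())
  vapply(iiv, function(b) rnorm(1, 0, b$omega), numeric(1))
}

.eta_for_param <- function(param, iiv, etas) {
  for (b in names(iiv)) {
    if (param %in% iiv[[b]]$params) return(etas[[b]])
  }
  0
}

#' Simulate a complete synthetic study
#'
#' Draws per-subject lognormal random effects (honoring shared-eta blocks),
#' simulates noise-free plasma and regional brain curves at the design's
#' frame midpoints for both scans, and adds proportional residual error
#' `y = f * (1 + e)`, `e ~ N(0, sigma^2)`, truncated so that `y >= 0`.
#' Each scan starts from zero tracer amounts (decay-corrected data, >= 6
#' tracer half-lives between scans).
#'
#' @param study a `study_design` from [make_rat_study()]/[make_human_study()].
#' @param model a [true_model()].
#' @param seed integer seed; a fixed seed reproduces the dataset exactly.
#' @param region label attached to brain observations.
#' @return A long-format observation tibble (class `pk_dataset`) with one row
#'   per (subject, scan, frame, observation type); columns `subject_id`,
#'   `species`, `group`, `dose_group`, `scan`, `time_min`, `obs_type`,
#'   `region`, `value` (kBq/ml), `body_weight_g`, `injected_kBq`,
#'   `inj_dur_min`, `tq_start_min`, `tq_dur_min`.
#' @examples
#' st <- make_rat_study(n_per_group = c(2, 1, 1, 1), seed = 7)
#' ds <- simulate_dataset(st, default_true_model("rat"), seed = 7)
#' @export
simulate_dataset <- function(study, model, seed = 1, region = "WB") {
  stopifnot(inherits(study, "study_design"), inherits(model, "true_model"))
  withr::with_seed(seed, .simulate_dataset_impl(study, model, region))
}

.simulate_dataset_impl <- function(study, model, region) {
  subj <- study$subjects
  rows <- vector("list", nrow(subj))
  for (i in seq_len(nrow(subj))) {
    s <- subj[i, ]
    eta_p <- .draw_etas(model$plasma_iiv)
    eta_b <- .draw_etas(model$brain_iiv)
    pp <- model$plasma
    pp_i <- plasma_params(
      Vc = pp$Vc * exp(.eta_for_param("Vc", model$plasma_iiv, eta_p)),
      Vp1 = pp$Vp1 * exp(.eta_for_param("Vp1", model$plasma_iiv, eta_p)),
      Vp2 = pp$Vp2 * exp(.eta_for_param("Vp2", model$plasma_iiv, eta_p)),
      CL = pp$CL * exp(.eta_for_param("CL", model$plasma_iiv, eta_p)),
      Q1 = pp$Q1 * exp(.eta_for_param("Q1", model$plasma_iiv, eta_p)),
      Q2 = pp$Q2 * exp(.eta_for_param("Q2", model$plasma_iiv, eta_p)))
    bp <- model$brain
    Vbr1_i <- apply_se_covariate(bp$Vbr1, model$effs$Eff_SE,
                                 if (s$group == "post_SE") "post_SE" else "control") *
      exp(.eta_for_param("Vbr1", model$brain_iiv, eta_b))
    bp_i <- brain_params(
      Vbr1 = Vbr1_i, Vbr2 = bp$Vbr2,
      Qin = bp$Qin * exp(.eta_for_param("Qin", model$brain_iiv, eta_b)),
      Qout = bp$Qout * exp(.eta_for_param("Qout", model$brain_iiv, eta_b)),
      Qbr = bp$Qbr * exp(.eta_for_param("Qbr", model$brain_iiv, eta_b)),
      Vbr2_fixed = bp$Vbr2_fixed)
    n_scans <- nrow(study$scans)
    scan_rows <- vector("list", n_scans)
    for (si in seq_len(n_scans)) {
      sc <- study$scans$scan[si]
      t_end <- study$scans$duration[si]
      mids <- study$frames[[si]]$mid
      injected <- if (sc == 1) s$injected_1 else s$injected_2
      inj_dur <- if (sc == 1) s$inj_dur_1 else s$inj_dur_2
      ev_all <- tibble::tibble(dose_group = s$dose_group,
                               start = study$tq$start,
                               duration = study$tq$duration)
      grid <- .forcing_grid(t_end, extra = c(mids, study$tq$start))
      doses <- tibble::tibble(amount = injected, start = 0, duration = inj_dur)
      pl_curve <- simulate_plasma(pp_i, doses, grid[grid > 0])
      pl_curve <- dplyr::bind_rows(
        tibble::tibble(label = "plasma", time_min = 0, value = 0,
                       unit = "kBq_per_ml"), pl_curve)
      br_curve <- simulate_brain(bp_i, model$effs, pl_curve, ev_all, sc, mids,
                                 label = region)
      f_pl <- approx(pl_curve$time_min, pl_curve$value, xout = mids)$y
      f_br <- br_curve$value
      y_pl <- pmax(f_pl * (1 + rnorm(length(f_pl), 0, model$sigma_plasma)), 0)
      y_br <- pmax(f_br * (1 + rnorm(length(f_br), 0, model$sigma_brain)), 0)
      scan_rows[[si]] <- tibble::tibble(
        subject_id = s$subject_id, species = s$species, group = s$group,
        dose_group = s$dose_group, scan = sc,
        time_min = rep(mids, 2),
        obs_type = rep(c("plasma", "brain"), each = length(mids)),
        region = rep(c(NA_character_, region), each = length(mids)),
        value = c(y_pl, y_br),
        body_weight_g = s$body_weight_g, injected_kBq = injected,
        inj_dur_min = inj_dur,
        tq_start_min = if (sc == 1) study$tq$start else NA_real_,
        tq_dur_min = if (sc == 1) study$tq$duration else NA_real_)
    }
    rows[[i]] <- dplyr::bind_rows(scan_rows)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pk_dataset", class(out))
  out
}
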