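#' Published population parameter estimates
#'
#' Reference population estimates from the paired-scan (R)-[11C]verapamil
#' tariquidar studies, used as defaults for the synthetic-study generator and
#' as inputs to the derived-quantity reports. `plasma_param_estimates()`
#' returns the three-compartment plasma model (fixed during the brain stage);
#' `brain_param_estimates()` returns the brain-stage model per region of
#' interest, for the fit to all data (`variant = "all_data"`) or to the data
#' set excluding the frames acquired during and immediately after tariquidar
#' administration (`variant = "truncated"`, the starred whole-brain column).
#'
#' Inter-individual variability entries are lognormal standard deviations
#' (`omega`); `eta_block` labels parameters that share a realized eta.
#' Residual errors are proportional-error standard deviations.
#'
#' @param species `"rat"` or `"human"`.
#' @param variant `"all_data"` or `"truncated"`.
#' @return A tibble.
#' @examples
#' plasma_param_estimates("rat")
#' brain_param_estimates("rat") |> dplyr::filter(region == "WB")
#' @export
plasma_param_estimates <- function(species = c("rat", "human")) {
  species <- match.arg(species)
  if (species == "rat") {
    tibble::tibble(
      parameter = c("Vc", "Vp1", "Vp2", "CL", "Q1", "Q2", "sigma_plasma"),
      estimate  = c(38.8, 141, 1580, 16.4, 29.1, 22.3, 0.482),
      unit      = c("ml", "ml", "ml", "ml/min", "ml/min", "ml/min", "prop"),
      omega     = c(0.162, 0.169, NA, 0.162, 0.169, 0.162, NA),
      eta_block = c("eta1", "eta2", NA, "eta1", "eta2", "eta1", NA)
    )
  } else {
    tibble::tibble(
      parameter = c("Vc", "Vp1", "Vp2", "CL", "Q1", "Q2", "sigma_plasma"),
      estimate  = c(2580, 57900, 41100, 538, 6550, 5880, 0.654),
      unit      = c("ml", "ml", "ml", "ml/min", "ml/min", "ml/min", "prop"),
      omega     = NA_real_,
      eta_block = NA_character_
    )
  }
}

# region x parameter estimates, rat brain stage (whole data set)
.rat_brain_regions <- function() {
  tibble::tribble(
    ~region, ~Vbr1, ~Qin, ~Qout, ~Qbr, ~sigma_brain, ~Eff_SE, ~Eff_tq_3, ~Eff_tq_15, ~Eff_scan,
    "WB",    0.132, 5.62, 3.60, 0.115, 0.382, 1.84,  0.161, 0.135, 1.33,
    "CS",    0.119, 2.05, 3.45, 0.114, 0.440, 1.88,  0.114, 0.101, 1.29,
    "EC",    0.155, 3.32, 3.91, 0.111, 0.387, 1.73,  0.233, 0.215, 1.37,
    "SHipp", 0.151, 2.49, 4.56, 0.113, 0.421, 1.86,  0.119, 0.101, 1.29,
    "THipp", 0.129, 1.98, 2.99, 0.108, 0.571, 2.21,  0.150, 0.134, 1.25,
    "Th",    0.156, 2.43, 4.39, 0.129, 0.016, 1.77,  0.120, 0.103, 1.21,
    "Cer",   0.192, 2.44, 3.01, 0.118, 0.407, 0.924, 0.226, 0.148, 1.52,
    "FMC",   0.088, 1.79, 1.97, 0.120, 0.454, 2.30,  0.194, 0.155, 1.40
  )
}

#' @rdname plasma_param_estimates
#' @export
brain_param_estimates <- function(species = c("rat", "human"),
                                  variant = c("all_data", "truncated")) {
  species <- match.arg(species)
  variant <- match.arg(variant)
  if (species == "rat") {
    if (variant == "all_data") {
      out <- .rat_brain_regions()
    } else {
      # whole-brain fit excluding during/post-tariquidar frames of scan 1;
      # no scan effect is estimable there (D = Eff_tariquidar in both scans)
      out <- tibble::tibble(
        region = "WB", Vbr1 = 0.132, Qin = 5.48, Qout = 3.56, Qbr = 0.115,
        sigma_brain = 0.404, Eff_SE = 1.84, Eff_tq_3 = 0.219,
        Eff_tq_15 = 0.168, Eff_scan = NA_real_
      )
    }
    dplyr::mutate(out, Vbr2 = 2, species = "rat", .after = "Vbr1")
  } else {
    if (variant == "all_data") {
      tibble::tibble(
        region = "WB", Vbr1 = 3.17, Vbr2 = 18.4, species = "human",
        Qin = 588, Qout = 1080, Qbr = 1.71, sigma_brain = 0.27,
        Eff_SE = NA_real_, Eff_tq_2 = 0.483, Eff_scan = 2.28
      )
    } else {
      tibble::tibble(
        region = "WB", Vbr1 = 2.29, Vbr2 = 13.0, species = "human",
        Qin = 713, Qout = 1410, Qbr = 1.26, sigma_brain = 0.295,
        Eff_SE = NA_real_, Eff_tq_2 = 0.993, Eff_scan = NA_real_
      )
    }
  }
}

#' Paired-scan study design summaries
#'
#' Group-level design statistics (group sizes, body weight, injected activity,
#' injection duration; mean and SD) for the rat and human paired-scan designs.
#' Units: weight g, activity kBq, duration min.
#'
#' @param species `"rat"` or `"human"`.
#' @return A tibble with one row per treatment group.
#' @export
study_design_table <- function(species = c("rat", "human")) {
  species <- match.arg(species)
  if (species == "rat") {
    tibble::tribble(
      ~group,     ~dose_group, ~n, ~bw_mean, ~bw_sd,
      ~act1_mean, ~act1_sd, ~dur1_mean, ~dur1_sd,
      ~act2_mean, ~act2_sd, ~dur2_mean, ~dur2_sd,
      "control",  3,  7, 260,  5, 97e3, 27e3, 18 / 60, 7 / 60, 93e3, 27e3, 18 / 60, 6 / 60,
      "control",  15, 4, 307, 18, 88e3, 17e3, 39 / 60, 10 / 60, 101e3, 28e3, 36 / 60, 5 / 60,
      "post_SE",  3,  5, 234, 14, 84e3, 20e3, 19 / 60, 2 / 60, 91e3, 9e3, 16 / 60, 2 / 60,
      "post_SE",  15, 5, 247, 16, 94e3, 25e3, 25 / 60, 11 / 60, 92e3, 16e3, 32 / 60, 18 / 60
    )
  } else {
    tibble::tibble(
      group = "control", dose_group = 2, n = 5,
      bw_mean = 74e3, bw_sd = 5e3,
      act1_mean = 379e3, act1_sd = 11e3, dur1_mean = 51 / 60, dur1_sd = 10 / 60,
      act2_mean = 389e3, act2_sd = 15e3, dur2_mean = 43 / 60, dur2_sd = 11 / 60
    )
  }
}

#' Mean plasma-to-blood concentration ratio of (R)-[11C]verapamil
#'
#' Constant used to convert whole-blood activity curves to plasma curves.
#' @return A single number (1.29).
#' @export
verapamil_plasma_blood_ratio <- function() 1.29
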