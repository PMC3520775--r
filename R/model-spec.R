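#' Population model specification
#'
#' Defines an estimable population model for one stage of the sequential
#' fitting strategy: `stage = "plasma"` (three-compartment plasma model, fit
#' first) or `stage = "brain"` (two-compartment brain model with the plasma
#' stage fixed and supplied as a per-subject forcing function).
#'
#' Fixed effects `theta` are strictly positive and estimated on the log
#' scale. Inter-individual variability is lognormal with shared-eta blocks:
#' each element of `iiv` is `list(params = <chr>, omega = <sd>)` and all
#' parameters in a block share one realized eta per subject. Residual error
#' is proportional with SD `sigma`. Static multiplicative covariates
#' (e.g. the status-epilepticus effect on `Vbr1`) live in `covariates`; the
#' time-dependent tariquidar effect is driven by `tq_doses`/`scan_effect`
#' and `placement` (see [effect_D()]).
#'
#' @param stage `"plasma"` or `"brain"`.
#' @param theta named positive numeric vector of fixed effects (initial or
#'   current values). Tariquidar effects are named `Eff_tq_<dose>`, the scan
#'   effect `Eff_scan`.
#' @param iiv named list of eta blocks, `list(params, omega)`.
#' @param sigma proportional residual error SD (> 0).
#' @param fixed named logical; which `theta` entries are frozen (defaults:
#'   `Vbr2` frozen when present, everything else free).
#' @param placement `"on_Qout"` or `"on_Qin"` (brain stage).
#' @param covariates a data frame with columns `effect` (theta name), `param`
#'   (target parameter), `column` (subject covariate column), `level` (value
#'   for which the effect applies), or `NULL`.
#' @param tq_doses numeric vector of tariquidar dose groups handled by the
#'   model (each needs a `Eff_tq_<dose>` entry in `theta`).
#' @param scan_effect logical; include `Eff_scan` in the inhibitor effect for
#'   scan 2.
#' @param region brain region to fit (brain stage; `NULL` means the single
#'   region present in the data).
#' @param omega_fixed named logical over blocks (default all free).
#' @param sigma_fixed logical.
#' @return A list with class `"pop_model"`.
#' @export
population_model <- function(stage = c("plasma", "brain"), theta,
                             iiv = list(), sigma = 0.4, fixed = NULL,
                             placement = c("on_Qout", "on_Qin"),
                             covariates = NULL, tq_doses = numeric(),
                             scan_effect = FALSE, region = NULL,
                             omega_fixed = NULL, sigma_fixed = FALSE) {
  stage <- match.arg(stage)
  placement <- match.arg(placement)
  if (is.null(names(theta)) || any(!nzchar(names(theta)))) {
    abort("`theta` must be fully named.")
  }
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    abort("All `theta` entries must be positive and finite.")
  }
  check_positive_scalar(sigma, "sigma")
  fx <- setNames(rep(FALSE, length(theta)), names(theta))
  if ("Vbr2" %in% names(theta)) fx["Vbr2"] <- TRUE
  if (!is.null(fixed)) fx[names(fixed)] <- fixed
  all_iiv_params <- unlist(lapply(iiv, `[[`, "params"))
  if (anyDuplicated(all_iiv_params)) {
    abort("IIV blocks must be disjoint.")
  }
  if (!all(all_iiv_params %in% names(theta))) {
    abort("IIV blocks reference parameters absent from `theta`.")
  }
  if (length(iiv) && is.null(names(iiv))) {
    names(iiv) <- paste0("eta", seq_along(iiv))
  }
  ofx <- setNames(rep(FALSE, length(iiv)), names(iiv))
  if (!is.null(omega_fixed)) ofx[names(omega_fixed)] <- omega_fixed
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    stopifnot(all(c("effect", "param", "column", "level") %in% names(covariates)))
    if (!all(covariates$effect %in% names(theta))) {
      abort("Covariate effects must have `theta` entries.")
    }
  }
  for (d in tq_doses) {
    if (!paste0("Eff_tq_", d) %in% names(theta)) {
      abort(sprintf("`theta` lacks Eff_tq_%s for dose group %s.", d, d))
    }
  }
  if (scan_effect && !"Eff_scan" %in% names(theta)) {
    abort("`scan_effect = TRUE` requires an `Eff_scan` entry in `theta`.")
  }
  structure(list(
    stage = stage, theta = theta, fixed = fx, iiv = iiv,
    omega_fixed = ofx, sigma = sigma, sigma_fixed = isTRUE(sigma_fixed),
    placement = placement, covariates = covariates,
    tq_doses = tq_doses, scan_effect = isTRUE(scan_effect), region = region
  ), class = "pop_model")
}

#' Default stage models seeded from the published estimates
#'
#' Convenience constructors: `default_plasma_model()` builds the plasma-stage
#' model (three compartments, shared-eta blocks on \{Vc, CL, Q2\} and
#' \{Vp1, Q1\}); `default_brain_model()` builds the brain-stage model for a
#' region, with the tariquidar effect on the chosen clearance, optional scan
#' effect and status-epilepticus covariate, and `Vbr2` fixed (rats). Initial
#' values come from the published tables unless overridden via `init`.
#'
#' @param species `"rat"` or `"human"`.
#' @param init optional named numeric, overrides initial `theta` entries.
#' @return A [population_model()].
#' @export
default_plasma_model <- function(species = c("rat", "human"), init = NULL) {
  species <- match.arg(species)
  tab <- plasma_param_estimates(species)
  theta <- setNames(tab$estimate[1:6], tab$parameter[1:6])
  theta[names(init)] <- init
  iiv <- if (species == "rat") {
    list(eta1 = list(params = c("Vc", "CL", "Q2"), omega = 0.162),
         eta2 = list(params = c("Vp1", "Q1"), omega = 0.169))
  } else {
    list()
  }
  population_model("plasma", theta = theta, iiv = iiv,
                   sigma = tab$estimate[tab$parameter == "sigma_plasma"])
}

#' @rdname default_plasma_model
#' @param region brain region.
#' @param placement `"on_Qout"` or `"on_Qin"`.
#' @param se_covariate include the SE effect on `Vbr1` (rat designs with a
#'   post-SE arm).
#' @param tq_doses dose groups present in the design; `NULL` picks the
#'   species default (3 and 15 mg/kg for rats, 2 mg/kg for humans).
#' @param scan_effect include `Eff_scan`.
#' @param iiv brain-stage IIV blocks; default lognormal SD 0.2 on `Qin` and
#'   `Qout` (published tables report no brain-stage IIV).
#' @param sigma initial residual error SD.
#' @export
default_brain_model <- function(species = c("rat", "human"), region = "WB",
                                placement = c("on_Qout", "on_Qin"),
                                se_covariate = species == "rat",
                                tq_doses = NULL, scan_effect = TRUE,
                                iiv = NULL, sigma = NULL, init = NULL) {
  species <- match.arg(species)
  placement <- match.arg(placement)
  tab <- brain_param_estimates(species)
  tab <- tab[tab$region == region, ]
  if (nrow(tab) != 1L) abort(sprintf("Unknown region '%s'.", region))
  if (is.null(tq_doses)) tq_doses <- if (species == "rat") c(3, 15) else 2
  theta <- c(Vbr1 = tab$Vbr1, Vbr2 = tab$Vbr2, Qin = tab$Qin,
             Qout = tab$Qout, Qbr = tab$Qbr)
  for (d in tq_doses) {
    nm <- paste0("Eff_tq_", d)
    col <- paste0("Eff_tq_", d)
    theta[nm] <- if (col %in% names(tab) && is.finite(tab[[col]])) tab[[col]] else 0.5
  }
  if (scan_effect) {
    theta["Eff_scan"] <- if (is.finite(tab$Eff_scan)) tab$Eff_scan else 1.3
  }
  covariates <- NULL
  if (isTRUE(se_covariate)) {
    theta["Eff_SE"] <- if (is.finite(tab$Eff_SE)) tab$Eff_SE else 1.5
    covariates <- tibble::tibble(effect = "Eff_SE", param = "Vbr1",
                                 column = "group", level = "post_SE")
  }
  theta[names(init)] <- init
  if (is.null(iiv)) {
    iiv <- list(etaQin = list(params = "Qin", omega = 0.2),
                etaQout = list(params = "Qout", omega = 0.2))
  }
  if (is.null(sigma)) sigma <- tab$sigma_brain
  population_model("brain", theta = theta, iiv = iiv, sigma = sigma,
                   fixed = c(Vbr2 = species == "rat"),
                   placement = placement, covariates = covariates,
                   tq_doses = tq_doses, scan_effect = scan_effect,
                   region = region)
}

#' Switch the transport clearance targeted by the inhibitor effect
#'
#' @param model a [population_model()].
#' @param placement `"on_Qout"` or `"on_Qin"`.
#' @return The modified model.
#' @export
set_placement <- function(model, placement = c("on_Qout", "on_Qin")) {
  stopifnot(inherits(model, "pop_model"))
  model$placement <- match.arg(placement)
  model
}

#' Covariate candidates for stepwise selection
#'
#' `candidate_covariate()` describes a static multiplicative covariate effect
#' (a new theta multiplying `param` for subjects whose `column` equals
#' `level`). `candidate_tariquidar()` describes the structured inhibitor
#' candidate: per-dose `Eff_tq_*` terms plus, optionally, the scan effect
#' (the scan effect is meaningless alone and is always tested jointly with
#' the tariquidar terms). `apply_candidate()` adds a candidate to a model.
#'
#' @param effect theta name for the new effect.
#' @param param target structural parameter.
#' @param column subject-level covariate column in the dataset.
#' @param level value of `column` for which the effect applies.
#' @param init initial value of the effect.
#' @return A `model_candidate` object.
#' @export
candidate_covariate <- function(effect, param, column, level, init = 1.2) {
  structure(list(name = effect, type = "covariate", effect = effect,
                 param = param, column = column,
                 level = as.character(level), init = init),
            class = "model_candidate")
}

#' @rdname candidate_covariate
#' @param doses tariquidar dose groups.
#' @param with_scan include `Eff_scan` jointly.
#' @param init_eff,init_scan initial values.
#' @export
candidate_tariquidar <- function(doses, with_scan = TRUE, init_eff = 0.5,
                                 init_scan = 1.2) {
  structure(list(name = paste0("Eff_tariquidar(",
                               paste(doses, collapse = ","), ")"),
                 type = "tariquidar", doses = doses, with_scan = with_scan,
                 init_eff = init_eff, init_scan = init_scan),
            class = "model_candidate")
}

#' @rdname candidate_covariate
#' @param model a [population_model()].
#' @param cand a `model_candidate`.
#' @export
apply_candidate <- function(model, cand) {
  stopifnot(inherits(model, "pop_model"), inherits(cand, "model_candidate"))
  if (cand$type == "covariate") {
    model$theta[cand$effect] <- cand$init
    model$fixed[cand$effect] <- FALSE
    row <- tibble::tibble(effect = cand$effect, param = cand$param,
                          column = cand$column, level = cand$level)
    model$covariates <- dplyr::bind_rows(model$covariates, row)
  } else {
    for (d in cand$doses) {
      nm <- paste0("Eff_tq_", d)
      model$theta[nm] <- cand$init_eff
      model$fixed[nm] <- FALSE
    }
    model$tq_doses <- sort(unique(c(model$tq_doses, cand$doses)))
    if (cand$with_scan) {
      model$theta["Eff_scan"] <- cand$init_scan
      model$fixed["Eff_scan"] <- FALSE
      model$scan_effect <- TRUE
    }
  }
  model
}

#' @rdname candidate_covariate
#' @export
drop_candidate <- function(model, cand) {
  stopifnot(inherits(model, "pop_model"), inherits(cand, "model_candidate"))
  if (cand$type == "covariate") {
    keep <- names(model$theta) != cand$effect
    model$theta <- model$theta[keep]
    model$fixed <- model$fixed[names(model$theta)]
    model$covariates <- dplyr::filter(model$covariates,
                                      .data$effect != cand$effect)
    if (nrow(model$covariates) == 0L) model$covariates <- NULL
  } else {
    rm_nm <- c(paste0("Eff_tq_", cand$doses),
               if (cand$with_scan) "Eff_scan")
    keep <- !names(model$theta) %in% rm_nm
    model$theta <- model$theta[keep]
    model$fixed <- model$fixed[names(model$theta)]
    model$tq_doses <- setdiff(model$tq_doses, cand$doses)
    if (cand$with_scan) model$scan_effect <- FALSE
  }
  model
}

#' @export
print.pop_model <- function(x, ...) {
  cat(sprintf("<pop_model: %s stage>\n", x$stage))
  if (x$stage == "brain") {
    cat(sprintf("  inhibitor effect placement: %s\n", x$placement))
  }
  cat("  theta:", paste(sprintf("%s=%.4g%s", names(x$theta), x$theta,
                                ifelse(x$fixed, " (fixed)", "")),
                        collapse = ", "), "\n")
  if (length(x$iiv)) {
    for (b in names(x$iiv)) {
      cat(sprintf("  eta[%s]: {%s} omega=%.3g\n", b,
                  paste(x$iiv[[b]]$params, collapse = ","), x$iiv[[b]]$omega))
    }
  }
  cat(sprintf("  proportional sigma = %.3g\n", x$sigma))
  invisible(x)
}
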