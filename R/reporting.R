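.condition_levels <- c("baseline", "during_tariquidar", "post_inhibition")

.eff_col <- function(params, dose_group) {
  col <- paste0("Eff_tq_", dose_group)
  if (!col %in% names(params) || any(!is.finite(params[[col]]))) {
    abort(sprintf("No tariquidar effect available for dose group %s mg/kg.",
                  dose_group))
  }
  col
}

#' Volume-of-distribution report from population estimates
#'
#' Computes the NLME volume of distribution `VT = Qin / (Qout * D)` per
#' region and condition, where the inhibitor effect is `D = 1` at baseline,
#' `D = Eff_tariquidar` during/immediately after tariquidar administration,
#' and `D = Eff_tariquidar * Eff_scan` in the post-inhibition scan. Reported
#' values follow the printed-table conventions: `VT` rounded to two
#' significant figures, fold changes versus baseline to one decimal (half
#' away from zero). The during-tariquidar fold change equals
#' `1/Eff_tariquidar` exactly before rounding. A missing scan effect
#' (`Eff_scan = NA`, the truncated-data fits) is treated as 1.
#'
#' @param params tibble of per-region estimates with columns `region`,
#'   `Qin`, `Qout`, `Eff_tq_<dose>` and `Eff_scan`, as returned by
#'   [brain_param_estimates()].
#' @param dose_group tariquidar dose group, mg/kg.
#' @param conditions subset of `"baseline"`, `"during_tariquidar"`,
#'   `"post_inhibition"`.
#' @return A tibble: `region`, `condition`, `D`, `VT`, `VT_reported`,
#'   `fold_change`, `fold_reported`.
#' @examples
#' vt_nlme_table(brain_param_estimates("rat"), dose_group = 3)
#' @export
vt_nlme_table <- function(params, dose_group,
                          conditions = .condition_levels) {
  conditions <- match.arg(conditions, .condition_levels, several.ok = TRUE)
  col <- .eff_col(params, dose_group)
  scan_eff <- ifelse(is.finite(params$Eff_scan), params$Eff_scan, 1)
  rows <- lapply(conditions, function(cond) {
    D <- switch(cond,
                baseline = rep(1, nrow(params)),
                during_tariquidar = params[[col]],
                post_inhibition = params[[col]] * scan_eff)
    vt <- params$Qin / (params$Qout * D)
    tibble::tibble(region = params$region, condition = cond, D = D, VT = vt,
                   fold_change = 1 / D)
  })
  out <- dplyr::bind_rows(rows)
  out$condition <- factor(out$condition, levels = .condition_levels)
  dplyr::mutate(out,
                VT_reported = signif2(.data$VT),
                fold_reported = round_half_up(.data$fold_change, 1),
                .after = "VT")
}

#' Efflux-clearance change summary across regions
#'
#' Per-region percentage decrease in the efflux clearance caused by
#' tariquidar, `100 * (1 - D)`, with `D = Eff_tariquidar` during/immediately
#' after administration or `D = Eff_tariquidar * Eff_scan` in the
#' post-inhibition scan, summarized as mean and sample SD across the
#' analysis regions (rounded to integer percent).
#'
#' @param params per-region estimates as in [vt_nlme_table()].
#' @param dose_group tariquidar dose group, mg/kg.
#' @param condition `"during_tariquidar"` or `"post_inhibition"`.
#' @return A list of class `qout_change_summary`: `$per_region` tibble
#'   (`region`, `D`, `percent_decrease`, `percent_reported`),
#'   `$mean`, `$sd`, `$mean_reported`, `$sd_reported`.
#' @examples
#' qout_change_summary(brain_param_estimates("rat"), dose_group = 3)
#' @export
qout_change_summary <- function(params, dose_group,
                                condition = c("during_tariquidar",
                                              "post_inhibition")) {
  condition <- match.arg(condition)
  if (nrow(params) < 1L) abort("Need at least one region.")
  col <- .eff_col(params, dose_group)
  scan_eff <- ifelse(is.finite(params$Eff_scan), params$Eff_scan, 1)
  D <- if (condition == "during_tariquidar") params[[col]]
       else params[[col]] * scan_eff
  dec <- 100 * (1 - D)
  per_region <- tibble::tibble(region = params$region, D = D,
                               percent_decrease = dec,
                               percent_reported = round_half_up(dec))
  structure(list(
    per_region = per_region,
    condition = condition, dose_group = dose_group,
    mean = mean(dec), sd = if (length(dec) > 1) sd(dec) else NA_real_,
    mean_reported = round_half_up(mean(dec)),
    sd_reported = if (length(dec) > 1) round_half_up(sd(dec)) else NA_real_
  ), class = "qout_change_summary")
}

#' @export
print.qout_change_summary <- function(x, ...) {
  cat(sprintf(
    "Qout decrease (%s, %s mg/kg): mean %d%% (SD %s%%) across %d regions\n",
    x$condition, format(x$dose_group), x$mean_reported,
    ifelse(is.na(x$sd_reported), "-", x$sd_reported),
    nrow(x$per_region)))
  invisible(x)
}

#' Parameter table in the published layout
#'
#' Formats a fitted population model as an estimate / RSE% / IIV table
#' mirroring the published presentation.
#'
#' @param fit a `popfit`.
#' @return A tibble: `parameter`, `estimate`, `rse_pct`, `iiv_omega`.
#' @export
parameter_table <- function(fit) {
  stopifnot(inherits(fit, "popfit"))
  model <- fit$model
  free <- fit$free
  omega_of <- function(p) {
    for (b in names(model$iiv)) {
      if (p %in% model$iiv[[b]]$params) return(model$iiv[[b]]$omega)
    }
    NA_real_
  }
  rows <- lapply(names(model$theta), function(p) {
    fr <- free[free$kind == "theta" & free$name == p, ]
    tibble::tibble(parameter = p, estimate = unname(model$theta[[p]]),
                   rse_pct = if (nrow(fr)) fr$rse_pct else NA_real_,
                   fixed = model$fixed[[p]], iiv_omega = omega_of(p))
  })
  sig <- free[free$kind == "sigma", ]
  rows[[length(rows) + 1L]] <- tibble::tibble(
    parameter = "sigma", estimate = model$sigma,
    rse_pct = if (nrow(sig)) sig$rse_pct else NA_real_,
    fixed = model$sigma_fixed, iiv_omega = NA_real_)
  dplyr::bind_rows(rows)
}
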