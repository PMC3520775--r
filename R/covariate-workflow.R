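#' Likelihood-ratio OFV threshold
#'
#' Drop in OFV required for a one-parameter (1 df) nested-model improvement
#' at a given significance level: the chi-square(1) quantile at `1 - p`
#' (3.84, 6.63, 10.83 for p = 0.05, 0.01, 0.001; the exact 0.05 quantile is
#' 3.84 although 3.83 is often quoted).
#'
#' @param p_level one of 0.05, 0.01, 0.001.
#' @return The OFV threshold (scalar).
#' @export
lrt_threshold <- function(p_level) {
  if (!p_level %in% c(0.05, 0.01, 0.001)) {
    abort("`p_level` must be one of 0.05, 0.01, 0.001.")
  }
  qchisq(1 - p_level, df = 1)
}

.fit_quiet <- function(data, model, plasma_fit, control) {
  tryCatch(fit_population(data, model, plasma_fit, control),
           error = function(e) {
             warn(paste0("Model fit failed: ", conditionMessage(e)))
             NULL
           })
}

#' Stepwise covariate selection by OFV
#'
#' Hypothesis-driven model building: a forward-addition phase adds, at each
#' step, the candidate with the largest significant OFV drop (at the
#' `forward_p` chi-square threshold with 1 df per added parameter) until no
#' candidate qualifies, followed by a backward-deletion phase that removes
#' any retained covariate whose deletion increases the OFV by less than the
#' `backward_p` threshold. Ties in OFV drop are broken lexicographically by
#' candidate name. Candidates whose fit fails are skipped with a warning.
#'
#' @param data a `pk_dataset`.
#' @param base_model the covariate-free [population_model()].
#' @param candidates list of [candidate_covariate()] /
#'   [candidate_tariquidar()] objects.
#' @param forward_p,backward_p significance levels (0.05, 0.01 or 0.001);
#'   backward defaults to the forward level.
#' @param plasma_fit fixed plasma stage (brain-stage models).
#' @param control passed to [fit_population()].
#' @return A list of class `selection_trace`: `$trace` (tibble of evaluated
#'   steps: phase, step, candidate, OFV, delta OFV, threshold, decision),
#'   `$final_fit` (popfit of the selected model), `$selected` (names of
#'   retained candidates).
#' @export
stepwise_select <- function(data, base_model, candidates,
                            forward_p = 0.05, backward_p = forward_p,
                            plasma_fit = NULL, control = list()) {
  control$se <- control$se %||% FALSE
  thr_f <- lrt_threshold(forward_p)
  thr_b <- lrt_threshold(backward_p)
  names(candidates) <- vapply(candidates, `[[`, character(1), "name")
  candidates <- candidates[order(names(candidates))]
  base_fit <- fit_population(data, base_model, plasma_fit, control)
  current_fit <- base_fit
  current_model <- base_fit$model
  included <- character()
  trace <- list()
  step <- 0L
  # forward addition
  repeat {
    remaining <- setdiff(names(candidates), included)
    if (!length(remaining)) break
    step <- step + 1L
    best <- NULL
    for (nm in remaining) {
      cand_model <- apply_candidate(current_model, candidates[[nm]])
      fit <- .fit_quiet(data, cand_model, plasma_fit, control)
      if (is.null(fit)) {
        trace[[length(trace) + 1L]] <- tibble::tibble(
          phase = "forward", step = step, candidate = nm,
          ofv = NA_real_, delta_ofv = NA_real_, threshold = thr_f,
          decision = "failed")
        next
      }
      d_ofv <- current_fit$ofv - fit$ofv
      trace[[length(trace) + 1L]] <- tibble::tibble(
        phase = "forward", step = step, candidate = nm, ofv = fit$ofv,
        delta_ofv = d_ofv, threshold = thr_f,
        decision = if (d_ofv >= thr_f) "significant" else "not significant")
      if (d_ofv >= thr_f && (is.null(best) || d_ofv > best$d_ofv)) {
        best <- list(name = nm, fit = fit, d_ofv = d_ofv)
      }
    }
    if (is.null(best)) break
    included <- c(included, best$name)
    current_fit <- best$fit
    current_model <- best$fit$model
    trace[[length(trace) + 1L]] <- tibble::tibble(
      phase = "forward", step = step, candidate = best$name,
      ofv = best$fit$ofv, delta_ofv = best$d_ofv, threshold = thr_f,
      decision = "added")
  }
  # backward deletion
  changed <- TRUE
  while (changed && length(included)) {
    changed <- FALSE
    step <- step + 1L
    for (nm in included) {
      reduced_model <- drop_candidate(current_model, candidates[[nm]])
      fit <- .fit_quiet(data, reduced_model, plasma_fit, control)
      if (is.null(fit)) {
        trace[[length(trace) + 1L]] <- tibble::tibble(
          phase = "backward", step = step, candidate = nm,
          ofv = NA_real_, delta_ofv = NA_real_, threshold = thr_b,
          decision = "failed")
        next
      }
      d_ofv <- fit$ofv - current_fit$ofv  # OFV increase caused by deletion
      keep <- d_ofv >= thr_b
      trace[[length(trace) + 1L]] <- tibble::tibble(
        phase = "backward", step = step, candidate = nm, ofv = fit$ofv,
        delta_ofv = d_ofv, threshold = thr_b,
        decision = if (keep) "retained" else "removed")
      if (!keep) {
        included <- setdiff(included, nm)
        current_fit <- fit
        current_model <- fit$model
        changed <- TRUE
        break
      }
    }
  }
  structure(list(trace = dplyr::bind_rows(trace), final_fit = current_fit,
                 selected = included, base_ofv = base_fit$ofv),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace>\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  print(x$trace, n = nrow(x$trace))
  invisible(x)
}

#' Compare inhibitor-effect placement on influx vs efflux
#'
#' Fits the two non-nested structural alternatives for the tariquidar effect
#' (on the efflux clearance `Qout` versus on the influx clearance `Qin`) on
#' the same dataset and reports both OFVs; the lower OFV identifies the
#' preferred transport mechanism. If one fit fails the comparison is marked
#' inconclusive.
#'
#' @param data a `pk_dataset`.
#' @param model brain-stage [population_model()] (its current placement is
#'   ignored; both are fit).
#' @param plasma_fit fixed plasma stage.
#' @param control passed to [fit_population()].
#' @return A list of class `placement_comparison`: `$ofv_on_Qout`,
#'   `$ofv_on_Qin`, `$preferred` (`"on_Qout"`, `"on_Qin"` or
#'   `"inconclusive"`), `$fits`.
#' @export
compare_transport_placement <- function(data, model, plasma_fit = NULL,
                                        control = list()) {
  control$se <- control$se %||% FALSE
  fit_out <- .fit_quiet(data, set_placement(model, "on_Qout"),
                        plasma_fit, control)
  fit_in <- .fit_quiet(data, set_placement(model, "on_Qin"),
                       plasma_fit, control)
  ofv_out <- if (is.null(fit_out)) NA_real_ else fit_out$ofv
  ofv_in <- if (is.null(fit_in)) NA_real_ else fit_in$ofv
  preferred <- if (is.na(ofv_out) || is.na(ofv_in)) {
    "inconclusive"
  } else if (ofv_out <= ofv_in) "on_Qout" else "on_Qin"
  structure(list(ofv_on_Qout = ofv_out, ofv_on_Qin = ofv_in,
                 preferred = preferred,
                 fits = list(on_Qout = fit_out, on_Qin = fit_in)),
            class = "placement_comparison")
}

#' @export
print.placement_comparison <- function(x, ...) {
  cat(sprintf("<placement_comparison> OFV on_Qout = %.2f, on_Qin = %.2f -> %s\n",
              x$ofv_on_Qout, x$ofv_on_Qin, x$preferred))
  invisible(x)
}
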