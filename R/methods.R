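#' Tidy a fitted population model
#'
#' `tidy()` returns one row per estimated or fixed quantity (fixed effects,
#' eta-block SDs, residual SD) with estimates and relative standard errors;
#' `glance()` returns a one-row model summary (OFV, sizes, convergence).
#'
#' @param x a `popfit`.
#' @param ... unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.popfit <- function(x, ...) {
  model <- x$model
  free <- x$free
  rse_of <- function(kind, name) {
    r <- free[free$kind == kind & free$name == name, ]
    if (nrow(r)) r$rse_pct else NA_real_
  }
  th <- tibble::tibble(
    term = names(model$theta), type = "theta",
    estimate = unname(model$theta),
    rse_pct = vapply(names(model$theta), function(p) rse_of("theta", p),
                     numeric(1)),
    fixed = unname(model$fixed))
  om <- tibble::tibble(
    term = names(model$iiv), type = "omega",
    estimate = vapply(model$iiv, `[[`, numeric(1), "omega"),
    rse_pct = vapply(names(model$iiv), function(b) rse_of("omega", b),
                     numeric(1)),
    fixed = unname(model$omega_fixed))
  sg <- tibble::tibble(term = "sigma", type = "sigma", estimate = model$sigma,
                       rse_pct = rse_of("sigma", "sigma"),
                       fixed = model$sigma_fixed)
  dplyr::bind_rows(th, om, sg)
}

#' @rdname tidy.popfit
#' @exportS3Method generics::glance
glance.popfit <- function(x, ...) {
  tibble::tibble(
    ofv = x$ofv, stage = x$stage,
    placement = if (x$stage == "brain") x$model$placement else NA_character_,
    n_subjects = nrow(x$etas), n_obs = x$prep$n_obs,
    n_free = nrow(x$free),
    converged = isTRUE(x$convergence$converged),
    iterations = x$convergence$iterations)
}

#' Tidy classic PET reference fits
#'
#' @param x a `fit_2t4k` or `logan_fit`.
#' @param ... unused.
#' @return A one-row tibble of the fitted quantities.
#' @exportS3Method generics::tidy
tidy.fit_2t4k <- function(x, ...) {
  tibble::tibble(K1 = x$K1, k2 = x$k2, k3 = x$k3, k4 = x$k4,
                 VT_2T4K = x$VT_2T4K, rss = x$rss, n_frames = x$n_frames,
                 converged = x$converged)
}

#' @rdname tidy.fit_2t4k
#' @exportS3Method generics::tidy
tidy.logan_fit <- function(x, ...) {
  tibble::tibble(VT_Logan = x$VT_Logan, intercept = x$intercept,
                 t_star = x$t_star, r_squared = x$r_squared,
                 n_points = x$n_points)
}

#' @rdname tidy.fit_2t4k
#' @exportS3Method generics::tidy
tidy.selection_trace <- function(x, ...) x$trace

#' @rdname tidy.fit_2t4k
#' @exportS3Method generics::tidy
tidy.placement_comparison <- function(x, ...) {
  pl <- c("on_Qout", "on_Qin")
  tibble::tibble(placement = pl,
                 ofv = c(x$ofv_on_Qout, x$ofv_on_Qin),
                 preferred = pl == x$preferred)
}

#' @rdname tidy.fit_2t4k
#' @exportS3Method generics::tidy
tidy.qout_change_summary <- function(x, ...) x$per_region
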