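# ---- data preparation -------------------------------------------------------

.subject_level_cols <- c("species", "group", "dose_group", "body_weight_g")

# Per-subject precomputed design: observation vectors, dosing, tariquidar
# events, and (brain stage) the fixed plasma forcing on a fine grid.
.prepare_stage <- function(data, model, plasma_fit = NULL,
                           forcing = c("individual", "population")) {
  forcing <- match.arg(forcing)
  validate_pk_dataset(data)
  stage <- model$stage
  obs <- data[data$obs_type == (if (stage == "plasma") "plasma" else "brain"), ]
  if (stage == "brain" && !is.null(model$region) && "region" %in% names(obs)) {
    obs <- obs[is.na(obs$region) | obs$region == model$region, ]
  }
  if (stage == "brain" && is.null(plasma_fit)) {
    abort("Brain-stage preparation needs a `plasma_fit` (popfit or fixed_plasma).")
  }
  ids <- unique(data$subject_id)
  pp_by_subject <- if (stage == "brain") {
    .individual_plasma(plasma_fit, ids, forcing)
  }
  subjects <- vector("list", length(ids))
  names(subjects) <- ids
  for (i in seq_along(ids)) {
    id <- ids[i]
    drows <- data[data$subject_id == id, ]
    orows <- obs[obs$subject_id == id, ]
    per_record <- c("scan", "time_min", "obs_type", "region", "value",
                    "injected_kBq", "inj_dur_min", "tq_start_min",
                    "tq_dur_min")
    covs <- as.list(drows[1, setdiff(names(drows), per_record)])
    ev <- NULL
    s1 <- drows[drows$scan == 1 & !is.na(drows$tq_start_min), ]
    if (nrow(s1)) {
      ev <- tibble::tibble(dose_group = s1$dose_group[1],
                           start = s1$tq_start_min[1],
                           duration = s1$tq_dur_min[1])
    }
    scans <- list()
    for (sc in sort(unique(orows$scan))) {
      srows <- orows[orows$scan == sc, ]
      srows <- srows[order(srows$time_min), ]
      times <- srows$time_min
      y <- srows$value
      doses <- tibble::tibble(amount = srows$injected_kBq[1], start = 0,
                              duration = srows$inj_dur_min[1])
      entry <- list(scan = sc, times = times, y = y, doses = doses)
      if (stage == "brain") {
        extra <- if (!is.null(ev) && sc == 1L) c(times, ev$start) else times
        grid <- .forcing_grid(max(times), extra = extra)
        entry$grid <- grid
        entry$obs_idx <- match(times, grid)
        entry$mids <- (grid[-1] + grid[-length(grid)]) / 2
        pp_i <- pp_by_subject[[id]]
        M <- .plasma_matrix(pp_i)
        seg <- .dose_segments(doses, max(grid))
        A <- .lin_const_solve(M, seg$breaks, seg$rates, grid)
        entry$cc <- pmax(A[1, ] / pp_i$Vc, 0)
      }
      scans[[as.character(sc)]] <- entry
    }
    subjects[[i]] <- list(id = id, covs = covs, ev = ev, scans = scans,
                          y_all = unlist(lapply(scans, `[[`, "y")) %||% numeric())
  }
  list(stage = stage, subjects = subjects, n_obs = nrow(obs))
}

# plasma forcing source for the brain stage --------------------------------

#' Fixed plasma stage for the sequential brain fit
#'
#' Wraps a known plasma parameter set for use as the fixed plasma stage when
#' fitting the brain model, in place of a fitted plasma-stage `popfit` (e.g.
#' when simulating, or fixing plasma at known values in tests).
#'
#' @param params a [plasma_params()] object (population values).
#' @param individual optional named list (by subject id) of
#'   [plasma_params()] overriding `params` per subject.
#' @return An object of class `fixed_plasma`.
#' @export
fixed_plasma <- function(params, individual = NULL) {
  stopifnot(inherits(params, "plasma_params"))
  structure(list(params = params, individual = individual),
            class = "fixed_plasma")
}

.pp_from_theta <- function(theta, eta_by_param = NULL) {
  val <- function(p) {
    e <- if (!is.null(eta_by_param) && p %in% names(eta_by_param)) {
      eta_by_param[[p]]
    } else 0
    unname(theta[[p]]) * exp(e)
  }
  plasma_params(Vc = val("Vc"), Vp1 = val("Vp1"), Vp2 = val("Vp2"),
                CL = val("CL"), Q1 = val("Q1"), Q2 = val("Q2"))
}

.individual_plasma <- function(plasma_fit, ids, forcing) {
  if (inherits(plasma_fit, "fixed_plasma")) {
    out <- lapply(ids, function(id) {
      plasma_fit$individual[[id]] %||% plasma_fit$params
    })
    names(out) <- ids
    return(out)
  }
  if (inherits(plasma_fit, "popfit")) {
    stopifnot(plasma_fit$model$stage == "plasma")
    theta <- plasma_fit$model$theta
    iiv <- plasma_fit$model$iiv
    etas <- plasma_fit$etas
    out <- lapply(ids, function(id) {
      eta_by_param <- NULL
      if (forcing == "individual" && length(iiv) && id %in% etas$subject_id) {
        row <- etas[etas$subject_id == id, , drop = FALSE]
        eta_by_param <- list()
        for (b in names(iiv)) {
          for (p in iiv[[b]]$params) eta_by_param[[p]] <- row[[b]][1]
        }
      }
      .pp_from_theta(theta, eta_by_param)
    })
    names(out) <- ids
    return(out)
  }
  abort("`plasma_fit` must be a plasma-stage popfit or a fixed_plasma object.")
}

# ---- parameter mapping ------------------------------------------------------

# named multiplier over theta entries from static covariates
.cov_mult <- function(model, covs) {
  mult <- setNames(rep(1, length(model$theta)), names(model$theta))
  cv <- model$covariates
  if (!is.null(cv)) {
    for (k in seq_len(nrow(cv))) {
      if (identical(as.character(covs[[cv$column[k]]]),
                    as.character(cv$level[k]))) {
        mult[cv$param[k]] <- mult[cv$param[k]] * model$theta[[cv$effect[k]]]
      }
    }
  }
  mult
}

# eta value per structural parameter, given block eta vector
.eta_by_param <- function(model, eta) {
  out <- list()
  if (!length(model$iiv) || !length(eta)) return(out)
  for (bi in seq_along(model$iiv)) {
    for (p in model$iiv[[bi]]$params) out[[p]] <- eta[bi]
  }
  out
}

.effs_from_theta <- function(model) {
  tq <- setNames(
    vapply(model$tq_doses,
           function(d) unname(model$theta[[paste0("Eff_tq_", d)]]), numeric(1)),
    as.character(model$tq_doses))
  structure(list(
    Eff_tariquidar = tq,
    Eff_scan = if (model$scan_effect) unname(model$theta[["Eff_scan"]]) else 1,
    Eff_SE = 1, placement = model$placement
  ), class = "covariate_effects")
}

# Build a fast per-subject prediction closure f(eta) for the current theta.
# Everything eta-independent (covariate multipliers, inhibitor-effect
# schedule, dosing segments, forcing curves) is precomputed once, so inner
# eta iterations cost only the compiled propagation.
.subject_predictor <- function(sub, model) {
  mult <- .cov_mult(model, sub$covs)
  th <- model$theta
  eidx <- function(p) {
    for (bi in seq_along(model$iiv)) {
      if (p %in% model$iiv[[bi]]$params) return(bi)
    }
    0L
  }
  if (model$stage == "plasma") {
    pn <- c("Vc", "Vp1", "Vp2", "CL", "Q1", "Q2")
    base <- vapply(pn, function(p) unname(th[[p]]) * mult[[p]], numeric(1))
    ei <- vapply(pn, eidx, integer(1)) + 1L
    scans <- lapply(sub$scans, function(scn) {
      seg <- .dose_segments(scn$doses, max(scn$times))
      list(breaks = seg$breaks, rates = seg$rates[1, ], times = scn$times)
    })
    function(eta) {
      v <- base * exp(c(0, eta)[ei])
      unlist(lapply(scans, function(s) {
        .plasma_conc_cpp(v[1], v[2], v[3], v[4], v[5], v[6],
                         s$breaks, s$rates, s$times)
      }), use.names = FALSE) %||% numeric()
    }
  } else {
    pn <- c("Vbr1", "Vbr2", "Qin", "Qout", "Qbr")
    base <- vapply(pn, function(p) unname(th[[p]]) * mult[[p]], numeric(1))
    ei <- vapply(pn, eidx, integer(1)) + 1L
    effs <- .effs_from_theta(model)
    on_qin <- as.integer(model$placement == "on_Qin")
    scans <- lapply(sub$scans, function(scn) {
      list(grid = scn$grid, cc = scn$cc, obs_idx = scn$obs_idx,
           Dmid = effect_D(sub$ev, scn$scan, scn$mids, effs))
    })
    function(eta) {
      v <- base * exp(c(0, eta)[ei])
      unlist(lapply(scans, function(s) {
        A <- .brain_propagate_cpp(v[1], v[2], v[3], v[4], v[5], on_qin,
                                  s$grid, s$cc, s$Dmid)
        (A[1, s$obs_idx] + A[2, s$obs_idx]) / (v[1] + v[2])
      }), use.names = FALSE) %||% numeric()
    }
  }
}

# model predictions for one subject at a given eta (both scans, concatenated)
.predict_subject <- function(sub, model, eta) {
  .subject_predictor(sub, model)(eta)
}

# ---- objective function -----------------------------------------------------

# -2 log-likelihood terms of the proportional-error model
.l_obs <- function(y, f, sigma) {
  s2f2 <- sigma^2 * f^2
  log(2 * pi * s2f2) + (y - f)^2 / s2f2
}

# exact d2/df2 of the per-observation -2 log-likelihood
.l_obs_d2f <- function(y, f, sigma) {
  r <- y - f
  -2 / f^2 + (2 / f^2 + 8 * r / f^3 + 6 * r^2 / f^4) / sigma^2
}

.num_hess <- function(fn, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      ei <- ej <- rep(0, n); ei[i] <- h; ej[j] <- h
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * h * h)
    }
  }
  H
}

# first derivative d/df of the per-observation -2 log-likelihood
.l_obs_d1f <- function(y, f, sigma) {
  r <- y - f
  2 / f - (2 * r / f^2 + 2 * r^2 / f^3) / sigma^2
}

# Damped Gauss-Newton search for the conditional mode of eta.
# Returns the mode, predictions and Jacobian there, and the penalized
# -2 log joint density (without the normalization constant).
.inner_newton <- function(pred, y, sigma, om2, start, tol = 1e-9,
                          max_iter = 40) {
  p <- length(om2)
  Oinv <- 1 / om2
  gval_of <- function(f, eta) {
    if (any(!is.finite(f)) || any(f <= 0)) return(Inf)
    sum(.l_obs(y, f, sigma)) + sum(eta^2 * Oinv)
  }
  eta <- start
  f <- pred(eta)
  g <- gval_of(f, eta)
  if (!is.finite(g)) {
    eta <- rep(0, p)
    f <- pred(eta)
    g <- gval_of(f, eta)
    if (!is.finite(g)) return(NULL)
  }
  h <- 1e-4
  jac_at <- function(eta, f) {
    J <- matrix(0, length(y), p)
    for (k in seq_len(p)) {
      ek <- rep(0, p); ek[k] <- h
      J[, k] <- (pred(eta + ek) - f) / h
    }
    J
  }
  for (it in seq_len(max_iter)) {
    J <- jac_at(eta, f)
    grad <- drop(crossprod(J, .l_obs_d1f(y, f, sigma))) + 2 * eta * Oinv
    w <- pmax(.l_obs_d2f(y, f, sigma), 0)
    Hn <- diag(2 * Oinv, p) + crossprod(J, J * w)
    step <- tryCatch(drop(-solve(Hn, grad)),
                     error = function(e) -grad / max(diag(Hn)))
    improved <- FALSE
    for (ls in 0:12) {
      eta_new <- eta + step
      f_new <- pred(eta_new)
      g_new <- gval_of(f_new, eta_new)
      if (is.finite(g_new) && g_new <= g) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    dec <- g - g_new
    eta <- eta_new
    f <- f_new
    g <- g_new
    if (dec < tol * (abs(g) + 1)) break
  }
  list(eta = eta, f = f, g = g, J = jac_at(eta, f))
}

# Laplace/FOCE-I marginal -2 log-likelihood contribution of one subject.
# Returns list(value, eta). cache_eta warm-starts the inner search.
.subject_neg2ll <- function(sub, model, sigma, omegas, cache_eta = NULL,
                            inner_tol = 1e-9, predictor = NULL) {
  y <- sub$y_all
  p <- length(omegas)
  pred <- predictor %||% .subject_predictor(sub, model)
  if (!length(y)) {
    return(list(value = 0, eta = rep(0, p)))
  }
  if (p == 0L) {
    f <- pred(numeric())
    if (any(!is.finite(f)) || any(f <= 0)) {
      return(list(value = 1e10, eta = numeric()))
    }
    return(list(value = sum(.l_obs(y, f, sigma)), eta = numeric()))
  }
  om2 <- omegas^2
  gconst <- p * log(2 * pi) + sum(log(om2))
  inn <- .inner_newton(pred, y, sigma, om2, start = cache_eta %||% rep(0, p),
                       tol = inner_tol)
  if (is.null(inn)) {
    return(list(value = 1e10, eta = rep(0, p)))
  }
  eta_hat <- inn$eta
  # FOCE-I curvature: Gauss-Newton in f with the exact d2l/df2 weights
  w <- .l_obs_d2f(y, inn$f, sigma)
  H <- diag(1 / om2, p) + 0.5 * crossprod(inn$J, inn$J * w)
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) {
    # Laplace fallback: exact numerical curvature of the joint density
    gfun <- function(eta) {
      f <- pred(eta)
      if (any(!is.finite(f)) || any(f <= 0)) return(1e10 * (1 + sum(eta^2)))
      sum(.l_obs(y, f, sigma)) + sum(eta^2 / om2)
    }
    H <- .num_hess(gfun, eta_hat, h = 1e-3) / 2
    ch <- tryCatch(chol(H), error = function(e) NULL)
  }
  if (is.null(ch)) {
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    logdet <- sum(log(pmax(ev, 1e-8)))
  } else {
    logdet <- 2 * sum(log(diag(ch)))
  }
  list(value = inn$g + gconst - p * log(2 * pi) + logdet, eta = eta_hat)
}

.ofv_core <- function(prep, model, sigma, omegas, cache = NULL,
                      inner_tol = 1e-8, details = FALSE) {
  total <- 0
  etas <- list()
  contribs <- numeric(length(prep$subjects))
  for (i in seq_along(prep$subjects)) {
    sub <- prep$subjects[[i]]
    res <- .subject_neg2ll(sub, model, sigma, omegas,
                           cache_eta = if (!is.null(cache)) cache$etas[[sub$id]],
                           inner_tol = inner_tol)
    total <- total + res$value
    contribs[i] <- res$value
    if (!is.null(cache)) cache$etas[[sub$id]] <- res$eta
    if (details) etas[[sub$id]] <- res$eta
  }
  if (!details) return(total)
  list(ofv = total, etas = etas, contribs = contribs)
}

#' Objective function value of a population model
#'
#' Computes the approximate -2 log marginal likelihood (OFV) of a population
#' model on a dataset: per subject, the random-effect vector is optimized
#' (conditional modes) and the marginal integral is approximated by a
#' Laplace-family correction with interaction-aware Gauss-Newton curvature,
#' falling back to an exact numerical Hessian when that curvature is not
#' positive definite. With no random effects the OFV is the closed-form
#' proportional-error sum \eqn{\sum_j [\ln(2\pi\sigma^2 f_j^2) +
#' (y_j - f_j)^2/(\sigma^2 f_j^2)]}. The OFV is additive over subjects.
#'
#' @param data a `pk_dataset`.
#' @param model a [population_model()].
#' @param plasma_fit for brain-stage models, the fixed plasma stage (a
#'   plasma-stage `popfit` or [fixed_plasma()]).
#' @param theta,omega,sigma optional overrides of the model's current values
#'   (`omega` named by block).
#' @param control list; `inner_tol` (inner eta-search relative tolerance,
#'   default 1e-8), `forcing` (`"individual"`/`"population"` plasma curves).
#' @return The OFV (scalar).
#' @export
ofv <- function(data, model, plasma_fit = NULL, theta = NULL, omega = NULL,
                sigma = NULL, control = list()) {
  stopifnot(inherits(model, "pop_model"))
  if (!is.null(theta)) model$theta[names(theta)] <- theta
  if (!is.null(omega)) {
    for (b in names(omega)) model$iiv[[b]]$omega <- omega[[b]]
  }
  if (!is.null(sigma)) model$sigma <- sigma
  prep <- .prepare_stage(data, model, plasma_fit,
                         forcing = control$forcing %||% "individual")
  omegas <- vapply(model$iiv, `[[`, numeric(1), "omega")
  .ofv_core(prep, model, model$sigma, omegas,
            inner_tol = control$inner_tol %||% 1e-8)
}

# ---- outer estimation -------------------------------------------------------

.free_params <- function(model) {
  rows <- list()
  for (nm in names(model$theta)) {
    if (!model$fixed[[nm]]) {
      rows[[length(rows) + 1L]] <-
        list(kind = "theta", name = nm, value = unname(model$theta[[nm]]))
    }
  }
  for (b in names(model$iiv)) {
    if (!model$omega_fixed[[b]]) {
      rows[[length(rows) + 1L]] <-
        list(kind = "omega", name = b, value = model$iiv[[b]]$omega)
    }
  }
  if (!model$sigma_fixed) {
    rows[[length(rows) + 1L]] <- list(kind = "sigma", name = "sigma",
                                      value = model$sigma)
  }
  rows
}

.set_free <- function(model, free, values) {
  for (k in seq_along(free)) {
    fp <- free[[k]]
    if (fp$kind == "theta") {
      model$theta[[fp$name]] <- values[k]
    } else if (fp$kind == "omega") {
      model$iiv[[fp$name]]$omega <- values[k]
    } else {
      model$sigma <- values[k]
    }
  }
  model
}

#' Fit a population model by approximate marginal likelihood
#'
#' Minimizes the OFV (see [ofv()]) over the log-transformed free parameters
#' (fixed effects, eta SDs, residual SD) with a bounded quasi-Newton outer
#' loop; the inner eta search is warm-started across outer iterations. For
#' the brain stage the plasma model is fixed: each subject's plasma forcing
#' is the individual (empirical-Bayes) plasma curve from `plasma_fit`
#' (population curves via `control$forcing = "population"`). Relative
#' standard errors come from the inverse observed Hessian of the OFV surface
#' on the log scale (delta method); when the Hessian is singular, RSEs are
#' suppressed with a warning.
#'
#' @inheritParams ofv
#' @param control list of options: `se` (compute RSEs, default TRUE),
#'   `inner_tol` (default 1e-8), `outer_rel_tol` (default 1e-6),
#'   `outer_iter` (default 300), `forcing` (`"individual"` default).
#' @return A `popfit` object; see [tidy.popfit()], [glance.popfit()],
#'   [diagnostics_table()].
#' @export
fit_population <- function(data, model, plasma_fit = NULL, control = list()) {
  stopifnot(inherits(model, "pop_model"))
  ctl <- utils::modifyList(
    list(se = TRUE, inner_tol = 1e-9, outer_rel_tol = 1e-7,
         outer_iter = 300, forcing = "individual", se_step = 1e-3,
         grad_step = 1e-5), control)
  prep <- .prepare_stage(data, model, plasma_fit, forcing = ctl$forcing)
  free <- .free_params(model)
  if (!length(free)) abort("Model has no free parameters.")
  x0 <- log(vapply(free, `[[`, numeric(1), "value"))
  cache <- new.env(parent = emptyenv())
  cache$etas <- list()
  trace <- new.env(parent = emptyenv())
  trace$vals <- numeric()
  objective <- function(x) {
    m <- .set_free(model, free, exp(x))
    omegas <- vapply(m$iiv, `[[`, numeric(1), "omega")
    val <- .ofv_core(prep, m, m$sigma, omegas, cache = cache,
                     inner_tol = ctl$inner_tol)
    if (!is.finite(val)) val <- 1e12
    trace$vals <- c(trace$vals, val)
    val
  }
  # explicit central-difference gradient: the objective carries O(inner_tol)
  # numerical noise, so the FD step must stay well above it
  gradient <- function(x) {
    h <- ctl$grad_step
    vapply(seq_along(x), function(i) {
      e <- rep(0, length(x)); e[i] <- h
      (objective(x + e) - objective(x - e)) / (2 * h)
    }, numeric(1))
  }
  opt <- nlminb(x0, objective, gradient = gradient, lower = -20, upper = 20,
                control = list(rel.tol = ctl$outer_rel_tol,
                               iter.max = ctl$outer_iter,
                               eval.max = 4 * ctl$outer_iter))
  grad_final <- gradient(opt$par)
  converged <- opt$convergence == 0 ||
    grepl("relative convergence|absolute function convergence|X-convergence",
          opt$message %||% "") ||
    max(abs(grad_final)) < 2
  model_hat <- .set_free(model, free, exp(opt$par))
  omegas_hat <- vapply(model_hat$iiv, `[[`, numeric(1), "omega")
  det <- .ofv_core(prep, model_hat, model_hat$sigma, omegas_hat,
                   cache = cache, inner_tol = ctl$inner_tol, details = TRUE)
  eta_tbl <- NULL
  if (length(model_hat$iiv)) {
    eta_tbl <- tibble::as_tibble(
      do.call(rbind, lapply(det$etas, function(e) setNames(e, names(model_hat$iiv)))))
    eta_tbl <- dplyr::bind_cols(
      tibble::tibble(subject_id = names(det$etas)), eta_tbl)
  } else {
    eta_tbl <- tibble::tibble(subject_id = names(prep$subjects))
  }
  rse <- rep(NA_real_, length(free))
  vcov <- NULL
  hess_ok <- NA
  if (isTRUE(ctl$se)) {
    H <- .num_hess(objective, opt$par, h = ctl$se_step)
    vcov <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(vcov) && all(diag(vcov) > 0)) {
      rse <- 100 * sqrt(diag(vcov))
      hess_ok <- TRUE
    } else {
      warn("OFV Hessian is singular or indefinite; RSEs suppressed.")
      hess_ok <- FALSE
      vcov <- NULL
    }
  }
  free_tbl <- tibble::tibble(
    kind = vapply(free, `[[`, character(1), "kind"),
    name = vapply(free, `[[`, character(1), "name"),
    estimate = exp(opt$par), rse_pct = rse)
  structure(list(
    model = model_hat, stage = model$stage, ofv = det$ofv,
    free = free_tbl, etas = eta_tbl, contribs = det$contribs,
    vcov = vcov,
    convergence = list(code = opt$convergence, message = opt$message,
                       converged = converged,
                       max_grad = max(abs(grad_final)),
                       iterations = opt$iterations, hessian_ok = hess_ok,
                       ofv_evals = length(trace$vals)),
    ofv_trace = trace$vals,
    prep = prep, plasma_fit = plasma_fit, control = ctl
  ), class = "popfit")
}

#' Empirical Bayes estimates of the random effects
#'
#' Conditional modes of each subject's eta vector at the fitted population
#' estimates. Subjects without observations get eta = 0 (the prior mode).
#'
#' @param fit a `popfit`.
#' @return A tibble with `subject_id` and one column per eta block.
#' @export
empirical_bayes <- function(fit) {
  stopifnot(inherits(fit, "popfit"))
  fit$etas
}

#' Observation-level fit diagnostics
#'
#' One row per observation with the population prediction (`PRED`, eta = 0),
#' individual prediction (`IPRED`, at the empirical Bayes eta), and the
#' individual weighted residual `IWRES = (y - IPRED)/(sigma * IPRED)`
#' (missing where `IPRED` is zero). The tabular analogue of the classic
#' goodness-of-fit panels.
#'
#' @param fit a `popfit`.
#' @return A tibble with columns `subject_id`, `scan`, `time_min`,
#'   `obs_type`, `value`, `PRED`, `IPRED`, `IWRES`.
#' @export
diagnostics_table <- function(fit) {
  stopifnot(inherits(fit, "popfit"))
  model <- fit$model
  p <- length(model$iiv)
  rows <- lapply(fit$prep$subjects, function(sub) {
    if (!length(sub$y_all)) return(NULL)
    eta_hat <- rep(0, p)
    if (p > 0) {
      r <- fit$etas[fit$etas$subject_id == sub$id, , drop = FALSE]
      eta_hat <- as.numeric(r[1, names(model$iiv)])
    }
    pred <- .predict_subject(sub, model, rep(0, p))
    ipred <- .predict_subject(sub, model, eta_hat)
    iwres <- ifelse(ipred > 0, (sub$y_all - ipred) / (model$sigma * ipred),
                    NA_real_)
    tibble::tibble(
      subject_id = sub$id,
      scan = unlist(lapply(sub$scans, function(s) rep(s$scan, length(s$times)))),
      time_min = unlist(lapply(sub$scans, `[[`, "times")),
      obs_type = if (fit$stage == "plasma") "plasma" else "brain",
      value = sub$y_all, PRED = pred, IPRED = ipred, IWRES = iwres)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.popfit <- function(x, ...) {
  cat(sprintf("<popfit: %s stage>  OFV = %.3f\n", x$stage, x$ofv))
  cat(sprintf("  %d subjects, %d free parameters, convergence code %d\n",
              nrow(x$etas), nrow(x$free), x$convergence$code))
  print(x$free, n = nrow(x$free))
  invisible(x)
}
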