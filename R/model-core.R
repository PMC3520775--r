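#' Structural parameter sets
#'
#' Constructors for the structural model parameters. `plasma_params()` holds
#' the three-compartment mammillary plasma model (central volume `Vc`,
#' peripheral volumes `Vp1`, `Vp2`, total body clearance `CL`, inter-
#' compartmental clearances `Q1`, `Q2`). `brain_params()` holds the
#' two-compartment brain model (central and peripheral distribution volumes
#' `Vbr1`, `Vbr2`, influx/efflux clearances `Qin`, `Qout` across the BBB and
#' the intra-brain exchange clearance `Qbr`). All volumes in ml, clearances
#' in ml/min.
#'
#' @param Vc,Vp1,Vp2,CL,Q1,Q2 plasma model parameters (positive).
#' @param Vbr1,Vbr2,Qin,Qout,Qbr brain model parameters (positive).
#' @param Vbr2_fixed logical; whether `Vbr2` is treated as fixed during
#'   estimation (the rat convention, `Vbr2 = 2` ml, the volume of a rat brain).
#' @return A named list with class `"plasma_params"` / `"brain_params"`.
#' @examples
#' plasma_params(Vc = 38.8, Vp1 = 141, Vp2 = 1580, CL = 16.4, Q1 = 29.1, Q2 = 22.3)
#' @export
plasma_params <- function(Vc, Vp1, Vp2, CL, Q1, Q2) {
  p <- list(Vc = Vc, Vp1 = Vp1, Vp2 = Vp2, CL = CL, Q1 = Q1, Q2 = Q2)
  for (nm in names(p)) check_positive_scalar(p[[nm]], nm)
  structure(p, class = "plasma_params")
}

#' @rdname plasma_params
#' @export
brain_params <- function(Vbr1, Vbr2, Qin, Qout, Qbr, Vbr2_fixed = TRUE) {
  p <- list(Vbr1 = Vbr1, Vbr2 = Vbr2, Qin = Qin, Qout = Qout, Qbr = Qbr)
  for (nm in names(p)) check_positive_scalar(p[[nm]], nm)
  p$Vbr2_fixed <- isTRUE(Vbr2_fixed)
  structure(p, class = "brain_params")
}

#' Categorical covariate effects on tracer transport
#'
#' Collects the multiplicative covariate effects of the population model: the
#' per-dose tariquidar effect (fractional change of the targeted transport
#' clearance while the inhibitor acts), the scan effect (additional fractional
#' change in the post-inhibition scan, reflecting inhibitor washout), and the
#' status-epilepticus effect on the central brain distribution volume. The
#' `placement` states which transport clearance the inhibitor effect `D`
#' multiplies: efflux (`"on_Qout"`, efflux-enhancement mechanism) or influx
#' (`"on_Qin"`, gatekeeper mechanism).
#'
#' @param Eff_tariquidar named positive vector, one entry per dose group in
#'   mg/kg (names like `"3"`, `"15"`, `"2"`).
#' @param Eff_scan positive scalar; 1 means no scan effect.
#' @param Eff_SE positive scalar; 1 means no disease-group effect.
#' @param placement `"on_Qout"` or `"on_Qin"`.
#' @return A list with class `"covariate_effects"`.
#' @examples
#' covariate_effects(Eff_tariquidar = c("3" = 0.161, "15" = 0.135), Eff_scan = 1.33)
#' @export
covariate_effects <- function(Eff_tariquidar = numeric(), Eff_scan = 1,
                              Eff_SE = 1, placement = c("on_Qout", "on_Qin")) {
  placement <- match.arg(placement)
  if (length(Eff_tariquidar)) {
    if (is.null(names(Eff_tariquidar)) || any(!nzchar(names(Eff_tariquidar)))) {
      abort("`Eff_tariquidar` must be named by dose group (mg/kg).")
    }
    if (any(!is.finite(Eff_tariquidar)) || any(Eff_tariquidar <= 0)) {
      abort("`Eff_tariquidar` entries must be positive and finite.")
    }
  }
  check_positive_scalar(Eff_scan, "Eff_scan")
  check_positive_scalar(Eff_SE, "Eff_SE")
  structure(
    list(Eff_tariquidar = Eff_tariquidar, Eff_scan = Eff_scan,
         Eff_SE = Eff_SE, placement = placement),
    class = "covariate_effects"
  )
}

#' Time-activity curves
#'
#' A time-activity curve (TAC) is stored as a tibble with columns `label`
#' (region name or `"plasma"`), `time_min` (frame midpoints, strictly
#' increasing), `value`, and `unit` (`"kBq_per_ml"` or `"SUV"`).
#'
#' @param label region label.
#' @param times frame midpoint times in minutes, strictly increasing.
#' @param values activity concentrations.
#' @param unit `"kBq_per_ml"` or `"SUV"`.
#' @return A tibble.
#' @export
tac <- function(label, times, values, unit = c("kBq_per_ml", "SUV")) {
  unit <- match.arg(unit)
  if (length(times) != length(values)) {
    abort("`times` and `values` must have equal length.")
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    abort("`times` must be finite and strictly increasing.")
  }
  if (any(!is.finite(values))) abort("`values` must be finite.")
  tibble::tibble(label = label, time_min = as.numeric(times),
                 value = as.numeric(values), unit = unit)
}

# ---- exact linear-system machinery -----------------------------------------

# phi1(lambda, h) = (exp(lambda h) - 1)/lambda, series-safe near 0
.phi1 <- function(lam, h) {
  x <- lam * h
  small <- abs(x) < 1e-7
  out <- lam
  out[!small] <- (exp(x[!small]) - 1) / lam[!small]
  out[small] <- h * (1 + x[small] / 2 + x[small]^2 / 6)
  out
}

# phi2(lambda, h) = (exp(lambda h) - 1 - lambda h)/lambda^2
.phi2 <- function(lam, h) {
  x <- lam * h
  small <- abs(x) < 1e-5
  out <- lam
  out[!small] <- (exp(x[!small]) - 1 - x[!small]) / lam[!small]^2
  out[small] <- h^2 * (1 / 2 + x[small] / 6 + x[small]^2 / 24)
  out
}

# rate matrix of the 3-compartment mammillary plasma model (amount form)
.plasma_matrix <- function(p) {
  with(p, matrix(c(
    -(CL + Q1 + Q2) / Vc, Q1 / Vp1, Q2 / Vp2,
    Q1 / Vc, -Q1 / Vp1, 0,
    Q2 / Vc, 0, -Q2 / Vp2
  ), nrow = 3, byrow = TRUE))
}

# Exact solution of dA/dt = M A + b(t) with piecewise-constant b over
# segments given by `breaks` (length s+1) and `rates` (n x s matrix), A(0)=0.
# Returns the state matrix (n x length(times)); times must be sorted, >= breaks[1].
.lin_const_solve <- function(M, breaks, rates, times) {
  eg <- eigen(M)
  if (all(abs(Im(eg$values)) < 1e-10 * max(abs(eg$values), 1))) {
    # compartmental matrices have a real spectrum: compiled fast path
    P <- Re(eg$vectors)
    lam <- Re(eg$values)
    beta <- solve(P, Re(rates))
    return(.lin_const_solve_cpp(lam, P, beta, breaks, times))
  }
  P <- eg$vectors
  lam <- eg$values
  Pinv <- solve(P)
  n <- nrow(M)
  z <- rep(0 + 0i, n)
  out <- matrix(0, n, length(times))
  for (s in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1L]
    beta <- drop(Pinv %*% rates[, s])
    for (j in which(times > t0 & times <= t1)) {
      h <- times[j] - t0
      out[, j] <- Re(P %*% (exp(lam * h) * z + .phi1(lam, h) * beta))
    }
    h <- t1 - t0
    z <- exp(lam * h) * z + .phi1(lam, h) * beta
  }
  if (any(times <= breaks[1])) out[, times <= breaks[1]] <- 0
  out
}

# infusion schedule (piecewise-constant central input rate) from dose events
.dose_segments <- function(doses, t_end) {
  if (is.null(doses) || nrow(doses) == 0L) {
    return(list(breaks = c(0, t_end), rates = matrix(0, 3, 1)))
  }
  stopifnot(all(doses$amount >= 0), all(doses$duration > 0))
  brk <- sort(unique(c(0, doses$start, doses$start + doses$duration, t_end)))
  brk <- brk[brk <= t_end + 1e-12]
  if (max(brk) < t_end) brk <- c(brk, t_end)
  rates <- matrix(0, 3, length(brk) - 1L)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  for (k in seq_len(nrow(doses))) {
    on <- mids > doses$start[k] & mids < doses$start[k] + doses$duration[k]
    rates[1, on] <- rates[1, on] + doses$amount[k] / doses$duration[k]
  }
  list(breaks = brk, rates = rates)
}

#' Simulate the plasma model
#'
#' Exact forward simulation of the three-compartment plasma model under a
#' schedule of zero-order infusions (the tracer injection is modelled as an
#' infusion over the recorded injection duration, not an instantaneous bolus).
#' The linear system is solved by eigendecomposition over piecewise-constant
#' input segments, so the result is exact at the requested times up to
#' floating-point error.
#'
#' @param params a [plasma_params()] object.
#' @param doses a data frame of dose events with columns `amount` (kBq),
#'   `start` (min), `duration` (min).
#' @param times output time grid (min), strictly increasing, non-negative.
#' @return A [tac()] tibble of central-compartment concentration `A_c/Vc`
#'   (kBq/ml), labelled `"plasma"`.
#' @examples
#' p <- plasma_params(38.8, 141, 1580, 16.4, 29.1, 22.3)
#' simulate_plasma(p, data.frame(amount = 91000, start = 0, duration = 0.4),
#'                 times = seq(0.5, 60, by = 0.5))
#' @export
simulate_plasma <- function(params, doses, times) {
  stopifnot(inherits(params, "plasma_params"))
  if (any(times < 0) || any(diff(times) <= 0)) {
    abort("`times` must be non-negative and strictly increasing.")
  }
  M <- .plasma_matrix(params)
  if (any(!is.finite(M))) abort("Non-finite plasma rate matrix.")
  seg <- .dose_segments(doses, max(times))
  A <- .lin_const_solve(M, seg$breaks, seg$rates, times)
  tac("plasma", times, pmax(A[1, ] / params$Vc, 0))
}

#' Tariquidar effect schedule D(t)
#'
#' Computes the multiplicative inhibitor effect `D` acting on the targeted
#' transport clearance. `D = 1` before any tariquidar administration;
#' `D = Eff_tariquidar(dose)` from the start of administration to the end of
#' scan 1; `D = Eff_tariquidar(dose) * Eff_scan` throughout the
#' post-inhibition scan (scan 2).
#'
#' @param events data frame of tariquidar events with columns `dose_group`
#'   (mg/kg), `start`, `duration` (min, within scan 1); `NULL` or zero rows
#'   means untreated.
#' @param scan_index 1 (baseline) or 2 (post-inhibition).
#' @param t time(s) within the scan, min.
#' @param effs a [covariate_effects()] object.
#' @return Numeric vector of `D` values, same length as `t`.
#' @examples
#' effs <- covariate_effects(Eff_tariquidar = c("3" = 0.161), Eff_scan = 1.33)
#' ev <- data.frame(dose_group = 3, start = 60, duration = 1)
#' effect_D(ev, scan_index = 1, t = c(30, 90), effs = effs)
#' @export
effect_D <- function(events, scan_index, t, effs) {
  stopifnot(inherits(effs, "covariate_effects"), scan_index %in% c(1L, 2L))
  if (is.null(events) || nrow(events) == 0L) return(rep(1, length(t)))
  key <- as.character(events$dose_group[1])
  if (!key %in% names(effs$Eff_tariquidar)) {
    abort(sprintf("No Eff_tariquidar configured for dose group %s mg/kg.", key))
  }
  eff <- unname(effs$Eff_tariquidar[[key]])
  if (scan_index == 2L) return(rep(eff * effs$Eff_scan, length(t)))
  ifelse(t >= events$start[1], eff, 1)
}

#' Simulate the brain model
#'
#' Exact forward simulation of the two-compartment brain model driven by a
#' plasma forcing curve. Amount-form dynamics are used (the published
#' concentration-form equations are dimensionally inconsistent; the amount
#' form preserves their steady-state brain-to-plasma ratio `Qin/(D*Qout)`):
#' \deqn{dA_{br1}/dt = m_{in} Q_{in} C_c(t) - m_{out} Q_{out} C_{br1} -
#'   Q_{br} (C_{br1} - C_{br2})}
#' \deqn{dA_{br2}/dt = Q_{br} (C_{br1} - C_{br2})}
#' with \eqn{C_x = A_x/V_x} and `(m_in, m_out) = (D, 1)` for placement
#' `"on_Qin"` or `(1, D)` for `"on_Qout"`. The plasma forcing is interpolated
#' linearly between its samples and the linear system is propagated exactly
#' (eigenbasis, closed-form response to linear-in-time forcing) across each
#' forcing segment. The observed concentration is
#' `(A_br1 + A_br2) / (Vbr1 + Vbr2)`, which makes the equilibrium
#' brain-to-plasma ratio equal `Qin/(D*Qout)` exactly.
#'
#' @param bp a [brain_params()] object (`Vbr1` already at its individual
#'   value, i.e. any disease-group effect applied).
#' @param effs a [covariate_effects()] object (supplies `D` and placement).
#' @param plasma plasma forcing as a [tac()] tibble in kBq/ml; must span
#'   `[0, max(times)]`.
#' @param events tariquidar events as in [effect_D()].
#' @param scan_index scan number, 1 or 2.
#' @param times output times (min), strictly increasing.
#' @param label output TAC label.
#' @return A [tac()] tibble of regional brain concentration (kBq/ml).
#' @export
simulate_brain <- function(bp, effs, plasma, events, scan_index, times,
                           label = "brain") {
  stopifnot(inherits(bp, "brain_params"), inherits(effs, "covariate_effects"))
  ft <- plasma$time_min
  fv <- plasma$value
  if (min(ft) > 0 || max(ft) < max(times) - 1e-9) {
    abort("Plasma forcing must be defined on [0, max(times)].")
  }
  grid <- sort(unique(c(ft, times)))
  if (scan_index == 1L && !is.null(events) && nrow(events) > 0L) {
    grid <- sort(unique(c(grid, events$start[1])))
  }
  grid <- grid[grid <= max(times) + 1e-12]
  cc <- approx(ft, fv, xout = grid, rule = 2)$y
  Dmid <- effect_D(events, scan_index,
                   (grid[-1] + grid[-length(grid)]) / 2, effs)
  A <- .brain_propagate(bp, effs$placement, grid, cc, Dmid)
  conc <- (A[1, ] + A[2, ]) / (bp$Vbr1 + bp$Vbr2)
  keep <- match(times, grid)
  tac(label, times, pmax(conc[keep], 0))
}

# Propagate the 2x2 brain system across forcing grid nodes (compiled core).
# grid: length m; cc: forcing at nodes; Dseg: D per segment (length m-1).
# Returns 2 x m amounts, A(grid[1]) = 0 (grid[1] is the scan start).
.brain_propagate <- function(bp, placement, grid, cc, Dseg) {
  .brain_propagate_cpp(bp$Vbr1, bp$Vbr2, bp$Qin, bp$Qout, bp$Qbr,
                       as.integer(placement == "on_Qin"),
                       as.numeric(grid), as.numeric(cc), as.numeric(Dseg))
}

# closed-form eigendecomposition of [[a, b], [c, d]] (real spectrum for
# compartmental matrices: b, c >= 0)
.eigen2 <- function(a, b, c, d) {
  disc <- sqrt(max(((a - d) / 2)^2 + b * c, 0))
  if (disc < 1e-12 * max(abs(c(a, b, c, d)), 1)) disc <- disc + 1e-12
  lam <- c((a + d) / 2 + disc, (a + d) / 2 - disc)
  if (abs(b) > 1e-300) {
    P <- matrix(c(b, lam[1] - a, b, lam[2] - a), 2, 2)
  } else if (abs(c) > 1e-300) {
    P <- matrix(c(lam[1] - d, c, lam[2] - d, c), 2, 2)
  } else {
    P <- diag(2)
    lam <- c(a, d)
  }
  det <- P[1, 1] * P[2, 2] - P[1, 2] * P[2, 1]
  Pinv <- matrix(c(P[2, 2], -P[2, 1], -P[1, 2], P[1, 1]), 2, 2) / det
  list(P = P, Pinv = Pinv, lam = lam)
}

#' Lognormal individual parameter model
#'
#' Individual parameter as a lognormal deviation from the population typical
#' value: `theta_i = theta_pop * exp(eta_i)`, with `eta_i ~ N(0, omega^2)`.
#'
#' @param theta_pop population typical value (> 0).
#' @param eta individual random effect(s).
#' @return `theta_pop * exp(eta)`.
#' @export
individual_from_population <- function(theta_pop, eta) {
  check_positive_scalar(theta_pop, "theta_pop")
  theta_pop * exp(eta)
}

#' Disease-group covariate on the central brain volume
#'
#' Applies the status-epilepticus effect to the population central brain
#' distribution volume: control animals keep `Vbr1_pop`; post-SE animals get
#' `Vbr1_pop * Eff_SE`.
#'
#' @param Vbr1_pop population value, ml (> 0).
#' @param Eff_SE multiplicative effect (> 0).
#' @param group `"control"` or `"post_SE"`.
#' @return Individual `Vbr1`, ml.
#' @export
apply_se_covariate <- function(Vbr1_pop, Eff_SE, group = c("control", "post_SE")) {
  group <- match.arg(group)
  check_positive_scalar(Vbr1_pop, "Vbr1_pop")
  check_positive_scalar(Eff_SE, "Eff_SE")
  if (group == "control") Vbr1_pop else Vbr1_pop * Eff_SE
}

#' Standardized uptake value normalization
#'
#' Normalizes an activity-concentration TAC to injected activity per body
#' weight: `SUV(t) = C(t) * body_weight / injected`.
#'
#' @param x a [tac()] tibble in kBq/ml.
#' @param injected injected activity, kBq (> 0).
#' @param body_weight body weight, g (> 0).
#' @return The TAC with `value` in SUV and `unit = "SUV"`.
#' @export
suv_normalize <- function(x, injected, body_weight) {
  check_positive_scalar(injected, "injected")
  check_positive_scalar(body_weight, "body_weight")
  if (!all(x$unit == "kBq_per_ml")) {
    abort("TAC is not in kBq_per_ml; refusing to re-normalize.")
  }
  dplyr::mutate(x, value = .data$value * body_weight / injected, unit = "SUV")
}
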