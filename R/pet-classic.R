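#' Convert whole-blood activity to plasma activity
#'
#' Pointwise multiplication of a whole-blood TAC by the (constant) plasma-to-
#' blood concentration ratio (1.29 for (R)-[11C]verapamil, see
#' [verapamil_plasma_blood_ratio()]); the label is set to `"plasma"`.
#'
#' @param blood_tac a [tac()] tibble of whole-blood activity.
#' @param ratio plasma-to-blood ratio (> 0).
#' @return A plasma [tac()] tibble.
#' @export
plasma_from_blood <- function(blood_tac, ratio = verapamil_plasma_blood_ratio()) {
  check_positive_scalar(ratio, "ratio")
  dplyr::mutate(blood_tac, value = .data$value * ratio, label = "plasma")
}

# tissue curve of the 2T4K model by exact propagation of the linear system
# driven by the piecewise-linear input function
.sim_2t4k <- function(K1, k2, k3, k4, input_t, input_c, times) {
  grid <- sort(unique(c(input_t, times)))
  cc <- approx(input_t, input_c, xout = grid, rule = 2)$y
  bp <- list(K1 = K1)
  m <- length(grid)
  C <- matrix(0, 2, m)
  eg <- .eigen2(-(k2 + k3), k4, k3, -k4)
  z <- c(0, 0)
  for (s in seq_len(m - 1L)) {
    h <- grid[s + 1L] - grid[s]
    alpha <- eg$Pinv[, 1] * (K1 * cc[s])
    gamma <- eg$Pinv[, 1] * (K1 * (cc[s + 1L] - cc[s]) / h)
    z <- exp(eg$lam * h) * z + alpha * .phi1(eg$lam, h) + gamma * .phi2(eg$lam, h)
    C[, s + 1L] <- Re(eg$P %*% z)
  }
  colSums(C)[match(times, grid)]
}

.apply_exclusion <- function(times, exclusion_window) {
  if (is.null(exclusion_window)) return(rep(TRUE, length(times)))
  stopifnot(length(exclusion_window) == 2L)
  !(times >= exclusion_window[1] & times <= exclusion_window[2])
}

#' Single-subject two-tissue compartment (2T4K) fit
#'
#' Least-squares fit of the standard two-tissue, four-rate-constant PET
#' model to a regional TAC given a metabolite-corrected plasma input
#' function: `dC1/dt = K1*Cp - (k2 + k3)*C1 + k4*C2`,
#' `dC2/dt = k3*C1 - k4*C2`, tissue signal `C1 + C2`. Frames inside
#' `exclusion_window` (the during/post-inhibitor segment, per the reference
#' practice) are dropped before fitting. Uniform frame weights. The total
#' volume of distribution is `VT = K1/k2 * (1 + k3/k4)`.
#'
#' @param x regional [tac()] tibble.
#' @param input_function plasma input [tac()] tibble covering the TAC
#'   support.
#' @param exclusion_window optional `c(start, end)` in min; frames inside
#'   are excluded.
#' @param start optional named starting values (`K1`, `k2`, `k3`, `k4`).
#' @return A list of class `fit_2t4k`: `K1`, `k2`, `k3`, `k4`, `VT_2T4K`,
#'   `rss`, `n_frames`, `converged`.
#' @export
fit_2t4k <- function(x, input_function, exclusion_window = NULL,
                     start = NULL) {
  keep <- .apply_exclusion(x$time_min, exclusion_window)
  times <- x$time_min[keep]
  y <- x$value[keep]
  if (length(times) < 8L) {
    abort("Fewer than 8 frames retained for the 2T4K fit.")
  }
  if (min(input_function$time_min) > min(times) ||
      max(input_function$time_min) < max(times) - 1e-9) {
    abort("Input function does not cover the TAC support.")
  }
  it <- input_function$time_min
  ic <- input_function$value
  st <- c(K1 = 0.3, k2 = 0.3, k3 = 0.05, k4 = 0.05)
  st[names(start)] <- start
  ssq <- function(lp) {
    p <- exp(lp)
    pred <- .sim_2t4k(p[1], p[2], p[3], p[4], it, ic, times)
    if (any(!is.finite(pred))) return(1e12)
    sum((y - pred)^2)
  }
  opt <- nlminb(log(st), ssq, lower = -20, upper = 10,
                control = list(rel.tol = 1e-12, iter.max = 500))
  p <- exp(opt$par)
  names(p) <- c("K1", "k2", "k3", "k4")
  vt <- unname(p["K1"] / p["k2"] * (1 + p["k3"] / p["k4"]))
  structure(list(K1 = unname(p["K1"]), k2 = unname(p["k2"]),
                 k3 = unname(p["k3"]), k4 = unname(p["k4"]),
                 VT_2T4K = vt, rss = opt$objective, n_frames = length(times),
                 converged = opt$convergence == 0),
            class = "fit_2t4k")
}

#' Logan graphical analysis
#'
#' Model-independent estimate of the total volume of distribution: ordinary
#' least squares of \eqn{\int_0^t C_T / C_T(t)} against
#' \eqn{\int_0^t C_p / C_T(t)} over late frames (`t >= t_star`), slope
#' reported as `VT_Logan`. Integrals are trapezoidal on frame midpoints
#' (curves taken as 0 at time 0). Frames inside `exclusion_window` are
#' dropped. If `t_star` is `NULL` it defaults to the earliest time after
#' which the regression over the retained points has R^2 >= 0.99.
#'
#' @param x regional [tac()] tibble.
#' @param input_function plasma input [tac()] tibble on the same time
#'   support (integrated on its own grid).
#' @param t_star start of the linear segment, min, or `NULL` to choose
#'   automatically.
#' @param exclusion_window optional `c(start, end)` exclusion interval.
#' @return A list of class `logan_fit`: `VT_Logan` (slope), `intercept`,
#'   `t_star`, `r_squared`, `n_points`.
#' @export
logan_vt <- function(x, input_function, t_star = NULL,
                     exclusion_window = NULL) {
  ct_t <- x$time_min
  ct <- x$value
  # both integrals by trapezoid on the frame midpoints (input resampled to
  # the frame grid), so proportional curves give the slope identity exactly
  cp <- approx(input_function$time_min, input_function$value, xout = ct_t,
               rule = 2)$y
  cum_ct <- .cumtrapz0(ct_t, ct)
  cum_cp <- .cumtrapz0(ct_t, cp)
  ok <- .apply_exclusion(ct_t, exclusion_window) & ct > 0
  xs <- cum_cp / ct
  ys <- cum_ct / ct
  fit_from <- function(ts) {
    use <- ok & ct_t >= ts
    if (sum(use) < 3L) return(NULL)
    m <- lm(ys[use] ~ xs[use])
    r2 <- suppressWarnings(summary(m)$r.squared)  # exact fits warn
    list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
         r2 = r2, n = sum(use))
  }
  if (is.null(t_star)) {
    cand <- sort(ct_t[ok])
    cand <- cand[seq_len(max(length(cand) - 2L, 1L))]
    t_star <- cand[1]
    for (ts in cand) {
      res <- fit_from(ts)
      if (!is.null(res) && is.finite(res$r2) && res$r2 >= 0.99) {
        t_star <- ts
        break
      }
      t_star <- ts
    }
  }
  res <- fit_from(t_star)
  if (is.null(res)) {
    abort("Fewer than 3 frames at t >= t_star outside the exclusion window.")
  }
  structure(list(VT_Logan = res$slope, intercept = res$intercept,
                 t_star = t_star, r_squared = res$r2, n_points = res$n),
            class = "logan_fit")
}

# cumulative trapezoid with an implicit (0, 0) origin
.cumtrapz0 <- function(t, v) {
  tt <- c(0, t)
  vv <- c(0, v)
  cumsum(c(0, diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2))[-1]
}

#' Batch classic PET analysis of a dataset
#'
#' Runs the single-subject reference analyses (2T4K fit and Logan analysis)
#' for every subject and scan of a long-format dataset, using each subject's
#' plasma records as input function and excluding, in scan 1, the frames
#' acquired during and after tariquidar administration (the reference
#' practice: the inhibitor breaks the steady state those methods assume).
#'
#' @param data a `pk_dataset`.
#' @param t_star passed to [logan_vt()].
#' @return A tibble with one row per subject x scan: rate constants,
#'   `VT_2T4K`, `VT_Logan`, `t_star`.
#' @export
pet_reference_analysis <- function(data, t_star = NULL) {
  validate_pk_dataset(data)
  combos <- dplyr::distinct(data, .data$subject_id, .data$scan)
  rows <- purrr::pmap(combos, function(subject_id, scan) {
    d <- data[data$subject_id == subject_id & data$scan == scan, ]
    pl <- d[d$obs_type == "plasma", ]
    br <- d[d$obs_type == "brain", ]
    pl <- pl[order(pl$time_min), ]
    br <- br[order(br$time_min), ]
    excl <- if (scan == 1 && any(!is.na(d$tq_start_min))) {
      c(d$tq_start_min[!is.na(d$tq_start_min)][1], max(br$time_min))
    }
    input <- tac("plasma", pl$time_min, pmax(pl$value, 0))
    reg <- tac(br$region[1] %||% "brain", br$time_min, pmax(br$value, 0))
    f2 <- tryCatch(fit_2t4k(reg, input, exclusion_window = excl),
                   error = function(e) NULL)
    fl <- tryCatch(logan_vt(reg, input, t_star = t_star,
                            exclusion_window = excl),
                   error = function(e) NULL)
    tibble::tibble(
      subject_id = subject_id, scan = scan,
      region = br$region[1] %||% "brain",
      K1 = f2$K1 %||% NA_real_, k2 = f2$k2 %||% NA_real_,
      k3 = f2$k3 %||% NA_real_, k4 = f2$k4 %||% NA_real_,
      VT_2T4K = f2$VT_2T4K %||% NA_real_,
      VT_Logan = fl$VT_Logan %||% NA_real_,
      t_star = fl$t_star %||% NA_real_)
  })
  dplyr::bind_rows(rows)
}
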