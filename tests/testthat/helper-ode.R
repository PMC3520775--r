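# Independent numerical ODE oracle: adaptive Dormand-Prince RK5(4).
# Used only by tests to cross-check the package's exact linear-system
# propagation; deliberately shares no code with the implementation.

rk45_segment <- function(deriv, y0, t0, t1, rtol = 1e-9, atol = 1e-12) {
  # Dormand-Prince coefficients
  a <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(44 / 45, -56 / 15, 32 / 9),
    c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
    c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
    c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
  c_nodes <- c(1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  t <- t0
  y <- y0
  h <- max((t1 - t0) / 50, 1e-8)
  k1 <- deriv(t, y)
  while (t < t1 - 1e-14) {
    h <- min(h, t1 - t)
    ks <- matrix(0, length(y), 7)
    ks[, 1] <- k1
    for (i in 1:6) {
      yi <- y + h * as.vector(ks[, seq_len(i), drop = FALSE] %*% a[[i]])
      ks[, i + 1] <- deriv(t + c_nodes[i] * h, yi)
    }
    y5 <- y + h * as.vector(ks %*% b5)
    y4 <- y + h * as.vector(ks %*% b4)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (err <= 1) {
      t <- t + h
      y <- y5
      k1 <- ks[, 7]  # FSAL
      h <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
    } else {
      h <- h * max(0.1, 0.9 * err^(-0.2))
    }
    if (h < 1e-13) stop("rk45: step size underflow")
  }
  y
}

# integrate across the given breakpoints (right-hand side smooth within each
# segment); returns the state at every breakpoint, y(breaks[1]) = y0
rk45_path <- function(deriv, y0, breaks, rtol = 1e-9, atol = 1e-12) {
  out <- matrix(0, length(y0), length(breaks))
  out[, 1] <- y0
  y <- y0
  for (i in seq_len(length(breaks) - 1L)) {
    y <- rk45_segment(deriv, y, breaks[i], breaks[i + 1L], rtol, atol)
    out[, i + 1L] <- y
  }
  out
}

# oracle for the three-compartment plasma model: central concentration at
# `times` under a single zero-order infusion (amount over [0, dur])
ode_plasma_oracle <- function(p, amount, dur, times, rtol = 1e-10) {
  M <- rbind(
    c(-(p$CL + p$Q1 + p$Q2) / p$Vc, p$Q1 / p$Vp1, p$Q2 / p$Vp2),
    c(p$Q1 / p$Vc, -p$Q1 / p$Vp1, 0),
    c(p$Q2 / p$Vc, 0, -p$Q2 / p$Vp2))
  rate <- amount / dur
  breaks <- sort(unique(c(0, dur, times)))
  deriv_on <- function(t, y) as.vector(M %*% y) + c(rate, 0, 0)
  deriv_off <- function(t, y) as.vector(M %*% y)
  b1 <- breaks[breaks <= dur + 1e-15]
  b2 <- breaks[breaks >= dur - 1e-15]
  y_on <- rk45_path(deriv_on, c(0, 0, 0), b1, rtol = rtol)
  y_all <- cbind(y_on, rk45_path(deriv_off, y_on[, ncol(y_on)], b2,
                                 rtol = rtol)[, -1, drop = FALSE])
  t_all <- c(b1, b2[-1])
  y_all[1, match(times, t_all)] / p$Vc
}

# oracle for the two-compartment brain model driven by the SAME
# piecewise-linear plasma forcing as the implementation (forcing_t/forcing_c)
# and a step inhibitor effect D(t)
ode_brain_oracle <- function(bp, placement, forcing_t, forcing_c, D_of_t,
                             times, rtol = 1e-10) {
  m_in <- function(t) if (placement == "on_Qin") D_of_t(t) else 1
  m_out <- function(t) if (placement == "on_Qout") D_of_t(t) else 1
  cc <- approxfun(forcing_t, forcing_c, rule = 2)
  deriv <- function(t, y) {
    c1 <- y[1] / bp$Vbr1
    c2 <- y[2] / bp$Vbr2
    c(m_in(t) * bp$Qin * cc(t) - m_out(t) * bp$Qout * c1 -
        bp$Qbr * (c1 - c2),
      bp$Qbr * (c1 - c2))
  }
  breaks <- sort(unique(c(forcing_t, times)))
  breaks <- breaks[breaks <= max(times) + 1e-12]
  y <- rk45_path(deriv, c(0, 0), breaks, rtol = rtol)
  (y[1, match(times, breaks)] + y[2, match(times, breaks)]) /
    (bp$Vbr1 + bp$Vbr2)
}
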