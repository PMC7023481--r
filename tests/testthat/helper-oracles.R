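# Independent numerical oracles used across the suite. These re-derive
# the model equations from scratch (plain R, fixed-step integration or
# closed forms) and never call the package's solver paths.

# Generic fixed-step classical RK4.
rk4_integrate <- function(f, y0, t0, t1, dt) {
  n_steps <- round((t1 - t0) / dt)
  stopifnot(abs(n_steps * dt - (t1 - t0)) < 1e-9)
  y <- y0
  t <- t0
  for (i in seq_len(n_steps)) {
    k1 <- f(t, y)
    k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2)
    k4 <- f(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t0 + i * dt
  }
  y
}

# Hand-written six-state RHS (pH-aware variant), independent of the
# package's compiled code: solubility via Henderson-Hasselbalch of the
# linearly interpolated pH series.
oracle_gis_rhs <- function(params, phys, solubility) {
  hh <- function(pH) {
    s <- solubility$s0 * (1 + 10^(pH - solubility$pka))
    if (!is.null(solubility$cap)) s <- min(s, solubility$s0 * solubility$cap)
    s
  }
  interp <- function(series, t) {
    stats::approx(series$time_h, series$pH, xout = t, rule = 2)$y
  }
  function(t, y) {
    cs_d <- hh(interp(phys$pH_duodenum, t))
    cs_j <- hh(interp(phys$pH_jejunum, t))
    r_d <- params$K_Diss * y[2] * max(0, cs_d - y[3] / phys$V1)
    r_j <- params$K_Diss * y[4] * max(0, cs_j - y[5] / phys$V2)
    c(-params$Kempt * y[1],
      params$Kempt * y[1] - params$K_TD * y[2] - r_d,
      r_d - params$Ka * y[3],
      params$K_TD * y[2] - params$K_TJ * y[4] - r_j,
      r_j - params$Ka * y[5],
      params$Ka * (y[3] + y[5]) - phys$Kel * y[6],
      phys$Kel * y[6],
      params$K_TJ * y[4])
  }
}

# RK4 solution of the pH-aware model at requested output times,
# handling the phase-III bolus by splitting at TMMC.
oracle_gis_rk4 <- function(params, phys, dose, t_grid, solubility,
                           dt = 1e-3) {
  f <- rk4_integrate
  rhs <- oracle_gis_rhs(params, phys, solubility)
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = 8)
  y <- c(dose, 0, 0, 0, 0, 0, 0, 0)
  t_cur <- 0
  event_done <- phys$TMMC > max(t_grid)
  for (i in seq_along(t_grid)) {
    tt <- t_grid[i]
    if (!event_done && tt >= phys$TMMC) {
      y <- f(rhs, y, t_cur, phys$TMMC, dt)
      y[2] <- y[2] + y[1]
      y[1] <- 0
      t_cur <- phys$TMMC
      event_done <- TRUE
    }
    if (tt > t_cur) {
      y <- f(rhs, y, t_cur, tt, dt)
      t_cur <- tt
    }
    out[i, ] <- y
  }
  colnames(out) <- c("M_stomach_solid", "M_duodenum_solid",
                     "M_duodenum_dissolved", "M_jejunum_solid",
                     "M_jejunum_dissolved", "M_plasma",
                     "cumulative_eliminated", "cumulative_distal_transit")
  out
}

# Bateman (first-order absorption, one-compartment disposition).
bateman_conc <- function(t, dose, ka, kel, V) {
  dose * ka / (V * (ka - kel)) * (exp(-kel * t) - exp(-ka * t))
}

# Two-compartment constant-rate infusion by plain lsoda on an R-coded
# RHS (independent of the package's eigendecomposition solution).
oracle_2cpt_infusion <- function(K10, K12, K21, Vc, dose, tinf, times) {
  rhs <- function(t, y, p) {
    inp <- if (t <= tinf) dose / tinf else 0
    list(c(inp - (K10 + K12) * y[1] + K21 * y[2],
           K12 * y[1] - K21 * y[2]))
  }
  tt <- sort(unique(c(0, tinf, times)))
  out <- deSolve::lsoda(c(0, 0), tt, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  stats::approx(out[, 1], out[, 2], xout = times)$y / Vc
}

# Two-compartment bolus central amounts via eigen-free 2x2 closed form.
oracle_2cpt_bolus_conc <- function(K10, K12, K21, Vc, dose, times) {
  a <- K10 + K12 + K21
  disc <- sqrt(a^2 - 4 * K10 * K21)
  l1 <- (a + disc) / 2
  l2 <- (a - disc) / 2
  A <- dose * (l1 - K21) / (l1 - l2)
  B <- dose * (K21 - l2) / (l1 - l2)
  (A * exp(-l1 * times) + B * exp(-l2 * times)) / Vc
}

# Reference subject used in several tests: flat-ish pH, median-like
# parameters.
make_ref_subject <- function(tmmc = 2.04, wiggly = FALSE) {
  if (wiggly) {
    set.seed(42)
    tt <- seq(0, 7, by = 0.25)
    ph_d <- data.frame(time_h = tt,
                       pH = pmin(7, pmax(5, 6 + cumsum(rnorm(length(tt), 0, 0.1)))))
    ph_j <- data.frame(time_h = tt,
                       pH = pmin(7.5, pmax(5.5, 6.6 + cumsum(rnorm(length(tt), 0, 0.1)))))
  } else {
    ph_d <- data.frame(time_h = c(0, 7), pH = c(6.0, 6.0))
    ph_j <- data.frame(time_h = c(0, 7), pH = c(6.6, 6.6))
  }
  subject_physiology(TMMC = tmmc, pH_duodenum = ph_d, pH_jejunum = ph_j,
                     V1 = 123.24, V2 = 49.99, Kel = 0.35, V3 = 1e4)
}

ref_params <- function() {
  gis_parameters(Kempt = 0.18, K_TD = 0.47, K_TJ = 0.081, K_Diss = 1.52e-3)
}

# Wilcoxon AUC of scores against binary labels.
rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
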