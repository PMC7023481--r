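acat_compartments <- c("stomach", "duodenum", "jejunum1", "jejunum2",
                       "ileum1", "ileum2", "ileum3", "caecum", "asc_colon")

# Effective absorptive radii (cm) per compartment; the stomach is
# excluded from absorption. Documented configuration of the simulator,
# in the range of adult fasted-state lumen radii.
acat_default_radii_cm <- c(stomach = NA, duodenum = 1.53, jejunum1 = 1.45,
                           jejunum2 = 1.29, ileum1 = 1.12, ileum2 = 0.98,
                           ileum3 = 0.82, caecum = 3.39, asc_colon = 2.41)

#' Time-stamped volume/pH schedule of one GI compartment
#'
#' Each compartment of the absorption-and-transit simulator carries a
#' fluid volume and pH that are either static (a single entry) or
#' time-varying (multiple entries applied by step-hold interpolation:
#' the most recent entry at or before `t` is in force).
#'
#' @param compartment one of `r paste(acat_compartments, collapse=", ")`.
#' @param entries data.frame with columns `time_h`, `volume_ml` (> 0),
#'   `pH`; time-sorted. One row makes the schedule static.
#' @param transit_time mean transit time of the compartment, h (> 0).
#' @return an object of class `compartment_schedule`.
#' @export
compartment_schedule <- function(compartment, entries, transit_time) {
  if (!compartment %in% acat_compartments) {
    stop("unknown compartment: ", compartment)
  }
  stopifnot(is.data.frame(entries),
            all(c("time_h", "volume_ml", "pH") %in% names(entries)),
            nrow(entries) >= 1L)
  if (is.unsorted(entries$time_h, strictly = FALSE)) {
    stop("schedule entries must be time-sorted")
  }
  if (any(entries$volume_ml <= 0)) stop("volumes must be > 0")
  if (!is.numeric(transit_time) || transit_time <= 0) {
    stop("`transit_time` must be > 0")
  }
  structure(list(compartment = compartment,
                 entries = entries[, c("time_h", "volume_ml", "pH")],
                 transit_time = transit_time,
                 static = nrow(entries) == 1L),
            class = "compartment_schedule")
}

# step-hold lookup
schedule_value_at <- function(sched, t) {
  e <- sched$entries
  i <- findInterval(t, e$time_h)
  i[i < 1L] <- 1L
  list(volume_ml = e$volume_ml[i], pH = e$pH[i])
}

#' Default static compartment schedules
#'
#' The standard fasted-state static configuration of the nine-compartment
#' simulator: one volume and pH per compartment plus its transit time
#' (stomach 48.92 mL at pH 1.3, 0.25 h; duodenum 44.57 mL at pH 6,
#' 0.26 h; and so on down to the ascending colon). Returned as a list of
#' nine [compartment_schedule()] objects.
#'
#' @param gastric_transit stomach transit time, h (default 0.25).
#' @return named list of nine `compartment_schedule`s.
#' @export
default_acat_schedules <- function(gastric_transit = 0.25) {
  tab <- acat_default_table()
  tab$transit_time_h[tab$compartment == "stomach"] <- gastric_transit
  sched <- lapply(seq_len(nrow(tab)), function(i) {
    compartment_schedule(
      tab$compartment[i],
      data.frame(time_h = 0, volume_ml = tab$volume_ml[i], pH = tab$pH[i]),
      tab$transit_time_h[i]
    )
  })
  names(sched) <- tab$compartment
  sched
}

#' Default compartment table of the simulator
#'
#' @return data.frame with columns `compartment`, `volume_ml`, `pH`,
#'   `transit_time_h`.
#' @export
acat_default_table <- function() {
  path <- system.file("extdata", "acat_default_schedule.csv",
                      package = "pbbm", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Drug card for the absorption-and-transit simulator
#'
#' @param dose dose, ug.
#' @param peff_cm_s human effective jejunal permeability, cm/s.
#' @param particle_radius_um initial particle radius of the monodisperse
#'   powder, um.
#' @param density_g_ml true density of the solid, g/mL.
#' @param diffusion_cm2_s aqueous diffusion coefficient, cm^2/s.
#' @param solubility an [acid_solubility_profile()].
#' @return an object of class `acat_drug`.
#' @export
acat_drug <- function(dose, peff_cm_s, particle_radius_um, density_g_ml,
                      diffusion_cm2_s, solubility) {
  vals <- c(dose, peff_cm_s, particle_radius_um, density_g_ml,
            diffusion_cm2_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all drug parameters must be positive and finite")
  }
  stopifnot(inherits(solubility, "acid_solubility_profile"))
  structure(list(dose = dose, peff_cm_s = peff_cm_s,
                 particle_radius_um = particle_radius_um,
                 density_g_ml = density_g_ml,
                 diffusion_cm2_s = diffusion_cm2_s,
                 solubility = solubility),
            class = "acat_drug")
}

#' Ibuprofen drug card
#'
#' The worked-system inputs: 800 mg dose, effective permeability
#' 4.1e-4 cm/s, particle radius 62 um, solubility anchored at
#' 1.99 mg/mL (pH 6.2) with pKa 4.54. True density and aqueous
#' diffusivity are not independently reported and default to values
#' typical of a small-molecule organic acid.
#'
#' @param dose dose in ug (default 8e5, i.e. 800 mg).
#' @return an [acat_drug()].
#' @export
ibuprofen_drug_card <- function(dose = 8e5) {
  acat_drug(dose = dose, peff_cm_s = 4.1e-4, particle_radius_um = 62,
            density_g_ml = 1.2, diffusion_cm2_s = 7.5e-6,
            solubility = ibuprofen_solubility_profile())
}

#' Two-compartment disposition constants of ibuprofen
#'
#' Micro-constants obtained from intravenous 800 mg infusion data:
#' K10 1.16/h, K12 4.55/h, K21 3.46/h, clearance 4.05 L/h (hence
#' Vc = CL/K10 = 3491 mL), infusion duration 0.1 h.
#'
#' @return a [mammillary_pk()].
#' @export
ibuprofen_iv_pk <- function() {
  mammillary_pk(2, K10 = 1.16, K12 = 4.55, K21 = 3.46,
                Vc = 4.05e3 / 1.16, infusion_duration = 0.1)
}

# ODE right-hand side of the ACAT-like model. State vector:
# Ms[1..9], Md[1..9], Ac, Ap, cum_absorbed, cum_eliminated,
# cum_exit_solid, cum_exit_dissolved, cum_dissolved
# Volume, pH and hence saturation solubility are step-hold constants
# within an integration segment and are supplied in `p`.
acat_rhs <- function(t, y, p) {
  Ms <- y[1:9]
  Md <- y[10:18]
  Ac <- y[19]
  Ap <- y[20]
  conc <- Md / p$vol
  # shrinking monodisperse spheres: radius from total remaining solid,
  # floored at 1% of the initial radius (a Lipschitz guard; below it the
  # remaining solid is < 1e-6 of the dose and dissolves immediately)
  frac_solid <- max(max(sum(Ms), 0) / p$dose, 1e-6)
  r_cm <- p$r0_cm * frac_solid^(1 / 3)
  h_eff <- min(r_cm, p$h_max_cm)
  z <- 3 * p$D_cm2_h / (p$rho_ug_ml * r_cm * h_eff)  # mL/(ug h)
  diss <- z * pmax(Ms, 0) * pmax(p$cs - conc, 0)
  kt <- p$k_transit
  out_s <- kt * Ms
  out_d <- kt * Md
  in_s <- c(0, out_s[1:8])
  in_d <- c(0, out_d[1:8])
  absn <- p$k_abs * Md
  dMs <- in_s - out_s - diss
  dMd <- in_d - out_d + diss - absn
  dAc <- sum(absn) - (p$K10 + p$K12) * Ac + p$K21 * Ap
  dAp <- p$K12 * Ac - p$K21 * Ap
  list(c(dMs, dMd, dAc, dAp,
         sum(absn), p$K10 * Ac, out_s[9L], out_d[9L], sum(diss)))
}

#' Simulate the nine-compartment absorption-and-transit model
#'
#' A chain of well-stirred GI compartments (stomach, duodenum, two
#' jejunal, three ileal, caecum, ascending colon) with linear transfer
#' of both solid and dissolved drug at rate `1/transit_time` per
#' compartment, per-compartment dissolution of shrinking monodisperse
#' spheres (Nernst-Brunner: `dM/dt = 3 D M_solid / (rho r(t) h_eff) *
#' (Cs(pH_n) - C_n)`, `h_eff = min(r, 30 um)`, particle radius computed
#' from the total remaining solid mass), absorption from solution at
#' `k_abs = 2 Peff / R_n` in every compartment except the stomach, and
#' two-compartment systemic disposition. Volume and pH follow the
#' compartment schedules by step-hold interpolation; the integration is
#' restarted at every schedule breakpoint so the solver never steps
#' across a discontinuity. Changing a compartment volume re-equilibrates
#' the concentration but moves no mass; only transit flows move drug.
#' Absorbed drug reaches the portal vein and the systemic circulation
#' identically (no first-pass loss is modeled).
#'
#' @param drug an [acat_drug()].
#' @param schedules named list of nine [compartment_schedule()]s (e.g.
#'   [default_acat_schedules()]).
#' @param gastric_transit optional stomach transit time override, h.
#' @param pk a [mammillary_pk()] with 2 compartments.
#' @param t_end simulation horizon, h (default 24).
#' @param dt output resolution, h (default 0.02).
#' @param radii_cm named vector of absorptive radii per compartment, cm.
#' @param rtol,atol integrator tolerances.
#' @return an object of class `acat_result`: list with `trajectory`
#'   (data.frame: time plus all states, plasma concentration, cumulative
#'   percentages), `pct_dissolved`, `pct_absorbed`, `pct_portal_vein`,
#'   `pct_systemic` (at `t_end`), `Cmax`, `Tmax`, `AUC_0_t`, and
#'   `mass_balance_error`.
#' @export
simulate_acat <- function(drug, schedules, gastric_transit = NULL,
                          pk, t_end = 24, dt = 0.02,
                          radii_cm = acat_default_radii_cm,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(drug, "acat_drug"), inherits(pk, "mammillary_pk"))
  if (pk$n_compartments != 2L) {
    stop("the simulator uses two-compartment disposition")
  }
  missing <- setdiff(acat_compartments, names(schedules))
  if (length(missing)) {
    stop("missing compartment schedule(s): ", paste(missing, collapse = ", "))
  }
  schedules <- schedules[acat_compartments]
  ok <- vapply(schedules, inherits, TRUE, "compartment_schedule")
  if (!all(ok)) stop("`schedules` must be compartment_schedule objects")
  if (!is.null(gastric_transit)) {
    if (gastric_transit <= 0) stop("`gastric_transit` must be > 0")
    schedules$stomach$transit_time <- gastric_transit
  }
  transit <- vapply(schedules, `[[`, 0, "transit_time")
  k_abs <- 2 * drug$peff_cm_s * 3600 / radii_cm[acat_compartments]
  k_abs["stomach"] <- 0

  p <- list(
    dose = drug$dose,
    solubility = drug$solubility,
    r0_cm = drug$particle_radius_um * 1e-4,
    h_max_cm = 30e-4,
    D_cm2_h = drug$diffusion_cm2_s * 3600,
    rho_ug_ml = drug$density_g_ml * 1e6,
    k_transit = 1 / transit,
    k_abs = unname(k_abs),
    K10 = pk$K10, K12 = pk$K12, K21 = pk$K21
  )
  state_names <- c(paste0("Ms_", acat_compartments),
                   paste0("Md_", acat_compartments),
                   "A_central", "A_peripheral", "cum_absorbed",
                   "cum_eliminated", "cum_exit_solid", "cum_exit_dissolved",
                   "cum_dissolved")
  y0 <- stats::setNames(rep(0, length(state_names)), state_names)
  y0[1L] <- drug$dose

  breaks <- sort(unique(unlist(lapply(schedules, function(s)
    s$entries$time_h))))
  breaks <- breaks[breaks > 0 & breaks < t_end]
  seg_bounds <- c(0, breaks, t_end)
  t_out <- seq(0, t_end, by = dt)

  rows <- list()
  y <- y0
  for (i in seq_len(length(seg_bounds) - 1L)) {
    a <- seg_bounds[i]; b <- seg_bounds[i + 1L]
    times <- unique(c(a, t_out[t_out > a & t_out < b], b))
    held <- lapply(schedules, schedule_value_at, t = a)
    p$vol <- vapply(held, `[[`, 0, "volume_ml")
    p$cs <- solubility_at_pH(drug$solubility,
                             vapply(held, `[[`, 0, "pH"))
    out <- deSolve::lsoda(y, times, acat_rhs, p, rtol = rtol, atol = atol,
                          maxsteps = 50000)
    if (attr(out, "istate")[1L] < 0) stop("ACAT integration failed")
    y <- out[nrow(out), -1L]
    keep <- out[, 1L] %in% t_out | out[, 1L] == t_end
    if (i > 1L) keep[1L] <- FALSE  # segment start already emitted
    rows[[i]] <- unclass(out)[keep, , drop = FALSE]
  }
  traj <- as.data.frame(do.call(rbind, rows))
  names(traj) <- c("time_h", state_names)
  traj$C_plasma <- traj$A_central / pk$Vc
  traj$pct_dissolved <- 100 * traj$cum_dissolved / drug$dose
  traj$pct_absorbed <- 100 * traj$cum_absorbed / drug$dose

  tot <- rowSums(traj[, c(paste0("Ms_", acat_compartments),
                          paste0("Md_", acat_compartments),
                          "A_central", "A_peripheral", "cum_eliminated",
                          "cum_exit_solid", "cum_exit_dissolved")])
  mbe <- max(abs(tot - drug$dose) / drug$dose)

  last <- traj[nrow(traj), ]
  structure(list(
    trajectory = traj,
    pct_dissolved = last$pct_dissolved,
    pct_absorbed = last$pct_absorbed,
    pct_portal_vein = last$pct_absorbed,
    pct_systemic = last$pct_absorbed,
    Cmax = max(traj$C_plasma),
    Tmax = traj$time_h[which.max(traj$C_plasma)],
    AUC_0_t = trapz_auc(traj$time_h, traj$C_plasma),
    mass_balance_error = mbe,
    dose = drug$dose, pk = pk
  ), class = "acat_result")
}

#' @export
print.acat_result <- function(x, ...) {
  cat(sprintf("<acat_result> %% dissolved %.1f  %% absorbed %.1f  Cmax %.4g ug/mL at %.3g h  AUC %.5g ug h/mL\n",
              x$pct_dissolved, x$pct_absorbed, x$Cmax, x$Tmax, x$AUC_0_t))
  cat(sprintf("  mass-balance error %.2g\n", x$mass_balance_error))
  invisible(x)
}

#' Parameter sensitivity of plasma Cmax to gastric transit time
#'
#' Re-simulates the absorption-and-transit model over a grid of gastric
#' (stomach) transit times and reports the plasma Cmax of each run. For
#' a rapidly dissolving, permeable acid, slower gastric emptying delays
#' intestinal delivery and lowers Cmax, so the curve is expected to be
#' monotone non-increasing.
#'
#' @param drug an [acat_drug()].
#' @param schedules compartment schedules (stomach transit overridden per
#'   grid point).
#' @param pk a two-compartment [mammillary_pk()].
#' @param transit_grid gastric transit times, h.
#' @param ... passed to [simulate_acat()].
#' @return data.frame with columns `gastric_transit_h`, `Cmax_ug_per_ml`.
#' @export
psa_gastric_transit <- function(drug, schedules, pk, transit_grid, ...) {
  stopifnot(length(transit_grid) >= 1L, all(transit_grid > 0))
  cmax <- vapply(transit_grid, function(gt) {
    simulate_acat(drug, schedules, gastric_transit = gt, pk = pk, ...)$Cmax
  }, 0)
  data.frame(gastric_transit_h = transit_grid, Cmax_ug_per_ml = cmax)
}

#' Static versus dynamic fluid-volume comparison
#'
#' Runs the simulator once with static and once with time-varying
#' volume schedules, holding the pH inputs identical between the runs,
#' and returns the aligned dissolved/undissolved trajectories together
#' with summary deltas (including percent dissolved at each run's plasma
#' Tmax).
#'
#' @param drug an [acat_drug()].
#' @param static_schedules,dynamic_schedules compartment schedule sets.
#' @param pk a two-compartment [mammillary_pk()].
#' @param ... passed to [simulate_acat()].
#' @return list with `static`, `dynamic` (both `acat_result`),
#'   `trajectories` (long data.frame: `model`, `time_h`,
#'   `amount_dissolved_ug`, `amount_undissolved_ug`), and `summary`.
#' @export
compare_fluid_models <- function(drug, static_schedules, dynamic_schedules,
                                 pk, ...) {
  res_s <- simulate_acat(drug, static_schedules, pk = pk, ...)
  res_d <- simulate_acat(drug, dynamic_schedules, pk = pk, ...)
  lumen_amounts <- function(res, label) {
    tr <- res$trajectory
    data.frame(
      model = label,
      time_h = tr$time_h,
      amount_dissolved_ug = rowSums(tr[, paste0("Md_", acat_compartments)]),
      amount_undissolved_ug = rowSums(tr[, paste0("Ms_", acat_compartments)])
    )
  }
  pct_dissolved_at <- function(res, tmax) {
    tr <- res$trajectory
    stats::approx(tr$time_h, tr$pct_dissolved, xout = tmax, rule = 2)$y
  }
  summary <- data.frame(
    model = c("static", "dynamic"),
    Cmax_ug_per_ml = c(res_s$Cmax, res_d$Cmax),
    Tmax_h = c(res_s$Tmax, res_d$Tmax),
    pct_dissolved_end = c(res_s$pct_dissolved, res_d$pct_dissolved),
    pct_absorbed_end = c(res_s$pct_absorbed, res_d$pct_absorbed),
    pct_dissolved_at_Tmax = c(pct_dissolved_at(res_s, res_s$Tmax),
                              pct_dissolved_at(res_d, res_d$Tmax))
  )
  list(static = res_s, dynamic = res_d,
       trajectories = rbind(lumen_amounts(res_s, "static"),
                            lumen_amounts(res_d, "dynamic")),
       summary = summary)
}
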