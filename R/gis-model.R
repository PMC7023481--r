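#' Per-subject physiology for the gastrointestinal simulation model
#'
#' Bundles the subject-level quantities that are fixed (not estimated)
#' when the six-state model is simulated or fitted: the time to the first
#' post-dose phase-III contraction front (TMMC), the duodenal and jejunal
#' pH time series used to recompute solubility along the simulation, the
#' average luminal fluid volumes, and the one-compartment disposition
#' constants obtained from non-compartmental analysis of plasma data.
#'
#' @param TMMC time to the next post-dose phase-III wave, h (>= 0).
#' @param pH_duodenum,pH_jejunum data.frames with columns `time_h`, `pH`,
#'   time-sorted, pH values in (0, 14). Required for the pH-aware model
#'   variant; may be `NULL` for the basic variant.
#' @param V1,V2 average duodenal and jejunal fluid volumes, mL (> 0).
#' @param Kel first-order elimination rate coefficient, 1/h (> 0).
#' @param V3 plasma distribution volume, mL (> 0).
#' @return an object of class `subject_physiology`.
#' @export
subject_physiology <- function(TMMC, pH_duodenum = NULL, pH_jejunum = NULL,
                               V1, V2, Kel, V3) {
  stopifnot(is.numeric(TMMC), length(TMMC) == 1L, is.finite(TMMC), TMMC >= 0)
  for (v in c(V1 = V1, V2 = V2, Kel = Kel, V3 = V3)) {
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  }
  if (V1 <= 0 || V2 <= 0 || V3 <= 0) stop("volumes V1, V2, V3 must be > 0")
  if (Kel <= 0) stop("`Kel` must be > 0")
  check_ph_series <- function(s, name) {
    if (is.null(s)) return(NULL)
    stopifnot(is.data.frame(s), all(c("time_h", "pH") %in% names(s)))
    if (nrow(s) < 1L) stop(sprintf("`%s` must have at least one row", name))
    if (is.unsorted(s$time_h, strictly = FALSE)) {
      stop(sprintf("`%s` times must be sorted", name))
    }
    if (any(s$pH <= 0 | s$pH >= 14)) {
      stop(sprintf("`%s` pH values must lie in (0, 14)", name))
    }
    s[, c("time_h", "pH")]
  }
  structure(
    list(TMMC = TMMC,
         pH_duodenum = check_ph_series(pH_duodenum, "pH_duodenum"),
         pH_jejunum = check_ph_series(pH_jejunum, "pH_jejunum"),
         V1 = V1, V2 = V2, Kel = Kel, V3 = V3),
    class = "subject_physiology"
  )
}

#' Rate parameters of the gastrointestinal simulation model
#'
#' The estimated parameter vector of the six-state model. Two variants are
#' supported:
#' \describe{
#'   \item{`"gis"`}{first-order dissolution everywhere: rate
#'     `Kd_simple * M_solid` (1/h), no pH dependence, purely exponential
#'     gastric emptying.}
#'   \item{`"gisplus"`}{pH-aware second-order dissolution
#'     `K_Diss * M_solid * (Cs(pH) - C)` with `K_Diss` in mL/(ug h), and
#'     gastric emptying that is first order until the phase-III wave at
#'     TMMC, when all remaining gastric solid is transferred to the
#'     duodenum at once.}
#' }
#' Exactly one of `K_Diss` / `Kd_simple` must be supplied; it determines
#' the variant. The absorption rate coefficient `Ka` defaults to the high
#' fixed value 12/h appropriate for a permeability-unlimited drug.
#'
#' @param Kempt first-order gastric emptying rate, 1/h.
#' @param K_TD duodenum-to-jejunum solid transit rate, 1/h.
#' @param K_TJ jejunum-to-distal solid transit rate, 1/h.
#' @param K_Diss pH-aware dissolution coefficient, mL/(ug h) (`gisplus`).
#' @param Kd_simple first-order dissolution rate, 1/h (`gis`).
#' @param Ka first-order absorption rate, 1/h (default 12).
#' @return an object of class `gis_parameters` with a `variant` field.
#' @export
gis_parameters <- function(Kempt, K_TD, K_TJ, K_Diss = NULL,
                           Kd_simple = NULL, Ka = 12) {
  vals <- c(Kempt = Kempt, K_TD = K_TD, K_TJ = K_TJ, Ka = Ka)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("rate parameters must be finite and >= 0")
  }
  if (is.null(K_Diss) == is.null(Kd_simple)) {
    stop("supply exactly one of `K_Diss` (gisplus) or `Kd_simple` (gis)")
  }
  if (!is.null(K_Diss) && (!is.finite(K_Diss) || K_Diss < 0)) {
    stop("`K_Diss` must be finite and >= 0")
  }
  if (!is.null(Kd_simple) && (!is.finite(Kd_simple) || Kd_simple < 0)) {
    stop("`Kd_simple` must be finite and >= 0")
  }
  structure(
    list(Kempt = Kempt, K_TD = K_TD, K_TJ = K_TJ,
         K_Diss = K_Diss, Kd_simple = Kd_simple, Ka = Ka,
         variant = if (is.null(K_Diss)) "gis" else "gisplus"),
    class = "gis_parameters"
  )
}

#' Interpolate a time-stamped pH series
#'
#' Piecewise-linear interpolation between observations with constant
#' extrapolation beyond the first and last knots — the scheme used to
#' recompute luminal solubility at every integration time point.
#'
#' @param series data.frame with columns `time_h`, `pH` (non-empty).
#' @param t query times, h.
#' @return interpolated pH values, same length as `t`.
#' @export
pH_at <- function(series, t) {
  stopifnot(is.data.frame(series), all(c("time_h", "pH") %in% names(series)))
  if (nrow(series) == 0L) stop("pH series is empty")
  if (nrow(series) == 1L) return(rep(series$pH, length(t)))
  stats::approx(series$time_h, series$pH, xout = t, rule = 2)$y
}

#' Luminal dissolution rate under the pH-aware law
#'
#' `K_Diss * M_solid * max(0, Cs(pH) - C_lumen)` in ug/h: proportional to
#' the remaining solid amount, driven by the gap between the
#' pH-dependent saturation solubility and the current luminal
#' concentration, and clamped at zero (no re-precipitation when the pH
#' drops).
#'
#' @param M_solid solid amount in the compartment, ug (>= 0).
#' @param C_lumen dissolved concentration in the compartment, ug/mL (>= 0).
#' @param pH luminal pH.
#' @param K_Diss dissolution coefficient, mL/(ug h).
#' @param solubility an [acid_solubility_profile()].
#' @return dissolution rate, ug/h.
#' @export
dissolution_rate <- function(M_solid, C_lumen, pH, K_Diss, solubility) {
  if (any(M_solid < 0) || any(C_lumen < 0)) {
    stop("`M_solid` and `C_lumen` must be >= 0")
  }
  K_Diss * M_solid * pmax(0, solubility_at_pH(solubility, pH) - C_lumen)
}

gis_state_names <- c("M_stomach_solid", "M_duodenum_solid",
                     "M_duodenum_dissolved", "M_jejunum_solid",
                     "M_jejunum_dissolved", "M_plasma",
                     "cumulative_eliminated", "cumulative_distal_transit")

# Saturation-solubility forcing for the compiled right-hand side: the
# subject's piecewise-linear pH series mapped through the solubility
# curve. Each pH segment is subdivided until the pH change per sample is
# <= 0.02, so linear interpolation of Cs between samples tracks the
# (convex) curve to ~0.1% or better.
gis_cs_forcing <- function(series, solubility, t_end, max_dpH = 0.02) {
  kt <- series$time_h
  kp <- series$pH
  if (kt[1L] > 0) { kt <- c(0, kt); kp <- c(kp[1L], kp) }
  if (kt[length(kt)] < t_end) { kt <- c(kt, t_end); kp <- c(kp, kp[length(kp)]) }
  pieces <- lapply(seq_len(length(kt) - 1L), function(i) {
    n_sub <- max(1L, ceiling(abs(kp[i + 1L] - kp[i]) / max_dpH))
    seq(kt[i], kt[i + 1L], length.out = n_sub + 1L)[-(n_sub + 1L)]
  })
  tt <- unique(c(unlist(pieces), kt[length(kt)]))
  cbind(tt, solubility_at_pH(solubility, pH_at(series, tt)))
}

#' Simulate the six-state gastrointestinal dissolution-and-transit model
#'
#' Integrates the amount of solid drug in the stomach, solid and dissolved
#' drug in the duodenum and jejunum, and drug in plasma, for one subject.
#' Model assumptions: no gastric dissolution or absorption (acidic pH far
#' below the acid's pKa); dissolution rates proportional to the remaining
#' solid amount; well-mixed luminal compartments; dissolved drug is
#' absorbed in place (high-permeability drug) and never transits; only
#' solid particles move from duodenum to jejunum and onwards (solids
#' leaving the jejunum are tracked as unabsorbed distal loss); no luminal
#' degradation; one-compartment plasma disposition (Kel, V3).
#'
#' Under the `"gisplus"` variant, gastric emptying is first order until
#' the phase-III wave at `phys$TMMC`, when the remaining gastric solid is
#' transferred to the duodenum as a bolus; the integration is split at the
#' event so the solver never steps across the discontinuity. Luminal
#' solubility is recomputed continuously from the subject's pH series.
#'
#' @param params a [gis_parameters()] object.
#' @param phys a [subject_physiology()] object.
#' @param dose administered dose, ug (> 0).
#' @param t_grid output times, h; sorted, starting at 0.
#' @param variant `"gis"`, `"gisplus"`, or `"auto"` (default: take the
#'   variant implied by `params`). A mismatch with `params` is an error.
#' @param solubility an [acid_solubility_profile()]; required for
#'   `"gisplus"`.
#' @param rtol,atol integrator tolerances (defaults 1e-8 and 1e-10 ug).
#' @return a `gis_trajectory`: a data.frame with `time_h`, the six state
#'   amounts (ug), `cumulative_eliminated`, `cumulative_distal_transit`,
#'   and derived concentrations `C_duodenum`, `C_jejunum`, `C_plasma`
#'   (ug/mL); attributes carry the dose, parameters and physiology.
#' @export
simulate_gis <- function(params, phys, dose, t_grid,
                         variant = c("auto", "gis", "gisplus"),
                         solubility = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "gis_parameters"),
            inherits(phys, "subject_physiology"))
  variant <- match.arg(variant)
  if (variant == "auto") variant <- params$variant
  if (variant != params$variant) {
    stop(sprintf("`params` carry the '%s' variant but '%s' was requested",
                 params$variant, variant))
  }
  stopifnot(is.numeric(dose), length(dose) == 1L, is.finite(dose))
  if (dose <= 0) stop("`dose` must be > 0")
  stopifnot(is.numeric(t_grid), length(t_grid) >= 1L)
  if (is.unsorted(t_grid, strictly = FALSE) || t_grid[1L] != 0) {
    stop("`t_grid` must be sorted and start at 0")
  }
  plus <- variant == "gisplus"
  if (plus) {
    if (is.null(solubility)) stop("`solubility` is required for 'gisplus'")
    if (is.null(phys$pH_duodenum) || is.null(phys$pH_jejunum)) {
      stop("gisplus requires duodenal and jejunal pH series in `phys`")
    }
  }
  y0 <- c(dose, 0, 0, 0, 0, 0, 0, 0)
  names(y0) <- gis_state_names
  t_end <- t_grid[length(t_grid)]

  p <- c(plus = as.numeric(plus), Kempt = params$Kempt, K_TD = params$K_TD,
         K_TJ = params$K_TJ, Ka = params$Ka, Kel = phys$Kel,
         V1 = phys$V1, V2 = phys$V2,
         KD = if (plus) params$K_Diss else params$Kd_simple)
  forcings <- if (plus) {
    list(gis_cs_forcing(phys$pH_duodenum, solubility, t_end),
         gis_cs_forcing(phys$pH_jejunum, solubility, t_end))
  } else {
    z <- cbind(c(0, max(t_end, 1)), c(0, 0))
    list(z, z)
  }

  integrate_piece <- function(y, times) {
    if (length(times) == 1L) {
      return(matrix(c(times, y), nrow = 1L,
                    dimnames = list(NULL, c("time", gis_state_names))))
    }
    out <- deSolve::lsoda(
      y, times, func = "gis_derivs", parms = p, dllname = "pbbm",
      initfunc = "gis_initmod", initforc = "gis_initforc",
      forcings = forcings, fcontrol = list(method = "linear", rule = 2),
      rtol = rtol, atol = atol, maxsteps = 20000
    )
    if (attr(out, "istate")[1L] < 0) {
      cond <- structure(
        class = c("pbbm_integrator_error", "error", "condition"),
        list(message = "ODE integration failed", call = sys.call(-1),
             last_state = out[nrow(out), ])
      )
      stop(cond)
    }
    unclass(out)
  }

  if (plus && phys$TMMC < t_end) {
    tm <- phys$TMMC
    pre_times <- unique(c(t_grid[t_grid < tm], tm))
    if (pre_times[1L] != 0) pre_times <- c(0, pre_times)
    pre <- integrate_piece(y0, pre_times)
    y_ev <- pre[nrow(pre), -1L]
    # phase-III bolus: remaining gastric solid moves to the duodenum
    y_ev[2L] <- y_ev[2L] + y_ev[1L]
    y_ev[1L] <- 0
    post_times <- unique(c(tm, t_grid[t_grid >= tm]))
    post <- integrate_piece(y_ev, post_times)
    keep_pre <- pre[pre[, 1L] %in% t_grid[t_grid < tm], , drop = FALSE]
    keep_post <- post[post[, 1L] %in% t_grid[t_grid >= tm], , drop = FALSE]
    out <- rbind(keep_pre, keep_post)
  } else {
    out <- integrate_piece(y0, t_grid)
  }

  traj <- as.data.frame(out)
  names(traj)[1L] <- "time_h"
  # clip solver-level negative round-off
  amt <- as.matrix(traj[, gis_state_names])
  amt[amt < 0 & amt > -atol * 10] <- 0
  traj[, gis_state_names] <- amt
  traj$C_duodenum <- traj$M_duodenum_dissolved / phys$V1
  traj$C_jejunum <- traj$M_jejunum_dissolved / phys$V2
  traj$C_plasma <- traj$M_plasma / phys$V3
  structure(traj, class = c("gis_trajectory", "data.frame"),
            dose = dose, params = params, phys = phys, variant = variant)
}

#' Mass-balance error of a simulated trajectory
#'
#' Relative deviation of (six state amounts + cumulative eliminated +
#' cumulative distal transit) from the administered dose, at each output
#' time. Closure to ~1e-6 or better is expected from the default
#' integrator tolerances.
#'
#' @param traj a `gis_trajectory` from [simulate_gis()].
#' @return numeric vector of relative errors, one per output time.
#' @export
gis_mass_balance_error <- function(traj) {
  stopifnot(inherits(traj, "gis_trajectory"))
  dose <- attr(traj, "dose")
  tot <- rowSums(traj[, gis_state_names])
  abs(tot - dose) / dose
}

#' Fraction of the dose remaining in the stomach
#'
#' Gastric emptying kinetics of solid particles under either variant:
#' `exp(-Kempt t)`, dropping to zero at the phase-III wave (TMMC) under
#' `"gisplus"`. Times at or after TMMC report the post-event value 0.
#'
#' @inheritParams simulate_gis
#' @return data.frame with columns `time_h`, `fraction_remaining`.
#' @export
gastric_fraction_remaining <- function(params, phys, t_grid,
                                       variant = c("auto", "gis", "gisplus")) {
  stopifnot(inherits(params, "gis_parameters"),
            inherits(phys, "subject_physiology"))
  variant <- match.arg(variant)
  if (variant == "auto") variant <- params$variant
  frac <- exp(-params$Kempt * t_grid)
  if (variant == "gisplus") frac[t_grid >= phys$TMMC] <- 0
  data.frame(time_h = t_grid, fraction_remaining = frac)
}
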