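#' Tidy multi-stream concentration dataset
#'
#' A per-subject set of concentration observations in the duodenum,
#' jejunum and plasma, together with the administered dose — the unit of
#' data that the six-state model is fitted to.
#'
#' @param records data.frame with columns `region` (one of `"duodenum"`,
#'   `"jejunum"`, `"plasma"`), `time_h` (>= 0) and `conc_ug_per_ml`
#'   (>= 0); an optional `subject` column is retained.
#' @param dose administered dose, ug (> 0).
#' @return an object of class `concentration_dataset`.
#' @export
concentration_dataset <- function(records, dose) {
  stopifnot(is.data.frame(records),
            all(c("region", "time_h", "conc_ug_per_ml") %in% names(records)))
  if (!all(records$region %in% c("duodenum", "jejunum", "plasma"))) {
    stop("`region` must be one of 'duodenum', 'jejunum', 'plasma'")
  }
  if (any(records$time_h < 0)) stop("times must be >= 0")
  if (any(records$conc_ug_per_ml < 0)) stop("concentrations must be >= 0")
  stopifnot(is.numeric(dose), length(dose) == 1L, dose > 0)
  structure(list(records = records, dose = dose),
            class = "concentration_dataset")
}

#' Fitting configuration for [fit_gis()]
#'
#' @param Ka fixed absorption rate coefficient, 1/h (default 12, the high
#'   value appropriate for a permeability-unlimited drug).
#' @param n_starts number of local least-squares polishes run from the
#'   best-scoring candidate starts (default 16).
#' @param n_candidates size of the space-filling candidate pool screened
#'   (one objective evaluation each) before polishing; default
#'   `8 * n_starts`.
#' @param seed integer seed making the candidate draws reproducible.
#' @param bounds named list of `c(lower, upper)` per estimated parameter;
#'   defaults span the observed fitted ranges of the reference cohort
#'   widened by a factor of 10 on each side.
#' @param maxiter per-start iteration cap for the local least-squares
#'   optimizer.
#' @return a list of class `gis_fit_config`.
#' @export
gis_fit_config <- function(Ka = 12, n_starts = 16, n_candidates = NULL,
                           seed = 1L, bounds = NULL, maxiter = 150) {
  default_bounds <- list(
    Kempt     = c(1e-4, 40.5),
    K_TD      = c(7e-3, 102.6),
    K_TJ      = c(1e-5, 11.4),
    K_Diss    = c(9e-6, 15.9),
    Kd_simple = c(1e-4, 100),
    V1        = c(1.5, 5000),
    V2        = c(0.25, 2900)
  )
  if (!is.null(bounds)) default_bounds[names(bounds)] <- bounds
  if (is.null(n_candidates)) n_candidates <- 8L * as.integer(n_starts)
  structure(list(Ka = Ka, n_starts = as.integer(n_starts),
                 n_candidates = as.integer(n_candidates),
                 seed = as.integer(seed), bounds = default_bounds,
                 maxiter = maxiter),
            class = "gis_fit_config")
}

# Residual vector of one candidate parameter vector (log scale), weighted
# per stream by the maximum observed concentration so that luminal
# (~1000 ug/mL) and plasma (~40 ug/mL) streams contribute on equal scales.
gis_fit_residuals <- function(logtheta, pnames, data_by_region, weights,
                              t_grid, phys0, dose, variant, solubility, Ka) {
  th <- exp(logtheta)
  names(th) <- pnames
  phys <- phys0
  phys$V1 <- th[["V1"]]
  phys$V2 <- th[["V2"]]
  params <- if (variant == "gisplus") {
    gis_parameters(th[["Kempt"]], th[["K_TD"]], th[["K_TJ"]],
                   K_Diss = th[["K_Diss"]], Ka = Ka)
  } else {
    gis_parameters(th[["Kempt"]], th[["K_TD"]], th[["K_TJ"]],
                   Kd_simple = th[["Kd_simple"]], Ka = Ka)
  }
  traj <- tryCatch(
    simulate_gis(params, phys, dose, t_grid, solubility = solubility),
    error = function(e) NULL
  )
  if (is.null(traj)) return(rep(1e6, sum(vapply(data_by_region, nrow, 1L))))
  pred_col <- c(duodenum = "C_duodenum", jejunum = "C_jejunum",
                plasma = "C_plasma")
  unlist(lapply(names(data_by_region), function(rg) {
    d <- data_by_region[[rg]]
    pred <- stats::approx(traj$time_h, traj[[pred_col[[rg]]]],
                          xout = d$time_h, rule = 2)$y
    (pred - d$conc_ug_per_ml) / weights[[rg]]
  }))
}

#' Fit the six-state model simultaneously to luminal and plasma data
#'
#' Estimates `{Kempt, K_TD, K_TJ, K_Diss (or Kd_simple), V1, V2}` by
#' bounded multi-start least squares, minimizing the sum over streams of
#' the residual sum of squares scaled by the squared maximum observed
#' concentration of that stream. `Kel`, `V3` and `TMMC` are fixed at the
#' subject's physiology values and `Ka` at the configured value, as in
#' the reference analysis. Parameters are optimized on the log scale
#' within bounds; starts are log-uniform draws (plus the geometric
#' mid-point of the bounds), reproducible from the configured seed.
#'
#' A stream whose observations are all zero carries no scale information;
#' it is dropped from the objective and the result is flagged rather than
#' erroring. Non-convergence of every start likewise yields a flagged
#' result.
#'
#' @param data a [concentration_dataset()].
#' @param phys a [subject_physiology()]; `V1`/`V2` entries are used only
#'   as placeholders (the fitted values replace them).
#' @param variant `"gis"` or `"gisplus"`.
#' @param config a [gis_fit_config()].
#' @param solubility an [acid_solubility_profile()] (gisplus only).
#' @return an object of class `gis_fit`: list with `estimates`
#'   (a [gis_parameters()]), `V1`, `V2`, `fixed`, `objective`,
#'   `residuals` (per stream), `converged`, `flags`, `n_starts`, `seed`.
#' @export
fit_gis <- function(data, phys, variant = c("gisplus", "gis"),
                    config = gis_fit_config(), solubility = NULL) {
  stopifnot(inherits(data, "concentration_dataset"),
            inherits(phys, "subject_physiology"),
            inherits(config, "gis_fit_config"))
  variant <- match.arg(variant)
  if (variant == "gisplus" && is.null(solubility)) {
    stop("`solubility` is required for the gisplus variant")
  }
  rec <- data$records
  rec <- rec[order(rec$region, rec$time_h), , drop = FALSE]
  data_by_region <- split(rec, rec$region, drop = TRUE)
  flags <- character(0)
  weights <- vapply(data_by_region, function(d) max(d$conc_ug_per_ml), 0)
  if (any(weights == 0)) {
    flags <- c(flags, paste0("all-zero stream dropped: ",
                             paste(names(weights)[weights == 0],
                                   collapse = ", ")))
    data_by_region <- data_by_region[weights > 0]
    weights <- weights[weights > 0]
  }
  if (length(data_by_region) == 0L) {
    stop("no stream with non-zero observations")
  }
  t_grid <- sort(unique(c(0, rec$time_h)))
  pnames <- c("Kempt", "K_TD", "K_TJ",
              if (variant == "gisplus") "K_Diss" else "Kd_simple",
              "V1", "V2")
  lower <- log(vapply(config$bounds[pnames], `[`, 0, 1L))
  upper <- log(vapply(config$bounds[pnames], `[`, 0, 2L))

  # screened multi-start: score a space-filling candidate pool with one
  # objective evaluation each, then polish the best n_starts candidates
  # with bounded Levenberg-Marquardt. Candidates are drawn from the
  # interior decade of the bounds (the observed parameter range before
  # x10 widening): corner starts tend to produce extremely stiff systems
  # and waste optimizer budget, while the bounds themselves stay wide.
  s_lower <- lower + log(10)
  s_upper <- upper - log(10)
  rng <- local({
    set.seed(config$seed)
    lhs::randomLHS(config$n_candidates, length(pnames))
  })
  cands <- sweep(sweep(rng, 2, s_upper - s_lower, `*`), 2, s_lower, `+`)
  scores <- apply(cands, 1L, function(th) {
    sum(gis_fit_residuals(th, pnames, data_by_region, weights, t_grid,
                          phys, data$dose, variant, solubility,
                          config$Ka)^2)
  })
  keep <- order(scores)[seq_len(min(config$n_starts - 1L, nrow(cands)))]
  # the geometric mid-point of the bounds is always polished
  starts <- rbind((lower + upper) / 2, cands[keep, , drop = FALSE])

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], lower = lower, upper = upper,
        fn = gis_fit_residuals, pnames = pnames,
        data_by_region = data_by_region, weights = weights,
        t_grid = t_grid, phys0 = phys, dose = data$dose,
        variant = variant, solubility = solubility, Ka = config$Ka,
        # finite-difference step (epsfcn) widened above the ODE-solver
        # noise floor, else the numerical Jacobian is dominated by
        # integrator round-off
        control = minpack.lm::nls.lm.control(maxiter = config$maxiter,
                                             ftol = 1e-12, ptol = 1e-12,
                                             gtol = 0, epsfcn = 1e-8)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    obj <- sum(fit$fvec^2)
    if (is.finite(obj) && (is.null(best) || obj < best$obj)) {
      best <- list(fit = fit, obj = obj)
    }
  }
  if (is.null(best)) {
    flags <- c(flags, "no start converged")
    return(structure(list(estimates = NULL, V1 = NA_real_, V2 = NA_real_,
                          fixed = list(Ka = config$Ka, Kel = phys$Kel,
                                       V3 = phys$V3, TMMC = phys$TMMC),
                          objective = NA_real_, residuals = NULL,
                          converged = FALSE, flags = flags,
                          n_starts = config$n_starts, seed = config$seed,
                          variant = variant),
                     class = "gis_fit"))
  }
  th <- exp(best$fit$par)
  names(th) <- pnames
  estimates <- if (variant == "gisplus") {
    gis_parameters(th[["Kempt"]], th[["K_TD"]], th[["K_TJ"]],
                   K_Diss = th[["K_Diss"]], Ka = config$Ka)
  } else {
    gis_parameters(th[["Kempt"]], th[["K_TD"]], th[["K_TJ"]],
                   Kd_simple = th[["Kd_simple"]], Ka = config$Ka)
  }
  res_vec <- gis_fit_residuals(best$fit$par, pnames, data_by_region,
                               weights, t_grid, phys, data$dose, variant,
                               solubility, config$Ka)
  n_per <- vapply(data_by_region, nrow, 1L)
  residuals <- split(res_vec, rep(names(data_by_region), n_per))
  structure(list(estimates = estimates, V1 = th[["V1"]], V2 = th[["V2"]],
                 fixed = list(Ka = config$Ka, Kel = phys$Kel,
                              V3 = phys$V3, TMMC = phys$TMMC),
                 objective = best$obj, residuals = residuals,
                 converged = TRUE, flags = flags,
                 n_starts = config$n_starts, seed = config$seed,
                 variant = variant),
            class = "gis_fit")
}

#' @export
print.gis_fit <- function(x, ...) {
  cat(sprintf("<gis_fit> variant %s, converged: %s, objective %.4g\n",
              x$variant, x$converged, x$objective))
  if (!is.null(x$estimates)) {
    e <- x$estimates
    kd <- if (x$variant == "gisplus") {
      sprintf("K_Diss %.3g mL/(ug h)", e$K_Diss)
    } else {
      sprintf("Kd_simple %.3g 1/h", e$Kd_simple)
    }
    cat(sprintf("  Kempt %.3g  K_TD %.3g  K_TJ %.3g  %s  V1 %.4g  V2 %.4g\n",
                e$Kempt, e$K_TD, e$K_TJ, kd, x$V1, x$V2))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Extract the estimated parameter vector of a fit as a one-row data.frame
#' @param fit a `gis_fit`.
#' @return one-row data.frame with columns Kempt, K_TD, K_TJ,
#'   K_Diss/Kd_simple, V1, V2.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "gis_fit"))
  e <- fit$estimates
  out <- data.frame(Kempt = e$Kempt, K_TD = e$K_TD, K_TJ = e$K_TJ)
  if (fit$variant == "gisplus") out$K_Diss <- e$K_Diss else
    out$Kd_simple <- e$Kd_simple
  out$V1 <- fit$V1
  out$V2 <- fit$V2
  out
}

#' Cohort-level parameter summary
#'
#' Mean, SD, CV% (100 SD/mean) and median (50th percentile, midpoint rule
#' for even n) of each parameter across subjects — the layout of a
#' per-cohort fitted-parameter summary table.
#'
#' @param x either a data.frame of per-subject parameter values (one row
#'   per subject) or a list of `gis_fit` objects.
#' @return data.frame with rows `mean`, `sd`, `cv_pct`, `median` and one
#'   column per parameter.
#' @export
summarize_parameters <- function(x) {
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, TRUE, "gis_fit"))) {
    x <- do.call(rbind, lapply(x, coef_table))
  }
  stopifnot(is.data.frame(x), nrow(x) >= 1L)
  num <- x[vapply(x, is.numeric, TRUE)]
  out <- rbind(
    mean = vapply(num, mean, 0),
    sd = vapply(num, function(v) if (length(v) > 1L) stats::sd(v) else 0, 0),
    cv_pct = NA_real_,
    median = vapply(num, stats::median, 0)
  )
  out["cv_pct", ] <- 100 * out["sd", ] / out["mean", ]
  as.data.frame(out)
}

#' Percentage deviation of predicted from observed exposure metrics
#'
#' For each region present in `observed`, computes Cmax, Tmax (first time
#' attaining the maximum) and AUC (linear trapezoid on the observation
#' grid) from both the predicted trajectory (evaluated at the observation
#' times) and the observations, and returns the absolute percentage
#' deviation `100 |pred - obs| / obs`.
#'
#' @param predicted a `gis_trajectory` from [simulate_gis()].
#' @param observed a [concentration_dataset()].
#' @return data.frame with columns `region`, `metric`,
#'   `predicted`, `observed`, `abs_pct_deviation`.
#' @export
deviation_metrics <- function(predicted, observed) {
  stopifnot(inherits(predicted, "gis_trajectory"),
            inherits(observed, "concentration_dataset"))
  pred_col <- c(duodenum = "C_duodenum", jejunum = "C_jejunum",
                plasma = "C_plasma")
  rec <- observed$records
  out <- lapply(sort(unique(rec$region)), function(rg) {
    d <- rec[rec$region == rg, ]
    d <- d[order(d$time_h), ]
    pred <- stats::approx(predicted$time_h, predicted[[pred_col[[rg]]]],
                          xout = d$time_h, rule = 2)$y
    metrics <- function(t, c) {
      c(Cmax = max(c), Tmax = t[which.max(c)], AUC = trapz_auc(t, c))
    }
    mp <- metrics(d$time_h, pred)
    mo <- metrics(d$time_h, d$conc_ug_per_ml)
    data.frame(region = rg, metric = names(mp), predicted = unname(mp),
               observed = unname(mo),
               abs_pct_deviation = unname(100 * abs(mp - mo) / mo))
  })
  do.call(rbind, out)
}

# linear trapezoid
trapz_auc <- function(t, c) {
  if (length(t) < 2L) return(0)
  sum(diff(t) * (utils::head(c, -1) + utils::tail(c, -1)) / 2)
}
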