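#' Non-compartmental analysis of a concentration-time profile
#'
#' Computes Cmax, Tmax (first time attaining the maximum), AUC by the
#' linear trapezoid rule, the terminal elimination slope lambda_z by
#' log-linear regression, and the extrapolated AUC to infinity
#' (`AUC_0_t + C_last / lambda_z`). The terminal fit considers the last
#' 3 to `max_points` positive concentrations and keeps the set with the
#' best adjusted R-squared (more points win ties).
#'
#' @param profile data.frame with columns `time_h` and `conc_ug_per_ml`
#'   (>= 3 rows, times sorted).
#' @param dose administered dose, ug (carried through for downstream use).
#' @param max_points most terminal points considered for lambda_z
#'   (default 6).
#' @return an object of class `nca_result`: list with `Cmax`, `Tmax`,
#'   `AUC_0_t`, `lambda_z`, `AUC_0_inf`, `n_points_lambda_z`, `dose`,
#'   `flags`.
#' @export
nca <- function(profile, dose = NA_real_, max_points = 6L) {
  stopifnot(is.data.frame(profile),
            all(c("time_h", "conc_ug_per_ml") %in% names(profile)))
  if (nrow(profile) < 3L) stop("at least 3 points are required")
  if (is.unsorted(profile$time_h, strictly = TRUE)) {
    stop("`time_h` must be strictly increasing")
  }
  t <- profile$time_h
  cc <- profile$conc_ug_per_ml
  flags <- character(0)
  cmax <- max(cc)
  tmax <- t[which.max(cc)]
  auc_t <- trapz_auc(t, cc)

  lambda_z <- NA_real_
  n_lz <- NA_integer_
  auc_inf <- NA_real_
  pos <- which(cc > 0)
  tail_pos <- pos[pos > which.max(cc)]  # strictly after Tmax
  if (length(tail_pos) < 3L) tail_pos <- utils::tail(pos, max_points)
  if (length(tail_pos) >= 3L && cc[length(cc)] > 0) {
    best <- NULL
    for (k in 3:min(max_points, length(tail_pos))) {
      idx <- utils::tail(tail_pos, k)
      fit <- stats::lm(log(cc[idx]) ~ t[idx])
      slope <- unname(stats::coef(fit)[2L])
      if (!is.finite(slope) || slope >= 0) next
      ss_tot <- sum((log(cc[idx]) - mean(log(cc[idx])))^2)
      r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
      r2adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
      if (is.null(best) || r2adj >= best$r2adj) {
        best <- list(slope = slope, r2adj = r2adj, k = k)
      }
    }
    if (!is.null(best)) {
      lambda_z <- -best$slope
      n_lz <- best$k
      auc_inf <- auc_t + cc[length(cc)] / lambda_z
    } else {
      flags <- c(flags, "no declining terminal phase; lambda_z unestimable")
    }
  } else {
    flags <- c(flags, "non-positive terminal concentrations; lambda_z unestimable")
  }
  structure(list(Cmax = cmax, Tmax = tmax, AUC_0_t = auc_t,
                 lambda_z = lambda_z, AUC_0_inf = auc_inf,
                 n_points_lambda_z = n_lz, dose = dose, flags = flags),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> Cmax %.4g  Tmax %.3g h  AUC_0_t %.5g  lambda_z %.4g 1/h  AUC_0_inf %.5g\n",
              x$Cmax, x$Tmax, x$AUC_0_t, x$lambda_z, x$AUC_0_inf))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Wagner-Nelson deconvolution to fraction absorbed
#'
#' Model-independent estimate of the cumulative fraction absorbed under
#' one-compartment disposition:
#' \deqn{F_{abs}(t) = \frac{C(t) + k_{el} AUC_{0-t}(t)}{k_{el} AUC_{0-\infty}}}
#' with the linear trapezoid used for the running AUC and
#' `AUC_0_inf = AUC_0_t(t_last) + C(t_last)/kel`. Values are clamped to
#' \[0, 1.05\]; any clamping is recorded in the `clamped` attribute.
#'
#' @param profile data.frame with `time_h`, `conc_ug_per_ml`.
#' @param kel first-order elimination rate, 1/h (> 0); typically the
#'   subject's NCA lambda_z.
#' @return data.frame with columns `time_h`, `fabs`; attribute `clamped`
#'   gives the number of clamped points.
#' @export
wagner_nelson <- function(profile, kel) {
  stopifnot(is.data.frame(profile),
            all(c("time_h", "conc_ug_per_ml") %in% names(profile)))
  if (!is.numeric(kel) || length(kel) != 1L || !is.finite(kel) || kel <= 0) {
    stop("`kel` must be a positive scalar")
  }
  t <- profile$time_h
  cc <- profile$conc_ug_per_ml
  n <- length(t)
  auc_run <- c(0, cumsum(diff(t) * (cc[-n] + cc[-1L]) / 2))
  auc_inf <- auc_run[n] + cc[n] / kel
  fabs <- (cc + kel * auc_run) / (kel * auc_inf)
  clamped <- sum(fabs < 0 | fabs > 1.05)
  if (clamped > 0) {
    message(sprintf("wagner_nelson: %d point(s) clamped to [0, 1.05]", clamped))
  }
  fabs <- pmin(pmax(fabs, 0), 1.05)
  structure(data.frame(time_h = t, fabs = fabs), clamped = clamped)
}

#' Absorption rate from a fraction-absorbed series
#'
#' Differentiates `dose * Fabs(t)` by central finite differences
#' (one-sided at the endpoints), giving the apparent absorption rate in
#' ug/h — the quantity overlaid against the model-estimated luminal
#' dissolution rate.
#'
#' @param fabs data.frame with `time_h`, `fabs` (e.g. from
#'   [wagner_nelson()]).
#' @param dose administered dose, ug.
#' @return data.frame with columns `time_h`, `rate_ug_per_h`.
#' @export
absorption_rate <- function(fabs, dose) {
  stopifnot(is.data.frame(fabs), all(c("time_h", "fabs") %in% names(fabs)))
  t <- fabs$time_h
  a <- dose * fabs$fabs
  n <- length(t)
  if (n < 2L) stop("need at least 2 points")
  rate <- numeric(n)
  rate[1L] <- (a[2L] - a[1L]) / (t[2L] - t[1L])
  rate[n] <- (a[n] - a[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    rate[2:(n - 1L)] <- (a[3:n] - a[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  }
  data.frame(time_h = t, rate_ug_per_h = rate)
}

#' Mammillary pharmacokinetic model
#'
#' Micro-constant parameterization of a 1-, 2- or 3-compartment
#' mammillary disposition model with central volume `Vc`; clearance is
#' the identity `CL = K10 * Vc`.
#'
#' @param n_compartments 1, 2 or 3.
#' @param K10 central elimination rate, 1/h.
#' @param K12,K21 central-peripheral exchange rates, 1/h (n >= 2).
#' @param K13,K31 second peripheral exchange rates, 1/h (n = 3).
#' @param Vc central volume, mL.
#' @param infusion_duration zero-order input duration, h.
#' @return an object of class `mammillary_pk`.
#' @export
mammillary_pk <- function(n_compartments, K10, K12 = NULL, K21 = NULL,
                          K13 = NULL, K31 = NULL, Vc,
                          infusion_duration = 0.1) {
  n <- as.integer(n_compartments)
  stopifnot(n %in% 1:3, K10 > 0, Vc > 0, infusion_duration > 0)
  if (n >= 2L) stopifnot(!is.null(K12), !is.null(K21), K12 > 0, K21 > 0)
  if (n == 3L) stopifnot(!is.null(K13), !is.null(K31), K13 > 0, K31 > 0)
  structure(list(n_compartments = n, K10 = K10, K12 = K12, K21 = K21,
                 K13 = K13, K31 = K31, Vc = Vc, CL = K10 * Vc,
                 infusion_duration = infusion_duration),
            class = "mammillary_pk")
}

# Rate matrix of the mammillary model (amount form).
mammillary_rate_matrix <- function(pk) {
  n <- pk$n_compartments
  if (n == 1L) return(matrix(-pk$K10, 1, 1))
  if (n == 2L) {
    return(matrix(c(-(pk$K10 + pk$K12), pk$K21,
                    pk$K12, -pk$K21), 2, 2, byrow = TRUE))
  }
  matrix(c(-(pk$K10 + pk$K12 + pk$K13), pk$K21, pk$K31,
           pk$K12, -pk$K21, 0,
           pk$K13, 0, -pk$K31), 3, 3, byrow = TRUE)
}

#' Central concentration after a constant-rate intravenous infusion
#'
#' Closed-form solution of the mammillary model under zero-order input
#' of `dose` over `pk$infusion_duration`, evaluated by eigendecomposition
#' of the rate matrix.
#'
#' @param pk a [mammillary_pk()].
#' @param dose administered dose, ug.
#' @param times output times, h.
#' @return central concentrations, ug/mL.
#' @export
predict_iv_infusion <- function(pk, dose, times) {
  K <- mammillary_rate_matrix(pk)
  Tinf <- pk$infusion_duration
  rate <- dose / Tinf
  eg <- eigen(K)
  V <- eg$vectors
  lam <- eg$values
  Vinv <- solve(V)
  b <- c(rate, rep(0, nrow(K) - 1L))
  beta <- Vinv %*% b
  # during infusion: A(t) = V diag((exp(lam t)-1)/lam) Vinv b
  a_at <- function(t) {
    if (t <= Tinf) {
      V %*% (beta * (exp(lam * t) - 1) / lam)
    } else {
      a_inf <- V %*% (beta * (exp(lam * Tinf) - 1) / lam)
      V %*% ((Vinv %*% a_inf) * exp(lam * (t - Tinf)))
    }
  }
  conc <- vapply(times, function(t) Re(a_at(t))[1L], 0) / pk$Vc
  pmax(conc, 0)
}

#' Fit a mammillary IV model to an infusion concentration profile
#'
#' Least-squares fit of the constant-rate-infusion solution of a 1-, 2-
#' or 3-compartment mammillary model (micro-constant parameterization,
#' optimized on the log scale from multiple starts). Model comparison
#' uses `AIC = n_obs * ln(SSR / n_obs) + 2 * n_params` together with
#' R-squared.
#'
#' @param profile data.frame with `time_h`, `conc_ug_per_ml`.
#' @param dose administered dose, ug.
#' @param infusion_duration zero-order input duration, h (> 0).
#' @param n number of compartments (1, 2 or 3).
#' @param n_starts multi-start count (default 12).
#' @param seed RNG seed for the starts.
#' @return a [mammillary_pk()] with extra fields `AIC`, `R2`, `SSR`,
#'   `n_obs`.
#' @export
fit_mammillary_iv <- function(profile, dose, infusion_duration, n,
                              n_starts = 12L, seed = 1L) {
  stopifnot(is.data.frame(profile),
            all(c("time_h", "conc_ug_per_ml") %in% names(profile)))
  if (infusion_duration <= 0) stop("`infusion_duration` must be > 0")
  n <- as.integer(n)
  stopifnot(n %in% 1:3)
  t <- profile$time_h
  obs <- profile$conc_ug_per_ml
  pnames <- switch(n, c("K10", "Vc"),
                   c("K10", "K12", "K21", "Vc"),
                   c("K10", "K12", "K21", "K13", "K31", "Vc"))
  n_par <- length(pnames)
  if (length(obs) <= n_par) stop("need more observations than parameters")

  make_pk <- function(th) {
    mammillary_pk(n, K10 = th[["K10"]],
                  K12 = if (n >= 2L) th[["K12"]],
                  K21 = if (n >= 2L) th[["K21"]],
                  K13 = if (n == 3L) th[["K13"]],
                  K31 = if (n == 3L) th[["K31"]],
                  Vc = th[["Vc"]], infusion_duration = infusion_duration)
  }
  resid_fn <- function(logtheta) {
    th <- exp(logtheta)
    names(th) <- pnames
    pred <- tryCatch(predict_iv_infusion(make_pk(th), dose, t),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(rep(1e6, length(obs)))
    pred - obs
  }
  lower <- log(c(rep(1e-3, n_par - 1L), 50))
  upper <- log(c(rep(50, n_par - 1L), 1e6))
  names(lower) <- names(upper) <- pnames
  # moment-based central-volume start: dose / (Cmax-ish scale)
  vc0 <- log(max(dose / max(obs), 60))
  set.seed(seed)
  starts <- rbind(
    stats::setNames(c(rep(log(1), n_par - 1L), vc0), pnames),
    matrix(stats::runif(n_starts * n_par, rep(lower, each = n_starts),
                        rep(upper, each = n_starts)),
           nrow = n_starts, dimnames = list(NULL, pnames))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.finite(ssr) && (is.null(best) || ssr < best$ssr)) {
      best <- list(par = fit$par, ssr = ssr)
    }
  }
  if (is.null(best)) stop("mammillary fit failed from all starts")
  th <- exp(best$par)
  names(th) <- pnames
  pk <- make_pk(th)
  n_obs <- length(obs)
  pk$SSR <- best$ssr
  pk$n_obs <- n_obs
  pk$AIC <- n_obs * log(best$ssr / n_obs) + 2 * n_par
  pk$R2 <- 1 - best$ssr / sum((obs - mean(obs))^2)
  pk
}

#' @export
print.mammillary_pk <- function(x, ...) {
  cat(sprintf("<mammillary_pk> %d-compartment  K10 %.4g 1/h  Vc %.5g mL  CL %.4g mL/h\n",
              x$n_compartments, x$K10, x$Vc, x$CL))
  if (x$n_compartments >= 2L) {
    cat(sprintf("  K12 %.4g  K21 %.4g", x$K12, x$K21))
    if (x$n_compartments == 3L) cat(sprintf("  K13 %.4g  K31 %.4g", x$K13, x$K31))
    cat("\n")
  }
  if (!is.null(x$AIC)) {
    cat(sprintf("  fit: SSR %.4g  AIC %.4g  R2 %.6g  (n_obs %d)\n",
                x$SSR, x$AIC, x$R2, x$n_obs))
  }
  invisible(x)
}
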