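#' pH-dependent solubility profile of a monoprotic acid
#'
#' Constructs the solubility model used as the thermodynamic driving force
#' for dissolution throughout the package. For a monoprotic acid the
#' Henderson-Hasselbalch relationship gives total solubility
#' \deqn{S(pH) = S_0 (1 + 10^{pH - pK_a})}
#' where \eqn{S_0} is the intrinsic (unionized) solubility. An optional
#' solubility factor `cap` bounds the curve at `S0 * cap`, emulating the
#' finite maximum solubility of the fully ionized species: the solubility
#' factor is the ratio of the maximum to the intrinsic solubility.
#'
#' @param s0 intrinsic solubility, ug/mL; must be > 0.
#' @param pka acid dissociation constant, in (0, 14).
#' @param cap optional solubility factor (dimensionless, >= 1); `NULL`
#'   (default) leaves the curve uncapped.
#' @param reference_pH,reference_solubility optional provenance: the
#'   measured anchor point the profile was derived from (not used in
#'   evaluation).
#' @return an object of class `acid_solubility_profile`.
#' @seealso [solubility_at_pH()], [anchor_intrinsic_solubility()]
#' @export
acid_solubility_profile <- function(s0, pka, cap = NULL,
                                    reference_pH = NULL,
                                    reference_solubility = NULL) {
  stopifnot(is.numeric(s0), length(s0) == 1L, is.finite(s0))
  if (s0 <= 0) stop("intrinsic solubility `s0` must be > 0")
  stopifnot(is.numeric(pka), length(pka) == 1L, is.finite(pka))
  if (pka <= 0 || pka >= 14) stop("`pka` must lie in (0, 14)")
  if (!is.null(cap)) {
    stopifnot(is.numeric(cap), length(cap) == 1L, is.finite(cap))
    if (cap < 1) stop("solubility factor `cap` must be >= 1")
  }
  structure(
    list(s0 = s0, pka = pka, cap = cap,
         reference_pH = reference_pH,
         reference_solubility = reference_solubility),
    class = "acid_solubility_profile"
  )
}

#' @export
print.acid_solubility_profile <- function(x, ...) {
  cat("<acid_solubility_profile>\n")
  cat(sprintf("  S0 (intrinsic): %.4g ug/mL   pKa: %.3g\n", x$s0, x$pka))
  if (!is.null(x$cap)) {
    cat(sprintf("  solubility factor cap: %.4g (max %.4g ug/mL)\n",
                x$cap, x$s0 * x$cap))
  } else {
    cat("  solubility factor cap: none\n")
  }
  if (!is.null(x$reference_pH)) {
    cat(sprintf("  anchored at pH %.3g = %.4g ug/mL\n",
                x$reference_pH, x$reference_solubility))
  }
  invisible(x)
}

#' Evaluate solubility at a given pH
#'
#' Henderson-Hasselbalch total solubility for a monoprotic acid,
#' `S0 * (1 + 10^(pH - pKa))`, truncated at `S0 * cap` when the profile
#' carries a solubility-factor cap. Vectorized over `pH`.
#'
#' @param profile an [acid_solubility_profile()].
#' @param pH bulk pH (finite, possibly a vector).
#' @return solubility in ug/mL, same length as `pH`.
#' @export
solubility_at_pH <- function(profile, pH) {
  stopifnot(inherits(profile, "acid_solubility_profile"), is.numeric(pH))
  if (any(!is.finite(pH))) stop("`pH` must be finite")
  s <- profile$s0 * (1 + 10^(pH - profile$pka))
  if (!is.null(profile$cap)) s <- pmin(s, profile$s0 * profile$cap)
  s
}

#' Recover the intrinsic solubility from a reference measurement
#'
#' Inverts the Henderson-Hasselbalch relationship at a single measured
#' (pH, solubility) point to obtain the intrinsic solubility, and returns
#' the anchored profile. Evaluating the result at `pH_ref` reproduces
#' `S_ref` (when the cap is not binding there).
#'
#' @param S_ref measured solubility at `pH_ref`, ug/mL; must be > 0.
#' @param pH_ref the pH of the reference measurement.
#' @param pka acid pKa.
#' @param cap optional solubility factor passed through to the profile.
#' @return an [acid_solubility_profile()] with provenance fields set.
#' @export
anchor_intrinsic_solubility <- function(S_ref, pH_ref, pka, cap = NULL) {
  stopifnot(is.numeric(S_ref), length(S_ref) == 1L, is.finite(S_ref))
  if (S_ref <= 0) stop("`S_ref` must be > 0")
  s0 <- S_ref / (1 + 10^(pH_ref - pka))
  acid_solubility_profile(s0, pka, cap = cap,
                          reference_pH = pH_ref,
                          reference_solubility = S_ref)
}

#' Ibuprofen solubility profile
#'
#' Convenience constructor for the package's worked system: ibuprofen,
#' a monoprotic acid with pKa 4.54, anchored so that solubility at the
#' reference pH 6.2 equals 1.99 mg/mL (1990 ug/mL).
#'
#' @param cap optional solubility factor (default none).
#' @return an [acid_solubility_profile()].
#' @export
ibuprofen_solubility_profile <- function(cap = NULL) {
  anchor_intrinsic_solubility(S_ref = 1990, pH_ref = 6.2, pka = 4.54,
                              cap = cap)
}

#' Measured ibuprofen solubilities in aspirated human GI fluids
#'
#' Shake-flask equilibrium solubilities of ibuprofen measured in
#' fasted-state human gastric and intestinal fluids, provided for
#' plotting/validation overlays. These real-fluid values reflect media
#' effects (buffer species, bile components) that the bulk
#' Henderson-Hasselbalch curve does not capture, so they are not forced
#' onto the model curve.
#'
#' @return a data.frame with columns `fluid`, `pH`, `solubility_ug_per_ml`.
#' @export
ibuprofen_fluid_solubilities <- function() {
  data.frame(
    fluid = c("fasted gastric", "fasted duodenal", "fasted jejunal"),
    pH = c(1.46, 3.74, 4.6),
    solubility_ug_per_ml = c(4.8, 10.2, 1200)
  )
}
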