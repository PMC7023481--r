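#' Configuration of the virtual-cohort generator
#'
#' Defines the statistical structure of generated subjects: an 800 mg
#' (8e5 ug) oral dose taken with 250 mL of water in the fasted state;
#' luminal sampling of duodenum and jejunum over 0-7 h and plasma
#' sampling to 28 h on the clinical grids; time to the post-dose
#' phase-III wave (TMMC) lognormal around a 2.04 h median; model
#' parameters lognormal around the reference cohort medians; and
#' fluctuating low-buffer-capacity intestinal pH emulated by a
#' mean-reverting (Ornstein-Uhlenbeck) walk on a 5-min grid, clipped to
#' physiological bounds. Observation noise is proportional lognormal;
#' values below the assay quantification limit are reported as zero.
#'
#' @param n_subjects number of virtual subjects.
#' @param seed integer master seed; subject `i` derives its own stream.
#' @param dose dose, ug (default 8e5).
#' @param tmmc_median_h,tmmc_gsd TMMC lognormal median (h) and geometric
#'   SD (defaults 2.04 h, 1.4).
#' @param param_medians named list of true-parameter medians (defaults:
#'   Kempt 0.18, K_TD 0.47, K_TJ 0.081 1/h, K_Diss 1.52e-3 mL/(ug h),
#'   V1 123.24, V2 49.99 mL, Kel 0.35 1/h, V3 1e4 mL).
#' @param param_cv between-subject lognormal coefficient of variation of
#'   the model parameters (default 0.3).
#' @param ph_params per-region pH process settings: list of lists with
#'   `mean`, `reversion_per_h`, `volatility`, `floor`, `ceiling`.
#' @param gi_grid_h,plasma_grid_h sampling grids, h.
#' @param noise_cv proportional observation-noise CV (default 0.10).
#' @param loq_ug_per_ml lower limit of quantification; observations below
#'   it are reported as 0 (default 0.32 ug/mL).
#' @param ph_dt_h pH process step, h (default 5 min).
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 20L, seed = 1L, dose = 8e5,
                          tmmc_median_h = 2.04, tmmc_gsd = 1.4,
                          param_medians = list(
                            Kempt = 0.18, K_TD = 0.47, K_TJ = 0.081,
                            K_Diss = 1.52e-3, V1 = 123.24, V2 = 49.99,
                            Kel = 0.35, V3 = 1e4),
                          param_cv = 0.3,
                          ph_params = list(
                            duodenum = list(mean = 6.0, reversion_per_h = 2,
                                            volatility = 1.0, floor = 4.0,
                                            ceiling = 7.0),
                            jejunum = list(mean = 6.6, reversion_per_h = 2,
                                           volatility = 1.0, floor = 4.5,
                                           ceiling = 7.5)),
                          gi_grid_h = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 2.5,
                                        3, 4, 5, 6, 7),
                          plasma_grid_h = c(0, 0.167, 0.33, 0.5, 0.75, 1,
                                            1.5, 2, 2.5, 3, 4, 5, 6, 7, 8,
                                            12, 28),
                          noise_cv = 0.10, loq_ug_per_ml = 0.32,
                          ph_dt_h = 1 / 12) {
  stopifnot(n_subjects >= 0, dose > 0, tmmc_median_h > 0, tmmc_gsd >= 1,
            param_cv >= 0, noise_cv >= 0)
  if (is.unsorted(gi_grid_h) || is.unsorted(plasma_grid_h)) {
    stop("sampling grids must be sorted")
  }
  if (any(unlist(param_medians) <= 0)) stop("parameter medians must be > 0")
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 dose = dose, tmmc_median_h = tmmc_median_h,
                 tmmc_gsd = tmmc_gsd, param_medians = param_medians,
                 param_cv = param_cv, ph_params = ph_params,
                 gi_grid_h = gi_grid_h, plasma_grid_h = plasma_grid_h,
                 noise_cv = noise_cv, loq_ug_per_ml = loq_ug_per_ml,
                 ph_dt_h = ph_dt_h),
            class = "cohort_config")
}

# Mean-reverting random walk on a fixed grid, clipped to bounds.
ou_ph_series <- function(t_end_h, dt_h, mean, reversion_per_h, volatility,
                         floor, ceiling) {
  tt <- seq(0, t_end_h, by = dt_h)
  n <- length(tt)
  ph <- numeric(n)
  ph[1L] <- min(max(stats::rnorm(1, mean, volatility / sqrt(2 * reversion_per_h)),
                    floor), ceiling)
  for (i in seq_len(n - 1L)) {
    step <- reversion_per_h * (mean - ph[i]) * dt_h +
      volatility * sqrt(dt_h) * stats::rnorm(1)
    ph[i + 1L] <- min(max(ph[i] + step, floor), ceiling)
  }
  data.frame(time_h = tt, pH = ph)
}

rlnorm_median <- function(n, median, cv) {
  if (cv == 0) return(rep(median, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

#' Generate one virtual subject
#'
#' Draws the subject's physiology and true model parameters, simulates
#' the noise-free pH-aware six-state model on the union of the sampling
#' grids, and applies proportional lognormal observation noise with
#' below-LOQ values reported as zero. Deterministic per
#' `(config$seed, index)`.
#'
#' @param config a [cohort_config()].
#' @param index subject index (1-based).
#' @param solubility an [acid_solubility_profile()] (default ibuprofen).
#' @return list with `subject` (id string), `physiology`
#'   ([subject_physiology()]), `true_params` ([gis_parameters()]),
#'   `truth` (noise-free `gis_trajectory`), and `dataset`
#'   ([concentration_dataset()] of noisy observations).
#' @export
generate_subject <- function(config, index,
                             solubility = ibuprofen_solubility_profile()) {
  stopifnot(inherits(config, "cohort_config"), index >= 1)
  set.seed(config$seed + 7919L * as.integer(index))
  pm <- config$param_medians
  cv <- config$param_cv
  draw <- function(name) rlnorm_median(1, pm[[name]], cv)
  tmmc <- stats::rlnorm(1, log(config$tmmc_median_h), log(config$tmmc_gsd))
  t_end <- max(config$plasma_grid_h)
  ph_end <- max(config$gi_grid_h)
  pd <- config$ph_params$duodenum
  pj <- config$ph_params$jejunum
  ph_duo <- ou_ph_series(ph_end, config$ph_dt_h, pd$mean, pd$reversion_per_h,
                         pd$volatility, pd$floor, pd$ceiling)
  ph_jej <- ou_ph_series(ph_end, config$ph_dt_h, pj$mean, pj$reversion_per_h,
                         pj$volatility, pj$floor, pj$ceiling)
  phys <- subject_physiology(
    TMMC = tmmc, pH_duodenum = ph_duo, pH_jejunum = ph_jej,
    V1 = draw("V1"), V2 = draw("V2"), Kel = draw("Kel"), V3 = draw("V3")
  )
  true_params <- gis_parameters(
    Kempt = draw("Kempt"), K_TD = draw("K_TD"), K_TJ = draw("K_TJ"),
    K_Diss = draw("K_Diss")
  )
  t_grid <- sort(unique(c(0, config$gi_grid_h, config$plasma_grid_h)))
  truth <- simulate_gis(true_params, phys, config$dose, t_grid,
                        solubility = solubility)
  noisy_stream <- function(region, col, grid) {
    clean <- stats::approx(truth$time_h, truth[[col]], xout = grid)$y
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      obs <- clean * stats::rlnorm(length(clean), 0, sdlog)
    } else {
      obs <- clean
    }
    obs[obs < config$loq_ug_per_ml] <- 0
    data.frame(subject = sprintf("S%03d", as.integer(index)),
               region = region, time_h = grid, conc_ug_per_ml = obs)
  }
  records <- rbind(
    noisy_stream("duodenum", "C_duodenum", config$gi_grid_h),
    noisy_stream("jejunum", "C_jejunum", config$gi_grid_h),
    noisy_stream("plasma", "C_plasma", config$plasma_grid_h)
  )
  list(subject = sprintf("S%03d", as.integer(index)),
       physiology = phys, true_params = true_params, truth = truth,
       dataset = concentration_dataset(records, config$dose))
}

#' Generate a virtual cohort with a manifest
#'
#' Generates `config$n_subjects` independent subjects plus, optionally,
#' duplicate visits for the first `n_duplicate_visits` subjects (same
#' subject id, an independent occasion draw) — mirroring a crossover-like
#' study shape in which a subset of volunteers participates twice.
#'
#' @param config a [cohort_config()].
#' @param n_duplicate_visits number of subjects receiving a second visit
#'   (default 0).
#' @param solubility an [acid_solubility_profile()].
#' @return list of class `cohort_bundle`: `subjects` (list of
#'   [generate_subject()] outputs), `manifest` (list with the config,
#'   seed, package version and per-visit ids).
#' @export
generate_cohort <- function(config, n_duplicate_visits = 0L,
                            solubility = ibuprofen_solubility_profile()) {
  stopifnot(inherits(config, "cohort_config"),
            n_duplicate_visits <= config$n_subjects)
  idx <- seq_len(config$n_subjects)
  subjects <- lapply(idx, generate_subject, config = config,
                     solubility = solubility)
  visits <- rep(1L, length(subjects))
  if (n_duplicate_visits > 0L) {
    extra <- lapply(seq_len(n_duplicate_visits), function(i) {
      s <- generate_subject(config, config$n_subjects + i,
                            solubility = solubility)
      s$subject <- sprintf("S%03d", i)  # same volunteer, second occasion
      s$dataset$records$subject <- s$subject
      s
    })
    subjects <- c(subjects, extra)
    visits <- c(visits, rep(2L, n_duplicate_visits))
  }
  manifest <- list(
    generator = "pbbm::generate_cohort",
    package_version = as.character(utils::packageVersion("pbbm")),
    seed = config$seed,
    n_subjects = config$n_subjects,
    n_duplicate_visits = as.integer(n_duplicate_visits),
    subject_ids = vapply(subjects, `[[`, "", "subject"),
    visit = visits,
    config = config[setdiff(names(config), "ph_params")],
    note = paste("pH fluctuation scale is a configured emulation of",
                 "low-buffer-capacity luminal pH, not a measured trace")
  )
  structure(list(subjects = subjects, manifest = manifest),
            class = "cohort_bundle")
}

#' Generate a synthetic manometry trace with labeled MMC phases
#'
#' Builds a two-channel (antral + duodenal) pressure trace for one
#' subject: baseline quiescence (phase I), sporadic phase-II
#' contractions, and a phase-III burst starting at the subject's TMMC —
#' antral contractions at 2-3/min averaging 75 mmHg, duodenal
#' contractions at 11-12/min averaging 33 mmHg. Segment labels are
#' returned alongside the trace.
#'
#' @param config a [cohort_config()] (supplies the seed).
#' @param subject a [generate_subject()] output (supplies TMMC), or a
#'   list with `physiology$TMMC`.
#' @param sampling_rate_hz sampling rate (default 2 Hz).
#' @param duration_h trace length from dose; default TMMC + 1 h.
#' @param noise_sd_mmHg baseline pressure noise (default 2 mmHg).
#' @param phase3_duration_min duodenal phase-III duration (default 5 min).
#' @return list with `trace` (a [manometry_trace()]) and `labels`
#'   (data.frame `start_h`, `end_h`, `region`, `phase`).
#' @export
generate_manometry <- function(config, subject, sampling_rate_hz = 2,
                               duration_h = NULL, noise_sd_mmHg = 2,
                               phase3_duration_min = 5) {
  stopifnot(inherits(config, "cohort_config"))
  tmmc <- subject$physiology$TMMC
  if (is.null(duration_h)) duration_h <- tmmc + 1
  set.seed(config$seed + 104729L +
             7919L * as.integer(gsub("\\D", "", subject$subject)))
  fs <- sampling_rate_hz
  n <- round(duration_h * 3600 * fs)
  tt_h <- (seq_len(n) - 1L) / fs / 3600

  burst <- function(n_samp, freq_per_min, amplitude) {
    # rectified sinusoid contraction train with slight cycle jitter
    tt <- seq_len(n_samp) / fs
    f_hz <- freq_per_min / 60
    phase <- 2 * pi * f_hz * tt + 0.3 * sin(2 * pi * 0.01 * tt)
    amplitude * pmax(sin(phase), 0)^2
  }
  make_channel <- function(region) {
    x <- stats::rnorm(n, 0, noise_sd_mmHg)
    # sporadic phase-II contractions: isolated random spikes
    n_spikes <- stats::rpois(1, duration_h * 20)
    if (n_spikes > 0) {
      at <- sample.int(n - 2 * fs, n_spikes, replace = TRUE)
      for (s in at) {
        span <- s:(s + round(2 * fs))
        x[span] <- x[span] + 25 * pmax(sin(seq(0, pi, length.out = length(span))), 0)
      }
    }
    # phase III burst at TMMC
    p3 <- if (region == "duodenum") {
      list(freq = stats::runif(1, 11, 12), amp = 33,
           dur = phase3_duration_min * 60)
    } else {
      list(freq = stats::runif(1, 2, 3), amp = 75,
           dur = max(3, phase3_duration_min - 1) * 60)
    }
    i0 <- round(tmmc * 3600 * fs) + 1L
    i1 <- min(n, i0 + round(p3$dur * fs) - 1L)
    if (i0 < n) {
      x[i0:i1] <- x[i0:i1] + burst(i1 - i0 + 1L, p3$freq, p3$amp)
    }
    list(x = x, end_h = (i1 - 1L) / fs / 3600)
  }
  ant <- make_channel("antrum")
  duo <- make_channel("duodenum")
  trace <- manometry_trace(
    fs, data.frame(antrum_1 = ant$x, duodenum_1 = duo$x),
    regions = c("antrum", "duodenum"), dose_time_h = 0
  )
  labels <- data.frame(
    start_h = c(tmmc, tmmc),
    end_h = c(ant$end_h, duo$end_h),
    region = c("antrum", "duodenum"),
    phase = "III"
  )
  list(trace = trace, labels = labels)
}

#' Generate time-varying compartment schedules for one subject
#'
#' Emulates the 15-min resolution dynamic fluid-volume/pH description of
#' the GI tract: every compartment receives entries every 15 min over
#' 0-7 h (29 entries), with volumes following a clipped mean-reverting
#' walk around the static default volume and pH around the static
#' default pH. Values are plausible emulations, not measured traces.
#'
#' @param config a [cohort_config()] (supplies the seed).
#' @param subject subject index or a [generate_subject()] output.
#' @param volume_cv relative volatility of the volume walk (default 0.25).
#' @param t_end_h schedule horizon, h (default 7).
#' @param dt_h stamp interval, h (default 0.25).
#' @return named list of nine [compartment_schedule()]s.
#' @export
generate_dynamic_schedules <- function(config, subject, volume_cv = 0.25,
                                       t_end_h = 7, dt_h = 0.25) {
  stopifnot(inherits(config, "cohort_config"))
  idx <- if (is.list(subject)) {
    as.integer(gsub("\\D", "", subject$subject))
  } else {
    as.integer(subject)
  }
  set.seed(config$seed + 224737L + 7919L * idx)
  base <- acat_default_table()
  tt <- seq(0, t_end_h, by = dt_h)
  scheds <- lapply(seq_len(nrow(base)), function(i) {
    v0 <- base$volume_ml[i]
    ph0 <- base$pH[i]
    vol <- numeric(length(tt)); vol[1L] <- v0
    ph <- numeric(length(tt)); ph[1L] <- ph0
    for (k in seq_len(length(tt) - 1L)) {
      vol[k + 1L] <- max(v0 * 0.2,
                         vol[k] + 2 * (v0 - vol[k]) * dt_h +
                           volume_cv * v0 * sqrt(dt_h) * stats::rnorm(1))
      ph[k + 1L] <- min(max(ph[k] + 2 * (ph0 - ph[k]) * dt_h +
                              0.4 * sqrt(dt_h) * stats::rnorm(1),
                            max(0.5, ph0 - 1.5)), ph0 + 1.5)
    }
    compartment_schedule(base$compartment[i],
                         data.frame(time_h = tt, volume_ml = vol, pH = ph),
                         base$transit_time_h[i])
  })
  names(scheds) <- base$compartment
  scheds
}
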