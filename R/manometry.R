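#' Multi-channel manometry pressure trace
#'
#' Water-perfused manometry recordings from which migrating-motor-complex
#' (MMC) phase-III windows and the post-dose phase-III onset time (TMMC)
#' are extracted. Channels are equal-length pressure series (mmHg) at a
#' fixed sampling rate, each labeled with the GI region it monitors.
#'
#' @param sampling_rate_hz samples per second (>= 1).
#' @param pressures data.frame or matrix of pressure series, one column
#'   per channel, mmHg.
#' @param regions character vector, one region label per channel
#'   (e.g. `"antrum"`, `"duodenum"`).
#' @param dose_time_h time of dose administration on the trace clock, h.
#' @return an object of class `manometry_trace`.
#' @export
manometry_trace <- function(sampling_rate_hz, pressures, regions,
                            dose_time_h = 0) {
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz < 1) {
    stop("`sampling_rate_hz` must be >= 1")
  }
  pressures <- as.data.frame(pressures)
  if (length(regions) != ncol(pressures)) {
    stop("`regions` must label every channel")
  }
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 pressures = pressures,
                 regions = as.character(regions),
                 dose_time_h = dose_time_h,
                 n_samples = nrow(pressures)),
            class = "manometry_trace")
}

#' Fraction of spectral energy in a cycles-per-minute band
#'
#' Phase-III contractile bursts concentrate spectral power near
#' 10-12 cycles/min, so the proportion of (mean-removed) power in the
#' 9-12 cycles/min band is the key discriminating feature. The spectrum
#' is a smoothed periodogram (modified Daniell smoother) of the demeaned,
#' detrended window.
#'
#' @param window numeric vector of pressure samples (>= 2 min of data).
#' @param sampling_rate_hz sampling rate, Hz.
#' @param band frequency band in cycles/min (default `c(9, 12)`).
#' @return fraction in \[0, 1\]; a constant window returns 0.
#' @export
band_energy_fraction <- function(window, sampling_rate_hz,
                                 band = c(9, 12)) {
  stopifnot(is.numeric(window), length(band) == 2L)
  if (length(window) < 2 * 60 * sampling_rate_hz) {
    stop("window must contain at least 2 min of samples")
  }
  if (stats::sd(window) == 0) return(0)
  sp <- stats::spec.pgram(stats::ts(window, frequency = sampling_rate_hz),
                          spans = c(3, 3), taper = 0.1, detrend = TRUE,
                          plot = FALSE)
  f_hz <- sp$freq  # cycles per second given ts frequency
  band_hz <- band / 60
  in_band <- f_hz >= band_hz[1L] & f_hz <= band_hz[2L]
  sum(sp$spec[in_band]) / sum(sp$spec)
}

# threshold-crossing peak detection on a demeaned window: local maxima
# exceeding `threshold` mmHg above the window median.
detect_contractions <- function(window, threshold = 10) {
  x <- window - stats::median(window)
  n <- length(x)
  if (n < 3L) return(integer(0))
  peaks <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                   x[2:(n - 1L)] >= x[3:n] &
                   x[2:(n - 1L)] > threshold) + 1L
  if (length(peaks) <= 1L) return(peaks)
  # collapse plateaus/ripples closer than 1 s
  keep <- c(TRUE, diff(peaks) > 1)
  peaks[keep]
}

#' Sliding-window motility features
#'
#' Cuts each channel into overlapping windows and computes, per window:
#' the 9-12 cycles/min band-energy fraction, the contraction rate
#' (threshold-crossing peaks per minute), the mean contraction amplitude
#' (mmHg above the window median), and the log mean rectified amplitude.
#'
#' @param trace a [manometry_trace()].
#' @param window_min window length, minutes (default 2).
#' @param hop_min hop between window starts, minutes (default 0.5).
#' @param peak_threshold_mmHg contraction detection threshold (default 10).
#' @return data.frame with one row per (channel, window): `channel`,
#'   `region`, `t_start_h`, `t_mid_h`, `band_fraction`,
#'   `contractions_per_min`, `mean_amplitude_mmHg`, `log_rect_amplitude`.
#' @export
extract_features <- function(trace, window_min = 2, hop_min = 0.5,
                             peak_threshold_mmHg = 10) {
  stopifnot(inherits(trace, "manometry_trace"))
  fs <- trace$sampling_rate_hz
  wlen <- round(window_min * 60 * fs)
  hop <- round(hop_min * 60 * fs)
  n <- trace$n_samples
  if (n < wlen) stop("trace shorter than one window")
  starts <- seq(1L, n - wlen + 1L, by = hop)
  out <- lapply(seq_along(trace$pressures), function(j) {
    x <- trace$pressures[[j]]
    rows <- lapply(starts, function(s) {
      w <- x[s:(s + wlen - 1L)]
      pk <- detect_contractions(w, peak_threshold_mmHg)
      amp <- if (length(pk)) mean(w[pk] - stats::median(w)) else 0
      data.frame(
        channel = names(trace$pressures)[j],
        region = trace$regions[j],
        t_start_h = (s - 1L) / fs / 3600,
        t_mid_h = (s - 1L + wlen / 2) / fs / 3600,
        band_fraction = band_energy_fraction(w, fs),
        contractions_per_min = length(pk) / window_min,
        mean_amplitude_mmHg = amp,
        log_rect_amplitude = log(mean(abs(w - mean(w))) + 1e-6)
      )
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

phase3_feature_names <- c("band_fraction", "contractions_per_min",
                          "log_rect_amplitude")

#' Train the penalized logistic phase-III classifier
#'
#' L2 (ridge) penalized logistic regression of the window label
#' (phase III or not) on the spectral band fraction, contraction rate and
#' log rectified amplitude. The fit is deterministic given the data and
#' penalty; as the penalty grows the weights shrink to zero and predicted
#' probabilities collapse to the class prevalence.
#'
#' @param features a feature table from [extract_features()] with an
#'   added logical/0-1 column `phase3`.
#' @param l2_penalty ridge penalty (glmnet `lambda`; default 1e-2).
#' @return an object of class `phase3_classifier` holding the weight
#'   vector.
#' @export
train_phase3_classifier <- function(features, l2_penalty = 1e-2) {
  stopifnot(is.data.frame(features), "phase3" %in% names(features),
            all(phase3_feature_names %in% names(features)))
  y <- as.numeric(features$phase3)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  x <- as.matrix(features[, phase3_feature_names])
  # glmnet is fitted along a decreasing penalty path ending at the
  # requested lambda (single-lambda fits of near-separable data do not
  # converge reliably)
  path <- exp(seq(log(max(50, l2_penalty * 10)), log(l2_penalty),
                  length.out = 50))
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = path, standardize = TRUE, maxit = 1e6)
  w <- as.numeric(stats::coef(fit, s = l2_penalty))
  names(w) <- c("(Intercept)", phase3_feature_names)
  structure(list(weights = w, l2_penalty = l2_penalty),
            class = "phase3_classifier")
}

#' Predict phase-III probabilities for feature windows
#' @param classifier a [train_phase3_classifier()] result.
#' @param features a feature table from [extract_features()].
#' @return numeric vector of probabilities.
#' @export
predict_phase3 <- function(classifier, features) {
  stopifnot(inherits(classifier, "phase3_classifier"))
  x <- as.matrix(features[, phase3_feature_names])
  eta <- classifier$weights[1L] + x %*% classifier$weights[-1L]
  as.numeric(stats::plogis(eta))
}

#' Detect phase-III windows and the post-dose onset time
#'
#' Scores every feature window with the classifier, keeps windows above
#' the probability threshold, merges overlapping/adjacent windows into
#' intervals per region (taking the maximum probability across that
#' region's channels), discards intervals shorter than the regional
#' minimum duration (antral bursts must persist two minutes or more, duodenal
#' three minutes or more), and reports TMMC as the start of the first retained
#' interval after the dose time.
#'
#' @param trace a [manometry_trace()].
#' @param classifier a [train_phase3_classifier()] result.
#' @param prob_threshold probability cutoff (default 0.5).
#' @param min_duration_min named vector of minimum durations (minutes)
#'   per region; unnamed regions fall back to 2 min.
#' @param window_min,hop_min passed to [extract_features()].
#' @return an object of class `phase3_call`: list with `intervals`
#'   (data.frame `start_h`, `end_h`, `region`), `TMMC` (h, `NA` with a
#'   flag when no post-dose interval exists), and `probabilities`.
#' @export
detect_phase3 <- function(trace, classifier, prob_threshold = 0.5,
                          min_duration_min = c(antrum = 2, duodenum = 3),
                          window_min = 2, hop_min = 0.5) {
  stopifnot(inherits(trace, "manometry_trace"))
  feats <- extract_features(trace, window_min = window_min,
                            hop_min = hop_min)
  feats$prob <- predict_phase3(classifier, feats)
  intervals <- list()
  for (rg in unique(feats$region)) {
    fr <- feats[feats$region == rg, ]
    # max probability across the region's channels per window; windows
    # are attributed at their midpoints, so a run of hot windows maps to
    # the stretch of trace their centers cover
    agg <- stats::aggregate(prob ~ t_mid_h, data = fr, FUN = max)
    agg <- agg[order(agg$t_mid_h), ]
    hot <- agg$prob >= prob_threshold
    if (!any(hot)) next
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s_h <- agg$t_mid_h[starts[k]]
      e_h <- agg$t_mid_h[ends[k]] + hop_min / 60
      min_d <- if (rg %in% names(min_duration_min)) {
        min_duration_min[[rg]]
      } else 2
      if ((e_h - s_h) * 60 >= min_d) {
        intervals[[length(intervals) + 1L]] <-
          data.frame(start_h = s_h, end_h = e_h, region = rg)
      }
    }
  }
  intervals <- if (length(intervals)) {
    do.call(rbind, intervals)
  } else {
    data.frame(start_h = numeric(0), end_h = numeric(0),
               region = character(0))
  }
  post <- intervals[intervals$start_h >= trace$dose_time_h, , drop = FALSE]
  flags <- character(0)
  tmmc <- NA_real_
  if (nrow(post)) {
    tmmc <- min(post$start_h) - trace$dose_time_h
  } else {
    flags <- c(flags, "no post-dose phase-III interval found")
  }
  structure(list(intervals = intervals, TMMC = tmmc,
                 probabilities = feats[, c("channel", "region", "t_start_h",
                                           "t_mid_h", "prob")],
                 flags = flags),
            class = "phase3_call")
}

#' @export
print.phase3_call <- function(x, ...) {
  cat(sprintf("<phase3_call> %d interval(s), TMMC %.3g h\n",
              nrow(x$intervals), x$TMMC))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
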