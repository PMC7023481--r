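stop_at_row <- function(file, rows, what) {
  stop(sprintf("%s: %s at row(s) %s", file, what,
               paste(utils::head(rows, 5L), collapse = ", ")),
       call. = FALSE)
}

#' Read / write tidy concentration tables
#'
#' The package-wide concentration format: columns `subject`, `region`
#' (duodenum/jejunum/plasma), `time_h`, `conc_ug_per_ml`. Units are fixed
#' by the column names (hours; micrograms per millilitre). Validation
#' reports the offending row numbers; a write followed by a read is the
#' identity.
#'
#' @param path CSV file path.
#' @return data.frame of validated records.
#' @export
read_concentration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "region", "time_h", "conc_ug_per_ml")
  if (!all(need %in% names(df))) {
    stop(path, ": missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  bad <- which(!df$region %in% c("duodenum", "jejunum", "plasma"))
  if (length(bad)) stop_at_row(path, bad, "unknown region")
  bad <- which(!is.finite(df$time_h) | df$time_h < 0)
  if (length(bad)) stop_at_row(path, bad, "invalid time_h")
  bad <- which(!is.finite(df$conc_ug_per_ml) | df$conc_ug_per_ml < 0)
  if (length(bad)) stop_at_row(path, bad, "negative or missing concentration")
  for (key in split(seq_len(nrow(df)), paste(df$subject, df$region))) {
    if (is.unsorted(df$time_h[key], strictly = FALSE)) {
      stop_at_row(path, key[1L], "unsorted times within subject/region")
    }
  }
  df[, need]
}

#' @rdname read_concentration_csv
#' @param records data.frame with the concentration columns.
#' @export
write_concentration_csv <- function(records, path) {
  need <- c("subject", "region", "time_h", "conc_ug_per_ml")
  stopifnot(all(need %in% names(records)))
  utils::write.csv(records[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write per-subject physiology tables
#'
#' Two companion CSVs: a scalar table (`subject`, `TMMC_h`, `V1_ml`,
#' `V2_ml`, `Kel_1h`, `V3_ml`) and a pH observation table (`subject`,
#' `region`, `time_h`, `pH`).
#'
#' @param scalar_path,ph_path file paths.
#' @return named list of [subject_physiology()] objects keyed by subject.
#' @export
read_physiology_csv <- function(scalar_path, ph_path) {
  sc <- utils::read.csv(scalar_path, stringsAsFactors = FALSE)
  need <- c("subject", "TMMC_h", "V1_ml", "V2_ml", "Kel_1h", "V3_ml")
  if (!all(need %in% names(sc))) {
    stop(scalar_path, ": missing column(s): ",
         paste(setdiff(need, names(sc)), collapse = ", "), call. = FALSE)
  }
  ph <- utils::read.csv(ph_path, stringsAsFactors = FALSE)
  need_ph <- c("subject", "region", "time_h", "pH")
  if (!all(need_ph %in% names(ph))) {
    stop(ph_path, ": missing column(s): ",
         paste(setdiff(need_ph, names(ph)), collapse = ", "), call. = FALSE)
  }
  bad <- which(ph$pH <= 0 | ph$pH >= 14)
  if (length(bad)) stop_at_row(ph_path, bad, "pH out of (0, 14)")
  out <- lapply(seq_len(nrow(sc)), function(i) {
    sid <- sc$subject[i]
    series <- function(rg) {
      d <- ph[ph$subject == sid & ph$region == rg,
              c("time_h", "pH"), drop = FALSE]
      if (nrow(d) == 0L) return(NULL)
      d[order(d$time_h), ]
    }
    subject_physiology(TMMC = sc$TMMC_h[i],
                       pH_duodenum = series("duodenum"),
                       pH_jejunum = series("jejunum"),
                       V1 = sc$V1_ml[i], V2 = sc$V2_ml[i],
                       Kel = sc$Kel_1h[i], V3 = sc$V3_ml[i])
  })
  names(out) <- sc$subject
  out
}

#' @rdname read_physiology_csv
#' @param subjects named list of [subject_physiology()] objects.
#' @export
write_physiology_csv <- function(subjects, scalar_path, ph_path) {
  sc <- do.call(rbind, lapply(names(subjects), function(sid) {
    p <- subjects[[sid]]
    data.frame(subject = sid, TMMC_h = p$TMMC, V1_ml = p$V1, V2_ml = p$V2,
               Kel_1h = p$Kel, V3_ml = p$V3)
  }))
  ph <- do.call(rbind, lapply(names(subjects), function(sid) {
    p <- subjects[[sid]]
    rbind(
      if (!is.null(p$pH_duodenum)) {
        data.frame(subject = sid, region = "duodenum", p$pH_duodenum)
      },
      if (!is.null(p$pH_jejunum)) {
        data.frame(subject = sid, region = "jejunum", p$pH_jejunum)
      }
    )
  }))
  utils::write.csv(sc, scalar_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(ph, ph_path, row.names = FALSE, quote = FALSE)
  invisible(c(scalar_path, ph_path))
}

#' Read / write compartment schedule tables
#'
#' The CSV analogue of per-compartment physiology files: columns
#' `compartment`, `time_h`, `volume_ml`, `pH`, `transit_time_h` (the
#' transit time is repeated on each of a compartment's rows).
#'
#' @param path CSV file path.
#' @return named list of [compartment_schedule()]s.
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compartment", "time_h", "volume_ml", "pH", "transit_time_h")
  if (!all(need %in% names(df))) {
    stop(path, ": missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$volume_ml) | df$volume_ml <= 0)
  if (length(bad)) stop_at_row(path, bad, "non-positive volume")
  out <- lapply(split(df, df$compartment), function(d) {
    d <- d[order(d$time_h), ]
    compartment_schedule(d$compartment[1L],
                         d[, c("time_h", "volume_ml", "pH")],
                         d$transit_time_h[1L])
  })
  out[intersect(acat_compartments, names(out))]
}

#' @rdname read_schedule_csv
#' @param schedules named list of [compartment_schedule()]s.
#' @export
write_schedule_csv <- function(schedules, path) {
  df <- do.call(rbind, lapply(schedules, function(s) {
    data.frame(compartment = s$compartment, s$entries,
               transit_time_h = s$transit_time)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a JSON analysis configuration
#'
#' Validated JSON configuration; the `solubility` block (`s0_ug_per_ml`,
#' `pka`, optional `cap`, optional `anchor {pH, s_ug_per_ml}`) is
#' converted to an [acid_solubility_profile()] — an anchor, when present,
#' takes precedence and `s0_ug_per_ml` is recomputed from it.
#'
#' @param path JSON file path.
#' @return list; element `solubility` is an `acid_solubility_profile`
#'   when the key is present.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(cfg$solubility)) {
    s <- cfg$solubility
    if (is.null(s$pka)) stop(path, ": solubility block needs `pka`")
    cfg$solubility <- if (!is.null(s$anchor)) {
      anchor_intrinsic_solubility(s$anchor$s_ug_per_ml, s$anchor$pH,
                                  s$pka, cap = s$cap)
    } else {
      if (is.null(s$s0_ug_per_ml)) {
        stop(path, ": solubility block needs `s0_ug_per_ml` or `anchor`")
      }
      acid_solubility_profile(s$s0_ug_per_ml, s$pka, cap = s$cap)
    }
  }
  cfg
}

#' Run manifest for reproducible execution
#'
#' Captures everything needed to re-execute a run bit-identically on the
#' same platform: the command name, a hash of the configuration, the
#' seed, input file checksums, the package version and a timestamp.
#'
#' @param command name of the operation performed.
#' @param config the configuration object used (hashed into the record).
#' @param seed integer seed of the run.
#' @param input_paths character vector of input files (checksummed).
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(command, config = NULL, seed = NA_integer_,
                         input_paths = character(0)) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  sums <- if (length(input_paths)) tools::md5sum(input_paths) else character(0)
  structure(list(
    command = command,
    config_hash = as.character(tools::md5sum(
      local({
        f <- tempfile()
        writeLines(cfg_json, f)
        f
      })
    )),
    seed = seed,
    inputs = data.frame(path = names(sums), md5 = unname(sums),
                        stringsAsFactors = FALSE),
    package_version = as.character(utils::packageVersion("pbbm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reference fitted parameters of the pH-aware model
#'
#' The published per-subject fitted parameter values of the pH-aware
#' six-state model for the 19 fasted-state visits of the reference
#' cohort (columns `Kempt`, `K_TD`, `K_TJ` in 1/h, `K_Diss` in
#' mL/(ug h), `V1`, `V2` in mL), packaged as a fixture for summary-table
#' recomputation and as truth anchors for the synthetic generator.
#'
#' @return data.frame, one row per subject visit.
#' @export
gisplus_reference_parameters <- function() {
  path <- system.file("extdata", "gisplus_fitted_parameters.csv",
                      package = "pbbm", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cohort parameter report in the standard layout
#'
#' Formats per-subject fitted parameters as the conventional cohort
#' table: Average, SD, CV% rows, the individual rows ordered by subject
#' id, and a Median row.
#'
#' @param per_subject data.frame with a `subject` column and parameter
#'   columns.
#' @return data.frame with a leading `row` label column; with zero
#'   subjects, the header-only frame.
#' @export
format_parameter_table <- function(per_subject) {
  stopifnot(is.data.frame(per_subject), "subject" %in% names(per_subject))
  pcols <- setdiff(names(per_subject), "subject")
  if (nrow(per_subject) == 0L) {
    out <- per_subject
    names(out)[names(out) == "subject"] <- "row"
    return(out)
  }
  per_subject <- per_subject[order(per_subject$subject), , drop = FALSE]
  s <- summarize_parameters(per_subject[, pcols, drop = FALSE])
  head_rows <- data.frame(row = c("Average", "SD", "CV%"),
                          rbind(s["mean", ], s["sd", ], s["cv_pct", ]))
  ind_rows <- data.frame(row = per_subject$subject,
                         per_subject[, pcols, drop = FALSE])
  med_row <- data.frame(row = "Median", s["median", , drop = FALSE])
  out <- rbind(head_rows, ind_rows, med_row)
  rownames(out) <- NULL
  out
}

#' Volumetric flow equivalent of a fluid volume over a duration
#'
#' Converts a total fluid volume encountered over a period into the
#' constant volumetric flow that would deliver it — used to translate
#' fitted average luminal volumes into a transfer-rate setting for a
#' multi-compartment dissolution apparatus (e.g. 220 mL over 8 h is
#' ~0.5 mL/min).
#'
#' @param volume_ml total volume, mL.
#' @param duration_h period, h.
#' @return flow in mL/min.
#' @export
flow_rate_ml_per_min <- function(volume_ml, duration_h) {
  stopifnot(volume_ml >= 0, duration_h > 0)
  volume_ml / (duration_h * 60)
}
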