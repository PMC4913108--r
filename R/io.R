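#' Write a session to disk as CSV time series plus a JSON sidecar
#'
#' Layout: `eeg.csv` (column 1 `time_s`, one column per channel),
#' `nirs.csv` (`time_s`, `left`, `right`), and `session.json` carrying the
#' schedule, the ground-truth record (for synthetic sessions) and the
#' generating configuration.
#'
#' @param session An `nvc_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_exact(session$eeg, file.path(dir, "eeg.csv"))
  write_csv_exact(session$nirs, file.path(dir, "nirs.csv"))
  sidecar <- list(schedule = session$schedule, truth = session$truth,
                  config = unclass(session$config))
  jsonlite::write_json(sidecar, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

# CSV writer that preserves doubles exactly ("%.17g" always round-trips).
write_csv_exact <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  lines <- do.call(paste, c(cols, sep = ","))
  writeLines(c(paste(names(df), collapse = ","), lines), path)
}

read_timeseries_csv <- function(path) {
  # fread parses doubles with correct rounding, so written sessions read
  # back bit-identically; warnings (truncated rows, ragged fields) are
  # promoted to parse errors naming the file.
  tb <- withCallingHandlers(
    tryCatch(
      data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE),
      error = function(e) {
        abort(sprintf("failed to parse %s: %s", path, conditionMessage(e)),
              class = "nvc_parse_error")
      }),
    warning = function(w) {
      abort(sprintf("malformed CSV %s: %s", path, conditionMessage(w)),
            class = "nvc_parse_error")
    })
  if (names(tb)[1] != "time_s") {
    abort(sprintf("%s: first column must be 'time_s'", path),
          class = "nvc_parse_error")
  }
  tibble::as_tibble(tb)
}

#' Read a session written by [write_session()]
#'
#' Validates sample counts against the declared rates and schedule times
#' against the recording span; malformed files raise descriptive parse
#' errors naming the file and line.
#'
#' @param dir Directory containing `eeg.csv`, `nirs.csv`, `session.json`.
#' @return An `nvc_session`.
#' @export
read_session <- function(dir) {
  paths <- file.path(dir, c("eeg.csv", "nirs.csv", "session.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("missing session file(s): ", paste(missing, collapse = ", ")),
          class = "nvc_parse_error")
  }
  eeg <- read_timeseries_csv(paths[1])
  nirs <- read_timeseries_csv(paths[2])
  side <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  schedule <- tibble::as_tibble(side$schedule)
  cfg <- side$config
  if (!is.null(cfg)) {
    for (f in c("planted_lag", "coupling_onset_trial")) {
      cfg[[f]] <- unlist(cfg[[f]])
    }
    cfg$artifact_trials <- as.integer(unlist(cfg$artifact_trials))
    class(cfg) <- "nvc_session_config"
    for (rate_field in list(c("eeg_rate", "eeg"), c("nirs_rate", "nirs"))) {
      rate <- cfg[[rate_field[1]]]
      tb <- if (rate_field[2] == "eeg") eeg else nirs
      span <- tb$time_s[nrow(tb)] - tb$time_s[1] + 1 / rate
      if (abs(nrow(tb) - span * rate) > 0.5) {
        abort(sprintf("%s.csv: %d samples inconsistent with %g Hz over %g s",
                      rate_field[2], nrow(tb), rate, span),
              class = "nvc_parse_error")
      }
    }
  }
  t_end <- max(eeg$time_s)
  if (any(schedule$off_end - 1 > t_end + 1e-9)) {
    abort("schedule extends beyond the recording span.",
          class = "nvc_parse_error")
  }
  truth <- side$truth
  if (!is.null(truth)) {
    for (f in c("planted_lag", "coupling_onset_trial")) {
      truth[[f]] <- unlist(truth[[f]])
    }
  }
  structure(list(eeg = eeg, nirs = nirs, schedule = schedule,
                 truth = truth, config = cfg),
            class = "nvc_session")
}

#' Write correlograms to a tidy CSV
#'
#' Columns: `trial`, `hemisphere`, `hemi_trial`, `pair_index`, `imf_nirs`,
#' `imf_eeg`, `lag_s`, `r`, `r_thresholded`, `bound`, `n`.
#'
#' @param ccgs Output of [analyze_session()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_correlograms <- function(ccgs, path) {
  readr::write_csv(ccgs, path)
  invisible(path)
}

#' Read correlograms written by [write_correlograms()]
#' @param path File path.
#' @return Correlogram tibble.
#' @export
read_correlograms <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Serialize a coupling report to JSON
#'
#' Full double precision; [read_report()] reproduces every matrix and
#' scalar exactly.
#'
#' @param report An `nvc_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a coupling report written by [write_report()]
#' @param path File path.
#' @return An `nvc_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$hemispheres <- lapply(x$hemispheres, function(r) {
    for (f in c("matrix", "trial_peaks", "pair_scores")) {
      r[[f]] <- tibble::as_tibble(r[[f]])
    }
    for (f in c("dominant_pair", "onset_trial")) {
      if (is.null(r[[f]])) r[[f]] <- NA_integer_
    }
    for (f in c("cumulative_stim_s", "recovered_lag_s")) {
      if (is.null(r[[f]])) r[[f]] <- NA_real_
    }
    r
  })
  x$rejections <- tibble::as_tibble(x$rejections)
  structure(x, class = "nvc_report")
}
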