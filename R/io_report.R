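# serialize doubles as 17-significant-digit text so CSV round trips are
# lossless at full double precision
full_precision <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- NA_character_
      out
    } else col
  })
  df
}

# canonical marker-table column order mirroring the deposited columns A-I
MARKER_COLUMNS <- c("cell", "A_1kHz", "A_100kHz", "L_instantaneous",
                    "L_transitional", "L_elongation", "C_specific_membrane",
                    "sigma_cytoplasm", "E_instantaneous")

RAW_COLUMNS <- c("time_impedance_s", "amplitude_1kHz", "phase_1kHz",
                 "amplitude_100kHz", "phase_100kHz", "time_camera_s",
                 "aspiration_length_um")

#' Cell diameter from the elongation length by volume conservation
#'
#' The cell fills the rectangular channel cross-section over a length
#' `L_elongation`; conserving the volume of the undeformed sphere gives
#' `D_cell = (6 width height L_elongation / pi)^(1/3)`. Exact inverse of
#' [elongation_from_diameter()].
#'
#' @param L_elongation Elongation length, um (> 0).
#' @param geom A [channel_geometry()].
#' @return `D_cell` in um.
#' @export
#' @examples
#' diameter_from_elongation(28.18, channel_geometry())
diameter_from_elongation <- function(L_elongation, geom) {
  if (!is.numeric(L_elongation) || any(!is.finite(L_elongation)) ||
      any(L_elongation <= 0))
    stop("L_elongation must be finite and > 0")
  (6 * geom$width * geom$height * L_elongation / pi)^(1 / 3)
}

#' Write / read raw per-cell measurement streams
#'
#' One CSV per cell in `dir`, named `cell_<id>.csv`, mirroring the
#' deposited seven-column layout: impedance time, amplitude and phase at
#' 1 kHz, amplitude and phase at 100 kHz, camera time, aspiration length.
#' The two instruments sample at different rates, so the shorter block is
#' padded with empty cells; the two time columns are kept separate on
#' read-back. Values round-trip losslessly at full double precision.
#'
#' @param cells List of `list(cell, trace, trajectory)` entries as produced
#'   by [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `write_raw_records()` returns the written paths invisibly;
#'   `read_raw_records()` returns a named list of
#'   `list(cell, trace, trajectory)`.
#' @export
write_raw_records <- function(cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cells, function(entry) {
    tr <- entry$trace; tj <- entry$trajectory
    n <- max(nrow(tr), nrow(tj))
    pad <- function(x) c(x, rep(NA_real_, n - length(x)))
    df <- data.frame(pad(tr$time), pad(tr$amplitude_1kHz), pad(tr$phase_1kHz),
                     pad(tr$amplitude_100kHz), pad(tr$phase_100kHz),
                     pad(tj$time), pad(tj$length))
    names(df) <- RAW_COLUMNS
    path <- file.path(dir, sprintf("cell_%04d.csv", as.integer(entry$cell)))
    data.table::fwrite(full_precision(df), path)
    path
  }, character(1))
  invisible(paths)
}

#' @rdname write_raw_records
#' @export
read_raw_records <- function(dir) {
  files <- sort(list.files(dir, pattern = "^cell_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    warning(sprintf("no per-cell records found in '%s'", dir))
    return(list())
  }
  out <- lapply(files, function(path) {
    df <- as.data.frame(data.table::fread(path))
    if (!identical(names(df), RAW_COLUMNS))
      stop(sprintf("malformed raw record '%s': expected columns %s, found %s",
                   basename(path), paste(RAW_COLUMNS, collapse = ", "),
                   paste(names(df), collapse = ", ")))
    imp <- !is.na(df$time_impedance_s)
    cam <- !is.na(df$time_camera_s)
    cell_id <- as.integer(sub("^cell_(\\d+)\\.csv$", "\\1", basename(path)))
    list(cell = cell_id,
         trace = impedance_trace(df$time_impedance_s[imp],
                                 df$amplitude_1kHz[imp], df$phase_1kHz[imp],
                                 df$amplitude_100kHz[imp],
                                 df$phase_100kHz[imp]),
         trajectory = aspiration_trajectory(df$time_camera_s[cam],
                                            df$aspiration_length_um[cam]))
  })
  names(out) <- vapply(out, function(x) sprintf("cell_%04d", x$cell),
                       character(1))
  out
}

#' Write / read the per-cell marker table
#'
#' Serializes per-cell records with the first nine columns in the deposited
#' order (cell number, `A_1kHz`, `A_100kHz`, `L_instantaneous`,
#' `L_transitional`, `L_elongation`, `C_specific_membrane`,
#' `sigma_cytoplasm`, `E_instantaneous` — columns A-I); any extra columns
#' (`f_c`, `D_cell`, `status`, ...) are appended after column I. Reading
#' verifies the nine-column schema and errors on mismatch.
#'
#' @param records Data frame containing at least the nine canonical
#'   columns.
#' @param path CSV file path.
#' @return `write_marker_table()` returns `path` invisibly;
#'   `read_marker_table()` returns the records data frame.
#' @export
write_marker_table <- function(records, path) {
  missing <- setdiff(MARKER_COLUMNS, names(records))
  if (length(missing))
    stop(sprintf("records are missing required columns: %s",
                 paste(missing, collapse = ", ")))
  extras <- setdiff(names(records), MARKER_COLUMNS)
  data.table::fwrite(
    full_precision(records[, c(MARKER_COLUMNS, extras), drop = FALSE]), path)
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  if (ncol(df) < length(MARKER_COLUMNS) ||
      !identical(names(df)[seq_along(MARKER_COLUMNS)], MARKER_COLUMNS))
    stop(sprintf(
      "marker table '%s' does not match the deposited A-I layout; expected leading columns %s",
      basename(path), paste(MARKER_COLUMNS, collapse = ", ")))
  df
}

#' Cohort summary statistics in the published table layout
#'
#' Mean and sample standard deviation (n - 1 denominator) per marker, with
#' missing records excluded per marker and the per-marker `n` reported. A
#' marker with a single non-missing value is an error when `strict = TRUE`
#' (the default); a marker with no values at all is reported as `NA` with a
#' warning (this is how `E_instantaneous` appears when no aspiration
#' pressure is available).
#'
#' @param records Per-cell records data frame (marker-table layout).
#' @param label Cohort label.
#' @param strict Error when a marker has exactly one non-missing value.
#' @return An object of class `cohort_summary`: data frame with columns
#'   `marker`, `n`, `mean`, `sd` and a `label` attribute.
#' @export
#' @examples
#' rec <- data.frame(cell = 1:3, A_1kHz = c(1, 2, 3), A_100kHz = 1,
#'                   L_instantaneous = 9, L_transitional = 18,
#'                   L_elongation = 28, C_specific_membrane = 2.1,
#'                   sigma_cytoplasm = 0.9, E_instantaneous = 5.5)
#' summarize_cohort(rec, "demo")
summarize_cohort <- function(records, label = "cohort", strict = TRUE) {
  markers <- setdiff(MARKER_COLUMNS, "cell")
  missing <- setdiff(markers, names(records))
  if (length(missing))
    stop(sprintf("records are missing marker columns: %s",
                 paste(missing, collapse = ", ")))
  rows <- lapply(markers, function(m) {
    v <- records[[m]]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0L) {
      warning(sprintf("marker '%s' has no non-missing values", m))
      return(data.frame(marker = m, n = 0L, mean = NA_real_, sd = NA_real_))
    }
    if (n == 1L) {
      if (strict)
        stop(sprintf("marker '%s' has fewer than 2 non-missing values", m))
      warning(sprintf("marker '%s' has fewer than 2 non-missing values", m))
      return(data.frame(marker = m, n = 1L, mean = v, sd = NA_real_))
    }
    data.frame(marker = m, n = n, mean = mean(v), sd = stats::sd(v))
  })
  out <- do.call(rbind, rows)
  attr(out, "label") <- label
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s\n", attr(x, "label")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-22s %s (n = %d)\n", x$marker[i],
                if (is.na(x$mean[i])) "NA" else
                  sprintf("%.3f +- %.3f", x$mean[i], x$sd[i]),
                x$n[i]))
  }
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Orchestrates marker extraction, electrical inversion, mechanical
#' inversion and cohort summary over a set of per-cell raw streams, either
#' simulated from a [cohort_config()] or read from disk with
#' [read_raw_records()]. Per-cell failures are logged and flagged with a
#' status string (`no_entry_event`, `creep_fit_failed`, `no_event`,
#' `electrical_no_convergence`, `mech_no_solution`, `pressure_missing`),
#' never silently dropped, and `n_ok + n_failed` always equals the number
#' of processed cells.
#'
#' Mechanical inversion needs the per-cell aspiration pressure, which the
#' deposited raw layout does not record: `pressure` may be `"truth"`
#' (per-cell pressures from the simulation ground truth), a single
#' cohort-level value in kPa, a named/numeric vector per cell, or `NA`, in
#' which case `E_instantaneous` is reported missing.
#'
#' @param cfg A [cohort_config()]; used to simulate when `cells` is `NULL`
#'   and for geometry/medium throughout.
#' @param cells Optional list of `list(cell, trace, trajectory)` entries
#'   (e.g. from [read_raw_records()]); when `NULL`, a cohort is simulated.
#' @param pressure `"truth"`, a scalar pressure (kPa), a per-cell numeric
#'   vector aligned with the cells, or `NA`.
#' @param label Cohort label for the summary.
#' @param coeffs Mechanical model coefficients.
#' @return A list with `records` (marker table plus `f_c`, `D_cell`,
#'   `status`), `summary` ([summarize_cohort()] output), `log` (per-cell
#'   status data frame), `truth` (when simulated), `skipped` (infeasible
#'   simulated cells) and `config`.
#' @export
#' @examples
#' res <- run_pipeline(cohort_config(n_cells = 5, seed = 7,
#'                                   amplitude_noise = 0, length_noise = 0))
#' res$summary
run_pipeline <- function(cfg, cells = NULL, pressure = "truth",
                         label = cfg$line, coeffs = mech_coefficients()) {
  stopifnot(inherits(cfg, "cohort_config"))
  truth <- NULL
  skipped <- data.frame(cell = integer(), reason = character())
  if (is.null(cells)) {
    sim <- simulate_cohort(cfg, coeffs)
    cells <- sim$cells
    truth <- sim$truth
    skipped <- sim$skipped
  }
  n <- length(cells)
  pressures <- rep(NA_real_, n)
  if (identical(pressure, "truth")) {
    if (!is.null(truth))
      pressures <- truth$P_aspiration[match(
        vapply(cells, `[[`, numeric(1), "cell"), truth$cell)]
  } else if (is.numeric(pressure)) {
    pressures <- rep_len(pressure, n)
  }

  rows <- vector("list", n)
  logs <- vector("list", n)
  for (i in seq_len(n)) {
    entry <- cells[[i]]
    status <- "ok"
    mk <- tryCatch(extract_markers(entry$trace, entry$trajectory),
                   error = function(e) conditionMessage(e))
    if (is.character(mk)) {
      status <- if (grepl("no entry event", mk)) "no_entry_event"
                else if (grepl("creep", mk)) "creep_fit_failed"
                else "no_event"
      rows[[i]] <- data.frame(cell = entry$cell, A_1kHz = NA_real_,
                              A_100kHz = NA_real_, L_instantaneous = NA_real_,
                              L_transitional = NA_real_,
                              L_elongation = NA_real_,
                              C_specific_membrane = NA_real_,
                              sigma_cytoplasm = NA_real_,
                              E_instantaneous = NA_real_, f_c = NA_real_,
                              D_cell = NA_real_, status = status)
      logs[[i]] <- data.frame(cell = entry$cell, stage = "extract",
                              status = status)
      next
    }

    elec <- tryCatch(
      invert_electrical(mk$A_1kHz, mk$A_100kHz, mk$phase_ratio_100kHz,
                        cfg$geom, cfg$medium, mk$L_elongation),
      error = function(e) conditionMessage(e))
    c_spec <- sigma <- NA_real_
    if (is.character(elec)) {
      status <- "electrical_no_convergence"
    } else {
      c_spec <- elec$C_specific_membrane
      sigma <- elec$sigma_cytoplasm
    }

    E <- f_c <- NA_real_
    if (is.na(pressures[i])) {
      if (status == "ok") status <- "pressure_missing"
    } else {
      mech <- tryCatch(
        invert_entry(mk$L_instantaneous, mk$L_transitional,
                     cfg$geom$d_channel, pressures[i], coeffs),
        error = function(e) NULL)
      if (is.null(mech) || mech$status == "no_solution") {
        if (status == "ok") status <- "mech_no_solution"
      } else {
        E <- mech$E_instantaneous
        f_c <- mech$f_c
      }
    }

    rows[[i]] <- data.frame(cell = entry$cell, A_1kHz = mk$A_1kHz,
                            A_100kHz = mk$A_100kHz,
                            L_instantaneous = mk$L_instantaneous,
                            L_transitional = mk$L_transitional,
                            L_elongation = mk$L_elongation,
                            C_specific_membrane = c_spec,
                            sigma_cytoplasm = sigma, E_instantaneous = E,
                            f_c = f_c,
                            D_cell = diameter_from_elongation(mk$L_elongation,
                                                              cfg$geom),
                            status = status)
    logs[[i]] <- data.frame(cell = entry$cell, stage = "pipeline",
                            status = status)
  }
  records <- do.call(rbind, rows)
  log <- do.call(rbind, logs)
  summary <- withCallingHandlers(
    summarize_cohort(records, label, strict = FALSE),
    warning = function(w) invokeRestart("muffleWarning"))
  list(records = records, summary = summary, log = log, truth = truth,
       skipped = skipped, config = cfg)
}
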