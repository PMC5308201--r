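#' Two-frequency impedance trace of a single cell event
#'
#' Raw lock-in output sampled nominally at 25 points per second: amplitude
#' and phase at 1 kHz and at 100 kHz against the impedance analyser's own
#' clock.
#'
#' @param time Sample times, s; strictly increasing, length >= 10.
#' @param amplitude_1kHz,phase_1kHz Amplitude (instrument units) and phase
#'   (radians) at 1 kHz.
#' @param amplitude_100kHz,phase_100kHz Amplitude and phase at 100 kHz.
#' @return A data frame of class `impedance_trace`.
#' @export
impedance_trace <- function(time, amplitude_1kHz, phase_1kHz,
                            amplitude_100kHz, phase_100kHz) {
  n <- length(time)
  lens <- c(length(amplitude_1kHz), length(phase_1kHz),
            length(amplitude_100kHz), length(phase_100kHz))
  if (any(lens != n))
    stop("all impedance columns must have the same length as 'time'")
  if (n < 10L) stop("an impedance trace needs at least 10 samples")
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop("'time' must be finite and strictly increasing")
  structure(data.frame(time = time,
                       amplitude_1kHz = amplitude_1kHz,
                       phase_1kHz = phase_1kHz,
                       amplitude_100kHz = amplitude_100kHz,
                       phase_100kHz = phase_100kHz),
            class = c("impedance_trace", "data.frame"))
}

#' Aspiration-length trajectory of a single cell
#'
#' Aspiration length versus time from high-speed-camera image processing,
#' nominally 200 frames per second, on the camera's own clock.
#'
#' @param time Frame times, s; strictly increasing.
#' @param length Aspiration length per frame, um; non-negative.
#' @return A data frame of class `aspiration_trajectory`.
#' @export
aspiration_trajectory <- function(time, length) {
  if (base::length(time) != base::length(length))
    stop("'time' and 'length' must have equal length")
  if (base::length(time) < 2L) stop("a trajectory needs at least 2 frames")
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop("'time' must be finite and strictly increasing")
  if (any(!is.finite(length)) || any(length < 0))
    stop("aspiration lengths must be finite and >= 0")
  structure(data.frame(time = time, length = length),
            class = c("aspiration_trajectory", "data.frame"))
}

#' Detect the entry jump in an aspiration trajectory
#'
#' A cell entering the constriction channel produces an instantaneous jump
#' in aspiration length. Returns the first frame index (1-based) whose
#' increment over the previous frame exceeds `jump_threshold`; that frame
#' starts the entry stage.
#'
#' @param traj An [aspiration_trajectory()].
#' @param jump_threshold Minimum single-frame increment counted as a jump, um.
#' @return Integer frame index.
#' @export
#' @examples
#' traj <- aspiration_trajectory(time = (0:9) / 200,
#'                               length = c(0, 0, 0, 6.1, 7, 7.5, 7.8, 8, 8.1, 8.2))
#' detect_entry_onset(traj, jump_threshold = 2)
detect_entry_onset <- function(traj, jump_threshold = 2) {
  if (nrow(traj) < 2L) stop("need at least 2 frames to detect an entry jump")
  jumps <- which(diff(traj$length) > jump_threshold)
  if (length(jumps) == 0L)
    stop(sprintf("no entry event: no single-frame increment exceeds %g um",
                 jump_threshold))
  jumps[1L] + 1L
}

#' Extract the instantaneous and transitional entry lengths
#'
#' `L_instantaneous` is the aspiration length at the onset frame (the
#' elastic jump). The creep segment — frames from the onset up to the next
#' jump exceeding `jump_threshold` (travel start), or the trajectory end —
#' is fitted by least squares to the saturating exponential
#' `L(t) = L_T - (L_T - L_I) exp(-(t - t0)/tau)` with `L_I` fixed at
#' `L_instantaneous`; `L_transitional` is the fitted asymptote `L_T` and
#' the creep end time is where the fit reaches `creep_end_fraction` of the
#' total creep amplitude. If the fit fails, a fallback declares creep ended
#' at the first frame whose centred 3-frame slope drops below
#' `slope_threshold`; if that also fails the value is marked missing, never
#' fabricated.
#'
#' @param traj An [aspiration_trajectory()].
#' @param onset Onset frame index from [detect_entry_onset()].
#' @param jump_threshold Jump threshold used to delimit the creep segment, um.
#' @param creep_end_fraction Fraction of the creep amplitude defining creep
#'   end (default 0.95).
#' @param slope_threshold Fallback creep-end slope criterion, um/s.
#' @return A list with `L_instantaneous`, `L_transitional`, `tau` (s, `NA`
#'   for the fallback), `creep_end_time` (s), `method` (`"exp_fit"`,
#'   `"slope_threshold"` or `"failed"`), `status` and `segment` (first and
#'   last creep frame index).
#' @export
extract_entry_lengths <- function(traj, onset, jump_threshold = 2,
                                  creep_end_fraction = 0.95,
                                  slope_threshold = 2) {
  n <- nrow(traj)
  if (!is.numeric(onset) || length(onset) != 1L || onset < 1L || onset > n)
    stop("'onset' must be a valid frame index")
  onset <- as.integer(onset)

  jumps <- which(diff(traj$length) > jump_threshold) + 1L
  nxt <- jumps[jumps > onset]
  seg_end <- if (length(nxt)) nxt[1L] - 1L else n
  if (seg_end - onset < 8L)
    stop(sprintf("creep segment too short: %d frames after onset (need >= 8)",
                 seg_end - onset))

  L_I <- traj$length[onset]
  t0 <- traj$time[onset]
  tt <- traj$time[onset:seg_end] - t0
  LL <- traj$length[onset:seg_end]

  # Levenberg-Marquardt on (L_T, log tau); log keeps tau positive without
  # box constraints
  fit <- tryCatch({
    resid_fn <- function(p) p[1L] - (p[1L] - L_I) * exp(-tt / exp(p[2L])) - LL
    start <- c(max(LL[length(LL)], L_I + 0.5),
               log(max(tt[length(tt)] / 3, tt[2L])))
    m <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- c(L_T = m$par[1L], tau = exp(m$par[2L]))
    if (!all(is.finite(cf)) || m$info < 1 || m$info > 4 ||
        cf[["L_T"]] < L_I) stop("bad fit")
    cf
  }, error = function(e) NULL)

  if (!is.null(fit)) {
    tau <- fit[["tau"]]
    return(list(L_instantaneous = L_I,
                L_transitional = fit[["L_T"]],
                tau = tau,
                creep_end_time = t0 + tau * log(1 / (1 - creep_end_fraction)),
                method = "exp_fit",
                status = "ok",
                segment = c(onset, seg_end)))
  }

  # fallback: centred 3-frame slope below threshold
  if (seg_end - onset >= 2L) {
    ii <- (onset + 1L):(seg_end - 1L)
    slope <- (traj$length[ii + 1L] - traj$length[ii - 1L]) /
      (traj$time[ii + 1L] - traj$time[ii - 1L])
    hit <- which(slope < slope_threshold)
    if (length(hit)) {
      i <- ii[hit[1L]]
      return(list(L_instantaneous = L_I,
                  L_transitional = traj$length[i],
                  tau = NA_real_,
                  creep_end_time = traj$time[i],
                  method = "slope_threshold",
                  status = "ok",
                  segment = c(onset, seg_end)))
    }
  }
  list(L_instantaneous = L_I, L_transitional = NA_real_, tau = NA_real_,
       creep_end_time = NA_real_, method = "failed",
       status = "creep_fit_failed", segment = c(onset, seg_end))
}

#' Extract the travel elongation length
#'
#' `L_elongation` is the aspiration length of the fully entered cell while
#' it travels along the channel: the median of all frame lengths after the
#' creep end time. A window whose spread exceeds `dispersion_warn` (e.g. a
#' monotone ramp with no plateau) still returns the median but with a
#' high-dispersion warning.
#'
#' @param traj An [aspiration_trajectory()].
#' @param creep_end Creep end time, s (camera clock).
#' @param min_frames Minimum number of travel frames required.
#' @param dispersion_warn Standard deviation (um) above which a warning is
#'   emitted.
#' @return `L_elongation` in um.
#' @export
extract_elongation_length <- function(traj, creep_end, min_frames = 3L,
                                      dispersion_warn = 1) {
  if (!is.numeric(creep_end) || length(creep_end) != 1L || !is.finite(creep_end))
    stop("'creep_end' must be a single finite time")
  vals <- traj$length[traj$time > creep_end]
  if (length(vals) < min_frames)
    stop(sprintf("insufficient travel frames after creep end (%d < %d)",
                 length(vals), min_frames))
  if (stats::sd(vals) > dispersion_warn)
    warning(sprintf("travel window is not a plateau (sd = %.3g um): L_elongation unreliable",
                    stats::sd(vals)))
  stats::median(vals)
}

#' Extract the amplitude ratios from an impedance trace
#'
#' The cell event is located on the 1 kHz amplitude channel (the channel
#' with the largest contrast) as the samples exceeding the median plus
#' `k` times the MAD; the same window is used at both frequencies so the
#' two ratios stay time-aligned. The baseline is the median amplitude
#' before the event; the travel value is the median over the central
#' `1 - 2 * plateau_trim` of the event, excluding the entry and exit
#' transients. `A_f` is travel/baseline per frequency; the phase change of
#' the travel window relative to baseline is returned for the 100 kHz
#' circuit inversion.
#'
#' @param trace An [impedance_trace()].
#' @param k Detection threshold in MADs above the median.
#' @param plateau_trim Fraction of the event trimmed at each end.
#' @return A list with `A_1kHz`, `A_100kHz`, `phase_ratio_1kHz`,
#'   `phase_ratio_100kHz` (radians), and window diagnostics `event`,
#'   `plateau` (index pairs) and `n_baseline`.
#' @export
extract_amplitude_ratios <- function(trace, k = 5, plateau_trim = 0.1) {
  a1 <- trace$amplitude_1kHz
  n <- length(a1)
  thr <- stats::median(a1) + k * stats::mad(a1)
  above <- which(a1 > thr)
  if (length(above) == 0L)
    stop("no impedance event: no sample exceeds baseline median + k * MAD")
  e1 <- above[1L]
  e2 <- above[length(above)]
  if (e1 <= 1L || e2 >= n)
    stop("impedance event touches the trace edge: no baseline or no return to baseline")

  ev_len <- e2 - e1 + 1L
  trim <- max(1L, as.integer(ceiling(plateau_trim * ev_len)))
  p1 <- e1 + trim
  p2 <- e2 - trim
  if (p2 < p1)
    stop("impedance event too short to define a travel plateau")

  base_idx <- seq_len(e1 - 1L)
  plat_idx <- p1:p2
  ratio <- function(col) {
    stats::median(trace[[col]][plat_idx]) / stats::median(trace[[col]][base_idx])
  }
  dphase <- function(col) {
    stats::median(trace[[col]][plat_idx]) - stats::median(trace[[col]][base_idx])
  }
  A1 <- ratio("amplitude_1kHz")
  A2 <- ratio("amplitude_100kHz")
  if (A1 < 1 || A2 < 1)
    warning(sprintf("amplitude ratio below 1 (A_1kHz = %.4g, A_100kHz = %.4g)",
                    A1, A2))
  list(A_1kHz = A1, A_100kHz = A2,
       phase_ratio_1kHz = dphase("phase_1kHz"),
       phase_ratio_100kHz = dphase("phase_100kHz"),
       event = c(e1, e2), plateau = c(p1, p2), n_baseline = e1 - 1L)
}

#' Extract all five preliminary markers from one cell's raw streams
#'
#' Runs onset detection, entry-length extraction, elongation extraction and
#' amplitude-ratio extraction on the impedance trace and aspiration
#' trajectory of one cell. The impedance and camera streams run on
#' different instrument clocks and are aligned by their own event onsets,
#' not by absolute time. When the trajectory contains a second jump (entry
#' completion into travel), the travel window for `L_elongation` starts
#' there; otherwise the fitted creep end time is used.
#'
#' A marker ordering violating `L_instantaneous <= L_transitional <=
#' L_elongation`, or amplitude ratios below 1, yields a warning, not an
#' error.
#'
#' @param trace An [impedance_trace()].
#' @param traj An [aspiration_trajectory()].
#' @param jump_threshold,k,plateau_trim,creep_end_fraction,slope_threshold
#'   Tuning parameters passed to the stage extractors.
#' @return An object of class `preliminary_markers`: list with the five
#'   markers, `phase_ratio_100kHz`, `status` and `diagnostics`.
#' @export
extract_markers <- function(trace, traj, jump_threshold = 2, k = 5,
                            plateau_trim = 0.1, creep_end_fraction = 0.95,
                            slope_threshold = 2) {
  onset <- detect_entry_onset(traj, jump_threshold)
  entry <- extract_entry_lengths(traj, onset, jump_threshold,
                                 creep_end_fraction, slope_threshold)
  if (entry$status != "ok")
    stop("creep fit failed and slope fallback found no creep end")

  travel_start <- if (entry$segment[2L] < nrow(traj)) {
    traj$time[entry$segment[2L]]
  } else entry$creep_end_time
  L_e <- extract_elongation_length(traj, travel_start)
  amps <- extract_amplitude_ratios(trace, k, plateau_trim)

  if (!(entry$L_instantaneous <= entry$L_transitional &&
        entry$L_transitional <= L_e))
    warning(sprintf(
      "marker ordering violated: L_inst = %.3g, L_trans = %.3g, L_elong = %.3g um",
      entry$L_instantaneous, entry$L_transitional, L_e))

  structure(list(A_1kHz = amps$A_1kHz,
                 A_100kHz = amps$A_100kHz,
                 L_instantaneous = entry$L_instantaneous,
                 L_transitional = entry$L_transitional,
                 L_elongation = L_e,
                 phase_ratio_100kHz = amps$phase_ratio_100kHz,
                 status = "ok",
                 diagnostics = list(onset = onset,
                                    creep_segment = entry$segment,
                                    creep_method = entry$method,
                                    tau = entry$tau,
                                    creep_end_time = entry$creep_end_time,
                                    event_window = amps$event,
                                    plateau_window = amps$plateau,
                                    n_baseline = amps$n_baseline)),
            class = "preliminary_markers")
}

#' @export
print.preliminary_markers <- function(x, ...) {
  cat(sprintf(
    "<preliminary_markers> A_1kHz = %.3f, A_100kHz = %.3f, L_inst = %.2f, L_trans = %.2f, L_elong = %.2f um\n",
    x$A_1kHz, x$A_100kHz, x$L_instantaneous, x$L_transitional, x$L_elongation))
  invisible(x)
}
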