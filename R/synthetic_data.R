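# truncated-normal sampling by inverse-CDF (exact, vectorized)
r_truncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (!is.finite(plo) || !is.finite(phi) || phi <= plo)
    stop(sprintf("impossible truncation bounds [%g, %g] for N(%g, %g)",
                 lower, upper, mean, sd))
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Per-cell-line ground-truth distribution presets
#'
#' Truncated-normal specifications for the intrinsic parameters of the five
#' lung-tumour lines (H460, H446, A549, 95D, 95C), centred on the published
#' cohort means and standard deviations of `C_specific_membrane`,
#' `sigma_cytoplasm` and `E_instantaneous`. Cell diameter is derived from
#' the cohort elongation length by volume conservation (location and
#' spread propagated through the cube root), and the leak-resistance
#' location/spread are mapped from the cohort 1 kHz amplitude ratio through
#' the open-membrane relation at the cohort mean elongation. The friction
#' coefficient and creep time constant are not reported per line; both use
#' a common default (`f_c`: 0.35 +- 0.05, `tau_creep`: 0.05 +- 0.01 s).
#' The friction preset (0.27 +- 0.03, truncated to \[0.15, 0.33\]) keeps the
#' cohort on the lower, uniquely invertible branch of the two-valued entry
#' model while maximizing the pressure-ratio window over which the model
#' yields ordered positive lengths. Parameters are sampled independently
#' per cell.
#'
#' @param geom A [channel_geometry()] used for the derived mappings.
#' @param medium A [medium_model()] used for the `R_leak` mapping.
#' @return A named list (one entry per line) of parameter specifications;
#'   each parameter is a list with `mean`, `sd`, `lower`, `upper`.
#' @export
#' @examples
#' names(cell_line_presets())
#' cell_line_presets()$H460$E_instantaneous
cell_line_presets <- function(geom = channel_geometry(),
                              medium = medium_model()) {
  tab <- data.frame(
    line      = c("H460", "H446", "A549", "95D", "95C"),
    A1_mean   = c(3.41, 2.94, 3.14, 3.49, 3.33),
    A1_sd     = c(0.47, 0.43, 0.56, 0.49, 0.43),
    Le_mean   = c(28.18, 28.29, 27.59, 27.86, 28.64),
    Le_sd     = c(2.42, 2.46, 3.66, 2.34, 2.31),
    C_mean    = c(2.10, 2.52, 2.45, 1.86, 2.03),
    C_sd      = c(0.38, 0.54, 0.57, 0.31, 0.35),
    sig_mean  = c(0.91, 0.83, 0.99, 1.07, 0.99),
    sig_sd    = c(0.15, 0.12, 0.18, 0.18, 0.16),
    E_mean    = c(5.52, 5.54, 5.16, 3.86, 3.49),
    E_sd      = c(0.95, 1.04, 1.68, 0.81, 0.70))
  r_total <- Re(baseline_impedance(geom, medium, 1e3))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    d_mean <- diameter_from_elongation(r$Le_mean, geom)
    d_sd <- r$Le_sd * d_mean / (3 * r$Le_mean)   # delta method through cube root
    rl_mean <- invert_leak_resistance(r$A1_mean, geom, medium, r$Le_mean)
    rl_sd <- r$A1_sd * r_total
    list(D_cell = list(mean = d_mean, sd = d_sd,
                       lower = geom$width + 2, upper = d_mean + 8 * d_sd),
         C_specific_membrane = list(mean = r$C_mean, sd = r$C_sd,
                                    lower = 0.5, upper = 6),
         sigma_cytoplasm = list(mean = r$sig_mean, sd = r$sig_sd,
                                lower = 0.2, upper = 2.5),
         E_instantaneous = list(mean = r$E_mean, sd = r$E_sd,
                                lower = 0.8, upper = 12),
         f_c = list(mean = 0.27, sd = 0.03, lower = 0.15, upper = 0.33),
         R_leak = list(mean = rl_mean, sd = rl_sd,
                       lower = 5e5, upper = rl_mean + 8 * rl_sd),
         tau_creep = list(mean = 0.05, sd = 0.01, lower = 0.01, upper = 0.2))
  })
  names(out) <- tab$line
  out
}

#' Configuration of a synthetic measurement cohort
#'
#' Bundles the cohort size, the per-parameter ground-truth distributions,
#' the acquisition settings (camera at 200 frames/s, impedance analyser at
#' 25 points/s), the noise model (multiplicative Gaussian on impedance
#' amplitudes, additive Gaussian on lengths) and the random seed.
#'
#' @param n_cells Number of cells (>= 0).
#' @param seed Integer random seed.
#' @param line Cell-line preset name (see [cell_line_presets()]); ignored
#'   when `distributions` is supplied.
#' @param geom A [channel_geometry()].
#' @param medium A [medium_model()].
#' @param frame_rate Camera frame rate, frames/s.
#' @param impedance_rate Impedance sampling rate, points/s.
#' @param amplitude_noise Multiplicative amplitude noise fraction.
#' @param length_noise Additive length noise SD, um.
#' @param pre_entry_s,creep_s,travel_s Trajectory phase durations, s.
#' @param baseline_s,post_event_s Impedance baseline and post-event
#'   durations, s.
#' @param transient_samples Entry/exit transient length in impedance
#'   samples.
#' @param pressure_range Aspiration-pressure range, kPa; sampled uniformly.
#' @param distributions Optional explicit parameter specification list
#'   replacing the preset.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cells = 300L, seed = 1L, line = "H460",
                          geom = channel_geometry(), medium = medium_model(),
                          frame_rate = 200, impedance_rate = 25,
                          amplitude_noise = 0.01, length_noise = 0.25,
                          pre_entry_s = 0.5, creep_s = 0.3, travel_s = 1.0,
                          baseline_s = 2.0, post_event_s = 1.0,
                          transient_samples = 2L,
                          pressure_range = c(0.5, 1.2),
                          distributions = NULL) {
  if (!is.numeric(n_cells) || n_cells < 0) stop("n_cells must be >= 0")
  if (frame_rate <= 0 || impedance_rate <= 0) stop("acquisition rates must be > 0")
  if (amplitude_noise < 0 || length_noise < 0) stop("noise levels must be >= 0")
  if (length(pressure_range) != 2L || any(pressure_range <= 0) ||
      pressure_range[2L] < pressure_range[1L])
    stop("pressure_range must be a positive increasing pair (kPa)")
  if (is.null(distributions)) {
    presets <- cell_line_presets(geom, medium)
    if (!line %in% names(presets))
      stop(sprintf("unknown cell line '%s' (known: %s)", line,
                   paste(names(presets), collapse = ", ")))
    distributions <- presets[[line]]
  }
  structure(list(n_cells = as.integer(n_cells), seed = as.integer(seed),
                 line = line, geom = geom, medium = medium,
                 frame_rate = frame_rate, impedance_rate = impedance_rate,
                 amplitude_noise = amplitude_noise, length_noise = length_noise,
                 pre_entry_s = pre_entry_s, creep_s = creep_s,
                 travel_s = travel_s, baseline_s = baseline_s,
                 post_event_s = post_event_s,
                 transient_samples = as.integer(transient_samples),
                 pressure_range = pressure_range,
                 distributions = distributions),
            class = "cohort_config")
}

#' Sample a cohort of ground-truth cells
#'
#' Draws `n_cells` independent cells from the configured truncated-normal
#' distributions; aspiration pressure is uniform on the configured range.
#' Reproducible: the configuration seed initialises the generator (set
#' `use_seed = FALSE` to continue from the caller's RNG state, as
#' [simulate_cohort()] does).
#'
#' @param cfg A [cohort_config()].
#' @param use_seed Set the RNG seed from `cfg$seed` first.
#' @return A data frame (one row per cell) with columns `cell`, `D_cell`,
#'   `C_specific_membrane`, `sigma_cytoplasm`, `E_instantaneous`, `f_c`,
#'   `R_leak`, `tau_creep`, `P_aspiration`.
#' @export
sample_cohort <- function(cfg, use_seed = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (use_seed) set.seed(cfg$seed)
  n <- cfg$n_cells
  draw <- function(sp) r_truncnorm(n, sp$mean, sp$sd, sp$lower, sp$upper)
  d <- cfg$distributions
  out <- data.frame(cell = seq_len(n),
                    D_cell = draw(d$D_cell),
                    C_specific_membrane = draw(d$C_specific_membrane),
                    sigma_cytoplasm = draw(d$sigma_cytoplasm),
                    E_instantaneous = draw(d$E_instantaneous),
                    f_c = draw(d$f_c),
                    R_leak = draw(d$R_leak),
                    tau_creep = draw(d$tau_creep),
                    P_aspiration = stats::runif(n, cfg$pressure_range[1L],
                                                cfg$pressure_range[2L]))
  if (n > 0 && any(out$D_cell <= cfg$geom$width))
    stop("sampled D_cell not larger than the channel width; cell would not deform")
  out
}

#' Elongation length of a fully entered cell by volume conservation
#'
#' A sphere of diameter `D_cell` deformed into the rectangular channel at
#' constant volume occupies a length `(pi/6) D_cell^3 / (width height)`.
#' Exact inverse of [diameter_from_elongation()].
#'
#' @param D_cell Cell diameter, um (> 0).
#' @param geom A [channel_geometry()].
#' @return `L_elongation` in um.
#' @export
#' @examples
#' elongation_from_diameter(17.525, channel_geometry())
elongation_from_diameter <- function(D_cell, geom) {
  if (!is.numeric(D_cell) || any(!is.finite(D_cell)) || any(D_cell <= 0))
    stop("D_cell must be finite and > 0")
  (pi / 6) * D_cell^3 / (geom$width * geom$height)
}

# classed condition for cells the forward models cannot produce
infeasible_cell <- function(reason) {
  stop(errorCondition(paste0("infeasible cell: ", reason),
                      class = c("infeasible_cell", "error", "condition")))
}

#' Simulate the aspiration-length trajectory of one cell
#'
#' Builds the camera stream the entry model implies: zero length before the
#' onset, an instantaneous jump to `L_instantaneous`, exponential creep
#' towards `L_transitional` with time constant `tau_creep`, then a step to
#' the travel plateau at `L_elongation` (from volume conservation) once the
#' cell has fully entered. As `tau_creep -> 0` the trajectory degenerates
#' to a two-step function. Additive Gaussian noise of SD `length_noise` is
#' applied and negative lengths are clipped at zero. Entry lengths come
#' from [forward_entry_lengths()]; cells for which the forward model gives
#' non-positive or non-ordered lengths raise an `infeasible_cell`
#' condition.
#'
#' @param truth One-row data frame (or list) of ground-truth parameters as
#'   produced by [sample_cohort()].
#' @param cfg A [cohort_config()].
#' @param coeffs Mechanical model coefficients.
#' @return An [aspiration_trajectory()].
#' @export
simulate_trajectory <- function(truth, cfg, coeffs = mech_coefficients()) {
  fw <- forward_entry_lengths(truth$f_c,
                              truth$P_aspiration / truth$E_instantaneous,
                              coeffs)
  L_i <- fw$l_inst * cfg$geom$d_channel
  L_t <- fw$l_trans * cfg$geom$d_channel
  L_e <- elongation_from_diameter(truth$D_cell, cfg$geom)
  if (L_i <= 0) infeasible_cell(sprintf("L_instantaneous = %.3g um <= 0", L_i))
  if (L_t <= L_i) infeasible_cell("L_transitional <= L_instantaneous")
  if (L_e <= L_t) infeasible_cell("L_elongation <= L_transitional")

  fr <- cfg$frame_rate
  n_pre <- round(cfg$pre_entry_s * fr)
  n_creep <- round(cfg$creep_s * fr)
  n_travel <- round(cfg$travel_s * fr)
  tt_creep <- (seq_len(n_creep) - 1L) / fr
  lengths <- c(rep(0, n_pre),
               L_t - (L_t - L_i) * exp(-tt_creep / truth$tau_creep),
               rep(L_e, n_travel))
  if (cfg$length_noise > 0)
    lengths <- lengths + stats::rnorm(length(lengths), 0, cfg$length_noise)
  aspiration_trajectory(time = (seq_along(lengths) - 1L) / fr,
                        length = pmax(lengths, 0))
}

#' Simulate the two-frequency impedance trace of one cell
#'
#' The cell's circuit is assembled from its intrinsic markers via
#' [intrinsic_to_circuit()] plus its `R_leak`; the with-cell/baseline
#' ratios at 1 and 100 kHz come from [forward_cell_impedance_ratio()]. The
#' trace holds the baseline amplitude before and after the event and the
#' scaled amplitude/shifted phase while the cell is in the channel, with a
#' short linear transient at event entry and exit, and multiplicative
#' Gaussian amplitude noise. Phases are noise-free (the lock-in phase is
#' far less noisy than its amplitude).
#'
#' @inheritParams simulate_trajectory
#' @return An [impedance_trace()].
#' @export
simulate_impedance <- function(truth, cfg) {
  L_e <- elongation_from_diameter(truth$D_cell, cfg$geom)
  if (L_e >= cfg$geom$length)
    infeasible_cell("elongated cell longer than the channel")
  circ <- intrinsic_to_circuit(truth$C_specific_membrane,
                               truth$sigma_cytoplasm, L_e, cfg$geom)
  circuit <- circuit_params(truth$R_leak, circ$R_cytoplasm, circ$C_membrane)
  a1 <- forward_cell_impedance_ratio(circuit, cfg$geom, cfg$medium, L_e, 1e3)
  a2 <- forward_cell_impedance_ratio(circuit, cfg$geom, cfg$medium, L_e, 1e5)
  z0 <- Mod(baseline_impedance(cfg$geom, cfg$medium, 1e3))

  ir <- cfg$impedance_rate
  n_base <- round(cfg$baseline_s * ir)
  n_event <- round((cfg$creep_s + cfg$travel_s) * ir)
  n_post <- round(cfg$post_event_s * ir)
  ts <- min(cfg$transient_samples, max((n_event - 1L) %/% 2L, 0L))

  event_profile <- function(level) {
    prof <- rep(level, n_event)
    if (ts > 0L) {
      ramp <- seq_len(ts) / (ts + 1)
      prof[seq_len(ts)] <- level * ramp               # relative rise from 0
      prof[n_event - seq_len(ts) + 1L] <- level * ramp
    }
    prof
  }
  amp_of <- function(a) z0 * c(rep(1, n_base),
                               1 + event_profile(Mod(a) - 1),
                               rep(1, n_post))
  phase_of <- function(a) c(rep(0, n_base), event_profile(Arg(a)),
                            rep(0, n_post))
  amp1 <- amp_of(a1); amp2 <- amp_of(a2)
  if (cfg$amplitude_noise > 0) {
    n <- length(amp1)
    amp1 <- amp1 * (1 + stats::rnorm(n, 0, cfg$amplitude_noise))
    amp2 <- amp2 * (1 + stats::rnorm(n, 0, cfg$amplitude_noise))
  }
  impedance_trace(time = (seq_along(amp1) - 1L) / ir,
                  amplitude_1kHz = amp1, phase_1kHz = phase_of(a1),
                  amplitude_100kHz = amp2, phase_100kHz = phase_of(a2))
}

#' Simulate a full measurement cohort
#'
#' Samples ground truth and generates both raw streams for every cell.
#' Cells whose parameter draw is infeasible under the forward entry model
#' (non-positive or non-ordered predicted lengths) are skipped with a
#' logged reason rather than silently dropped. Bit-identical output for
#' identical seed and configuration.
#'
#' @param cfg A [cohort_config()].
#' @param coeffs Mechanical model coefficients.
#' @return A list with `truth` (ground-truth rows of the simulated cells),
#'   `cells` (list of `list(cell, trace, trajectory)`), and `skipped`
#'   (data frame of cell ids and reasons).
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_config(n_cells = 3, seed = 42))
#' length(sim$cells)
simulate_cohort <- function(cfg, coeffs = mech_coefficients()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  truth <- sample_cohort(cfg, use_seed = FALSE)
  cells <- vector("list", nrow(truth))
  skipped <- list()
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    streams <- tryCatch({
      traj <- simulate_trajectory(row, cfg, coeffs)
      trace <- simulate_impedance(row, cfg)
      list(cell = row$cell, trace = trace, trajectory = traj)
    }, infeasible_cell = function(e) conditionMessage(e))
    if (is.character(streams)) {
      skipped[[length(skipped) + 1L]] <- data.frame(cell = row$cell,
                                                    reason = streams)
      cells[i] <- list(NULL)
    } else {
      cells[[i]] <- streams
    }
  }
  keep <- !vapply(cells, is.null, logical(1))
  list(truth = truth[keep, , drop = FALSE],
       cells = cells[keep],
       skipped = if (length(skipped)) do.call(rbind, skipped)
                 else data.frame(cell = integer(), reason = character()))
}
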