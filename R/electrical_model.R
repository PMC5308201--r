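#' Lumped circuit parameters of a cell travelling in the channel
#'
#' While a cell travels inside the constriction channel its electrical
#' response is modelled as a cytoplasm resistance `R_cytoplasm` in series
#' with a lumped membrane capacitance `C_membrane`, the whole branch
#' shunted by a leak resistance `R_leak` describing the imperfect seal
#' between cell and channel walls. Ion channels and organelle membranes are
#' deliberately neglected.
#'
#' @param R_leak Leak (seal) resistance, Ohm.
#' @param R_cytoplasm Cytoplasm resistance, Ohm.
#' @param C_membrane Lumped series membrane capacitance, F.
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(R_leak, R_cytoplasm, C_membrane) {
  vals <- c(R_leak = R_leak, R_cytoplasm = R_cytoplasm,
            C_membrane = C_membrane)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0))
    stop("R_leak, R_cytoplasm and C_membrane must all be finite and > 0")
  structure(as.list(vals), class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf("<circuit_params> R_leak = %.4g Ohm, R_cytoplasm = %.4g Ohm, C_membrane = %.4g F\n",
              x$R_leak, x$R_cytoplasm, x$C_membrane))
  invisible(x)
}

# series resistance of a channel segment of given length (um) filled with medium
segment_resistance <- function(length_um, geom, medium) {
  length_um * 1e-6 / (medium$conductivity * cross_section_m2(geom))
}

#' Baseline impedance of the unoccupied channel
#'
#' The empty channel filled with culture medium is purely resistive:
#' access resistance plus the medium resistance of the full channel length.
#' The value is independent of frequency; `frequency` is accepted for
#' interface symmetry and must be positive.
#'
#' @param geom A [channel_geometry()].
#' @param medium A [medium_model()].
#' @param frequency Measurement frequency, Hz (> 0).
#' @return Complex impedance (Ohm) with zero imaginary part.
#' @export
#' @examples
#' baseline_impedance(channel_geometry(), medium_model(), 1e3)
baseline_impedance <- function(geom, medium, frequency) {
  if (!is.numeric(frequency) || any(!is.finite(frequency)) || any(frequency <= 0))
    stop("frequency must be finite and > 0")
  complex(real = medium$access_resistance +
            segment_resistance(geom$length, geom, medium),
          imaginary = 0)
}

#' Forward impedance ratio with a cell travelling in the channel
#'
#' With a cell of elongated length `L_elongation` inside the channel, the
#' occupied segment is replaced by the cell circuit `R_leak || (R_cytoplasm
#' + 1/(j w C_membrane))` while the remaining `length - L_elongation` of
#' channel stays medium-filled. The returned complex ratio `A` is the
#' with-cell impedance divided by the baseline impedance; its modulus is
#' the amplitude ratio the instrument reports. `|A| >= 1` is not enforced
#' (parameter sets can violate it); a warning is emitted when it fails.
#'
#' @param circuit A [circuit_params()].
#' @inheritParams baseline_impedance
#' @param L_elongation Elongated cell length inside the channel (um),
#'   with `0 < L_elongation < length`.
#' @return Complex impedance ratio (dimensionless).
#' @export
#' @examples
#' cc <- circuit_params(R_leak = 3e6, R_cytoplasm = 2.8e5, C_membrane = 1e-12)
#' Mod(forward_cell_impedance_ratio(cc, channel_geometry(), medium_model(),
#'                                  L_elongation = 28, frequency = 1e5))
forward_cell_impedance_ratio <- function(circuit, geom, medium,
                                         L_elongation, frequency) {
  if (!inherits(circuit, "circuit_params"))
    stop("'circuit' must be a circuit_params object")
  if (!is.numeric(L_elongation) || length(L_elongation) != 1L ||
      !is.finite(L_elongation) ||
      L_elongation <= 0 || L_elongation >= geom$length)
    stop("L_elongation must satisfy 0 < L_elongation < channel length")
  if (!is.numeric(frequency) || length(frequency) != 1L ||
      !is.finite(frequency) || frequency <= 0)
    stop("frequency must be finite and > 0")

  w <- 2 * pi * frequency
  z_branch <- circuit$R_cytoplasm + 1 / (1i * w * circuit$C_membrane)
  z_seg <- circuit$R_leak * z_branch / (circuit$R_leak + z_branch)
  z_rest <- medium$access_resistance +
    segment_resistance(geom$length - L_elongation, geom, medium)
  a <- (z_rest + z_seg) / baseline_impedance(geom, medium, frequency)
  if (Mod(a) < 1)
    warning(sprintf("|A| = %.4g < 1: cell less resistive than displaced medium",
                    Mod(a)))
  a
}

#' Invert the 1 kHz amplitude ratio for the leak resistance
#'
#' At low frequency the membrane capacitor approaches an open circuit, so
#' the occupied segment reduces to `R_leak` alone and the amplitude ratio
#' gives `R_leak = A_1kHz * R_total - R_rest`, where `R_total` is the
#' baseline resistance and `R_rest` the unoccupied-channel remainder plus
#' access resistance. `A_1kHz` below `R_rest / R_total` is infeasible (it
#' would imply negative seal resistance) and raises an error naming the
#' bound. This open-membrane value is exact as `w C -> 0`; the chain-level
#' [invert_electrical()] refines it against the full circuit.
#'
#' @param A_1kHz Amplitude ratio at 1 kHz (dimensionless).
#' @inheritParams forward_cell_impedance_ratio
#' @return `R_leak` in Ohm.
#' @export
#' @examples
#' invert_leak_resistance(3.41, channel_geometry(), medium_model(),
#'                        L_elongation = 28)
invert_leak_resistance <- function(A_1kHz, geom, medium, L_elongation) {
  if (!is.numeric(A_1kHz) || length(A_1kHz) != 1L || !is.finite(A_1kHz))
    stop("A_1kHz must be a single finite number")
  if (!is.numeric(L_elongation) || !is.finite(L_elongation) ||
      L_elongation <= 0 || L_elongation >= geom$length)
    stop("L_elongation must satisfy 0 < L_elongation < channel length")
  r_total <- Re(baseline_impedance(geom, medium, 1e3))
  r_rest <- medium$access_resistance +
    segment_resistance(geom$length - L_elongation, geom, medium)
  bound <- r_rest / r_total
  if (A_1kHz <= bound)
    stop(sprintf("A_1kHz = %.4g is infeasible: it must exceed R_rest/R_total = %.4g",
                 A_1kHz, bound))
  A_1kHz * r_total - r_rest
}

#' Invert the 100 kHz amplitude and phase for the cell branch
#'
#' Given `R_leak`, the amplitude and phase of the with-cell/baseline ratio
#' at 100 kHz determine the complex occupied-segment impedance exactly:
#' `Z_seg = A exp(j phase) Z_total - R_rest`, and the series branch follows
#' from `1/Z_branch = 1/Z_seg - 1/R_leak`, giving `R_cytoplasm =
#' Re(Z_branch)` and `C_membrane = -1/(w Im(Z_branch))`. The recovered pair
#' is verified by running the forward model; the relative residual must be
#' below `tol`.
#'
#' A non-negative imaginary part of the branch (e.g. zero phase at the
#' low-frequency amplitude limit) leaves the capacitance unidentifiable and
#' raises an error, as does a non-positive real part.
#'
#' @param A_100kHz Amplitude ratio at 100 kHz (dimensionless).
#' @param phase_100kHz Phase of the with-cell/baseline impedance ratio at
#'   100 kHz, radians.
#' @param R_leak Leak resistance (Ohm), > 0.
#' @inheritParams forward_cell_impedance_ratio
#' @param frequency Measurement frequency, Hz.
#' @param tol Maximum relative forward-model residual accepted.
#' @return A list with `R_cytoplasm` (Ohm), `C_membrane` (F) and
#'   `residual` (relative).
#' @export
invert_cell_circuit <- function(A_100kHz, phase_100kHz, R_leak, geom, medium,
                                L_elongation, frequency = 1e5, tol = 1e-8) {
  if (!is.numeric(R_leak) || length(R_leak) != 1L || !is.finite(R_leak) ||
      R_leak <= 0)
    stop("R_leak must be a single finite positive number")
  if (!is.numeric(A_100kHz) || !is.finite(A_100kHz) || A_100kHz <= 0)
    stop("A_100kHz must be finite and > 0")
  if (!is.numeric(phase_100kHz) || !is.finite(phase_100kHz))
    stop("phase_100kHz must be finite")

  w <- 2 * pi * frequency
  z_total <- baseline_impedance(geom, medium, frequency)
  r_rest <- medium$access_resistance +
    segment_resistance(geom$length - L_elongation, geom, medium)
  z_seg <- A_100kHz * exp(1i * phase_100kHz) * z_total - r_rest
  if (Re(z_seg) <= 0)
    stop(sprintf(
      "A_100kHz = %.4g at phase %.4g rad is infeasible: occupied segment resistance would be <= 0",
      A_100kHz, phase_100kHz))
  y_branch <- 1 / z_seg - 1 / R_leak
  if (Mod(y_branch) == 0)
    stop("degenerate input: occupied segment indistinguishable from R_leak alone")
  z_branch <- 1 / y_branch
  if (Im(z_branch) >= 0)
    stop("phase inconsistent with any positive membrane capacitance (capacitance unidentifiable)")
  r_cyt <- Re(z_branch)
  if (r_cyt <= 0)
    stop("recovered cytoplasm resistance is not positive; inputs inconsistent with the circuit")
  c_mem <- -1 / (w * Im(z_branch))

  a_check <- suppressWarnings(forward_cell_impedance_ratio(
    circuit_params(R_leak, r_cyt, c_mem), geom, medium, L_elongation,
    frequency))
  residual <- Mod(a_check - A_100kHz * exp(1i * phase_100kHz)) / A_100kHz
  if (residual > tol)
    stop(sprintf("circuit inversion did not reproduce the inputs (relative residual %.3g)",
                 residual))
  list(R_cytoplasm = r_cyt, C_membrane = c_mem, residual = residual)
}

#' Translate lumped circuit values to intrinsic electrical markers
#'
#' The lumped membrane capacitance is modelled as the two cross-sectional
#' membrane caps (leading and trailing faces, each `width x height`) in
#' series along the current path, so the specific membrane capacitance is
#' `2 C_membrane / (width height)`; the cytoplasm column of length
#' `L_elongation` gives `sigma_cytoplasm = L_elongation / (R_cytoplasm
#' width height)`. Values far outside the physiological ranges 0.5-10
#' uF/cm^2 and 0.1-3 S/m trigger a warning.
#'
#' @param R_cytoplasm Cytoplasm resistance, Ohm (> 0).
#' @param C_membrane Lumped membrane capacitance, F (> 0).
#' @param L_elongation Elongated cell length (um), > 0.
#' @param geom A [channel_geometry()].
#' @return An object of class `intrinsic_electrical`: list with
#'   `C_specific_membrane` (uF/cm^2) and `sigma_cytoplasm` (S/m).
#' @export
#' @examples
#' circuit_to_intrinsic(2.8e5, 1e-12, 28, channel_geometry())
circuit_to_intrinsic <- function(R_cytoplasm, C_membrane, L_elongation, geom) {
  vals <- c(R_cytoplasm = R_cytoplasm, C_membrane = C_membrane,
            L_elongation = L_elongation)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0))
    stop("R_cytoplasm, C_membrane and L_elongation must all be finite and > 0")
  area <- cross_section_m2(geom)
  c_spec_si <- 2 * C_membrane / area                     # F/m^2
  c_spec <- c_spec_si * 100                              # 1 F/m^2 = 100 uF/cm^2
  sigma <- L_elongation * 1e-6 / (R_cytoplasm * area)    # S/m
  if (c_spec < 0.5 || c_spec > 10)
    warning(sprintf("C_specific_membrane = %.3g uF/cm^2 outside plausible range [0.5, 10]",
                    c_spec))
  if (sigma < 0.1 || sigma > 3)
    warning(sprintf("sigma_cytoplasm = %.3g S/m outside plausible range [0.1, 3]",
                    sigma))
  structure(list(C_specific_membrane = c_spec, sigma_cytoplasm = sigma),
            class = "intrinsic_electrical")
}

#' @export
print.intrinsic_electrical <- function(x, ...) {
  cat(sprintf("<intrinsic_electrical> C_specific_membrane = %.3g uF/cm^2, sigma_cytoplasm = %.3g S/m\n",
              x$C_specific_membrane, x$sigma_cytoplasm))
  invisible(x)
}

#' Inverse translation: intrinsic markers to lumped circuit values
#'
#' Exact inverse of [circuit_to_intrinsic()]; used by the synthetic-data
#' generator to build the circuit a simulated cell presents.
#'
#' @param C_specific_membrane Specific membrane capacitance, uF/cm^2 (> 0).
#' @param sigma_cytoplasm Cytoplasm conductivity, S/m (> 0).
#' @inheritParams circuit_to_intrinsic
#' @return A list with `R_cytoplasm` (Ohm) and `C_membrane` (F).
#' @export
intrinsic_to_circuit <- function(C_specific_membrane, sigma_cytoplasm,
                                 L_elongation, geom) {
  vals <- c(C_specific_membrane, sigma_cytoplasm, L_elongation)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0))
    stop("C_specific_membrane, sigma_cytoplasm and L_elongation must all be > 0")
  area <- cross_section_m2(geom)
  c_mem <- (C_specific_membrane / 100) * area / 2
  r_cyt <- L_elongation * 1e-6 / (sigma_cytoplasm * area)
  list(R_cytoplasm = r_cyt, C_membrane = c_mem)
}

#' Full electrical inversion from measured ratios to intrinsic markers
#'
#' Chains the two inversion steps and, by default, refines them jointly.
#' The open-membrane estimate of `R_leak` from the 1 kHz amplitude is exact
#' only in the zero-frequency limit; with realistic membrane capacitances
#' it carries a relative error of order `(R_leak w C)^2` that propagates
#' into the 100 kHz solve. The refinement alternates (a) the exact 100 kHz
#' elimination at the current `R_leak` with (b) a scalar solve of the full
#' 1 kHz amplitude equation (amplitude only; the 1 kHz phase is not used)
#' for `R_leak` at the current branch values, until `R_leak` is stationary.
#'
#' @param A_1kHz,A_100kHz Measured amplitude ratios (dimensionless).
#' @param phase_100kHz Phase of the impedance ratio at 100 kHz, radians.
#' @inheritParams forward_cell_impedance_ratio
#' @param f_low,f_high The two measurement frequencies, Hz.
#' @param refine Run the joint fixed-point refinement (default `TRUE`).
#' @param tol Relative convergence tolerance on `R_leak`.
#' @param max_iter Maximum refinement iterations.
#' @return A list with `R_leak`, `R_cytoplasm`, `C_membrane`,
#'   `C_specific_membrane`, `sigma_cytoplasm`, `iterations` and `residual`
#'   (relative 100 kHz forward residual).
#' @export
#' @examples
#' geom <- channel_geometry(); med <- medium_model()
#' cc <- circuit_params(3e6, 2.8e5, 1e-12)
#' a1 <- forward_cell_impedance_ratio(cc, geom, med, 28, 1e3)
#' a2 <- forward_cell_impedance_ratio(cc, geom, med, 28, 1e5)
#' invert_electrical(Mod(a1), Mod(a2), Arg(a2), geom, med, 28)
invert_electrical <- function(A_1kHz, A_100kHz, phase_100kHz, geom, medium,
                              L_elongation, f_low = 1e3, f_high = 1e5,
                              refine = TRUE, tol = 1e-12, max_iter = 40L) {
  r_leak <- invert_leak_resistance(A_1kHz, geom, medium, L_elongation)
  branch <- invert_cell_circuit(A_100kHz, phase_100kHz, r_leak, geom, medium,
                                L_elongation, frequency = f_high)
  iterations <- 0L
  if (refine) {
    w_low <- 2 * pi * f_low
    z_total_low <- Re(baseline_impedance(geom, medium, f_low))
    r_rest <- medium$access_resistance +
      segment_resistance(geom$length - L_elongation, geom, medium)
    target <- A_1kHz * z_total_low
    converged <- FALSE
    for (iterations in seq_len(max_iter)) {
      z_branch <- branch$R_cytoplasm + 1 / (1i * w_low * branch$C_membrane)
      # |r_rest + R || z_branch| is strictly increasing in R
      amp_mismatch <- function(r) {
        Mod(r_rest + r * z_branch / (r + z_branch)) - target
      }
      sol <- stats::uniroot(amp_mismatch, lower = r_leak * 1e-6,
                            upper = max(r_leak, target) * 1e6,
                            tol = r_leak * 1e-14)
      r_new <- sol$root
      step <- abs(r_new - r_leak) / r_leak
      r_leak <- r_new
      branch <- invert_cell_circuit(A_100kHz, phase_100kHz, r_leak, geom,
                                    medium, L_elongation, frequency = f_high)
      if (step < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop(sprintf("electrical inversion did not converge in %d iterations (last step %.3g)",
                   max_iter, step))
  }
  intr <- suppressWarnings(circuit_to_intrinsic(
    branch$R_cytoplasm, branch$C_membrane, L_elongation, geom))
  list(R_leak = r_leak,
       R_cytoplasm = branch$R_cytoplasm,
       C_membrane = branch$C_membrane,
       C_specific_membrane = intr$C_specific_membrane,
       sigma_cytoplasm = intr$sigma_cytoplasm,
       iterations = iterations,
       residual = branch$residual)
}
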