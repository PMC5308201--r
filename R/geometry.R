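#' Constriction-channel geometry
#'
#' Dimensions of the constriction channel and the normalizing diameter used
#' by the mechanical entry model. The default geometry is a 10 x 10 um
#' square cross-section, 200 um long channel; `d_channel`, the length scale
#' that normalizes aspiration lengths, defaults to the channel width (the
#' single length scale of a square cross-section).
#'
#' @param width Channel width (um).
#' @param height Channel height (um).
#' @param length Channel length (um).
#' @param d_channel Normalizing diameter for the mechanical model (um).
#' @return An object of class `channel_geometry`.
#' @export
#' @examples
#' channel_geometry()
channel_geometry <- function(width = 10, height = 10, length = 200,
                             d_channel = width) {
  vals <- c(width = width, height = height, length = length,
            d_channel = d_channel)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0))
    stop("all channel dimensions must be finite and > 0")
  structure(as.list(vals), class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    "<channel_geometry> %g x %g um cross-section, %g um long (D_channel = %g um)\n",
    x$width, x$height, x$length, x$d_channel))
  invisible(x)
}

#' Suspending-medium electrical model
#'
#' Conductivity of the culture medium filling the channel and a lumped
#' series access resistance for everything outside the constriction
#' (loading channels, wiring). Default conductivity 1.5 S/m, typical for
#' culture medium.
#'
#' @param conductivity Medium conductivity (S/m).
#' @param access_resistance Series resistance outside the constriction (Ohm).
#' @return An object of class `medium_model`.
#' @export
medium_model <- function(conductivity = 1.5, access_resistance = 0) {
  if (!is.numeric(conductivity) || !is.finite(conductivity) || conductivity <= 0)
    stop("medium conductivity must be finite and > 0")
  if (!is.numeric(access_resistance) || !is.finite(access_resistance) ||
      access_resistance < 0)
    stop("access_resistance must be finite and >= 0")
  structure(list(conductivity = conductivity,
                 access_resistance = access_resistance),
            class = "medium_model")
}

#' @export
print.medium_model <- function(x, ...) {
  cat(sprintf("<medium_model> sigma_m = %g S/m, R_access = %g Ohm\n",
              x$conductivity, x$access_resistance))
  invisible(x)
}

# cross-sectional area in m^2 (geometry is stored in um)
cross_section_m2 <- function(geom) geom$width * 1e-6 * geom$height * 1e-6
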