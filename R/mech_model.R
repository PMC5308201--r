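#' Coefficients of the viscoelastic constriction-entry model
#'
#' The entry of a cell into the constriction channel is described by two
#' linear relations between the normalized aspiration lengths and the
#' pressure-to-modulus ratio `x = P_aspiration / E_instantaneous`:
#'
#' \deqn{L_{inst}/D_{channel} = a_{inst}(f_c) \, x + b_{inst}(f_c)}
#' \deqn{L_{trans}/D_{channel} = a_{trans}(f_c) \, x + b_{trans}(f_c)}
#'
#' where each slope/intercept is a quadratic polynomial in the cell-wall
#' friction coefficient `f_c`. The twelve default coefficients come from
#' finite-element simulation of an incompressible viscoelastic cell entering
#' a rigid channel and are taken as given.
#'
#' Each coefficient vector is ordered (quadratic, linear, constant). With
#' the defaults the instantaneous slope polynomial is positive for every
#' real `f_c` and the transitional slope polynomial negative for every real
#' `f_c` (both discriminants are negative), so the instantaneous relation
#' always increases with pressure and the transitional one always decreases.
#'
#' @param a_inst Slope polynomial of the instantaneous relation.
#' @param b_inst Intercept polynomial of the instantaneous relation.
#' @param a_trans Slope polynomial of the transitional relation.
#' @param b_trans Intercept polynomial of the transitional relation.
#' @return An object of class `mech_coefficients`.
#' @export
#' @examples
#' mech_coefficients()
mech_coefficients <- function(a_inst = c(44.27, -37.24, 13.70),
                              b_inst = c(-5.31, 2.84, -0.59),
                              a_trans = c(-60.40, 40.05, -8.68),
                              b_trans = c(1.99, 0.03, 1.60)) {
  coefs <- list(a_inst = a_inst, b_inst = b_inst,
                a_trans = a_trans, b_trans = b_trans)
  for (nm in names(coefs)) {
    v <- coefs[[nm]]
    if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v)))
      stop(sprintf("'%s' must be 3 finite coefficients (quadratic, linear, constant)",
                   nm))
  }
  structure(coefs, class = "mech_coefficients")
}

# evaluate quadratic p[1]*f^2 + p[2]*f + p[3]
quad_eval <- function(p, f) p[1L] * f * f + p[2L] * f + p[3L]

#' Forward entry model: normalized aspiration lengths
#'
#' Evaluates the two entry relations exactly (plain polynomial arithmetic,
#' no clipping): at small `x` the instantaneous relation is formally
#' negative because of its negative intercept; callers that need a physical
#' cell must check positivity themselves.
#'
#' @param f_c Friction coefficient (dimensionless), finite.
#' @param x Pressure ratio `P_aspiration / E_instantaneous`
#'   (dimensionless), finite and `>= 0`. Recycled against `f_c`.
#' @param coeffs A [mech_coefficients()] object.
#' @return A list with vectors `l_inst` and `l_trans`, the normalized
#'   lengths `L_instantaneous / D_channel` and `L_transitional / D_channel`.
#' @export
#' @examples
#' forward_entry_lengths(f_c = 0, x = 0)   # the two intercepts
#' forward_entry_lengths(f_c = 0.2, x = 0.1)
forward_entry_lengths <- function(f_c, x, coeffs = mech_coefficients()) {
  if (!inherits(coeffs, "mech_coefficients"))
    stop("'coeffs' must be a mech_coefficients object")
  if (!is.numeric(f_c) || !is.numeric(x) ||
      any(!is.finite(f_c)) || any(!is.finite(x)))
    stop("f_c and x must be finite numbers")
  if (any(x < 0))
    stop("pressure ratio x = P_aspiration/E_instantaneous must be >= 0")
  list(l_inst  = quad_eval(coeffs$a_inst,  f_c) * x + quad_eval(coeffs$b_inst,  f_c),
       l_trans = quad_eval(coeffs$a_trans, f_c) * x + quad_eval(coeffs$b_trans, f_c))
}

#' Invert the entry model for Young's modulus and friction coefficient
#'
#' Solves the two entry relations for the two unknowns `E_instantaneous`
#' and `f_c` given the measured aspiration lengths and the applied
#' pressure. The transitional relation is eliminated first: for a candidate
#' `f_c`, `x(f_c) = (l_trans - b_trans(f_c)) / a_trans(f_c)`; the scalar
#' residual `g(f_c) = a_inst(f_c) x(f_c) + b_inst(f_c) - l_inst` is
#' evaluated on a dense grid over `search_interval`, sign changes between
#' feasible grid points (`x > 0`) are refined by bisection, and
#' `E_instantaneous = P_aspiration / x` at the accepted root.
#'
#' Candidates with non-positive pressure ratio are discarded. If several
#' roots survive, the one with smallest absolute residual is returned
#' (residuals at root-finder noise level count as tied, broken by smallest
#' `f_c`) and the status records the multiplicity. The system is genuinely
#' two-valued over much of its domain — two `(E, f_c)` pairs can reproduce
#' the same measured length pair exactly — so the multiplicity status
#' deserves attention; the smallest-`f_c` rule selects the lower solution
#' branch. If
#' none survive no values are fabricated: the solution carries status
#' `"no_solution"` and `NA` estimates. A root within one grid spacing of an
#' interval edge is flagged `"out_of_domain"`.
#'
#' @param L_instantaneous,L_transitional Measured aspiration lengths (um), > 0.
#' @param D_channel Normalizing channel diameter (um), > 0.
#' @param P_aspiration Applied aspiration pressure (kPa), > 0.
#' @param coeffs A [mech_coefficients()] object.
#' @param search_interval Bounds of the `f_c` search (length-2, increasing).
#' @param tol Bisection tolerance on `f_c`.
#' @param n_grid Number of bracketing grid points.
#' @return An object of class `mech_solution`: a list with
#'   `E_instantaneous` (kPa), `f_c`, `residual` (dimensionless `|g|`),
#'   `status` (one of `"ok"`, `"multiple_solutions_resolved"`,
#'   `"no_solution"`, `"out_of_domain"`) and `n_roots`.
#' @export
#' @examples
#' fw <- forward_entry_lengths(f_c = 0.2, x = 0.1)
#' invert_entry(fw$l_inst * 10, fw$l_trans * 10,
#'              D_channel = 10, P_aspiration = 0.5)
invert_entry <- function(L_instantaneous, L_transitional, D_channel = 10,
                         P_aspiration, coeffs = mech_coefficients(),
                         search_interval = c(0, 1), tol = 1e-10,
                         n_grid = 2001L) {
  for (nm in c("L_instantaneous", "L_transitional", "D_channel", "P_aspiration")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single finite positive number", nm))
  }
  if (!is.numeric(search_interval) || length(search_interval) != 2L ||
      any(!is.finite(search_interval)) ||
      search_interval[2L] <= search_interval[1L])
    stop("'search_interval' must be an increasing pair of finite f_c bounds")

  l_i <- L_instantaneous / D_channel
  l_t <- L_transitional / D_channel

  x_of <- function(f) (l_t - quad_eval(coeffs$b_trans, f)) / quad_eval(coeffs$a_trans, f)
  g_of <- function(f) {
    x <- x_of(f)
    quad_eval(coeffs$a_inst, f) * x + quad_eval(coeffs$b_inst, f) - l_i
  }

  fgrid <- seq(search_interval[1L], search_interval[2L], length.out = n_grid)
  xg <- x_of(fgrid)
  gg <- g_of(fgrid)
  feas <- is.finite(gg) & xg > 0

  roots <- numeric(0)
  # exact zeros at feasible grid points
  hit <- which(feas & gg == 0)
  roots <- c(roots, fgrid[hit])
  # sign changes between consecutive feasible points, refined by bisection
  idx <- which(feas[-n_grid] & feas[-1L] & gg[-n_grid] * gg[-1L] < 0)
  for (i in idx) {
    lo <- fgrid[i]; hi <- fgrid[i + 1L]
    glo <- gg[i]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      gm <- g_of(mid)
      if (gm == 0) { lo <- mid; hi <- mid; break }
      if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }

  if (length(roots) == 0L) {
    return(structure(list(E_instantaneous = NA_real_, f_c = NA_real_,
                          residual = NA_real_, status = "no_solution",
                          n_roots = 0L),
                     class = "mech_solution"))
  }

  res <- abs(vapply(roots, g_of, numeric(1)))
  # smallest |g| first; residuals at root-finder noise level (< 1e-8) are
  # genuine roots and count as tied, broken by smallest f_c
  ord <- order(pmax(res, 1e-8), roots)
  f_best <- roots[ord[1L]]
  x_best <- x_of(f_best)
  spacing <- (search_interval[2L] - search_interval[1L]) / (n_grid - 1L)
  status <- if (min(f_best - search_interval[1L],
                    search_interval[2L] - f_best) <= spacing) {
    "out_of_domain"
  } else if (length(roots) > 1L) {
    "multiple_solutions_resolved"
  } else "ok"

  structure(list(E_instantaneous = P_aspiration / x_best,
                 f_c = f_best,
                 residual = abs(g_of(f_best)),
                 status = status,
                 n_roots = length(roots)),
            class = "mech_solution")
}

#' @export
print.mech_solution <- function(x, ...) {
  cat(sprintf("<mech_solution> status = %s\n", x$status))
  if (!is.na(x$E_instantaneous))
    cat(sprintf("  E_instantaneous = %.4g kPa, f_c = %.4g (|residual| = %.3g, %d root%s)\n",
                x$E_instantaneous, x$f_c, x$residual, x$n_roots,
                if (x$n_roots == 1L) "" else "s"))
  invisible(x)
}
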