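#' Flory-Huggins interaction parameter from solubility parameters
#'
#' Estimates the interaction parameter from the solubility parameter
#' mismatch, \eqn{\chi = 0.34 + v (\delta_1-\delta_2)^2 / (RT)}, where `v`
#' is the drug molar volume (cm^3/mol; the lattice-site volume), the deltas
#' are in MPa^(1/2) so the squared difference is in J/cm^3, and the 0.34
#' offset is the customary empirical entropic correction.
#'
#' @param v_drug Drug molar volume (cm^3/mol).
#' @param delta_drug,delta_polymer Total solubility parameters (MPa^(1/2)).
#' @param temperature Temperature in K (default 298.15, i.e. 25 C).
#' @param offset Empirical offset (default 0.34).
#' @return A `pair_interaction` list: `chi`, `delta_diff` (absolute
#'   difference, MPa^(1/2)), `temperature`.
#' @export
chi_interaction <- function(v_drug, delta_drug, delta_polymer,
                            temperature = 298.15, offset = 0.34) {
  if (!is.numeric(v_drug) || any(v_drug <= 0))
    stop("v_drug must be positive")
  if (temperature <= 0) stop("temperature must be positive (K)")
  stopifnot(is.finite(delta_drug), is.finite(delta_polymer))
  ddelta <- abs(delta_drug - delta_polymer)
  chi <- offset + v_drug * ddelta^2 / (gas_constant * temperature)
  structure(list(chi = chi, delta_diff = ddelta, temperature = temperature,
                 offset = offset),
            class = "pair_interaction")
}

gas_constant <- 8.314  # J/(mol K)

#' @export
print.pair_interaction <- function(x, ...) {
  cat(sprintf("<pair_interaction> chi %.3f (ddelta %.2f MPa^1/2, T %.2f K)\n",
              x$chi, x$delta_diff, x$temperature))
  invisible(x)
}

#' Lattice ratio for the Flory-Huggins entropy term
#'
#' Ratio of the volume of one polymer chain to the volume of a lattice
#' site, with the drug molar volume taken as the site volume.
#'
#' @param chain_volume Polymer chain molar volume (cm^3/mol), typically
#'   [polymer_chain_volume()].
#' @param v_drug Drug molar volume (cm^3/mol).
#' @return Dimensionless ratio `m`.
#' @export
lattice_ratio <- function(chain_volume, v_drug) {
  if (!is.numeric(chain_volume) || chain_volume <= 0)
    stop("chain_volume must be positive")
  if (!is.numeric(v_drug) || v_drug <= 0) stop("v_drug must be positive")
  chain_volume / v_drug
}

#' Free energy of mixing per lattice site
#'
#' \deqn{\Delta G_{mix}/RT = \phi\ln\phi + \frac{1-\phi}{m}\ln(1-\phi)
#'       + \chi\,\phi(1-\phi)}
#' with `phi` the drug volume fraction. Vectorized over `phi`; the open
#' interval (0,1) is enforced (the function tends to 0 at both limits).
#'
#' @param phi Drug volume fraction(s), strictly inside (0,1).
#' @param chi Interaction parameter.
#' @param m Lattice ratio (> 0).
#' @return Dimensionless free energy of mixing values.
#' @export
gibbs_mixing <- function(phi, chi, m) {
  if (m <= 0) stop("m must be positive")
  if (any(phi <= 0 | phi >= 1))
    stop("phi must lie strictly inside (0, 1)")
  phi * log(phi) + (1 - phi) / m * log(1 - phi) + chi * phi * (1 - phi)
}

#' Spinodal compositions
#'
#' Roots of the second composition derivative of the mixing free energy,
#' \eqn{1/\phi + 1/(m(1-\phi)) - 2\chi = 0}, rearranged as the quadratic
#' \eqn{2\chi m\,\phi^2 - (2\chi m + m - 1)\phi + m = 0}. The unstable
#' (spinodal) region exists only above the critical interaction strength
#' \eqn{\chi_c = (1 + 1/\sqrt m)^2/2}.
#'
#' @param chi Interaction parameter (> 0).
#' @param m Lattice ratio (> 0).
#' @return Numeric vector of 0-2 roots inside (0,1), ascending.
#' @export
spinodal_compositions <- function(chi, m) {
  if (chi <= 0) stop("chi must be positive")
  if (m <= 0) stop("m must be positive")
  a <- 2 * chi * m
  b <- -(2 * chi * m + m - 1)
  cc <- m
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(numeric(0))
  roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  roots[roots > 0 & roots < 1]
}

#' Phase diagram with profile classification
#'
#' Evaluates the mixing free energy on a composition grid, locates the free
#' energy minimum and the critical composition (first sign change from
#' negative to positive, refined by bisection), attaches the spinodal
#' roots, and classifies the profile:
#' \describe{
#'   \item{miscible_all_proportions}{free energy negative over the whole
#'     evaluation grid;}
#'   \item{immiscible_bulk}{free energy positive over the bulk composition
#'     range (0.05-0.95; the dilute tails are excluded because the entropic
#'     term forces the exact curve below zero near the endpoints for any
#'     finite chi);}
#'   \item{partially_miscible}{negative up to a finite critical drug
#'     fraction, positive beyond.}
#' }
#'
#' @param chi Interaction parameter.
#' @param m Lattice ratio.
#' @param n_grid Number of grid points (>= 101; default 2001).
#' @param phi_limits Evaluation interval, strictly inside (0,1).
#' @return A `phase_diagram` object: grid, free-energy values, `phi_min`,
#'   `phi_crit`, `spinodal`, `profile_class`, plus `chi` and `m`.
#' @export
phase_diagram <- function(chi, m, n_grid = 2001,
                          phi_limits = c(1e-4, 1 - 1e-4)) {
  if (n_grid < 101) stop("n_grid must be at least 101")
  stopifnot(phi_limits[1] > 0, phi_limits[2] < 1,
            phi_limits[1] < phi_limits[2])
  phi <- seq(phi_limits[1], phi_limits[2], length.out = n_grid)
  g <- gibbs_mixing(phi, chi, m)

  phi_min <- if (any(g < 0)) {
    opt <- stats::optimize(gibbs_mixing, interval = phi_limits,
                           chi = chi, m = m, tol = 1e-10)
    opt$minimum
  } else NA_real_

  # first negative-to-positive sign change, bisected to 1e-10
  phi_crit <- NA_real_
  sgn <- sign(g)
  idx <- which(sgn[-length(sgn)] < 0 & sgn[-1] >= 0)
  if (length(idx) > 0) {
    i <- idx[1]
    phi_crit <- stats::uniroot(function(p) gibbs_mixing(p, chi, m),
                               lower = phi[i], upper = phi[i + 1],
                               tol = 1e-10)$root
  }

  sp <- if (chi > 0) spinodal_compositions(chi, m) else numeric(0)
  bulk <- phi >= 0.05 & phi <= 0.95
  profile_class <- if (all(g < 0)) "miscible_all_proportions"
  else if (all(g[bulk] > 0)) "immiscible_bulk"
  else "partially_miscible"

  structure(list(chi = chi, m = m, phi = phi, g = g,
                 phi_min = phi_min, phi_crit = phi_crit,
                 spinodal = sp, profile_class = profile_class),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> chi %.3f, m %.4g: %s\n",
              x$chi, x$m, x$profile_class))
  if (!is.na(x$phi_min))
    cat(sprintf("  free-energy minimum at phi = %.4f\n", x$phi_min))
  if (!is.na(x$phi_crit))
    cat(sprintf("  critical drug fraction phi_crit = %.4f\n", x$phi_crit))
  if (length(x$spinodal) > 0)
    cat("  spinodal:", paste(sprintf("%.4f", x$spinodal), collapse = ", "),
        "\n")
  invisible(x)
}
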