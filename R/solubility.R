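#' Solubility parameters from the Fedors scheme
#'
#' The Hildebrand total solubility parameter is the square root of the
#' cohesive energy density: group cohesive energies (J/mol) are summed over
#' the fragmentation and divided by the summed molar volume (cm^3/mol), so
#' that the ratio is in J/cm^3 = MPa and its square root in MPa^(1/2).
#'
#' @param group_counts Named vector or list of group counts (fractional
#'   counts are allowed, e.g. for averaged substituent proportions).
#' @param table A Fedors `gc_table` (defaults to the bundled constants).
#' @return A `solubility_parameters` object with `delta_total` (MPa^(1/2))
#'   and `v` (cm^3/mol); the dispersive/polar/hydrogen-bonding components
#'   are not defined under this scheme.
#' @export
fedors_parameters <- function(group_counts, table = gc_table("fedors")) {
  stopifnot(attr(table, "method") == "fedors")
  s <- gc_sums(group_counts, table, c("E", "V"))
  if (s[["V"]] <= 0)
    stop("summed molar volume must be positive (got ", format(s[["V"]]), ")")
  new_solubility_parameters(
    method = "fedors",
    delta_total = sqrt(s[["E"]] / s[["V"]]),
    v = s[["V"]])
}

#' Solubility parameters from the Hoftyzer-van Krevelen scheme
#'
#' Splits the solubility parameter into dispersive, polar and
#' hydrogen-bonding components:
#' \deqn{\delta_d = \sum F_{d,i} / V,\quad
#'       \delta_p = \sqrt{\sum F_{p,i}^2} / V,\quad
#'       \delta_h = \sqrt{\sum E_{h,i} / V}.}
#' Note the polar term: each group's squared constant is multiplied by its
#' count before the square root (`count * Fp^2`, not `(count*Fp)^2`) --
#' the standard Hoftyzer-van Krevelen convention, which makes the polar
#' component shrink (per volume) as the repeat unit grows. The total is
#' \eqn{\delta_{tot} = \sqrt{\delta_d^2+\delta_p^2+\delta_h^2}} and the
#' Bagley combined parameter \eqn{\delta_v = \sqrt{\delta_d^2+\delta_p^2}}.
#'
#' @inheritParams fedors_parameters
#' @param table A van Krevelen `gc_table`.
#' @return A `solubility_parameters` object with components `dd`, `dp`,
#'   `dh`, `delta_total`, `delta_v` (all MPa^(1/2)) and `v` (cm^3/mol).
#' @export
van_krevelen_parameters <- function(group_counts,
                                    table = gc_table("van_krevelen")) {
  stopifnot(attr(table, "method") == "van_krevelen")
  counts <- unlist(group_counts)
  s <- gc_sums(counts, table, c("Fd", "Eh", "V"))
  if (s[["V"]] <= 0)
    stop("summed molar volume must be positive (got ", format(s[["V"]]), ")")
  fp2 <- sum(counts * table[names(counts), "Fp"]^2)
  dd <- s[["Fd"]] / s[["V"]]
  dp <- sqrt(fp2) / s[["V"]]
  dh <- sqrt(s[["Eh"]] / s[["V"]])
  new_solubility_parameters(
    method = "van_krevelen",
    dd = dd, dp = dp, dh = dh,
    delta_total = sqrt(dd^2 + dp^2 + dh^2),
    delta_v = sqrt(dd^2 + dp^2),
    v = s[["V"]])
}

new_solubility_parameters <- function(method, delta_total, v,
                                      dd = NA_real_, dp = NA_real_,
                                      dh = NA_real_, delta_v = NA_real_) {
  stopifnot(is.finite(delta_total), delta_total >= 0, is.finite(v))
  structure(list(method = method, dd = dd, dp = dp, dh = dh,
                 delta_total = delta_total, delta_v = delta_v, v = v),
            class = "solubility_parameters")
}

#' @export
print.solubility_parameters <- function(x, ...) {
  cat(sprintf("<solubility_parameters> method: %s\n", x$method))
  if (!is.na(x$dd))
    cat(sprintf("  dd %.1f  dp %.1f  dh %.1f  (MPa^1/2)\n", x$dd, x$dp, x$dh))
  cat(sprintf("  delta_total %.1f MPa^1/2   v %.1f cm^3/mol\n",
              x$delta_total, x$v))
  invisible(x)
}

#' Copolymer solubility parameters
#'
#' Combines per-repeat-unit solubility parameters by mole fraction. The
#' default mode averages the unit-level parameter values (each delta
#' component, the total, and the molar volume are mole-fraction-weighted
#' means of the unit values). The alternative `"average_counts"` mode
#' instead averages the group counts across units and applies the
#' single-unit computation to the averaged fragmentation.
#'
#' Under `"average_parameters"` the reported total for a copolymer is the
#' weighted mean of the unit totals and is therefore not exactly the
#' Pythagorean combination of the averaged components; under
#' `"average_counts"` the Pythagorean identity holds exactly.
#'
#' @param units List of group-count vectors, one per repeat unit (all under
#'   the same scheme).
#' @param fractions Mole fractions, summing to 1.
#' @param method `"fedors"` or `"van_krevelen"`.
#' @param table Optional `gc_table`; defaults to the bundled constants for
#'   `method`.
#' @param mode `"average_parameters"` (default) or `"average_counts"`.
#' @return A `solubility_parameters` object.
#' @export
copolymer_parameters <- function(units, fractions,
                                 method = c("fedors", "van_krevelen"),
                                 table = NULL,
                                 mode = c("average_parameters",
                                          "average_counts")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (is.null(table)) table <- gc_table(method)
  if (attr(table, "method") != method)
    stop("table method (", attr(table, "method"),
         ") does not match requested method (", method, ")")
  if (length(units) != length(fractions))
    stop("'units' and 'fractions' must have the same length")
  fractions <- as.numeric(fractions)
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("mole fractions must sum to 1 (got ", format(sum(fractions)), ")")
  single <- if (method == "fedors") fedors_parameters else
    van_krevelen_parameters

  if (mode == "average_counts") {
    all_labels <- unique(unlist(lapply(units, names)))
    avg <- setNames(numeric(length(all_labels)), all_labels)
    for (i in seq_along(units)) {
      cnt <- unlist(units[[i]])
      avg[names(cnt)] <- avg[names(cnt)] + fractions[i] * cnt
    }
    return(single(avg[avg > 0], table))
  }

  per_unit <- lapply(units, single, table = table)
  wmean <- function(field)
    sum(fractions * vapply(per_unit, `[[`, numeric(1), field))
  if (method == "fedors") {
    new_solubility_parameters(method = method,
                              delta_total = wmean("delta_total"),
                              v = wmean("v"))
  } else {
    structure(list(method = method,
                   dd = wmean("dd"), dp = wmean("dp"), dh = wmean("dh"),
                   delta_total = wmean("delta_total"),
                   delta_v = wmean("delta_v"),
                   v = wmean("v")),
              class = "solubility_parameters")
  }
}

#' Solubility parameters for a compound descriptor
#'
#' Dispatches to the single-fragment or copolymer computation depending on
#' whether the descriptor defines `groups` directly or per repeat unit.
#'
#' @param compound A `compound` object.
#' @param method `"fedors"` or `"van_krevelen"`.
#' @param table Optional `gc_table` override.
#' @param ... Passed on to [copolymer_parameters()] (e.g. `mode`).
#' @return A `solubility_parameters` object.
#' @export
solubility_parameters <- function(compound,
                                  method = c("fedors", "van_krevelen"),
                                  table = NULL, ...) {
  method <- match.arg(method)
  if (is.null(table)) table <- gc_table(method)
  if (!is.null(compound$repeat_units)) {
    units <- lapply(compound$repeat_units, function(u) {
      g <- u$groups[[method]]
      if (is.null(g))
        stop(compound$abbreviation, ": repeat unit '", u$name,
             "' has no group counts for method ", method)
      g
    })
    fr <- vapply(compound$repeat_units, function(u) as.numeric(u$fraction),
                 numeric(1))
    copolymer_parameters(units, fr, method = method, table = table, ...)
  } else {
    g <- compound$groups[[method]]
    if (is.null(g))
      stop(compound$abbreviation, ": no group counts for method ", method)
    if (method == "fedors") fedors_parameters(g, table) else
      van_krevelen_parameters(g, table)
  }
}

#' Molar volume of a whole polymer chain
#'
#' The chain volume (cm^3/mol of chains) is molecular weight over true
#' density. It enters the Flory-Huggins lattice ratio `m`; it is distinct
#' from the per-repeat-unit group-contribution volume reported alongside the
#' solubility parameters.
#'
#' @param mw Molecular weight (g/mol).
#' @param density True density (g/cm^3).
#' @return Chain molar volume in cm^3/mol.
#' @export
polymer_chain_volume <- function(mw, density) {
  if (!is.numeric(mw) || mw <= 0) stop("mw must be positive")
  if (!is.numeric(density) || density <= 0) stop("density must be positive")
  mw / density
}
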