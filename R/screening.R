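#' Greenhalgh solubility-parameter difference criterion
#'
#' An absolute difference below 7 MPa^(1/2) between the drug and polymer
#' total solubility parameters is taken to indicate favorable mixing; the
#' cutoff is strict, so a difference of exactly 7 or more is flagged.
#'
#' @param delta_drug,delta_polymer Total solubility parameters (MPa^(1/2)).
#' @param cutoff Favorability cutoff (default 7 MPa^(1/2)).
#' @return List with `delta_diff` and `verdict` (`"favorable"` or
#'   `"borderline_or_unfavorable"`).
#' @export
greenhalgh <- function(delta_drug, delta_polymer, cutoff = 7) {
  stopifnot(is.finite(delta_drug), is.finite(delta_polymer))
  d <- abs(delta_drug - delta_polymer)
  list(delta_diff = d,
       verdict = if (d < cutoff) "favorable" else "borderline_or_unfavorable")
}

#' Bagley-plot coordinates
#'
#' Projects van Krevelen components onto the Bagley plane: the combined
#' dispersive/polar parameter \eqn{\delta_v=\sqrt{\delta_d^2+\delta_p^2}}
#' against the hydrogen-bonding parameter \eqn{\delta_h}.
#'
#' @param params A `solubility_parameters` object computed under the van
#'   Krevelen scheme (Fedors parameters carry no components and are
#'   rejected).
#' @return A `bagley_point` list with `dv` and `dh` (MPa^(1/2)).
#' @export
bagley_point <- function(params) {
  if (inherits(params, "solubility_parameters")) {
    if (params$method != "van_krevelen" || is.na(params$dd))
      stop("Bagley coordinates require van Krevelen component parameters")
    dv <- sqrt(params$dd^2 + params$dp^2)
    dh <- params$dh
  } else {
    stop("'params' must be a solubility_parameters object")
  }
  structure(list(dv = dv, dh = dh), class = "bagley_point")
}

#' Distance between two Bagley points
#'
#' Euclidean distance in the (delta_v, delta_h) plane; small drug-polymer
#' distances suggest similar interaction capacity and hence miscibility.
#'
#' @param a,b `bagley_point` objects (or lists with `dv` and `dh`).
#' @return Distance in MPa^(1/2).
#' @export
bagley_distance <- function(a, b) {
  sqrt((a$dv - b$dv)^2 + (a$dh - b$dh)^2)
}

#' Pairwise screening table
#'
#' Computes, for every drug-polymer pair, the Greenhalgh differences under
#' both schemes, the Flory-Huggins interaction parameters, and the
#' Bagley-plot distance -- the standard theoretical screening summary.
#'
#' @param compounds Named list of `compound` objects (drugs and polymers),
#'   e.g. from [load_compounds()].
#' @param temperature Temperature in K for the interaction parameter.
#' @return Data frame with one row per (drug, polymer) pair: `ddelta_f`,
#'   `ddelta_vk`, `chi_f`, `chi_vk`, `euc_d`, and verdict columns.
#' @export
screening_table <- function(compounds, temperature = 298.15) {
  roles <- vapply(compounds, function(x) x$role, character(1))
  drugs <- compounds[roles == "drug"]
  polymers <- compounds[roles == "polymer"]
  if (length(drugs) == 0 || length(polymers) == 0)
    stop("need at least one drug and one polymer")
  pf <- lapply(compounds, solubility_parameters, method = "fedors")
  pv <- lapply(compounds, solubility_parameters, method = "van_krevelen")
  rows <- list()
  for (d in names(drugs)) for (p in names(polymers)) {
    gf <- greenhalgh(pf[[d]]$delta_total, pf[[p]]$delta_total)
    gv <- greenhalgh(pv[[d]]$delta_total, pv[[p]]$delta_total)
    cf <- chi_interaction(pf[[d]]$v, pf[[d]]$delta_total,
                          pf[[p]]$delta_total, temperature)
    cv <- chi_interaction(pv[[d]]$v, pv[[d]]$delta_total,
                          pv[[p]]$delta_total, temperature)
    eu <- bagley_distance(bagley_point(pv[[d]]), bagley_point(pv[[p]]))
    rows[[length(rows) + 1]] <- data.frame(
      drug = d, polymer = p,
      ddelta_f = gf$delta_diff, verdict_f = gf$verdict,
      ddelta_vk = gv$delta_diff, verdict_vk = gv$verdict,
      chi_f = cf$chi, chi_vk = cv$chi, euc_d = eu,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "temperature") <- temperature
  out
}
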