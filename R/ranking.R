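#' Experimental polymer ranking for one drug and method
#'
#' Orders polymers by their potential to deliver glass solutions at high
#' drug loading: the primary key is the highest loading whose aggregated
#' class is A (descending). Ties are broken by (1) higher mixed-Tg value at
#' that loading, (2) narrower Tg width, (3) abbreviation, alphabetically.
#' Polymers that never reach class A rank after all that do, ordered first
#' by their best (least severe) achieved class and then by the same
#' tie-breaks at the loading of that best class.
#'
#' @param cells Aggregated classification cells for one drug and one method
#'   (the `cells` component of [classify_campaign()], subset accordingly).
#' @param top Number of leading polymers to keep (`NULL` for all).
#' @return A `polymer_ranking` list: `polymers` (ordered abbreviations),
#'   `basis`, and a `detail` data frame with the sort keys.
#' @export
rank_experimental <- function(cells, top = NULL) {
  stopifnot(nrow(cells) > 0)
  if (length(unique(cells$drug)) != 1 || length(unique(cells$method)) != 1)
    stop("cells must belong to a single drug and method")
  per <- lapply(split(cells, cells$polymer), function(e) {
    a <- e[e$class == "A", , drop = FALSE]
    if (nrow(a) > 0) {
      best <- a[which.max(a$drug_loading), ]
      data.frame(polymer = best$polymer, reaches_a = TRUE,
                 best_dl = best$drug_loading, severity = 0,
                 tg_value = best$tg_value, tg_width = best$tg_width,
                 stringsAsFactors = FALSE)
    } else {
      sev <- min(class_severity[e$class])
      bb <- e[class_severity[e$class] == sev, , drop = FALSE]
      best <- bb[which.max(bb$drug_loading), ]
      data.frame(polymer = best$polymer, reaches_a = FALSE,
                 best_dl = best$drug_loading, severity = sev,
                 tg_value = best$tg_value, tg_width = best$tg_width,
                 stringsAsFactors = FALSE)
    }
  })
  d <- do.call(rbind, per)
  ord <- order(!d$reaches_a, d$severity, -d$best_dl,
               -ifelse(is.na(d$tg_value), -Inf, d$tg_value),
               ifelse(is.na(d$tg_width), Inf, d$tg_width),
               d$polymer)
  d <- d[ord, ]
  rownames(d) <- NULL
  polymers <- d$polymer
  if (!is.null(top)) polymers <- utils::head(polymers, top)
  structure(list(polymers = polymers, basis = "max_DL_glass_solution",
                 detail = d),
            class = "polymer_ranking")
}

#' Theoretical polymer ranking from pair scores
#'
#' Ranks polymers by one theoretical miscibility score (solubility
#' parameter difference, interaction parameter, or Bagley distance),
#' ascending -- smaller means more miscible. Ties are broken
#' alphabetically by abbreviation.
#'
#' @param scores Named numeric vector: one score per polymer.
#' @param basis Label recording which score was used.
#' @param top Number of leading polymers to keep (`NULL` for all).
#' @return A `polymer_ranking` object.
#' @export
rank_theoretical <- function(scores, basis = "score_asc", top = NULL) {
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("scores must be named by polymer abbreviation")
  if (anyNA(scores)) stop("missing score for polymer(s): ",
                          paste(names(scores)[is.na(scores)], collapse = ", "))
  ord <- order(scores, names(scores))
  polymers <- names(scores)[ord]
  if (!is.null(top)) polymers <- utils::head(polymers, top)
  structure(list(polymers = polymers, basis = basis,
                 detail = data.frame(polymer = names(scores)[ord],
                                     score = unname(scores[ord]))),
            class = "polymer_ranking")
}

#' @export
print.polymer_ranking <- function(x, ...) {
  cat(sprintf("<polymer_ranking> (%s) %s\n", x$basis,
              paste(x$polymers, collapse = " > ")))
  invisible(x)
}

#' Top-3 concordance between two polymer rankings
#'
#' Compares a predicted top-3 polymer list against a reference list with
#' two fractions: `f_position` (f1), the share of the three rank positions
#' occupied by the same polymer in both lists, and `f_identity` (f2), the
#' share of polymers common to both lists regardless of position. By
#' construction f1 <= f2. Values are reported both as exact fractions and
#' formatted as 0 / 0.33 / 0.66 / 1 (two-decimal truncation of thirds,
#' the customary presentation).
#'
#' @param predicted,reference Character vectors of length 3 (or
#'   `polymer_ranking` objects), duplicate-free.
#' @return A `concordance_scores` list: `f1`, `f2` (aliases `f_position`,
#'   `f_identity`), `f1_formatted`, `f2_formatted`.
#' @export
concordance <- function(predicted, reference) {
  top3 <- function(x) if (inherits(x, "polymer_ranking")) x$polymers else x
  p <- top3(predicted); r <- top3(reference)
  if (length(p) != 3 || length(r) != 3)
    stop("both lists must contain exactly 3 polymers")
  if (anyDuplicated(p) || anyDuplicated(r))
    stop("ranking lists must be duplicate-free")
  f1 <- sum(p == r) / 3
  f2 <- length(intersect(p, r)) / 3
  structure(list(f1 = f1, f2 = f2, f_position = f1, f_identity = f2,
                 f1_formatted = format_thirds(f1),
                 f2_formatted = format_thirds(f2)),
            class = "concordance_scores")
}

#' Format a fraction of thirds as 0 / 0.33 / 0.66 / 1
#'
#' @param x Fractions in {0, 1/3, 2/3, 1}.
#' @return Character vector.
#' @export
format_thirds <- function(x) {
  vapply(x, function(v) {
    if (abs(v) < 1e-9) "0"
    else if (abs(v - 1) < 1e-9) "1"
    else sprintf("%.2f", floor(v * 100) / 100)
  }, character(1))
}

#' @export
print.concordance_scores <- function(x, ...) {
  cat(sprintf("<concordance> f1 = %s (position), f2 = %s (identity)\n",
              x$f1_formatted, x$f2_formatted))
  invisible(x)
}
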