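#' Merge glass transitions the instrument cannot resolve
#'
#' Modulated DSC cannot separate two glass transitions closer than about
#' 10 degC, so detected events nearer than the resolution limit are merged
#' (single-linkage: chains of events with pairwise gaps below the limit
#' collapse into one). The merged event sits at the height-weighted mean
#' (unweighted when no heights are given) and its width spans the union of
#' the member transition regions. The operation is idempotent.
#'
#' @param events Data frame with columns `value` (degC), `width` (degC) and
#'   optionally `height` (step height, used as the weight).
#' @param resolution Minimum resolvable separation in degC (default 10).
#' @return Data frame of merged events, sorted by `value`.
#' @export
merge_unresolvable_tgs <- function(events, resolution = 10) {
  if (is.null(events) || nrow(events) == 0) return(events)
  stopifnot(all(c("value", "width") %in% names(events)),
            all(events$width > 0))
  events <- events[order(events$value), , drop = FALSE]
  gaps <- diff(events$value)
  grp <- cumsum(c(1, as.integer(gaps >= resolution)))
  out <- lapply(split(events, grp), function(e) {
    w <- if ("height" %in% names(e) && !anyNA(e$height)) e$height
         else rep(1, nrow(e))
    lo <- min(e$value - e$width / 2)
    hi <- max(e$value + e$width / 2)
    data.frame(value = sum(e$value * w) / sum(w), width = hi - lo,
               height = if ("height" %in% names(e)) sum(e$height) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!"height" %in% names(events)) out$height <- NULL
  out
}

#' Classify one screening observation
#'
#' Assigns the three-way miscibility class from the detected thermal and
#' diffraction features, in strict precedence order:
#' \describe{
#'   \item{AC (residual crystallinity)}{sharp diffraction peaks, a drug
#'     melting endotherm, or a recrystallization exotherm;}
#'   \item{AA (amorphous phase separation)}{two or more resolved glass
#'     transitions, or a single transition at a pure-component Tg (within
#'     `tol`), or mesophase endotherms accompanying a drug-like Tg;}
#'   \item{A (glass solution)}{one glass transition strictly between the
#'     pure-component values (beyond `tol` of either).}
#' }
#' Records without any glass transition are rejected, and a single Tg
#' outside the interval spanned by the pure components (widened by `tol`)
#' raises an anomaly error (plasticization by residual solvent suspected)
#' rather than a class.
#'
#' @param obs List or one-row data frame with fields `tg_events` (data
#'   frame of `value`/`width`), `melting_detected`,
#'   `recrystallization_detected`, `mesophase_endotherms` (count),
#'   `xrpd_crystalline`.
#' @param tg_drug,tg_polymer Pure-component glass transitions (degC).
#' @param tol Tolerance for "equal to a pure-component Tg" (degC,
#'   default 3).
#' @param resolution Tg resolution limit passed to
#'   [merge_unresolvable_tgs()].
#' @return A `miscibility_class` list: `label` (`"A"`, `"AA"` or `"AC"`)
#'   and `rationale` (character vector of fired rules).
#' @export
classify_observation <- function(obs, tg_drug, tg_polymer, tol = 3,
                                 resolution = 10) {
  stopifnot(is.finite(tg_drug), is.finite(tg_polymer))
  rationale <- character(0)

  if (isTRUE(obs$xrpd_crystalline))
    rationale <- c(rationale, "xrpd_sharp_peaks")
  if (isTRUE(obs$melting_detected))
    rationale <- c(rationale, "melting_endotherm")
  if (isTRUE(obs$recrystallization_detected))
    rationale <- c(rationale, "recrystallization_exotherm")
  if (length(rationale) > 0)
    return(structure(list(label = "AC", rationale = rationale),
                     class = "miscibility_class"))

  ev <- merge_unresolvable_tgs(obs$tg_events, resolution)
  if (is.null(ev) || nrow(ev) == 0)
    stop("no glass transition detected: record cannot be classified")

  lo <- min(tg_drug, tg_polymer)
  hi <- max(tg_drug, tg_polymer)
  if (nrow(ev) >= 2) {
    return(structure(list(label = "AA", rationale = "multiple_tg"),
                     class = "miscibility_class"))
  }
  tg <- ev$value[1]
  if (tg < lo - tol || tg > hi + tol)
    stop(sprintf(paste0("anomalous glass transition at %.1f degC outside ",
                        "[%.1f, %.1f]: plasticization suspected"),
                 tg, lo - tol, hi + tol))
  near_drug <- abs(tg - tg_drug) <= tol
  near_polymer <- abs(tg - tg_polymer) <= tol
  meso <- !is.null(obs$mesophase_endotherms) &&
    isTRUE(obs$mesophase_endotherms > 0)
  if (near_drug || near_polymer) {
    rationale <- c(if (near_drug) "tg_at_pure_drug",
                   if (near_polymer) "tg_at_pure_polymer",
                   if (meso && near_drug) "mesophase_with_drug_tg")
    return(structure(list(label = "AA", rationale = rationale),
                     class = "miscibility_class"))
  }
  structure(list(label = "A", rationale = "single_intermediate_tg"),
            class = "miscibility_class")
}

#' @export
print.miscibility_class <- function(x, ...) {
  cat(sprintf("<miscibility_class> %s  [%s]\n", x$label,
              paste(x$rationale, collapse = ", ")))
  invisible(x)
}

class_severity <- c(A = 0, AA = 1, AC = 2)

#' Classify a table of screening observations
#'
#' Applies [classify_observation()] to every row of an observation table
#' and aggregates replicates: the campaign-level class of each (drug,
#' polymer, loading, method) cell is the modal class across replicates,
#' with ties resolved toward the less miscible class.
#'
#' @param observations Data frame in the observation-table layout (see
#'   [read_observations()]).
#' @param compounds Named list of `compound` objects supplying the
#'   pure-component glass transitions.
#' @param tol,resolution Passed to [classify_observation()].
#' @return List with `records` (the input plus a `class` column) and
#'   `cells` (one row per cell with the aggregated `class`).
#' @export
classify_campaign <- function(observations, compounds, tol = 3,
                              resolution = 10) {
  obs <- observations
  obs$class <- vapply(seq_len(nrow(obs)), function(i) {
    row <- obs[i, ]
    rec <- list(
      tg_events = parse_tg_events(row$tg_events),
      melting_detected = as.logical(row$melting_detected),
      recrystallization_detected = as.logical(row$recrystallization_detected),
      mesophase_endotherms = as.numeric(row$mesophase_endotherms),
      xrpd_crystalline = as.logical(row$xrpd_crystalline))
    classify_observation(rec,
                         tg_drug = compounds[[row$drug]]$tg_c,
                         tg_polymer = compounds[[row$polymer]]$tg_c,
                         tol = tol, resolution = resolution)$label
  }, character(1))

  key <- interaction(obs$drug, obs$polymer, obs$drug_loading, obs$method,
                     drop = TRUE)
  cells <- do.call(rbind, lapply(split(obs, key), function(e) {
    tab <- table(e$class)
    winners <- names(tab)[tab == max(tab)]
    cls <- winners[which.max(class_severity[winners])]
    tgv <- suppressWarnings(
      mean(vapply(e$tg_events, function(s) parse_tg_events(s)$value[1],
                  numeric(1)), na.rm = TRUE))
    tgw <- suppressWarnings(
      mean(vapply(e$tg_events, function(s) parse_tg_events(s)$width[1],
                  numeric(1)), na.rm = TRUE))
    data.frame(drug = e$drug[1], polymer = e$polymer[1],
               drug_loading = e$drug_loading[1], method = e$method[1],
               class = cls, tg_value = tgv, tg_width = tgw,
               n_replicates = nrow(e), stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  list(records = obs, cells = cells)
}

# "value:width;value:width" <-> data.frame(value, width)
parse_tg_events <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(value = numeric(0), width = numeric(0)))
  parts <- strsplit(strsplit(as.character(s), ";", fixed = TRUE)[[1]],
                    ":", fixed = TRUE)
  data.frame(value = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
             width = vapply(parts, function(p) as.numeric(p[2]), numeric(1)))
}

format_tg_events <- function(events) {
  if (is.null(events) || nrow(events) == 0) return("")
  paste(sprintf("%g:%g", events$value, events$width), collapse = ";")
}

#' Read / write observation tables
#'
#' Observation tables are tab-separated text with one row per (drug,
#' polymer, drug loading, method, replicate); glass transitions are encoded
#' in a single column as semicolon-separated `value:width` pairs.
#'
#' @param path File path.
#' @return Data frame of observations.
#' @export
read_observations <- function(path) {
  obs <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("drug", "polymer", "drug_loading", "method", "tg_events",
            "melting_detected", "recrystallization_detected",
            "mesophase_endotherms", "xrpd_crystalline")
  miss <- setdiff(need, names(obs))
  if (length(miss) > 0)
    stop("observation table missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(obs$drug_loading <= 0 | obs$drug_loading >= 1))
    stop("drug_loading must lie strictly inside (0, 1)")
  obs
}

#' @param observations Data frame of observations.
#' @rdname read_observations
#' @export
write_observations <- function(observations, path) {
  utils::write.table(observations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
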