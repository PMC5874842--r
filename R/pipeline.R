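#' Solubility-parameter summary table
#'
#' One row per compound with both schemes' parameters and molar volumes --
#' the standard first table of a screening report.
#'
#' @param compounds Named list of `compound` objects.
#' @return Data frame: `abbreviation`, `role`, `delta_f`, `delta_vk`,
#'   `dd_vk`, `dp_vk`, `dh_vk`, `v_f`, `v_vk` (full precision).
#' @export
parameter_table <- function(compounds) {
  rows <- lapply(compounds, function(cp) {
    pf <- solubility_parameters(cp, "fedors")
    pv <- solubility_parameters(cp, "van_krevelen")
    data.frame(abbreviation = cp$abbreviation, role = cp$role,
               delta_f = pf$delta_total, delta_vk = pv$delta_total,
               dd_vk = pv$dd, dp_vk = pv$dp, dh_vk = pv$dh,
               v_f = pf$v, v_vk = pv$v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ranking and concordance table
#'
#' Builds the per-method, per-drug top-3 polymer rankings (theoretical
#' rankings from the screening metrics; experimental rankings from the
#' classified campaign cells) and scores each against the reference method
#' with the f1/f2 concordance fractions.
#'
#' @param cells Aggregated classification cells (may be `NULL` to rank
#'   theoretical methods only).
#' @param screening Screening metric table from [screening_table()].
#' @param reference_method Experimental method used as reference
#'   (default `"SD"`).
#' @return Data frame: `method`, `drug`, `ranking` ("A > B > C"), `f1`,
#'   `f2` (formatted), `f1_raw`, `f2_raw`.
#' @export
ranking_table <- function(cells, screening, reference_method = "SD") {
  drugs <- unique(screening$drug)
  theo <- list(delta_chi_f = "ddelta_f", delta_chi_vk = "ddelta_vk",
               euc_d = "euc_d")
  rankings <- list()
  for (d in drugs) {
    sub <- screening[screening$drug == d, ]
    for (mth in names(theo)) {
      sc <- setNames(sub[[theo[[mth]]]], sub$polymer)
      rankings[[paste(mth, d, sep = "|")]] <-
        rank_theoretical(sc, basis = mth, top = 3)$polymers
    }
  }
  exp_methods <- character(0)
  if (!is.null(cells)) {
    exp_methods <- sort(unique(cells$method))
    for (d in unique(cells$drug)) for (mth in exp_methods) {
      sub <- cells[cells$drug == d & cells$method == mth, ]
      if (nrow(sub) == 0) next
      rankings[[paste(mth, d, sep = "|")]] <-
        rank_experimental(sub, top = 3)$polymers
    }
  }
  methods <- c(names(theo), exp_methods)
  rows <- list()
  for (mth in methods) for (d in drugs) {
    key <- paste(mth, d, sep = "|")
    if (is.null(rankings[[key]])) next
    ref <- rankings[[paste(reference_method, d, sep = "|")]]
    f1 <- f2 <- NA_real_
    if (!is.null(ref) && mth != reference_method) {
      cc <- concordance(rankings[[key]], ref)
      f1 <- cc$f1; f2 <- cc$f2
    }
    rows[[length(rows) + 1]] <- data.frame(
      method = mth, drug = d,
      ranking = paste(rankings[[key]], collapse = " > "),
      f1 = if (is.na(f1)) NA_character_ else format_thirds(f1),
      f2 = if (is.na(f2)) NA_character_ else format_thirds(f2),
      f1_raw = f1, f2_raw = f2, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the full in-silico screening pipeline
#'
#' Orchestrates every stage for a compound library: solubility parameters,
#' pairwise screening metrics, phase diagrams, campaign classification
#' (from a provided observation table or a simulated campaign), polymer
#' ranking with concordance scores, and the PCA method comparison. All
#' outputs are written as tab-separated UTF-8 text plus a JSON manifest;
#' the run is deterministic for a fixed configuration and seed.
#'
#' @param config List (or path to a YAML file) with optional fields:
#'   `compounds_dir`, `temperature` (K), `observations` (path; when absent
#'   a campaign is simulated), `seed`, `tg_tol`, `tg_resolution`,
#'   `greenhalgh_cutoff`, `n_grid`, `out_dir` (required).
#' @return Invisibly, a list with all computed tables.
#' @export
run_full_screen <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(compounds_dir = NULL, temperature = 298.15,
                   observations = NULL, seed = 1L, tg_tol = 3,
                   tg_resolution = 10, n_grid = 2001, out_dir = NULL)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  if (config$temperature <= 0) stop("temperature must be positive (K)")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  compounds <- load_compounds(config$compounds_dir)
  roles <- vapply(compounds, `[[`, character(1), "role")
  if (!any(roles == "polymer")) stop("compound library holds no polymers")
  if (!any(roles == "drug")) stop("compound library holds no drugs")

  params <- parameter_table(compounds)
  screening <- screening_table(compounds, temperature = config$temperature)

  # phase-diagram summaries for all pairs (Fedors-based interaction)
  pd_rows <- list()
  for (i in seq_len(nrow(screening))) {
    d <- compounds[[screening$drug[i]]]
    p <- compounds[[screening$polymer[i]]]
    vd <- solubility_parameters(d, "fedors")$v
    m <- lattice_ratio(polymer_chain_volume(p$mw, p$density), vd)
    pd <- phase_diagram(screening$chi_f[i], m, n_grid = config$n_grid)
    pd_rows[[i]] <- data.frame(
      drug = d$abbreviation, polymer = p$abbreviation,
      chi = pd$chi, m = pd$m, phi_min = pd$phi_min,
      phi_crit = pd$phi_crit,
      spinodal_lo = if (length(pd$spinodal) > 0) pd$spinodal[1] else NA_real_,
      spinodal_hi = if (length(pd$spinodal) > 1) pd$spinodal[2] else NA_real_,
      profile_class = pd$profile_class, stringsAsFactors = FALSE)
  }
  phase_summary <- do.call(rbind, pd_rows)

  if (!is.null(config$observations)) {
    observations <- read_observations(config$observations)
    truth <- NULL
  } else {
    spec <- campaign_spec(drugs = compounds[roles == "drug"],
                          polymers = compounds[roles == "polymer"],
                          seed = config$seed)
    campaign <- make_campaign(spec)
    observations <- campaign$observations
    truth <- campaign$ground_truth
  }
  classified <- classify_campaign(observations, compounds,
                                  tol = config$tg_tol,
                                  resolution = config$tg_resolution)
  rankings <- ranking_table(classified$cells, screening)

  mat <- encode_class_matrix(classified$cells)
  pca <- pca_screen(mat, n_components = min(2, nrow(mat) - 1))
  proximity <- proximity_report(pca, "SD")

  out <- list(parameters = params, screening = screening,
              phase_summary = phase_summary,
              observations = observations, ground_truth = truth,
              cells = classified$cells, rankings = rankings,
              pca = pca, proximity = proximity, config = config)

  write_tsv(params, file.path(config$out_dir, "solubility_parameters.tsv"))
  write_tsv(screening, file.path(config$out_dir, "screening_metrics.tsv"))
  write_tsv(phase_summary, file.path(config$out_dir, "phase_diagrams.tsv"))
  write_tsv(classified$cells, file.path(config$out_dir, "class_grid.tsv"))
  write_tsv(rankings, file.path(config$out_dir, "rankings.tsv"))
  write_tsv(data.frame(method = rownames(pca$scores),
                       round(pca$scores, 10)),
            file.path(config$out_dir, "pca_scores.tsv"))
  write_tsv(proximity, file.path(config$out_dir, "pca_proximity.tsv"))
  manifest <- list(seed = config$seed, temperature = config$temperature,
                   n_compounds = length(compounds),
                   simulated = is.null(config$observations),
                   explained_variance = round(pca$explained_variance_ratio,
                                              6))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
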