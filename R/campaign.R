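#' Campaign specification
#'
#' Defines a synthetic screening campaign with known ground truth. Each
#' (drug, polymer) pair has a true maximum miscible drug loading (the class
#' boundary); each screening method shifts that boundary by an additive
#' bias emulating its systematic tendency (quench cooling over-predicts
#' miscibility, slow film casting under-predicts, the atomization device
#' tracks the spray dryer). Loadings up to the shifted boundary are glass
#' solutions (A), loadings within `aa_band` above it are amorphous
#' phase-separated (AA), anything beyond retains crystallinity (AC).
#'
#' @param drugs,polymers Named lists of `compound` objects (or subset of
#'   [load_compounds()]).
#' @param loadings Drug mass fractions screened (default 0.2/0.4/0.6/0.8).
#' @param methods Screening methods simulated.
#' @param boundaries Named matrix (drugs x polymers) of true maximum
#'   miscible loadings; defaults to a spread of boundary levels assigned
#'   per pair.
#' @param biases Named numeric vector of per-method boundary shifts.
#' @param aa_band Width of the amorphous-phase-separated band above the
#'   boundary (default 0.15).
#' @param tg_noise_sd Measurement noise on Tg centers/widths in degC
#'   (default 1; set 0 for noiseless campaigns).
#' @param p_subresolution Probability that a phase-separated sample has
#'   domains below the ~30 nm detection limit and therefore shows a single
#'   averaged Tg (default 0.03; 0 for noiseless campaigns).
#' @param replicates mDSC replicates per cell (default 3).
#' @param seed Integer seed.
#' @return A `campaign_spec` list.
#' @export
campaign_spec <- function(drugs, polymers,
                          loadings = c(0.2, 0.4, 0.6, 0.8),
                          methods = c("FC_RT", "FC_RP", "QC", "AD", "SD"),
                          boundaries = NULL,
                          biases = c(FC_RT = -0.15, FC_RP = -0.05,
                                     QC = 0.2, AD = 0, SD = 0),
                          aa_band = 0.15,
                          tg_noise_sd = 1,
                          p_subresolution = 0.03,
                          replicates = 3,
                          seed = 1L) {
  if (length(polymers) == 0 || length(drugs) == 0)
    stop("campaign needs at least one drug and one polymer")
  dn <- vapply(drugs, `[[`, character(1), "abbreviation")
  pn <- vapply(polymers, `[[`, character(1), "abbreviation")
  if (is.null(boundaries)) {
    levels_pool <- c(0.85, 0.65, 0.45, 0.3, 0.25, 0.15, 0.1)
    boundaries <- matrix(levels_pool[pmin(seq_along(pn), length(levels_pool))],
                         nrow = length(dn), ncol = length(pn), byrow = TRUE)
    dimnames(boundaries) <- list(dn, pn)
  }
  if (!all(dn %in% rownames(boundaries)) || !all(pn %in% colnames(boundaries)))
    stop("boundaries must cover every (drug, polymer) pair")
  if (any(boundaries < 0 | boundaries > 1))
    stop("boundaries must lie in [0, 1]")
  miss <- setdiff(methods, names(biases))
  if (length(miss) > 0)
    stop("missing bias for method(s): ", paste(miss, collapse = ", "))
  shifted <- outer(as.vector(boundaries), biases[methods], `+`)
  if (any(shifted < -1 | shifted > 2))
    stop("shifted boundaries stray far outside [0, 1]; check biases")
  if (aa_band < 0) stop("aa_band must be non-negative")
  if (any(loadings <= 0 | loadings >= 1))
    stop("loadings must lie strictly inside (0, 1)")
  structure(list(drugs = drugs, polymers = polymers, loadings = loadings,
                 methods = methods, boundaries = boundaries,
                 biases = biases, aa_band = aa_band,
                 tg_noise_sd = tg_noise_sd,
                 p_subresolution = p_subresolution,
                 replicates = replicates, seed = as.integer(seed)),
            class = "campaign_spec")
}

#' Simulate a screening campaign
#'
#' Generates the observation table a full screening campaign would
#' produce, together with the planted ground truth. Class-A cells carry a
#' single mixed Tg placed by the Fox rule; class-AA cells carry drug-rich
#' and polymer-rich transitions (collapsed to one averaged transition for
#' sub-resolution domains); class-AC cells carry a drug-like Tg plus
#' melting/diffraction signatures (or a recrystallization exotherm when
#' just beyond the amorphous band). Deterministic for a fixed seed.
#'
#' @param spec A [campaign_spec()].
#' @return List: `observations` (observation-table data frame),
#'   `ground_truth` (one row per cell with planted class and boundary
#'   bookkeeping), `reference_ranking` (list per drug: polymers by true
#'   boundary, descending), `spec`.
#' @export
make_campaign <- function(spec) {
  stopifnot(inherits(spec, "campaign_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  dn <- vapply(spec$drugs, `[[`, character(1), "abbreviation")
  pn <- vapply(spec$polymers, `[[`, character(1), "abbreviation")
  noise <- function(n, sd) if (sd > 0) stats::rnorm(n, sd = sd) else
    numeric(n)

  obs <- list(); truth <- list()
  for (d in dn) for (p in pn) for (mth in spec$methods) for (dl in
                                                             spec$loadings) {
    b <- spec$boundaries[d, p]
    b_eff <- min(max(b + spec$biases[[mth]], 0), 1)
    planted <- if (dl <= b_eff) "A"
    else if (dl <= b_eff + spec$aa_band) "AA" else "AC"
    tg_d <- spec$drugs[[which(dn == d)]]$tg_c
    tg_p <- spec$polymers[[which(pn == p)]]$tg_c
    sub_res <- FALSE
    for (rep_i in seq_len(spec$replicates)) {
      meso <- 0L; melt <- FALSE; recr <- FALSE; xrpd <- FALSE
      if (planted == "A") {
        ev <- data.frame(value = fox_tg(dl, tg_d, tg_p) +
                           noise(1, spec$tg_noise_sd),
                         width = abs(8 + noise(1, spec$tg_noise_sd)))
      } else if (planted == "AA") {
        if (rep_i == 1)
          sub_res <- spec$p_subresolution > 0 &&
            stats::runif(1) < spec$p_subresolution
        if (sub_res) {
          # domains below the ~30 nm limit: one averaged transition
          ev <- data.frame(value = fox_tg(dl, tg_d, tg_p) +
                             noise(1, spec$tg_noise_sd),
                           width = abs(12 + noise(1, spec$tg_noise_sd)))
        } else {
          ev <- data.frame(
            value = c(tg_d + noise(1, spec$tg_noise_sd),
                      tg_p + noise(1, spec$tg_noise_sd)),
            width = abs(8 + noise(2, spec$tg_noise_sd)))
          ev <- ev[order(ev$value), ]
        }
        if (d == "ITR") meso <- 2L
      } else {
        ev <- data.frame(value = tg_d + noise(1, spec$tg_noise_sd),
                         width = abs(10 + noise(1, spec$tg_noise_sd)))
        if (dl - (b_eff + spec$aa_band) > 0.2) {
          melt <- TRUE; xrpd <- TRUE
        } else recr <- TRUE
        if (d == "ITR") meso <- 2L
      }
      obs[[length(obs) + 1]] <- data.frame(
        drug = d, polymer = p, drug_loading = dl, method = mth,
        replicate = rep_i, tg_events = format_tg_events(ev),
        melting_detected = melt, recrystallization_detected = recr,
        mesophase_endotherms = meso, xrpd_crystalline = xrpd,
        stringsAsFactors = FALSE)
    }
    truth[[length(truth) + 1]] <- data.frame(
      drug = d, polymer = p, drug_loading = dl, method = mth,
      class = planted, boundary = b, shifted_boundary = b_eff,
      sub_resolution = sub_res, stringsAsFactors = FALSE)
  }
  observations <- do.call(rbind, obs)
  ground_truth <- do.call(rbind, truth)
  reference_ranking <- lapply(setNames(dn, dn), function(d) {
    b <- spec$boundaries[d, pn]
    names(sort(b, decreasing = TRUE))
  })
  list(observations = observations, ground_truth = ground_truth,
       reference_ranking = reference_ranking, spec = spec)
}
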