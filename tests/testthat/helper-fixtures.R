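# Shared fixtures: bundled compound library and published reference tables.

fixture_path <- function(...) {
  system.file("extdata", ..., package = "asdscreen", mustWork = TRUE)
}

bundled_compounds <- load_compounds()

published_parameters <- local({
  x <- utils::read.delim(fixture_path("reference",
                                      "solubility_parameters.tsv"),
                         comment.char = "#")
  rownames(x) <- x$abbreviation
  x
})

published_metrics <- utils::read.delim(
  fixture_path("reference", "screening_metrics.tsv"), comment.char = "#")

published_rankings <- utils::read.delim(
  fixture_path("reference", "polymer_rankings.tsv"), comment.char = "#")

# small campaign used across synthetic-data tests: two drugs, three polymers
small_campaign_spec <- function(tg_noise_sd = 0, p_subresolution = 0,
                                seed = 42L, ...) {
  cmp <- bundled_compounds
  campaign_spec(drugs = cmp[c("IBU", "ITR")],
                polymers = cmp[c("PK30", "PVA", "SOL")],
                tg_noise_sd = tg_noise_sd,
                p_subresolution = p_subresolution,
                seed = seed, ...)
}

# second composition derivative of the mixing free energy (spinodal oracle)
d2_gibbs <- function(phi, chi, m) 1 / phi + 1 / (m * (1 - phi)) - 2 * chi

# brute-force spinodal roots: sign-change scan + uniroot refinement
spinodal_bruteforce <- function(chi, m, n = 1e5) {
  phi <- seq(1e-8, 1 - 1e-8, length.out = n)
  v <- d2_gibbs(phi, chi, m)
  idx <- which(v[-1] * v[-n] < 0)
  vapply(idx, function(i) {
    stats::uniroot(d2_gibbs, c(phi[i], phi[i + 1]), chi = chi, m = m,
                   tol = 1e-14)$root
  }, numeric(1))
}
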