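test_that("thermogram synthesis round-trips a single glass transition", {
  ev <- list(thermal_event("glass_transition", 85, 10, 0.3))
  tr <- make_thermogram(ev, noise_sd = 0, seed = 1)
  got <- detect_tg_events(tr)
  expect_equal(nrow(got), 1)
  expect_lt(abs(got$value - 85), 0.11)          # within one grid step
  expect_lt(abs(got$width - 10) / 10, 0.1)      # width within 10%
  expect_lt(abs(got$height - 0.3) / 0.3, 0.1)
})

test_that("two transitions 5 degC apart are reported as one merged event", {
  ev <- list(thermal_event("glass_transition", 60, 8, 0.2),
             thermal_event("glass_transition", 65, 8, 0.2))
  tr <- make_thermogram(ev, noise_sd = 0, seed = 1)
  got <- merge_unresolvable_tgs(detect_tg_events(tr))
  expect_equal(nrow(got), 1)
  expect_lt(abs(got$value - 62.5), 1.5)
})

test_that("peak events carry the specified sign and area", {
  ev <- list(thermal_event("glass_transition", 60, 8, 0.2),
             thermal_event("melting", 160, 6, -4),
             thermal_event("recrystallization", 120, 10, 2.5))
  tr <- make_thermogram(ev, noise_sd = 0, seed = 1)
  peaks <- detect_thermal_peaks(tr)
  expect_equal(nrow(peaks), 2)
  melt <- peaks[peaks$sign == "endotherm", ]
  recr <- peaks[peaks$sign == "exotherm", ]
  # areas within 5% of specification (trapezoidal integration oracle)
  expect_lt(abs(melt$area - (-4)) / 4, 0.05)
  expect_lt(abs(recr$area - 2.5) / 2.5, 0.05)
  expect_lt(abs(melt$center - 160), 0.5)
  expect_error(make_thermogram(list(thermal_event("melting", 500, 5, -1))),
               "inside the temperature grid")
  expect_error(thermal_event("melting", 100, 5, 1), "negative")
  expect_error(thermal_event("recrystallization", 100, 5, -1), "positive")
})

test_that("traces and patterns are bit-reproducible from their seed", {
  ev <- list(thermal_event("glass_transition", 85, 10, 0.3),
             thermal_event("melting", 160, 6, -4))
  t1 <- make_thermogram(ev, noise_sd = 0.01, seed = 99)
  t2 <- make_thermogram(ev, noise_sd = 0.01, seed = 99)
  expect_identical(t1$reverse, t2$reverse)
  expect_identical(t1$total, t2$total)
  x1 <- make_xrpd(1, list(two_theta = c(10, 15), intensity = c(1, 2)),
                  seed = 7)
  x2 <- make_xrpd(1, list(two_theta = c(10, 15), intensity = c(1, 2)),
                  seed = 7)
  expect_identical(x1$intensity, x2$intensity)
})

test_that("crystallinity detection separates halo from sharp reflections", {
  halo <- make_xrpd(halo_weight = 1, noise_sd = 0.01, seed = 3)
  expect_false(detect_crystallinity(halo)$crystalline)
  cryst <- make_xrpd(halo_weight = 1,
                     bragg_peaks = list(two_theta = c(10.1, 17.3, 24.8),
                                        intensity = c(0.5, 0.8, 0.4)),
                     noise_sd = 0.01, seed = 3)
  det <- detect_crystallinity(cryst)
  expect_true(det$crystalline)
  expect_equal(nrow(det$peaks), 3)
  expect_error(make_xrpd(1, list(two_theta = 40, intensity = 1)),
               "4.5-30")
})

test_that("detection at the limit matches a brute-force prominence scan", {
  for (inten in c(0.05, 0.12, 0.3)) {
    p <- make_xrpd(halo_weight = 1,
                   bragg_peaks = list(two_theta = 12, intensity = inten),
                   noise_sd = 0.005, seed = 21)
    det <- detect_crystallinity(p, prominence_min = 0.1)
    # oracle: exhaustive scan of prominence over a running-median background
    bg <- stats::runmed(p$intensity, 151)
    resid <- p$intensity - bg
    thr <- max(0.05, 4 * stats::mad(resid))
    oracle <- any(resid > max(thr, 0.1))
    expect_equal(det$crystalline, oracle, label = paste("intensity", inten))
  }
})

test_that("Fox-rule mixed Tg interpolates monotonically between pure values", {
  tgs <- fox_tg(seq(0.1, 0.9, by = 0.1), -44, 162)
  expect_true(all(diff(tgs) < 0))
  expect_true(all(tgs > -44 & tgs < 162))
  expect_equal(fox_tg(0, -44, 162), 162)
  expect_equal(fox_tg(1, -44, 162), -44)
})

test_that("campaigns are deterministic and validate their specification", {
  spec <- small_campaign_spec(tg_noise_sd = 1, p_subresolution = 0.05)
  c1 <- make_campaign(spec)
  c2 <- make_campaign(spec)
  expect_identical(c1$observations, c2$observations)
  expect_identical(c1$ground_truth, c2$ground_truth)
  expect_error(small_campaign_spec(aa_band = -0.1), "non-negative")
  expect_error(small_campaign_spec(loadings = c(0, 0.5)),
               "strictly inside")
})

test_that("noiseless campaigns are recovered perfectly end to end", {
  spec <- small_campaign_spec(tg_noise_sd = 0, p_subresolution = 0)
  camp <- make_campaign(spec)
  cl <- classify_campaign(camp$observations, bundled_compounds)
  merged <- merge(cl$cells, camp$ground_truth,
                  by = c("drug", "polymer", "drug_loading", "method"),
                  suffixes = c("_got", "_true"))
  expect_equal(nrow(merged), nrow(camp$ground_truth))
  expect_true(all(merged$class_got == merged$class_true))

  # planted polymer ranking is recovered with perfect concordance
  for (d in names(camp$reference_ranking)) {
    cells_sd <- cl$cells[cl$cells$drug == d & cl$cells$method == "SD", ]
    got <- rank_experimental(cells_sd, top = 3)$polymers
    cc <- concordance(got, camp$reference_ranking[[d]][1:3])
    expect_equal(cc$f1, 1)
    expect_equal(cc$f2, 1)
  }
})

test_that("quench-cooling bias shifts the apparent boundary by one level", {
  spec <- small_campaign_spec(tg_noise_sd = 0, p_subresolution = 0)
  camp <- make_campaign(spec)
  gt <- camp$ground_truth
  # QC bias +0.2 equals the loading grid step, so the maximum class-A
  # loading moves up exactly one level wherever the shift crosses a grid
  # point (and the boundary is not already saturated)
  max_a <- function(m, d, p) {
    x <- gt[gt$method == m & gt$drug == d & gt$polymer == p & gt$class == "A", ]
    if (nrow(x) == 0) 0 else max(x$drug_loading)
  }
  for (d in c("IBU", "ITR")) for (p in c("PK30", "PVA", "SOL")) {
    b <- spec$boundaries[d, p]
    sd_max <- max_a("SD", d, p)
    qc_max <- max_a("QC", d, p)
    grid_cross <- sum(spec$loadings > b & spec$loadings <= b + 0.2)
    expect_equal(qc_max, if (grid_cross > 0) sd_max + 0.2 else sd_max,
                 label = paste(d, p))
  }
  # identical biases give identical campaigns method-wise: AD matches SD
  for (d in c("IBU", "ITR")) {
    ad <- gt[gt$method == "AD" & gt$drug == d, ]
    sd_ <- gt[gt$method == "SD" & gt$drug == d, ]
    expect_equal(ad$class, sd_$class)
  }
})

test_that("class recovery stays high under the default noise model", {
  spec <- small_campaign_spec(tg_noise_sd = 1, p_subresolution = 0.03,
                              seed = 2024L)
  camp <- make_campaign(spec)
  cl <- classify_campaign(camp$observations, bundled_compounds)
  merged <- merge(cl$cells, camp$ground_truth,
                  by = c("drug", "polymer", "drug_loading", "method"),
                  suffixes = c("_got", "_true"))
  expect_gte(mean(merged$class_got == merged$class_true), 0.95)
})
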