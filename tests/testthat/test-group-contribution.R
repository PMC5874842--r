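test_that("Fedors parameters follow the cohesive-energy-density definition", {
  # single group with E numerically equal to V gives delta = 1 exactly
  tab <- structure(data.frame(label = "X", E = 16.1, V = 16.1,
                              neg_v = FALSE, row.names = "X"),
                   method = "fedors", class = c("gc_table", "data.frame"))
  p <- fedors_parameters(c(X = 1), tab)
  expect_equal(p$delta_total, 1)
  expect_equal(p$v, 16.1)

  # ibuprofen fragmentation against the bundled table, exact at printed
  # precision
  ibu <- fedors_parameters(c(CH3 = 3, CH = 2, CH2 = 1, phenylene = 1,
                             COOH = 1))
  expect_equal(round(ibu$delta_total, 1), 20.9)
  expect_equal(round(ibu$v, 1), 195.5)
})

test_that("Fedors sums agree with an independent hand summation (naproxen)", {
  tab <- utils::read.delim(fixture_path("group_tables", "fedors.tsv"),
                           comment.char = "#")
  rownames(tab) <- tab$label
  counts <- yaml::read_yaml(
    fixture_path("compounds", "nap.yaml"))$groups$fedors
  e <- sum(vapply(names(counts),
                  function(g) counts[[g]] * tab[g, "E"], numeric(1)))
  v <- sum(vapply(names(counts),
                  function(g) counts[[g]] * tab[g, "V"], numeric(1)))
  p <- fedors_parameters(counts)
  expect_equal(p$v, v, tolerance = 1e-12)
  expect_equal(p$delta_total, sqrt(e / v), tolerance = 1e-12)
})

test_that("van Krevelen components follow the three-term definitions", {
  # zero polar / zero H-bond groups collapse the total onto delta_d
  p <- van_krevelen_parameters(c(CH3 = 2, CH2 = 3))
  expect_equal(p$dp, 0)
  expect_equal(p$dh, 0)
  expect_equal(p$delta_total, p$dd)
  expect_equal(p$delta_v, p$dd)

  ibu <- van_krevelen_parameters(c(CH3 = 3, CH = 2, CH2 = 1,
                                   phenylene = 1, COOH = 1))
  expect_equal(round(c(ibu$dd, ibu$dp, ibu$dh), 1), c(17.9, 2.2, 7.2))
  expect_equal(round(ibu$delta_total, 1), 19.4)
  # Pythagorean identities hold exactly for a single fragment
  expect_equal(ibu$delta_total^2, ibu$dd^2 + ibu$dp^2 + ibu$dh^2,
               tolerance = 1e-12)
  expect_equal(ibu$delta_v^2, ibu$dd^2 + ibu$dp^2, tolerance = 1e-12)

  # carbamazepine against an independent hand summation
  tab <- utils::read.delim(fixture_path("group_tables", "van_krevelen.tsv"),
                           comment.char = "#")
  rownames(tab) <- tab$label
  counts <- yaml::read_yaml(
    fixture_path("compounds", "car.yaml"))$groups$van_krevelen
  s <- function(col) sum(vapply(names(counts),
                                function(g) counts[[g]] * tab[g, col],
                                numeric(1)))
  fp2 <- sum(vapply(names(counts),
                    function(g) counts[[g]] * tab[g, "Fp"]^2, numeric(1)))
  car <- van_krevelen_parameters(counts)
  expect_equal(car$dd, s("Fd") / s("V"), tolerance = 1e-12)
  expect_equal(car$dp, sqrt(fp2) / s("V"), tolerance = 1e-12)
  expect_equal(car$dh, sqrt(s("Eh") / s("V")), tolerance = 1e-12)
})

test_that("count scaling behaves as expected under both schemes", {
  counts <- c(CH3 = 2, CH2 = 1, COOH = 1, O = 1)
  for (k in c(2, 5, 0.5)) {
    f1 <- fedors_parameters(counts)
    f2 <- fedors_parameters(counts * k)
    expect_equal(f2$delta_total, f1$delta_total, tolerance = 1e-12)
    expect_equal(f2$v, k * f1$v, tolerance = 1e-12)
    v1 <- van_krevelen_parameters(counts)
    v2 <- van_krevelen_parameters(counts * k)
    expect_equal(v2$dd, v1$dd, tolerance = 1e-12)
    expect_equal(v2$dh, v1$dh, tolerance = 1e-12)
    # the polar term sums squared constants, so it scales by 1/sqrt(k)
    expect_equal(v2$dp, v1$dp / sqrt(k), tolerance = 1e-12)
  }
})

test_that("unit conversion round-trips", {
  # a table converted to kJ/mol and m^3/mol gives the same delta once the
  # cohesive energy density is converted back to MPa:
  # E'/V' = (E/1000) / (V*1e-6) = 1000 * E/V, so delta = sqrt((E'/V')/1000)
  counts <- c(CH2 = 4, COOH = 1)
  tab <- gc_table("fedors")
  base <- fedors_parameters(counts, tab)
  tab_kj <- tab
  tab_kj$E <- tab_kj$E / 1000          # kJ/mol
  tab_kj$V <- tab_kj$V * 1e-6          # m^3/mol
  p <- fedors_parameters(counts, tab_kj)
  expect_equal(sqrt(p$delta_total^2 / 1000), base$delta_total,
               tolerance = 1e-9)
})

test_that("errors: unknown labels, non-positive volume, bad counts", {
  expect_error(fedors_parameters(c(NOPE = 1)), "NOPE")
  expect_error(fedors_parameters(c(N = 3)), "positive")  # V sum < 0
  expect_error(fedors_parameters(c(CH3 = 0)), "positive count")
  expect_error(fedors_parameters(c(CH3 = -1)), "non-negative")
})

test_that("copolymer averaging: identity, symmetry, and the PVPVA fixture", {
  vp <- list(CH2 = 4, CH = 1, CON = 1, ring_ge5 = 1)
  vac <- list(CH2 = 1, CH = 1, COO = 1, CH3 = 1)
  single <- fedors_parameters(vp)
  # one unit at fraction 1 is the unit itself
  p1 <- copolymer_parameters(list(vp), 1, "fedors")
  expect_equal(p1$delta_total, single$delta_total, tolerance = 1e-12)
  # two identical units at 0.5/0.5 are the unit itself (both modes)
  for (mode in c("average_parameters", "average_counts")) {
    p2 <- copolymer_parameters(list(vp, vp), c(0.5, 0.5), "fedors",
                               mode = mode)
    expect_equal(p2$delta_total, single$delta_total, tolerance = 1e-12)
    expect_equal(p2$v, single$v, tolerance = 1e-12)
  }
  # PVPVA at 0.6/0.4 reproduces the published value
  pva <- copolymer_parameters(list(vp, vac), c(0.6, 0.4), "fedors")
  expect_equal(round(pva$delta_total, 1), 25.0)
  expect_lt(abs(pva$delta_total - 25.1), 0.15)
  expect_equal(round(pva$v, 1), 69.7)
  # validation
  expect_error(copolymer_parameters(list(vp, vac), c(0.7, 0.4), "fedors"),
               "sum to 1")
  expect_error(copolymer_parameters(list(vp), c(0.5, 0.5), "fedors"),
               "same length")
})

test_that("polymer chain volume is Mw over density", {
  expect_equal(polymer_chain_volume(1, 1), 1)
  expect_equal(polymer_chain_volume(115000, 1.03), 115000 / 1.03)
  expect_equal(round(polymer_chain_volume(78000, 1.82)), 42857)
  expect_error(polymer_chain_volume(-1, 1), "positive")
  expect_error(polymer_chain_volume(1, 0), "positive")
})

test_that("group tables validate structural invariants", {
  tab <- utils::read.delim(fixture_path("group_tables", "fedors.tsv"),
                           comment.char = "#")
  bad <- tab; bad$label[2] <- bad$label[1]
  expect_error(asdscreen:::validate_gc_table(bad, "fedors"), "duplicated")
  bad2 <- tab; bad2$V[bad2$label == "CH3"] <- -5; bad2$neg_v <- FALSE
  expect_error(asdscreen:::validate_gc_table(bad2, "fedors"),
               "negative molar volume")
})
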