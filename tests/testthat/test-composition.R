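test_that("mass and molar fractions follow the composition arithmetic", {
  single <- membrane_composition("POPC", 100, 76000)
  expect_equal(mass_fraction(single, "POPC"), 100)

  half <- membrane_composition(c("A", "B"), c(50, 50), c(1000, 3000))
  expect_equal(molar_fraction(half, "A"), 50)
  expect_equal(mass_fraction(half, "B"), 75)

  expect_error(mass_fraction(half, "CHOL"), "unknown")
})

test_that("the reference membrane compositions reproduce their printed percentages", {
  sm1 <- sm1_composition()
  expect_equal(mass_fraction(sm1, "POPC", digits = 1), 66.4)
  expect_equal(mass_fraction(sm1, "POPE", digits = 1), 33.6)
  expect_equal(molar_fraction(sm1, "POPC", digits = 1), 65.1)
  expect_equal(molar_fraction(sm1, "POPE", digits = 1), 34.9)

  suppressWarnings(sm2 <- sm2_composition())
  expect_equal(mass_fraction(sm2, "POPC", digits = 1), 62.1)
  expect_equal(molar_fraction(sm2, "CHOL", digits = 1), 9.7)
  expect_equal(sum(sm2$count), 1100)
  expect_equal(sum(sm2$mass_da), 775523)  # printed total is 775,524 (rounding)
})

test_that("percentage columns sum to 100 within rounding for any composition", {
  set.seed(61)
  for (k in 1:20) {
    n <- sample(2:6, 1)
    comp <- membrane_composition(paste0("L", seq_len(n)),
                                 count = sample(10:800, n),
                                 mass_da = round(runif(n, 1e3, 8e5)))
    rep_ <- composition_report(comp)
    tot <- rep_[rep_$species == "Tot", ]
    expect_equal(tot$pct_w, 100, tolerance = 0.2)
    expect_equal(tot$pct_mol, 100, tolerance = 0.2)
  }
})

test_that("mass-to-molar ratio conversion is exact and monotone", {
  expect_equal(lipid_protein_molar_ratio(1, 500, 500), 1)
  expect_equal(lipid_protein_molar_ratio(3, 745, 34766), 140, tolerance = 0.001)
  r1 <- lipid_protein_molar_ratio(3, 745, 30000)
  r2 <- lipid_protein_molar_ratio(3, 745, 40000)
  expect_lt(r1, r2)
})

test_that("compositions round-trip through the structured text format", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("species count per_leaflet mass_da",
               "POPC 716 358 536747",
               "POPE 384 192 272111"), f)
  comp <- read_composition(f)
  expect_s3_class(comp, "membrane_composition")
  expect_equal(mass_fraction(comp, "POPC", digits = 1), 66.4)

  # inconsistent leaflet counts are flagged, not fixed
  expect_warning(membrane_composition("X", 107, 41205, per_leaflet = 54),
                 "leaflet")
})
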