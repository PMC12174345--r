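test_that("uniform beads give near-unit enrichment almost everywhere", {
  set.seed(51)
  n <- 1e5
  # 3.2 x 3.2 nm at 0.2 nm cells: 256 cells, ~390 beads per cell
  beads <- data.frame(x = runif(n, 0, 3.2), y = runif(n, 0, 3.2),
                      species = "PC")
  map <- compute_occupancy_map(beads, bbox = c(0, 3.2, 0, 3.2))
  e <- map$leaflets[["all"]]$enrichment[["PC"]]
  occ <- map$leaflets[["all"]]$occupied
  expect_gte(mean(e[occ] >= 0.9 & e[occ] <= 1.1), 0.95)
  # counts conserved; mean enrichment over the occupied region is 1
  expect_equal(sum(map$leaflets[["all"]]$counts[["PC"]]), n)
  expect_equal(mean(e[occ]), 1, tolerance = 1e-9)
})

test_that("a quadrant-confined species is enriched fourfold there", {
  set.seed(52)
  n <- 4e4
  bg <- data.frame(x = runif(n, 0, 4), y = runif(n, 0, 4), species = "PC")
  qd <- data.frame(x = runif(n, 0, 2), y = runif(n, 0, 2), species = "CHOL")
  map <- compute_occupancy_map(rbind(bg, qd), bbox = c(0, 4, 0, 4))
  e <- map$leaflets[["all"]]$enrichment[["CHOL"]]
  nr <- nrow(e); nc <- ncol(e)
  quadrant <- e[seq_len(nr / 2), seq_len(nc / 2)]
  expect_equal(mean(quadrant), 4.0, tolerance = 0.05)
  outside <- e[(nr / 2 + 1):nr, (nc / 2 + 1):nc]
  expect_equal(mean(outside), 0)
  # thresholding helpers expose the conventional cutoffs
  expect_true(all(enrichment_region(map, "CHOL", fold = 1.2)[
    seq_len(nr / 2), seq_len(nc / 2)][quadrant >= 1.2]))
  expect_gte(sum(enrichment_region(map, "CHOL", fold = 1.2)),
             sum(enrichment_region(map, "CHOL", fold = 1.8)))
})

test_that("species absent from a leaflet are skipped with a warning", {
  beads <- data.frame(x = c(1, 2), y = c(1, 2),
                      species = c("PC", "CHOL"),
                      leaflet = c("cytosolic", "ims"))
  w <- capture_warnings(map <- compute_occupancy_map(beads))
  expect_length(w, 2)          # one per leaflet missing a species
  expect_match(w, "skipped", all = TRUE)
  expect_null(map$leaflets[["cytosolic"]]$counts[["CHOL"]])
  expect_error(enrichment_region(map, "CHOL", leaflet = "cytosolic"),
               "unknown")
})

test_that("assembly beads feed occupancy maps per leaflet", {
  p <- generate_pattern("glassy", 6, region(45, 45), seed = 53)
  m <- build_assembly(p, generate_template(seed = 54), seed = 55)
  beads <- assembly_beads(m)
  map <- compute_occupancy_map(beads)
  expect_setequal(names(map$leaflets), c("cytosolic", "ims"))
  total <- sum(vapply(map$leaflets, function(lf)
    sum(vapply(lf$counts, sum, numeric(1))), numeric(1)))
  expect_equal(total, nrow(beads))
})
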