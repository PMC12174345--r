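test_that("two particles put all pair mass in the bin containing their distance", {
  p <- particle_set(c(0, 6.3), c(0, 0))
  patch <- compute_patch_surface(p, 10, mode = "convex")
  r <- compute_rdf(p, patch, dr = 0.2, r_max = 15)
  nz <- which(r$g > 0)
  expect_length(nz, 1)
  expect_true(6.3 >= r$r[nz] - 0.1 && 6.3 < r$r[nz] + 0.1)

  expect_error(compute_rdf(particle_set(1, 1), patch), "two particles")
})

test_that("library g(r) matches the brute-force double-loop oracle", {
  set.seed(21)
  p <- generate_pattern("glassy", 40, region(80, 80), seed = 21)
  xy <- cbind(p$x_nm, p$y_nm)
  patch <- compute_patch_surface(p, 5, mode = "convex")
  r <- compute_rdf(p, patch, dr = 0.5, r_max = 12)
  orc <- oracle_rdf(xy, 5, 0.5, 12)
  expect_equal(patch$area, orc$area, tolerance = 0.01)
  expect_equal(r$g, orc$g, tolerance = 0.02)
})

test_that("effective ring areas never exceed the full ring", {
  p <- generate_pattern("glassy", 40, region(80, 80), seed = 22)
  patch <- compute_patch_surface(p, 5, mode = "concave")
  r <- compute_rdf(p, patch, dr = 0.4, r_max = 15)
  full <- 2 * pi * r$r * r$dr
  expect_true(all(r$area_eff <= rep(full, each = r$n) * (1 + 1e-9)))
})

test_that("boundary correction removes the edge bias of a Poisson pattern", {
  p <- generate_pattern("poisson", 800, region(150, 150), seed = 23)
  patch <- compute_patch_surface(p, 5, mode = "convex")
  corr <- compute_rdf(p, patch, dr = 0.5, r_max = 30)
  unc <- compute_rdf(p, patch, dr = 0.5, r_max = 30, edge_correction = FALSE)
  sel <- corr$r >= 10
  expect_lt(abs(mean(corr$g[sel]) - 1), abs(mean(unc$g[sel]) - 1))
  expect_lt(abs(mean(corr$g[sel]) - 1), 0.08)
})

test_that("distance classes carry the documented shell structure", {
  cls <- distance_classes()
  expect_equal(cls$hi_A - cls$lo_A,
               c(50, 6, 6, 6, 12, 6))
  expect_true(!is.unsorted(cls$lo_A))
})

test_that("shell occurrences count single pairs and conserve neighbours", {
  p <- particle_set(c(0, 5.2), c(0, 0))
  prof <- shell_occurrences(p)
  expect_equal(prof$occurrence[prof$label == "direct"], 1)
  expect_equal(sum(prof$occurrence), 1)

  set.seed(31)
  q <- generate_pattern("glassy", 50, region(80, 80), seed = 31)
  wide <- shell_occurrences(q, class_bins = seq(0, 3000, by = 100))
  expect_equal(sum(wide$occurrence), n_particles(q) - 1)

  expect_error(shell_occurrences(p, class_bins = c(50, 40, 60)), "ascending")
})

test_that("patch heterogeneity is deterministic, bounded, and consistent", {
  p <- generate_pattern("glassy", 120, region(130, 130), seed = 41)
  e1 <- patch_heterogeneity(p, seed = 5)
  e2 <- patch_heterogeneity(p, seed = 5)
  expect_identical(e1$profiles, e2$profiles)

  # fewer proteins than repeats: each sampled at most once
  small <- generate_pattern("glassy", 30, region(80, 80), seed = 42)
  es <- patch_heterogeneity(small, n_repeats = 100, seed = 6)
  expect_equal(nrow(es$profiles), 30)
  expect_equal(anyDuplicated(es$centers), 0)

  # ensemble mean within 2 SD of the whole-structure profile
  whole <- shell_occurrences(p)
  whole <- whole[whole$lo_A < 100, ]
  for (k in seq_len(nrow(whole))) {
    lab <- whole$label[k]
    expect_lte(abs(e1$mean[[lab]] - whole$occurrence[k]),
               2 * max(e1$sd[[lab]], 0.05))
  }
  expect_true(all(e1$profiles >= 0))
})
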