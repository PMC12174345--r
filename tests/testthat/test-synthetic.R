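test_that("empty and hard-core trivial cases behave", {
  reg <- region(100, 100)
  expect_equal(n_particles(generate_pattern("poisson", 0, reg, seed = 1)), 0)

  p2 <- generate_pattern("glassy", 2, reg, spacing = 5.5, jitter = 0,
                         seed = 1)
  expect_gte(min(dist(cbind(p2$x_nm, p2$y_nm))), 5.5 - 1e-9)
})

test_that("glassy packing honours the relaxed hard core and contact spacing", {
  p <- generate_pattern("glassy", 300, region(200, 200), spacing = 5.5,
                        jitter = 0.3, seed = 1)
  expect_equal(n_particles(p), 300)
  nn <- brute_nn(cbind(p$x_nm, p$y_nm))
  expect_gte(min(nn), 5.5 - 0.3 - 1e-9)
  expect_gte(mean(nn), 5.2)
  expect_lte(mean(nn), 5.9)
  # the pattern stays inside the region
  expect_true(all(p$x_nm >= 0 & p$x_nm <= 200))
  expect_true(all(p$y_nm >= 0 & p$y_nm <= 200))
})

test_that("generators are bit-identical under a fixed seed", {
  reg <- region(150, 150)
  for (kind in c("glassy", "filament", "dense", "poisson")) {
    a <- generate_pattern(kind, 60, reg, seed = 42)
    b <- generate_pattern(kind, 60, reg, seed = 42)
    expect_identical(a, b)
  }
})

test_that("poisson pattern passes a quadrat chi-square uniformity test", {
  p <- generate_pattern("poisson", 2000, region(300, 300), seed = 11)
  qx <- cut(p$x_nm, breaks = seq(0, 300, length.out = 7))
  qy <- cut(p$y_nm, breaks = seq(0, 300, length.out = 7))
  counts <- as.vector(table(qx, qy))
  pval <- stats::chisq.test(counts)$p.value
  expect_gt(pval, 0.01)
})

test_that("infeasible densities raise a packing error", {
  expect_error(generate_pattern("glassy", 200, region(20, 20), seed = 1),
               "infeasible")
})

test_that("dense aggregates pack at protein-contact spacing", {
  p <- generate_pattern("dense", 80, region(120, 120), jitter = 0, seed = 3)
  nn <- brute_nn(cbind(p$x_nm, p$y_nm))
  expect_gte(min(nn), 4.5 - 1e-9)
  expect_lt(mean(nn), 5.0)
})

test_that("filament chains produce the requested count inside the region", {
  p <- generate_pattern("filament", 90, region(250, 250), chains = 4,
                        seed = 5)
  expect_equal(n_particles(p), 90)
  expect_true(all(p$x_nm >= 0 & p$x_nm <= 250))
})

test_that("topography rendering matches the pore and bead signatures", {
  reg <- region(30, 30)
  # no particles, no noise -> constant image
  flat <- render_topography(particle_set(numeric(0), numeric(0)),
                            noise_sd = 0, region = reg)
  expect_equal(diff(range(flat$heights)), 0)

  # single pore: depression of full width ~4.5 nm at half depth
  one <- particle_set(15, 15, region = reg)
  img <- render_topography(one, noise_sd = 0)
  prof <- extract_profile(img, c(3, 15), c(27, 15))
  expect_lt(min(prof$height_nm), -0.5)
  expect_equal(profile_fwhd(prof), 4.5, tolerance = img$pixel_size / 4.5)

  # nanobead: a peak, not a hole
  bead <- render_topography(one, noise_sd = 0, bead_fraction = 1, seed = 1)
  bprof <- extract_profile(bead, c(3, 15), c(27, 15))
  expect_gt(max(bprof$height_nm), 1.5)
  expect_gt(bprof$height_nm[which.max(abs(bprof$height_nm))], 0)

  # resolution guard
  expect_error(render_topography(one, pixel_size = 2), "coarse")
})

test_that("topography images round-trip through TIFF and text", {
  img <- render_topography(particle_set(10, 10, region = region(20, 20)),
                           noise_sd = 0.02, seed = 7)
  tf <- tempfile(fileext = ".tif")
  write_topography(img, tf)
  back <- read_topography(tf, img$pixel_size)
  expect_equal(back$heights, img$heights, tolerance = 1e-6)

  tx <- tempfile(fileext = ".txt")
  write_topography(img, tx)
  back2 <- read_topography(tx, img$pixel_size)
  expect_equal(back2$heights, img$heights, tolerance = 1e-12)
})

test_that("templates respect counts, the cylinder, and determinism", {
  tpl <- generate_template(seed = 9)
  expect_equal(sum(tpl$lipids$first_shell & tpl$lipids$leaflet == "cytosolic"),
               20)
  expect_equal(sum(tpl$lipids$first_shell & tpl$lipids$leaflet == "ims"), 20)
  expect_true(all(sqrt(tpl$lipids$x^2 + tpl$lipids$y^2) <=
                    tpl$cylinder_radius + 1e-9))
  expect_setequal(unique(tpl$lipids$leaflet), c("cytosolic", "ims"))

  bare <- generate_template(0, seed = 9)
  expect_false(any(bare$lipids$first_shell))

  expect_identical(generate_template(seed = 4), generate_template(seed = 4))
  expect_error(generate_template(200, seed = 1), "overflow")
})

test_that("templates round-trip through PDB", {
  tpl <- generate_template(seed = 2)
  f <- tempfile(fileext = ".pdb")
  write_template_pdb(tpl, f)
  back <- read_template_pdb(f)
  expect_equal(nrow(back$protein), nrow(tpl$protein))
  expect_equal(nrow(back$lipids), nrow(tpl$lipids))
  expect_equal(back$lipids$leaflet, tpl$lipids$leaflet)
  expect_equal(back$lipids$first_shell, tpl$lipids$first_shell)
  expect_equal(back$lipids$x, tpl$lipids$x, tolerance = 1e-3)
})
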