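test_that("pore template is zero-mean, symmetric, and centre-minimal", {
  tpl <- build_pore_template(4.5, 0.5)
  m <- tpl$heights
  expect_equal(mean(m), 0, tolerance = 1e-12)
  ctr <- (nrow(m) + 1) / 2
  expect_equal(which.min(m), which(row(m) == ctr & col(m) == ctr))
  expect_equal(m, t(m), tolerance = 1e-12)                 # mirror
  expect_equal(m, m[nrow(m):1, ncol(m):1], tolerance = 1e-12)  # 180 deg
  expect_equal(m, t(m[nrow(m):1, ]), tolerance = 1e-12)    # 90 deg
  expect_error(build_pore_template(4.5, 2), "coarse")
})

test_that("detection recovers a grid of pores at tier 1 within a pixel", {
  fx <- grid_pore_fixture(5, 5, spacing = 10, noise_sd = 0.05, seed = 1)
  tpl <- build_pore_template(4.5, fx$image$pixel_size)
  det <- detect_pores(fx$image, tpl)
  expect_equal(sum(det$tier == 1L), 25)
  m <- match_detections(filter_tier(det, 1L), fx$truth,
                        tolerance = fx$image$pixel_size)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_lt(m$mean_error_nm, fx$image$pixel_size)
})

test_that("a blank noisy image yields no stringent detections", {
  img <- render_topography(particle_set(numeric(0), numeric(0)),
                           noise_sd = 0.05, region = region(40, 40),
                           seed = 3)
  tpl <- build_pore_template(4.5, img$pixel_size)
  det <- detect_pores(img, tpl, thresholds = c(0.9, 0.8, 0.7))
  expect_equal(sum(det$tier == 1L), 0)
})

test_that("tier sets are nested and empty inputs give empty sets", {
  fx <- grid_pore_fixture(3, 3, spacing = 9, noise_sd = 0.3, seed = 2)
  tpl <- build_pore_template(4.5, fx$image$pixel_size)
  det <- detect_pores(fx$image, tpl)
  n1 <- sum(det$tier <= 1); n2 <- sum(det$tier <= 2); n3 <- sum(det$tier <= 3)
  expect_lte(n1, n2)
  expect_lte(n2, n3)

  blank <- topography_image(matrix(0, 40, 40), 0.5)
  expect_equal(n_particles(detect_pores(blank, tpl)), 0)
  big <- build_pore_template(4.5, 0.5, window_factor = 6)
  expect_error(detect_pores(topography_image(matrix(0, 10, 10), 0.5), big),
               "larger")
})

test_that("detection is equivariant under integer pixel shifts", {
  fx <- grid_pore_fixture(3, 3, spacing = 10, noise_sd = 0.05, seed = 4)
  tpl <- build_pore_template(4.5, fx$image$pixel_size)
  det0 <- detect_pores(fx$image, tpl)

  shift <- 3L  # pixels, rightward and downward
  h <- fx$image$heights
  h2 <- matrix(0, nrow(h), ncol(h))
  h2[(shift + 1):nrow(h), (shift + 1):ncol(h)] <-
    h[1:(nrow(h) - shift), 1:(ncol(h) - shift)]
  det1 <- detect_pores(topography_image(h2, fx$image$pixel_size), tpl)

  px <- fx$image$pixel_size
  # compare the central detections unaffected by the wrapped-in border
  common0 <- det0[det0$x_nm > 10 & det0$y_nm > 10, ]
  shifted_x <- common0$x_nm + shift * px
  shifted_y <- common0$y_nm - shift * px
  for (k in seq_along(shifted_x)) {
    d <- sqrt((det1$x_nm - shifted_x[k])^2 + (det1$y_nm - shifted_y[k])^2)
    expect_lt(min(d), 0.05)
  }
})

test_that("profiles are constant on flat images and measure pores/beads", {
  flat <- topography_image(matrix(1.5, 30, 30), 0.5)
  prof <- extract_profile(flat, c(2, 7), c(12, 7))
  expect_equal(var(prof$height_nm), 0)
  expect_error(extract_profile(flat, c(-1, 5), c(5, 5)), "inside")

  one <- particle_set(15, 15, region = region(30, 30))
  img <- render_topography(one, noise_sd = 0)
  fw <- profile_fwhd(extract_profile(img, c(4, 15), c(26, 15)))
  expect_equal(fw, 4.5, tolerance = img$pixel_size / 4.5)

  bead <- render_topography(one, noise_sd = 0, bead_fraction = 1, seed = 1)
  bprof <- extract_profile(bead, c(4, 15), c(26, 15))
  base <- median(bprof$height_nm)
  expect_gt(max(bprof$height_nm) - base, 1)
})
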