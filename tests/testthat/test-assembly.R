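test_that("a single site places cleanly with zero clash score", {
  tpl <- generate_template(seed = 1)
  m <- build_assembly(particle_set(10, 10), tpl, seed = 2)
  expect_equal(m$instances[[1]]$clash_score, 0)
  expect_true(all(m$instances[[1]]$lipids$retained))
  expect_null(m$pruned)
})

test_that("greedy rotation matches the exhaustive joint-grid oracle for disc-like pairs", {
  tpl <- generate_template(irregularity = 0, seed = 3)   # disc-like barrel
  sites <- particle_set(c(0, 4.0), c(0, 0))
  nrot <- 16L
  expect_warning(
    m <- build_assembly(sites, tpl, n_rotations = nrot, prune = FALSE,
                        seed = 4),
    "clashing")
  greedy_total <- sum(vapply(m$instances, `[[`, numeric(1), "clash_score"))

  # oracle: joint clash over all nrot^2 angle pairs, same phases
  pm <- as.matrix(tpl$protein[, c("x", "y", "z")])
  phases <- vapply(m$instances, `[[`, numeric(1), "angle")
  grid <- 2 * pi * (seq_len(nrot) - 1L) / nrot
  joint <- function(a1, a2) {
    p1 <- porescape:::rotate_xy(pm, a1); p1[, 1] <- p1[, 1] + 0
    p2 <- porescape:::rotate_xy(pm, a2); p2[, 1] <- p2[, 1] + 4.0
    sum(outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2 +
          outer(p1[, 3], p2[, 3], "-")^2 < m$clash_cutoff^2)
  }
  best <- Inf
  for (a1 in phases[1] + grid - grid[1])
    for (a2 in phases[2] + grid - grid[1])
      best <- min(best, joint(a1, a2))
  expect_equal(greedy_total, best)
})

test_that("two sites at 5.8 nm fall in the first lipid-separated class", {
  tpl <- generate_template(seed = 5)
  m <- build_assembly(particle_set(c(0, 5.8), c(0, 0)), tpl, seed = 6)
  cc <- classify_contacts(m)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$class, "lipid_shell_1")   # [56, 62) A
})

test_that("pruning is brute-force-correct, conservative, and idempotent", {
  tpl <- generate_template(seed = 7)
  n_lip <- nrow(tpl$lipids)

  # far apart: disjoint cylinders, nothing pruned
  far <- build_assembly(particle_set(c(0, 25), c(0, 0)), tpl, seed = 8)
  expect_null(far$pruned)

  # overlapping cylinders at 6 nm
  m0 <- build_assembly(particle_set(c(0, 6), c(0, 0)), tpl, prune = FALSE,
                       seed = 9)
  m <- prune_overlapping_lipids(m0)
  cut <- m$clash_cutoff

  # brute-force oracle of the sequential rule
  l1 <- m0$instances[[1]]$lipids; l2 <- m0$instances[[2]]$lipids
  p1 <- m0$instances[[1]]$protein; p2 <- m0$instances[[2]]$protein
  near <- function(a, b) {
    d2 <- outer(a$x, b[, 1], "-")^2 + outer(a$y, b[, 2], "-")^2 +
      outer(a$z, b[, 3], "-")^2
    apply(d2, 1, function(r) any(r < cut^2))
  }
  kill1 <- near(l1, p2)
  ret1 <- as.matrix(l1[!kill1, c("x", "y", "z")])
  kill2 <- near(l2, p1) | near(l2, ret1)
  expect_equal(sum(!m$instances[[1]]$lipids$retained), sum(kill1))
  expect_equal(sum(!m$instances[[2]]$lipids$retained), sum(kill2))

  # conservation and idempotence
  expect_equal(sum(m$instances[[1]]$lipids$retained) +
                 sum(m$instances[[2]]$lipids$retained) + nrow(m$pruned),
               2L * n_lip)
  m2 <- prune_overlapping_lipids(m)
  expect_equal(vapply(m2$instances, function(i) sum(i$lipids$retained),
                      numeric(1)),
               vapply(m$instances, function(i) sum(i$lipids$retained),
                      numeric(1)))
})

test_that("pruned assemblies have no residual inter-instance overlap", {
  p <- generate_pattern("glassy", 12, region(60, 60), seed = 10)
  tpl <- generate_template(seed = 11)
  m <- build_assembly(p, tpl, seed = 12)
  cut <- m$clash_cutoff
  # full pairwise scan: every retained lipid vs all beads of other instances
  beads <- lapply(m$instances, function(i) {
    lip <- i$lipids[i$lipids$retained, , drop = FALSE]
    list(lip = as.matrix(lip[, c("x", "y", "z")]), prot = i$protein)
  })
  for (a in seq_along(beads))
    for (b in seq_along(beads)) {
      if (a == b || !nrow(beads[[a]]$lip)) next
      other <- rbind(beads[[b]]$lip, beads[[b]]$prot)
      d2 <- outer(beads[[a]]$lip[, 1], other[, 1], "-")^2 +
        outer(beads[[a]]$lip[, 2], other[, 2], "-")^2 +
        outer(beads[[a]]$lip[, 3], other[, 3], "-")^2
      expect_gte(min(d2), cut^2)
    }
})

test_that("assembly building is deterministic under a fixed seed", {
  p <- generate_pattern("glassy", 8, region(50, 50), seed = 13)
  tpls <- list(generate_template(seed = 14), generate_template(seed = 15))
  a <- build_assembly(p, tpls, seed = 16)
  b <- build_assembly(p, tpls, seed = 16)
  expect_identical(lapply(a$instances, `[[`, "angle"),
                   lapply(b$instances, `[[`, "angle"))
  expect_identical(lapply(a$instances, `[[`, "template_id"),
                   lapply(b$instances, `[[`, "template_id"))
})

test_that("first-shell counts match the template and a brute-force scan", {
  tpl <- generate_template(seed = 17)
  iso <- build_assembly(particle_set(10, 10), tpl, seed = 18)
  fs <- first_shell_lipids(iso)
  expect_equal(fs$cytosolic, 20)
  expect_equal(fs$ims, 20)

  expect_equal(unname(unlist(first_shell_lipids(iso, shell_cutoff = 0)[, 2:3])),
               c(0L, 0L))

  # brute force at another cutoff
  cutoff <- 0.9
  inst <- iso$instances[[1]]
  lip <- inst$lipids[inst$lipids$retained, ]
  d2 <- outer(lip$x, inst$protein[, 1], "-")^2 +
    outer(lip$y, inst$protein[, 2], "-")^2 +
    outer(lip$z, inst$protein[, 3], "-")^2
  hit <- apply(d2, 1, function(r) any(r < cutoff^2))
  fs2 <- first_shell_lipids(iso, shell_cutoff = cutoff)
  expect_equal(fs2$cytosolic + fs2$ims, sum(hit))
})

test_that("assembly models round-trip to PDB with retained beads only", {
  p <- particle_set(c(0, 6), c(0, 0))
  tpl <- generate_template(seed = 19)
  m <- build_assembly(p, tpl, seed = 20)
  f <- tempfile(fileext = ".pdb")
  write_assembly_pdb(m, f)
  pdb <- bio3d::read.pdb(f)
  n_expected <- 2L * nrow(tpl$protein) +
    sum(vapply(m$instances, function(i) sum(i$lipids$retained), numeric(1)))
  expect_equal(nrow(pdb$atom), n_expected)
})
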