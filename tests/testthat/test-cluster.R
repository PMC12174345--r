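test_that("singletons, dimers and empty input follow the cluster definition", {
  one <- cluster_particles(particle_set(3, 3))
  expect_equal(one$n_total, 1)
  expect_equal(one$f_mono, 1)
  expect_equal(one$n_clusters, 0)

  dimer <- cluster_particles(particle_set(c(0, 5.0), c(0, 0)), epsilon = 5.3)
  expect_equal(dimer$sizes, 2L)
  expect_equal(dimer$f_clust, 1)
  expect_equal(dimer$f_mono, 0)

  apart <- cluster_particles(particle_set(c(0, 6.0), c(0, 0)), epsilon = 5.3)
  expect_equal(apart$f_mono, 1)

  empty <- cluster_particles(particle_set(numeric(0), numeric(0)))
  expect_equal(empty$n_total, 0)
})

test_that("labels equal the union-find oracle over 200 random instances", {
  set.seed(77)
  for (k in 1:200) {
    n <- sample(5:300, 1)
    side <- runif(1, 30, 120)
    xy <- cbind(runif(n, 0, side), runif(n, 0, side))
    p <- particle_set(xy[, 1], xy[, 2])
    rep_ <- cluster_particles(p, epsilon = 5.3)
    oracle <- union_find_clusters(xy, 5.3)
    expect_true(same_partition(rep_$labels, oracle))
    # partition identities
    expect_equal(rep_$f_mono + rep_$f_clust, 1)
    expect_equal(sum(rep_$labels == 0L) + sum(rep_$sizes), rep_$n_total)
    expect_true(all(rep_$sizes >= 2))
  }
})

test_that("clusters grow monotonically with epsilon", {
  set.seed(88)
  for (k in 1:20) {
    n <- sample(20:150, 1)
    xy <- cbind(runif(n, 0, 80), runif(n, 0, 80))
    p <- particle_set(xy[, 1], xy[, 2])
    r1 <- cluster_particles(p, epsilon = 4.0)
    r2 <- cluster_particles(p, epsilon = 6.5)
    expect_lte(r2$f_mono, r1$f_mono)
    # every eps1-cluster is inside some eps2-cluster
    for (cl in setdiff(unique(r1$labels), 0L)) {
      members <- which(r1$labels == cl)
      expect_equal(length(unique(r2$labels[members])), 1)
      expect_true(all(r2$labels[members] != 0L))
    }
  }
})

test_that("condition summaries reproduce the partition table arithmetic", {
  # two dimers, no monomers: f_mono = 0, mean size 2.0 +/- 0
  p <- particle_set(c(0, 5, 30, 35), c(0, 0, 0, 0))
  rep_ <- cluster_particles(p, epsilon = 5.3)
  tab <- summarize_conditions(list(rep_))
  expect_equal(tab$f_mono, 0)
  expect_equal(tab$f_clust, 1)
  expect_equal(tab$mean_size, 2.0)
  expect_equal(tab$sem_size, 0)

  # SEM/SD equal a direct recomputation from the size list
  set.seed(9)
  q <- particle_set(runif(120, 0, 70), runif(120, 0, 70),
                    condition = "random")
  rq <- cluster_particles(q)
  tq <- summarize_conditions(list(rq))
  expect_equal(tq$mean_size, mean(rq$sizes))
  expect_equal(tq$sd_size, sd(rq$sizes))
  expect_equal(tq$sem_size, sd(rq$sizes) / sqrt(length(rq$sizes)))
  expect_equal(tq$f_mono + tq$f_clust, 1)
  expect_equal(tq$condition, "random")
})
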