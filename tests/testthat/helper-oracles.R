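# Independent oracles used across tests. Kept deliberately naive: brute
# force over all pairs, union-find, literal formulas.

# union-find connected components of the epsilon-distance graph;
# singletons are labelled 0, components numbered by smallest member index
union_find_clusters <- function(xy, eps) {
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (sqrt(sum((xy[i, ] - xy[j, ])^2)) <= eps) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  sizes <- table(root)
  labels <- integer(n)
  comp_roots <- as.integer(names(sizes)[sizes >= 2])
  for (k in seq_along(comp_roots)) labels[root == comp_roots[k]] <- k
  labels
}

# same-partition check that is label-permutation invariant:
# identical monomer sets and identical co-membership relations
same_partition <- function(a, b) {
  identical(a == 0L, b == 0L) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# nearest-neighbour distances by full pairwise scan
brute_nn <- function(xy) {
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  apply(d, 1, min)
}

# independent point-in-dilated-convex-hull membership (re-derived from
# scratch: chull + half-plane tests + segment distances)
oracle_in_dilated_hull <- function(px, py, xy, R) {
  xy <- unique(xy)
  if (nrow(xy) == 1L)
    return(sqrt((px - xy[1, 1])^2 + (py - xy[1, 2])^2) <= R)
  h <- grDevices::chull(xy)
  v <- xy[h, , drop = FALSE]
  seg_d <- function(a, b) {
    ab <- b - a
    tt <- pmin(pmax(((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) /
                      max(sum(ab^2), 1e-30), 0), 1)
    sqrt((px - (a[1] + tt * ab[1]))^2 + (py - (a[2] + tt * ab[2]))^2)
  }
  nv <- nrow(v)
  if (nv <= 2L) {
    dmin <- seg_d(v[1, ], v[nv, ])
    return(dmin <= R)
  }
  if (shoelace_oracle(v) < 0) v <- v[nv:1, , drop = FALSE]
  inside <- rep(TRUE, length(px))
  dmin <- rep(Inf, length(px))
  for (i in seq_len(nv)) {
    a <- v[i, ]; b <- v[if (i == nv) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- inside & cr >= 0
    dmin <- pmin(dmin, seg_d(a, b))
  }
  inside | dmin <= R
}

shoelace_oracle <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# brute-force boundary-corrected g(r): double loop over particles and bins,
# ring areas by dense angular sampling against the oracle hull membership
oracle_rdf <- function(xy, R_dilate, dr, r_max, n_theta = 2048L) {
  n <- nrow(xy)
  # oracle patch area via fine-grid counting
  pad <- R_dilate + 1
  gx <- seq(min(xy[, 1]) - pad, max(xy[, 1]) + pad, by = 0.1)
  gy <- seq(min(xy[, 2]) - pad, max(xy[, 2]) + pad, by = 0.1)
  gg <- expand.grid(x = gx, y = gy)
  area <- sum(oracle_in_dilated_hull(gg$x, gg$y, xy, R_dilate)) * 0.01
  rho <- n / area
  nb <- ceiling(r_max / dr)
  r_mid <- (seq_len(nb) - 0.5) * dr
  theta <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
  g <- numeric(nb)
  for (b in seq_len(nb)) {
    tot <- 0
    for (i in seq_len(n)) {
      cnt <- 0L
      for (j in seq_len(n)) {
        if (i == j) next
        dij <- sqrt(sum((xy[i, ] - xy[j, ])^2))
        if (dij >= r_mid[b] - dr / 2 && dij < r_mid[b] + dr / 2)
          cnt <- cnt + 1L
      }
      frac <- mean(oracle_in_dilated_hull(xy[i, 1] + r_mid[b] * cos(theta),
                                          xy[i, 2] + r_mid[b] * sin(theta),
                                          xy, R_dilate))
      a_eff <- frac * 2 * pi * r_mid[b] * dr
      tot <- tot + if (a_eff > 0) cnt / (rho * a_eff) else 0
    }
    g[b] <- tot / n
  }
  list(r = r_mid, g = g, area = area)
}

# a clean grid-of-pores fixture with ground truth
grid_pore_fixture <- function(nx = 5, ny = 5, spacing = 10, margin = 10,
                              noise_sd = 0.05, seed = 1) {
  g <- expand.grid(x = margin + spacing * (seq_len(nx) - 1L),
                   y = margin + spacing * (seq_len(ny) - 1L))
  reg <- region(2 * margin + spacing * (nx - 1L),
                2 * margin + spacing * (ny - 1L))
  truth <- particle_set(g$x, g$y, region = reg)
  img <- render_topography(truth, noise_sd = noise_sd, seed = seed)
  list(truth = truth, image = img)
}
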