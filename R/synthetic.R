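#' Generate synthetic pore-center point patterns
#'
#' Produces planar point patterns with the statistical structure of
#' membrane-protein assemblies observed by AFM, so downstream analyses can be
#' exercised and benchmarked without instrument data. Four pattern kinds are
#' available:
#'
#' * `"glassy"` — a dense, noncrystalline (glass-like) honeycomb packing:
#'   cohesive sequential adsorption with a hard-core exclusion of `spacing`
#'   nm. The first particle is placed at the region center; each subsequent
#'   particle adsorbs at contact distance `spacing` from a randomly chosen
#'   placed particle at a random angle, rejected if it violates the hard
#'   core against any other particle. Random anchor/angle choices frustrate
#'   crystalline order, so the packing is amorphous but contact-dominated
#'   (modal nearest-neighbour distance = `spacing`). `relax_passes` sweeps
#'   of local jitter relaxation then perturb each particle by up to `jitter`
#'   nm around its adsorption position while never letting any pair come
#'   closer than `spacing - jitter`. The default spacing, 5.5 nm, is one
#'   4.5 nm pore diameter plus a 1.0 nm lipid annulus.
#' * `"filament"` — chains of pores along correlated random walks
#'   (persistence controls curvature), a few molecules wide.
#' * `"dense"` — as `"glassy"` but with protein-contact spacing
#'   (default 4.5 nm, no lipid annulus), emulating tight aggregates.
#' * `"poisson"` — complete spatial randomness: `n` i.i.d. uniform points,
#'   the null control for the radial distribution function.
#'
#' The glassy/dense assembly grows as a compact patch around the region
#' center (the surrounding region is bare lipid), mirroring the compact
#' structures seen in micrographs.
#'
#' @param kind one of `"glassy"`, `"filament"`, `"dense"`, `"poisson"`.
#' @param n number of particles to place.
#' @param region a [region()] bounding the pattern.
#' @param spacing hard-core nearest-neighbour spacing in nm (pore diameter
#'   plus lipid annulus); default 5.5 for glassy/filament/poisson, 4.5 for
#'   dense.
#' @param jitter local positional disorder amplitude in nm (>= 0).
#' @param chains number of filament chains (filament kind only); default
#'   `max(1, round(n / 25))`.
#' @param persistence directional persistence of filament chains in `[0, 1]`;
#'   1 is a straight row.
#' @param relax_passes number of jitter-relaxation sweeps for glassy/dense.
#' @param condition condition label stored on the particles.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param max_tries candidate draws allowed per particle before a
#'   packing-failure error.
#' @return a [particle_set()] with the generator's ground-truth positions.
#' @examples
#' p <- generate_pattern("glassy", 50, region(80, 80), seed = 1)
#' min(dist(cbind(p$x_nm, p$y_nm)))   # >= spacing - jitter
#' @export
generate_pattern <- function(kind = c("glassy", "filament", "dense", "poisson"),
                             n, region, spacing = NULL, jitter = 0.3,
                             chains = NULL, persistence = 0.85,
                             relax_passes = 5L,
                             condition = kind, seed = NULL,
                             max_tries = 5000L) {
  kind <- match.arg(kind)
  stopifnot_scalar(n, "n", nonneg = TRUE)
  if (!inherits(region, "region")) stop("`region` must be a region()", call. = FALSE)
  if (is.null(spacing)) spacing <- if (kind == "dense") 4.5 else 5.5
  stopifnot_scalar(spacing, "spacing", positive = TRUE)
  stopifnot_scalar(jitter, "jitter", nonneg = TRUE)
  set_seed_if(seed)
  n <- as.integer(n)
  condition <- as.character(condition)[1]

  if (n == 0L)
    return(particle_set(numeric(0), numeric(0), condition = condition,
                        region = region))

  xy <- switch(kind,
    poisson = cbind(stats::runif(n, 0, region$width),
                    stats::runif(n, 0, region$height)),
    glassy = ,
    dense = cohesive_pack(n, region, spacing, jitter, relax_passes,
                          max_tries),
    filament = filament_chains(n, region, spacing, jitter, chains,
                               persistence, max_tries)
  )
  particle_set(xy[, 1], xy[, 2], condition = condition, region = region)
}

# Cohesive sequential adsorption with hard core `spacing`, then local
# jitter relaxation with hard core `spacing - jitter`. The assembly grows
# from the region center; every new particle adsorbs at contact distance
# from a randomly chosen placed particle.
cohesive_pack <- function(n, region, spacing, jitter, relax_passes,
                          max_tries) {
  # rough feasibility: the grown patch needs room around the center
  patch_radius <- spacing * sqrt(n / pi) + spacing
  if (2 * patch_radius > min(region$width, region$height))
    stop(sprintf(paste0("region (%.1f x %.1f nm) too small for a compact ",
                        "assembly of %d particles at %.2f nm spacing; ",
                        "density infeasible"),
                 region$width, region$height, n, spacing), call. = FALSE)
  pts <- matrix(NA_real_, n, 2)
  pts[1, ] <- c(region$width / 2, region$height / 2)
  placed <- 1L
  while (placed < n) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      anchor <- pts[sample.int(placed, 1L), ]
      ang <- stats::runif(1, 0, 2 * pi)
      cand <- anchor + spacing * c(cos(ang), sin(ang))
      if (cand[1] < 0 || cand[1] > region$width ||
          cand[2] < 0 || cand[2] > region$height) next
      # hard core against everyone (contact with the anchor is exactly
      # `spacing`, so a tiny slack absorbs floating-point rounding)
      if (min_dist_to(cand, pts, placed) >= spacing - 1e-9) {
        placed <- placed + 1L
        pts[placed, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(paste0("packing failure: could not place particle %d of %d ",
                          "after %d tries (spacing %.2f nm)"),
                   placed + 1L, n, max_tries, spacing), call. = FALSE)
  }

  if (jitter > 0 && relax_passes > 0) {
    # Local jitter relaxation anchored at the RSA positions: each sweep
    # proposes a displacement inside the jitter disc around the particle's
    # anchor, accepted if the relaxed hard core (spacing - jitter) holds.
    # Anchoring keeps the modal pair distance at `spacing` instead of
    # letting repeated sweeps diffuse the packing apart.
    anchors <- pts
    core <- spacing - jitter
    for (pass in seq_len(relax_passes)) {
      for (i in sample.int(n)) {
        repeat {
          d <- stats::runif(2, -jitter, jitter)
          if (sum(d^2) <= jitter^2) break
        }
        cand <- anchors[i, ] + d
        if (cand[1] < 0 || cand[1] > region$width ||
            cand[2] < 0 || cand[2] > region$height) next
        other <- pts[-i, , drop = FALSE]
        if (nrow(other) == 0L || min_dist_to(cand, other, nrow(other)) >= core)
          pts[i, ] <- cand
      }
    }
  }
  pts
}

min_dist_to <- function(p, pts, k) {
  dx <- pts[seq_len(k), 1] - p[1]
  dy <- pts[seq_len(k), 2] - p[2]
  sqrt(min(dx * dx + dy * dy))
}

# Correlated random-walk chains with particles at spacing d0 along the axis.
filament_chains <- function(n, region, spacing, jitter, chains, persistence,
                            max_tries) {
  if (persistence < 0 || persistence > 1)
    stop("`persistence` must be in [0, 1]", call. = FALSE)
  chains <- as.integer(chains %||% max(1L, round(n / 25)))
  per_chain <- diff(round(seq(0, n, length.out = chains + 1L)))
  turn_sd <- (1 - persistence) * pi / 2
  core <- max(spacing - jitter, 0.5 * spacing)

  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  margin <- spacing
  for (m in per_chain) {
    if (m <= 0L) next
    # seed each chain away from the border
    for (try in seq_len(max_tries)) {
      pos <- c(stats::runif(1, margin, region$width - margin),
               stats::runif(1, margin, region$height - margin))
      if (placed == 0L || min_dist_to(pos, pts, placed) >= spacing) break
      if (try == max_tries)
        stop("packing failure: could not seed filament chain", call. = FALSE)
    }
    theta <- stats::runif(1, 0, 2 * pi)
    k <- 0L
    fails <- 0L
    while (k < m) {
      cand <- pos + jitter * stats::rnorm(2, sd = 0.5)
      inside <- cand[1] >= 0 && cand[1] <= region$width &&
        cand[2] >= 0 && cand[2] <= region$height
      if (inside && (placed == 0L || min_dist_to(cand, pts, placed) >= core)) {
        placed <- placed + 1L
        pts[placed, ] <- cand
        k <- k + 1L
        fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails > max_tries)
          stop("packing failure: filament chain stalled", call. = FALSE)
      }
      theta <- theta + stats::rnorm(1, sd = turn_sd)
      pos <- pos + spacing * c(cos(theta), sin(theta))
      if (pos[1] < 0 || pos[1] > region$width ||
          pos[2] < 0 || pos[2] > region$height) {
        # reflect back into the region and keep growing
        pos <- pmin(pmax(pos, 0), c(region$width, region$height))
        theta <- theta + pi / 2
      }
    }
  }
  pts[seq_len(placed), , drop = FALSE]
}
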