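#' Build a protein-lipid assembly model at measured coordinates
#'
#' Positions coarse-grained protein+lipid templates at the measured pore
#' centers to produce a stereochemical model of the assembly. Sites are
#' processed in particle order; each receives a template drawn at random
#' from `templates`. Because the experimental in-plane orientation of each
#' protein is unknown, every instance is rotated about its channel axis
#' (the membrane normal): a random phase plus a uniform grid of
#' `n_rotations` angles is evaluated and the angle minimizing the clash
#' score — the count of inter-instance protein-bead pairs closer than
#' `clash_cutoff` against already-placed instances — is kept (ties go to
#' the first grid angle, i.e. the random phase). Sites closer than the
#' protein hard-core diameter are flagged as clashing pairs with a warning;
#' they correspond to the strong-contact (< 50 A) distance class.
#'
#' After placement, call [prune_overlapping_lipids()] to remove lipids
#' overlapping previously placed instances, then [classify_contacts()],
#' [first_shell_lipids()] or [compute_occupancy_map()].
#'
#' @param particles a [particle_set()] of pore centers (nm).
#' @param templates a list of [generate_template()] objects (>= 1), or a
#'   single template.
#' @param n_rotations rotation-grid density (default 64).
#' @param clash_cutoff bead-pair clash distance in nm (default 0.47,
#'   one coarse bead diameter).
#' @param prune if `TRUE` (default) sequential lipid pruning is applied.
#' @param seed integer seed (template draws and rotation phases).
#' @return an object of class `"assembly_model"`: a list with `sites`,
#'   `instances` (per site: `template_id`, `angle`, `clash_score`,
#'   `protein` bead matrix, `lipids` data.frame with `retained` flag),
#'   `clash_pairs`, `clash_cutoff`, `pruned` (log of removed lipid beads).
#' @export
build_assembly <- function(particles, templates, n_rotations = 64L,
                           clash_cutoff = 0.47, prune = TRUE, seed = NULL) {
  if (inherits(templates, "cg_template")) templates <- list(templates)
  if (!length(templates)) stop("need at least one template", call. = FALSE)
  if (n_rotations < 1L) stop("`n_rotations` must be >= 1", call. = FALSE)
  stopifnot_scalar(clash_cutoff, "clash_cutoff", positive = TRUE)
  set_seed_if(seed)
  n <- n_particles(particles)
  xy <- coords(particles)

  protein_diam <- 2 * max(vapply(templates, function(t)
    max(sqrt(t$protein$x^2 + t$protein$y^2)), numeric(1)))

  # flag site pairs below the protein hard core
  clash_pairs <- NULL
  if (n >= 2L) {
    d <- pair_dist(xy)
    idx <- which(upper.tri(d) & d < protein_diam, arr.ind = TRUE)
    if (nrow(idx)) {
      clash_pairs <- data.frame(i = idx[, 1], j = idx[, 2],
                                dist_nm = d[idx])
      warning(sprintf("%d site pair(s) closer than the protein hard-core diameter (%.2f nm); flagged as clashing",
                      nrow(idx), protein_diam), call. = FALSE)
    }
  }

  grid <- 2 * pi * (seq_len(n_rotations) - 1L) / n_rotations
  instances <- vector("list", n)
  placed_protein <- NULL   # accumulated protein beads (x, y, z, site)

  for (i in seq_len(n)) {
    tid <- sample.int(length(templates), 1L)
    tpl <- templates[[tid]]
    phase <- stats::runif(1, 0, 2 * pi)
    angles <- phase + grid

    # neighbours that can possibly clash
    cand <- placed_protein
    if (!is.null(cand)) {
      near <- sqrt((cand[, 1] - xy[i, 1])^2 + (cand[, 2] - xy[i, 2])^2) <
        protein_diam + clash_cutoff
      cand <- cand[near, , drop = FALSE]
      if (!nrow(cand)) cand <- NULL
    }

    pm <- as.matrix(tpl$protein[, c("x", "y", "z")])
    scores <- vapply(angles, function(a) {
      pr <- rotate_xy(pm, a)
      pr[, 1] <- pr[, 1] + xy[i, 1]; pr[, 2] <- pr[, 2] + xy[i, 2]
      clash_count(pr, cand, clash_cutoff)
    }, numeric(1))
    best <- which.min(scores)       # ties -> first grid angle (the phase)
    a_best <- angles[best]

    pr <- rotate_xy(pm, a_best)
    pr[, 1] <- pr[, 1] + xy[i, 1]; pr[, 2] <- pr[, 2] + xy[i, 2]
    lip <- tpl$lipids
    if (nrow(lip)) {
      lm <- rotate_xy(as.matrix(lip[, c("x", "y", "z")]), a_best)
      lip$x <- lm[, 1] + xy[i, 1]; lip$y <- lm[, 2] + xy[i, 2]
      lip$z <- lm[, 3]
    }
    lip$retained <- rep(TRUE, nrow(lip))
    instances[[i]] <- list(template_id = tid, angle = a_best %% (2 * pi),
                           clash_score = scores[best],
                           protein = pr, lipids = lip)
    placed_protein <- rbind(placed_protein, pr)
  }

  model <- structure(list(sites = particles, instances = instances,
                          clash_pairs = clash_pairs,
                          clash_cutoff = clash_cutoff,
                          protein_diameter = protein_diam,
                          pruned = NULL),
                     class = "assembly_model")
  if (prune) model <- prune_overlapping_lipids(model, clash_cutoff)
  model
}

rotate_xy <- function(m, a) {
  out <- m
  out[, 1] <- m[, 1] * cos(a) - m[, 2] * sin(a)
  out[, 2] <- m[, 1] * sin(a) + m[, 2] * cos(a)
  out
}

clash_count <- function(beads, other, cutoff) {
  if (is.null(other) || !nrow(other)) return(0)
  d2 <- outer(beads[, 1], other[, 1], "-")^2 +
    outer(beads[, 2], other[, 2], "-")^2 +
    outer(beads[, 3], other[, 3], "-")^2
  sum(d2 < cutoff^2)
}

#' @export
print.assembly_model <- function(x, ...) {
  nl <- sum(vapply(x$instances, function(i) sum(i$lipids$retained), numeric(1)))
  np <- if (is.null(x$pruned)) 0L else nrow(x$pruned)
  cat(sprintf("<assembly_model> %d sites, %d retained lipid beads (%d pruned), %d flagged clashing site pair(s)\n",
              length(x$instances), nl, np,
              if (is.null(x$clash_pairs)) 0L else nrow(x$clash_pairs)))
  invisible(x)
}

#' Sequentially remove overlapping lipids from an assembly
#'
#' Iterates over instances in placement order; a lipid bead of a later
#' instance is removed when it lies within `overlap_cutoff` of any protein
#' bead of another instance or of any still-retained lipid bead of an
#' earlier instance (earlier-placed instances win). The result has no
#' inter-instance lipid bead pair below the cutoff, lipid beads are
#' conserved (`retained + pruned = initial`), and the operation is
#' idempotent. The removal log is kept in `model$pruned`.
#'
#' @param model an [build_assembly()] result.
#' @param overlap_cutoff overlap distance in nm; defaults to the model's
#'   clash cutoff.
#' @return the pruned `assembly_model`.
#' @export
prune_overlapping_lipids <- function(model, overlap_cutoff = NULL) {
  overlap_cutoff <- overlap_cutoff %||% model$clash_cutoff
  m <- length(model$instances)
  all_protein <- lapply(model$instances, `[[`, "protein")
  retained_prev <- NULL   # lipid beads retained from earlier instances
  log <- NULL
  for (k in seq_len(m)) {
    inst <- model$instances[[k]]
    lip <- inst$lipids
    if (!nrow(lip)) { retained_prev <- retained_prev; next }
    alive <- which(lip$retained)
    if (length(alive)) {
      lxyz <- as.matrix(lip[alive, c("x", "y", "z")])
      other_prot <- do.call(rbind, all_protein[-k])
      kill <- rep(FALSE, length(alive))
      if (!is.null(other_prot) && nrow(other_prot))
        kill <- kill | near_any(lxyz, other_prot, overlap_cutoff)
      if (!is.null(retained_prev) && nrow(retained_prev))
        kill <- kill | near_any(lxyz, retained_prev, overlap_cutoff)
      if (any(kill)) {
        idx <- alive[kill]
        lip$retained[idx] <- FALSE
        log <- rbind(log, data.frame(site = k, bead = idx,
                                     species = lip$species[idx],
                                     leaflet = lip$leaflet[idx]))
        model$instances[[k]]$lipids <- lip
      }
    }
    keep <- lip$retained
    if (any(keep))
      retained_prev <- rbind(retained_prev,
                             as.matrix(lip[keep, c("x", "y", "z")]))
  }
  model$pruned <- rbind(model$pruned, log)
  model
}

near_any <- function(a, b, cutoff) {
  # for each row of a: any row of b within cutoff (3-D)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 +
    outer(a[, 3], b[, 3], "-")^2
  apply(d2, 1, function(r) any(r < cutoff^2))
}

#' First-shell lipid counts per instance and leaflet
#'
#' Counts the retained lipid beads lying within `shell_cutoff` of any
#' protein bead of their own instance — the lipids in direct contact with
#' the protein wall — split by leaflet. For the isolated default
#' disc-and-shell template this is 20 per leaflet.
#'
#' @param model an [build_assembly()] result.
#' @param shell_cutoff contact distance in nm (default 1.2, separating the
#'   annular shell from the next lipid row).
#' @return a `data.frame` with columns `site`, `cytosolic`, `ims`.
#' @export
first_shell_lipids <- function(model, shell_cutoff = 1.2) {
  stopifnot_scalar(shell_cutoff, "shell_cutoff", nonneg = TRUE)
  out <- lapply(seq_along(model$instances), function(k) {
    inst <- model$instances[[k]]
    lip <- inst$lipids[inst$lipids$retained, , drop = FALSE]
    if (!nrow(lip) || shell_cutoff == 0)
      return(data.frame(site = k, cytosolic = 0L, ims = 0L))
    near <- near_any(as.matrix(lip[, c("x", "y", "z")]), inst$protein,
                     shell_cutoff)
    data.frame(site = k,
               cytosolic = sum(near & lip$leaflet == "cytosolic"),
               ims = sum(near & lip$leaflet == "ims"))
  })
  do.call(rbind, out)
}

#' Classify pairwise contacts of an assembly
#'
#' Assigns every site pair within the distance-context range its class from
#' [distance_classes()] (determined solely by the center distance) and a
#' mediation label from the retained lipid content of the inter-protein
#' corridor — the rectangle of width one protein diameter between the two
#' centers: no corridor lipids gives `direct`, corridor lipids at direct-
#' contact distance (< 56 A) give `mixed`, otherwise `lipid-bridged`.
#'
#' @param model an [build_assembly()] result.
#' @param max_dist_A largest center distance classified, in Angstrom
#'   (default 86, the outer boundary of the row class).
#' @return a `data.frame` with `i`, `j`, `dist_A`, `class`, `mediation`.
#' @export
classify_contacts <- function(model, max_dist_A = 86) {
  xy <- coords(model$sites)
  n <- nrow(xy)
  if (n < 2L)
    return(data.frame(i = integer(0), j = integer(0), dist_A = numeric(0),
                      class = character(0), mediation = character(0)))
  cls <- distance_classes()
  d <- pair_dist(xy) * A_PER_NM
  idx <- which(upper.tri(d) & d < max_dist_A, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(i = integer(0), j = integer(0), dist_A = numeric(0),
                      class = character(0), mediation = character(0)))

  lip_all <- do.call(rbind, lapply(model$instances, function(i)
    i$lipids[i$lipids$retained, c("x", "y"), drop = FALSE]))
  half_w <- model$protein_diameter / 2

  out <- lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    dist_A <- d[i, j]
    k <- which(cls$lo_A <= dist_A & dist_A < cls$hi_A)
    lab <- if (length(k)) cls$label[k] else NA_character_
    n_lip <- corridor_count(lip_all, xy[i, ], xy[j, ], half_w)
    med <- if (n_lip == 0L) "direct"
           else if (dist_A < 56) "mixed" else "lipid-bridged"
    data.frame(i = i, j = j, dist_A = dist_A, class = lab, mediation = med,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# count points inside the rectangle between a and b (width 2*half_w),
# excluding the disc of radius half_w around each endpoint
corridor_count <- function(pts, a, b, half_w) {
  if (is.null(pts) || !nrow(pts)) return(0L)
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len < 1e-9) return(0L)
  u <- ab / len
  rel_x <- (pts[, 1] - a[1]) * u[1] + (pts[, 2] - a[2]) * u[2]
  rel_y <- -(pts[, 1] - a[1]) * u[2] + (pts[, 2] - a[2]) * u[1]
  sum(rel_x > half_w & rel_x < len - half_w & abs(rel_y) <= half_w)
}

#' Write an assembly model to PDB
#'
#' One PDB file with protein beads on chain P and lipid beads on chains
#' C/I by leaflet, species in the residue name; pruned lipids are omitted.
#' Coordinates written in Angstrom.
#'
#' @param model an [build_assembly()] result.
#' @param path output path.
#' @export
write_assembly_pdb <- function(model, path) {
  rows <- list()
  for (k in seq_along(model$instances)) {
    inst <- model$instances[[k]]
    rows[[length(rows) + 1L]] <-
      data.frame(x = inst$protein[, 1], y = inst$protein[, 2],
                 z = inst$protein[, 3], resid = "PRO", chain = "P",
                 resno = k)
    lip <- inst$lipids[inst$lipids$retained, , drop = FALSE]
    if (nrow(lip))
      rows[[length(rows) + 1L]] <-
        data.frame(x = lip$x, y = lip$y, z = lip$z,
                   resid = species_to_pdb(lip$species),
                   chain = ifelse(lip$leaflet == "cytosolic", "C", "I"),
                   resno = k)
  }
  df <- do.call(rbind, rows)
  atomic_write(path, function(tmp)
    bio3d::write.pdb(file = tmp,
                     xyz = as.numeric(t(as.matrix(df[, c("x", "y", "z")]) *
                                          A_PER_NM)),
                     resno = df$resno, resid = df$resid, chain = df$chain,
                     elety = rep("L1", nrow(df))))
}
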