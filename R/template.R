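#' Generate a disc-and-shell protein-lipid template
#'
#' Builds a synthetic coarse-grained template mimicking a beta-barrel pore
#' with its extracted lipid environment: a barrel-like ring of protein
#' beads (19 per ring, one ring per leaflet plane plus a midplane ring,
#' outer diameter 4.5 nm, with small per-template radial irregularity so
#' orientation matters), surrounded by lipid beads inside a cylinder of
#' `cylinder_radius` (default 5 nm) about the protein axis. Exactly
#' `n_first_shell_per_leaflet` lipids per leaflet (default 20) are tagged
#' as the first shell — lipids in direct contact with the protein wall —
#' and the remaining lipids fill the cylinder annulus at bilayer packing
#' density. Lipid species are drawn from `species_weights`; the leaflet tag
#' (`cytosolic` at z > 0, `ims` at z < 0) partitions the lipids.
#'
#' Real MD-derived templates can be used instead via [read_template_pdb()].
#'
#' @param n_first_shell_per_leaflet first-shell lipid count per leaflet
#'   (>= 0; limited by the shell circumference).
#' @param cylinder_radius lipid extrusion radius about the protein axis, nm.
#' @param species_weights named numeric vector of lipid species
#'   probabilities summing to 1 (default `c(PC = .6, PE = .3, CHOL = .1)`).
#' @param irregularity amplitude of the per-strand radial irregularity of
#'   the barrel wall, nm (default 0.15); 0 gives a perfectly disc-like
#'   (rotationally symmetric) barrel.
#' @param seed integer seed; fixed seed gives identical bead positions.
#' @return an object of class `"cg_template"`: a list with `protein`
#'   (data.frame x, y, z in nm), `lipids` (x, y, z, species, leaflet,
#'   first_shell), `cylinder_radius`, `protein_radius`.
#' @export
generate_template <- function(n_first_shell_per_leaflet = 20L,
                              cylinder_radius = 5,
                              species_weights = c(PC = 0.6, PE = 0.3,
                                                  CHOL = 0.1),
                              irregularity = 0.15, seed = NULL) {
  if (n_first_shell_per_leaflet < 0)
    stop("first-shell count must be >= 0", call. = FALSE)
  stopifnot_scalar(cylinder_radius, "cylinder_radius", positive = TRUE)
  if (abs(sum(species_weights) - 1) > 1e-6)
    stop("`species_weights` must sum to 1", call. = FALSE)
  set_seed_if(seed)

  barrel_r <- 2.1          # bead-center radius; outer surface ~2.25 nm
  shell_r <- 2.85          # first-shell lipid radius (annulus contact)
  lipid_spacing <- 0.82    # in-plane bead spacing of the filler lipids
  leaflet_z <- 1.0

  n_strands <- 19L
  ang <- seq(0, 2 * pi, length.out = n_strands + 1L)[-(n_strands + 1L)]
  rr <- barrel_r + stats::runif(n_strands, -irregularity, irregularity)
  protein <- do.call(rbind, lapply(c(-leaflet_z, 0, leaflet_z), function(z)
    data.frame(x = rr * cos(ang), y = rr * sin(ang), z = z)))

  max_shell <- floor(2 * pi * shell_r / 0.6)
  if (n_first_shell_per_leaflet > max_shell)
    stop(sprintf("geometric overflow: at most %d first-shell lipids fit per leaflet",
                 max_shell), call. = FALSE)
  if (shell_r >= cylinder_radius)
    stop("cylinder_radius too small for a lipid shell", call. = FALSE)

  one_leaflet <- function(z, leaflet) {
    lips <- NULL
    n1 <- n_first_shell_per_leaflet
    if (n1 > 0) {
      a <- seq(0, 2 * pi, length.out = n1 + 1L)[-(n1 + 1L)] +
        stats::runif(1, 0, 2 * pi / n1)
      r1 <- shell_r + stats::runif(n1, -0.08, 0.08)
      lips <- data.frame(x = r1 * cos(a), y = r1 * sin(a), z = z,
                         first_shell = TRUE)
    }
    r <- shell_r + lipid_spacing
    while (r < cylinder_radius - 0.05) {
      nk <- max(1L, floor(2 * pi * r / lipid_spacing))
      a <- seq(0, 2 * pi, length.out = nk + 1L)[-(nk + 1L)] +
        stats::runif(1, 0, 2 * pi / nk)
      rk <- pmin(r + stats::runif(nk, -0.1, 0.1), cylinder_radius - 1e-6)
      lips <- rbind(lips, data.frame(x = rk * cos(a), y = rk * sin(a), z = z,
                                     first_shell = FALSE))
      r <- r + lipid_spacing
    }
    if (is.null(lips)) return(NULL)
    lips$leaflet <- leaflet
    lips
  }
  lipids <- rbind(one_leaflet(leaflet_z, "cytosolic"),
                  one_leaflet(-leaflet_z, "ims"))
  if (!is.null(lipids) && nrow(lipids)) {
    lipids$species <- sample(names(species_weights), nrow(lipids),
                             replace = TRUE, prob = species_weights)
    lipids <- lipids[, c("x", "y", "z", "species", "leaflet", "first_shell")]
    rownames(lipids) <- NULL
  } else {
    lipids <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                         species = character(0), leaflet = character(0),
                         first_shell = logical(0))
  }
  structure(list(protein = protein, lipids = lipids,
                 cylinder_radius = cylinder_radius, protein_radius = barrel_r),
            class = "cg_template")
}

#' @export
print.cg_template <- function(x, ...) {
  cat(sprintf("<cg_template> %d protein beads, %d lipid beads (%d first-shell) in a %.3g nm cylinder\n",
              nrow(x$protein), nrow(x$lipids), sum(x$lipids$first_shell),
              x$cylinder_radius))
  invisible(x)
}

#' Read / write coarse-grained templates as PDB
#'
#' Templates are exchanged as PDB coordinate files (via \pkg{bio3d}):
#' protein beads as `BB` atoms of residue `PRO` on chain `P`, lipid beads
#' with the species in the residue name (3-character PDB codes: `CHL` for
#' cholesterol) and the leaflet in the chain identifier (`C` = cytosolic,
#' `I` = IMS); first-shell lipids carry B-factor 1. Coordinates are stored
#' in Angstrom per PDB convention and converted to nm on read.
#'
#' @param template a [generate_template()] result.
#' @param path file path.
#' @param cylinder_radius cylinder radius (nm) to record on read.
#' @export
write_template_pdb <- function(template, path) {
  p <- template$protein; l <- template$lipids
  n <- nrow(p) + nrow(l)
  xyz <- rbind(as.matrix(p[, c("x", "y", "z")]),
               as.matrix(l[, c("x", "y", "z")])) * A_PER_NM
  resid <- c(rep("PRO", nrow(p)), species_to_pdb(l$species))
  chain <- c(rep("P", nrow(p)), ifelse(l$leaflet == "cytosolic", "C", "I"))
  bfac <- c(rep(0, nrow(p)), as.numeric(l$first_shell))
  atomnm <- c(rep("BB", nrow(p)), rep("L1", nrow(l)))
  atomic_write(path, function(tmp)
    bio3d::write.pdb(file = tmp, xyz = as.numeric(t(xyz)),
                     resno = seq_len(n), resid = resid, chain = chain,
                     elety = atomnm, b = bfac))
}

# PDB residue names are 3 characters; map the common lipid species codes
species_to_pdb <- function(sp) {
  map <- c(CHOL = "CHL", CDL = "CDL", POPC = "PC", POPE = "PE")
  out <- ifelse(sp %in% names(map), map[sp], substr(sp, 1, 3))
  unname(out)
}

species_from_pdb <- function(res) {
  map <- c(CHL = "CHOL")
  out <- ifelse(res %in% names(map), map[res], res)
  unname(out)
}

#' @rdname write_template_pdb
#' @export
read_template_pdb <- function(path, cylinder_radius = 5) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  is_prot <- a$chain %in% "P"
  protein <- data.frame(x = a$x[is_prot], y = a$y[is_prot],
                        z = a$z[is_prot]) / A_PER_NM
  li <- !is_prot
  lipids <- data.frame(x = a$x[li] / A_PER_NM, y = a$y[li] / A_PER_NM,
                       z = a$z[li] / A_PER_NM,
                       species = species_from_pdb(a$resid[li]),
                       leaflet = ifelse(a$chain[li] %in% "C", "cytosolic",
                                        "ims"),
                       first_shell = a$b[li] > 0.5)
  pr <- if (any(is_prot))
    max(sqrt(protein$x^2 + protein$y^2)) else NA_real_
  structure(list(protein = protein, lipids = lipids,
                 cylinder_radius = cylinder_radius, protein_radius = pr),
            class = "cg_template")
}
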