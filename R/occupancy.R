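#' Lipid occupancy and enrichment maps
#'
#' Bins bead positions per species and leaflet on a fine planar grid
#' (default resolution 2 Angstrom = 0.2 nm) without any Gaussian averaging,
#' and converts counts to enrichment: the local count divided by the
#' species' mean count over the occupied region (cells holding at least one
#' bead of any species in that leaflet). Enrichment is therefore the
#' probability of presence of a lipid relative to its own abundance —
#' species with different copy numbers are directly comparable — and its
#' count-weighted interpretation guarantees a mean of 1 over the occupied
#' region. Regions above a fold cutoff (conventionally 1.2 or 1.8)
#' delineate lipid enrichment; see [enrichment_region()].
#'
#' @param beads a `data.frame` with columns `x`, `y` (nm), `species`, and
#'   optionally `leaflet` (default one leaflet `"all"`); typically the
#'   retained lipid beads of an [build_assembly()] model via
#'   [assembly_beads()].
#' @param grid_resolution cell edge in nm (default 0.2 = 2 A).
#' @param bbox optional `c(xmin, xmax, ymin, ymax)`; default the bead
#'   bounding box.
#' @return an object of class `"occupancy_map"`: per leaflet a list with
#'   `counts` (named list of species matrices), `enrichment`, `occupied`
#'   (logical matrix), plus `resolution`, `origin`, `species`.
#' @export
compute_occupancy_map <- function(beads, grid_resolution = 0.2, bbox = NULL) {
  stopifnot_scalar(grid_resolution, "grid_resolution", positive = TRUE)
  if (!nrow(beads)) stop("need at least one bead", call. = FALSE)
  if (is.null(beads$leaflet)) beads$leaflet <- "all"
  bb <- bbox %||% c(min(beads$x), max(beads$x), min(beads$y), max(beads$y))
  res <- grid_resolution
  nc <- max(1L, ceiling((bb[2] - bb[1]) / res))
  nr <- max(1L, ceiling((bb[4] - bb[3]) / res))

  leaflets <- unique(beads$leaflet)
  species <- sort(unique(beads$species))
  out <- list()
  for (lf in leaflets) {
    sub <- beads[beads$leaflet == lf, , drop = FALSE]
    cols <- pmin(pmax(floor((sub$x - bb[1]) / res) + 1L, 1L), nc)
    rows <- pmin(pmax(floor((sub$y - bb[3]) / res) + 1L, 1L), nr)
    counts <- list()
    occupied <- matrix(FALSE, nr, nc)
    for (sp in species) {
      sel <- sub$species == sp
      if (!any(sel)) {
        warning(sprintf("species %s has no beads in leaflet %s; skipped",
                        sp, lf), call. = FALSE)
        next
      }
      m <- matrix(0, nr, nc)
      tab <- table(factor(rows[sel], levels = seq_len(nr)),
                   factor(cols[sel], levels = seq_len(nc)))
      m[] <- as.numeric(tab)
      counts[[sp]] <- m
      occupied <- occupied | m > 0
    }
    n_occ <- sum(occupied)
    enrichment <- lapply(counts, function(m) {
      mean_density <- sum(m) / n_occ
      e <- m / mean_density
      e[!occupied] <- 0
      e
    })
    out[[lf]] <- list(counts = counts, enrichment = enrichment,
                      occupied = occupied)
  }
  structure(list(leaflets = out, resolution = res,
                 origin = c(bb[1], bb[3]), species = species),
            class = "occupancy_map")
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy_map> %.3g nm cells, leaflets: %s, species: %s\n",
              x$resolution, paste(names(x$leaflets), collapse = ", "),
              paste(x$species, collapse = ", ")))
  invisible(x)
}

#' Threshold an enrichment map
#'
#' Returns the boolean region where a species' enrichment is at least
#' `fold` times its mean density (cutoffs of 1.2 and 1.8 are the
#' conventional contour levels for lipid enrichment maps).
#'
#' @param map an [compute_occupancy_map()] result.
#' @param species species name.
#' @param leaflet leaflet name (default the first).
#' @param fold enrichment cutoff (default 1.2; 1.8 for the stricter
#'   contour).
#' @return a logical matrix.
#' @export
enrichment_region <- function(map, species, leaflet = NULL, fold = 1.2) {
  lf <- leaflet %||% names(map$leaflets)[1]
  e <- map$leaflets[[lf]]$enrichment[[species]]
  if (is.null(e)) stop("unknown species or leaflet", call. = FALSE)
  e >= fold
}

#' Collect the retained beads of an assembly model
#'
#' Flattens an assembly into one bead table (lipids, and optionally the
#' protein beads as species `"PROT"`) for occupancy mapping.
#'
#' @param model an [build_assembly()] result.
#' @param include_protein also include protein beads.
#' @return a `data.frame` with `x`, `y`, `z`, `species`, `leaflet`.
#' @export
assembly_beads <- function(model, include_protein = FALSE) {
  rows <- lapply(seq_along(model$instances), function(k) {
    inst <- model$instances[[k]]
    lip <- inst$lipids[inst$lipids$retained, , drop = FALSE]
    df <- if (nrow(lip))
      data.frame(x = lip$x, y = lip$y, z = lip$z, species = lip$species,
                 leaflet = lip$leaflet, stringsAsFactors = FALSE)
    else NULL
    if (include_protein) {
      pr <- data.frame(x = inst$protein[, 1], y = inst$protein[, 2],
                       z = inst$protein[, 3], species = "PROT",
                       leaflet = ifelse(inst$protein[, 3] >= 0,
                                        "cytosolic", "ims"),
                       stringsAsFactors = FALSE)
      df <- rbind(df, pr)
    }
    df
  })
  do.call(rbind, rows)
}
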