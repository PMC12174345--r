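#' Membrane composition bookkeeping
#'
#' A membrane composition is a per-species table of lipid counts, optional
#' per-leaflet counts, and total species masses in Dalton, from which mass
#' and molar percentages are derived. Two reference compositions used in
#' coarse-grained simulations of the mitochondrial outer membrane ship as
#' constructors: [sm1_composition()] (POPC/POPE 65/35 w:w, 1100 lipids) and
#' [sm2_composition()] (POPC/POPE/CHOL/CDL ~ 62.5/31.5/5.3/1.1 w:w).
#'
#' @param species character vector of species labels.
#' @param count total lipid count per species.
#' @param mass_da total species mass in Dalton (mass of all copies).
#' @param per_leaflet optional per-leaflet count (assumed symmetric if
#'   omitted).
#' @return an object of class `"membrane_composition"` (a data.frame).
#' @export
membrane_composition <- function(species, count, mass_da, per_leaflet = NULL) {
  if (length(unique(c(length(species), length(count), length(mass_da)))) != 1L)
    stop("species, count and mass_da must have equal length", call. = FALSE)
  if (any(count < 0) || any(mass_da < 0))
    stop("counts and masses must be non-negative", call. = FALSE)
  per_leaflet <- per_leaflet %||% (count / 2)
  df <- data.frame(species = as.character(species), count = count,
                   per_leaflet = per_leaflet, mass_da = mass_da,
                   stringsAsFactors = FALSE)
  if (any(abs(df$per_leaflet * 2 - df$count) > 1e-9)) {
    # leaflet counts that do not sum to the species count are flagged, not
    # silently fixed (printed tables are occasionally inconsistent)
    warning("per-leaflet counts do not sum to species counts for: ",
            paste(df$species[abs(df$per_leaflet * 2 - df$count) > 1e-9],
                  collapse = ", "), call. = FALSE)
  }
  structure(df, class = c("membrane_composition", "data.frame"))
}

#' @rdname membrane_composition
#' @export
sm1_composition <- function() {
  membrane_composition(c("POPC", "POPE"),
                       count = c(716, 384),
                       mass_da = c(536747, 272111),
                       per_leaflet = c(358, 192))
}

#' @rdname membrane_composition
#' @export
sm2_composition <- function() {
  # CDL count/leaflet reconstructed from the totals (1100 lipids,
  # 775,524 Da): 1100 - 642 - 345 - 107 = 6 cardiolipins, 3 per leaflet
  membrane_composition(c("POPC", "POPE", "CDL", "CHOL"),
                       count = c(642, 345, 6, 107),
                       mass_da = c(481622, 244164, 8532, 41205),
                       per_leaflet = c(321, 172, 3, 54))
}

#' @export
print.membrane_composition <- function(x, ...) {
  df <- as.data.frame(x)
  df$pct_w <- round(100 * df$mass_da / sum(df$mass_da), 1)
  df$pct_mol <- round(100 * df$count / sum(df$count), 1)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("  total: %d lipids, %s Da\n", sum(df$count),
              format(sum(df$mass_da), big.mark = ",")))
  invisible(x)
}

check_species <- function(composition, species) {
  if (!species %in% composition$species)
    stop(sprintf("unknown species '%s' (have: %s)", species,
                 paste(composition$species, collapse = ", ")), call. = FALSE)
}

#' Mass and molar fractions of a composition
#'
#' `mass_fraction()` is the species mass over the total mass (the %W
#' column of a composition table); `molar_fraction()` is the species count
#' over the total count (%mol). Both are returned in percent; display
#' rounding to 1 decimal is applied only when `digits` is given.
#'
#' @param composition a [membrane_composition()].
#' @param species species label.
#' @param digits optional rounding for display.
#' @return percentage (numeric scalar).
#' @examples
#' mass_fraction(sm1_composition(), "POPC", digits = 1)   # 66.4
#' molar_fraction(sm1_composition(), "POPC", digits = 1)  # 65.1
#' @export
mass_fraction <- function(composition, species, digits = NULL) {
  check_species(composition, species)
  tot <- sum(composition$mass_da)
  if (tot <= 0) stop("total mass must be > 0", call. = FALSE)
  out <- 100 * composition$mass_da[composition$species == species] / tot
  if (is.null(digits)) out else round(out, digits)
}

#' @rdname mass_fraction
#' @export
molar_fraction <- function(composition, species, digits = NULL) {
  check_species(composition, species)
  tot <- sum(composition$count)
  if (tot <= 0) stop("total count must be > 0", call. = FALSE)
  out <- 100 * composition$count[composition$species == species] / tot
  if (is.null(digits)) out else round(out, digits)
}

#' Convert a lipid:protein mass ratio to a molar ratio
#'
#' `molar = mass_ratio * protein_mass / mean_lipid_mass`. With a mean
#' lipid mass of 745 Da and a protein mass of 34,766 Da (a His-tagged
#' ~31 kDa beta-barrel as prepared for reconstitution), the conventional
#' 3:1 w:w reconstitution ratio corresponds to 140:1 mol:mol.
#'
#' @param mass_ratio lipid:protein mass ratio (w:w), dimensionless.
#' @param mean_lipid_mass mean lipid molecular mass, Da.
#' @param protein_mass protein molecular mass, Da.
#' @return the lipid:protein molar ratio.
#' @examples
#' lipid_protein_molar_ratio(3, 745, 34766)  # 140
#' @export
lipid_protein_molar_ratio <- function(mass_ratio, mean_lipid_mass = 745,
                                      protein_mass = 34766) {
  stopifnot_scalar(mass_ratio, "mass_ratio", positive = TRUE)
  stopifnot_scalar(mean_lipid_mass, "mean_lipid_mass", positive = TRUE)
  stopifnot_scalar(protein_mass, "protein_mass", positive = TRUE)
  mass_ratio * protein_mass / mean_lipid_mass
}

#' Read a composition from a structured text file
#'
#' The file is whitespace-delimited with a header line
#' `species count per_leaflet mass_da` (per_leaflet optional).
#'
#' @param path file path.
#' @return a [membrane_composition()].
#' @export
read_composition <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  membrane_composition(df$species, df$count, df$mass_da,
                       per_leaflet = df$per_leaflet)
}

#' Composition report
#'
#' Full percentage table of a composition; the %W and %mol columns each
#' sum to 100 within rounding.
#'
#' @param composition a [membrane_composition()].
#' @return a `data.frame` with species rows plus a `Tot` row.
#' @export
composition_report <- function(composition) {
  pw <- vapply(composition$species, function(s)
    mass_fraction(composition, s), numeric(1))
  pm <- vapply(composition$species, function(s)
    molar_fraction(composition, s), numeric(1))
  rbind(data.frame(species = composition$species,
                   count = composition$count,
                   per_leaflet = composition$per_leaflet,
                   mass_da = composition$mass_da,
                   pct_w = round(pw, 1), pct_mol = round(pm, 1)),
        data.frame(species = "Tot", count = sum(composition$count),
                   per_leaflet = sum(composition$per_leaflet),
                   mass_da = sum(composition$mass_da),
                   pct_w = round(sum(pw), 1), pct_mol = round(sum(pm), 1)))
}
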