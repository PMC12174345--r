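#' Particle coordinate set
#'
#' A set of planar pore-center positions, the elementary input of all spatial
#' analyses. Positions are the geometric centers of pores identified in AFM
#' topographies (or synthetic equivalents), in nm, lower-left origin.
#'
#' Each particle carries a detection-confidence `tier` (1 = most stringent;
#' tiers are nested so the tier-1 set is a subset of tier-2, which is a
#' subset of tier-3) and a free-text `condition` label (e.g. the lipid
#' composition of the membrane).
#'
#' @param x,y numeric vectors of equal length, coordinates in nm.
#' @param tier integer vector (recycled) of confidence tiers.
#' @param condition character scalar or vector (recycled), condition label.
#' @param region optional [region()] the particles live in.
#' @return an object of class `"particle_set"`: a `data.frame` with columns
#'   `id`, `x_nm`, `y_nm`, `tier`, `condition`, plus a `region` attribute.
#' @seealso [read_particles()], [write_particles()], [generate_pattern()]
#' @examples
#' p <- particle_set(c(0, 5.5), c(0, 0))
#' n_particles(p)
#' @export
particle_set <- function(x, y, tier = 1L, condition = "unspecified",
                         region = NULL) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y))))
    stop("particle coordinates must be finite", call. = FALSE)
  n <- length(x)
  df <- data.frame(
    id = seq_len(n),
    x_nm = as.numeric(x),
    y_nm = as.numeric(y),
    tier = rep_len(as.integer(tier), n),
    condition = rep_len(as.character(condition), n),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("particle_set", "data.frame"), region = region)
}

#' @rdname particle_set
#' @param p a `particle_set`.
#' @export
n_particles <- function(p) nrow(p)

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles", nrow(x)))
  if (nrow(x))
    cat(sprintf(", condition(s): %s", paste(unique(x$condition), collapse = ", ")))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

# n x 2 coordinate matrix of a particle set
coords <- function(p) cbind(p$x_nm, p$y_nm)

#' Restrict a particle set to a confidence tier
#'
#' Returns the particles whose tier is at most `tier` (stringency tiers are
#' nested: tier 1 passed the most stringent detection threshold).
#'
#' @param p a [particle_set()].
#' @param tier maximum tier to keep.
#' @return a `particle_set`.
#' @export
filter_tier <- function(p, tier) {
  keep <- p$tier <= tier
  particle_set(p$x_nm[keep], p$y_nm[keep], p$tier[keep], p$condition[keep],
               region = attr(p, "region"))
}

#' Read / write particle tables
#'
#' Particle tables are plain CSV with header `id,x_nm,y_nm,tier,condition`.
#' Writing is atomic (temporary file + rename).
#'
#' @param path file path.
#' @return `read_particles()` returns a [particle_set()];
#'   `write_particles()` returns `path` invisibly.
#' @export
read_particles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_nm", "y_nm")
  if (!all(need %in% names(df)))
    stop("particle CSV must contain columns x_nm and y_nm", call. = FALSE)
  particle_set(df$x_nm, df$y_nm,
               tier = df$tier %||% 1L,
               condition = df$condition %||% "unspecified")
}

#' @rdname read_particles
#' @param p a [particle_set()].
#' @export
write_particles <- function(p, path) {
  atomic_write(path, function(tmp)
    utils::write.csv(as.data.frame(p), tmp, row.names = FALSE, quote = FALSE))
}
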