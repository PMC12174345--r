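#' @keywords internal
"_PACKAGE"

# Angstrom <-> nanometre conversion used throughout: coordinates are stored
# in nm, distance-class boundaries are quoted in Angstrom.
A_PER_NM <- 10

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot_scalar(seed, "seed")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

#' Atomically write a file
#'
#' Writes via a temporary file in the destination directory followed by
#' `file.rename()`, so an interrupted run never leaves a truncated file and
#' reruns never corrupt prior outputs.
#'
#' @param path destination path.
#' @param writer function of one argument (the temporary path) that performs
#'   the actual write.
#' @return `path`, invisibly.
#' @export
atomic_write <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("atomic rename failed for ", path, call. = FALSE)
  invisible(path)
}

# Pairwise Euclidean distance matrix for an n x 2 coordinate matrix.
pair_dist <- function(xy) {
  as.matrix(stats::dist(xy))
}

#' Rectangular membrane region
#'
#' Planar analysis region in nm. Coordinates use a lower-left origin with y
#' pointing up; raster images derived from a region are row-major with row 1
#' at the top (see [render_topography()]).
#'
#' @param width,height extents in nm; both must be positive.
#' @return an object of class `"region"`.
#' @examples
#' region(200, 150)
#' @export
region <- function(width, height = width) {
  stopifnot_scalar(width, "width", positive = TRUE)
  stopifnot_scalar(height, "height", positive = TRUE)
  structure(list(width = width, height = height, origin = "lower-left"),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %.6g x %.6g nm (origin lower-left, y up)\n",
              x$width, x$height))
  invisible(x)
}
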