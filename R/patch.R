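#' Patch surface of a particle set
#'
#' The analysis surface S_patch of an assembly: the hull (concave or convex)
#' of all particle positions, dilated by `dilation_radius`. Its area defines
#' the global particle density `rho = N / S_patch` used to normalize the
#' radial distribution function, and its geometry supplies the per-bin
#' ring/patch intersection areas of the boundary correction.
#'
#' The convex mode uses exact geometry: the hull from [grDevices::chull()],
#' with the dilated area given in closed form by the Minkowski sum
#' `A + P * R + pi * R^2` (hull area A, perimeter P, radius R); degenerate
#' hulls (a single point, or collinear points) reduce to a disc or a
#' capsule. The concave mode is a raster alpha-hull: a morphological
#' closing of the rasterized positions with a disc of radius
#' `alpha = 2 * dilation_radius` (computed with Euclidean distance
#' transforms), then dilation by `dilation_radius`; its area is the pixel
#' count at `raster_res` nm/px. If the closed set is disconnected the patch
#' falls back to the convex hull.
#'
#' Both modes also carry a raster mask (at `raster_res` nm/px) and an
#' interior-distance map used by [compute_rdf()] to evaluate ring-patch
#' intersections.
#'
#' @param particles a [particle_set()] with at least one particle.
#' @param dilation_radius dilation radius R in nm (> 0).
#' @param mode `"concave"` (default) or `"convex"`.
#' @param raster_res raster resolution in nm/px (default 0.5).
#' @param alpha closing radius for the concave mode; default
#'   `2 * dilation_radius`.
#' @return an object of class `"patch_geometry"` with elements `area`
#'   (nm^2), `mode`, `dilation_radius`, `mask`, `raster_res`, `origin`
#'   (nm coordinates of the mask's lower-left corner), `hull`
#'   (convex-hull vertices), and `interior_dist` (distance-to-boundary map,
#'   nm).
#' @examples
#' p <- particle_set(c(0, 10, 20), c(0, 0, 0))
#' patch <- compute_patch_surface(p, dilation_radius = 5, mode = "convex")
#' patch$area  # capsule: pi * 25 + 4 * 10 * 5
#' @export
compute_patch_surface <- function(particles, dilation_radius,
                                  mode = c("concave", "convex"),
                                  raster_res = 0.5, alpha = NULL) {
  mode <- match.arg(mode)
  if (n_particles(particles) < 1L)
    stop("patch surface needs at least one particle", call. = FALSE)
  stopifnot_scalar(dilation_radius, "dilation_radius", positive = TRUE)
  stopifnot_scalar(raster_res, "raster_res", positive = TRUE)
  alpha <- alpha %||% (2 * dilation_radius)
  xy <- coords(particles)

  pad <- dilation_radius + (if (mode == "concave") alpha else 0) + 2 * raster_res
  x0 <- min(xy[, 1]) - pad
  y0 <- min(xy[, 2]) - pad
  nc <- ceiling((max(xy[, 1]) + pad - x0) / raster_res)
  nr <- ceiling((max(xy[, 2]) + pad - y0) / raster_res)
  # pixel centers
  xc <- x0 + (seq_len(nc) - 0.5) * raster_res
  yc <- y0 + (seq_len(nr) - 0.5) * raster_res

  hull <- convex_hull_geom(xy)

  if (mode == "convex") {
    dmat <- dist_to_hull(xc, yc, hull)        # nr x nc, nm
    mask <- dmat <= dilation_radius
    area <- hull$area + hull$perimeter * dilation_radius +
      pi * dilation_radius^2
  } else {
    mask <- concave_mask(xy, xc, yc, x0, y0, nr, nc, raster_res, alpha,
                         dilation_radius)
    if (is.null(mask)) {                      # disconnected: convex fallback
      return(compute_patch_surface(particles, dilation_radius, "convex",
                                   raster_res))
    }
    area <- sum(mask) * raster_res^2
  }

  interior <- EBImage::distmap(matrix(as.numeric(mask), nr, nc)) * raster_res
  structure(list(area = area, mode = mode, dilation_radius = dilation_radius,
                 alpha = if (mode == "concave") alpha else NA_real_,
                 mask = mask, raster_res = raster_res, origin = c(x0, y0),
                 hull = hull, interior_dist = interior,
                 n = n_particles(particles)),
            class = "patch_geometry")
}

#' @export
print.patch_geometry <- function(x, ...) {
  cat(sprintf("<patch_geometry> %s hull of %d particles, dilated %.3g nm: area %.4g nm^2\n",
              x$mode, x$n, x$dilation_radius, x$area))
  invisible(x)
}

# Convex hull with degenerate handling. Returns vertices (counter-clockwise),
# shoelace area and perimeter; for collinear input the "hull" is the extreme
# segment (area 0, perimeter twice its length), for a single point both are 0.
convex_hull_geom <- function(xy) {
  xy <- unique(round(xy, 12))
  if (!is.matrix(xy)) xy <- matrix(xy, ncol = 2)
  n <- nrow(xy)
  if (n == 1L)
    return(list(vertices = xy, area = 0, perimeter = 0, degenerate = "point"))
  idx <- grDevices::chull(xy[, 1], xy[, 2])
  v <- xy[idx, , drop = FALSE]
  if (nrow(v) <= 2L || hull_collinear(v)) {
    # extreme segment along the principal direction
    d <- xy[which.max(rowSums((xy - xy[rep(1, n), ])^2)), ] - xy[1, ]
    t <- (xy %*% d)
    seg <- xy[c(which.min(t), which.max(t)), , drop = FALSE]
    len <- sqrt(sum((seg[2, ] - seg[1, ])^2))
    return(list(vertices = seg, area = 0, perimeter = 2 * len,
                degenerate = "segment"))
  }
  a <- shoelace(v)
  if (a < 0) { v <- v[nrow(v):1, , drop = FALSE]; a <- -a }
  per <- sum(sqrt(rowSums((v - v[c(2:nrow(v), 1), ])^2)))
  list(vertices = v, area = a, perimeter = per, degenerate = "none")
}

hull_collinear <- function(v, tol = 1e-9) {
  if (nrow(v) < 3L) return(TRUE)
  a <- v[2, ] - v[1, ]
  all(abs((v[, 1] - v[1, 1]) * a[2] - (v[, 2] - v[1, 2]) * a[1]) < tol *
        (1 + max(abs(v))))
}

shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Distance from every pixel center (grid yc x xc) to a convex hull
# (0 inside). Vectorized over pixels, looped over the few hull edges.
dist_to_hull <- function(xc, yc, hull) {
  nr <- length(yc); nc <- length(xc)
  px <- rep(xc, each = nr)
  py <- rep(yc, times = nc)
  v <- hull$vertices
  if (hull$degenerate == "point") {
    d <- sqrt((px - v[1, 1])^2 + (py - v[1, 2])^2)
    return(matrix(d, nr, nc))
  }
  nv <- nrow(v)
  dmin <- rep(Inf, length(px))
  inside <- rep(TRUE, length(px))
  closed <- hull$degenerate == "none"
  for (i in seq_len(if (closed) nv else nv - 1L)) {
    a <- v[i, ]; b <- v[if (i == nv) 1L else i + 1L, ]
    dseg <- point_segment_dist(px, py, a, b)
    dmin <- pmin(dmin, dseg)
    if (closed) {
      # counter-clockwise polygon: inside iff left of every edge
      cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
      inside <- inside & cr >= 0
    }
  }
  if (!closed) inside <- FALSE
  d <- ifelse(inside, 0, dmin)
  matrix(d, nr, nc)
}

point_segment_dist <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  t <- if (len2 < 1e-24) rep(0, length(px)) else
    pmin(pmax(((px - a[1]) * abx + (py - a[2]) * aby) / len2, 0), 1)
  sqrt((px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2)
}

# Raster morphological closing (radius alpha) of the particle positions,
# dilated by R. Returns the mask, or NULL if the closed set is disconnected.
concave_mask <- function(xy, xc, yc, x0, y0, nr, nc, res, alpha, R) {
  seeds <- matrix(0, nr, nc)
  rows <- pmin(pmax(round((xy[, 2] - y0) / res + 0.5), 1), nr)
  cols <- pmin(pmax(round((xy[, 1] - x0) / res + 0.5), 1), nc)
  seeds[cbind(rows, cols)] <- 1
  a_px <- alpha / res
  r_px <- R / res

  d_to_seed <- EBImage::distmap(1 - seeds)
  dil <- d_to_seed <= a_px
  d_inside <- EBImage::distmap(matrix(as.numeric(dil), nr, nc))
  closed <- (d_inside >= a_px - 0.75) | (seeds > 0)

  d_to_closed <- EBImage::distmap(1 - closed)
  mask <- d_to_closed <= r_px

  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nr, nc))
  if (max(lab) > 1L) return(NULL)
  mask
}

#' Test whether points lie inside a patch
#'
#' @param patch a [compute_patch_surface()] result.
#' @param x,y coordinates in nm.
#' @return logical vector.
#' @export
patch_contains <- function(patch, x, y) {
  if (patch$mode == "convex")
    point_in_patch_convex(patch, x, y)
  else
    point_in_patch_mask(patch, x, y)
}

point_in_patch_convex <- function(patch, x, y) {
  hull <- patch$hull
  v <- hull$vertices
  if (hull$degenerate == "point") {
    d <- sqrt((x - v[1, 1])^2 + (y - v[1, 2])^2)
    return(d <= patch$dilation_radius)
  }
  nv <- nrow(v)
  closed <- hull$degenerate == "none"
  dmin <- rep(Inf, length(x))
  inside <- rep(closed, length(x))
  for (i in seq_len(if (closed) nv else nv - 1L)) {
    a <- v[i, ]; b <- v[if (i == nv) 1L else i + 1L, ]
    dmin <- pmin(dmin, point_segment_dist(x, y, a, b))
    if (closed) {
      cr <- (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
      inside <- inside & cr >= 0
    }
  }
  inside | dmin <= patch$dilation_radius
}

point_in_patch_mask <- function(patch, x, y) {
  res <- patch$raster_res
  rows <- round((y - patch$origin[2]) / res + 0.5)
  cols <- round((x - patch$origin[1]) / res + 0.5)
  ok <- rows >= 1 & rows <= nrow(patch$mask) & cols >= 1 & cols <= ncol(patch$mask)
  out <- rep(FALSE, length(x))
  out[ok] <- patch$mask[cbind(rows[ok], cols[ok])]
  out
}

# distance from a particle to the patch boundary (conservative, nm)
boundary_distance <- function(patch, x, y) {
  res <- patch$raster_res
  rows <- pmin(pmax(round((y - patch$origin[2]) / res + 0.5), 1),
               nrow(patch$mask))
  cols <- pmin(pmax(round((x - patch$origin[1]) / res + 0.5), 1),
               ncol(patch$mask))
  pmax(patch$interior_dist[cbind(rows, cols)] - res, 0)
}
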