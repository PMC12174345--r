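#' Topography image container
#'
#' An AFM-like height image: a numeric matrix of heights in nm with a pixel
#' size in nm/px. The matrix is row-major with row 1 at the top of the field
#' of view; particle coordinates use a lower-left origin with y up. The
#' conversion between the two conventions is handled by the accessors below
#' and round-trip tested.
#'
#' @param heights numeric matrix of heights (nm), finite values.
#' @param pixel_size pixel size in nm/px (> 0).
#' @param condition,temperature optional metadata.
#' @return an object of class `"topography_image"`.
#' @export
topography_image <- function(heights, pixel_size, condition = "unspecified",
                             temperature = NA_real_) {
  if (!is.matrix(heights) || !is.numeric(heights))
    stop("`heights` must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(heights)))
    stop("heights must be finite", call. = FALSE)
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  structure(list(heights = heights, pixel_size = pixel_size,
                 condition = condition, temperature = temperature),
            class = "topography_image")
}

#' @export
print.topography_image <- function(x, ...) {
  cat(sprintf("<topography_image> %d x %d px @ %.3g nm/px (%.4g x %.4g nm), height range [%.3g, %.3g] nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              ncol(x$heights) * x$pixel_size, nrow(x$heights) * x$pixel_size,
              min(x$heights), max(x$heights)))
  invisible(x)
}

# (row, col) pixel centers -> (x, y) nm, lower-left origin, y up
px_to_xy <- function(row, col, nrow_img, pixel_size) {
  cbind(x = (col - 0.5) * pixel_size,
        y = (nrow_img - row + 0.5) * pixel_size)
}

# (x, y) nm -> fractional (row, col); row 1 at top
xy_to_px <- function(x, y, nrow_img, pixel_size) {
  cbind(row = nrow_img - y / pixel_size + 0.5,
        col = x / pixel_size + 0.5)
}

#' Render a synthetic AFM topography of membrane pores
#'
#' Renders a flat membrane (height 0) with Gaussian pixel noise and one
#' radially symmetric feature per particle. Pores are inverted Gaussian
#' depressions whose full width at half depth equals `pore_diameter`
#' (default 4.5 nm, the AFM signature of a beta-barrel pore). A random
#' subset of particles (`bead_fraction`) is instead rendered as the
#' protrusion of a gold nanobead: a sphere of `bead_diameter` whose bottom
#' sits `bead_offset` above the membrane, converting the depression into a
#' peak (the orientation-reporting signature).
#'
#' @param particles a [particle_set()] with a `region` attribute (or pass
#'   `region`).
#' @param pore_diameter pore full width at half depth, nm.
#' @param pore_depth depression depth, nm.
#' @param pixel_size nm/px; must be at most `pore_diameter / 4` so pores are
#'   resolvable.
#' @param noise_sd Gaussian height-noise standard deviation, nm.
#' @param bead_fraction fraction of particles rendered as nanobead
#'   protrusions, in `[0, 1]`.
#' @param bead_diameter,bead_offset nanobead sphere diameter and gap above
#'   the membrane surface, nm (defaults 5 and 1.5).
#' @param region optional [region()] overriding the particle set's.
#' @param seed integer seed for the noise and the bead subset.
#' @return a [topography_image()].
#' @examples
#' p <- particle_set(10, 10, region = region(20, 20))
#' img <- render_topography(p, noise_sd = 0)
#' range(img$heights)
#' @export
render_topography <- function(particles, pore_diameter = 4.5, pore_depth = 1.2,
                              pixel_size = 0.5, noise_sd = 0.05,
                              bead_fraction = 0, bead_diameter = 5,
                              bead_offset = 1.5, region = NULL, seed = NULL) {
  reg <- region %||% attr(particles, "region")
  if (is.null(reg))
    stop("particles carry no region; supply `region`", call. = FALSE)
  if (pixel_size > pore_diameter / 4)
    stop(sprintf("pixel_size %.3g nm too coarse to resolve %.3g nm pores (need <= diameter/4)",
                 pixel_size, pore_diameter), call. = FALSE)
  if (bead_fraction < 0 || bead_fraction > 1)
    stop("`bead_fraction` must be in [0, 1]", call. = FALSE)
  set_seed_if(seed)

  nr <- max(1L, round(reg$height / pixel_size))
  nc <- max(1L, round(reg$width / pixel_size))
  img <- matrix(0, nr, nc)

  n <- n_particles(particles)
  is_bead <- rep(FALSE, n)
  if (n > 0 && bead_fraction > 0)
    is_bead[sample.int(n, size = round(bead_fraction * n))] <- TRUE

  for (i in seq_len(n)) {
    if (is_bead[i]) {
      img <- add_bead(img, particles$x_nm[i], particles$y_nm[i], pixel_size,
                      bead_diameter / 2, bead_offset)
    } else {
      img <- add_pore(img, particles$x_nm[i], particles$y_nm[i], pixel_size,
                      pore_diameter, pore_depth)
    }
  }
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
  topography_image(img, pixel_size,
                   condition = if (n) particles$condition[1] else "unspecified")
}

# window of pixel (row, col) indices within `radius_nm` of (x, y)
feature_window <- function(img, x, y, pixel_size, radius_nm) {
  nr <- nrow(img); nc <- ncol(img)
  rc <- xy_to_px(x, y, nr, pixel_size)
  rad_px <- ceiling(radius_nm / pixel_size) + 1L
  rows <- max(1L, floor(rc[1] - rad_px)):min(nr, ceiling(rc[1] + rad_px))
  cols <- max(1L, floor(rc[2] - rad_px)):min(nc, ceiling(rc[2] + rad_px))
  if (!length(rows) || !length(cols)) return(NULL)
  xy <- px_to_xy(rep(rows, times = length(cols)),
                 rep(cols, each = length(rows)), nr, pixel_size)
  list(rows = rows, cols = cols,
       r = sqrt((xy[, 1] - x)^2 + (xy[, 2] - y)^2))
}

# inverted Gaussian depression, FWHM = diameter
add_pore <- function(img, x, y, pixel_size, diameter, depth) {
  w <- feature_window(img, x, y, pixel_size, 1.5 * diameter)
  if (is.null(w)) return(img)
  dh <- -depth * exp(-4 * log(2) * (w$r / diameter)^2)
  img[w$rows, w$cols] <- img[w$rows, w$cols] + matrix(dh, length(w$rows))
  img
}

# spherical cap of a nanobead resting `offset` above the surface
add_bead <- function(img, x, y, pixel_size, radius, offset) {
  w <- feature_window(img, x, y, pixel_size, radius)
  if (is.null(w)) return(img)
  h <- ifelse(w$r < radius,
              offset + radius + sqrt(pmax(radius^2 - w$r^2, 0)),
              -Inf)
  img[w$rows, w$cols] <- pmax(img[w$rows, w$cols], matrix(h, length(w$rows)))
  img
}

#' Read / write topography images
#'
#' Images are stored either as 32-bit TIFF or as a whitespace-delimited
#' plain-text matrix of heights in nm. TIFF samples are min-max scaled to
#' `[0, 1]` (the TIFF storage range) with the affine height scale written
#' to a `<path>.scale.txt` sidecar (in the spirit of world files); on read
#' the sidecar, when present, restores heights in nm. The text format
#' stores heights verbatim. The pixel size is not stored in either format
#' and must be supplied on read.
#'
#' @param image a [topography_image()].
#' @param path file path; format chosen by extension (`.tif`/`.tiff` vs
#'   anything else = text matrix).
#' @return `read_topography()` returns a [topography_image()].
#' @export
write_topography <- function(image, path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    h <- image$heights
    lo <- min(h); hi <- max(h)
    scaled <- if (hi > lo) (h - lo) / (hi - lo) else h * 0
    atomic_write(path, function(tmp)
      tiff::writeTIFF(scaled, tmp, bits.per.sample = 32L, reduce = FALSE))
    atomic_write(paste0(path, ".scale.txt"), function(tmp)
      writeLines(sprintf("height_nm lo=%.12g hi=%.12g", lo, hi), tmp))
    invisible(path)
  } else {
    atomic_write(path, function(tmp)
      utils::write.table(image$heights, tmp, row.names = FALSE,
                         col.names = FALSE))
  }
}

#' @rdname write_topography
#' @param pixel_size nm/px of the stored image.
#' @export
read_topography <- function(path, pixel_size) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    m <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    sidecar <- paste0(path, ".scale.txt")
    if (file.exists(sidecar)) {
      desc <- readLines(sidecar, n = 1L)
      lo <- as.numeric(sub(".*lo=([-0-9.eE+]+).*", "\\1", desc))
      hi <- as.numeric(sub(".*hi=([-0-9.eE+]+).*", "\\1", desc))
      m <- m * (hi - lo) + lo
    }
    m <- matrix(as.numeric(m), nrow = dim(m)[1])
  } else {
    m <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(m) <- NULL
  }
  topography_image(m, pixel_size)
}

#' Extract a height profile along a segment
#'
#' Samples bilinearly interpolated heights along the segment from `a` to `b`
#' (nm coordinates, lower-left origin) at roughly half-pixel steps.
#'
#' @param image a [topography_image()].
#' @param a,b numeric length-2 endpoints `c(x, y)` in nm; must lie inside
#'   the image.
#' @param n_samples number of samples; default spans the segment at
#'   `pixel_size / 2` steps.
#' @return a `data.frame` with columns `s_nm` (arc length) and `height_nm`.
#' @seealso [profile_fwhd()]
#' @export
extract_profile <- function(image, a, b, n_samples = NULL) {
  h <- image$heights; px <- image$pixel_size
  wmax <- ncol(h) * px; hmax <- nrow(h) * px
  for (pt in list(a, b))
    if (length(pt) != 2 || pt[1] < 0 || pt[1] > wmax || pt[2] < 0 || pt[2] > hmax)
      stop("profile endpoints must lie inside the image", call. = FALSE)
  len <- sqrt(sum((b - a)^2))
  ns <- n_samples %||% max(2L, ceiling(len / (px / 2)) + 1L)
  t <- seq(0, 1, length.out = ns)
  xs <- a[1] + t * (b[1] - a[1])
  ys <- a[2] + t * (b[2] - a[2])
  data.frame(s_nm = t * len, height_nm = bilinear(h, xs, ys, px))
}

# bilinear interpolation at nm coordinates (clamped to pixel-center hull)
bilinear <- function(h, xs, ys, px) {
  nr <- nrow(h); nc <- ncol(h)
  rc <- xy_to_px(xs, ys, nr, px)
  r <- pmin(pmax(rc[, 1], 1), nr)
  c_ <- pmin(pmax(rc[, 2], 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c_), nc - 1L)
  fr <- r - r0; fc <- c_ - c0
  h[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    h[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    h[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    h[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Full width at half depth of a profile's central depression
#'
#' Measures the width of the deepest depression in a height profile at half
#' of its depth relative to the baseline, by linear interpolation of the
#' half-level crossings on either side of the minimum. The baseline is the
#' mean height of the outer 15% of samples at each end of the profile (the
#' flat membrane on both sides of the pore), so the profile should extend
#' well past the depression. This is the standard way a pore diameter is
#' read off an AFM line profile.
#'
#' @param profile a profile as returned by [extract_profile()].
#' @return width in nm, or `NA` if there is no depression.
#' @export
profile_fwhd <- function(profile) {
  s <- profile$s_nm; z <- profile$height_nm
  ntail <- max(2L, ceiling(0.15 * length(z)))
  base <- mean(c(utils::head(z, ntail), utils::tail(z, ntail)))
  imin <- which.min(z)
  if (imin == 1L || imin == length(z)) return(NA_real_)
  depth <- base - z[imin]
  if (depth <= 0) return(NA_real_)
  half <- base - depth / 2
  left <- NA_real_; right <- NA_real_
  for (i in rev(seq_len(imin - 1L)))
    if (z[i] >= half) {
      left <- s[i] + (s[i + 1] - s[i]) * (z[i] - half) / (z[i] - z[i + 1])
      break
    }
  for (i in seq(imin + 1L, length(z)))
    if (z[i] >= half) {
      right <- s[i - 1] + (s[i] - s[i - 1]) * (half - z[i - 1]) / (z[i] - z[i - 1])
      break
    }
  right - left
}
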