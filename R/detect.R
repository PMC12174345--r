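#' Build a pore matching template
#'
#' Constructs the zero-mean template used for cross-correlation pore
#' localization: an inverted radially symmetric Gaussian whose full width at
#' half depth equals `pore_diameter`, sampled on an odd-sized square window
#' and shifted to zero mean.
#'
#' @param pore_diameter pore FWHM in nm (default 4.5).
#' @param pixel_size nm/px; must be at most `pore_diameter / 4`.
#' @param window_factor half-width of the template window in units of
#'   `pore_diameter`.
#' @return a [topography_image()] holding the template.
#' @export
build_pore_template <- function(pore_diameter = 4.5, pixel_size = 0.5,
                                window_factor = 1) {
  if (pixel_size > pore_diameter / 4)
    stop(sprintf("pixel_size %.3g nm too coarse to resolve %.3g nm pores (need <= diameter/4)",
                 pixel_size, pore_diameter), call. = FALSE)
  half <- ceiling(window_factor * pore_diameter / pixel_size)
  ax <- (-half:half) * pixel_size
  r2 <- outer(ax, ax, function(a, b) a^2 + b^2)
  tpl <- -exp(-4 * log(2) * r2 / pore_diameter^2)
  tpl <- tpl - mean(tpl)
  topography_image(tpl, pixel_size, condition = "template")
}

# 2-D cross-correlation, "valid" region, via FFT.
# Returns matrix C with C[u, v] = sum_{i,j} I[u+i-1, v+j-1] * T[i, j].
xcorr2_valid <- function(img, tpl) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(tpl); kc <- ncol(tpl)
  pr <- nr; pc <- nc
  ip <- matrix(0, pr, pc); ip[1:nr, 1:nc] <- img
  tp <- matrix(0, pr, pc); tp[1:kr, 1:kc] <- tpl
  cc <- Re(stats::fft(stats::fft(ip) * Conj(stats::fft(tp)), inverse = TRUE)) /
    (pr * pc)
  cc[1:(nr - kr + 1), 1:(nc - kc + 1), drop = FALSE]
}

# Sliding-window sums over k x k windows via a summed-area table ("valid").
box_sums <- function(img, k) {
  sat <- apply(img, 2, cumsum)        # cumulate down columns
  sat <- t(apply(sat, 1, cumsum))     # then along rows
  pad <- matrix(0, nrow(sat) + 1, ncol(sat) + 1)
  pad[-1, -1] <- sat
  nr <- nrow(img) - k + 1; nc <- ncol(img) - k + 1
  i <- 1:nr; j <- 1:nc
  pad[i + k, j + k, drop = FALSE] - pad[i, j + k, drop = FALSE] -
    pad[i + k, j, drop = FALSE] + pad[i, j, drop = FALSE]
}

# Pearson-normalized cross-correlation map of a zero-mean template.
ncc_map <- function(img, tpl) {
  k <- nrow(tpl)
  num <- xcorr2_valid(img, tpl)
  s1 <- box_sums(img, k)
  s2 <- box_sums(img * img, k)
  var_local <- pmax(s2 - s1^2 / (k * k), 0)
  den <- sqrt(var_local * sum(tpl^2))
  out <- num / den
  out[den < 1e-12] <- 0
  out
}

#' Detect pores in a topography image by template matching
#'
#' Computes a Pearson-normalized cross-correlation map between the image and
#' a zero-mean pore template, keeps local maxima above the least stringent
#' threshold, applies greedy non-maximum suppression at `min_separation`
#' (higher correlation wins; exact ties broken by row then column), refines
#' each center to sub-pixel precision by a centroid over its 3x3 correlation
#' neighbourhood, and assigns each detection the most stringent confidence
#' tier whose threshold its correlation passes. Tier sets are therefore
#' nested: tier 1 (most stringent) is a subset of tier 2, which is a subset
#' of tier 3.
#'
#' @param image a [topography_image()].
#' @param template a template from [build_pore_template()]; must not be
#'   larger than the image.
#' @param thresholds three correlation cutoffs, strictly decreasing
#'   (most to least stringent); defaults `c(0.8, 0.6, 0.45)`.
#' @param min_separation minimum center-to-center distance between
#'   detections, nm.
#' @return a [particle_set()] with per-particle `tier`; positions in nm,
#'   lower-left origin. An empty image yields an empty set.
#' @export
detect_pores <- function(image, template, thresholds = c(0.8, 0.6, 0.45),
                         min_separation = 4.0) {
  if (length(thresholds) != 3L || any(diff(thresholds) >= 0))
    stop("`thresholds` must be three strictly decreasing cutoffs", call. = FALSE)
  stopifnot_scalar(min_separation, "min_separation", positive = TRUE)
  img <- image$heights; tpl <- template$heights
  if (nrow(tpl) > nrow(img) || ncol(tpl) > ncol(img))
    stop("template larger than image", call. = FALSE)
  px <- image$pixel_size
  k <- nrow(tpl)

  cc <- ncc_map(img, tpl)
  nr <- nrow(cc); nc <- ncol(cc)

  # local maxima (8-neighbourhood, >= so plateaus survive until NMS)
  if (nr < 3L || nc < 3L) return(empty_detection(image))
  inner <- cc[2:(nr - 1), 2:(nc - 1)]
  is_max <- inner >= cc[1:(nr - 2), 2:(nc - 1)] &
    inner >= cc[3:nr, 2:(nc - 1)] &
    inner >= cc[2:(nr - 1), 1:(nc - 2)] &
    inner >= cc[2:(nr - 1), 3:nc] &
    inner >= cc[1:(nr - 2), 1:(nc - 2)] &
    inner >= cc[1:(nr - 2), 3:nc] &
    inner >= cc[3:nr, 1:(nc - 2)] &
    inner >= cc[3:nr, 3:nc] &
    inner >= thresholds[3]
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty_detection(image))
  rows <- idx[, 1] + 1L
  cols <- idx[, 2] + 1L
  score <- cc[cbind(rows, cols)]

  # deterministic order: score desc, then row, then col
  ord <- order(-score, rows, cols)
  rows <- rows[ord]; cols <- cols[ord]; score <- score[ord]

  # greedy non-maximum suppression at min_separation (in correlation-map px)
  sep_px <- min_separation / px
  keep <- logical(length(rows))
  kr_ <- numeric(0); kc_ <- numeric(0)
  for (i in seq_along(rows)) {
    if (!length(kr_) ||
        min((kr_ - rows[i])^2 + (kc_ - cols[i])^2) >= sep_px^2) {
      keep[i] <- TRUE
      kr_ <- c(kr_, rows[i]); kc_ <- c(kc_, cols[i])
    }
  }
  rows <- rows[keep]; cols <- cols[keep]; score <- score[keep]

  # sub-pixel centroid over the 3x3 neighbourhood of positive excess score
  sub <- t(vapply(seq_along(rows), function(i) {
    nb <- cc[(rows[i] - 1):(rows[i] + 1), (cols[i] - 1):(cols[i] + 1)]
    w <- pmax(nb - min(nb), 0)
    if (sum(w) < 1e-12) return(c(rows[i], cols[i]))
    dr <- sum(w * matrix(c(-1, 0, 1), 3, 3)) / sum(w)
    dc <- sum(w * matrix(c(-1, 0, 1), 3, 3, byrow = TRUE)) / sum(w)
    c(rows[i] + dr, cols[i] + dc)
  }, numeric(2)))

  # correlation-map offset -> image pixel of the window center
  center_off <- (k - 1) / 2
  img_row <- sub[, 1] + center_off
  img_col <- sub[, 2] + center_off
  xy <- px_to_xy(img_row, img_col, nrow(img), px)

  tier <- ifelse(score >= thresholds[1], 1L,
                 ifelse(score >= thresholds[2], 2L, 3L))
  particle_set(xy[, 1], xy[, 2], tier = tier, condition = image$condition,
               region = region(ncol(img) * px, nrow(img) * px))
}

empty_detection <- function(image) {
  particle_set(numeric(0), numeric(0), condition = image$condition,
               region = region(ncol(image$heights) * image$pixel_size,
                               nrow(image$heights) * image$pixel_size))
}

#' Match detections to ground-truth positions
#'
#' Greedy nearest-pair matching between detected and true positions within a
#' tolerance, used to benchmark detection (recall, precision, localization
#' error) against a generator's ground truth.
#'
#' @param detected,truth [particle_set()]s.
#' @param tolerance maximum match distance, nm.
#' @return a list with `n_matched`, `recall`, `precision`,
#'   `mean_error_nm`, and the matched index pairs.
#' @export
match_detections <- function(detected, truth, tolerance) {
  nd <- n_particles(detected); nt <- n_particles(truth)
  if (nd == 0L || nt == 0L)
    return(list(n_matched = 0L, recall = 0, precision = if (nd) 0 else NA_real_,
                mean_error_nm = NA_real_, pairs = cbind(integer(0), integer(0))))
  d <- sqrt(outer(detected$x_nm, truth$x_nm, "-")^2 +
            outer(detected$y_nm, truth$y_nm, "-")^2)
  pairs <- NULL; errs <- numeric(0)
  while (TRUE) {
    m <- which.min(d)
    if (!length(m) || d[m] > tolerance) break
    ij <- arrayInd(m, dim(d))
    pairs <- rbind(pairs, ij)
    errs <- c(errs, d[m])
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
  }
  nm <- if (is.null(pairs)) 0L else nrow(pairs)
  list(n_matched = nm, recall = nm / nt, precision = nm / nd,
       mean_error_nm = if (nm) mean(errs) else NA_real_,
       pairs = pairs %||% cbind(integer(0), integer(0)))
}
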