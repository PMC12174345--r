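#' Density-based clustering of pore centers
#'
#' Partitions particles into clusters and isolated monomers with DBSCAN
#' semantics on the pairwise-distance matrix: neighbourhood radius
#' `epsilon` (default 5.3 nm) and minimum sample size `min_neighbors`
#' (default 2, counting the point itself), so that two particles within
#' `epsilon` — a dimer — already form a cluster. With `min_neighbors = 2`
#' every point with a neighbour is a core point and the clusters are
#' exactly the connected components of the graph joining pairs at distance
#' <= epsilon; singletons are monomers. Direct protein contact is
#' alternatively quoted as 5.6 nm; pass `epsilon = 5.6` for that
#' convention.
#'
#' Cluster labels are deterministic: clusters are numbered by the
#' lexicographically smallest (x, y) coordinate of their members.
#'
#' @param particles a [particle_set()].
#' @param epsilon neighbourhood radius in nm (> 0).
#' @param min_neighbors DBSCAN minimum sample count including the point
#'   itself (>= 2).
#' @return an object of class `"cluster_report"`: a list with `labels`
#'   (0 = monomer/noise, otherwise cluster id), `n_total`, `f_mono`,
#'   `n_clusters`, `f_clust`, `sizes`, `mean_size`, `sd_size`, `sem_size`,
#'   `epsilon`, `min_neighbors`, `condition`.
#' @examples
#' p <- particle_set(c(0, 5, 30), c(0, 0, 0))
#' cluster_particles(p)$sizes
#' @export
cluster_particles <- function(particles, epsilon = 5.3, min_neighbors = 2L) {
  stopifnot_scalar(epsilon, "epsilon", positive = TRUE)
  if (min_neighbors < 2L) stop("`min_neighbors` must be >= 2", call. = FALSE)
  n <- n_particles(particles)
  condition <- if (n) particles$condition[1] else "unspecified"
  if (n == 0L)
    return(new_cluster_report(integer(0), epsilon, min_neighbors, condition))

  labels <- dbscan_labels(coords(particles), epsilon, min_neighbors)
  # renumber clusters by the lexicographically smallest member coordinate
  ids <- setdiff(unique(labels), 0L)
  if (length(ids)) {
    key <- vapply(ids, function(k) {
      m <- which(labels == k)
      i <- m[order(particles$x_nm[m], particles$y_nm[m])][1]
      i
    }, integer(1))
    ord <- ids[order(particles$x_nm[key], particles$y_nm[key])]
    labels <- match(labels, ord, nomatch = 0L)
    labels[is.na(labels)] <- 0L
  }
  new_cluster_report(labels, epsilon, min_neighbors, condition)
}

# Plain DBSCAN on coordinates; min_pts counts the point itself.
dbscan_labels <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  d <- pair_dist(xy)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))  # includes self
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (core[j]) {
        for (k in nb[[j]]) {
          if (labels[k] == 0L) {
            labels[k] <- cl
            if (core[k]) queue <- c(queue, k)
          }
        }
      }
    }
  }
  labels
}

new_cluster_report <- function(labels, epsilon, min_neighbors, condition) {
  n <- length(labels)
  sizes <- if (any(labels > 0L)) as.integer(table(labels[labels > 0L])) else integer(0)
  n_mono <- sum(labels == 0L)
  f_mono <- if (n) n_mono / n else NA_real_
  structure(list(
    labels = labels,
    n_total = n,
    f_mono = f_mono,
    n_clusters = length(sizes),
    f_clust = if (n) 1 - f_mono else NA_real_,
    sizes = sizes,
    mean_size = if (length(sizes)) mean(sizes) else NA_real_,
    sd_size = if (length(sizes) > 1L) stats::sd(sizes) else if (length(sizes)) 0 else NA_real_,
    sem_size = if (length(sizes) > 1L) stats::sd(sizes) / sqrt(length(sizes))
               else if (length(sizes)) 0 else NA_real_,
    epsilon = epsilon,
    min_neighbors = as.integer(min_neighbors),
    condition = condition
  ), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %s: %d particles, f_mono = %.2f, %d clusters (f_clust = %.2f), <size> = %s\n",
              x$condition, x$n_total, x$f_mono, x$n_clusters, x$f_clust,
              if (is.na(x$mean_size)) "NA" else
                sprintf("%.2f +/- %.2f (SEM)", x$mean_size, x$sem_size)))
  invisible(x)
}

#' Tabulate cluster reports across conditions
#'
#' Collects one row per condition with the standard column set of a
#' monomer/cluster partition table: number of particles, monomer fraction,
#' cluster count, clustered fraction, and mean cluster size with its
#' dispersion. The displayed `+/-` value is the standard error of the mean
#' (SEM) over clusters; the SD is also reported.
#'
#' @param reports a list of [cluster_particles()] results (at least one).
#' @return a `data.frame` with columns `condition`, `n_vdac`, `f_mono`,
#'   `n_clusters`, `f_clust`, `mean_size`, `sem_size`, `sd_size`.
#' @export
summarize_conditions <- function(reports) {
  if (inherits(reports, "cluster_report")) reports <- list(reports)
  if (!length(reports)) stop("need at least one report", call. = FALSE)
  do.call(rbind, lapply(reports, function(r)
    data.frame(condition = r$condition,
               n_vdac = r$n_total,
               f_mono = r$f_mono,
               n_clusters = r$n_clusters,
               f_clust = r$f_clust,
               mean_size = r$mean_size,
               sem_size = r$sem_size,
               sd_size = r$sd_size,
               stringsAsFactors = FALSE)))
}
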