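#' Pipeline configuration
#'
#' Assembles the full configuration of an end-to-end run: stage toggles and
#' per-stage parameters. The configuration round-trips losslessly through
#' YAML ([read_pipeline_config()] / [write_pipeline_config()]) and the
#' resolved configuration is logged with every run.
#'
#' @param particles path to a particle CSV, or `NULL` to synthesize a
#'   pattern from the `synth` parameters.
#' @param stages character vector of stages to run, from
#'   `c("synth", "render", "detect", "rdf", "contexts", "cluster",
#'   "assembly", "occupancy")`.
#' @param synth,render,detect,rdf,contexts,cluster,assembly,occupancy named
#'   lists of stage parameters (see the stage functions for meanings);
#'   omitted entries use the package defaults.
#' @param seed integer seed for all stochastic stages.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(particles = NULL,
                            stages = c("synth", "rdf", "contexts", "cluster"),
                            synth = list(), render = list(), detect = list(),
                            rdf = list(), contexts = list(), cluster = list(),
                            assembly = list(), occupancy = list(),
                            seed = 1L) {
  known <- c("synth", "render", "detect", "rdf", "contexts", "cluster",
             "assembly", "occupancy")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(particles = particles, stages = stages, synth = synth,
                 render = render, detect = detect, rdf = rdf,
                 contexts = contexts, cluster = cluster, assembly = assembly,
                 occupancy = occupancy, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  atomic_write(path, function(tmp)
    yaml::write_yaml(unclass(config), tmp))
}

#' Run the analysis pipeline
#'
#' Chains synthesis (or particle input), topography rendering, pore
#' detection, radial distribution, distance contexts, clustering, assembly
#' building and occupancy mapping, writing each stage's outputs into
#' `out_dir` (`particles.csv`, `rdf.csv`, `contexts.json`, `clusters.json`,
#' `model.pdb`, `occupancy_<leaflet>_<species>.txt`, `summary.json`,
#' `config.yaml`). Disabled stages are skipped and produce no files. All
#' writes are atomic.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the summary list, invisibly; the same content is written to
#'   `summary.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  on <- function(s) s %in% config$stages
  summary <- list(seed = config$seed, stages = config$stages)

  # --- particles: synthesized or read ---------------------------------
  if (!is.null(config$particles)) {
    if (!file.exists(config$particles))
      stop("stage input: particle file not found: ", config$particles,
           call. = FALSE)
    particles <- read_particles(config$particles)
  } else if (on("synth")) {
    sp <- config$synth
    particles <- generate_pattern(
      kind = sp$kind %||% "glassy",
      n = sp$n %||% 300,
      region = region(sp$width %||% 200, sp$height %||% 200),
      spacing = sp$spacing,
      jitter = sp$jitter %||% 0.3,
      seed = config$seed)
  } else {
    stop("stage synth disabled and no particle file given", call. = FALSE)
  }
  write_particles(particles, file.path(out_dir, "particles.csv"))
  summary$n_particles <- n_particles(particles)

  # --- optional render + detect round trip ----------------------------
  if (on("render")) {
    rp <- config$render
    img <- render_topography(particles,
                             pixel_size = rp$pixel_size %||% 0.5,
                             noise_sd = rp$noise_sd %||% 0.05,
                             bead_fraction = rp$bead_fraction %||% 0,
                             seed = config$seed + 1L)
    write_topography(img, file.path(out_dir, "topography.txt"))
    if (on("detect")) {
      dp <- config$detect
      tpl <- build_pore_template(dp$pore_diameter %||% 4.5,
                                 img$pixel_size)
      det <- detect_pores(img, tpl,
                          thresholds = dp$thresholds %||% c(0.8, 0.6, 0.45),
                          min_separation = dp$min_separation %||% 4.0)
      write_particles(det, file.path(out_dir, "detected.csv"))
      summary$n_detected <- n_particles(det)
      summary$n_detected_tier1 <- sum(det$tier == 1L)
    }
  }

  # --- patch + rdf ----------------------------------------------------
  patch <- NULL
  if (on("rdf") || on("contexts")) {
    pp <- config$rdf
    patch <- compute_patch_surface(particles,
                                   dilation_radius = pp$dilate %||% 5,
                                   mode = pp$hull %||% "concave")
    summary$patch_area_nm2 <- patch$area
  }
  if (on("rdf")) {
    pp <- config$rdf
    r <- compute_rdf(particles, patch, dr = pp$dr %||% 0.2,
                     r_max = pp$r_max %||% 20)
    atomic_write(file.path(out_dir, "rdf.csv"), function(tmp)
      utils::write.csv(data.frame(r_nm = r$r, g = r$g,
                                  effective_area_nm2 = colMeans(r$area_eff)),
                       tmp, row.names = FALSE))
    pk <- rdf_peaks(r)
    summary$rdf_first_peak_nm <- if (nrow(pk)) pk$r[1] else NA_real_
  }

  # --- distance contexts ---------------------------------------------
  if (on("contexts")) {
    cp <- config$contexts
    prof <- shell_occurrences(particles)
    ens <- patch_heterogeneity(particles,
                               patch_radius = cp$patch_radius %||% 15,
                               integral_max = cp$integral_max %||% 10,
                               n_repeats = cp$n_repeats %||% 100,
                               seed = config$seed + 2L)
    ctx <- list(whole = as.list(stats::setNames(prof$occurrence, prof$label)),
                patch_mean = as.list(ens$mean),
                patch_sd = as.list(ens$sd),
                n_patches = nrow(ens$profiles))
    atomic_write(file.path(out_dir, "contexts.json"), function(tmp)
      jsonlite::write_json(ctx, tmp, auto_unbox = TRUE, digits = NA))
    summary$contexts <- ctx$whole
  }

  # --- clustering -----------------------------------------------------
  if (on("cluster")) {
    kp <- config$cluster
    rep_ <- cluster_particles(particles, epsilon = kp$epsilon %||% 5.3,
                              min_neighbors = kp$min_neighbors %||% 2L)
    tab <- summarize_conditions(list(rep_))
    atomic_write(file.path(out_dir, "clusters.json"), function(tmp)
      jsonlite::write_json(as.list(tab[1, ]), tmp, auto_unbox = TRUE,
                           digits = NA))
    summary$f_mono <- rep_$f_mono
    summary$f_clust <- rep_$f_clust
    summary$n_clusters <- rep_$n_clusters
    summary$mean_cluster_size <- rep_$mean_size
  }

  # --- assembly + occupancy ------------------------------------------
  if (on("assembly")) {
    ap <- config$assembly
    tpl <- generate_template(seed = config$seed + 3L)
    model <- build_assembly(particles, list(tpl),
                            n_rotations = ap$n_rotations %||% 64L,
                            clash_cutoff = ap$clash_cutoff %||% 0.47,
                            seed = config$seed + 4L)
    write_assembly_pdb(model, file.path(out_dir, "model.pdb"))
    contacts <- classify_contacts(model)
    atomic_write(file.path(out_dir, "contacts.json"), function(tmp)
      jsonlite::write_json(contacts, tmp, dataframe = "rows", digits = NA))
    summary$n_contacts <- nrow(contacts)
    summary$n_pruned_lipids <- if (is.null(model$pruned)) 0L else
      nrow(model$pruned)
    if (on("occupancy")) {
      op <- config$occupancy
      beads <- assembly_beads(model)
      map <- compute_occupancy_map(beads,
                                   grid_resolution = op$resolution %||% 0.2)
      for (lf in names(map$leaflets))
        for (sp in names(map$leaflets[[lf]]$counts))
          atomic_write(file.path(out_dir,
                                 sprintf("occupancy_%s_%s.txt", lf, sp)),
                       function(tmp)
                         utils::write.table(map$leaflets[[lf]]$counts[[sp]],
                                            tmp, row.names = FALSE,
                                            col.names = FALSE))
      summary$occupancy_species <- map$species
    }
  }

  atomic_write(file.path(out_dir, "summary.json"), function(tmp)
    jsonlite::write_json(summary, tmp, auto_unbox = TRUE, digits = NA))
  invisible(summary)
}
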