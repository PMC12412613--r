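# End-to-end orchestration: configuration, the full analysis chain, and
# CSV/JSON result emission with provenance.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain. Either `input` (a
#' [write_movie()] stem) or `spec` (a [movie_spec()] to simulate) must be
#' given.
#'
#' @param input path stem of a movie written with [write_movie()], or
#'   `NULL` to simulate from `spec`.
#' @param spec a [movie_spec()] used when `input` is `NULL`.
#' @param pixel_size,frame_interval calibration overrides (taken from the
#'   input/spec when `NULL`).
#' @param nf oligomer symmetry assumed for particle refinement.
#' @param areas molecular cross-section areas, see [cross_section_areas()].
#' @param dtheta angular bin width, radians.
#' @param kmax highest boundary Fourier mode.
#' @param d_max neighbor-pair distance cutoff, nm (`NULL` = automatic).
#' @param temperature K.
#' @param chi DOPC / total lipid fraction label of the condition, in
#'   `[0, 1]` (metadata carried into the feature table).
#' @param time_average frames per block for particle picking.
#' @param outdir output directory (`NULL` = no files written).
#' @param seed RNG seed for every stochastic step.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, spec = NULL, pixel_size = NULL,
                            frame_interval = NULL, nf = 5L,
                            areas = cross_section_areas(),
                            dtheta = 2 * pi / 180, kmax = 12L, d_max = NULL,
                            temperature = 298, chi = NA_real_,
                            time_average = 5L, outdir = NULL, seed = 1L) {
  if (is.null(input) && is.null(spec))
    stop("configuration error: need `input` or `spec`")
  if (!is.na(chi) && (chi < 0 || chi > 1))
    stop("configuration error: chi must be in [0, 1]")
  if (!is.null(pixel_size) && pixel_size <= 0)
    stop("configuration error: pixel_size must be > 0")
  structure(list(input = input, spec = spec, pixel_size = pixel_size,
                 frame_interval = frame_interval, nf = as.integer(nf),
                 areas = areas, dtheta = dtheta, kmax = as.integer(kmax),
                 d_max = d_max, temperature = temperature, chi = chi,
                 time_average = as.integer(time_average), outdir = outdir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full cluster-analysis pipeline
#'
#' Loads (or simulates) a topography movie and chains preprocessing
#' (flatten, align, isodata masks, walking average), isolated-cluster
#' selection, contour dynamics (radius change, leading-edge velocity, line
#' tension), particle geometry (refinement, edge/center classes, neighbor
#' pairs, interaction angles, distance statistics) and cluster metrics
#' (packing fraction, eccentricity, composition). When `outdir` is set,
#' per-cluster and per-pair CSV tables, the mode spectrum and a provenance
#' log are written; reruns with the same config and seed produce identical
#' tables.
#'
#' @param config a [pipeline_config()].
#' @return A results bundle (list of class `memclust_results`): `clusters`
#'   (per-cluster data frame), `pairs` (per-pair data frame), `spectrum`
#'   (per-mode data frame), `particles`, `traces`, `truth` (for simulated
#'   input), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  truth <- NULL
  if (!is.null(config$input)) {
    rd <- read_movie(config$input)
    movie <- rd$movie
    truth <- rd$extra$truth
  } else {
    sim <- render_movie(config$spec)
    movie <- sim$movie
    truth <- sim$truth
  }
  if (!is.null(config$pixel_size)) movie$pixel_size <- config$pixel_size
  if (!is.null(config$frame_interval))
    movie$frame_interval <- config$frame_interval
  if (is.null(movie$pixel_size))
    stop("configuration error: pixel_size unknown")

  # --- preprocess ---------------------------------------------------------
  movie$frames <- lapply(movie$frames, flatten_frame)
  al <- align_frames(movie)
  movie <- al$movie
  ms <- mask_stack(movie)
  traces_masks <- select_isolated_clusters(ms)
  if (length(traces_masks) == 0) stop("preprocess: no isolated cluster trace")

  clusters <- list()
  pairs_all <- list()
  spectra <- list()
  particles_by_cluster <- list()
  traces <- list()

  avg <- time_average_frames(movie, config$time_average)

  for (ci in seq_along(traces_masks)) {
    tm <- traces_masks[[ci]]
    tr <- cluster_trace(tm, pixel_size = movie$pixel_size,
                        frame_interval = movie$frame_interval,
                        dtheta = config$dtheta)
    traces[[ci]] <- tr
    muv <- mean_leading_edge_velocity(tr)
    tf <- fit_line_tension(tr, kmax = config$kmax)
    ecc <- contour_eccentricity(list(theta = tr$theta,
                                     radius = colMeans(tr$radius)))
    area <- mean(vapply(tm, sum, numeric(1))) * movie$pixel_size^2

    # --- particles on the time-averaged first block -----------------------
    frame_avg <- avg$frames[[1]]
    seeds <- if (!is.null(truth) && !is.null(truth$centers)) {
      m <- matrix(unlist(truth$centers), ncol = 2)
      colnames(m) <- c("x", "y"); m
    } else {
      detect_particles(frame_avg, min_sep = 4 * movie$pixel_size,
                       pixel_size = movie$pixel_size)
    }
    parts <- list()
    for (s in seq_len(nrow(seeds))) {
      p <- tryCatch(
        refine_particle(frame_avg, as.numeric(seeds[s, 1:2]), nf = config$nf,
                        pixel_size = movie$pixel_size),
        error = function(e) NULL)
      if (!is.null(p) && !p$low_confidence) parts[[length(parts) + 1]] <- p
    }
    mean_contour <- list(theta = tr$theta, radius = colMeans(tr$radius),
                         center = colMeans(tr$centers))
    if (length(parts) > 0)
      parts <- classify_edge_center(parts, mean_contour)
    particles_by_cluster[[ci]] <- parts

    pr <- if (length(parts) >= 2) delaunay_pairs(parts, d_max = config$d_max)
    else NULL
    if (!is.null(pr) && nrow(pr) > 0) {
      pr$cluster <- ci
      pairs_all[[length(pairs_all) + 1]] <- as.data.frame(pr)
    }

    n_total <- length(parts)
    nf_vec <- vapply(parts, function(p) p$nf, integer(1))
    n_foca <- sum(nf_vec == 5L)
    n_glpf <- sum(nf_vec == 4L)
    f <- packing_fraction(n_glpf, n_foca, area, config$areas)
    tilts <- vapply(parts, function(p) p$tilt_deg, numeric(1))
    loc <- vapply(parts, function(p) p$location_class, character(1))

    clusters[[ci]] <- data.frame(
      cluster = ci, n_frames = nrow(tr$radius), r0 = mean(tr$radius),
      area_nm2 = area, mu_v = muv, lambda = tf$lambda,
      lambda_r2 = tf$r_squared, eccentricity = ecc,
      n_particles = n_total, n_pentamer = n_foca, n_tetramer = n_glpf,
      packing_fraction = as.numeric(f),
      nonplanar = isTRUE(attr(f, "nonplanar")),
      mean_tilt_edge = if (any(loc == "edge")) mean(tilts[loc == "edge"]) else NA,
      mean_tilt_center = if (any(loc == "center")) mean(tilts[loc == "center"]) else NA,
      chi = config$chi)
    spectra[[ci]] <- data.frame(cluster = ci, k = tf$k,
                                mode_power = tf$mode_power,
                                predictor = tf$predictor)
  }

  res <- structure(list(
    clusters = do.call(rbind, clusters),
    pairs = do.call(rbind, pairs_all),
    spectrum = do.call(rbind, spectra),
    particles = particles_by_cluster,
    traces = traces,
    drift = al$drift,
    truth = truth,
    config = config), class = "memclust_results")

  if (!is.null(config$outdir)) write_results(res, config$outdir)
  res
}

#' Write a results bundle to CSV + provenance JSON
#'
#' @param res a `memclust_results` bundle.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_results <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$clusters, file.path(outdir, "clusters.csv"),
                   row.names = FALSE)
  if (!is.null(res$pairs) && nrow(res$pairs) > 0)
    utils::write.csv(res$pairs, file.path(outdir, "pairs.csv"),
                     row.names = FALSE)
  utils::write.csv(res$spectrum, file.path(outdir, "spectrum.csv"),
                   row.names = FALSE)
  prov <- list(
    package = "memclust",
    version = as.character(utils::packageVersion("memclust")),
    r_version = R.version.string,
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = res$config$seed,
    parameters = res$config[c("nf", "dtheta", "kmax", "temperature", "chi",
                              "time_average")])
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}

#' @export
print.memclust_results <- function(x, ...) {
  cat(sprintf("memclust_results: %d cluster(s), %d pair(s)\n",
              if (is.null(x$clusters)) 0 else nrow(x$clusters),
              if (is.null(x$pairs)) 0 else nrow(x$pairs)))
  if (!is.null(x$clusters))
    print(x$clusters[, c("cluster", "r0", "mu_v", "lambda",
                         "packing_fraction")])
  invisible(x)
}
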