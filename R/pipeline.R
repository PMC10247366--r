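#' Run configuration for the pipeline arms
#'
#' Builds a validated configuration whose defaults are the standard
#' analysis parameters: vesicle threshold 0.15 1/nm, single-linkage
#' cut-off 10 nm, DBSCAN 31 nm / 10 localizations, linking over at most 8
#' dark frames, fiducial runs > 20 frames, precision < 50 nm, PSF symmetry
#' 0.7-1.4, Voronoi 800 localizations / 100 nm minimum diameter, reference
#' rate 0.0018 1/ns, pixel size 158 nm. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults (named).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1,
    vesicle_threshold = 0.15,    # 1/nm
    k_ref = 0.0018,              # 1/ns
    cluster_cutoff = 10,         # nm
    contact_cutoff = 0.6,        # nm
    gap_tolerance = 0,
    budding_f = 0.05,
    budding_persist = 10,
    spacing = 1.0,               # nm, height-field lattice
    eps = 31,                    # nm, DBSCAN radius
    min_pts = 10,
    radius_factor = 5,
    max_dark_frames = 8,
    fiducial_max = 20,
    precision_max = 50,          # nm
    symmetry_low = 0.7,
    symmetry_high = 1.4,
    intensity_min = 1,
    delta = 4,
    min_locs = 800,
    min_diameter = 100,          # nm
    frame_rate = 10,             # Hz
    pixel_size = 158             # nm
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults[names(over)] <- over
  }
  structure(c(defaults, list(.overridden = names(over))),
            class = "run_config")
}

#' Read / write a run configuration (JSON)
#'
#' @param path JSON file path.
#' @return [read_run_config()] returns a `run_config`;
#'   [write_run_config()] returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- config[setdiff(names(config), ".overridden")]
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# small deterministic FNV-1a hash of the serialized config, for provenance
config_hash <- function(config) {
  vals <- config[setdiff(names(config), ".overridden")]
  bytes <- utf8ToInt(paste(names(vals), unlist(vals), sep = "=",
                           collapse = ";"))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2^31  # exact in double precision
  sprintf("%08x", h)
}

#' Membrane-arm pipeline: curvature, kinetics and clustering
#'
#' Chains the membrane analyses over in-memory inputs: classifies
#' bicelle-to-vesicle transitions from per-replicate curvature series,
#' fits the Poisson-with-lag model and the acceleration factor, and (when
#' a protein trajectory is supplied) computes the largest-cluster series,
#' ubiquitin contacts and budding metrics. Results are returned as a
#' summary list and optionally written as CSV/JSON with provenance
#' (config hash and seed).
#'
#' @param curvature_series list of data frames with columns `time_ns`,
#'   `H`; one per replicate.
#' @param trajectory optional list of [protein_frame()] objects.
#' @param config a [run_config()].
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return A list with `fit`, `acceleration`, `closure`, and (when a
#'   trajectory is given) `clusters`, `contacts`, `budding`; plus
#'   `provenance`.
#' @export
run_membrane_arm <- function(curvature_series, trajectory = NULL,
                             config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (length(curvature_series) == 0L)
    stop("no curvature series supplied", call. = FALSE)
  records <- lapply(seq_along(curvature_series), function(i) {
    s <- curvature_series[[i]]
    if (is.null(s$time_ns) || is.null(s$H))
      stop("curvature series ", i, " lacks time_ns/H columns",
           call. = FALSE)
    classify_transition(s$time_ns, s$H,
                        threshold = config$vesicle_threshold, replicate = i)
  })
  sample <- as_waiting_time_sample(records)
  fit <- fit_shifted_exponential(sample, method = "mle")
  acc <- acceleration_factor(fit, k_ref = config$k_ref)
  closure <- closure_count(records)
  out <- list(fit = fit, acceleration = acc, closure = closure)
  if (!is.null(trajectory)) {
    out$clusters <- cluster_series(trajectory, cutoff = config$cluster_cutoff)
    out$contacts <- ub_contacts(trajectory,
                                contact_cutoff = config$contact_cutoff,
                                gap_tolerance = config$gap_tolerance)
    out$budding <- budding_metrics(trajectory, f = config$budding_f,
                                   persist = config$budding_persist)
  }
  out$provenance <- list(config_hash = config_hash(config),
                         seed = config$seed, n_replicates = length(records))
  if (!is.null(out_dir)) write_membrane_outputs(out, out_dir)
  out
}

write_membrane_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    k_prime = out$fit$k_prime, tau = out$fit$tau,
    k_overall = out$fit$k_overall, acc = out$acceleration$acc,
    n_uncensored = out$fit$n_uncensored, n_censored = out$fit$n_censored,
    closure_fraction = out$closure$fraction,
    provenance = out$provenance)
  jsonlite::write_json(summary, file.path(out_dir, "membrane_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(out$clusters))
    utils::write.csv(out$clusters, file.path(out_dir, "cluster_series.csv"),
                     row.names = FALSE)
  if (!is.null(out$contacts))
    utils::write.csv(out$contacts$records,
                     file.path(out_dir, "contacts.csv"), row.names = FALSE)
  if (!is.null(out$budding))
    utils::write.csv(out$budding$traces,
                     file.path(out_dir, "budding_traces.csv"),
                     row.names = FALSE)
  invisible(out_dir)
}

#' SMLM-arm pipeline: QC to nanoclusters and copy numbers
#'
#' Chains localization processing: quality filter, NeNa precision, trace
#' linking, fiducial removal, DBSCAN nanocluster detection and a
#' log-normal fit of the nanocluster diameter distribution; optionally
#' Voronoi microcluster segmentation and per-cluster dark-time / qPAINT
#' analysis against a calibration table.
#'
#' @param table a [localization_table()].
#' @param calibration optional calibration localization table (single
#'   docking-site complexes) for copy-number inference.
#' @param config a [run_config()].
#' @param voronoi run Voronoi microcluster segmentation as well.
#' @param out_dir optional output directory.
#' @return A list with `qc`, `precision`, `traces`, `nanoclusters`,
#'   `diameter_fit` (log-normal fit of nanocluster diameters, when at
#'   least 10 clusters were found), optionally `voronoi` and
#'   `copy_number`, plus `provenance`.
#' @export
run_smlm_arm <- function(table, calibration = NULL, config = run_config(),
                         voronoi = FALSE, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  qc <- qc_filter(table, qc_params(symmetry_low = config$symmetry_low,
                                   symmetry_high = config$symmetry_high,
                                   precision_max = config$precision_max,
                                   intensity_min = config$intensity_min))
  prec <- nena_precision(qc$table)
  traces <- link_localizations(qc$table, precision = prec,
                               radius_factor = config$radius_factor,
                               max_dark_frames = config$max_dark_frames)
  traces <- remove_fiducials(traces, max_consecutive = config$fiducial_max)
  clean <- drop_fiducial_localizations(qc$table, traces)
  ncl <- dbscan_nanoclusters(clean, eps = config$eps,
                             min_pts = config$min_pts)
  out <- list(qc = qc, precision = prec, traces = traces,
              nanoclusters = ncl)
  if (nrow(ncl$clusters) >= 10L)
    out$diameter_fit <- fit_lognormal(ncl$clusters$diameter_nm)
  if (voronoi)
    out$voronoi <- voronoi_microclusters(clean, delta = config$delta,
                                         min_locs = config$min_locs,
                                         min_diameter = config$min_diameter)
  if (!is.null(calibration)) {
    idx_cluster <- cluster_qpaint_indices(clean, ncl,
                                          frame_rate = config$frame_rate)
    cal_qc <- qc_filter(calibration)
    cal_ncl <- dbscan_nanoclusters(cal_qc$table, eps = config$eps,
                                   min_pts = config$min_pts)
    idx_cal <- cluster_qpaint_indices(cal_qc$table, cal_ncl,
                                      frame_rate = config$frame_rate)
    if (length(idx_cluster) >= 10L && length(idx_cal) >= 10L)
      out$copy_number <- copy_number(idx_cluster, idx_cal)
  }
  out$provenance <- list(config_hash = config_hash(config),
                         seed = config$seed)
  if (!is.null(out_dir)) write_smlm_outputs(out, out_dir)
  out
}

#' Per-nanocluster qPAINT indices
#'
#' Computes the dark-time based qPAINT index (inverse mean dark time) for
#' every detected nanocluster with at least `min_events` bright events.
#'
#' @param table the localization table that was clustered.
#' @param clusters a [dbscan_nanoclusters()] result on that table.
#' @param frame_rate acquisition rate, Hz.
#' @param min_events minimum bright events per cluster.
#' @return Numeric vector of qPAINT indices (1/s), one per usable cluster.
#' @export
cluster_qpaint_indices <- function(table, clusters, frame_rate = 10,
                                   min_events = 5) {
  stopifnot(inherits(clusters, "nanocluster_set"))
  ids <- setdiff(sort(unique(clusters$labels)), 0L)
  out <- numeric(0)
  for (k in ids) {
    fr <- table$frame[clusters$labels == k]
    dt <- tryCatch(dark_times(fr, frame_rate = frame_rate),
                   error = function(e) NULL)
    if (!is.null(dt) && dt$n_events >= min_events)
      out <- c(out, dt$qpaint_index)
  }
  out
}

write_smlm_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$nanoclusters$clusters,
                   file.path(out_dir, "nanoclusters.csv"),
                   row.names = FALSE)
  summary <- list(sigma_nena = out$precision$sigma_nena,
                  n_removed_qc = out$qc$n_removed,
                  n_fiducial_traces = sum(out$traces$traces$is_fiducial),
                  n_nanoclusters = nrow(out$nanoclusters$clusters),
                  provenance = out$provenance)
  if (!is.null(out$diameter_fit))
    summary$modal_diameter_nm <- out$diameter_fit$mode
  if (!is.null(out$copy_number))
    summary$copy_number <- out$copy_number$n
  if (!is.null(out$voronoi))
    summary$n_microclusters <- nrow(out$voronoi$clusters)
  jsonlite::write_json(summary, file.path(out_dir, "smlm_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
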