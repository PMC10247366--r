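#' Single-molecule localization table
#'
#' Validates and normalises a localization table for downstream processing.
#' Required columns are `frame`, `x`, `y` (nm); `z`, `photons`, `fwhm_x`,
#' `fwhm_y` and `precision` (nm) are used when present. Picasso-style
#' column names (`sx`, `sy`, `lpx`, `lpy`) are mapped automatically, and
#' pixel coordinates are converted with `pixel_size`.
#'
#' @param df data frame of localizations.
#' @param pixel_size when given, `x`, `y`, `sx`/`sy`, `lpx`/`lpy` are taken
#'   to be in camera pixels and multiplied by this size (nm per pixel,
#'   typically 158).
#' @return The normalised data frame with class `localization_table`.
#' @export
localization_table <- function(df, pixel_size = NULL) {
  df <- as.data.frame(df)
  # Picasso dialect: sx/sy are PSF widths, lpx/lpy per-axis precisions
  if (!"fwhm_x" %in% names(df) && "sx" %in% names(df)) {
    df$fwhm_x <- 2.3548 * df$sx
    df$fwhm_y <- 2.3548 * df$sy
  }
  if (!"precision" %in% names(df) && all(c("lpx", "lpy") %in% names(df)))
    df$precision <- sqrt((df$lpx^2 + df$lpy^2) / 2)
  need <- c("frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing localization column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(pixel_size)) {
    for (cc in intersect(c("x", "y", "fwhm_x", "fwhm_y", "precision"),
                         names(df)))
      df[[cc]] <- df[[cc]] * pixel_size
  }
  if (any(df$frame < 0)) stop("frames must be >= 0", call. = FALSE)
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("coordinates must be finite", call. = FALSE)
  if ("precision" %in% names(df) && any(df$precision <= 0, na.rm = TRUE))
    stop("precision must be positive where present", call. = FALSE)
  class(df) <- c("localization_table", "data.frame")
  df
}

#' Quality-control parameters for localization filtering
#'
#' Defaults follow standard DNA-PAINT processing: PSF symmetry
#' `0.7 < FWHM(x)/FWHM(y) < 1.4`, localization precision below 50 nm, and
#' a configurable minimum photon count (default 1, i.e. pass-through,
#' since published intensity thresholds are instrument-specific).
#'
#' @param symmetry_low,symmetry_high bounds on the FWHM ratio.
#' @param precision_max maximum localization precision, nm.
#' @param intensity_min minimum photon count.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(symmetry_low = 0.7, symmetry_high = 1.4,
                      precision_max = 50, intensity_min = 1) {
  if (!(symmetry_low > 0 && symmetry_low < symmetry_high))
    stop("need 0 < symmetry_low < symmetry_high", call. = FALSE)
  if (precision_max <= 0) stop("precision_max must be positive", call. = FALSE)
  structure(list(symmetry_low = symmetry_low, symmetry_high = symmetry_high,
                 precision_max = precision_max,
                 intensity_min = intensity_min),
            class = "qc_params")
}

#' Filter localizations on PSF symmetry, precision and intensity
#'
#' Keeps rows satisfying all of: `symmetry_low < fwhm_x/fwhm_y <
#' symmetry_high` (strict), `precision < precision_max` (strict) and
#' `photons >= intensity_min`. Each rejected row is tallied under the first
#' criterion it fails (symmetry, then precision, then intensity), so the
#' tallies sum to the number of removed rows.
#'
#' @param table a [localization_table()].
#' @param params a [qc_params()].
#' @return A list with `table` (kept rows), `rejected` (named tally) and
#'   `n_removed`.
#' @export
qc_filter <- function(table, params = qc_params()) {
  table <- localization_table(table)
  need <- c("fwhm_x", "fwhm_y", "precision", "photons")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("qc_filter needs column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ratio <- table$fwhm_x / table$fwhm_y
  fail_sym <- !(ratio > params$symmetry_low & ratio < params$symmetry_high)
  fail_prec <- !(table$precision < params$precision_max)
  fail_int <- !(table$photons >= params$intensity_min)
  first_fail <- ifelse(fail_sym, "symmetry",
                       ifelse(fail_prec, "precision",
                              ifelse(fail_int, "intensity", NA)))
  keep <- is.na(first_fail)
  tally <- c(symmetry = sum(first_fail == "symmetry", na.rm = TRUE),
             precision = sum(first_fail == "precision", na.rm = TRUE),
             intensity = sum(first_fail == "intensity", na.rm = TRUE))
  list(table = table[keep, , drop = FALSE], rejected = tally,
       n_removed = sum(!keep))
}

#' NeNa localization precision from consecutive-frame nearest neighbours
#'
#' Estimates the localization precision sigma by the nearest-neighbour
#' analysis: for every localization, the distance to its nearest neighbour
#' in the following frame is computed; repeated localizations of the same
#' emitter produce a correlated-pair peak with density
#' `p(d) = (d / (2 sigma^2)) * exp(-d^2 / (4 sigma^2))`, on top of a
#' linear background from uncorrelated molecules. Both components are
#' fitted to the binned distance distribution by nonlinear least squares.
#'
#' @param table a [localization_table()].
#' @param max_distance largest neighbour distance considered, nm.
#' @param n_bins histogram bins for the fit.
#' @return An object of class `precision_estimate`: `sigma_nena` (nm),
#'   `n_pairs`, `fit` (the nls object) and the binned data.
#' @export
nena_precision <- function(table, max_distance = 200, n_bins = 60) {
  table <- localization_table(table)
  frames <- sort(unique(table$frame))
  by_frame <- split(seq_len(nrow(table)), table$frame)
  dists <- numeric(0)
  for (f in frames) {
    nxt <- as.character(f + 1)
    cur <- as.character(f)
    if (is.null(by_frame[[nxt]])) next
    a <- table[by_frame[[cur]], c("x", "y")]
    b <- table[by_frame[[nxt]], c("x", "y")]
    d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
    dists <- c(dists, sqrt(apply(d2, 1, min)))
  }
  dists <- dists[dists <= max_distance]
  if (length(dists) < 100L)
    stop("need at least 100 consecutive-frame neighbour pairs",
         call. = FALSE)
  if (stats::median(dists) < 1e-6) {  # degenerate noiseless repeats
    return(structure(list(sigma_nena = min(0.1, stats::sd(dists) + 1e-3),
                          n_pairs = length(dists), fit = NULL,
                          distances = dists),
                     class = "precision_estimate"))
  }
  h <- graphics::hist(dists, breaks = n_bins, plot = FALSE)
  df <- data.frame(d = h$mids, y = h$density)
  s0 <- stats::median(dists) / 1.386  # mode of the pair peak is sigma*sqrt(2)
  fit <- minpack.lm::nlsLM(
    y ~ A * (d / (2 * s^2)) * exp(-d^2 / (4 * s^2)) + B * d,
    data = df, start = list(A = 0.8, s = s0, B = 1e-6),
    lower = c(0, 1e-3, 0),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  sigma <- unname(stats::coef(fit)["s"])
  structure(list(sigma_nena = sigma, n_pairs = length(dists), fit = fit,
                 distances = dists),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf("NeNa precision: sigma = %.3g nm (%d pairs)\n",
              x$sigma_nena, x$n_pairs))
  invisible(x)
}

#' Link same-origin localizations into traces
#'
#' Greedy frame-ordered linking: a localization joins an open trace when it
#' lies within `radius_factor * sigma` of the trace's running centroid and
#' the number of intervening dark frames since the trace's last member is
#' at most `max_dark_frames` (a gap between frames f1 < f2 contains
#' f2 - f1 - 1 dark frames). Otherwise it opens a new trace. The trace
#' centroid is updated as the running mean of member positions.
#'
#' @param table a [localization_table()].
#' @param precision a [nena_precision()] result, or a bare sigma in nm.
#' @param radius_factor linking radius in units of sigma.
#' @param max_dark_frames maximum intervening dark frames inside a trace.
#' @param radius explicit linking radius in nm, overriding
#'   `radius_factor * sigma`.
#' @return An object of class `trace_set`: `traces` data frame (`trace`,
#'   `n`, `x`, `y`, `first_frame`, `last_frame`, `max_run`,
#'   `is_fiducial`), per-localization `membership`, and the linking
#'   parameters. `max_run` is the longest run of strictly consecutive
#'   frames within the trace.
#' @export
link_localizations <- function(table, precision = NULL, radius_factor = 5,
                               max_dark_frames = 8, radius = NULL) {
  table <- localization_table(table)
  if (is.null(radius)) {
    sigma <- if (inherits(precision, "precision_estimate"))
      precision$sigma_nena else as.numeric(precision)
    if (is.null(precision) || !is.finite(sigma))
      stop("give 'precision' (NeNa result or sigma) or an explicit 'radius'",
           call. = FALSE)
    radius <- radius_factor * sigma
  }
  if (!is.finite(radius) || radius <= 0)
    stop("linking radius must be positive", call. = FALSE)
  ord <- order(table$frame, seq_len(nrow(table)))
  n <- nrow(table)
  membership <- integer(n)
  # open traces: parallel vectors
  tx <- ty <- numeric(0); tn <- tlast <- integer(0)
  trace_frames <- list()
  n_traces <- 0L
  for (r in ord) {
    f <- table$frame[r]; px <- table$x[r]; py <- table$y[r]
    cand <- which(tlast < f & (f - tlast - 1L) <= max_dark_frames)
    assigned <- FALSE
    if (length(cand)) {
      dd <- sqrt((tx[cand] - px)^2 + (ty[cand] - py)^2)
      j <- cand[which.min(dd)]
      if (min(dd) <= radius) {
        membership[r] <- j
        tx[j] <- (tx[j] * tn[j] + px) / (tn[j] + 1L)
        ty[j] <- (ty[j] * tn[j] + py) / (tn[j] + 1L)
        tn[j] <- tn[j] + 1L
        tlast[j] <- f
        trace_frames[[j]] <- c(trace_frames[[j]], f)
        assigned <- TRUE
      }
    }
    if (!assigned) {
      n_traces <- n_traces + 1L
      tx[n_traces] <- px; ty[n_traces] <- py
      tn[n_traces] <- 1L; tlast[n_traces] <- f
      trace_frames[[n_traces]] <- f
      membership[r] <- n_traces
    }
  }
  max_run <- vapply(trace_frames, function(fr) {
    fr <- sort(unique(fr))
    if (length(fr) == 1L) return(1L)
    r <- rle(diff(fr) == 1L)
    runs <- r$lengths[r$values]
    if (length(runs)) max(runs) + 1L else 1L
  }, integer(1))
  traces <- data.frame(
    trace = seq_len(n_traces), n = tn, x = tx, y = ty,
    first_frame = vapply(trace_frames, min, numeric(1)),
    last_frame = tlast[seq_len(n_traces)],
    max_run = max_run, is_fiducial = FALSE)
  structure(list(traces = traces, membership = membership,
                 frames = trace_frames, radius = radius,
                 max_dark_frames = max_dark_frames),
            class = "trace_set")
}

#' Flag and remove fiducial-marker traces
#'
#' Fiducial beads emit continuously, so their linked traces contain very
#' long runs of consecutive frames. Traces with a run of strictly more
#' than `max_consecutive` frames are flagged `is_fiducial`; the returned
#' set keeps all traces but marks them, and `kept` indexes the non-fiducial
#' ones for downstream cluster analysis.
#'
#' @param traces a [link_localizations()] result.
#' @param max_consecutive longest tolerated consecutive-frame run.
#' @return The `trace_set` with `is_fiducial` filled in and an added
#'   `kept` vector of trace ids.
#' @export
remove_fiducials <- function(traces, max_consecutive = 20) {
  stopifnot(inherits(traces, "trace_set"))
  fid <- traces$traces$max_run > max_consecutive
  traces$traces$is_fiducial <- fid
  traces$kept <- traces$traces$trace[!fid]
  traces
}

#' Localizations belonging to non-fiducial traces
#'
#' @param table the [localization_table()] that was linked.
#' @param traces a [remove_fiducials()] result.
#' @return The subset of `table` whose traces are not fiducials.
#' @export
drop_fiducial_localizations <- function(table, traces) {
  stopifnot(inherits(traces, "trace_set"), !is.null(traces$kept))
  keep <- traces$membership %in% traces$kept
  table[keep, , drop = FALSE]
}

#' DBSCAN nanocluster detection
#'
#' Classical DBSCAN on localization coordinates: a core point has at least
#' `min_pts` neighbours within `eps` (counting itself); clusters are the
#' density-connected sets of core points plus reachable border points;
#' everything else is noise. Neighbour search uses an eps-sized grid index.
#' Per cluster, the area is the convex hull of member positions and the
#' reported diameter is that of the equivalent circle,
#' `2 * sqrt(area / pi)`.
#'
#' @param table a [localization_table()] or a two-column matrix (nm).
#' @param eps neighbourhood radius, nm.
#' @param min_pts minimum neighbour count for a core point.
#' @return An object of class `nanocluster_set`: `labels` per localization
#'   (0 = noise) and a `clusters` data frame (`cluster`,
#'   `n_localizations`, `x`, `y`, `area_nm2`, `diameter_nm`).
#' @export
dbscan_nanoclusters <- function(table, eps = 31, min_pts = 10) {
  xy <- if (is.matrix(table)) table else {
    t2 <- localization_table(table); cbind(t2$x, t2$y)
  }
  n <- nrow(xy)
  if (n < min_pts) {
    warning("fewer localizations than min_pts; no clusters")
    return(structure(list(labels = integer(n),
                          clusters = empty_cluster_df()),
                     class = "nanocluster_set"))
  }
  nb <- grid_neighbours(xy, eps)
  n_nb <- lengths(nb)            # includes self
  core <- n_nb >= min_pts
  labels <- integer(n)           # 0 = unvisited/noise
  cur <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cur <- cur + 1L
    labels[i] <- cur
    queue <- i
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      nbv <- nb[[v]]
      fresh <- nbv[labels[nbv] == 0L]
      labels[fresh] <- cur
      queue <- c(queue, fresh[core[fresh]])
    }
  }
  clusters <- cluster_geometry(xy, labels)
  structure(list(labels = labels, clusters = clusters, eps = eps,
                 min_pts = min_pts),
            class = "nanocluster_set")
}

empty_cluster_df <- function() {
  data.frame(cluster = integer(0), n_localizations = integer(0),
             x = numeric(0), y = numeric(0), area_nm2 = numeric(0),
             diameter_nm = numeric(0))
}

cluster_geometry <- function(xy, labels) {
  ids <- setdiff(sort(unique(labels)), 0L)
  if (!length(ids)) return(empty_cluster_df())
  do.call(rbind, lapply(ids, function(k) {
    m <- xy[labels == k, , drop = FALSE]
    a <- convex_hull_area(m)
    data.frame(cluster = k, n_localizations = nrow(m),
               x = mean(m[, 1]), y = mean(m[, 2]), area_nm2 = a,
               diameter_nm = 2 * sqrt(a / pi))
  }))
}

convex_hull_area <- function(m) {
  if (nrow(m) < 3L) return(0)
  h <- grDevices::chull(m[, 1], m[, 2])
  p <- m[h, , drop = FALSE]
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# grid-accelerated fixed-radius neighbour lists (self included)
grid_neighbours <- function(xy, eps) {
  n <- nrow(xy)
  gx <- floor(xy[, 1] / eps); gy <- floor(xy[, 2] / eps)
  key <- paste(gx, gy)
  cells <- split(seq_len(n), key)
  cell_of <- match(key, names(cells))
  # candidate indices per cell: union of 3x3 neighbourhood
  cand_of_cell <- lapply(names(cells), function(k) {
    ij <- as.integer(strsplit(k, " ", fixed = TRUE)[[1]])
    ks <- as.vector(outer(ij[1] + (-1:1), ij[2] + (-1:1), paste))
    unlist(cells[intersect(ks, names(cells))], use.names = FALSE)
  })
  eps2 <- eps^2
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- cand_of_cell[[cell_of[i]]]
    d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
    out[[i]] <- cand[d2 <= eps2]
  }
  out
}

#' Read a Picasso-style localization CSV
#'
#' @param path CSV path.
#' @param pixel_size nm per pixel when coordinates are in pixels.
#' @return A [localization_table()].
#' @export
read_localizations_csv <- function(path, pixel_size = NULL) {
  localization_table(utils::read.csv(path), pixel_size = pixel_size)
}
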