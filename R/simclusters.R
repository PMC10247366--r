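#' Per-frame protein state of a membrane simulation
#'
#' Holds the centre-of-mass positions of all proteins in one frame along
#' with the box dimensions, the membrane headgroup z-extrema and, when
#' contact analysis is wanted, the coordinates of tethered ubiquitin beads.
#'
#' @param com n x 3 matrix of protein COM positions, nm.
#' @param box box dimensions `c(Lx, Ly, Lz)`, nm.
#' @param time frame time, ns.
#' @param z_membrane `c(z_min, z_max)` of the membrane headgroup beads, nm.
#' @param ub_beads optional data frame of ubiquitin bead coordinates with
#'   columns `mol` (molecule id), `res` (residue index), `attachment`
#'   (e.g. `"K160"`, `"K264"`), `x`, `y`, `z`.
#' @param periodic per-axis periodicity flags.
#' @return An object of class `protein_frame`.
#' @export
protein_frame <- function(com, box = NULL, time = 0, z_membrane = NULL,
                          ub_beads = NULL, periodic = TRUE) {
  com <- as.matrix(com)
  if (ncol(com) != 3L)
    stop("'com' must be an n x 3 matrix", call. = FALSE)
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(box <= 0))
      stop("'box' must be three positive lengths", call. = FALSE)
  }
  if (!is.null(z_membrane) && z_membrane[1] > z_membrane[2])
    stop("z_membrane must be c(z_min, z_max)", call. = FALSE)
  if (!is.null(ub_beads)) {
    need <- c("mol", "res", "x", "y", "z")
    miss <- setdiff(need, names(ub_beads))
    if (length(miss))
      stop("ub_beads missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  structure(list(com = com, box = box, time = as.numeric(time),
                 z_membrane = z_membrane, ub_beads = ub_beads,
                 periodic = rep_len(as.logical(periodic), 3L)),
            class = "protein_frame")
}

#' Pairwise COM distance matrix under the minimum-image convention
#'
#' @param frame a [protein_frame()], or an n x 3 coordinate matrix.
#' @param box box dimensions when `frame` is a bare matrix.
#' @param periodic per-axis periodicity flags.
#' @return Symmetric n x n matrix of distances, nm; zero diagonal.
#' @export
com_distance_matrix <- function(frame, box = NULL, periodic = TRUE) {
  if (inherits(frame, "protein_frame")) {
    xyz <- frame$com; box <- frame$box; periodic <- frame$periodic
  } else {
    xyz <- as.matrix(frame)
    periodic <- rep_len(as.logical(periodic), 3L)
  }
  if (ncol(xyz) != 3L)
    stop("coordinates must be n x 3", call. = FALSE)
  if (any(periodic) && is.null(box))
    stop("periodic axes require box dimensions", call. = FALSE)
  n <- nrow(xyz)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(xyz[, k], xyz[, k], "-")
    if (!is.null(box) && periodic[k]) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

#' Protein clusters by single-linkage at a distance cut-off
#'
#' Clusters are the connected components of the graph whose edges join
#' protein pairs strictly closer than `cutoff`; this equals cutting the
#' single-linkage dendrogram at that height. The strict inequality means
#' that proteins at exactly the cut-off distance (e.g. a pristine 3 x 3
#' grid with 10 nm spacing) remain singletons.
#'
#' @param dist symmetric non-negative distance matrix, nm.
#' @param cutoff clustering cut-off, nm (edges require `d < cutoff`).
#' @param time optional frame time carried through.
#' @return An object of class `cluster_assignment`: integer `labels`
#'   (1-based, consecutive in order of first member), `sizes`,
#'   `largest_size`, `n_clusters`, `time`.
#' @export
single_linkage_clusters <- function(dist, cutoff = 10, time = NA) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n != ncol(dist) || any(dist < 0) ||
      max(abs(dist - t(dist))) > 1e-8 * max(1, max(dist)))
    stop("'dist' must be a symmetric non-negative matrix", call. = FALSE)
  adj <- dist < cutoff
  labels <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    labels[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & labels == 0L)
      labels[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(labels, nbins = cur)
  structure(list(labels = labels, sizes = sizes,
                 largest_size = if (cur) max(sizes) else 0L,
                 n_clusters = cur, time = time),
            class = "cluster_assignment")
}

#' Largest-cluster time series over a trajectory
#'
#' Applies [com_distance_matrix()] and [single_linkage_clusters()] to every
#' frame independently and tabulates the number of clusters and the size of
#' the largest cluster over time.
#'
#' @param traj list of [protein_frame()] objects.
#' @param cutoff single-linkage cut-off, nm.
#' @return A data frame with columns `frame`, `time_ns`, `n_clusters`,
#'   `largest_size`, plus the per-frame assignments as attribute
#'   `"assignments"`.
#' @export
cluster_series <- function(traj, cutoff = 10) {
  if (length(traj) == 0L)
    stop("empty trajectory", call. = FALSE)
  asg <- lapply(seq_along(traj), function(i) {
    fr <- traj[[i]]
    single_linkage_clusters(com_distance_matrix(fr), cutoff = cutoff,
                            time = fr$time)
  })
  out <- data.frame(
    frame = seq_along(traj),
    time_ns = vapply(traj, function(f) f$time, numeric(1)),
    n_clusters = vapply(asg, function(a) a$n_clusters, integer(1)),
    largest_size = vapply(asg, function(a) as.integer(a$largest_size),
                          integer(1)))
  attr(out, "assignments") <- asg
  out
}

#' Ubiquitin-ubiquitin contacts and lifetimes across a trajectory
#'
#' A residue pair of two ubiquitin moieties is in contact in a frame when
#' any of its bead-bead distances falls below `contact_cutoff`. Contacts on
#' the same molecule are `cis`, across molecules `trans`. Maximal runs of
#' contact frames (gaps of up to `gap_tolerance` missing frames bridged)
#' become contact records with lifetimes `(last - first + 1) *
#' frame_spacing`.
#'
#' @param frames list of [protein_frame()] objects carrying `ub_beads`.
#' @param contact_cutoff bead-bead contact distance, nm.
#' @param gap_tolerance maximum number of consecutive non-contact frames
#'   bridged inside one record.
#' @param frame_spacing time between frames, ns (defaults to the spacing of
#'   the frame times, or 1).
#' @return A list with `records` (data frame: `mol_i, mol_j, res_i, res_j,
#'   type, first_frame, last_frame, lifetime_ns`) and `frequency` (data
#'   frame per residue pair with the fraction of frames in contact).
#' @export
ub_contacts <- function(frames, contact_cutoff = 0.6, gap_tolerance = 0,
                        frame_spacing = NULL) {
  if (length(frames) == 0L) stop("empty trajectory", call. = FALSE)
  if (is.null(frame_spacing)) {
    tt <- vapply(frames, function(f) f$time, numeric(1))
    frame_spacing <- if (length(tt) > 1L) stats::median(diff(tt)) else 1
    if (!is.finite(frame_spacing) || frame_spacing <= 0) frame_spacing <- 1
  }
  # per frame: set of contacting (mol_i, mol_j, res_i, res_j) keys
  contact_keys <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    ub <- frames[[f]]$ub_beads
    if (is.null(ub)) stop("frame ", f, " lacks ub_beads", call. = FALSE)
    if (anyNA(ub$mol)) stop("missing molecule ids in ub_beads", call. = FALSE)
    if (nrow(ub) < 2L) { contact_keys[[f]] <- character(0); next }
    xyz <- cbind(ub$x, ub$y, ub$z)
    d <- com_distance_matrix(xyz, box = frames[[f]]$box,
                             periodic = frames[[f]]$periodic)
    hit <- which(d < contact_cutoff & upper.tri(d), arr.ind = TRUE)
    if (!nrow(hit)) { contact_keys[[f]] <- character(0); next }
    i <- hit[, 1]; j <- hit[, 2]
    # order pair so the key is canonical
    mi <- ub$mol[i]; mj <- ub$mol[j]; ri <- ub$res[i]; rj <- ub$res[j]
    swap <- mi > mj | (mi == mj & ri > rj)
    key <- ifelse(swap,
                  paste(mj, mi, rj, ri, sep = "|"),
                  paste(mi, mj, ri, rj, sep = "|"))
    drop_self <- mi == mj & ri == rj   # same residue with itself
    contact_keys[[f]] <- unique(key[!drop_self])
  }
  all_keys <- unique(unlist(contact_keys))
  recs <- list(); freq <- list()
  for (key in all_keys) {
    present <- which(vapply(contact_keys, function(k) key %in% k, logical(1)))
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    mol_i <- parts[1]; mol_j <- parts[2]
    res_i <- as.integer(parts[3]); res_j <- as.integer(parts[4])
    type <- if (mol_i == mol_j) "cis" else "trans"
    runs <- merge_runs(present, gap_tolerance)
    for (r in seq_len(nrow(runs))) {
      recs[[length(recs) + 1L]] <- data.frame(
        mol_i = mol_i, mol_j = mol_j, res_i = res_i, res_j = res_j,
        type = type, first_frame = runs[r, 1], last_frame = runs[r, 2],
        lifetime_ns = (runs[r, 2] - runs[r, 1] + 1) * frame_spacing)
    }
    freq[[length(freq) + 1L]] <- data.frame(
      mol_i = mol_i, mol_j = mol_j, res_i = res_i, res_j = res_j,
      type = type, fraction = length(present) / length(frames))
  }
  list(records = if (length(recs)) do.call(rbind, recs) else
         data.frame(mol_i = character(0), mol_j = character(0),
                    res_i = integer(0), res_j = integer(0),
                    type = character(0), first_frame = integer(0),
                    last_frame = integer(0), lifetime_ns = numeric(0)),
       frequency = if (length(freq)) do.call(rbind, freq) else
         data.frame(mol_i = character(0), mol_j = character(0),
                    res_i = integer(0), res_j = integer(0),
                    type = character(0), fraction = numeric(0)),
       frame_spacing = frame_spacing)
}

# merge sorted integer frame indices into inclusive runs, bridging gaps of
# at most `tol` missing frames
merge_runs <- function(idx, tol = 0) {
  idx <- sort(unique(idx))
  if (!length(idx)) return(matrix(numeric(0), 0, 2))
  brk <- which(diff(idx) > tol + 1)
  starts <- idx[c(1, brk + 1)]
  ends <- idx[c(brk, length(idx))]
  cbind(starts, ends)
}

#' Box-width and protein-height budding metrics
#'
#' Extracts the time traces that signal spontaneous membrane budding: the
#' box width `L_X(t)` (a bud consumes projected membrane area, contracting
#' the box under constant-tension coupling), the per-protein z positions
#' and the membrane headgroup z-extrema. An advisory flag marks sustained
#' box contraction: `L_X` below `(1 - f)` of its initial value for at least
#' `persist` consecutive frames. The traces, not the flag, are the primary
#' output.
#'
#' @param traj list of [protein_frame()] objects with `box` and
#'   `z_membrane` set.
#' @param f relative contraction threshold.
#' @param persist minimum number of consecutive sub-threshold frames.
#' @return An object of class `budding_metrics`: data frame `traces`
#'   (`frame, time_ns, L_X, z_min, z_max`, one `z_<i>` column per protein),
#'   `budding_flag`, `onset_time` (NA when not flagged), `f`, `persist`.
#' @export
budding_metrics <- function(traj, f = 0.05, persist = 10) {
  if (length(traj) == 0L) stop("empty trajectory", call. = FALSE)
  if (is.null(traj[[1]]$box) || is.null(traj[[1]]$z_membrane))
    stop("budding metrics need box and z_membrane in every frame",
         call. = FALSE)
  n_prot <- nrow(traj[[1]]$com)
  lx <- vapply(traj, function(fr) fr$box[1], numeric(1))
  tt <- vapply(traj, function(fr) fr$time, numeric(1))
  zmin <- vapply(traj, function(fr) fr$z_membrane[1], numeric(1))
  zmax <- vapply(traj, function(fr) fr$z_membrane[2], numeric(1))
  zs <- do.call(rbind, lapply(traj, function(fr) fr$com[, 3]))
  bad <- zs < (min(zmin) - 20) | zs > (max(zmax) + 20)
  if (any(bad))
    warning("protein z positions far outside the membrane bounds")
  below <- lx < (1 - f) * lx[1]
  runs <- merge_runs(which(below), 0)
  long <- which(runs[, 2] - runs[, 1] + 1 >= persist)
  flag <- length(long) > 0
  onset <- if (flag) tt[runs[long[1], 1]] else NA_real_
  traces <- data.frame(frame = seq_along(traj), time_ns = tt, L_X = lx,
                       z_min = zmin, z_max = zmax)
  colnames(zs) <- paste0("z_", seq_len(n_prot))
  traces <- cbind(traces, zs)
  structure(list(traces = traces, budding_flag = flag, onset_time = onset,
                 f = f, persist = persist),
            class = "budding_metrics")
}

#' Scaled protein-protein interaction well depth
#'
#' Linear interpolation of the Lennard-Jones protein-protein well depth
#' between a floor `eps_0` and the native `eps_original`:
#' `eps_alpha = eps_0 + alpha * (eps_original - eps_0)`. `alpha = 1`
#' recovers the full native interaction; `alpha = 0.65` is the standard
#' reduced-PPI condition.
#'
#' @param eps_0 floor well depth, kJ/mol.
#' @param eps_original native well depth, kJ/mol.
#' @param alpha interpolation factor in `[0, 1]`.
#' @return A list with `eps_0`, `eps_original`, `alpha`, `eps_alpha`.
#' @export
ppi_scale <- function(eps_0, eps_original, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  list(eps_0 = eps_0, eps_original = eps_original, alpha = alpha,
       eps_alpha = eps_0 + alpha * (eps_original - eps_0))
}
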