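#' Bead point cloud for one membrane frame
#'
#' Container for lipid/protein bead coordinates of a single frame, the unit
#' of input for all curvature operations. Coordinates are in nanometres,
#' time in nanoseconds.
#'
#' @param coords numeric matrix with three columns (x, y, z) in nm.
#' @param leaflet per-point leaflet label, one of `"upper"` (cytosolic),
#'   `"lower"` (luminal) or `"unassigned"`. Recycled if length 1.
#' @param bead_role per-point role label (e.g. `"headgroup"` for PO4-like
#'   marker beads vs `"other"`). Recycled if length 1.
#' @param time frame time in ns.
#' @param box optional box dimensions `c(Lx, Ly, Lz)` in nm; must be positive.
#' @param periodic logical flags per axis; recycled to length 3.
#'
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(coords, leaflet = "unassigned", bead_role = "other",
                        time = 0, box = NULL, periodic = FALSE) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("'coords' must have three columns (x, y, z)", call. = FALSE)
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite", call. = FALSE)
  n <- nrow(coords)
  leaflet <- rep_len(as.character(leaflet), n)
  ok <- leaflet %in% c("upper", "lower", "unassigned")
  if (!all(ok))
    stop("leaflet labels must be 'upper', 'lower' or 'unassigned'",
         call. = FALSE)
  bead_role <- rep_len(as.character(bead_role), n)
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("'box' must be three positive dimensions", call. = FALSE)
  }
  periodic <- rep_len(as.logical(periodic), 3L)
  structure(list(coords = coords, leaflet = leaflet, bead_role = bead_role,
                 time = as.numeric(time), box = box, periodic = periodic),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d beads at t = %g ns\n", nrow(x$coords), x$time))
  tab <- table(x$leaflet)
  cat("  leaflets:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (!is.null(x$box))
    cat(sprintf("  box: %.2f x %.2f x %.2f nm\n",
                x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

# Coerce a point_cloud or bare coordinate matrix to an n x 3 matrix,
# optionally restricted to a bead role.
cloud_coords <- function(cloud, bead_role = NULL) {
  if (inherits(cloud, "point_cloud")) {
    xyz <- cloud$coords
    if (!is.null(bead_role)) xyz <- xyz[cloud$bead_role %in% bead_role, ,
                                        drop = FALSE]
    xyz
  } else {
    m <- as.matrix(cloud)
    if (ncol(m) != 3L)
      stop("coordinate input must have three columns", call. = FALSE)
    m
  }
}

#' Read a point-cloud CSV
#'
#' Reads frames from a CSV with columns `time_ns, x_nm, y_nm, z_nm` and
#' optional `leaflet` and `role` columns, returning one `point_cloud` per
#' distinct time.
#'
#' @param path CSV file path.
#' @param box,periodic passed to [point_cloud()] for every frame.
#' @return A list of `point_cloud` objects ordered by time.
#' @export
read_point_cloud_csv <- function(path, box = NULL, periodic = FALSE) {
  df <- utils::read.csv(path)
  need <- c("time_ns", "x_nm", "y_nm", "z_nm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$leaflet)) df$leaflet <- "unassigned"
  if (is.null(df$role)) df$role <- "other"
  lapply(split(df, df$time_ns)[order(unique(df$time_ns))], function(d)
    point_cloud(cbind(d$x_nm, d$y_nm, d$z_nm), leaflet = d$leaflet,
                bead_role = d$role, time = d$time_ns[1], box = box,
                periodic = periodic))
}

#' Write point clouds to CSV
#'
#' @param clouds a `point_cloud` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_point_cloud_csv <- function(clouds, path) {
  if (inherits(clouds, "point_cloud")) clouds <- list(clouds)
  df <- do.call(rbind, lapply(clouds, function(cl)
    data.frame(time_ns = cl$time, x_nm = cl$coords[, 1],
               y_nm = cl$coords[, 2], z_nm = cl$coords[, 3],
               leaflet = cl$leaflet, role = cl$bead_role)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
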