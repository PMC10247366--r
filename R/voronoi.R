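# Voronoi tessellation by incremental half-plane clipping.
#
# Each point's cell starts as the clipped bounding rectangle and is cut by
# the perpendicular bisector of every sufficiently close other point,
# visited in order of distance with an early-exit bound: once half the
# distance to the next candidate exceeds the farthest cell vertex, no
# further point can clip the cell. Edge provenance tags identify which
# neighbour contributed each surviving edge, giving the cell adjacency
# (first-rank neighbour) graph for free.

# clip convex polygon (vx, vy, tag-per-edge starting at each vertex) by the
# half-plane a*x + b*y <= c; new edges get tag `tag`
clip_halfplane <- function(poly, a, b, c, tag) {
  vx <- poly$x; vy <- poly$y; tg <- poly$tag
  n <- length(vx)
  if (n == 0L) return(poly)
  s <- a * vx + b * vy - c
  inside <- s <= 1e-12 * (abs(c) + 1)
  if (all(inside)) return(poly)
  if (!any(inside)) return(list(x = numeric(0), y = numeric(0),
                                tag = integer(0)))
  nx <- ny <- numeric(0); ntg <- integer(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      nx <- c(nx, vx[i]); ny <- c(ny, vy[i]); ntg <- c(ntg, tg[i])
      if (!inside[j]) {
        t <- s[i] / (s[i] - s[j])
        nx <- c(nx, vx[i] + t * (vx[j] - vx[i]))
        ny <- c(ny, vy[i] + t * (vy[j] - vy[i]))
        ntg <- c(ntg, tag)       # edge along the bisector starts here
      }
    } else if (inside[j]) {
      t <- s[i] / (s[i] - s[j])
      nx <- c(nx, vx[i] + t * (vx[j] - vx[i]))
      ny <- c(ny, vy[i] + t * (vy[j] - vy[i]))
      ntg <- c(ntg, tg[i])       # remainder of the original edge
    }
  }
  list(x = nx, y = ny, tag = ntg)
}

polygon_area <- function(p) {
  x <- p$x; y <- p$y
  if (length(x) < 3L) return(0)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# full tessellation: cells, areas, adjacency
voronoi_tessellation <- function(xy, bbox = NULL) {
  n <- nrow(xy)
  if (n < 4L) stop("Voronoi tessellation needs at least 4 points",
                   call. = FALSE)
  if (is.null(bbox)) {
    # inflate the data range by the median nearest-neighbour distance so
    # that edge cells are closed without dominating the area budget
    nn <- median_nn_distance(xy)
    bbox <- c(min(xy[, 1]) - nn, max(xy[, 1]) + nn,
              min(xy[, 2]) - nn, max(xy[, 2]) + nn)
  }
  rect <- list(x = bbox[c(1, 2, 2, 1)], y = bbox[c(3, 3, 4, 4)],
               tag = rep(0L, 4L))
  cells <- vector("list", n)
  areas <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    dx <- xy[, 1] - xy[i, 1]; dy <- xy[, 2] - xy[i, 2]
    d2 <- dx^2 + dy^2
    ord <- order(d2)
    ord <- ord[ord != i]
    poly <- rect
    for (j in ord) {
      dj <- sqrt(d2[j])
      # early exit: no farther point can cut the current cell
      rmax2 <- max((poly$x - xy[i, 1])^2 + (poly$y - xy[i, 2])^2)
      if ((dj / 2)^2 > rmax2) break
      mx <- (xy[i, 1] + xy[j, 1]) / 2; my <- (xy[i, 2] + xy[j, 2]) / 2
      a <- dx[j]; b <- dy[j]
      poly <- clip_halfplane(poly, a, b, a * mx + b * my, j)
      if (!length(poly$x)) break
    }
    cells[[i]] <- poly
    areas[i] <- polygon_area(poly)
    nbrs[[i]] <- setdiff(unique(poly$tag), 0L)
  }
  # adjacency must be symmetric; keep the union (a degenerate short edge
  # can be recorded on one side only)
  for (i in seq_len(n)) for (j in nbrs[[i]])
    if (!(i %in% nbrs[[j]])) nbrs[[j]] <- c(nbrs[[j]], i)
  list(cells = cells, areas = areas, neighbours = nbrs, bbox = bbox)
}

median_nn_distance <- function(xy) {
  n <- nrow(xy)
  take <- if (n > 2000L) unique(round(seq(1L, n, length.out = 2000L)))
          else seq_len(n)
  nn <- vapply(take, function(i) {
    d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
    sqrt(min(d2[-i]))
  }, numeric(1))
  stats::median(nn)
}

#' Voronoi first-rank-density microcluster segmentation
#'
#' Segments micrometre-scale clusters from a localization map by Voronoi
#' tessellation, in the manner of SR-Tesseler. For every localization the
#' first-rank local density is
#' `(1 + number of first-rank neighbours) / (own cell area + neighbour
#' cell areas)`. Localizations whose first-rank density exceeds
#' `delta` times the global mean density (total localizations over the
#' clipped bounding region) seed candidate objects; seeds whose cells
#' share an edge are merged; each object then annexes adjacent border
#' cells whose first-rank density still exceeds half the seed threshold
#' (a two-level hysteresis akin to DBSCAN border points, keeping the rim
#' of a dense object from being clipped by the hard seed threshold). A
#' candidate is reported only when it has at least `min_locs` member
#' localizations and an equivalent-circle diameter of at least
#' `min_diameter`, the candidate area being the convex hull of its member
#' localizations (the same estimator used for nanocluster areas; summed
#' Voronoi cell areas would count the large rim cells of the
#' object--background transition into the object).
#' Unbounded edge cells are closed by clipping to the bounding box
#' inflated by the median nearest-neighbour distance.
#'
#' @param table a [localization_table()] or two-column matrix (nm).
#' @param delta density factor, between 2 and 6.
#' @param min_locs minimum localizations per microcluster.
#' @param min_diameter minimum equivalent-circle diameter, nm.
#' @return An object of class `voronoi_segmentation`: per-localization
#'   `density` (1/nm^2), `global_mean_density`, `seed` flags,
#'   `cluster` labels (0 = none) and a `clusters` data frame (`cluster`,
#'   `n_localizations`, `area_nm2`, `diameter_nm`, `x`, `y`).
#' @export
voronoi_microclusters <- function(table, delta, min_locs = 800,
                                  min_diameter = 100) {
  if (!is.numeric(delta) || length(delta) != 1L || delta < 2 || delta > 6)
    stop("'delta' must lie in [2, 6]", call. = FALSE)
  xy <- if (is.matrix(table)) table else {
    t2 <- localization_table(table); cbind(t2$x, t2$y)
  }
  n <- nrow(xy)
  if (n < 10L) stop("need at least 10 localizations", call. = FALSE)
  vt <- voronoi_tessellation(xy)
  dens <- vapply(seq_len(n), function(i) {
    nb <- vt$neighbours[[i]]
    (1 + length(nb)) / (vt$areas[i] + sum(vt$areas[nb]))
  }, numeric(1))
  region_area <- (vt$bbox[2] - vt$bbox[1]) * (vt$bbox[4] - vt$bbox[3])
  mean_density <- n / region_area
  seed <- is.finite(dens) & dens > delta * mean_density
  # merge adjacent seed cells into candidate objects
  labels <- integer(n)
  cur <- 0L
  for (i in which(seed)) {
    if (labels[i] != 0L) next
    cur <- cur + 1L
    stack <- i
    labels[i] <- cur
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      nb <- vt$neighbours[[v]]
      nb <- nb[seed[nb] & labels[nb] == 0L]
      labels[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  # annex border cells: adjacent to an object and above the hysteresis
  # threshold (half the seed factor, floored at the global mean)
  border_ok <- is.finite(dens) &
    dens > max(1, delta / 2) * mean_density & !seed
  repeat {
    grew <- FALSE
    for (i in which(labels > 0L)) {
      nb <- vt$neighbours[[i]]
      nb <- nb[border_ok[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- labels[i]
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  keep_rows <- list()
  relabel <- integer(cur)
  kept <- 0L
  for (k in seq_len(cur)) {
    idx <- which(labels == k)
    area <- convex_hull_area(xy[idx, , drop = FALSE])
    diam <- 2 * sqrt(area / pi)
    if (length(idx) >= min_locs && diam >= min_diameter) {
      kept <- kept + 1L
      relabel[k] <- kept
      keep_rows[[kept]] <- data.frame(
        cluster = kept, n_localizations = length(idx), area_nm2 = area,
        diameter_nm = diam, x = mean(xy[idx, 1]), y = mean(xy[idx, 2]))
    }
  }
  labels <- ifelse(labels > 0L, relabel[pmax(labels, 1L)], 0L)
  clusters <- if (kept) do.call(rbind, keep_rows) else
    data.frame(cluster = integer(0), n_localizations = integer(0),
               area_nm2 = numeric(0), diameter_nm = numeric(0),
               x = numeric(0), y = numeric(0))
  structure(list(density = dens, global_mean_density = mean_density,
                 seed = seed, cluster = labels, clusters = clusters,
                 areas = vt$areas, bbox = vt$bbox, delta = delta,
                 min_locs = min_locs, min_diameter = min_diameter),
            class = "voronoi_segmentation")
}
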