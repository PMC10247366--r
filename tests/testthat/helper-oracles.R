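# Independent brute-force oracles and small samplers used across tests.

# uniform points on a sphere surface
sample_sphere <- function(n, R = 10, center = c(0, 0, 0)) {
  z <- stats::runif(n, -1, 1)
  ph <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  sweep(R * cbind(s * cos(ph), s * sin(ph), z), 2, center, "+")
}

# geometric sphere fit by multi-start nonlinear least squares (oracle)
oracle_sphere_fit <- function(xyz, n_starts = 20) {
  obj <- function(p) {
    d <- sqrt(rowSums(sweep(xyz, 2, p[1:3])^2))
    sum((d - p[4])^2)
  }
  best <- NULL
  ctr <- colMeans(xyz)
  span <- max(apply(xyz, 2, function(v) diff(range(v))))
  for (s in seq_len(n_starts)) {
    p0 <- c(ctr + stats::rnorm(3, 0, span / 4),
            abs(stats::rnorm(1, span / 2, span / 4)) + 1e-3)
    o <- stats::optim(p0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(center = best$par[1:3], radius = best$par[4])
}

# connected components of d < cutoff by boolean transitive closure (oracle)
oracle_single_linkage <- function(d, cutoff) {
  n <- nrow(d)
  A <- (d < cutoff) | diag(n) > 0
  repeat {
    A2 <- (A %*% A) > 0
    if (all(A2 == A)) break
    A <- A2
  }
  labels <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      cur <- cur + 1L
      labels[A[i, ]] <- cur
    }
  }
  labels
}

# canonical form of a partition label vector (order of first appearance)
canon_labels <- function(l) {
  match(l, unique(l))
}

# brute-force DBSCAN oracle by density-reachability closure on <= 100 pts
oracle_dbscan <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  nb_count <- rowSums(d <= eps)        # includes self
  core <- nb_count >= min_pts
  # components of core points under mutual eps-reachability
  lab <- integer(n)
  cur <- 0L
  if (any(core)) {
    A <- (d <= eps) & outer(core, core, "&")
    diag(A) <- core
    repeat {
      A2 <- (A %*% A) > 0
      if (all(A2 == A)) break
      A <- A2
    }
    for (i in which(core)) {
      if (lab[i] == 0L) {
        cur <- cur + 1L
        lab[which(A[i, ])] <- cur
      }
    }
  }
  # border points: any core within eps; allowed set of clusters
  allowed <- lapply(seq_len(n), function(i) {
    if (core[i]) return(lab[i])
    unique(lab[core & d[i, ] <= eps])
  })
  list(core = core, core_labels = lab, allowed = allowed)
}

# merge sorted frame indices into runs, gaps <= tol bridged (oracle)
oracle_merge_runs <- function(idx, tol) {
  idx <- sort(unique(idx))
  out <- NULL
  start <- prev <- idx[1]
  for (v in idx[-1]) {
    if (v - prev > tol + 1) {
      out <- rbind(out, c(start, prev))
      start <- v
    }
    prev <- v
  }
  rbind(out, c(start, prev))
}

# square grid of k cluster centres for SMLM simulations
grid_centers <- function(k, spacing = 600) {
  side <- ceiling(sqrt(k))
  g <- expand.grid(x = (0:(side - 1)) * spacing,
                   y = (0:(side - 1)) * spacing)
  as.matrix(g[seq_len(k), ])
}
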