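#' Least-squares sphere fit of a membrane point cloud
#'
#' Fits a sphere to bead coordinates to quantify global membrane curvature,
#' the per-frame statistic used to follow bicelle-to-vesicle transitions.
#' An algebraic least-squares fit (linear in the sphere parameters) seeds a
#' geometric Gauss--Newton refinement that minimises the sum of squared
#' radial residuals.
#'
#' The signed mean curvature is `H_signed = orientation_sign / R`, positive
#' when the membrane bends away from the upper (cytosolic) leaflet, i.e.
#' when the fitted centre lies on the luminal side. When leaflet labels are
#' present the sign is inferred by comparing mean radial distances of the
#' two leaflets (the cytosolic leaflet of a vesicle is the outer one);
#' otherwise `+1` is assumed.
#'
#' Quasi-flat clouds (bicelles) have no finite best-fit radius; the radius
#' is capped at `r_cap` so that `|H_signed| <= 1/r_cap` and such frames
#' classify as non-vesicles.
#'
#' @param cloud a [point_cloud()] or an n x 3 coordinate matrix (nm).
#' @param bead_role optional role filter, e.g. `"headgroup"` to fit only
#'   headgroup marker beads.
#' @param r_cap radius cap for quasi-flat clouds, nm.
#' @return An object of class `sphere_fit` with fields `center`, `radius`,
#'   `rms_residual`, `H_signed` and `orientation_sign`.
#' @examples
#' th <- acos(runif(200, -1, 1)); ph <- runif(200, 0, 2 * pi)
#' xyz <- 10 * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
#' fit_sphere(xyz)$radius
#' @export
fit_sphere <- function(cloud, bead_role = NULL, r_cap = 1e4) {
  xyz <- cloud_coords(cloud, bead_role)
  n <- nrow(xyz)
  if (n < 4L)
    stop("sphere fit requires at least 4 points", call. = FALSE)
  ctr0 <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr0)
  sv <- svd(xc, nu = 0, nv = 0)$d
  coplanar <- sv[3] < 1e-9 * max(sv[1], .Machine$double.eps)

  flat_result <- function() {
    sgn <- sphere_orientation_sign(cloud, ctr0, flat = TRUE)
    new_sphere_fit(center = ctr0 - c(0, 0, sgn * r_cap), radius = r_cap,
                   rms = sphere_rms(xyz, ctr0 - c(0, 0, sgn * r_cap), r_cap),
                   sign = sgn)
  }
  if (coplanar) return(flat_result())

  # Algebraic (Coope) fit: |x|^2 = 2 c.x + (R^2 - |c|^2), linear LS.
  b <- rowSums(xc^2)
  A <- cbind(2 * xc, 1)
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(flat_result())
  ctr <- sol[1:3]
  r2 <- sol[4] + sum(ctr^2)
  if (!is.finite(r2) || r2 <= 0) return(flat_result())
  center <- ctr + ctr0
  radius <- sqrt(r2)

  # Geometric refinement on radial residuals; radius is profiled out.
  obj <- function(c3) {
    d <- sqrt(rowSums(sweep(xyz, 2, c3)^2))
    sum((d - mean(d))^2)
  }
  opt <- stats::optim(center, obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 200))
  center <- opt$par
  radius <- mean(sqrt(rowSums(sweep(xyz, 2, center)^2)))

  if (!is.finite(radius) || radius > r_cap) return(flat_result())
  # quasi-flat guard: when the best plane explains the cloud at least as
  # well as the best sphere, the curvature is not resolved -> capped R
  plane_rms <- sv[3] / sqrt(n)
  if (plane_rms <= sphere_rms(xyz, center, radius) * (1 + 1e-9))
    return(flat_result())
  sgn <- sphere_orientation_sign(cloud, center)
  new_sphere_fit(center, radius, sphere_rms(xyz, center, radius), sgn)
}

sphere_rms <- function(xyz, center, radius) {
  d <- sqrt(rowSums(sweep(xyz, 2, center)^2))
  sqrt(mean((d - radius)^2))
}

# +1 when the centre lies on the luminal side (upper leaflet is the outer
# one); for flat clouds the +z normal convention gives +1 by default.
sphere_orientation_sign <- function(cloud, center, flat = FALSE) {
  if (!inherits(cloud, "point_cloud")) return(1)
  up <- cloud$leaflet == "upper"
  lo <- cloud$leaflet == "lower"
  if (!any(up) || !any(lo)) return(1)
  if (flat) {
    # planar bilayer: upper leaflet should sit at larger z
    if (mean(cloud$coords[up, 3]) >= mean(cloud$coords[lo, 3])) 1 else -1
  } else {
    du <- sqrt(rowSums(sweep(cloud$coords[up, , drop = FALSE], 2, center)^2))
    dl <- sqrt(rowSums(sweep(cloud$coords[lo, , drop = FALSE], 2, center)^2))
    if (mean(du) >= mean(dl)) 1 else -1
  }
}

new_sphere_fit <- function(center, radius, rms, sign) {
  structure(list(center = as.numeric(center), radius = radius,
                 rms_residual = rms, H_signed = sign / radius,
                 orientation_sign = sign),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("sphere_fit: R = %.4g nm, H = %+.4g 1/nm, rms = %.3g nm\n",
              x$radius, x$H_signed, x$rms_residual))
  invisible(x)
}

#' Rasterise a point cloud into a Monge height field z(x, y)
#'
#' Bins bead coordinates on a regular x--y lattice and records the mean z
#' per bin, producing the height function required for Monge-representation
#' curvature analysis of buckled or flat membranes. Isolated empty bins are
#' filled by averaging populated 4-neighbours (at least two required);
#' remaining empty bins stay masked and are excluded from derivatives.
#'
#' @param cloud a [point_cloud()] or n x 3 matrix (nm).
#' @param spacing lattice spacing in nm.
#' @param bead_role optional role filter.
#' @param smooth_sd optional Gaussian smoothing bandwidth (nm) applied to
#'   the gridded heights; recorded in the result's provenance.
#' @param periodic logical flags for the x and y axes (taken from the cloud
#'   when it carries them). For periodic axes the lattice covers the full
#'   box dimension.
#' @return An object of class `height_field`: matrix `z` (nx rows = x,
#'   ny cols = y), logical `mask` of populated nodes, `spacing`, node
#'   coordinates `x`, `y`, and `periodic` flags.
#' @export
height_field_from_cloud <- function(cloud, spacing, bead_role = NULL,
                                    smooth_sd = NULL, periodic = NULL) {
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("'spacing' must be a positive number", call. = FALSE)
  xyz <- cloud_coords(cloud, bead_role)
  if (is.null(periodic)) {
    periodic <- if (inherits(cloud, "point_cloud")) cloud$periodic[1:2]
                else c(FALSE, FALSE)
  }
  periodic <- rep_len(as.logical(periodic), 2L)
  box <- if (inherits(cloud, "point_cloud")) cloud$box else NULL

  rng_axis <- function(k) {
    if (periodic[k] && !is.null(box)) c(0, box[k]) else range(xyz[, k])
  }
  rx <- rng_axis(1); ry <- rng_axis(2)
  nx <- max(1L, ceiling((rx[2] - rx[1]) / spacing - 1e-9))
  ny <- max(1L, ceiling((ry[2] - ry[1]) / spacing - 1e-9))
  if (nx < 3L || ny < 3L)
    stop("cloud must span at least 3x3 bins in x-y at this spacing",
         call. = FALSE)
  ix <- pmin(nx, pmax(1L, 1L + floor((xyz[, 1] - rx[1]) / spacing)))
  iy <- pmin(ny, pmax(1L, 1L + floor((xyz[, 2] - ry[1]) / spacing)))
  idx <- (iy - 1L) * nx + ix
  zsum <- numeric(nx * ny); cnt <- numeric(nx * ny)
  tz <- tapply(xyz[, 3], idx, mean)
  z <- matrix(NA_real_, nx, ny)
  z[as.integer(names(tz))] <- tz
  mask <- !is.na(z)
  if (mean(!mask) > 0.5)
    stop("degenerate coverage: more than 50% of bins are empty",
         call. = FALSE)

  # fill isolated holes from populated 4-neighbours (>= 2 required)
  if (any(!mask)) {
    holes <- which(!mask, arr.ind = TRUE)
    shift <- function(i, n, d, per) {
      j <- i + d
      if (per) ((j - 1L) %% n) + 1L else j
    }
    for (r in seq_len(nrow(holes))) {
      i <- holes[r, 1]; j <- holes[r, 2]
      nb <- c()
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- shift(i, nx, d[1], periodic[1])
        jj <- shift(j, ny, d[2], periodic[2])
        if (ii >= 1L && ii <= nx && jj >= 1L && jj <= ny && mask[ii, jj])
          nb <- c(nb, z[ii, jj])
      }
      if (length(nb) >= 2L) {
        z[i, j] <- mean(nb)
        mask[i, j] <- TRUE
      }
    }
  }
  if (!is.null(smooth_sd) && smooth_sd > 0)
    z <- gauss_smooth_grid(z, mask, smooth_sd / spacing, periodic)

  structure(list(z = z, mask = mask, spacing = spacing,
                 x = rx[1] + (seq_len(nx) - 0.5) * spacing,
                 y = ry[1] + (seq_len(ny) - 0.5) * spacing,
                 periodic = periodic,
                 provenance = list(spacing = spacing,
                                   smooth_sd = smooth_sd %||% 0)),
            class = "height_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a height field from a precomputed grid
#'
#' Builds a `height_field` directly from a matrix of heights, e.g. an
#' analytic surface evaluated on a lattice, bypassing the binning of
#' [height_field_from_cloud()].
#'
#' @param z matrix of heights, nm; rows index x, columns y.
#' @param spacing lattice spacing, nm.
#' @param x0,y0 coordinates of the first node.
#' @param periodic logical flags for the x and y axes.
#' @return An object of class `height_field`.
#' @export
height_field <- function(z, spacing, x0 = 0, y0 = 0,
                         periodic = c(FALSE, FALSE)) {
  z <- as.matrix(z)
  if (!is.numeric(spacing) || spacing <= 0)
    stop("'spacing' must be positive", call. = FALSE)
  periodic <- rep_len(as.logical(periodic), 2L)
  structure(list(z = z, mask = is.finite(z), spacing = spacing,
                 x = x0 + (seq_len(nrow(z)) - 1) * spacing,
                 y = y0 + (seq_len(ncol(z)) - 1) * spacing,
                 periodic = periodic,
                 provenance = list(spacing = spacing, smooth_sd = 0)),
            class = "height_field")
}

# separable Gaussian smoothing on the grid, NA-aware
gauss_smooth_grid <- function(z, mask, sd_bins, periodic) {
  half <- max(1L, ceiling(3 * sd_bins))
  w <- stats::dnorm(-half:half, sd = sd_bins)
  zs <- z; zs[!mask] <- 0
  ms <- matrix(as.numeric(mask), nrow(z), ncol(z))
  conv_axis <- function(m, along, per) {
    out <- matrix(0, nrow(m), ncol(m))
    n <- if (along == 1) nrow(m) else ncol(m)
    for (k in -half:half) {
      wt <- w[k + half + 1]
      idx <- seq_len(n) + k
      if (per) idx <- ((idx - 1L) %% n) + 1L else idx[idx < 1 | idx > n] <- NA
      keep <- !is.na(idx)
      if (along == 1) out[keep, ] <- out[keep, ] + wt * m[idx[keep], ]
      else out[, keep] <- out[, keep] + wt * m[, idx[keep]]
    }
    out
  }
  num <- conv_axis(conv_axis(zs, 1, periodic[1]), 2, periodic[2])
  den <- conv_axis(conv_axis(ms, 1, periodic[1]), 2, periodic[2])
  out <- num / den
  out[!mask] <- NA_real_
  out
}

#' Monge-representation curvature of a height field
#'
#' Computes local principal curvatures k1, k2, the mean curvature H and the
#' Gaussian curvature K_G at every interior (or periodic-wrapped) node of a
#' height field, using central finite differences for the derivatives of
#' z(x, y):
#' \deqn{H = \frac{(1+z_y^2) z_{xx} - 2 z_x z_y z_{xy} + (1+z_x^2) z_{yy}}
#'            {2 (1+z_x^2+z_y^2)^{3/2}}, \quad
#'       K_G = \frac{z_{xx} z_{yy} - z_{xy}^2}{(1+z_x^2+z_y^2)^2}.}
#' The principal curvatures are \eqn{k_{1,2} = H \pm \sqrt{H^2 - K_G}}, the
#' radicand clamped at zero when within -1e-9 of it. Nodes lacking a full
#' difference stencil (grid boundary on non-periodic axes, or masked
#' neighbours) are masked in the output.
#'
#' @param field a [height_field_from_cloud()] result.
#' @return An object of class `curvature_field` with matrices `k1`, `k2`,
#'   `H`, `K_G` and a validity `mask`, plus the node coordinates.
#' @export
monge_curvature <- function(field) {
  stopifnot(inherits(field, "height_field"))
  z <- field$z; h <- field$spacing
  nx <- nrow(z); ny <- ncol(z)
  per <- field$periodic
  pad <- function(i, n, per) if (per) ((i - 1L) %% n) + 1L else i

  ip <- pad(seq_len(nx) + 1L, nx, per[1]); im <- pad(seq_len(nx) - 1L, nx, per[1])
  jp <- pad(seq_len(ny) + 1L, ny, per[2]); jm <- pad(seq_len(ny) - 1L, ny, per[2])
  okx <- ip >= 1L & ip <= nx & im >= 1L & im <= nx
  oky <- jp >= 1L & jp <= ny & jm >= 1L & jm <= ny
  # out-of-range indices clamped; their nodes are masked below
  ipc <- pmin(nx, pmax(1L, ip)); imc <- pmin(nx, pmax(1L, im))
  jpc <- pmin(ny, pmax(1L, jp)); jmc <- pmin(ny, pmax(1L, jm))

  zx  <- (z[ipc, ] - z[imc, ]) / (2 * h)
  zy  <- (z[, jpc] - z[, jmc]) / (2 * h)
  zxx <- (z[ipc, ] - 2 * z + z[imc, ]) / h^2
  zyy <- (z[, jpc] - 2 * z + z[, jmc]) / h^2
  zxy <- (z[ipc, jpc] - z[ipc, jmc] - z[imc, jpc] + z[imc, jmc]) / (4 * h^2)

  g <- 1 + zx^2 + zy^2
  H <- ((1 + zy^2) * zxx - 2 * zx * zy * zxy + (1 + zx^2) * zyy) /
    (2 * g^1.5)
  K <- (zxx * zyy - zxy^2) / g^2
  disc <- H^2 - K
  disc[disc < 0 & disc > -1e-9] <- 0
  s <- sqrt(disc)
  k1 <- H + s; k2 <- H - s

  mask <- field$mask & outer(okx, oky, "&") &
    field$mask[ipc, ] & field$mask[imc, ] &
    field$mask[, jpc] & field$mask[, jmc] &
    field$mask[ipc, jpc] & field$mask[ipc, jmc] &
    field$mask[imc, jpc] & field$mask[imc, jmc] &
    is.finite(H) & is.finite(K)
  H[!mask] <- NA_real_; K[!mask] <- NA_real_
  k1[!mask] <- NA_real_; k2[!mask] <- NA_real_
  structure(list(k1 = k1, k2 = k2, H = H, K_G = K, mask = mask,
                 x = field$x, y = field$y, spacing = field$spacing,
                 periodic = per),
            class = "curvature_field")
}

#' Classify a bicelle-to-vesicle transition from a curvature time series
#'
#' A vesicle has formed at the first time point where the absolute signed
#' mean curvature strictly exceeds `threshold`; a replicate whose series
#' never crosses is right-censored at the horizon.
#'
#' @param time monotone increasing times, ns.
#' @param H signed mean curvature series, 1/nm.
#' @param threshold vesicle curvature threshold, 1/nm (strict `>`).
#' @param horizon observation horizon, ns; defaults to the last time point.
#' @param replicate optional replicate identifier.
#' @param temperature simulation temperature, K.
#' @return An object of class `transition_record` with `censored`,
#'   `waiting_time` (NA when censored), `horizon`, `threshold_used`,
#'   `replicate` and `temperature`.
#' @export
classify_transition <- function(time, H, threshold = 0.15, horizon = NULL,
                                replicate = NA, temperature = 300) {
  time <- as.numeric(time); H <- as.numeric(H)
  if (length(time) == 0L || length(H) == 0L)
    stop("empty curvature series", call. = FALSE)
  if (length(time) != length(H))
    stop("'time' and 'H' lengths differ", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE))
    stop("'time' must be strictly increasing", call. = FALSE)
  if (is.null(horizon)) horizon <- time[length(time)]
  hit <- which(abs(H) > threshold)
  if (length(hit)) {
    t0 <- time[hit[1]]
    structure(list(censored = FALSE, waiting_time = t0, horizon = horizon,
                   threshold_used = threshold, replicate = replicate,
                   temperature = temperature),
              class = "transition_record")
  } else {
    structure(list(censored = TRUE, waiting_time = NA_real_,
                   horizon = horizon, threshold_used = threshold,
                   replicate = replicate, temperature = temperature),
              class = "transition_record")
  }
}

# bilinear interpolation of a curvature-field matrix at (x, y) positions;
# returns NA outside a non-periodic field
interp_field <- function(m, fx, fy, spacing, periodic, x, y) {
  nx <- nrow(m); ny <- ncol(m)
  gx <- (x - fx[1]) / spacing + 1
  gy <- (y - fy[1]) / spacing + 1
  wrap <- function(g, n, per) {
    if (per) ((g - 1) %% n) + 1 else g
  }
  gx <- wrap(gx, nx, periodic[1]); gy <- wrap(gy, ny, periodic[2])
  i0 <- floor(gx); j0 <- floor(gy)
  tx <- gx - i0; ty <- gy - j0
  idx <- function(i, n, per) if (per) ((i - 1) %% n) + 1 else i
  i1 <- idx(i0 + 1, nx, periodic[1]); i0 <- idx(i0, nx, periodic[1])
  j1 <- idx(j0 + 1, ny, periodic[2]); j0 <- idx(j0, ny, periodic[2])
  out <- rep(NA_real_, length(x))
  ok <- i0 >= 1 & i1 <= nx & i1 >= 1 & i0 <= nx &
        j0 >= 1 & j1 <= ny & j1 >= 1 & j0 <= ny
  ok[is.na(ok)] <- FALSE
  if (any(ok)) {
    f <- function(i, j) m[cbind(i[ok], j[ok])]
    v00 <- f(i0, j0); v10 <- f(i1, j0); v01 <- f(i0, j1); v11 <- f(i1, j1)
    out[ok] <- (1 - tx[ok]) * (1 - ty[ok]) * v00 + tx[ok] * (1 - ty[ok]) * v10 +
      (1 - tx[ok]) * ty[ok] * v01 + tx[ok] * ty[ok] * v11
  }
  out
}

#' Curvature sampled by embedded proteins
#'
#' Looks up the local mean curvature under protein positions across frames
#' (bilinear interpolation on the curvature field) and summarises the
#' curvature occupancy: a histogram of sampled H values and the
#' occupancy-weighted mean. Used to ask whether proteins prefer particular
#' curvatures on a buckled membrane.
#'
#' @param protein_xy matrix with columns x, y (nm): one row per
#'   (protein, frame) sample.
#' @param curvature a [monge_curvature()] result.
#' @param breaks histogram bin edges in 1/nm, or a bin count.
#' @return An object of class `curvature_occupancy`: `samples` (H per
#'   sample), `histogram`, `mean_H` (occupancy-weighted), `n_samples`,
#'   `n_dropped` (positions outside a non-periodic field or on masked
#'   nodes).
#' @export
curvature_preference <- function(protein_xy, curvature, breaks = 25) {
  stopifnot(inherits(curvature, "curvature_field"))
  xy <- as.matrix(protein_xy)
  if (ncol(xy) < 2L) stop("'protein_xy' needs x and y columns", call. = FALSE)
  Hs <- interp_field(curvature$H, curvature$x, curvature$y,
                     curvature$spacing, curvature$periodic,
                     xy[, 1], xy[, 2])
  dropped <- sum(is.na(Hs))
  Hok <- Hs[!is.na(Hs)]
  if (!length(Hok))
    stop("no protein positions fall inside the curvature field",
         call. = FALSE)
  h <- graphics::hist(Hok, breaks = breaks, plot = FALSE)
  structure(list(samples = Hok, histogram = h, mean_H = mean(Hok),
                 n_samples = length(Hok), n_dropped = dropped),
            class = "curvature_occupancy")
}
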