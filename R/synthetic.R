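# Seeded generators for every pipeline stage. Each generator sets the RNG
# from its `seed` argument inside a local RNG scope and returns its ground
# truth alongside the data, so recovery tests compare against emitted
# truth rather than hard-coded numbers.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Synthetic membrane point clouds with known curvature
#'
#' Samples bead positions uniformly from an analytic surface and adds
#' isotropic Gaussian noise, together with the surface's exact curvature:
#' sphere of radius R (`H = 1/R`), flat disc (`H = 0`), sinusoidal buckle
#' `z = A sin(2 pi x / lambda)` (closed-form crest curvature
#' `A (2 pi / lambda)^2 / 2`), or tubule (cylinder) of radius r
#' (`|H| = 1/(2 r)`). Spheres are emitted as two concentric leaflet shells
#' (upper = outer) separated by `leaflet_offset` so that orientation-aware
#' fits see a bilayer.
#'
#' @param shape `"sphere"`, `"disc"`, `"buckle"` or `"tubule"`.
#' @param n number of beads.
#' @param noise_sd isotropic Gaussian noise, nm.
#' @param seed RNG seed.
#' @param R sphere radius, nm.
#' @param disc_radius flat disc radius, nm.
#' @param A,lambda,width buckle amplitude, wavelength and y-extent, nm.
#' @param r,length tubule radius and length, nm (defaults mimic a
#'   ~14 nm diameter, ~100 nm long membrane tubule).
#' @param leaflet_offset half bilayer thickness for sphere shells, nm.
#' @return A [point_cloud()] with attribute `"truth"`: list with the shape
#'   parameters and analytic `H` (and `K_G` where defined).
#' @export
gen_membrane <- function(shape = c("sphere", "disc", "buckle", "tubule"),
                         n = 1000, noise_sd = 0, seed = 1,
                         R = 10, disc_radius = 20,
                         A = 5, lambda = 57, width = 28,
                         r = 7, length = 100, leaflet_offset = 1) {
  shape <- match.arg(shape)
  with_seed(seed, {
    noise <- function(m) m + matrix(stats::rnorm(3 * nrow(m), 0, noise_sd),
                                    ncol = 3)
    if (shape == "sphere") {
      n_up <- ceiling(n / 2); n_lo <- n - n_up
      sph <- function(k, rad) {
        z <- stats::runif(k, -1, 1); ph <- stats::runif(k, 0, 2 * pi)
        s <- sqrt(1 - z^2)
        rad * cbind(s * cos(ph), s * sin(ph), z)
      }
      xyz <- rbind(sph(n_up, R + leaflet_offset),
                   sph(n_lo, R - leaflet_offset))
      cl <- point_cloud(noise(xyz),
                        leaflet = rep(c("upper", "lower"), c(n_up, n_lo)),
                        bead_role = "headgroup")
      truth <- list(shape = "sphere", R = R, H = 1 / R, K_G = 1 / R^2)
    } else if (shape == "disc") {
      rr <- disc_radius * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      xyz <- cbind(rr * cos(th), rr * sin(th), 0)
      cl <- point_cloud(noise(xyz), bead_role = "headgroup")
      truth <- list(shape = "disc", radius = disc_radius, H = 0, K_G = 0)
    } else if (shape == "buckle") {
      x <- stats::runif(n, 0, lambda)
      y <- stats::runif(n, 0, width)
      z <- A * sin(2 * pi * x / lambda)
      cl <- point_cloud(noise(cbind(x, y, z)), bead_role = "headgroup",
                        box = c(lambda, width, 4 * A + 1),
                        periodic = c(TRUE, TRUE, FALSE))
      truth <- list(shape = "buckle", A = A, lambda = lambda,
                    H_crest = A * (2 * pi / lambda)^2 / 2,
                    k1_crest = A * (2 * pi / lambda)^2, K_G = 0)
    } else {
      x <- stats::runif(n, 0, length)
      th <- stats::runif(n, 0, 2 * pi)
      xyz <- cbind(x, r * cos(th), r * sin(th))
      cl <- point_cloud(noise(xyz), bead_role = "headgroup")
      truth <- list(shape = "tubule", r = r, length = length,
                    H = 1 / (2 * r), K_G = 0)
    }
    attr(cl, "truth") <- truth
    cl
  })
}

#' Synthetic vesiculation waiting times (shifted exponential)
#'
#' Draws waiting times `t = tau + Exp(k_prime)`; draws exceeding the
#' horizon are recorded as censored.
#'
#' @param k_prime Poisson rate, 1/ns.
#' @param tau lag time, ns.
#' @param n number of replicates.
#' @param horizon observation horizon, ns (`Inf` for no censoring).
#' @param seed RNG seed.
#' @param temperature,label carried into the sample.
#' @return A [waiting_time_sample()] with attribute `"truth"`.
#' @export
gen_waiting_times <- function(k_prime, tau = 0, n = 100, horizon = Inf,
                              seed = 1, temperature = 300, label = "") {
  if (k_prime <= 0 || tau < 0) stop("need k_prime > 0 and tau >= 0",
                                    call. = FALSE)
  if (n <= 0) stop("'n' must be positive", call. = FALSE)
  with_seed(seed, {
    t <- tau + stats::rexp(n, rate = k_prime)
    cen <- t > horizon
    s <- waiting_time_sample(t[!cen], rep(horizon, sum(cen)),
                             temperature = temperature, label = label)
    attr(s, "truth") <- list(k_prime = k_prime, tau = tau,
                             k_overall = 1 / (1 / k_prime + tau),
                             horizon = horizon, n = n)
    s
  })
}

#' Synthetic protein trajectory with optional aggregation and budding
#'
#' Emulates the nine-protein experiment: proteins start on a square grid
#' with 10 nm nearest-neighbour spacing, diffuse in the membrane plane
#' (2D Brownian motion with periodic wrapping), and optionally coalesce
#' toward a common point after `t_aggregate` and bud after `t_bud`
#' (the box width contracts by 10% and clustered proteins rise above the
#' membrane). Two ubiquitin beads per protein (K160- and K264-linked) ride
#' at fixed offsets from the COM for contact analysis.
#'
#' @param n_proteins number of proteins (a perfect-square grid is used).
#' @param box box dimensions, nm.
#' @param grid_spacing nearest-neighbour spacing of the start grid, nm.
#' @param diffusion_coeff lateral diffusion coefficient, nm^2/ns.
#' @param n_frames,dt number of frames and frame spacing, ns.
#' @param t_aggregate time after which proteins coalesce (NA = never), ns.
#' @param t_bud time after which the budding signature appears (NA =
#'   never), ns.
#' @param seed RNG seed.
#' @return A list of [protein_frame()] objects with attribute `"truth"`.
#' @export
gen_trajectory <- function(n_proteins = 9, box = c(30, 30, 20),
                           grid_spacing = 10, diffusion_coeff = 0.01,
                           n_frames = 200, dt = 10, t_aggregate = NA,
                           t_bud = NA, seed = 1) {
  side <- round(sqrt(n_proteins))
  if (side^2 != n_proteins)
    stop("'n_proteins' must be a perfect square for the start grid",
         call. = FALSE)
  if ((side - 1) * grid_spacing > min(box[1:2]))
    stop("box too small for the start grid", call. = FALSE)
  with_seed(seed, {
    off <- (box[1:2] - (side - 1) * grid_spacing) / 2
    gx <- rep(seq_len(side) - 1, side) * grid_spacing + off[1]
    gy <- rep(seq_len(side) - 1, each = side) * grid_spacing + off[2]
    pos <- cbind(gx, gy)
    z0 <- 0
    sd_step <- sqrt(2 * diffusion_coeff * dt)
    ub_off <- list(K160 = c(0.4, 0, 0.8), K264 = c(-0.4, 0, 0.8))
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      t_now <- (f - 1) * dt
      lx <- box[1]
      zvec <- rep(z0, n_proteins)
      budding_now <- !is.na(t_bud) && t_now >= t_bud
      if (budding_now) {
        lx <- 0.9 * box[1]
        zvec <- zvec + 4   # proteins ride up the bud
      }
      ub <- do.call(rbind, lapply(seq_len(n_proteins), function(i) {
        do.call(rbind, lapply(names(ub_off), function(a) {
          o <- ub_off[[a]]
          data.frame(mol = i, res = if (a == "K160") 160L else 264L,
                     attachment = a, x = pos[i, 1] + o[1],
                     y = pos[i, 2] + o[2], z = zvec[i] + o[3])
        }))
      }))
      frames[[f]] <- protein_frame(
        com = cbind(pos, zvec), box = c(lx, box[2], box[3]), time = t_now,
        z_membrane = c(-2, 2), ub_beads = ub,
        periodic = c(TRUE, TRUE, FALSE))
      # propagate positions to the next frame: diffusion, then the
      # coalescence pull once aggregation has started
      pos <- pos + matrix(stats::rnorm(2 * n_proteins, 0, sd_step), ncol = 2)
      if (!is.na(t_aggregate) && t_now >= t_aggregate) {
        target <- box[1:2] / 2
        pos <- pos + 0.25 * sweep(-pos, 2, -target)
      }
      pos[, 1] <- pos[, 1] %% box[1]
      pos[, 2] <- pos[, 2] %% box[2]
    }
    attr(frames, "truth") <- list(n_proteins = n_proteins,
                                  grid_spacing = grid_spacing,
                                  t_aggregate = t_aggregate, t_bud = t_bud,
                                  diffusion_coeff = diffusion_coeff, dt = dt)
    frames
  })
}

#' Ground truth for a synthetic DNA-PAINT acquisition
#'
#' @param centers matrix of cluster centres (nm), one row per cluster.
#' @param n_strands docking strands per cluster (recycled).
#' @param k_on_c per-strand binding rate `k_on * c`, 1/s.
#' @param bright_mean mean bright (bound) time, s.
#' @param sigma_loc localization noise, nm.
#' @param background_rate background localizations per frame over the
#'   whole field.
#' @param frames,frame_rate acquisition length and rate (defaults: 20000
#'   frames at 10 Hz).
#' @param fiducials optional matrix of fiducial positions (nm).
#' @param field field-of-view `c(xmin, xmax, ymin, ymax)`, nm.
#' @return A list of class `smlm_ground_truth`.
#' @export
smlm_ground_truth <- function(centers, n_strands = 1, k_on_c = 0.01,
                              bright_mean = 0.4, sigma_loc = 10,
                              background_rate = 0, frames = 20000,
                              frame_rate = 10, fiducials = NULL,
                              field = NULL) {
  centers <- as.matrix(centers)
  if (nrow(centers) == 0L) stop("empty ground truth", call. = FALSE)
  n_strands <- rep_len(as.integer(n_strands), nrow(centers))
  if (k_on_c <= 0 || bright_mean <= 0)
    stop("rates must be positive", call. = FALSE)
  expected_events <- frames / frame_rate * k_on_c
  if (expected_events < 2)
    stop("kinetics too slow: fewer than 2 expected events per strand",
         call. = FALSE)
  if (is.null(field))
    field <- c(min(centers[, 1]) - 200, max(centers[, 1]) + 200,
               min(centers[, 2]) - 200, max(centers[, 2]) + 200)
  structure(list(centers = centers, n_strands = n_strands, k_on_c = k_on_c,
                 bright_mean = bright_mean, sigma_loc = sigma_loc,
                 background_rate = background_rate, frames = frames,
                 frame_rate = frame_rate, fiducials = fiducials,
                 field = field),
            class = "smlm_ground_truth")
}

#' Simulate a DNA-PAINT localization table
#'
#' Each docking strand alternates exponentially distributed dark
#' (`Exp(k_on_c)`) and bright (`Exp(1/bright_mean)`) intervals over the
#' acquisition. A strand is bright in a frame when its bright interval
#' overlaps the frame window; bright episodes shorter than half a frame
#' are dropped (finite camera integration). Every bright frame of a strand
#' yields one localization at the cluster centre plus Gaussian
#' `sigma_loc` displacement, with plausible PSF width, photon and
#' precision columns. Fiducials emit in every frame; background
#' localizations are homogeneous Poisson over the field.
#'
#' @param truth an [smlm_ground_truth()].
#' @param seed RNG seed.
#' @return A [localization_table()] with extra columns `origin`
#'   (`"cluster"`, `"fiducial"` or `"background"`) and `truth_cluster`
#'   (cluster index, NA otherwise), and attribute `"truth"`.
#' @export
gen_smlm <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "smlm_ground_truth"))
  with_seed(seed, {
    total_time <- truth$frames / truth$frame_rate
    dt <- 1 / truth$frame_rate
    rows <- list()
    for (ci in seq_len(nrow(truth$centers))) {
      bright_frames <- integer(0)
      for (s in seq_len(truth$n_strands[ci])) {
        bright_frames <- c(bright_frames,
                           strand_bright_frames(truth$k_on_c,
                                                truth$bright_mean,
                                                total_time, dt,
                                                truth$frames))
      }
      if (!length(bright_frames)) next
      k <- length(bright_frames)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = bright_frames,
        x = truth$centers[ci, 1] + stats::rnorm(k, 0, truth$sigma_loc),
        y = truth$centers[ci, 2] + stats::rnorm(k, 0, truth$sigma_loc),
        origin = "cluster", truth_cluster = ci)
    }
    if (!is.null(truth$fiducials)) {
      fid <- as.matrix(truth$fiducials)
      for (fi in seq_len(nrow(fid))) {
        rows[[length(rows) + 1L]] <- data.frame(
          frame = seq_len(truth$frames) - 1L,
          x = fid[fi, 1] + stats::rnorm(truth$frames, 0, 1),
          y = fid[fi, 2] + stats::rnorm(truth$frames, 0, 1),
          origin = "fiducial", truth_cluster = NA_integer_)
      }
    }
    if (truth$background_rate > 0) {
      nb <- stats::rpois(1, truth$background_rate * truth$frames)
      if (nb > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          frame = sample.int(truth$frames, nb, replace = TRUE) - 1L,
          x = stats::runif(nb, truth$field[1], truth$field[2]),
          y = stats::runif(nb, truth$field[3], truth$field[4]),
          origin = "background", truth_cluster = NA_integer_)
      }
    }
    if (!length(rows)) stop("simulation produced no localizations",
                            call. = FALSE)
    df <- do.call(rbind, rows)
    n <- nrow(df)
    fw <- 330 * exp(stats::rnorm(n, 0, 0.05))
    df$fwhm_x <- fw * exp(stats::rnorm(n, 0, 0.03))
    df$fwhm_y <- fw * exp(stats::rnorm(n, 0, 0.03))
    df$photons <- round(5000 * exp(stats::rnorm(n, 0, 0.3)))
    df$precision <- pmin(49, truth$sigma_loc * exp(stats::rnorm(n, 0, 0.2)))
    df <- df[order(df$frame), ]
    rownames(df) <- NULL
    out <- localization_table(df)
    attr(out, "truth") <- truth
    out
  })
}

# frames (0-based) in which one strand is bright
strand_bright_frames <- function(k_on_c, bright_mean, total_time, dt,
                                 n_frames) {
  t <- 0
  out <- integer(0)
  repeat {
    t <- t + stats::rexp(1, rate = k_on_c)       # dark interval
    if (t >= total_time) break
    b <- stats::rexp(1, rate = 1 / bright_mean)  # bright interval
    t_end <- min(t + b, total_time)
    if (t_end - t >= dt / 2) {                   # camera integration floor
      f0 <- floor(t / dt)
      f1 <- min(floor((t_end - 1e-12) / dt), n_frames - 1L)
      if (f1 >= f0) out <- c(out, f0:f1)
    }
    t <- t + b
    if (t >= total_time) break
  }
  unique(out)
}
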