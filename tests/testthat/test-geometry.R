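test_that("sphere fit is exact on noiseless spheres of any radius and center", {
  set.seed(1)
  for (R in c(2, 6, 10, 47, 100)) {
    ctr <- stats::runif(3, -50, 50)
    xyz <- sample_sphere(400, R, ctr)
    f <- fit_sphere(xyz)
    expect_lt(abs(f$radius - R) / R, 1e-9)
    expect_lt(f$rms_residual, 1e-9)
    expect_lt(abs(abs(f$H_signed) - 1 / R) / (1 / R), 1e-8)
  }
})

test_that("sphere fit on noisy data matches a multi-start NLS oracle", {
  set.seed(2)
  xyz <- sample_sphere(500, 6) + matrix(stats::rnorm(1500, 0, 0.1), ncol = 3)
  f <- fit_sphere(xyz)
  expect_lt(abs(f$radius - 6), 0.05)
  o <- oracle_sphere_fit(xyz)
  expect_lt(abs(f$radius - o$radius), 1e-4)
  expect_lt(max(abs(f$center - o$center)), 1e-3)
})

test_that("flat and coplanar clouds report the capped radius, not an error", {
  set.seed(3)
  rr <- 20 * sqrt(stats::runif(500)); th <- stats::runif(500, 0, 2 * pi)
  disc <- cbind(rr * cos(th), rr * sin(th), 0)
  f <- fit_sphere(disc)
  expect_equal(f$radius, 1e4)
  expect_lte(abs(f$H_signed), 1e-4)
  # slightly noisy quasi-flat disc also capped
  f2 <- fit_sphere(disc + matrix(stats::rnorm(1500, 0, 0.01), ncol = 3))
  expect_lte(abs(f2$H_signed), 1e-4)
  expect_error(fit_sphere(disc[1:3, ]), "at least 4")
})

test_that("sphere orientation sign follows the leaflet labels", {
  set.seed(4)
  out_shell <- sample_sphere(300, 11)
  in_shell <- sample_sphere(300, 9)
  cl <- point_cloud(rbind(out_shell, in_shell),
                    leaflet = rep(c("upper", "lower"), each = 300))
  expect_gt(fit_sphere(cl)$H_signed, 0)
  cl_flip <- point_cloud(rbind(out_shell, in_shell),
                         leaflet = rep(c("lower", "upper"), each = 300))
  expect_lt(fit_sphere(cl_flip)$H_signed, 0)
})

test_that("height field reproduces plane, linear, and sinusoidal surfaces", {
  set.seed(5)
  xy <- cbind(stats::runif(4000, 0, 20), stats::runif(4000, 0, 20))
  hf <- height_field_from_cloud(cbind(xy, 3), spacing = 1)
  expect_true(all(abs(hf$z[hf$mask] - 3) < 1e-12))
  # z = x: node values within half-spacing of node x
  hf2 <- height_field_from_cloud(cbind(xy, xy[, 1]), spacing = 1)
  err <- abs(sweep(hf2$z, 1, hf2$x))
  expect_lt(max(err[hf2$mask]), 0.5)
  # dense sinusoid sampled on a regular sub-grid (16 points per nm^2,
  # four sample columns per bin so bin means sit at bin centres)
  gxy <- as.matrix(expand.grid(x = seq(0.125, 56.875, by = 0.25),
                               y = seq(0.125, 27.875, by = 0.25)))
  z <- 5 * sin(2 * pi * gxy[, 1] / 57)
  cl3 <- point_cloud(cbind(gxy, z), box = c(57, 28, 12),
                     periodic = c(TRUE, TRUE, FALSE))
  hf3 <- height_field_from_cloud(cl3, spacing = 1)
  ref <- 5 * sin(2 * pi * outer(hf3$x, rep(1, length(hf3$y))) / 57)
  expect_lt(max(abs(hf3$z - ref)[hf3$mask]), 0.05)
  expect_error(height_field_from_cloud(cbind(xy, 0), spacing = -1),
               "positive")
})

test_that("Monge curvature matches closed forms for plane, sphere cap, buckle", {
  # plane
  hp <- height_field(matrix(2, 20, 20), 1)
  cp <- monge_curvature(hp)
  expect_true(all(abs(cp$H[cp$mask]) < 1e-12))
  expect_true(all(abs(cp$K_G[cp$mask]) < 1e-12))
  # sphere cap, R = 20, apex region
  R <- 20; h <- 0.2
  xs <- seq(-4, 4, by = h)
  zc <- outer(xs, xs, function(x, y) sqrt(R^2 - x^2 - y^2))
  cc <- monge_curvature(height_field(zc, h, x0 = -4, y0 = -4))
  apex <- which.min(abs(xs))
  expect_lt(abs(abs(cc$H[apex, apex]) - 1 / R) / (1 / R), 0.02)
  expect_lt(abs(cc$K_G[apex, apex] - 1 / R^2) / (1 / R^2), 0.02)
  # sinusoidal buckle, periodic, crest
  lam <- 57; A <- 5; hs <- 0.5
  x <- seq(0, lam - hs, by = hs); y <- seq(0, 28 - hs, by = hs)
  zb <- outer(x, y, function(x, y) A * sin(2 * pi * x / lam))
  cb <- monge_curvature(height_field(zb, hs, periodic = c(TRUE, TRUE)))
  crest <- which.min(abs(x - lam / 4))
  k1_true <- A * (2 * pi / lam)^2
  expect_lt(abs(cb$k1[crest, 5]), 1e-12)  # flat direction along the ridge
  expect_lt(abs(abs(cb$k2[crest, 5]) - k1_true) / k1_true, 0.02)
  expect_lt(abs(abs(cb$H[crest, 5]) - k1_true / 2) / (k1_true / 2), 0.02)
  # crest |H| lies inside the +-0.05 1/nm curvature-sensing range
  expect_lt(abs(cb$H[crest, 5]), 0.05)
})

test_that("curvature field satisfies its algebraic invariants", {
  set.seed(6)
  z <- matrix(stats::rnorm(900, 0, 0.5), 30, 30)
  cf <- monge_curvature(height_field(z, 1))
  m <- cf$mask
  expect_lt(max(abs(cf$k1[m] * cf$k2[m] - cf$K_G[m])), 1e-9)
  expect_lt(max(abs((cf$k1[m] + cf$k2[m]) / 2 - cf$H[m])), 1e-9)
  expect_true(all(cf$H[m]^2 - cf$K_G[m] >= -1e-9))
})

test_that("halving the spacing reduces the Monge discretization error >= 3x", {
  R <- 20
  err_at <- function(h) {
    xs <- seq(-4, 4, by = h)
    zc <- outer(xs, xs, function(x, y) sqrt(R^2 - x^2 - y^2))
    cc <- monge_curvature(height_field(zc, h, x0 = -4, y0 = -4))
    max(abs(abs(cc$H[cc$mask]) - 1 / R))
  }
  expect_gt(err_at(0.8) / err_at(0.4), 3)
})

test_that("transition classification uses strict threshold and censoring", {
  tt <- seq(10, 1000, by = 10)
  H <- rep(0.05, length(tt)); H[tt == 320] <- 0.151
  r <- classify_transition(tt, H, threshold = 0.15)
  expect_false(r$censored)
  expect_equal(r$waiting_time, 320)
  # below threshold: censored at horizon
  r2 <- classify_transition(tt, rep(0.12, length(tt)), horizon = 1000)
  expect_true(r2$censored)
  expect_equal(r2$horizon, 1000)
  # exact touch never fires (strict >)
  H3 <- rep(0.15, length(tt))
  expect_true(classify_transition(tt, H3)$censored)
  # sign invariance
  r4 <- classify_transition(tt, -H)
  expect_equal(r4$waiting_time, 320)
  # threshold monotonicity: raising threshold never shortens waiting time
  set.seed(7)
  for (i in 1:20) {
    Hr <- cumsum(stats::rnorm(100, 0.002, 0.01))
    t1 <- classify_transition(1:100, Hr, threshold = 0.1)
    t2 <- classify_transition(1:100, Hr, threshold = 0.2)
    w1 <- if (t1$censored) Inf else t1$waiting_time
    w2 <- if (t2$censored) Inf else t2$waiting_time
    expect_gte(w2, w1)
  }
  expect_error(classify_transition(numeric(0), numeric(0)), "empty")
})

test_that("curvature preference recovers fixed, uniform and biased sampling", {
  lam <- 57; A <- 5; hs <- 0.5
  x <- seq(0, lam - hs, by = hs); y <- seq(0, 28 - hs, by = hs)
  zb <- outer(x, y, function(x, y) A * sin(2 * pi * x / lam))
  cf <- monge_curvature(height_field(zb, hs, periodic = c(TRUE, TRUE)))
  crest_x <- lam / 4
  # protein pinned at the crest: mean H equals crest H (node value)
  occ <- curvature_preference(cbind(rep(crest_x, 100), rep(14, 100)), cf)
  expect_equal(occ$n_samples, 100)
  crest_H <- cf$H[which.min(abs(cf$x - crest_x)), which.min(abs(cf$y - 14))]
  expect_lt(abs(occ$mean_H - crest_H), 1e-3)
  # uniform positions: occupancy mean within 2 s.e. of area-weighted mean
  set.seed(8)
  pos <- cbind(stats::runif(4000, 0, lam), stats::runif(4000, 0, 28))
  occ2 <- curvature_preference(pos, cf)
  field_mean <- mean(cf$H[cf$mask])
  se <- stats::sd(occ2$samples) / sqrt(occ2$n_samples)
  expect_lt(abs(occ2$mean_H - field_mean), 2 * se)
  # sampler biased to the high-|H| ridge exceeds the field average |H|
  ridge <- cbind(stats::rnorm(500, crest_x, 2), stats::runif(500, 0, 28))
  occ3 <- curvature_preference(ridge, cf)
  expect_gt(mean(abs(occ3$samples)), mean(abs(cf$H[cf$mask])))
})
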