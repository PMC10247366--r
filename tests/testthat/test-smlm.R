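toy_table <- function(n = 5, frame = seq_len(n), x = 0, y = 0,
                      photons = 5000, fwhm_x = 300, fwhm_y = 300,
                      precision = 10) {
  localization_table(data.frame(frame = frame, x = x, y = y,
                                photons = photons, fwhm_x = fwhm_x,
                                fwhm_y = fwhm_y, precision = precision))
}

test_that("QC filter enforces symmetry, precision and intensity bounds", {
  tab <- toy_table(5)
  res <- qc_filter(tab)
  expect_equal(nrow(res$table), 5)
  expect_equal(unname(res$rejected), c(0, 0, 0))
  # symmetry bound 1.4 rejected, 1.39 kept (strict)
  bad_sym <- toy_table(2, fwhm_x = c(420, 417), fwhm_y = 300)
  r2 <- qc_filter(bad_sym)
  expect_equal(nrow(r2$table), 1)
  expect_equal(unname(r2$rejected["symmetry"]), 1)
  # precision 60 rejected; 50 rejected (strict <); 49.9 kept
  r3 <- qc_filter(toy_table(3, precision = c(60, 50, 49.9)))
  expect_equal(nrow(r3$table), 1)
  expect_equal(unname(r3$rejected["precision"]), 2)
  # idempotence and tally bookkeeping
  set.seed(41)
  big <- toy_table(200, precision = stats::runif(200, 5, 80),
                   fwhm_x = stats::rnorm(200, 300, 60))
  rb <- qc_filter(big)
  expect_equal(sum(rb$rejected), rb$n_removed)
  again <- qc_filter(rb$table)
  expect_equal(nrow(again$table), nrow(rb$table))
  expect_equal(sum(again$rejected), 0)
  expect_error(qc_filter(localization_table(
    data.frame(frame = 1, x = 0, y = 0))), "fwhm")
})

test_that("NeNa precision recovers simulated localization noise", {
  set.seed(42)
  em <- cbind(stats::runif(40, 0, 5000), stats::runif(40, 0, 5000))
  mk <- function(bg_per_frame = 0) {
    rows <- lapply(0:199, function(f) {
      d <- data.frame(frame = f, x = em[, 1] + stats::rnorm(40, 0, 10),
                      y = em[, 2] + stats::rnorm(40, 0, 10))
      if (bg_per_frame > 0)
        d <- rbind(d, data.frame(frame = f,
                                 x = stats::runif(bg_per_frame, 0, 5000),
                                 y = stats::runif(bg_per_frame, 0, 5000)))
      d
    })
    localization_table(do.call(rbind, rows))
  }
  p <- nena_precision(mk())
  expect_lt(abs(p$sigma_nena - 10), 1)
  # background is absorbed by the linear term
  p_bg <- nena_precision(mk(bg_per_frame = 10))
  expect_lt(abs(p_bg$sigma_nena - p$sigma_nena) / p$sigma_nena, 0.10)
  # noiseless repeats: sigma reported below 0.1 nm
  still <- localization_table(
    data.frame(frame = rep(0:199, each = 5),
               x = rep(em[1:5, 1], 200), y = rep(em[1:5, 2], 200)))
  expect_lt(nena_precision(still)$sigma_nena, 0.1)
  expect_error(nena_precision(toy_table(5, frame = rep(1, 5))), "pairs")
})

test_that("linking merges gaps of up to 8 dark frames and splits at 9", {
  same_pos <- function(frames) localization_table(
    data.frame(frame = frames, x = 0, y = 0))
  t3 <- link_localizations(same_pos(1:3), precision = 10)
  expect_equal(nrow(t3$traces), 1)
  expect_equal(t3$traces$n, 3)
  # frames 1 and 10: 8 intervening dark frames -> linked
  expect_equal(nrow(link_localizations(same_pos(c(1, 10)),
                                       precision = 10)$traces), 1)
  # frames 1 and 11: 9 dark frames -> two traces
  expect_equal(nrow(link_localizations(same_pos(c(1, 11)),
                                       precision = 10)$traces), 2)
  # distant emitters never linked (500 nm apart, radius 50 nm)
  two <- localization_table(data.frame(frame = 1:2, x = c(0, 500), y = 0))
  expect_equal(nrow(link_localizations(two, precision = 10)$traces), 2)
  # max_dark_frames = 0 splits any gap: per-consecutive-run traces
  gappy <- same_pos(c(1, 2, 4, 5))
  t0 <- link_localizations(gappy, precision = 10, max_dark_frames = 0)
  expect_equal(nrow(t0$traces), 2)
  expect_error(link_localizations(same_pos(1:3), radius = -5), "positive")
})

test_that("fiducial traces are flagged by long consecutive runs", {
  set.seed(43)
  mk_trace <- function(frames, x) data.frame(frame = frames, x = x, y = 0)
  tab <- localization_table(rbind(
    mk_trace(0:24, 0),                      # 25 consecutive -> fiducial
    mk_trace(0:19, 500),                    # exactly 20 -> kept
    mk_trace(sort(sample(0:100, 30)), 1000) # blinking -> kept
  ))
  ts <- link_localizations(tab, precision = 5)
  ts <- remove_fiducials(ts, max_consecutive = 20)
  flagged <- ts$traces[ts$traces$is_fiducial, ]
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$x, 0, tolerance = 1e-9)
  kept_tab <- drop_fiducial_localizations(tab, ts)
  expect_false(any(kept_tab$x == 0))
  expect_true(any(kept_tab$x == 500))
})

test_that("DBSCAN finds planted clusters and flags sparse noise", {
  set.seed(44)
  # 12 points in a 20 nm disc + 1 far point
  rr <- 10 * sqrt(stats::runif(12)); th <- stats::runif(12, 0, 2 * pi)
  pts <- rbind(cbind(rr * cos(th), rr * sin(th)), c(500, 500))
  db <- dbscan_nanoclusters(pts, eps = 31, min_pts = 10)
  expect_equal(nrow(db$clusters), 1)
  expect_equal(db$clusters$n_localizations, 12)
  expect_equal(sum(db$labels == 0), 1)
  # 9 mutually close points: below the minimum density of ten
  expect_warning(db9 <- dbscan_nanoclusters(pts[1:9, ], eps = 31,
                                            min_pts = 10),
                 "min_pts")
  expect_equal(nrow(db9$clusters), 0)
  # two planted 30-point Gaussian clusters, 500 nm apart
  g1 <- cbind(stats::rnorm(30, 0, 10), stats::rnorm(30, 0, 10))
  g2 <- cbind(stats::rnorm(30, 500, 10), stats::rnorm(30, 500, 10))
  db2 <- dbscan_nanoclusters(rbind(g1, g2), eps = 31, min_pts = 10)
  expect_equal(nrow(db2$clusters), 2)
  expect_equal(length(unique(db2$labels[1:30])), 1)
  expect_equal(length(unique(db2$labels[31:60])), 1)
  expect_false(db2$labels[1] == db2$labels[31])
  # diameter/area identity
  expect_equal(db2$clusters$diameter_nm,
               2 * sqrt(db2$clusters$area_nm2 / pi))
})

test_that("DBSCAN matches the brute-force oracle and ignores row order", {
  set.seed(45)
  for (i in 1:30) {
    n <- sample(20:100, 1)
    xy <- cbind(stats::runif(n, 0, 300), stats::runif(n, 0, 300))
    db <- dbscan_nanoclusters(xy, eps = 31, min_pts = 5)
    o <- oracle_dbscan(xy, eps = 31, min_pts = 5)
    # core points: identical partition
    expect_equal(canon_labels(db$labels[o$core]),
                 canon_labels(o$core_labels[o$core]))
    # border/noise: implementation label must be an allowed oracle label
    for (j in which(!o$core)) {
      if (db$labels[j] == 0) {
        expect_equal(length(o$allowed[[j]]), 0)
      } else {
        core_match <- which(o$core & db$labels == db$labels[j])[1]
        expect_true(o$core_labels[core_match] %in% o$allowed[[j]])
      }
    }
    # row-order invariance: core partition and noise set are stable
    # (border points between two clusters may legitimately switch)
    p <- sample(n)
    dbp <- dbscan_nanoclusters(xy[p, ], eps = 31, min_pts = 5)
    core_p <- o$core[p]
    expect_equal(dbp$labels == 0, db$labels[p] == 0)
    expect_equal(canon_labels(dbp$labels[core_p]),
                 canon_labels(db$labels[p][core_p]))
  }
})

test_that("Voronoi segmentation recovers a planted disc and applies thresholds", {
  set.seed(46)
  bg <- cbind(stats::runif(1590, 0, 2000), stats::runif(1590, 0, 2000))
  planted <- function(n_locs) {
    rr <- 200 * sqrt(stats::runif(n_locs))
    th <- stats::runif(n_locs, 0, 2 * pi)
    cbind(1000 + rr * cos(th), 1000 + rr * sin(th))
  }
  disc <- planted(1000)
  vs <- voronoi_microclusters(rbind(bg, disc), delta = 4)
  expect_equal(nrow(vs$clusters), 1)
  expect_gte(mean(vs$cluster[1591:2590] > 0), 0.95)
  expect_gte(vs$clusters$n_localizations, 800)
  expect_gte(vs$clusters$diameter_nm, 100)
  # same disc with 700 localizations: rejected by min_locs = 800
  v7 <- voronoi_microclusters(rbind(bg, planted(700)), delta = 4)
  expect_equal(nrow(v7$clusters), 0)
  # dense but tiny cluster: rejected by min_diameter = 100 nm
  tiny <- cbind(1000 + stats::rnorm(900, 0, 10), 1000 + stats::rnorm(900, 0, 10))
  vt <- voronoi_microclusters(rbind(bg, tiny), delta = 4)
  expect_equal(nrow(vt$clusters), 0)
  # uniform points yield no microclusters
  u <- cbind(stats::runif(2000, 0, 2000), stats::runif(2000, 0, 2000))
  expect_equal(nrow(voronoi_microclusters(u, delta = 2)$clusters), 0)
  expect_error(voronoi_microclusters(u, delta = 7), "2, 6")
})

test_that("Voronoi cell areas tile the clipped bounding region", {
  set.seed(47)
  xy <- cbind(stats::runif(600, 0, 1000), stats::runif(600, 0, 1000))
  vt <- clusterkit:::voronoi_tessellation(xy)
  region <- (vt$bbox[2] - vt$bbox[1]) * (vt$bbox[4] - vt$bbox[3])
  expect_lt(abs(sum(vt$areas) - region) / region, 0.001)
  # adjacency is symmetric
  for (i in seq_len(50))
    for (j in vt$neighbours[[i]])
      expect_true(i %in% vt$neighbours[[j]])
})

test_that("Picasso-style columns and pixel units are normalised", {
  df <- data.frame(frame = 0:4, x = 1:5, y = 1, sx = 0.9, sy = 1.0,
                   lpx = 0.06, lpy = 0.08, photons = 4000)
  tab <- localization_table(df, pixel_size = 158)
  expect_equal(tab$x, (1:5) * 158)
  expect_equal(tab$fwhm_x / tab$fwhm_y, rep(0.9, 5), tolerance = 1e-9)
  expect_equal(tab$precision, rep(sqrt((0.06^2 + 0.08^2) / 2) * 158, 5))
  expect_error(localization_table(data.frame(x = 1, y = 2)), "frame")
})
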