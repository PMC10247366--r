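test_that("COM distances honour the minimum-image convention", {
  d <- com_distance_matrix(rbind(c(0, 0, 0), c(3, 4, 0)), periodic = FALSE)
  expect_equal(d[1, 2], 5)
  expect_equal(diag(d), c(0, 0))
  # wrap case: x = 1 and x = 29 in a 30 nm box
  dw <- com_distance_matrix(rbind(c(1, 0, 0), c(29, 0, 0)),
                            box = c(30, 30, 30), periodic = TRUE)
  expect_equal(dw[1, 2], 2)
  # periodicity off on a well-separated system changes nothing
  xyz <- matrix(stats::runif(30, 10, 12), ncol = 3)
  expect_equal(com_distance_matrix(xyz, box = c(100, 100, 100),
                                   periodic = TRUE),
               com_distance_matrix(xyz, periodic = FALSE))
  # minimum-image distances never exceed half the box diagonal
  set.seed(31)
  xyz2 <- cbind(stats::runif(40, 0, 30), stats::runif(40, 0, 30),
                stats::runif(40, 0, 20))
  dm <- com_distance_matrix(xyz2, box = c(30, 30, 20), periodic = TRUE)
  expect_lte(max(dm), sqrt(sum((c(30, 30, 20) / 2)^2)))
})

test_that("single-linkage clustering chains and uses a strict cutoff", {
  # mutual 5 nm: one cluster of 3
  d3 <- matrix(5, 3, 3); diag(d3) <- 0
  a <- single_linkage_clusters(d3, cutoff = 10)
  expect_equal(a$n_clusters, 1L)
  expect_equal(a$largest_size, 3L)
  # chain A-B = 8, B-C = 8, A-C = 16: chaining joins all three
  dc <- matrix(c(0, 8, 16, 8, 0, 8, 16, 8, 0), 3, 3)
  ac <- single_linkage_clusters(dc, cutoff = 10)
  expect_equal(ac$n_clusters, 1L)
  # 3 x 3 grid at exactly 10 nm spacing: strict < keeps 9 singletons
  g <- as.matrix(expand.grid(x = c(0, 10, 20), y = c(0, 10, 20)))
  dg <- com_distance_matrix(cbind(g, 0), periodic = FALSE)
  expect_equal(min(dg[dg > 0]), 10)
  ag <- single_linkage_clusters(dg, cutoff = 10)
  expect_equal(ag$n_clusters, 9L)
  expect_equal(ag$largest_size, 1L)
})

test_that("single-linkage equals transitive-closure oracle and hclust", {
  set.seed(32)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    xyz <- matrix(stats::runif(3 * n, 0, 40), ncol = 3)
    d <- com_distance_matrix(xyz, periodic = FALSE)
    cutoff <- stats::runif(1, 5, 20)
    a <- single_linkage_clusters(d, cutoff)
    expect_equal(canon_labels(a$labels),
                 canon_labels(oracle_single_linkage(d, cutoff)))
    expect_equal(sum(a$sizes), n)
    expect_equal(a$largest_size, max(a$sizes))
    # independent cross-check: cut the single-linkage dendrogram just
    # below the cutoff (cutree cuts at height <= h; strictness epsilon)
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    ct <- stats::cutree(hc, h = cutoff - 1e-9)
    expect_equal(canon_labels(a$labels), canon_labels(unname(ct)))
  }
  # permutation equivariance
  n <- 20
  xyz <- matrix(stats::runif(60, 0, 30), ncol = 3)
  d <- com_distance_matrix(xyz, periodic = FALSE)
  a <- single_linkage_clusters(d, 8)
  p <- sample(n)
  ap <- single_linkage_clusters(d[p, p], 8)
  expect_equal(canon_labels(ap$labels), canon_labels(a$labels[p]))
})

test_that("cluster series tracks aggregation over a trajectory", {
  traj <- gen_trajectory(n_proteins = 9, t_aggregate = 1000, n_frames = 300,
                         dt = 10, seed = 33)
  cs <- cluster_series(traj, cutoff = 10)
  expect_equal(nrow(cs), 300)
  # pristine 10 nm grid at t = 0: strict cutoff keeps singletons
  expect_equal(cs$largest_size[1], 1L)
  # after coalescence the largest cluster reaches all nine proteins
  expect_equal(max(cs$largest_size), 9L)
  expect_equal(cs$largest_size[300], 9L)
  # frames are independent: a subset gives identical per-frame values
  cs_sub <- cluster_series(traj[c(5, 100, 250)], cutoff = 10)
  expect_equal(cs_sub$largest_size,
               cs$largest_size[c(5, 100, 250)])
  expect_error(cluster_series(list(), 10), "empty")
})

test_that("ubiquitin contacts split cis/trans with run-length lifetimes", {
  mk_frame <- function(t, close) {
    ub <- data.frame(
      mol = c(1L, 1L, 2L, 2L), res = c(160L, 264L, 160L, 264L),
      attachment = c("K160", "K264", "K160", "K264"),
      x = c(0, 0.5, if (close) 0.9 else 5, if (close) 1.4 else 5.5),
      y = 0, z = 0)
    protein_frame(com = rbind(c(0, 0, 0), c(5, 0, 0)), box = c(30, 30, 20),
                  time = t, z_membrane = c(-2, 2), ub_beads = ub,
                  periodic = FALSE)
  }
  # molecules approach during frames 10-20 (1-based: 10..20)
  frames <- lapply(1:30, function(f) mk_frame(f, close = f >= 10 & f <= 20))
  res <- ub_contacts(frames, contact_cutoff = 0.6, frame_spacing = 1)
  trans <- res$records[res$records$type == "trans", ]
  cis <- res$records[res$records$type == "cis", ]
  expect_true(nrow(cis) > 0)   # 0.5 nm intra-molecule pairs persist always
  expect_true(all(cis$mol_i == cis$mol_j))
  expect_true(all(trans$mol_i != trans$mol_j))
  tr <- trans[trans$res_i == 264 & trans$res_j == 160, ]
  expect_equal(nrow(tr), 1)
  expect_equal(tr$first_frame, 10)
  expect_equal(tr$last_frame, 20)
  expect_equal(tr$lifetime_ns, 11)
  # frequency map fraction
  fq <- res$frequency
  expect_equal(fq$fraction[fq$type == "trans" & fq$res_i == 264], 11 / 30)
})

test_that("contact gap tolerance merges interrupted runs like the oracle", {
  present <- c(1:5, 7:9)
  m0 <- clusterkit:::merge_runs(present, 0)
  expect_equal(nrow(m0), 2)
  m1 <- clusterkit:::merge_runs(present, 1)
  expect_equal(unname(m1[1, ]), c(1, 9))
  set.seed(34)
  for (i in 1:50) {
    idx <- sort(sample(1:60, sample(5:30, 1)))
    tol <- sample(0:3, 1)
    expect_equal(unname(clusterkit:::merge_runs(idx, tol)),
                 unname(oracle_merge_runs(idx, tol)))
  }
})

test_that("budding flag needs a sustained box-width contraction", {
  mk <- function(lx_series) {
    lapply(seq_along(lx_series), function(f)
      protein_frame(com = matrix(c(5, 5, 0), 1), box = c(lx_series[f], 30, 20),
                    time = f * 10, z_membrane = c(-2, 2)))
  }
  const <- budding_metrics(mk(rep(30, 50)))
  expect_false(const$budding_flag)
  # step 30 -> 27 nm (10% > 5% threshold) sustained
  step <- budding_metrics(mk(c(rep(30, 20), rep(27, 30))))
  expect_true(step$budding_flag)
  expect_equal(step$onset_time, 210)
  # single-frame dip is debounced
  dip <- budding_metrics(mk(c(rep(30, 20), 27, rep(30, 29))))
  expect_false(dip$budding_flag)
})

test_that("PPI scaling is the exact linear interpolation", {
  expect_equal(ppi_scale(2, 5, 1)$eps_alpha, 5)
  expect_equal(ppi_scale(2, 5, 0)$eps_alpha, 2)
  expect_equal(ppi_scale(2, 5, 0.65)$eps_alpha, 3.95)
  expect_error(ppi_scale(2, 5, 1.2), "0, 1")
})
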