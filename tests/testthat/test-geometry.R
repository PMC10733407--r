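test_that("hydrogen-bond criteria apply the stated distance and angle rules", {
  m <- get_model("K")
  tr <- scripted_trajectory(m, data.frame(ha_dist = c(2.1, 2.3),
                                          angle = c(160, 179)))
  expect_equal(hbond_frequency(tr), 0.5)  # only the 2.1 A / 160 deg frame
  expect_equal(hbond_frequency(tr, criteria = hbond_criteria(2.4, 50)), 1)
  expect_error(hbond_frequency(tr, donor = "H2p", h = "H2p"), "distinct")
  expect_error(hbond_criteria(-1))
  expect_error(hbond_criteria(2.2, 95))
})

test_that("hbond frequency is monotone in both criteria thresholds", {
  m <- get_model("K")
  set.seed(13)
  script <- data.frame(ha_dist = runif(60, 1.6, 3.0),
                       angle = runif(60, 120, 180))
  tr <- scripted_trajectory(m, script)
  freqs_d <- vapply(seq(1.6, 3.0, 0.2), function(d)
    hbond_frequency(tr, criteria = hbond_criteria(d, 50)), numeric(1))
  expect_true(!is.unsorted(freqs_d))
  freqs_a <- vapply(seq(10, 80, 10), function(a)
    hbond_frequency(tr, criteria = hbond_criteria(2.2, a)), numeric(1))
  expect_true(!is.unsorted(freqs_a))
})

test_that("pair-distance statistics: static and alternating fixtures", {
  m <- get_model("K")
  static <- scripted_trajectory(m, data.frame(d1 = rep(3.0, 8)))
  ps <- pair_distance_series(static, list(M1_M2 = c("M1", "M2")))
  expect_equal(ps$sd, 0)
  expect_equal(ps$mean, model_distance(m, "M1", "M2"), tolerance = 1e-9)
  alt <- scripted_trajectory(
    m, data.frame(d1 = rep(3.0, 100)),
    pair_dists = list(list(roles = c("M1", "M2"),
                           dist = rep(c(4.0, 4.2), 50))))
  pa <- pair_distance_series(alt, list(M1_M2 = c("M1", "M2")))
  expect_equal(pa$mean, 4.1, tolerance = 1e-9)
  expect_equal(pa$sd, sd(rep(c(4.0, 4.2), 50)), tolerance = 1e-9)
  # scripted product-state target: M1-M2 opens to 4.4 A
  prod <- scripted_trajectory(
    m, data.frame(d1 = rep(1.6, 50)),
    pair_dists = list(list(roles = c("M1", "M2"), dist = 4.4)))
  pp <- pair_distance_series(prod, list(M1_M2 = c("M1", "M2")))
  expect_equal(pp$mean, 4.4, tolerance = 1e-9)
  expect_error(pair_distance_series(static, list(x = c("M1", "nope"))),
               "unknown")
})

test_that("proton-transfer detection ignores rattling below the dwell window", {
  m <- get_model("K")
  static <- scripted_trajectory(m, data.frame(hd_dist = rep(1.0, 40),
                                              ha_dist = rep(1.8, 40)))
  expect_equal(nrow(detect_proton_transfer(static)), 0)
  rattle <- scripted_trajectory(
    m, data.frame(hd_dist = rep(c(1.0, 1.6), 30),
                  ha_dist = rep(c(1.6, 1.0), 30)))
  expect_equal(nrow(detect_proton_transfer(rattle, dwell = 10)), 0)
  expect_gt(nrow(detect_proton_transfer(rattle, dwell = 1)), 0)
  expect_error(detect_proton_transfer(static, dwell = 0), "dwell")
})

test_that("relative MSF separates mobile from static groups as variance ratios", {
  m <- get_model("K")
  base <- scripted_trajectory(m, data.frame(d1 = rep(3.3, 400)))
  groups <- list(g52 = "G52_O", a59 = "A59_O", g60 = "G60_O")
  expect_equal(unname(rmsf_relative(base, groups)), c(0, 0, 0))
  jit <- scripted_trajectory(m, data.frame(d1 = rep(3.3, 400)),
                             jitter = c(G52_O = 0.2), seed = 5)
  r1 <- rmsf_relative(jit, groups)
  expect_equal(unname(r1["g52"]), 1)
  expect_lt(max(r1[c("a59", "g60")]), 0.02)
  jit2 <- scripted_trajectory(m, data.frame(d1 = rep(3.3, 2000)),
                              jitter = c(G52_O = 0.2, A59_O = 0.1),
                              seed = 6)
  r2 <- rmsf_relative(jit2, groups)
  # best-fit superposition leaks a little mobile-atom motion into the
  # frame, biasing the ratio slightly above sigma2^2/sigma1^2
  expect_equal(unname(r2["a59"] / r2["g52"]), 0.25, tolerance = 0.3)
  expect_error(rmsf_relative(base, list(a = "G52_O", b = "G52_O")),
               "overlap")
})

test_that("relative MSF is invariant under per-frame rigid motion", {
  m <- get_model("K")
  jit <- scripted_trajectory(m, data.frame(d1 = rep(3.3, 300)),
                             jitter = c(G52_O = 0.15, A59_O = 0.05),
                             seed = 8)
  groups <- list(g52 = "G52_O", a59 = "A59_O", g60 = "G60_O")
  r0 <- rmsf_relative(jit, groups)
  rot <- jit
  set.seed(9)
  for (f in seq_len(n_frames(rot))) {
    th <- runif(1, 0, 2 * pi); ax <- runif(3)
    ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    rot$coords[f, , ] <- rot$coords[f, , ] %*% R +
      matrix(runif(3, -5, 5), nrow(rot$coords[f, , ]), 3, byrow = TRUE)
  }
  r1 <- rmsf_relative(rot, groups)
  expect_equal(unname(r1), unname(r0), tolerance = 1e-6)
})

test_that("ion pose classification covers both sub-sites, unbound and ties", {
  m <- get_model("Li")
  tr <- scripted_trajectory(m, data.frame(pose = c(1, 2, 0, 1)))
  cl <- classify_ion_pose(tr, ion_type = "Li")
  expect_equal(cl$labels, c("pose1", "pose2", "unbound", "pose1"))
  expect_equal(unname(as.numeric(cl$occupancy)), c(0.5, 0.25, 0.25))
  # enormous cutoff satisfies both sub-sites; tie goes to the closer one
  cl2 <- classify_ion_pose(tr, ion_type = "Li", cutoff = 50)
  expect_equal(length(cl2$tie_frames), 4)
  expect_equal(cl2$labels[1], "pose1")
})

test_that("Coulomb field follows the inverse-square law, symmetry and additivity", {
  pos <- rbind(t = c(0, 0, 0), a = c(2, 0, 0), b = c(-2, 0, 0))
  f1 <- coulomb_field(pos, c(a = 1.5), "t")
  expect_equal(unname(f1$field["t", ]), c(-1.5 / 4, 0, 0), tolerance = 1e-12)
  fsym <- coulomb_field(pos, c(a = 1.5, b = 1.5), "t")
  expect_equal(max(abs(fsym$field)), 0, tolerance = 1e-12)
  # additivity in sources and 1/eps scaling
  fa <- coulomb_field(pos, c(a = 1.5), "t")$field
  fb <- coulomb_field(pos, c(b = 0.7), "t")$field
  fab <- coulomb_field(pos, c(a = 1.5, b = 0.7), "t")$field
  expect_equal(fab, fa + fb, tolerance = 1e-12)
  feps <- coulomb_field(pos, c(a = 1.5, b = 0.7), "t", dielectric = 4)$field
  expect_equal(feps, fab / 4, tolerance = 1e-12)
})

test_that("Coulomb sum matches an independent summation on a 50-charge frame", {
  set.seed(17)
  n <- 50
  pos <- matrix(runif(3 * n, -8, 8), n, 3)
  rownames(pos) <- paste0("q", seq_len(n))
  q <- setNames(runif(n, -1, 1), rownames(pos))
  tgt <- "q1"
  out <- coulomb_field(pos, q, tgt,
                       projection_pairs = list(c("q1", "q2")))
  # brute force in reversed order with explicit loop
  E <- c(0, 0, 0)
  for (i in rev(seq_len(n))) {
    if (rownames(pos)[i] == tgt) next
    dr <- pos[tgt, ] - pos[i, ]
    E <- E + q[i] * dr / sum(dr^2)^1.5
  }
  expect_equal(unname(out$field[tgt, ]), unname(E), tolerance = 1e-10)
  u <- (pos["q2", ] - pos["q1", ]); u <- u / sqrt(sum(u^2))
  expect_equal(out$projections$value, sum(E * u), tolerance = 1e-10)
  pos2 <- pos; pos2["q2", ] <- pos2["q1", ]
  expect_error(coulomb_field(pos2, q, "q1"), "coincides")
})
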