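test_that("hydrogen-bond scripts are realised exactly and recorded in metadata", {
  m <- get_model("K")
  script <- data.frame(ha_dist = c(2.1, 2.1, 2.1, 2.4),
                       hd_dist = 1.0,
                       angle = c(160, 170, 180, 160))
  tr <- scripted_trajectory(m, script)
  md <- attr(tr, "metadata")
  expect_equal(md$hb_frames, 1:3)
  # generated geometry carries the scripted distances and angles exactly
  dHA <- sqrt(rowSums((bluemoonti:::.traj_pos(tr, "H2p") -
                         bluemoonti:::.traj_pos(tr, "OSp"))^2))
  expect_equal(dHA, script$ha_dist, tolerance = 1e-9)
  ang <- bluemoonti:::.dha_angle(tr, "BPA_O2p", "H2p", "OSp")
  expect_equal(ang, script$angle, tolerance = 1e-6)
  expect_equal(hbond_frequency(tr), 0.75)
})

test_that("proton hand-off at the scripted frame and d1 is recorded", {
  m <- get_model("K")
  n <- 120
  script <- data.frame(d1 = 2.42, d2 = 1.8,
                       hd_dist = c(rep(1.0, 49), rep(1.6, n - 49)),
                       ha_dist = c(rep(1.8, 49), rep(1.0, n - 49)),
                       angle = 175)
  tr <- scripted_trajectory(m, script)
  md <- attr(tr, "metadata")
  expect_equal(md$pt_frames, 50L)
  ev <- detect_proton_transfer(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, 50L)
  expect_equal(ev$d1, 2.42, tolerance = 1e-9)
})

test_that("lithium shuttling between sub-sites yields 50/50 occupancy", {
  m <- get_model("Li")
  n <- 600
  script <- data.frame(pose = rep(rep(c(1, 2), each = 100), 3))
  tr <- scripted_trajectory(m, script)
  md <- attr(tr, "metadata")
  expect_equal(unname(md$occupancy[["pose1"]]), 0.5)
  expect_equal(unname(md$occupancy[["pose2"]]), 0.5)
  cl <- classify_ion_pose(tr, ion_type = "Li")
  expect_identical(cl$labels, md$pose)
  expect_equal(sum(cl$occupancy), 1)
})

test_that("inconsistent scripts are rejected", {
  m <- get_model("K")
  expect_error(scripted_trajectory(m, data.frame(ha_dist = -1)), "positive")
  expect_error(scripted_trajectory(m, data.frame(ha_dist = 2, angle = 190)),
               "180")
  expect_error(scripted_trajectory(m, data.frame(pose = 3)), "pose")
  expect_error(scripted_trajectory(m, data.frame()[0, ]), "empty")
  expect_error(
    scripted_trajectory(m, data.frame(ha_dist = 2),
                        jitter = c(H2p = 0.1)), "script-driven")
  expect_error(
    scripted_trajectory(m, data.frame(pose = 1),
                        pair_dists = list(list(roles = c("M1", "K1"),
                                               dist = 3))),
    "pose and a pair")
})

test_that("jitter is seed-reproducible and only touches the listed roles", {
  m <- get_model("K")
  script <- data.frame(d1 = rep(3.0, 10))
  t1 <- scripted_trajectory(m, script, jitter = c(M1 = 0.1), seed = 4)
  t2 <- scripted_trajectory(m, script, jitter = c(M1 = 0.1), seed = 4)
  expect_identical(t1$coords, t2$coords)
  i_m2 <- match("M2", t1$labels)
  expect_true(all(apply(t1$coords[, i_m2, ], 2, sd) == 0))
  i_m1 <- match("M1", t1$labels)
  expect_true(all(apply(t1$coords[, i_m1, ], 2, sd) > 0))
})
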