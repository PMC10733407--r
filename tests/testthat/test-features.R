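test_that("features of a two-barrier profile match the printed-node values", {
  xi <- c(-1.4, -0.9, -0.4, 0, 0.2, 0.9, 1.6)
  Fv <- c(0, 6, 13.6, 12.0, 14.0, 5, -4.2)
  fe <- extract_features(free_energy_profile(xi, Fv))
  expect_equal(fe$type, "two_ts")
  expect_equal(fe$features$state, c("R", "TS1", "I", "TS2", "P"))
  # R and P are edge minima (no refinement), so dF(R->P) is exact
  expect_equal(feature_value(fe, "dF_R_P")[1], -4.2, tolerance = 1e-12)
  # interior extrema are refined through their 3 points; the refined
  # barrier can only exceed the node value, and only modestly
  ts1 <- feature_value(fe, "dF_R_TS1")[1]
  expect_gte(ts1, 13.6 - 1e-9)
  expect_lt(ts1, 14.2)
  # ordering and saddle-above-minima invariants
  expect_true(!is.unsorted(fe$features$xi))
  F <- setNames(fe$features$F, fe$features$state)
  expect_gt(F["TS1"], max(F["R"], F["I"]) - 1e-9)
  expect_gt(F["TS2"], max(F["I"], F["P"]) - 1e-9)
})

test_that("a strictly monotone profile reports a single minimum and no TS", {
  xi <- seq(0, 1, by = 0.1)
  fe <- extract_features(free_energy_profile(xi, 5 - 4 * xi))
  expect_equal(fe$type, "minimum_only")
  expect_false(any(grepl("TS", fe$features$state)))
})

test_that("a single-barrier profile reports the one-TS variant", {
  xi <- seq(-1, 1, by = 0.2)
  fe <- extract_features(free_energy_profile(xi, 3 * (1 - xi^2)^2 - 2 * xi))
  expect_equal(fe$type, "one_ts")
  expect_true("TS" %in% fe$features$state)
  expect_true(all(c("dF_R_TS", "dF_R_P") %in% fe$barriers$name))
})

test_that("features are invariant under an additive constant (gauge)", {
  xi <- c(-1.4, -0.9, -0.4, 0, 0.2, 0.9, 1.6)
  Fv <- c(0, 6, 13.6, 12.0, 14.0, 5, -4.2)
  f1 <- extract_features(free_energy_profile(xi, Fv))
  f2 <- extract_features(free_energy_profile(xi, Fv + 57.3))
  expect_equal(f1$barriers$value, f2$barriers$value, tolerance = 1e-9)
  expect_equal(f1$features$xi, f2$features$xi, tolerance = 1e-9)
})

test_that("feature errors combine the node errors in quadrature", {
  xi <- c(-1.4, -0.9, -0.4, 0, 0.2, 0.9, 1.6)
  Fv <- c(0, 6, 13.6, 12.0, 14.0, 5, -4.2)
  sg <- c(0, 0.1, 0.3, 0.2, 0.25, 0.15, 0.4)
  fe <- extract_features(free_energy_profile(xi, Fv, sg))
  expect_equal(attr(feature_value(fe, "dF_R_P"), "sigma"),
               sqrt(0^2 + 0.4^2), tolerance = 1e-12)
  expect_equal(attr(feature_value(fe, "dF_R_TS1"), "sigma"),
               sqrt(0^2 + 0.3^2), tolerance = 1e-12)
})

test_that("short profiles are rejected", {
  expect_error(extract_features(free_energy_profile(1:4, rep(0, 4))),
               "5 points")
})
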