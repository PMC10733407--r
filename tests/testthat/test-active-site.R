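test_that("reactant build reproduces the equilibrated active-site distances", {
  m <- get_model("K")
  expect_equal(model_distance(m, "BPA_O2p", "Gp1_P"), 3.3, tolerance = 1e-6)
  expect_equal(model_distance(m, "G1_O3p", "Gp1_P"), 1.6, tolerance = 1e-6)
  expect_equal(model_distance(m, "M1", "M2"), 4.1, tolerance = 1e-6)
  expect_equal(model_distance(m, "K1", "M2"), 4.3, tolerance = 1e-6)
  expect_equal(model_distance(m, "K1", "M1"), 6.2, tolerance = 1e-6)
  # Mg coordination contacts in 2.0-2.3 A, monovalent contacts in 2.8-3.4 A
  for (ion in c("M1", "M2")) {
    d <- coordination_sphere(m, ion, cutoff = 2.4)$distance
    expect_gt(length(d), 1)
    expect_true(all(d >= 2.0 & d <= 2.3))
  }
  dk <- coordination_sphere(m, "K1", cutoff = 3.5)
  expect_setequal(dk$role, c("G52_O", "A59_O", "G60_O", "U80_O"))
  expect_true(all(dk$distance >= 2.8 & dk$distance <= 3.4))
})

test_that("build invariants hold and bad input errors", {
  m <- get_model("K")
  expect_silent(validate_active_site(m))
  expect_false(anyDuplicated(m$atoms$role) > 0)
  expect_true(all(m$atoms$mass > 0))
  d1 <- model_distance(m, "BPA_O2p", "Gp1_P")
  d2 <- model_distance(m, "G1_O3p", "Gp1_P")
  expect_true(d2 < d1 && d2 > 0)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
  dm <- as.matrix(dist(xyz)); diag(dm) <- Inf
  expect_gte(min(dm), 0.8)
  expect_error(build_active_site("Na"))
  bad <- m; bad$atoms$role[2] <- bad$atoms$role[1]
  expect_error(validate_active_site(bad), "duplicate")
})

test_that("lithium build sits in binding pose 1 with ~2 A contacts", {
  ml <- get_model("Li")
  expect_equal(ml$atoms$element[ml$atoms$role == "K1"], "Li")
  expect_equal(model_distance(ml, "K1", "G52_O"), 2.0, tolerance = 1e-6)
  expect_equal(model_distance(ml, "K1", "U80_O"), 2.0, tolerance = 1e-6)
  expect_gt(model_distance(ml, "K1", "A59_O"), 2.5)
  expect_gt(model_distance(ml, "K1", "G60_O"), 2.5)
})

test_that("coordination sphere is sorted, bounded by the cutoff, and empty at tiny cutoff", {
  m <- get_model("K")
  cs <- coordination_sphere(m, "K1", cutoff = 3.5)
  expect_true(!is.unsorted(cs$distance))
  expect_true(all(cs$distance <= 3.5))
  # brute-force re-scan
  ox <- m$atoms[m$atoms$element == "O", ]
  ion <- model_position(m, "K1")
  d <- sqrt((ox$x - ion[1])^2 + (ox$y - ion[2])^2 + (ox$z - ion[3])^2)
  expect_equal(nrow(cs), sum(d <= 3.5))
  expect_equal(nrow(coordination_sphere(m, "K1", cutoff = 0.1)), 0)
  expect_error(coordination_sphere(m, "K1", cutoff = -1))
})

test_that("model and trajectory export round-trip through XYZ and PDB", {
  m <- get_model("K")
  xyz <- tempfile(fileext = ".xyz")
  write_xyz(m, xyz)
  back <- read_xyz(xyz, labels = m$atoms$role)
  expect_equal(back$coords[1, , ],
               unname(as.matrix(m$atoms[, c("x", "y", "z")])),
               tolerance = 1e-7)
  pdb <- tempfile(fileext = ".pdb")
  write_pdb(m, pdb)
  lines <- readLines(pdb)
  expect_equal(sum(grepl("^HETATM", lines)), 3)  # M1, M2, K1
  expect_equal(sum(grepl("^ATOM", lines)), nrow(m$atoms) - 3)
})
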