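test_that("forces are the exact negative gradient (finite-difference check)", {
  m <- get_model("K")
  p <- quick_double_well()
  # include a shaping term so its Hermite derivative is covered too
  p$shape <- list(x0 = -2, h = 0.25, value = sin(seq(-2, 2, by = 0.25)),
                  deriv = cos(seq(-2, 2, by = 0.25)))
  set.seed(7)
  for (rep in 1:5) {
    pos <- as.matrix(get_model("K")$atoms[, c("x", "y", "z")])
    pos <- pos + matrix(rnorm(length(pos), 0, 0.15), nrow(pos))
    ef <- reactive_energy_forces(pos, m, p)
    expect_true(is.finite(ef$energy))
    num <- numeric_gradient(pos, m, p)
    scale <- max(abs(num), 1)
    expect_lt(max(abs(ef$force + num)) / scale, 1e-6)
  }
})

test_that("net force vanishes at a basin center", {
  m <- get_model("K")
  p <- quick_single_well(xi_c = 0, s_c = 4.0)
  # place the reactive core at d1 = d2 = 2.0 (xi = 0, s = 4), collinear
  pos <- as.matrix(m$atoms[, c("x", "y", "z")])
  rownames(pos) <- m$atoms$role
  pos["BPA_O2p", ] <- pos["Gp1_P", ] + c(-2, 0, 0)
  pos["G1_O3p", ] <- pos["Gp1_P", ] + c(2, 0, 0)
  p2 <- p; p2$wall_a <- 0   # remove the (tiny) wall asymmetry
  ef <- reactive_energy_forces(pos, m, p2)
  core <- m$atoms$role %in% c("BPA_O2p", "Gp1_P", "G1_O3p")
  expect_lt(max(abs(ef$force[core, ])), 1e-10)
})

test_that("reactive energy is invariant under rigid rotation and translation", {
  m <- get_model("K")
  p <- quick_double_well()
  pos <- as.matrix(m$atoms[, c("x", "y", "z")])
  e0 <- reactive_energy_forces(pos, m, p)$energy
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  # rotate/translate everything, including the restraint centers
  m2 <- m
  xyz2 <- pos %*% R + matrix(c(1.5, -2, 0.5), nrow(pos), 3, byrow = TRUE)
  m2$atoms$x <- xyz2[, 1]; m2$atoms$y <- xyz2[, 2]; m2$atoms$z <- xyz2[, 3]
  e1 <- reactive_energy_forces(xyz2, m2, p)$energy
  expect_equal(e1, e0, tolerance = 1e-10)
})

test_that("overlapping reactive atoms trigger the hard wall", {
  m <- get_model("K")
  p <- quick_double_well()
  pos <- as.matrix(m$atoms[, c("x", "y", "z")])
  rownames(pos) <- m$atoms$role
  pos["G1_O3p", ] <- pos["Gp1_P", ] + c(0.3, 0, 0)
  expect_error(reactive_energy_forces(pos, m, p), "overlap")
})

test_that("parameter validation rejects non-well depths and bad widths", {
  b <- data.frame(depth = 2, xi_c = 0, s_c = 4, w_xi = 0.3, w_s = 0.5)
  expect_error(pes_params(b), "negative")
  b$depth <- -2; b$w_xi <- -0.1
  expect_error(pes_params(b), "widths")
  expect_error(pes_params(data.frame(depth = -2)), "columns")
})
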