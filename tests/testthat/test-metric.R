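# Blue-moon metric correction: Z and kappa for the difference-of-distances
# constraint, checked against finite-difference oracles, plus the exact
# identity for a plain distance constraint.

.masses <- c(BPA_O2p = 15.999, Gp1_P = 30.974, G1_O3p = 15.999)

make_core_traj <- function(frames_list, lambda = NULL) {
  nf <- length(frames_list)
  coords <- array(NA_real_, c(nf, 3, 3))
  for (f in seq_len(nf)) coords[f, , ] <- frames_list[[f]]
  make_traj(coords, names(.masses),
            lambda = if (is.null(lambda)) rep(1, nf) else lambda)
}

test_that("correction is exactly the identity for a distance constraint", {
  set.seed(21)
  frames <- replicate(20, matrix(rnorm(9, sd = 2), 3, 3), simplify = FALSE)
  lam <- rnorm(20, 5)
  traj <- make_core_traj(frames, lam)
  mc <- metric_correction(traj, c("BPA_O2p", "Gp1_P"), .masses,
                          type = "distance")
  expect_equal(mc$corrected, mc$raw, tolerance = 1e-14)
  expect_equal(mc$ratio, 0)
  expect_true(all(mc$kappa == 0))
  expect_equal(mc$Z, rep(1 / 15.999 + 1 / 30.974, 20))
})

test_that("Z and kappa match finite-difference evaluation on fixed frames", {
  sigma_of <- function(x) {
    a <- x[1, ]; p <- x[2, ]; b <- x[3, ]
    sqrt(sum((b - p)^2)) - sqrt(sum((a - p)^2))
  }
  grad_of <- function(x, h = 1e-6) {
    g <- matrix(0, 3, 3)
    for (i in 1:3) for (k in 1:3) {
      xp <- x; xp[i, k] <- xp[i, k] + h
      xm <- x; xm[i, k] <- xm[i, k] - h
      g[i, k] <- (sigma_of(xp) - sigma_of(xm)) / (2 * h)
    }
    g
  }
  set.seed(12)
  for (rep in 1:4) {
    x <- matrix(rnorm(9, sd = 1.5), 3, 3)
    x[1, ] <- x[2, ] + c(2.5, 0.3, -0.4); x[3, ] <- x[2, ] + c(-1, 1.5, 0.8)
    traj <- make_core_traj(list(x))
    mc <- metric_correction(traj, names(.masses), .masses)
    g <- grad_of(x)
    mv <- unname(.masses)
    Z_fd <- sum(rowSums(g^2) / mv)
    expect_equal(mc$Z[1], Z_fd, tolerance = 1e-6)
    # kappa = Z^-2 sum_ij (1/mi mj) grad_i . Hess_ij . grad_j by finite
    # differences of the analytic gradient
    h <- 1e-5
    S <- 0
    for (j in 1:3) for (k in 1:3) {
      xp <- x; xp[j, k] <- xp[j, k] + h
      xm <- x; xm[j, k] <- xm[j, k] - h
      dH <- (grad_of(xp) - grad_of(xm)) / (2 * h)  # d grad / d x_{jk}
      S <- S + sum((g / mv) * dH) * g[j, k] / mv[j]
    }
    # second differences of an already finite-differenced gradient carry
    # ~1e-3 relative noise
    expect_equal(mc$kappa[1], S / Z_fd^2, tolerance = 5e-3)
  }
})

test_that("correction on steep-force windows of the toy run is below 1 percent", {
  p <- get_calibrated("K")
  m <- get_model("K")
  set.seed(31)
  st <- init_state(m, p, xi = -1.0)
  lp <- langevin_params(seed = 31)
  w <- sample_window(st, m, p, lp, xi = -1.0, n_steps = 12000)
  keep <- which(w$trajectory$step > 4000)
  mc <- metric_correction(w$trajectory, c("BPA_O2p", "Gp1_P", "G1_O3p"),
                          setNames(m$atoms$mass, m$atoms$role),
                          frames = keep)
  expect_gt(abs(mc$raw), 5)
  expect_lt(mc$ratio, 0.01)
})
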