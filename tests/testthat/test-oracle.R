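test_that("a d1<->d2 symmetric well gives a profile symmetric about 0", {
  p <- quick_single_well(xi_c = 0, s_c = 4.0)
  grid <- seq(-0.8, 0.8, by = 0.02)
  pr <- oracle_profile(p, grid, reactant_max = 0.8)
  # V(d1, d2) = V(d2, d1) here, so F(xi) = F(-xi) exactly
  expect_equal(pr$F, rev(pr$F), tolerance = 1e-6)
  expect_equal(pr$xi[which.min(pr$F)], 0, tolerance = 0.021)
})

test_that("quadrature agrees with stats::integrate and is grid-halving stable", {
  p <- quick_double_well()
  kT <- kB_kcal() * p$temperature
  grid <- c(-0.9, -0.3, 0.2, 0.7)
  pr <- oracle_profile(p, grid, tol = 0.005, reactant_max = 0)
  expect_lt(attr(pr, "quad_tol"), 0.005)
  ref <- vapply(grid, function(xi) {
    h <- function(d1) d1^2 * (d1 + xi)^2 *
      exp(-(pes_energy_line(d1, xi, p)) / kT)
    -kT * log(stats::integrate(h, max(0.55, 0.55 - xi),
                               p$confine_d + 2.5 - max(0, xi),
                               rel.tol = 1e-10)$value)
  }, numeric(1))
  ref <- ref - min(ref[grid <= 0])
  expect_equal(pr$F, ref, tolerance = 1e-4)
})

test_that("profile is invariant under adding a constant to the potential", {
  p <- quick_double_well()
  grid <- seq(-1, 1, by = 0.1)
  f1 <- oracle_profile(p, grid, reactant_max = 0)$F
  p2 <- p
  p2$shape <- list(x0 = -3, h = 6, value = c(7.3, 7.3), deriv = c(0, 0))
  f2 <- oracle_profile(p2, grid, reactant_max = 0)$F
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("unconfined parameters raise the non-integrability diagnostic", {
  p <- quick_double_well()
  p$confine_k <- 0
  expect_error(oracle_profile(p, seq(-0.5, 0.5, 0.1)), "confine")
})

test_that("oracle profile matches a brute-force histogram of unconstrained sampling", {
  p <- quick_double_well()
  m <- get_model("K")
  st <- init_state(m, p, xi = -0.5)
  sp <- bluemoonti:::.spectator_restraints(m, p)
  set.seed(99)
  r <- bluemoonti:::cpp_run(st$pos, st$vel, m$atoms$mass, sp$k, sp$centers,
                            bluemoonti:::.core_idx0(m),
                            bluemoonti:::.pes_clist(p),
                            FALSE, 0, 0, 2e6L, 1.0, 0.05, 300, 2L,
                            1e-8, 500L, TRUE)
  xi <- r$frame_xi
  br <- seq(-1.2, 1.2, by = 0.08)
  hc <- hist(xi[xi > br[1] & xi < br[length(br)]], breaks = br,
             plot = FALSE)
  keep <- hc$counts > 4000   # well-sampled bins only
  kT <- kB_kcal() * 300
  Fh <- -kT * log(hc$counts[keep])
  ctr <- hc$mids[keep]
  pr <- oracle_profile(p, ctr, reactant_max = 1.3)
  Fo <- pr$F
  # align gauges and compare with a statistical + binning allowance
  Fh <- Fh - mean(Fh); Fo <- Fo - mean(Fo)
  se <- kT / sqrt(hc$counts[keep])   # Poisson, ignoring correlation
  expect_lt(max(abs(Fh - Fo)), 2 * max(se) + 0.08)
})
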