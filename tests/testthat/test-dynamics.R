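test_that("constraint residual and gradient are exact", {
  m <- get_model("K")
  pos <- as.matrix(m$atoms[, c("x", "y", "z")])
  # reactant build: d1 = 3.3, d2 = 1.6, so sigma = (d2 - d1) - xi
  cs <- constraint_spec(xi = -1.4)
  r <- constraint_residual(pos, cs, m)
  expect_equal(r$sigma, -0.3, tolerance = 1e-9)
  cs0 <- constraint_spec(xi = -1.7)
  expect_equal(constraint_residual(pos, cs0, m)$sigma, 0, tolerance = 1e-9)
  # central-difference check of the gradient at a random geometry
  set.seed(3)
  pos2 <- pos + matrix(rnorm(length(pos), 0, 0.2), nrow(pos))
  r2 <- constraint_residual(pos2, cs, m)
  h <- 1e-6
  idx <- match(cs$roles, m$atoms$role)
  for (a in seq_along(idx))
    for (k in 1:3) {
      pp <- pos2; pp[idx[a], k] <- pp[idx[a], k] + h
      pm <- pos2; pm[idx[a], k] <- pm[idx[a], k] - h
      num <- (constraint_residual(pp, cs, m)$sigma -
                constraint_residual(pm, cs, m)$sigma) / (2 * h)
      expect_equal(r2$grad[a, k], num, tolerance = 1e-6)
    }
  expect_error(constraint_spec(roles = c("a", "a", "b")), "distinct")
})

test_that("zero temperature, zero force leaves the state unchanged with lambda = 0", {
  m <- get_model("K")
  p <- quick_single_well(xi_c = 0, s_c = 4.0)
  p$wall_a <- 0; p$restraint_k <- 0
  st <- init_state(m, p, xi = 0)
  lp <- langevin_params(temperature = 0, friction = 0, timestep = 0.5)
  out <- step_constrained(st, m, p, lp, constraint_spec(xi = 0))
  expect_equal(out$lambda, 0, tolerance = 1e-9)
  expect_equal(unname(out$state$pos), unname(st$pos), tolerance = 1e-9)
})

test_that("zero-temperature lambda equals the analytic restoring force (sign convention)", {
  m <- get_model("K")
  p <- quick_single_well(depth = -6, xi_c = 0, s_c = 4.0)
  xi_hold <- 0.3
  # damped dynamics at T = 0 relax onto the constrained minimum
  st <- init_state(m, p, xi = xi_hold)
  lp <- langevin_params(temperature = 0, friction = 0.05, timestep = 0.25)
  w <- sample_window(st, m, p, lp, xi = xi_hold, n_steps = 4000)
  lam <- tail(w$lambda, 1)
  # analytic: dE/dxi of the transversally relaxed potential energy
  Emin <- function(xi) optimize(function(d1) pes_energy_line(d1, xi, p),
                                c(1.0, 4.0))$objective
  dEdxi <- (Emin(xi_hold + 1e-4) - Emin(xi_hold - 1e-4)) / 2e-4
  expect_equal(lam, dEdxi, tolerance = 1e-3)
  expect_gt(lam, 0)  # restoring force pulls back towards the minimum
})

test_that("NVE dynamics with the constraint conserve energy", {
  m <- get_model("K")
  p <- quick_double_well()
  st <- init_state(m, p, xi = -0.5)
  # thermalise briefly, then switch the thermostat off
  lp_eq <- langevin_params(temperature = 300, friction = 0.05,
                           timestep = 0.5, seed = 11)
  weq <- sample_window(st, m, p, lp_eq, xi = -0.5, n_steps = 2000)
  lp0 <- langevin_params(temperature = 300, friction = 0, timestep = 0.5)
  w <- sample_window(weq$state, m, p, lp0, xi = -0.5, n_steps = 20000,
                     stride = 5)
  E <- w$trajectory$ke + w$trajectory$pe
  n <- length(E)
  drift_per_1000 <- abs(mean(E[(n - 200):n]) - mean(E[1:200])) /
    (w$trajectory$step[n] - w$trajectory$step[100]) * 1000
  expect_lt(drift_per_1000, 1e-4)
})

test_that("drag duration follows the growth rate and lands on target", {
  m <- get_model("K")
  p <- quick_double_well()
  st <- init_state(m, p, xi = -0.5)
  lp <- langevin_params(seed = 5)
  out <- drag_rc(st, m, p, lp, -0.5, -0.3, growth_rate = 0.003)
  expect_equal(attr(out, "nsteps"), 134L)  # 0.2 / 0.003 / 0.5 fs, rounded up
  cs <- constraint_spec(xi = -0.3)
  expect_lt(abs(constraint_residual(out$pos, cs, m)$sigma), 1e-8)
  same <- drag_rc(st, m, p, lp, -0.5, -0.5)
  expect_equal(attr(same, "nsteps"), 0L)
  expect_equal(same$pos, st$pos)
})

test_that("default-protocol windows store the expected step counts", {
  m <- get_model("K")
  p <- quick_double_well()
  st <- init_state(m, p, xi = 0)
  lp <- langevin_params(seed = 8)
  w <- sample_window(st, m, p, lp, xi = 0, n_steps = 10000)
  expect_length(w$lambda, 10000)      # 5 ps at 0.5 fs
  expect_equal(n_frames(w$trajectory), 2000)  # stride 5
  expect_lt(w$sigma_max, 1e-8)
})

test_that("schedules are deterministic and extend the proton-transfer windows", {
  m <- get_model("K")
  p <- quick_double_well()
  lp <- langevin_params()
  grid <- seq(-0.6, 0.6, by = 0.2)
  s1 <- run_schedule(m, p, grid = grid, lp = lp, window_ps = 0.4,
                     equil_ps = 0.1, extended_ps = 0.8,
                     extended_equil_ps = 0.2, master_seed = 17)
  s2 <- run_schedule(m, p, grid = grid, lp = lp, window_ps = 0.4,
                     equil_ps = 0.1, extended_ps = 0.8,
                     extended_equil_ps = 0.2, master_seed = 17)
  expect_identical(lapply(s1$windows, `[[`, "lambda"),
                   lapply(s2$windows, `[[`, "lambda"))
  lens <- vapply(s1$windows, function(w) length(w$lambda), numeric(1))
  expect_equal(lens, ifelse(abs(abs(grid) - 0.6) < 1e-9, 1600, 800))
  eq <- vapply(s1$windows, `[[`, numeric(1), "equil_steps")
  expect_equal(eq, ifelse(abs(abs(grid) - 0.6) < 1e-9, 400, 200))
  expect_true(all(vapply(s1$windows, `[[`, numeric(1), "sigma_max") < 1e-8))
  # single-window grid degenerates to sample_window
  s3 <- run_schedule(m, p, grid = 0, lp = lp, window_ps = 0.4,
                     equil_ps = 0.1, master_seed = 17)
  set.seed(bluemoonti:::.window_seed(17, 1))
  ref <- sample_window(init_state(m, p, xi = 0), m, p, lp, xi = 0,
                       n_steps = 800)
  expect_identical(s3$windows[[1]]$lambda, ref$lambda)
})

test_that("default schedule grid is the 16-point protocol", {
  g <- default_rc_grid()
  expect_length(g, 16)
  expect_equal(g[1], -1.4)
  expect_equal(g[length(g)], 1.6)
  expect_equal(unique(round(diff(g), 10)), 0.2)
})

test_that("kinetic temperature matches the thermostat within 3 sigma", {
  m <- get_model("K")
  p <- quick_double_well()
  st <- init_state(m, p, xi = 0)
  lp <- langevin_params(temperature = 300, friction = 0.01,
                        timestep = 0.5, seed = 23)
  w <- sample_window(st, m, p, lp, xi = 0, n_steps = 12000)
  ke <- w$trajectory$ke[w$trajectory$step > 2000]
  dof <- 3 * nrow(m$atoms) - 1
  Tinst <- 2 * ke / (dof * kB_kcal())
  phi <- cor(Tinst[-1], Tinst[-length(Tinst)])
  g <- (1 + phi) / (1 - phi)
  se <- sd(Tinst) * sqrt(g / length(Tinst))
  expect_lt(abs(mean(Tinst) - 300), 3 * se + 3)  # +3 K discretisation slack
})
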