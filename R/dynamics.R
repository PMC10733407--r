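# Constrained Langevin dynamics drivers. The reaction coordinate is
# xi = d2 - d1 (breaking minus forming bond length at the scissile
# phosphate); the holonomic constraint sigma(r) = d2 - d1 - xi_target is
# enforced by SHAKE position projection plus RATTLE velocity projection.
# The recorded Lagrange multiplier is the total constraint impulse per
# step expressed as a force (the coefficient of grad sigma), with the sign
# fixed so that dF/dxi equals the window-averaged multiplier; the
# convention is pinned by a closed-form zero-temperature test.

#' Constraint specification for the reaction coordinate
#'
#' @param roles Atom roles: for the difference constraint, (nucleophile O,
#'   shared P, leaving O); for a plain distance, two roles.
#' @param xi Target value (A).
#' @param tol Convergence tolerance on |sigma| (A).
#' @param maxiter Maximum projection iterations.
#' @param type `"difference"` (d2 - d1) or `"distance"`.
#' @return Object of class `constraint_spec`.
#' @export
constraint_spec <- function(roles = c("BPA_O2p", "Gp1_P", "G1_O3p"),
                            xi = 0, tol = 1e-8, maxiter = 500,
                            type = c("difference", "distance")) {
  type <- match.arg(type)
  if (tol <= 0) stop("tolerance must be positive")
  if (anyDuplicated(roles)) stop("constraint roles must be distinct")
  if (type == "difference" && length(roles) != 3)
    stop("difference constraint needs three roles")
  if (type == "distance" && length(roles) != 2)
    stop("distance constraint needs two roles")
  structure(list(roles = roles, xi = xi, tol = tol, maxiter = maxiter,
                 type = type), class = "constraint_spec")
}

#' Langevin dynamics parameters
#'
#' The canonical ensemble is generated by a Langevin thermostat (velocity
#' Ornstein-Uhlenbeck refresh each step); friction 0 gives NVE dynamics.
#'
#' @param temperature Temperature (K).
#' @param friction Friction (1/fs).
#' @param timestep Timestep (fs).
#' @param seed Optional RNG seed applied before propagation.
#' @return Object of class `langevin_params`.
#' @export
langevin_params <- function(temperature = 300, friction = 0.01,
                            timestep = 0.5, seed = NULL) {
  if (timestep <= 0) stop("timestep must be positive")
  if (friction < 0) stop("friction must be non-negative")
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, seed = seed),
            class = "langevin_params")
}

#' Constraint value and analytic gradient
#'
#' @param positions n_atoms x 3 matrix ordered as `model$atoms`.
#' @param spec A `constraint_spec`.
#' @param model The `active_site_model` resolving roles to rows.
#' @return List with `sigma` (A) and `grad`, a (n_roles x 3) matrix of
#'   d sigma / d r for the constrained atoms (rows named by role).
#' @export
constraint_residual <- function(positions, spec, model) {
  positions <- as.matrix(positions)
  idx <- match(spec$roles, model$atoms$role)
  if (any(is.na(idx))) stop("unknown constraint role")
  if (spec$type == "distance") {
    a <- positions[idx[1], ]; b <- positions[idx[2], ]
    d <- sqrt(sum((a - b)^2))
    if (d < 1e-10) stop("coincident atoms: constraint direction undefined")
    u <- (a - b) / d
    grad <- rbind(u, -u)
    rownames(grad) <- spec$roles
    return(list(sigma = d - spec$xi, grad = grad))
  }
  a <- positions[idx[1], ]; p <- positions[idx[2], ]; b <- positions[idx[3], ]
  d1 <- sqrt(sum((a - p)^2)); d2 <- sqrt(sum((b - p)^2))
  if (d1 < 1e-10 || d2 < 1e-10)
    stop("coincident atoms: constraint direction undefined")
  u <- (a - p) / d1; w <- (b - p) / d2
  grad <- rbind(-u, u - w, w)
  rownames(grad) <- spec$roles
  list(sigma = (d2 - d1) - spec$xi, grad = grad)
}

#' Initial dynamics state at a reaction-coordinate value
#'
#' Places the reactive core on the constrained minimum of the reactive
#' surface at the requested xi (forming-bond length optimised along the
#' constraint line), keeps spectators at their build positions and zeroes
#' all velocities.
#'
#' @param model An `active_site_model`.
#' @param params A `pes_params`.
#' @param xi Reaction-coordinate value (A).
#' @return List with `pos`, `vel` (n_atoms x 3) and `xi`.
#' @export
init_state <- function(model, params, xi = 0) {
  opt <- stats::optimize(function(d1) pes_energy_line(d1, xi, params),
                         interval = c(max(0.8, 0.8 - xi),
                                      params$confine_d + 1))
  d1s <- opt$minimum
  d2s <- d1s + xi
  pos <- as.matrix(model$atoms[, c("x", "y", "z")])
  rownames(pos) <- model$atoms$role
  p <- pos["Gp1_P", ]
  ua <- .unit(pos["BPA_O2p", ] - p)
  ub <- .unit(pos["G1_O3p", ] - p)
  pos["BPA_O2p", ] <- p + d1s * ua
  pos["G1_O3p", ] <- p + d2s * ub
  list(pos = pos, vel = matrix(0, nrow(pos), 3), xi = xi)
}

.run_cpp <- function(state, model, params, lp, constrained, xi_from, xi_to,
                     nsteps, stride, tol = 1e-8, maxiter = 500,
                     record_frames = TRUE) {
  sp <- .spectator_restraints(model, params)
  cpp_run(state$pos, state$vel, model$atoms$mass, sp$k, sp$centers,
          .core_idx0(model), .pes_clist(params),
          constrained, xi_from, xi_to, as.integer(nsteps), lp$timestep,
          lp$friction, lp$temperature, as.integer(stride), tol,
          as.integer(maxiter), record_frames)
}

#' One constrained integration step
#'
#' A velocity-Verlet step with Langevin velocity refresh, followed by
#' SHAKE/RATTLE projection onto the constraint; returns the updated state
#' and the recorded Lagrange multiplier (kcal/mol/A).
#'
#' @param state State from [init_state()] or a previous step.
#' @param model,params,lp Model, surface and Langevin parameters.
#' @param spec A `constraint_spec` (its `xi` is held fixed).
#' @return List with `state` and `lambda`.
#' @export
step_constrained <- function(state, model, params, lp, spec) {
  if (!is.null(lp$seed)) set.seed(lp$seed)
  r <- .run_cpp(state, model, params, lp, TRUE, spec$xi, spec$xi, 1L, 1L,
                tol = spec$tol, maxiter = spec$maxiter,
                record_frames = FALSE)
  list(state = list(pos = r$pos, vel = r$vel, xi = spec$xi),
       lambda = r$lambda[1])
}

#' Drag the reaction coordinate at a fixed growth rate
#'
#' Moves the constraint target linearly in time from `xi_from` to `xi_to`
#' at `growth_rate`, stepping the constrained dynamics; duration is
#' |xi_to - xi_from| / growth_rate, rounded up to whole steps.
#'
#' @param state Current state (assumed at `xi_from`).
#' @param model,params,lp Model, surface and Langevin parameters.
#' @param xi_from,xi_to Start and end targets (A).
#' @param growth_rate Rate of change of xi (A/fs).
#' @param tol,maxiter Constraint projection controls.
#' @return Updated state (at `xi_to`), with attribute `nsteps`.
#' @export
drag_rc <- function(state, model, params, lp, xi_from, xi_to,
                    growth_rate = 0.003, tol = 1e-8, maxiter = 500) {
  if (growth_rate <= 0) stop("growth rate must be positive")
  if (xi_from == xi_to) {
    out <- state
    attr(out, "nsteps") <- 0L
    return(out)
  }
  nsteps <- as.integer(ceiling(abs(xi_to - xi_from) /
                                 (growth_rate * lp$timestep)))
  r <- .run_cpp(state, model, params, lp, TRUE, xi_from, xi_to, nsteps,
                nsteps, tol = tol, maxiter = maxiter, record_frames = FALSE)
  out <- list(pos = r$pos, vel = r$vel, xi = xi_to)
  attr(out, "nsteps") <- nsteps
  out
}

.make_trajectory <- function(r, model, lp, stride, xi_target) {
  nf <- nrow(r$frames)
  na <- nrow(model$atoms)
  coords <- array(r$frames, dim = c(nf, 3, na))
  coords <- aperm(coords, c(1, 3, 2))  # frames stored column-major (xyz, atom)
  structure(list(coords = coords, labels = model$atoms$role,
                 elements = model$atoms$element,
                 rc = r$frame_xi, lambda = r$frame_lambda,
                 ke = r$frame_ke, pe = r$frame_pe, step = r$frame_step,
                 dt = lp$timestep, stride = stride, xi_target = xi_target),
            class = "bm_trajectory")
}

#' Sample a constrained window
#'
#' Runs `n_steps` of constrained dynamics at fixed xi, storing frames every
#' `stride` steps and the Lagrange multiplier at every step.
#'
#' @param state State positioned at (or near) `xi`; project first with
#'   [drag_rc()] if needed.
#' @param model,params,lp Model, surface and Langevin parameters.
#' @param xi Constraint target (A).
#' @param n_steps Number of dynamics steps.
#' @param stride Frame-storage stride (steps).
#' @param tol,maxiter Constraint projection controls.
#' @return List with `trajectory` (a `bm_trajectory`), `lambda` (full
#'   series), `state` (end state) and `sigma_max` (largest |sigma| on any
#'   stored frame).
#' @export
sample_window <- function(state, model, params, lp, xi, n_steps,
                          stride = 5L, tol = 1e-8, maxiter = 500) {
  if (!is.null(lp$seed)) set.seed(lp$seed)
  r <- .run_cpp(state, model, params, lp, TRUE, xi, xi, n_steps, stride,
                tol = tol, maxiter = maxiter, record_frames = TRUE)
  list(trajectory = .make_trajectory(r, model, lp, stride, xi),
       lambda = r$lambda,
       state = list(pos = r$pos, vel = r$vel, xi = xi),
       sigma_max = r$sigma_max)
}

#' Default reaction-coordinate schedule
#'
#' @return The 16-point grid from -1.4 to 1.6 A in 0.2 A steps.
#' @export
default_rc_grid <- function() seq(-1.4, 1.6, by = 0.2)

.window_seed <- function(master_seed, widx) {
  as.integer((as.numeric(master_seed) * 131L + widx * 7919) %% 2147483647)
}

#' Run the full constrained-sampling schedule
#'
#' Samples every grid point, proceeding outward from xi = 0 towards the
#' reactant and the product ends; each window starts from the endpoint of
#' its neighbour dragged to the new target at the stated growth rate. Each
#' window draws from its own RNG stream derived from (`master_seed`,
#' window index), so results are reproducible window by window.
#'
#' @param model,params Model and calibrated surface.
#' @param grid Sorted xi grid containing 0.
#' @param lp A `langevin_params`.
#' @param window_ps Window length (ps) including equilibration.
#' @param equil_ps Equilibration time (ps) later discarded by
#'   [window_stats()]; recorded in the result.
#' @param extended_at Grid values whose windows are extended.
#' @param extended_ps,extended_equil_ps Window/equilibration length (ps)
#'   for extended windows.
#' @param growth_rate Drag rate between windows (A/fs).
#' @param master_seed Master seed for the per-window streams.
#' @param stride Frame-storage stride.
#' @return Object of class `bm_schedule`: list of windows, each with `xi`,
#'   `trajectory`, `lambda`, `equil_steps`, `sigma_max`, `seed`.
#' @export
run_schedule <- function(model, params, grid = default_rc_grid(),
                         lp = langevin_params(),
                         window_ps = 5, equil_ps = 2,
                         extended_at = c(-0.6, 0.6),
                         extended_ps = 7, extended_equil_ps = 4,
                         growth_rate = 0.003, master_seed = 1,
                         stride = 5L) {
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be sorted")
  if (!any(abs(grid) < 1e-9))
    stop("bidirectional protocol requires 0 in the grid")
  i0 <- which(abs(grid) < 1e-9)
  steps_of <- function(xi) {
    ext <- any(abs(xi - extended_at) < 1e-9)
    ps <- if (ext) extended_ps else window_ps
    eq <- if (ext) extended_equil_ps else equil_ps
    c(total = round(ps * 1000 / lp$timestep),
      equil = round(eq * 1000 / lp$timestep))
  }
  windows <- vector("list", length(grid))
  run_one <- function(state, xi_prev, widx) {
    xi <- grid[widx]
    set.seed(.window_seed(master_seed, widx))
    if (abs(xi - xi_prev) > 1e-12)
      state <- drag_rc(state, model, params, lp, xi_prev, xi, growth_rate)
    ns <- steps_of(xi)
    w <- sample_window(state, model, params, lp, xi, ns[["total"]],
                       stride = stride)
    list(window = list(xi = xi, trajectory = w$trajectory,
                       lambda = w$lambda, equil_steps = ns[["equil"]],
                       sigma_max = w$sigma_max,
                       seed = .window_seed(master_seed, widx)),
         state = w$state)
  }
  state0 <- init_state(model, params, xi = grid[i0])
  r0 <- run_one(state0, grid[i0], i0)
  windows[[i0]] <- r0$window
  state <- r0$state
  if (i0 > 1) {
    for (widx in (i0 - 1):1) {
      r <- run_one(state, grid[widx + 1], widx)
      windows[[widx]] <- r$window
      state <- r$state
    }
  }
  state <- r0$state
  if (i0 < length(grid)) {
    for (widx in (i0 + 1):length(grid)) {
      r <- run_one(state, grid[widx - 1], widx)
      windows[[widx]] <- r$window
      state <- r$state
    }
  }
  structure(list(windows = windows, grid = grid, lp = lp,
                 master_seed = master_seed),
            class = "bm_schedule")
}

#' Window statistics for a whole schedule
#'
#' Applies [window_stats()] to every window and, when `correction` is
#' `"apply"` or `"report"`, evaluates the blue-moon metric correction on
#' the retained stored frames; the corrected mean force shifts the
#' full-resolution raw mean by the frame-level correction increment.
#'
#' @param schedule A `bm_schedule`.
#' @param model The model (for masses).
#' @param conv_tol,se_mode Passed to [window_stats()].
#' @param correction `"apply"` (default), `"report"` (computed, not used
#'   for integration) or `"off"`.
#' @return Data frame of per-window statistics sorted by xi.
#' @export
schedule_stats <- function(schedule, model,
                           conv_tol = 0.5,
                           se_mode = c("autocorr", "naive", "sd"),
                           correction = c("apply", "report", "off")) {
  se_mode <- match.arg(se_mode)
  correction <- match.arg(correction)
  masses <- stats::setNames(model$atoms$mass, model$atoms$role)
  rows <- lapply(schedule$windows, function(w) {
    st <- window_stats(w$lambda, dt = schedule$lp$timestep,
                       n_discard = w$equil_steps, xi = w$xi,
                       conv_tol = conv_tol, se_mode = se_mode)
    st$sigma_max <- w$sigma_max
    if (correction != "off") {
      keep <- w$trajectory$step > w$equil_steps
      mc <- metric_correction(w$trajectory, c("BPA_O2p", "Gp1_P", "G1_O3p"),
                              masses,
                              temperature = schedule$lp$temperature,
                              frames = which(keep))
      delta <- mc$corrected - mc$raw
      st$corrected_force <- st$mean_force + delta
      st$correction_ratio <- if (abs(st$mean_force) > 0)
        abs(delta) / abs(st$mean_force) else NA_real_
      if (correction == "report") st$corrected_force <- NA_real_
    }
    st
  })
  out <- do.call(rbind, rows)
  out[order(out$xi), , drop = FALSE]
}
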