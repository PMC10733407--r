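# Shared fixtures. Calibrated surfaces are cached per session because the
# least-squares stage takes tens of seconds.

.fixture_cache <- new.env(parent = emptyenv())

get_calibrated <- function(ion) {
  key <- paste0("pes_", ion)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- suppressWarnings(calibrated_pes(ion))
  .fixture_cache[[key]]
}

get_model <- function(ion = "K") {
  key <- paste0("model_", ion)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- build_active_site(ion)
  .fixture_cache[[key]]
}

# the full-protocol pipeline runs used by the acceptance checks
get_pipeline <- function(ion, seeds = c(101, 102, 103)) {
  key <- paste0("pipe_", ion)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- run_profile_pipeline(
      get_model(ion), get_calibrated(ion), master_seeds = seeds,
      window_ps = 12, equil_ps = 2)
  .fixture_cache[[key]]
}

# a small smooth double-well surface for sampler-vs-oracle checks
quick_double_well <- function(depths = c(-3, -2.2), centers = c(-0.5, 0.5)) {
  pes_params(data.frame(depth = depths, xi_c = centers,
                        s_c = c(4.0, 4.0), w_xi = c(0.35, 0.35),
                        w_s = c(0.8, 0.8)))
}

# a single-basin surface (optionally symmetric in d1 <-> d2)
quick_single_well <- function(depth = -4, xi_c = 0, s_c = 4.0,
                              w_xi = 0.4, w_s = 0.8) {
  pes_params(data.frame(depth = depth, xi_c = xi_c, s_c = s_c,
                        w_xi = w_xi, w_s = w_s))
}

# central-difference gradient of the model energy
numeric_gradient <- function(positions, model, params, h = 1e-5) {
  g <- matrix(0, nrow(positions), 3)
  for (i in seq_len(nrow(positions)))
    for (k in 1:3) {
      pp <- positions; pp[i, k] <- pp[i, k] + h
      pm <- positions; pm[i, k] <- pm[i, k] - h
      g[i, k] <- (reactive_energy_forces(pp, model, params)$energy -
                    reactive_energy_forces(pm, model, params)$energy) /
        (2 * h)
    }
  g
}

# minimal hand-built trajectory object for analysis-operator tests
make_traj <- function(coords, labels, elements = NULL, rc = NULL,
                      lambda = NULL) {
  nf <- dim(coords)[1]
  structure(list(coords = coords, labels = labels,
                 elements = if (is.null(elements))
                   rep("O", length(labels)) else elements,
                 rc = if (is.null(rc)) rep(NA_real_, nf) else rc,
                 lambda = lambda, dt = NA_real_, stride = 1L,
                 xi_target = NA_real_),
            class = "bm_trajectory")
}
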