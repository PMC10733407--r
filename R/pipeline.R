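# End-to-end profile pipeline: replicate constrained-sampling schedules,
# per-window statistics pooled across replicates, trapezoid integration
# and feature extraction. This is the driver behind the analysis scripts
# and the acceptance recomputation.

#' Pool window statistics across replicate schedules
#'
#' Mean forces are averaged per window; standard errors combine in
#' quadrature assuming independent replicates (SE = sqrt(sum SE_i^2) / k).
#'
#' @param stats_list List of per-replicate window-statistics data frames.
#' @return Pooled data frame, one row per window.
#' @export
combine_window_stats <- function(stats_list) {
  k <- length(stats_list)
  if (k == 1) return(stats_list[[1]])
  xi <- stats_list[[1]]$xi
  for (s in stats_list)
    if (!isTRUE(all.equal(s$xi, xi))) stop("replicates have different grids")
  get <- function(col) sapply(stats_list, function(s) s[[col]])
  mf <- rowMeans(get("mean_force"))
  cf <- rowMeans(get("corrected_force"))
  se <- sqrt(rowSums(get("se")^2)) / k
  data.frame(xi = xi, mean_force = mf,
             sd = rowMeans(get("sd")),
             se = se,
             n_used = rowSums(get("n_used")),
             n_discarded = rowSums(get("n_discarded")),
             converged = apply(get("converged"), 1, all),
             corrected_force = cf,
             correction_ratio = apply(get("correction_ratio"), 1, max),
             sigma_max = apply(get("sigma_max"), 1, max))
}

#' Full free-energy profile pipeline on a calibrated surface
#'
#' Runs `length(master_seeds)` independent constrained-sampling schedules,
#' pools the per-window mean constraint forces, integrates with the
#' trapezoid rule and extracts the profile features.
#'
#' @param model An `active_site_model`.
#' @param params Calibrated `pes_params`.
#' @param master_seeds Integer vector of replicate seeds.
#' @param grid Reaction-coordinate grid.
#' @param lp A `langevin_params`.
#' @param window_ps,equil_ps,extended_at,extended_ps,extended_equil_ps
#'   Window schedule; see [run_schedule()].
#' @param se_mode,correction See [schedule_stats()].
#' @param stride Frame-storage stride.
#' @return List: `stats` (pooled), `per_seed` (list of per-replicate
#'   stats), `profile` (a `free_energy_profile`), `features`
#'   (a `profile_features`).
#' @export
run_profile_pipeline <- function(model, params, master_seeds = c(1, 2, 3),
                                 grid = default_rc_grid(),
                                 lp = langevin_params(),
                                 window_ps = 12, equil_ps = 2,
                                 extended_at = numeric(0),
                                 extended_ps = window_ps,
                                 extended_equil_ps = equil_ps,
                                 se_mode = "autocorr",
                                 correction = "apply", stride = 5L) {
  per_seed <- lapply(master_seeds, function(ms) {
    sch <- run_schedule(model, params, grid = grid, lp = lp,
                        window_ps = window_ps, equil_ps = equil_ps,
                        extended_at = extended_at,
                        extended_ps = extended_ps,
                        extended_equil_ps = extended_equil_ps,
                        master_seed = ms, stride = stride)
    schedule_stats(sch, model, se_mode = se_mode, correction = correction)
  })
  stats <- combine_window_stats(per_seed)
  profile <- integrate_profile(stats, allow_unconverged = TRUE)
  features <- extract_features(profile)
  list(stats = stats, per_seed = per_seed, profile = profile,
       features = features)
}
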