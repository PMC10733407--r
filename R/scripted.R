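# Scripted trajectories: deterministic fixture generator for the geometry
# analyses. Hydrogen-bond geometry, proton hand-off and monovalent-ion
# sub-site occupancy are injected frame by frame from a script, and the
# injected events are recorded as exact ground-truth metadata. Classical
# dynamics on the toy surface cannot perform the proton chemistry, so the
# observables that depend on it are exercised on scripted geometry instead.

#' Scripted trajectory from a frame-by-frame geometry script
#'
#' The script is a data frame with one row per frame; all columns are
#' optional:
#' \describe{
#'   \item{d1, d2}{forming/breaking bond lengths (A); core atoms move along
#'     their build directions from the phosphorus.}
#'   \item{hd_dist, ha_dist, angle}{proton geometry: distances (A) from the
#'     proton to the donor and acceptor oxygens and the donor-H-acceptor
#'     angle (degrees). The proton sits on the donor-side; the acceptor is
#'     repositioned to realise the scripted distance and angle exactly.}
#'   \item{pose}{monovalent-ion sub-site: 1 (G52+U80), 2 (A59+G60+U80),
#'     0 (unbound, displaced from the site).}
#'   \item{rc}{reaction-coordinate value recorded for the frame (defaults
#'     to d2 - d1 of the realised geometry).}
#' }
#'
#' @param model An `active_site_model` providing the base geometry.
#' @param script Data frame as above.
#' @param hb_triplet Roles of (donor, proton, acceptor).
#' @param ion_role Role of the shuttling ion.
#' @param pair_dists Optional list of `list(roles = c(a, b), dist = ...)`
#'   entries: atom `b` is moved along its build direction from `a` so that
#'   the pair distance follows `dist` (scalar or one value per frame).
#' @param pose_dist Ion-ligand contact distance used to realise poses (A).
#' @param jitter Named vector of per-role Gaussian jitter SD (A), applied
#'   to roles not driven by the script.
#' @param criteria [hbond_criteria()] used to record ground-truth H-bond
#'   flags in the metadata.
#' @param dwell Dwell window (frames) used to record ground-truth
#'   proton-transfer frames.
#' @param seed RNG seed for the jitter.
#' @return A `bm_trajectory` whose `metadata` attribute records, exactly,
#'   the H-bond frames, proton-transfer frames, per-frame pose labels and
#'   occupancy fractions implied by the script.
#' @export
scripted_trajectory <- function(model, script,
                                hb_triplet = c("BPA_O2p", "H2p", "OSp"),
                                ion_role = "K1", pair_dists = NULL,
                                pose_dist = 2.0, jitter = NULL,
                                criteria = hbond_criteria(),
                                dwell = 10, seed = NULL) {
  n <- nrow(script)
  if (n < 1) stop("empty script")
  num_cols <- intersect(c("d1", "d2", "hd_dist", "ha_dist", "angle"),
                        names(script))
  for (cl in num_cols)
    if (any(!is.na(script[[cl]]) & script[[cl]] <= 0))
      stop("script column ", cl, " must be positive")
  if ("angle" %in% names(script) &&
      any(!is.na(script$angle) & script$angle > 180))
    stop("script angle must be <= 180 degrees")
  driven <- c(
    if (any(c("hd_dist", "ha_dist") %in% names(script)))
      hb_triplet[2:3],
    if ("d1" %in% names(script)) .roles_core[1],
    if ("d2" %in% names(script)) .roles_core[3],
    if ("pose" %in% names(script)) ion_role)
  if (!is.null(jitter) && any(names(jitter) %in% driven))
    stop("jitter cannot be applied to script-driven atoms")
  if (!is.null(pair_dists)) {
    for (pd in pair_dists) {
      if (length(pd$roles) != 2) stop("pair_dists entries need two roles")
      if ("pose" %in% names(script) && pd$roles[2] == ion_role)
        stop("cannot script both a pose and a pair distance for the ion")
      if (any(pd$dist <= 0)) stop("pair distances must be positive")
    }
  }

  base <- as.matrix(model$atoms[, c("x", "y", "z")])
  rownames(base) <- model$atoms$role
  roles <- model$atoms$role
  p0 <- base["Gp1_P", ]
  ua <- .unit(base["BPA_O2p", ] - p0)
  ub <- .unit(base["G1_O3p", ] - p0)

  # proton frame: donor direction and a fixed normal for the angle plane
  dn <- base[hb_triplet[1], ]
  ac0 <- base[hb_triplet[3], ]
  uda <- .unit(ac0 - dn)
  nrm <- c(0, 0, 1) - sum(c(0, 0, 1) * uda) * uda
  if (sqrt(sum(nrm^2)) < 1e-6) nrm <- c(0, 1, 0) - sum(c(0, 1, 0) * uda) * uda
  nrm <- .unit(nrm)

  pose_sites <- NULL
  if ("pose" %in% names(script)) {
    g52 <- base["G52_O", ]; u80 <- base["U80_O", ]
    a59 <- base["A59_O", ]; g60 <- base["G60_O", ]
    k1b <- base["K1", ]
    p1 <- .place2(g52, pose_dist, u80, pose_dist,
                  pref = .unit(k1b - (g52 + u80) / 2))
    # pose 2: least-squares point at pose_dist from the three ligands
    obj <- function(x) {
      d <- sqrt(rowSums((rbind(a59, g60, u80) -
                           matrix(x, 3, 3, byrow = TRUE))^2))
      sum((d - pose_dist)^2)
    }
    p2 <- stats::optim(( a59 + g60 + u80) / 3 +
                         0.5 * .unit(k1b - (a59 + g60 + u80) / 3), obj,
                       method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-12))$par
    far <- k1b + 10 * .unit(k1b - (base["M1", ] + base["M2", ]) / 2)
    pose_sites <- list(`1` = p1, `2` = p2, `0` = far)
  }

  if (!is.null(seed)) set.seed(seed)
  coords <- array(NA_real_, dim = c(n, length(roles), 3))
  rc <- numeric(n)
  for (f in seq_len(n)) {
    pos <- base
    if (!is.null(script$d1) && !is.na(script$d1[f]))
      pos[.roles_core[1], ] <- p0 + script$d1[f] * ua
    if (!is.null(script$d2) && !is.na(script$d2[f]))
      pos[.roles_core[3], ] <- p0 + script$d2[f] * ub
    hd <- if (!is.null(script$hd_dist)) script$hd_dist[f] else NA
    ha <- if (!is.null(script$ha_dist)) script$ha_dist[f] else NA
    ang <- if (!is.null(script$angle)) script$angle[f] else 180
    if (!is.na(hd) || !is.na(ha)) {
      if (is.na(hd)) hd <- 1.0
      dpos <- pos[hb_triplet[1], ]
      hpos <- dpos + hd * uda
      pos[hb_triplet[2], ] <- hpos
      if (!is.na(ha)) {
        th <- ang * pi / 180
        vdir <- cos(th) * (-uda) + sin(th) * nrm
        pos[hb_triplet[3], ] <- hpos + ha * vdir
      }
    }
    if (!is.null(script$pose) && !is.na(script$pose[f])) {
      key <- as.character(script$pose[f])
      if (!key %in% names(pose_sites)) stop("pose must be 0, 1 or 2")
      pos[ion_role, ] <- pose_sites[[key]]
    }
    if (!is.null(pair_dists))
      for (pd in pair_dists) {
        d <- if (length(pd$dist) == 1) pd$dist else pd$dist[f]
        u <- .unit(base[pd$roles[2], ] - base[pd$roles[1], ])
        pos[pd$roles[2], ] <- pos[pd$roles[1], ] + d * u
      }
    if (!is.null(jitter))
      for (rl in names(jitter))
        pos[rl, ] <- pos[rl, ] + stats::rnorm(3, 0, jitter[[rl]])
    coords[f, , ] <- pos
    rc[f] <- if (!is.null(script$rc) && !is.na(script$rc[f])) script$rc[f]
    else sqrt(sum((pos[.roles_core[3], ] - pos[.roles_core[2], ])^2)) -
      sqrt(sum((pos[.roles_core[1], ] - pos[.roles_core[2], ])^2))
  }

  hb_flag <- rep(NA, n)
  if (!is.null(script$ha_dist)) {
    dev <- abs(180 - (if (!is.null(script$angle)) script$angle else
      rep(180, n)))
    hb_flag <- !is.na(script$ha_dist) &
      script$ha_dist < criteria$max_dist & dev <= criteria$max_angle_dev
  }
  pt_frames <- integer(0)
  if (!is.null(script$ha_dist) && !is.null(script$hd_dist)) {
    crossing <- script$ha_dist < script$hd_dist
    pt_frames <- .sustained_onsets(crossing, dwell)
  }
  pose_lab <- NULL
  occupancy <- NULL
  if (!is.null(script$pose)) {
    pose_lab <- ifelse(is.na(script$pose), NA,
                       ifelse(script$pose == 0, "unbound",
                              paste0("pose", script$pose)))
    occupancy <- prop.table(table(factor(pose_lab,
                                         c("pose1", "pose2", "unbound"))))
  }
  structure(list(coords = coords, labels = roles,
                 elements = model$atoms$element, rc = rc, lambda = NULL,
                 dt = NA_real_, stride = 1L, xi_target = NA_real_),
            class = "bm_trajectory",
            metadata = list(hb = hb_flag, hb_frames = which(hb_flag %in% TRUE),
                            pt_frames = pt_frames, pose = pose_lab,
                            occupancy = occupancy, script = script))
}

# onsets of TRUE-runs of length >= dwell, requiring a fresh onset
.sustained_onsets <- function(x, dwell) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  starts[r$values & r$lengths >= dwell]
}

#' Stationary AR(1) constraint-force series
#'
#' Gaussian first-order autoregressive series with the requested mean,
#' marginal SD and lag-1 autocorrelation; used to exercise the mean-force
#' estimators on series with known sampling error.
#'
#' @param mean Series mean (kcal/mol/A).
#' @param sd Marginal standard deviation.
#' @param lag1_corr Lag-1 autocorrelation, |phi| < 1.
#' @param n Length.
#' @param seed RNG seed (reproducible series).
#' @return Numeric vector of length `n`.
#' @export
synth_force_series <- function(mean, sd, lag1_corr, n, seed = NULL) {
  if (abs(lag1_corr) >= 1) stop("|lag1_corr| must be < 1")
  if (n <= 0) stop("n must be positive")
  if (sd < 0) stop("sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(rep(mean, n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  innov_sd <- sd * sqrt(1 - lag1_corr^2)
  eps <- stats::rnorm(n - 1, 0, innov_sd)
  for (t in seq_len(n - 1)) x[t + 1] <- lag1_corr * x[t] + eps[t]
  mean + x
}
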