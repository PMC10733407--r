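# Trajectory observables: labeled pair distances per window, hydrogen-bond
# frequency under distance/angle criteria, proton-transfer detection,
# relative mean square fluctuation, monovalent-ion pose classification,
# coordination spheres and a bare-Coulomb electric-field surrogate.

.traj_pos <- function(traj, role) {
  i <- match(role, traj$labels)
  if (is.na(i)) stop("unknown role label: ", role)
  p <- traj$coords[, i, , drop = FALSE][, 1, ]
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  p
}

.traj_dist <- function(traj, a, b) {
  pa <- .traj_pos(traj, a); pb <- .traj_pos(traj, b)
  sqrt(rowSums((pa - pb)^2))
}

#' Number of frames in a trajectory
#' @param traj A `bm_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Per-pair distance statistics of a trajectory
#'
#' Mean and SD of labeled atom-pair distances over the frames, the
#' mean +/- SD per reaction-coordinate window presentation used for
#' active-site distance tracking.
#'
#' @param traj A `bm_trajectory`.
#' @param pairs Named list of two-role vectors, e.g.
#'   [default_distance_pairs()].
#' @return Data frame: `pair`, `mean`, `sd`, `n`.
#' @export
pair_distance_series <- function(traj, pairs = default_distance_pairs()) {
  rows <- lapply(names(pairs), function(nm) {
    d <- .traj_dist(traj, pairs[[nm]][1], pairs[[nm]][2])
    data.frame(pair = nm, mean = mean(d), sd = stats::sd(d), n = length(d))
  })
  out <- do.call(rbind, rows)
  out$sd[is.na(out$sd)] <- 0
  out
}

#' Hydrogen-bond acceptance criteria
#'
#' A frame counts as hydrogen bonded when the proton-acceptor distance is
#' below `max_dist` and the donor-H-acceptor angle deviates from linearity
#' by at most `max_angle_dev` degrees (i.e. angle within 180 +/- dev).
#'
#' @param max_dist Maximum proton-acceptor distance (A).
#' @param max_angle_dev Maximum deviation from 180 degrees.
#' @return Object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_dist = 2.2, max_angle_dev = 50) {
  if (max_dist <= 0) stop("max_dist must be positive")
  if (max_angle_dev <= 0 || max_angle_dev >= 90)
    stop("max_angle_dev must be in (0, 90)")
  structure(list(max_dist = max_dist, max_angle_dev = max_angle_dev),
            class = "hbond_criteria")
}

.dha_angle <- function(traj, donor, h, acceptor) {
  pd <- .traj_pos(traj, donor); ph <- .traj_pos(traj, h)
  pa <- .traj_pos(traj, acceptor)
  v1 <- pd - ph; v2 <- pa - ph
  cth <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  acos(pmax(pmin(cth, 1), -1)) * 180 / pi
}

#' Hydrogen-bond frequency over a trajectory
#'
#' Exact fraction of frames satisfying both criteria; no smoothing.
#'
#' @param traj A `bm_trajectory`.
#' @param donor,h,acceptor Role labels (distinct).
#' @param criteria An [hbond_criteria()].
#' @return Fraction in `[0, 1]`.
#' @export
hbond_frequency <- function(traj, donor = "BPA_O2p", h = "H2p",
                            acceptor = "OSp",
                            criteria = hbond_criteria()) {
  if (anyDuplicated(c(donor, h, acceptor))) stop("labels must be distinct")
  d <- .traj_dist(traj, h, acceptor)
  ang <- .dha_angle(traj, donor, h, acceptor)
  mean(d < criteria$max_dist & (180 - ang) <= criteria$max_angle_dev)
}

#' Detect proton-transfer events
#'
#' An event is the first frame where the proton is closer to the acceptor
#' than to the donor and remains so for at least `dwell` consecutive
#' frames; the reaction coordinate and the forming-bond length d1 at the
#' event frame are reported.
#'
#' @param traj A `bm_trajectory`.
#' @param donor,h,acceptor Role labels.
#' @param dwell Minimum sustained crossing length (frames, >= 1).
#' @return Data frame (possibly empty): `frame`, `xi`, `donor`, `acceptor`,
#'   `d1`.
#' @export
detect_proton_transfer <- function(traj, donor = "BPA_O2p", h = "H2p",
                                   acceptor = "OSp", dwell = 10) {
  if (dwell < 1) stop("dwell must be >= 1 frame")
  dd <- .traj_dist(traj, h, donor)
  da <- .traj_dist(traj, h, acceptor)
  onsets <- .sustained_onsets(da < dd, dwell)
  if (length(onsets) == 0)
    return(data.frame(frame = integer(0), xi = numeric(0),
                      donor = character(0), acceptor = character(0),
                      d1 = numeric(0)))
  d1 <- .traj_dist(traj, "BPA_O2p", "Gp1_P")
  data.frame(frame = onsets, xi = traj$rc[onsets], donor = donor,
             acceptor = acceptor, d1 = d1[onsets])
}

# Kabsch rotation R (right-multiplied: x %*% R) aligning x onto y, both
# centred n x 3 row-vector point sets
.kabsch <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Relative mean square fluctuation per residue group
#'
#' Every frame is superposed (best-fit rigid rotation/translation over all
#' trajectory atoms) onto the mean structure; each group's mean square
#' fluctuation about the mean positions is then normalised by the largest
#' group value, so the most mobile group is 1. A static trajectory yields
#' zeros.
#'
#' @param traj A `bm_trajectory`.
#' @param groups Named list of role vectors; must not overlap.
#' @return Named numeric vector of relative MSF values.
#' @export
rmsf_relative <- function(traj, groups) {
  if (any(lengths(groups) < 1)) stop("each group needs at least one atom")
  all_roles <- unlist(groups)
  if (anyDuplicated(all_roles)) stop("groups must not overlap")
  gidx <- match(all_roles, traj$labels)
  if (any(is.na(gidx))) stop("unknown role in groups")
  nf <- n_frames(traj)
  na <- dim(traj$coords)[2]
  sel <- traj$coords
  # iterate superposition of all atoms onto the running mean structure
  ref <- matrix(sel[1, , ], ncol = 3)
  aligned <- array(NA_real_, dim(sel))
  for (pass in 1:3) {
    refc <- sweep(ref, 2, colMeans(ref))
    for (f in seq_len(nf)) {
      x <- matrix(sel[f, , ], ncol = 3)
      xc <- sweep(x, 2, colMeans(x))
      aligned[f, , ] <- xc %*% .kabsch(xc, refc)
    }
    ref <- apply(aligned, c(2, 3), mean)
  }
  msf_atom <- rowMeans(vapply(seq_len(nf), function(f)
    rowSums((matrix(aligned[f, , ], ncol = 3) - ref)^2), numeric(na)))
  pos <- 0
  msf <- vapply(groups, function(g) {
    v <- mean(msf_atom[gidx[pos + seq_along(g)]])
    pos <<- pos + length(g)
    v
  }, numeric(1))
  mx <- max(msf)
  if (mx <= 1e-12) return(stats::setNames(rep(0, length(msf)), names(groups)))
  msf / mx
}

#' Default monovalent-ion sub-site definitions
#'
#' Binding pose 1 coordinates the G52 and U80 oxygens; binding pose 2 the
#' A59, G60 and U80 oxygens.
#'
#' @return Named list of role vectors.
#' @export
default_subsites <- function() {
  list(pose1 = c("G52_O", "U80_O"),
       pose2 = c("A59_O", "G60_O", "U80_O"))
}

#' Classify monovalent-ion binding pose per frame
#'
#' A frame is assigned to a sub-site when every member ligand lies within
#' `cutoff` of the ion; if both sub-sites qualify the one with the smaller
#' mean ion-ligand distance wins (tie frames are reported); otherwise the
#' frame is unbound.
#'
#' @param traj A `bm_trajectory`.
#' @param ion Ion role label.
#' @param subsites Named list of ligand role sets.
#' @param ion_type `"Li"` or `"K"`, setting the default cutoff (2.5 /
#'   3.5 A).
#' @param cutoff Override contact cutoff (A).
#' @return List with `labels` (per frame), `occupancy` (fractions over
#'   pose1/pose2/unbound, summing to 1) and `tie_frames`.
#' @export
classify_ion_pose <- function(traj, ion = "K1",
                              subsites = default_subsites(),
                              ion_type = c("Li", "K"), cutoff = NULL) {
  ion_type <- match.arg(ion_type)
  if (is.null(cutoff)) cutoff <- if (ion_type == "Li") 2.5 else 3.5
  dmat <- lapply(subsites, function(set)
    sapply(set, function(rl) .traj_dist(traj, ion, rl)))
  nf <- n_frames(traj)
  labels <- character(nf)
  ties <- integer(0)
  for (f in seq_len(nf)) {
    ok <- vapply(dmat, function(m) {
      row <- if (is.matrix(m)) m[f, ] else m[f]
      all(row < cutoff)
    }, logical(1))
    if (sum(ok) == 0) labels[f] <- "unbound"
    else if (sum(ok) == 1) labels[f] <- names(subsites)[ok]
    else {
      means <- vapply(dmat[ok], function(m) {
        row <- if (is.matrix(m)) m[f, ] else m[f]
        mean(row)
      }, numeric(1))
      labels[f] <- names(means)[which.min(means)]
      ties <- c(ties, f)
    }
  }
  occ <- prop.table(table(factor(labels, c(names(subsites), "unbound"))))
  list(labels = labels, occupancy = occ, tie_frames = ties)
}

#' Bare-Coulomb electric field at target atoms
#'
#' Field at each target from all other charges, `E = sum q_i rhat / (eps
#' r^2)` in e/A^2 per unit dielectric, plus signed projections onto
#' specified bond unit vectors (positive when the field at the first atom
#' of a pair pushes a positive charge towards the second atom). A
#' uniform-dielectric Coulomb sum stands in for a continuum-electrostatics
#' solve; there is no solvent in the toy model.
#'
#' @param positions n x 3 coordinate matrix with rownames (roles).
#' @param charges Named charge vector (e) covering the rows used.
#' @param targets Roles at which the field is evaluated (excluded from
#'   their own field).
#' @param projection_pairs List of two-role vectors; the projection is
#'   evaluated at the first role along the unit vector towards the second.
#' @param dielectric Uniform relative dielectric.
#' @return List with `field` (targets x 3 matrix, e/A^2) and `projections`
#'   (data frame: `from`, `to`, `value`).
#' @export
coulomb_field <- function(positions, charges, targets,
                          projection_pairs = list(), dielectric = 1) {
  positions <- as.matrix(positions)
  if (is.null(rownames(positions))) stop("positions need role rownames")
  if (!all(names(charges) %in% rownames(positions)) ||
      is.null(names(charges)))
    stop("charges must be named by roles present in positions")
  field <- matrix(0, length(targets), 3,
                  dimnames = list(targets, c("x", "y", "z")))
  for (tgt in targets) {
    rt <- positions[tgt, ]
    E <- c(0, 0, 0)
    for (src in names(charges)) {
      if (src == tgt) next
      dr <- rt - positions[src, ]
      r2 <- sum(dr^2)
      if (r2 < 1e-12) stop("target ", tgt, " coincides with charge ", src)
      E <- E + charges[[src]] * dr / (dielectric * r2^1.5)
    }
    field[tgt, ] <- E
  }
  proj <- data.frame(from = character(0), to = character(0),
                     value = numeric(0))
  for (p in projection_pairs) {
    u <- .unit(positions[p[2], ] - positions[p[1], ])
    if (!p[1] %in% rownames(field))
      stop("projection origin ", p[1], " is not a field target")
    proj <- rbind(proj, data.frame(from = p[1], to = p[2],
                                   value = sum(field[p[1], ] * u)))
  }
  list(field = field, projections = proj)
}

#' Coordination sphere of an ion
#'
#' All oxygen atoms within the cutoff of the ion, sorted by distance.
#'
#' @param model An `active_site_model` (or a `bm_trajectory` with `frame`).
#' @param ion Ion role.
#' @param cutoff Cutoff distance (A), positive.
#' @param frame Frame index when `model` is a trajectory.
#' @return Data frame: `role`, `distance`, sorted increasing.
#' @export
coordination_sphere <- function(model, ion = "K1", cutoff = 3.5,
                                frame = 1) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (inherits(model, "bm_trajectory")) {
    pos <- model$coords[frame, , ]
    if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
    rownames(pos) <- model$labels
    elements <- model$elements
  } else {
    pos <- as.matrix(model$atoms[, c("x", "y", "z")])
    rownames(pos) <- model$atoms$role
    elements <- model$atoms$element
  }
  rion <- pos[ion, ]
  ox <- which(elements == "O" & rownames(pos) != ion)
  d <- sqrt(rowSums((pos[ox, , drop = FALSE] -
                       matrix(rion, length(ox), 3, byrow = TRUE))^2))
  keep <- d <= cutoff
  out <- data.frame(role = rownames(pos)[ox][keep], distance = d[keep])
  out[order(out$distance), , drop = FALSE]
}
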