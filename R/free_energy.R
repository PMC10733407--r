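# From constraint-force series to the free-energy profile:
# equilibration discard + convergence check, mean force with an
# autocorrelation-aware standard error, the blue-moon (Fixman) metric
# correction, trapezoid thermodynamic integration with error propagation,
# and extraction of the R / TS1 / I / TS2 / P features.

#' Per-window statistics of a Lagrange-multiplier series
#'
#' Discards the equilibration segment, averages the remainder and estimates
#' the standard error. With `se_mode = "autocorr"` (default) the SE is
#' SD * sqrt(g / n) with statistical inefficiency g = (1 + phi)/(1 - phi)
#' from the lag-1 autocorrelation phi of the retained series; `"naive"`
#' ignores correlation (SD/sqrt(n)); `"sd"` reports the plain SD.
#' Convergence is flagged when every running mean over the second half of
#' the retained series stays within `conv_tol` of the full retained mean.
#'
#' @param lambda Numeric series of per-step multipliers (kcal/mol/A).
#' @param dt Timestep (fs), used when `equil_time` is given.
#' @param equil_time Equilibration time to discard (fs). Ignored when
#'   `n_discard` is given.
#' @param n_discard Number of leading steps to discard.
#' @param xi Reaction-coordinate value to record (optional).
#' @param conv_tol Convergence tolerance (kcal/mol/A).
#' @param se_mode One of `"autocorr"`, `"naive"`, `"sd"`.
#' @return One-row data frame: `xi`, `mean_force`, `sd`, `se`, `n_used`,
#'   `n_discarded`, `converged`, `corrected_force`, `correction_ratio`.
#' @export
window_stats <- function(lambda, dt = 0.5, equil_time = 2000,
                         n_discard = NULL, xi = NA_real_,
                         conv_tol = 0.5,
                         se_mode = c("autocorr", "naive", "sd")) {
  se_mode <- match.arg(se_mode)
  if (!all(is.finite(lambda))) stop("non-finite values in multiplier series")
  if (is.null(n_discard)) n_discard <- round(equil_time / dt)
  n <- length(lambda)
  if (n_discard >= n) stop("discard length exceeds series length")
  x <- lambda[(n_discard + 1):n]
  m <- length(x)
  mu <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s)) s <- 0
  phi <- if (m > 2 && s > 0) stats::cor(x[-1], x[-m]) else 0
  if (!is.finite(phi)) phi <- 0
  phi <- max(min(phi, 0.999), -0.999)
  g <- max((1 + phi) / (1 - phi), 1e-12)
  se <- switch(se_mode,
               autocorr = s * sqrt(g / m),
               naive = s / sqrt(m),
               sd = s)
  cm <- cumsum(x) / seq_len(m)
  second <- cm[ceiling(m / 2):m]
  converged <- all(abs(second - mu) <= conv_tol)
  data.frame(xi = xi, mean_force = mu, sd = s, se = se,
             n_used = m, n_discarded = n_discard, converged = converged,
             corrected_force = NA_real_, correction_ratio = NA_real_)
}

# per-frame geometry of the difference constraint from a trajectory
.diff_constraint_geom <- function(traj, roles) {
  ia <- match(roles[1], traj$labels)  # nucleophile O (d1)
  ip <- match(roles[2], traj$labels)  # shared P
  ib <- match(roles[3], traj$labels)  # leaving O (d2)
  if (any(is.na(c(ia, ip, ib)))) stop("constraint roles not in trajectory")
  get <- function(i) {
    p <- traj$coords[, i, , drop = FALSE][, 1, ]
    if (is.null(dim(p))) p <- matrix(p, ncol = 3)
    p
  }
  u <- get(ia) - get(ip)
  w <- get(ib) - get(ip)
  d1 <- sqrt(rowSums(u^2)); d2 <- sqrt(rowSums(w^2))
  list(u = u / d1, w = w / d2, d1 = d1, d2 = d2)
}

#' Blue-moon metric correction of a constrained window
#'
#' For the difference-of-distances constraint sigma = d2 - d1 - xi the
#' mass-metric factor is Z = 1/m_A + 1/m_B + 2(1 - cos alpha)/m_P with
#' alpha the O-P-O angle, and the corrected mean force is
#' `<Z^-1/2 (lambda + kT kappa)> / <Z^-1/2>` with the geometric term kappa
#' assembled from the constraint Hessian in closed form. For a plain
#' distance constraint Z is constant and kappa vanishes, so the correction
#' is exactly the identity.
#'
#' @param traj A `bm_trajectory` carrying per-frame multipliers.
#' @param roles For `type = "difference"`, the three roles (nucleophile O,
#'   shared P, leaving O); for `type = "distance"`, two roles.
#' @param masses Named vector of masses (amu) covering `roles`.
#' @param temperature Temperature (K).
#' @param type Constraint type.
#' @param frames Optional frame subset (indices) to use.
#' @return List with per-frame `Z` and `kappa`, the `raw` and `corrected`
#'   mean force, and `ratio` = |corrected - raw| / |raw|.
#' @export
metric_correction <- function(traj, roles, masses, temperature = 300,
                              type = c("difference", "distance"),
                              frames = NULL) {
  type <- match.arg(type)
  lam <- traj$lambda
  if (is.null(lam)) stop("trajectory carries no multiplier series")
  nf <- dim(traj$coords)[1]
  if (is.null(frames)) frames <- seq_len(nf)
  kT <- .kB * temperature
  if (type == "distance") {
    mA <- masses[[roles[1]]]; mB <- masses[[roles[2]]]
    Z <- rep(1 / mA + 1 / mB, length(frames))
    kap <- rep(0, length(frames))
  } else {
    mA <- masses[[roles[1]]]; mP <- masses[[roles[2]]]; mB <- masses[[roles[3]]]
    g <- .diff_constraint_geom(traj, roles)
    u <- g$u[frames, , drop = FALSE]; w <- g$w[frames, , drop = FALSE]
    d1 <- g$d1[frames]; d2 <- g$d2[frames]
    cth <- rowSums(u * w)
    Z <- 1 / mA + 1 / mB + (2 - 2 * cth) / mP
    # kappa = S / Z^2 with S from the constraint Hessian:
    #   S = (aB-aP)' Q2 (aB-aP) - (aA-aP)' Q1 (aA-aP),
    #   Q1 = (I - u u')/d1, Q2 = (I - w w')/d2,
    #   aA = -u/mA, aB = w/mB, aP = (u-w)/mP.
    aA <- -u / mA; aB <- w / mB; aP <- (u - w) / mP
    xB <- aB - aP; xA <- aA - aP
    qB <- (rowSums(xB^2) - rowSums(w * xB)^2) / d2
    qA <- (rowSums(xA^2) - rowSums(u * xA)^2) / d1
    kap <- (qB - qA) / Z^2
  }
  if (any(Z <= 0)) stop("non-positive metric factor")
  lamf <- lam[frames]
  wgt <- 1 / sqrt(Z)
  raw <- mean(lamf)
  corrected <- sum(wgt * (lamf + kT * kap)) / sum(wgt)
  ratio <- if (abs(raw) > 0) abs(corrected - raw) / abs(raw) else NA_real_
  list(Z = Z, kappa = kap, raw = raw, corrected = corrected, ratio = ratio)
}

#' Trapezoid thermodynamic integration with error propagation
#'
#' Integrates the per-window mean force over the reaction coordinate with
#' the trapezoid rule, accumulating the error in quadrature:
#' `sigma_F^2(xi_k) = sum_i (dxi_i/2)^2 (SE_i^2 + SE_{i+1}^2)` from the
#' gauge point. The gauge is the leftmost window (F = 0 there).
#'
#' @param stats Data frame of window statistics (from [window_stats()]),
#'   one row per window, sorted by `xi`.
#' @param force_col Column to integrate: `"auto"` uses `corrected_force`
#'   where finite and `mean_force` otherwise.
#' @param allow_unconverged Integrate even if some windows failed the
#'   convergence check.
#' @return A `free_energy_profile`.
#' @export
integrate_profile <- function(stats, force_col = c("auto", "mean_force",
                                                   "corrected_force"),
                              allow_unconverged = FALSE) {
  force_col <- match.arg(force_col)
  if (nrow(stats) < 2) stop("need at least two windows")
  if (is.unsorted(stats$xi, strictly = TRUE))
    stop("windows must be sorted by xi without duplicates")
  if (!allow_unconverged && !all(stats$converged))
    stop("unconverged windows at xi = ",
         paste(stats$xi[!stats$converged], collapse = ", "),
         " (use allow_unconverged = TRUE to override)")
  f <- switch(force_col,
              mean_force = stats$mean_force,
              corrected_force = stats$corrected_force,
              auto = ifelse(is.finite(stats$corrected_force),
                            stats$corrected_force, stats$mean_force))
  if (!all(is.finite(f))) stop("non-finite mean forces")
  xi <- stats$xi
  se <- stats$se
  n <- length(xi)
  dxi <- diff(xi)
  Fv <- c(0, cumsum(dxi * (f[-n] + f[-1]) / 2))
  var_inc <- (dxi / 2)^2 * (se[-n]^2 + se[-1]^2)
  sig <- sqrt(c(0, cumsum(var_inc)))
  free_energy_profile(xi, Fv, sig,
                      gauge = sprintf("F(%g) = 0 (leftmost window)", xi[1]))
}

.parab_refine <- function(x, y, i) {
  # vertex of the parabola through points i-1, i, i+1 (equal or unequal h)
  x0 <- x[i - 1]; x1 <- x[i]; x2 <- x[i + 1]
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  denom <- (x0 - x1) * (x0 - x2) * (x1 - x2)
  A <- (x2 * (y1 - y0) + x1 * (y0 - y2) + x0 * (y2 - y1)) / denom
  B <- (x2^2 * (y0 - y1) + x1^2 * (y2 - y0) + x0^2 * (y1 - y2)) / denom
  if (abs(A) < 1e-12) return(c(x1, y1))
  xv <- -B / (2 * A)
  if (xv < x0 || xv > x2) return(c(x1, y1))
  C <- y1 - A * x1^2 - B * x1
  c(xv, A * xv^2 + B * xv + C)
}

#' Extract R / TS1 / I / TS2 / P features from a profile
#'
#' Locates grid minima and maxima (with parabolic refinement through each
#' interior extremum's three points), assigns the reactant to the leftmost
#' minimum, the product to the rightmost, the intermediate to the interior
#' minimum and the transition states to its flanking maxima, and reports
#' the two activation free energies and the reaction free energy with
#' errors combined in quadrature. Profiles with fewer than two maxima are
#' reported as a single-transition-state (or single-minimum) variant
#' instead of failing.
#'
#' @param profile A `free_energy_profile` with at least 5 points.
#' @return Object of class `profile_features`: list with `type`
#'   (`"two_ts"`, `"one_ts"` or `"minimum_only"`), `features` (state, xi,
#'   F, sigma_F) and `barriers` (dF_R_TS1, dF_I_TS2, dF_R_P where defined).
#' @export
extract_features <- function(profile) {
  xi <- profile$xi; Fv <- profile$F; sg <- profile$sigma_F
  n <- length(xi)
  if (n < 5) stop("profile needs at least 5 points")
  is_min <- is_max <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    if (Fv[i] < Fv[i - 1] && Fv[i] <= Fv[i + 1]) is_min[i] <- TRUE
    if (Fv[i] > Fv[i - 1] && Fv[i] >= Fv[i + 1]) is_max[i] <- TRUE
  }
  if (Fv[1] < Fv[2]) is_min[1] <- TRUE
  if (Fv[n] < Fv[n - 1]) is_min[n] <- TRUE
  refine <- function(i) {
    if (i > 1 && i < n) .parab_refine(xi, Fv, i) else c(xi[i], Fv[i])
  }
  mins <- which(is_min); maxs <- which(is_max)
  feat <- function(state, i) {
    r <- refine(i)
    data.frame(state = state, xi = r[1], F = r[2], sigma_F = sg[i])
  }
  quad <- function(a, b) sqrt(a^2 + b^2)
  if (length(mins) == 0) {
    i <- which.min(Fv)
    out <- list(type = "minimum_only", features = feat("min", i),
                barriers = data.frame())
    class(out) <- "profile_features"
    return(out)
  }
  iR <- mins[1]; iP <- mins[length(mins)]
  interior_max <- maxs[maxs > iR & maxs < iP]
  if (length(interior_max) < 2) {
    fr <- feat("R", iR)
    fp <- feat("P", iP)
    feats <- rbind(fr, fp)
    barriers <- data.frame(name = "dF_R_P", value = fp$F - fr$F,
                           sigma = quad(sg[iR], sg[iP]))
    if (length(interior_max) == 1) {
      fts <- feat("TS", interior_max[1])
      feats <- rbind(fr, fts, fp)
      barriers <- rbind(
        data.frame(name = "dF_R_TS", value = fts$F - fr$F,
                   sigma = quad(sg[iR], sg[interior_max[1]])),
        barriers)
    }
    out <- list(type = if (length(interior_max)) "one_ts" else "minimum_only",
                features = feats, barriers = barriers)
    class(out) <- "profile_features"
    return(out)
  }
  interior_min <- mins[mins > iR & mins < iP]
  if (length(interior_min) == 0) stop("no interior minimum between maxima")
  iI <- interior_min[which.min(Fv[interior_min])]
  left_max <- interior_max[interior_max < iI]
  right_max <- interior_max[interior_max > iI]
  if (length(left_max) == 0 || length(right_max) == 0)
    stop("intermediate minimum is not flanked by maxima")
  iT1 <- left_max[which.max(Fv[left_max])]
  iT2 <- right_max[which.max(Fv[right_max])]
  fr <- feat("R", iR); f1 <- feat("TS1", iT1); fi <- feat("I", iI)
  f2 <- feat("TS2", iT2); fp <- feat("P", iP)
  feats <- rbind(fr, f1, fi, f2, fp)
  barriers <- rbind(
    data.frame(name = "dF_R_TS1", value = f1$F - fr$F,
               sigma = quad(sg[iR], sg[iT1])),
    data.frame(name = "dF_I_TS2", value = f2$F - fi$F,
               sigma = quad(sg[iI], sg[iT2])),
    data.frame(name = "dF_R_P", value = fp$F - fr$F,
               sigma = quad(sg[iR], sg[iP])))
  out <- list(type = "two_ts", features = feats, barriers = barriers)
  class(out) <- "profile_features"
  out
}

#' @export
print.profile_features <- function(x, ...) {
  cat("Profile features (", x$type, ")\n", sep = "")
  print(x$features, digits = 4, row.names = FALSE)
  if (nrow(x$barriers)) print(x$barriers, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Barrier or reaction free energy from a feature set
#'
#' @param features A `profile_features`.
#' @param name One of `"dF_R_TS1"`, `"dF_I_TS2"`, `"dF_R_P"`.
#' @return Named value (kcal/mol) with attribute `sigma`.
#' @export
feature_value <- function(features, name) {
  i <- match(name, features$barriers$name)
  if (is.na(i)) stop("feature not present: ", name)
  structure(features$barriers$value[i], sigma = features$barriers$sigma[i])
}
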