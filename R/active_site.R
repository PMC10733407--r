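# Toy model of the C-complex branching active site: the three reactive atoms
# (nucleophile O2', scissile P, leaving O3'), the two catalytic Mg2+ ions,
# the monovalent ion at the K1 site, and the U6 ligand oxygens that
# coordinate it. Spectator atoms are restrained to their build positions
# during dynamics; only the three reactive atoms feel the reactive surface.

.roles_core <- c("BPA_O2p", "Gp1_P", "G1_O3p")

.element_mass <- c(O = 15.999, P = 30.974, H = 1.008,
                   Mg = 24.305, K = 39.098, Li = 6.94)

# toy partial charges (e); magnitudes typical of nucleic-acid force fields
.role_charge <- c(
  BPA_O2p = -0.8, Gp1_P = 1.3, G1_O3p = -0.6, H2p = 0.4,
  OSp = -0.9, ORp = -0.9, M1 = 2, M2 = 2, K1 = 1,
  G52_O = -0.8, A59_O = -0.8, G60_O = -0.8, U80_O = -0.8, G78_O = -0.8)

.unit <- function(v) v / sqrt(sum(v^2))

# point at distances da, db from a, b; among the solution circle take the
# one whose offset from the a-b axis best aligns with `pref`
.place2 <- function(a, da, b, db, pref) {
  e1 <- .unit(b - a)
  dab <- sqrt(sum((b - a)^2))
  t <- (dab^2 + da^2 - db^2) / (2 * dab)
  rho2 <- da^2 - t^2
  if (rho2 < 0) stop("inconsistent placement distances")
  p <- pref - sum(pref * e1) * e1
  if (sqrt(sum(p^2)) < 1e-8) {
    p <- c(0, 0, 1) - e1[3] * e1
    if (sqrt(sum(p^2)) < 1e-8) p <- c(0, 1, 0) - e1[2] * e1
  }
  a + t * e1 + sqrt(rho2) * .unit(p)
}

# trilateration: point at distances da, db, dc from a, b, c; sign picks the
# mirror solution across the abc plane
.place3 <- function(a, da, b, db, c, dc, sign = 1) {
  ex <- .unit(b - a)
  d <- sqrt(sum((b - a)^2))
  i <- sum(ex * (c - a))
  ey <- .unit(c - a - i * ex)
  j <- sum(ey * (c - a))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  x <- (da^2 - db^2 + d^2) / (2 * d)
  y <- (da^2 - dc^2 + i^2 + j^2 - 2 * i * x) / (2 * j)
  z2 <- da^2 - x^2 - y^2
  if (z2 < -1e-9) stop("inconsistent placement distances")
  z <- sign * sqrt(max(z2, 0))
  a + x * ex + y * ey + z * ez
}

#' Build the toy branching active-site model
#'
#' Constructs the reduced reactive core (nucleophile O2', scissile P,
#' leaving O3') in the reactant geometry together with the Mg2+/monovalent
#' metal cluster and the U6 ligand-oxygen sites, at the equilibrated
#' distances of the reference system: forming-bond distance d1 = 3.3 A,
#' M1-M2 = 4.1 A, the monovalent site 4.3 A from M2 and 6.2 A from M1,
#' Mg-ligand contacts in 2.0-2.3 A and K-ligand contacts in 2.8-3.4 A.
#' For `ion_type = "Li"` the monovalent ion is lithium placed in binding
#' pose 1 (coordinating G52 and U80) at ~2 A contacts.
#'
#' @param ion_type `"K"` or `"Li"`.
#' @return An object of class `active_site_model`: a list with `atoms`
#'   (data frame of role, element, mass, charge, x, y, z) and `ion_type`.
#' @examples
#' m <- build_active_site("K")
#' model_distance(m, "BPA_O2p", "Gp1_P")   # 3.3
#' @export
build_active_site <- function(ion_type = c("K", "Li")) {
  ion_type <- match.arg(ion_type)
  P <- c(0, 0, 0)
  O3p <- c(1.6, 0, 0)
  O2p <- c(-3.3, 0, 0)
  OSp <- 1.56 * c(0, 0.9499, 0.3126)
  ORp <- 1.56 * c(0, -0.9499, 0.3126)
  H2p <- O2p + 1.0 * .unit(OSp - O2p)
  M1 <- .place2(O3p, 2.10, ORp, 2.15, pref = c(1, -0.2, -1))
  M2 <- .place3(O2p, 2.20, ORp, 2.20, M1, 4.10, sign = -1)
  K1 <- .place2(M2, 4.30, M1, 6.20, pref = .unit((M1 + M2) / 2 - P))

  a <- .unit(K1 - (M1 + M2) / 2)
  b <- c(0, 0, 1) - sum(c(0, 0, 1) * a) * a
  if (sqrt(sum(b^2)) < 1e-6) b <- c(0, 1, 0) - sum(c(0, 1, 0) * a) * a
  b <- .unit(b)
  cc <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  U80_O <- K1 + 2.90 * a
  G52_O <- K1 + 2.90 * .unit(0.25 * a + b)
  A59_O <- K1 + 3.00 * .unit(0.25 * a - b + 0.35 * cc)
  G60_O <- K1 + 3.10 * .unit(0.25 * a - b - 0.35 * cc)
  G78_O <- M1 + 2.05 * .unit(M1 - P)

  ion_pos <- K1
  ion_el <- "K"
  if (ion_type == "Li") {
    ion_el <- "Li"
    # binding pose 1: ~2 A from the G52 and U80 oxygens, on the K1 side
    ion_pos <- .place2(G52_O, 2.0, U80_O, 2.0,
                       pref = .unit(K1 - (G52_O + U80_O) / 2))
  }

  coords <- rbind(BPA_O2p = O2p, Gp1_P = P, G1_O3p = O3p, H2p = H2p,
                  OSp = OSp, ORp = ORp, M1 = M1, M2 = M2, K1 = ion_pos,
                  G52_O = G52_O, A59_O = A59_O, G60_O = G60_O,
                  U80_O = U80_O, G78_O = G78_O)
  element <- c("O", "P", "O", "H", "O", "O", "Mg", "Mg", ion_el,
               "O", "O", "O", "O", "O")
  atoms <- data.frame(
    role = rownames(coords),
    element = element,
    mass = unname(.element_mass[element]),
    charge = unname(.role_charge[rownames(coords)]),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    row.names = NULL, stringsAsFactors = FALSE)
  m <- structure(list(atoms = atoms, ion_type = ion_type),
                 class = "active_site_model")
  validate_active_site(m)
  m
}

#' Validate an active-site model
#'
#' Checks role uniqueness, positive masses, finite coordinates, the
#' reactant-state ordering d2 < d1 of the breaking and forming bonds, and a
#' 0.8 A minimum inter-atomic separation.
#'
#' @param model An `active_site_model`.
#' @return The model, invisibly; errors if any invariant fails.
#' @export
validate_active_site <- function(model) {
  a <- model$atoms
  if (anyDuplicated(a$role)) stop("duplicate role labels")
  if (any(a$mass <= 0)) stop("non-positive mass")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  d1 <- model_distance(model, "BPA_O2p", "Gp1_P")
  d2 <- model_distance(model, "G1_O3p", "Gp1_P")
  if (!(d1 > 0 && d2 > 0 && d2 < d1))
    stop("reactant build requires 0 < d2 < d1")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  diag(dm) <- Inf
  if (min(dm) < 0.8) {
    idx <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    stop(sprintf("atoms %s and %s closer than 0.8 A (%.2f)",
                 a$role[idx[1]], a$role[idx[2]], min(dm)))
  }
  invisible(model)
}

#' @export
print.active_site_model <- function(x, ...) {
  cat(sprintf("Active-site model (%s+ at the monovalent site), %d atoms\n",
              x$ion_type, nrow(x$atoms)))
  cat(sprintf("  d1 (O2'-P) = %.2f A, d2 (O3'-P) = %.2f A\n",
              model_distance(x, "BPA_O2p", "Gp1_P"),
              model_distance(x, "G1_O3p", "Gp1_P")))
  invisible(x)
}

#' Coordinates of a model atom by role
#'
#' @param model An `active_site_model`.
#' @param role Role label.
#' @return Numeric xyz vector.
#' @export
model_position <- function(model, role) {
  i <- match(role, model$atoms$role)
  if (is.na(i)) stop("unknown role: ", role)
  as.numeric(model$atoms[i, c("x", "y", "z")])
}

#' Distance between two model atoms
#'
#' @param model An `active_site_model`.
#' @param role1,role2 Role labels.
#' @return Distance in Angstrom.
#' @export
model_distance <- function(model, role1, role2) {
  sqrt(sum((model_position(model, role1) - model_position(model, role2))^2))
}

#' Named atom-pair distances of the model
#'
#' Eleven active-site distances (d1-d11) are conventionally labeled for
#' this site but only a few have unambiguous definitions; rather than
#' guessing the full mapping, any labeled pair can be requested. The
#' default set covers the unambiguous ones:
#' d1 (forming bond), d2 (breaking bond), d4 (2'-OH proton to the pro-Sp
#' oxygen), d6 (leaving O3' to M1), plus the metal-cluster separations.
#'
#' @param model An `active_site_model`.
#' @param pairs Named list of two-element role vectors.
#' @return Named numeric vector of distances in Angstrom.
#' @export
model_distances <- function(model, pairs = default_distance_pairs()) {
  vapply(pairs, function(p) model_distance(model, p[1], p[2]), numeric(1))
}

#' @rdname model_distances
#' @export
default_distance_pairs <- function() {
  list(d1 = c("BPA_O2p", "Gp1_P"),
       d2 = c("G1_O3p", "Gp1_P"),
       d4 = c("H2p", "OSp"),
       d6 = c("G1_O3p", "M1"),
       M1_M2 = c("M1", "M2"),
       K1_M1 = c("K1", "M1"),
       K1_M2 = c("K1", "M2"))
}
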