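#' Deterministic unit-sphere point lattice (Fibonacci spiral)
#'
#' A spiral lattice distributes points nearly uniformly on the unit sphere
#' without randomness, so surface areas are exactly reproducible between
#' runs.
#' @param n number of points (>= 92 recommended for stable areas).
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i         # golden-angle increments
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere of radius `r_i + probe` is sampled with a
#' deterministic spiral lattice; a sample point is exposed when it lies
#' outside every neighbour's probe-inflated sphere. Per-atom SASA is the
#' exposed fraction times the analytic sphere area.
#'
#' @param coords n x 3 matrix (Angstrom).
#' @param radii per-atom radii (Angstrom, >= 0).
#' @param probe_radius probe radius (Angstrom, default 1.4).
#' @param n_points lattice points per atom (>= 92; default 960).
#' @return numeric vector of per-atom SASA (Angstrom^2).
#' @export
shrake_rupley_sasa <- function(coords, radii, probe_radius = 1.4,
                               n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(radii) != n) stop("one radius per atom required")
  if (any(radii < 0)) stop("negative radius")
  if (n_points < 92) stop("n_points must be >= 92")
  lattice <- sphere_lattice(n_points)
  rs <- radii + probe_radius
  out <- numeric(n)
  d2all <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    pts <- sweep(lattice * rs[i], 2, coords[i, ], "+")
    # neighbours whose inflated sphere can reach atom i's surface
    nb <- which(d2all[i, ] < (rs[i] + rs)^2 & seq_len(n) != i)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
        (pts[, 3] - coords[j, 3])^2
      exposed <- exposed & d2 >= rs[j]^2
      if (!any(exposed)) break
    }
    out[i] <- mean(exposed) * 4 * pi * rs[i]^2
  }
  out
}

#' Nonpolar solvation energy from SASA
#'
#' Linear surface-area model `G = gamma * SASA_total + beta`.
#' @param sasa per-atom SASA (Angstrom^2), summed internally.
#' @param gamma surface tension coefficient (kcal/mol/A^2, default 0.0072).
#' @param beta offset (kcal/mol, default 0).
#' @return energy in kcal/mol.
#' @export
sasa_nonpolar_energy <- function(sasa, gamma = 0.0072, beta = 0) {
  gamma * sum(sasa) + beta
}
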