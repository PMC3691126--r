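#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the (weighted) RMSD
#' between two point sets, via SVD of the weighted covariance matrix with
#' the usual determinant correction so that reflections are never returned.
#'
#' @param ref n x 3 reference coordinates.
#' @param mov n x 3 coordinates to superpose onto `ref`.
#' @param weights optional non-negative weights (default uniform).
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3;
#'   the fitted points are `mov %*% t(rotation) + translation`), `rmsd`,
#'   and `fitted` (the transformed `mov`).
#' @export
kabsch_superpose <- function(ref, mov, weights = NULL) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) != nrow(mov) || ncol(ref) != 3 || ncol(mov) != 3)
    stop("point sets must be equal-size n x 3 matrices")
  n <- nrow(ref)
  if (n < 3) stop("need at least 3 points to superpose")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  w <- weights / sum(weights)
  cref <- colSums(ref * w); cmov <- colSums(mov * w)
  a <- sweep(ref, 2, cref); b <- sweep(mov, 2, cmov)
  h <- t(b * w) %*% a
  sv <- svd(h)
  if (min(sv$d) < 1e-12 && sv$d[2] < 1e-12)
    stop("degenerate (collinear) point set: superposition is not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- b %*% t(rot)
  fitted <- sweep(fitted, 2, cref, "+")
  rmsd <- sqrt(sum(w * rowSums((fitted - ref)^2)))
  list(rotation = rot, translation = cref - as.vector(rot %*% cmov),
       rmsd = rmsd, fitted = fitted)
}

.series <- function(times, values, label) {
  structure(list(times = times, values = values, label = label),
            class = "SeriesResult")
}

#' @export
print.SeriesResult <- function(x, ...) {
  cat("SeriesResult '", x$label, "': ", length(x$values), " frames, mean ",
      sprintf("%.3f", mean(x$values)), ", range [",
      sprintf("%.3f", min(x$values)), ", ",
      sprintf("%.3f", max(x$values)), "]\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.SeriesResult <- function(x, ...) {
  data.frame(time_ps = x$times, value = x$values)
}

#' Per-frame RMSD after superposition
#'
#' Every frame is rigid-body fitted onto the reference frame using the fit
#' selection, then the RMSD is measured over the measure selection. This
#' supports the two fitting conventions used for receptor/G-protein
#' complexes: measuring a moiety after fitting on itself (internal
#' mobility) or after fitting on the partner moiety (relative motion).
#'
#' @param traj a `Trajectory`.
#' @param top the matching `Topology`.
#' @param fit_selection,measure_selection selections understood by
#'   [select_atoms()]; `measure_selection` defaults to the fit selection.
#' @param ref_frame reference frame index (default 1).
#' @param label series label.
#' @return a `SeriesResult` in Angstrom.
#' @export
rmsd_series <- function(traj, top, fit_selection,
                        measure_selection = fit_selection,
                        ref_frame = 1, label = "rmsd") {
  fit <- select_atoms(top, fit_selection)
  mea <- select_atoms(top, measure_selection)
  if (!length(fit) || !length(mea)) stop("selection resolves to 0 atoms")
  ref <- frame_coords(traj, ref_frame)
  vals <- vapply(seq_len(traj$n_frames), function(f) {
    xyz <- frame_coords(traj, f)
    k <- kabsch_superpose(ref[fit, , drop = FALSE],
                          xyz[fit, , drop = FALSE])
    moved <- xyz[mea, , drop = FALSE] %*% t(k$rotation)
    moved <- sweep(moved, 2, k$translation, "+")
    sqrt(mean(rowSums((moved - ref[mea, , drop = FALSE])^2)))
  }, numeric(1))
  .series(traj$times, vals, label)
}

#' Per-atom root-mean-square fluctuation
#'
#' Frames are first superposed on the fit selection (against frame 1), the
#' time-mean position of each measured atom is computed, and the
#' fluctuation is the RMS deviation from that mean. Fitting on the moiety
#' itself or on the partner moiety gives the two conventions used for
#' complexes.
#'
#' @param traj a `Trajectory`.
#' @param top the matching `Topology`.
#' @param fit_selection,measure_selection see [rmsd_series()].
#' @return data frame `atom`, `res_id`, `chain_id`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, top, fit_selection,
                 measure_selection = fit_selection) {
  if (traj$n_frames < 2) stop("RMSF needs at least 2 frames")
  fit <- select_atoms(top, fit_selection)
  mea <- select_atoms(top, measure_selection)
  if (!length(fit) || !length(mea)) stop("selection resolves to 0 atoms")
  ref <- frame_coords(traj, 1)
  fitted <- array(NA_real_, c(traj$n_frames, length(mea), 3))
  for (f in seq_len(traj$n_frames)) {
    xyz <- frame_coords(traj, f)
    k <- kabsch_superpose(ref[fit, , drop = FALSE],
                          xyz[fit, , drop = FALSE])
    moved <- xyz[mea, , drop = FALSE] %*% t(k$rotation)
    fitted[f, , ] <- sweep(moved, 2, k$translation, "+")
  }
  meanpos <- apply(fitted, c(2, 3), mean)
  dev2 <- vapply(seq_along(mea), function(i)
    mean(rowSums(sweep(fitted[, i, , drop = TRUE], 2, meanpos[i, ])^2)),
    numeric(1))
  data.frame(atom = top$atoms$name[mea], res_id = top$atoms$res_id[mea],
             chain_id = top$atoms$chain_id[mea], rmsf = sqrt(dev2),
             stringsAsFactors = FALSE)
}

#' Signed dihedral angle of four points
#'
#' Standard torsion convention (atan2 form), degrees in (-180, 180].
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1^2) < 1e-20 || sum(b2^2) < 1e-20 || sum(b3^2) < 1e-20)
    stop("coincident consecutive atoms in dihedral")
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral-angle series over a trajectory
#'
#' @param traj a `Trajectory`.
#' @param atom_quadruple four distinct atom indices, e.g. the C-CA-CB-CG
#'   side-chain torsion of a histidine.
#' @param label series label.
#' @return a `SeriesResult` in degrees, range (-180, 180].
#' @export
dihedral_series <- function(traj, atom_quadruple, label = "dihedral") {
  q <- as.integer(atom_quadruple)
  if (length(q) != 4 || length(unique(q)) != 4)
    stop("atom_quadruple must be 4 distinct atom indices")
  vals <- vapply(seq_len(traj$n_frames), function(f) {
    xyz <- frame_coords(traj, f)
    dihedral_angle(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
  }, numeric(1))
  .series(traj$times, vals, label)
}

#' Classify a dihedral series into rotamer states
#'
#' `state_boundaries` are angles (degrees) partitioning the circle; the bin
#' from `boundaries[k]` (inclusive) counter-clockwise to `boundaries[k+1]`
#' (exclusive) is state `k`. The default boundaries -120, 0, +120 define the
#' three states commonly seen for a chi-1-like side-chain torsion.
#'
#' @param series a `SeriesResult` of angles in degrees.
#' @param state_boundaries strictly increasing angles in (-180, 180];
#'   default `c(-120, 0, 120)`.
#' @param state_labels labels, defaults `"state1"..`.
#' @return object of class `RotamerStateSeries`: list with `angles`,
#'   `states` (per-frame label) and `state_occupancies` (fractions summing
#'   to 1).
#' @export
classify_rotamer_states <- function(series, state_boundaries = c(-120, 0, 120),
                                    state_labels = NULL) {
  b <- sort(state_boundaries)
  if (any(duplicated(b))) stop("overlapping state bins")
  if (any(b <= -180) || any(b > 180))
    stop("state boundaries must lie in (-180, 180]")
  k <- length(b)
  if (is.null(state_labels)) state_labels <- paste0("state", seq_len(k))
  if (length(state_labels) != k) stop("need one label per bin")
  ang <- series$values
  # bin index: angles in [b[k], b[k+1]) -> state k; wrap-around bin covers
  # [b[last], 180] plus (-180, b[1]).
  idx <- findInterval(ang, b)
  idx[idx == 0] <- k
  states <- state_labels[idx]
  occ <- vapply(state_labels, function(s) mean(states == s), numeric(1))
  structure(list(angles = ang, states = states,
                 state_occupancies = occ, boundaries = b,
                 times = series$times),
            class = "RotamerStateSeries")
}

#' @export
print.RotamerStateSeries <- function(x, ...) {
  cat("RotamerStateSeries:", length(x$states), "frames\n")
  for (s in names(x$state_occupancies))
    cat(sprintf("  %-8s %5.1f%%\n", s, 100 * x$state_occupancies[[s]]))
  invisible(x)
}

#' Centre-of-mass distance series between two groups
#'
#' @param traj a `Trajectory`.
#' @param top the matching `Topology`.
#' @param group_a,group_b selections understood by [select_atoms()].
#' @param mass_weighted use atomic masses (default) or unit weights.
#' @param label series label.
#' @return a `SeriesResult` in Angstrom.
#' @export
com_distance_series <- function(traj, top, group_a, group_b,
                                mass_weighted = TRUE, label = "com_distance") {
  ga <- select_atoms(top, group_a); gb <- select_atoms(top, group_b)
  if (!length(ga) || !length(gb)) stop("empty group")
  wa <- if (mass_weighted) atom_masses(top, ga) else rep(1, length(ga))
  wb <- if (mass_weighted) atom_masses(top, gb) else rep(1, length(gb))
  if (sum(wa) <= 0 || sum(wb) <= 0) stop("zero total weight")
  vals <- vapply(seq_len(traj$n_frames), function(f) {
    xyz <- frame_coords(traj, f)
    ca <- colSums(xyz[ga, , drop = FALSE] * wa) / sum(wa)
    cb <- colSums(xyz[gb, , drop = FALSE] * wb) / sum(wb)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  .series(traj$times, vals, label)
}

#' Atom-atom distance series
#'
#' @param traj a `Trajectory`.
#' @param atom_i,atom_j distinct atom indices.
#' @param label series label.
#' @return a `SeriesResult` in Angstrom.
#' @export
atom_distance_series <- function(traj, atom_i, atom_j, label = "distance") {
  if (atom_i == atom_j) stop("atom indices must differ")
  vals <- vapply(seq_len(traj$n_frames), function(f) {
    xyz <- frame_coords(traj, f)
    sqrt(sum((xyz[atom_i, ] - xyz[atom_j, ])^2))
  }, numeric(1))
  .series(traj$times, vals, label)
}

#' Longest conformationally stable window of a series
#'
#' Finds the longest contiguous frame window whose values all stay within
#' `tolerance` of the window median and whose length is at least
#' `min_length`; ties go to the earliest window. This formalises selecting
#' a stable time period from an RMSD trace before energetic post-processing.
#'
#' @param series a `SeriesResult`.
#' @param tolerance same units as the series values.
#' @param min_length minimum window length in frames (default 2).
#' @return list with `start`, `end` (1-based frame indices), `start_time`,
#'   `end_time` (ps) and `found`; when no window qualifies, `found` is
#'   `FALSE` and the indices are `NA`.
#' @export
select_stable_window <- function(series, tolerance, min_length = 2) {
  v <- series$values
  n <- length(v)
  if (!n) stop("empty series")
  best_len <- 0L; best_start <- NA_integer_
  for (i in seq_len(n)) {
    if (n - i + 1 <= best_len) break
    sorted <- numeric(0)
    for (j in i:n) {
      # incremental sorted insert keeps median lookups O(1)
      pos <- findInterval(v[j], sorted)
      sorted <- append(sorted, v[j], after = pos)
      len <- j - i + 1L
      med <- if (len %% 2) sorted[(len + 1) / 2] else
        (sorted[len / 2] + sorted[len / 2 + 1]) / 2
      if (sorted[len] - sorted[1] > 2 * tolerance)
        break  # no superset window can recover once the spread exceeds 2*tol
      if (sorted[len] - med > tolerance || med - sorted[1] > tolerance)
        next  # off-centre median: a longer window may still qualify
      if (len >= min_length && len > best_len) {
        best_len <- len; best_start <- i
      }
    }
  }
  if (!best_len)
    return(list(found = FALSE, start = NA_integer_, end = NA_integer_,
                start_time = NA_real_, end_time = NA_real_))
  list(found = TRUE, start = best_start, end = best_start + best_len - 1L,
       start_time = series$times[best_start],
       end_time = series$times[best_start + best_len - 1L])
}
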