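#' Full GBSA free energy of one frame for one partition
#'
#' Molecular-mechanics terms from [compute_mm_energy()] plus the
#' generalized-Born polar term (effective radii recomputed for the subset,
#' so burial changes between complex and separated parts are captured) and
#' the SASA-proportional nonpolar term. Intrinsic GB radii double as the
#' atomic radii of the surface calculation.
#'
#' @param xyz full-topology coordinate matrix.
#' @param top a parameterised `Topology`.
#' @param subset atom indices or selection.
#' @param config an [analysis_config()].
#' @return an `EnergyDecomposition` with all slots filled.
#' @export
gbsa_frame_energy <- function(xyz, top, subset, config = analysis_config()) {
  idx <- select_atoms(top, subset)
  e <- compute_mm_energy(xyz, top, idx)
  a <- top$atoms
  if (any(is.na(a$gb_radius[idx])))
    stop("missing GB radii for subset atoms")
  screen <- a$gb_screen[idx]
  fall <- unname(.GB_SCREEN[toupper(a$element[idx])])
  screen[is.na(screen)] <- fall[is.na(screen)]
  screen[is.na(screen)] <- .GB_SCREEN_DEFAULT
  x <- xyz[idx, , drop = FALSE]
  reff <- effective_born_radii(x, a$gb_radius[idx], screen)
  e$g_gb <- gb_polar_energy(x, a$charge[idx], reff,
                            config$eps_in, config$eps_out)
  sasa <- shrake_rupley_sasa(x, a$gb_radius[idx], config$probe_radius,
                             config$sasa_points)
  e$g_sa <- sasa_nonpolar_energy(sasa, config$gamma, config$beta)
  e$total <- e$total + e$g_gb + e$g_sa
  e
}

#' Snapshot frames for energetic post-processing
#'
#' Chooses frames inside the window so that consecutive snapshots are
#' `stride_ps` apart when the frame spacing allows, otherwise the nearest
#' achievable spacing (with a message).
#' @param traj a `Trajectory`.
#' @param window integer frame range `c(start, end)` or `NULL` for all.
#' @param stride_ps snapshot spacing in ps.
#' @return integer vector of frame indices.
#' @export
snapshot_frames <- function(traj, window = NULL, stride_ps = 500) {
  if (stride_ps <= 0) stop("stride must be > 0")
  frames <- if (is.null(window)) seq_len(traj$n_frames) else
    seq.int(window[1], window[2])
  if (!length(frames)) stop("empty window")
  if (length(frames) == 1) return(frames)
  dt <- stats::median(diff(traj$times[frames]))
  step <- max(1L, as.integer(round(stride_ps / dt)))
  if (abs(step * dt - stride_ps) > 1e-9)
    message("snapshot stride: requested ", stride_ps, " ps, using ",
            step * dt, " ps (frame spacing ", dt, " ps)")
  out <- frames[seq.int(1L, length(frames), by = step)]
  if (!length(out)) stop("empty window after striding")
  out
}

#' Single-trajectory MM-GBSA binding free energy
#'
#' For every sampled frame the complex, receptor and G-protein energies are
#' evaluated on the same coordinates (the single-trajectory protocol):
#' \deqn{\Delta G = G_{complex} - G_{receptor} - G_{gprotein}.}
#' The internal bonded terms cancel identically under this protocol -- no
#' bond, angle or torsion spans the two partitions -- and are reported as
#' exact zeros; entropic contributions are neglected. The per-frame series
#' is summarised as mean, standard deviation, and an ordinary-least-squares
#' trend line (slope in kcal/mol per ns).
#'
#' @param traj a `Trajectory`.
#' @param top a parameterised `Topology` with `receptor` and `gprotein`
#'   partitions.
#' @param config an [analysis_config()]; `snapshot_stride` sets the frame
#'   sampling.
#' @param window frame range `c(start, end)` (e.g. from
#'   [select_stable_window()]) or `NULL` for the full trajectory.
#' @param partition_a,partition_b partition names.
#' @return object of class `BindingEnergyResult`: per-frame `dg` series and
#'   component deltas, `mean`, `sd`, `trend` (slope, intercept), frame
#'   indices and times.
#' @export
binding_free_energy <- function(traj, top, config = analysis_config(),
                                window = NULL,
                                partition_a = "receptor",
                                partition_b = "gprotein") {
  ga <- top$partitions[[partition_a]]
  gb <- top$partitions[[partition_b]]
  if (is.null(ga) || is.null(gb)) stop("binding partitions not defined")
  if (length(intersect(ga, gb))) stop("binding partitions overlap")
  .check_no_cross_bonded(top, ga, gb)
  frames <- snapshot_frames(traj, window, config$snapshot_stride)
  cx <- sort(c(ga, gb))
  comp <- data.frame(frame = frames, time_ps = traj$times[frames],
                     d_bond = 0, d_angle = 0, d_dihedral = 0,
                     d_vdw = NA_real_, d_coulomb = NA_real_,
                     d_gb = NA_real_, d_sa = NA_real_, dg = NA_real_)
  for (r in seq_along(frames)) {
    xyz <- frame_coords(traj, frames[r])
    ec <- gbsa_frame_energy(xyz, top, cx, config)
    er <- gbsa_frame_energy(xyz, top, ga, config)
    eg <- gbsa_frame_energy(xyz, top, gb, config)
    comp$d_vdw[r] <- ec$e_vdw - er$e_vdw - eg$e_vdw
    comp$d_coulomb[r] <- ec$e_coulomb - er$e_coulomb - eg$e_coulomb
    comp$d_gb[r] <- ec$g_gb - er$g_gb - eg$g_gb
    comp$d_sa[r] <- ec$g_sa - er$g_sa - eg$g_sa
    comp$dg[r] <- comp$d_vdw[r] + comp$d_coulomb[r] + comp$d_gb[r] +
      comp$d_sa[r]
  }
  trend <- if (length(frames) >= 2 && stats::sd(comp$time_ps) > 0)
    fit_energy_trend(comp$time_ps, comp$dg) else
      list(slope = NA_real_, intercept = NA_real_)
  structure(list(components = comp, dg = comp$dg, times = comp$time_ps,
                 frames = frames, mean = mean(comp$dg),
                 sd = if (length(frames) > 1) stats::sd(comp$dg) else NA_real_,
                 trend = trend, config = config),
            class = "BindingEnergyResult")
}

# The single-trajectory cancellation is only exact when no bonded term
# spans the two partitions; refuse to silently mis-handle covalent links.
.check_no_cross_bonded <- function(top, ga, gb) {
  ina <- logical(nrow(top$atoms)); ina[ga] <- TRUE
  inb <- logical(nrow(top$atoms)); inb[gb] <- TRUE
  cross <- function(ii) {
    some_a <- Reduce(`|`, lapply(ii, function(v) ina[v]))
    some_b <- Reduce(`|`, lapply(ii, function(v) inb[v]))
    any(some_a & some_b)
  }
  if ((nrow(top$bonds) && cross(top$bonds[c("i", "j")])) ||
      (nrow(top$angles) && cross(top$angles[c("i", "j", "k")])) ||
      (nrow(top$dihedrals) && cross(top$dihedrals[c("i", "j", "k", "l")])))
    stop("bonded term spans the binding partitions; the single-trajectory ",
         "protocol requires covalently separate partners")
  invisible(TRUE)
}

#' @export
print.BindingEnergyResult <- function(x, ...) {
  cat(sprintf("Binding free energy (MM-GBSA, single trajectory): %.2f",
              x$mean))
  if (!is.na(x$sd)) cat(sprintf(" +/- %.2f", x$sd))
  cat(sprintf(" kcal/mol over %d snapshots\n", length(x$dg)))
  if (!is.na(x$trend$slope))
    cat(sprintf("  trend: %+.4f kcal/mol per ns\n", x$trend$slope))
  invisible(x)
}

#' Least-squares trend of an energy series
#'
#' Closed-form ordinary least squares of value against time; the slope is
#' reported per ns (times are ps).
#' @param times_ps time axis in ps.
#' @param values energies in kcal/mol.
#' @return list with `slope` (kcal/mol/ns) and `intercept` (kcal/mol).
#' @export
fit_energy_trend <- function(times_ps, values) {
  if (length(times_ps) < 2) stop("need at least 2 points")
  if (stats::sd(times_ps) == 0) stop("constant time axis")
  tns <- times_ps / 1000
  slope <- stats::cov(tns, values) / stats::var(tns)
  list(slope = slope, intercept = mean(values) - slope * mean(tns))
}
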