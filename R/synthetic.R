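# Simplified residue templates for the synthetic complexes: backbone plus a
# short side chain whose last atom is the interaction tip. Tips carry the
# formal charge for basic/acidic residues; everything else is neutral.
.SYN_RESIDUES <- list(
  GLY = list(atoms = c("N", "CA", "C", "O"),
             elements = c("N", "C", "C", "O"), tip_charge = 0),
  ALA = list(atoms = c("N", "CA", "C", "O", "CB"),
             elements = c("N", "C", "C", "O", "C"), tip_charge = 0),
  LEU = list(atoms = c("N", "CA", "C", "O", "CB", "CG", "CD1"),
             elements = c("N", "C", "C", "O", "C", "C", "C"), tip_charge = 0),
  HIS = list(atoms = c("N", "CA", "C", "O", "CB", "CG", "ND1"),
             elements = c("N", "C", "C", "O", "C", "C", "N"), tip_charge = 0),
  LYS = list(atoms = c("N", "CA", "C", "O", "CB", "CG", "NZ"),
             elements = c("N", "C", "C", "O", "C", "C", "N"),
             tip_charge = 1),
  GLU = list(atoms = c("N", "CA", "C", "O", "CB", "CG", "OE1"),
             elements = c("N", "C", "C", "O", "C", "C", "O"),
             tip_charge = -1)
)

# Element-based parameters of the synthetic force field.
.SYN_GB_RADII <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.5, S = 1.8)
.SYN_LJ_RMIN <- c(H = 1.387, C = 1.908, N = 1.824, O = 1.661, S = 2.0)
.SYN_LJ_EPS <- c(H = 0.0157, C = 0.1094, N = 0.17, O = 0.21, S = 0.25)

.RES_SPACING <- 6.0    # Angstrom between residue slots along x
.APART_DEFAULT <- 25.0 # tip-tip separation of non-interface residues

#' Parameter entries matching the synthetic residue templates
#'
#' One `(res_name, name)` row per template atom, in the JSON schema of
#' [load_parameters()]; used to exercise the parameter reader against
#' generator-built topologies.
#' @return data frame of atom parameter entries.
#' @export
synthetic_parameter_entries <- function() {
  rows <- list()
  for (rn in names(.SYN_RESIDUES)) {
    tpl <- .SYN_RESIDUES[[rn]]
    k <- length(tpl$atoms)
    q <- numeric(k); q[k] <- tpl$tip_charge
    rows[[rn]] <- data.frame(
      res_name = rn, name = tpl$atoms,
      charge = q,
      gb_radius = unname(.SYN_GB_RADII[tpl$elements]),
      lj_rmin_half = unname(.SYN_LJ_RMIN[tpl$elements]),
      lj_epsilon = unname(.SYN_LJ_EPS[tpl$elements]),
      mass = unname(.ELEMENT_MASSES[tpl$elements]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.syn_residue_coords <- function(rn, x, direction, tip_y) {
  # direction +1: side chain points toward +y (chain A); -1: toward -y.
  tpl <- .SYN_RESIDUES[[rn]]
  n_side <- length(tpl$atoms) - 4L
  # side-chain atoms sit 1.4 A apart ending at the tip
  side_y <- if (n_side > 0)
    tip_y - direction * 1.4 * rev(seq_len(n_side) - 1) else numeric(0)
  back_y <- (if (n_side > 0) side_y[1] else tip_y) - direction * 1.5
  # stagger the backbone in z per residue slot so CA traces are never
  # collinear (rigid-body fits need a non-degenerate point set)
  zig <- 0.4 * (round(x / .RES_SPACING) %% 3)
  xyz <- rbind(
    c(x - 1.2, back_y - direction * 1.0, 0.5 + zig),   # N
    c(x, back_y - direction * 1.0, zig),               # CA
    c(x + 1.2, back_y - direction * 1.0, 0.5 + zig),   # C
    c(x + 1.2, back_y - direction * 2.0, 1.2 + zig))   # O
  if (n_side > 0)
    xyz <- rbind(xyz, cbind(x, side_y, 0))
  dimnames(xyz) <- NULL
  xyz
}

#' Build a synthetic two-chain complex with a designed interface
#'
#' Two short chains of simplified residues (chain `R`, partition
#' `receptor`; chain `G`, partition `gprotein`) face each other across a
#' gap. Residue pairs named in `interface_spec` are placed so the two
#' side-chain tip atoms sit exactly at the requested distance; every other
#' chain-G residue is held far from the interface. Basic (LYS) and acidic
#' (GLU) residue types carry +1/-1 tip charges, creating designed salt
#' bridges. All per-atom parameters are populated from the synthetic
#' force field; intra-residue bonds get harmonic constants with `r0` equal
#' to the built geometry.
#'
#' @param n_res_a,n_res_b chain lengths (>= 2).
#' @param interface_spec `NULL` or data frame with columns `res_a`,
#'   `res_b` (1-based residue positions) and `distance` (Angstrom).
#' @param res_types_a,res_types_b residue-type vectors (names of the
#'   synthetic templates), recycled; default `"ALA"`.
#' @param apart tip-tip separation of non-interface residues (Angstrom).
#' @param seed integer; the generator is a pure function of its arguments.
#' @return list with `topology` and `coords`.
#' @export
make_two_chain_complex <- function(n_res_a, n_res_b, interface_spec = NULL,
                                   res_types_a = "ALA", res_types_b = "ALA",
                                   apart = .APART_DEFAULT, seed = 1L) {
  if (n_res_a < 2 || n_res_b < 2) stop("chains need at least 2 residues")
  types_a <- rep_len(res_types_a, n_res_a)
  types_b <- rep_len(res_types_b, n_res_b)
  bad <- setdiff(c(types_a, types_b), names(.SYN_RESIDUES))
  if (length(bad)) stop("unknown synthetic residue type: ",
                        paste(bad, collapse = ", "))
  if (!is.null(interface_spec)) {
    interface_spec <- as.data.frame(interface_spec)
    if (any(interface_spec$distance <= 0)) stop("non-positive distance")
    if (any(duplicated(interface_spec$res_b)) ||
        any(duplicated(interface_spec$res_a)))
      stop("overlapping placements: a residue appears in two interface pairs")
    if (any(interface_spec$res_a > n_res_a |
              interface_spec$res_b > n_res_b))
      stop("interface residue index out of range")
  }

  tip_a_y <- 3.3
  rows <- list(); coords <- list(); serial <- 0L
  bonds <- list()
  add_res <- function(chain, rid, rn, x, direction, tip_y) {
    tpl <- .SYN_RESIDUES[[rn]]
    xyz <- .syn_residue_coords(rn, x, direction, tip_y)
    k <- length(tpl$atoms)
    q <- numeric(k); q[k] <- tpl$tip_charge
    rows[[length(rows) + 1]] <<- data.frame(
      serial = serial + seq_len(k), name = tpl$atoms,
      element = tpl$elements, res_name = rn, res_id = rid,
      chain_id = chain, charge = q,
      gb_radius = unname(.SYN_GB_RADII[tpl$elements]),
      lj_rmin_half = unname(.SYN_LJ_RMIN[tpl$elements]),
      lj_epsilon = unname(.SYN_LJ_EPS[tpl$elements]),
      mass = unname(.ELEMENT_MASSES[tpl$elements]),
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1]] <<- xyz
    # intra-residue bonds: N-CA, CA-C, C-O, CA-CB, CB-CG, CG-tip
    con <- list(c(1, 2), c(2, 3), c(3, 4))
    if (k >= 5) con <- c(con, list(c(2, 5)))
    if (k >= 6) for (s in 6:k) con <- c(con, list(c(s - 1, s)))
    for (cn in con) {
      i <- serial + cn[1]; j <- serial + cn[2]
      r0 <- sqrt(sum((xyz[cn[1], ] - xyz[cn[2], ])^2))
      bonds[[length(bonds) + 1]] <<- data.frame(i = i, j = j, k = 300,
                                                r0 = r0)
    }
    serial <<- serial + k
  }

  for (i in seq_len(n_res_a))
    add_res("R", i, types_a[i], .RES_SPACING * i, +1, tip_a_y)
  pair_of_b <- if (is.null(interface_spec)) integer(0) else
    stats::setNames(interface_spec$res_a, interface_spec$res_b)
  for (j in seq_len(n_res_b)) {
    key <- as.character(j)
    if (!is.null(interface_spec) && key %in% names(pair_of_b)) {
      ia <- pair_of_b[[key]]
      d <- interface_spec$distance[interface_spec$res_b == j]
      x <- .RES_SPACING * ia           # share the partner's x slot
      tip_y <- tip_a_y + d
    } else {
      x <- .RES_SPACING * j
      tip_y <- tip_a_y + apart
    }
    add_res("G", j, types_b[j], x, -1, tip_y)
  }
  atoms <- do.call(rbind, rows)
  xyz <- do.call(rbind, coords)
  part <- list(receptor = which(atoms$chain_id == "R"),
               gprotein = which(atoms$chain_id == "G"))
  top <- topology(atoms, do.call(rbind, bonds), partitions = part)
  list(topology = top, coords = xyz)
}

#' Trajectory with exact per-pair contact occupancies
#'
#' For every scheduled residue pair, exactly `round(occupancy * n_frames)`
#' frames place the pair's tip atoms at `contact_distance`; all remaining
#' frames use `apart_distance`. Which frames are contact frames is decided
#' by a seeded permutation, so the schedule is deterministic and the target
#' occupancies are recovered exactly by the contact analysis.
#'
#' @param complex output of [make_two_chain_complex()].
#' @param schedule data frame `res_a`, `res_b`, `occupancy` (fractions in
#'   `[0, 1]`).
#' @param n_frames number of frames.
#' @param contact_distance,apart_distance tip-tip separations (Angstrom).
#' @param dt frame spacing in ps (default 100).
#' @param seed integer driving the frame interleaving.
#' @return a `Trajectory`.
#' @export
make_contact_trajectory <- function(complex, schedule, n_frames,
                                    contact_distance = 3.0,
                                    apart_distance = .APART_DEFAULT,
                                    dt = 100, seed = 1L) {
  schedule <- as.data.frame(schedule)
  if (any(duplicated(schedule$res_b)))
    stop("conflicting schedules on shared atoms: residue_b reused")
  top <- complex$topology
  rt <- residue_table(top)
  base <- complex$coords
  coords <- array(rep(base, each = n_frames),
                  c(n_frames, nrow(base), 3))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  for (r in seq_len(nrow(schedule))) {
    ia <- which(rt$chain_id == "R" & rt$res_id == schedule$res_a[r])
    ib <- which(rt$chain_id == "G" & rt$res_id == schedule$res_b[r])
    if (!length(ia) || !length(ib)) stop("scheduled pair not in complex")
    tip_a <- rt$last_atom[ia]; tip_b <- rt$last_atom[ib]
    atoms_b <- seq.int(rt$first_atom[ib], rt$last_atom[ib])
    n_contact <- round(schedule$occupancy[r] * n_frames)
    set.seed(seed + r)
    contact_frames <- logical(n_frames)
    contact_frames[sample.int(n_frames, n_contact)] <- TRUE
    # each schedule row keeps its own z lane so several partners of one
    # residue can touch it simultaneously without overlapping
    dz <- 0.6 * (r - 1)
    if (dz >= contact_distance)
      stop("infeasible schedule: too many simultaneous partners for the ",
           "requested contact distance")
    for (f in seq_len(n_frames)) {
      d <- if (contact_frames[f]) contact_distance else apart_distance
      dy <- sqrt(d^2 - dz^2)
      target_tip <- base[tip_a, ] + c(0, dy, dz)
      shift <- target_tip - base[tip_b, ]
      coords[f, atoms_b, ] <- sweep(base[atoms_b, , drop = FALSE], 2,
                                    shift, "+")
    }
  }
  trajectory(coords, times = dt * (seq_len(n_frames) - 1))
}

#' Static (frozen-coordinate) trajectory of a complex
#'
#' @param complex output of [make_two_chain_complex()].
#' @param n_frames number of identical frames.
#' @param dt frame spacing in ps (default 500, one energetic snapshot per
#'   frame under the default stride).
#' @return a `Trajectory`.
#' @export
make_static_trajectory <- function(complex, n_frames = 5, dt = 500) {
  coords <- array(rep(complex$coords, each = n_frames),
                  c(n_frames, nrow(complex$coords), 3))
  trajectory(coords, times = dt * (seq_len(n_frames) - 1))
}

#' Four-atom trajectory cycling through designed rotamer states
#'
#' Builds a C-CA-CB-CG-like quadruple whose torsion visits each state
#' angle; frame counts per state are exact (largest-remainder allocation)
#' and a seeded permutation interleaves the states. Angular jitter is
#' bounded so no frame crosses a bin boundary of the default three-state
#' classification.
#'
#' @param state_angles torsion of each state, degrees; default
#'   `c(-60, 60, 180)` (the centres of the default bins).
#' @param state_fractions fractions summing to 1.
#' @param jitter_degrees uniform jitter half-width (must stay below the
#'   distance from each state angle to its nearest bin boundary).
#' @param n_frames number of frames.
#' @param seed integer.
#' @param boundaries bin boundaries used for the margin check; default
#'   `c(-120, 0, 120)`.
#' @return list with `topology`, `trajectory`, `quadruple` (atom indices),
#'   and `states` (the designed per-frame state index).
#' @export
make_dihedral_trajectory <- function(state_angles = c(-60, 60, 180),
                                     state_fractions = c(0.5, 0.3, 0.2),
                                     jitter_degrees = 10, n_frames = 1000,
                                     seed = 1L,
                                     boundaries = c(-120, 0, 120)) {
  if (abs(sum(state_fractions) - 1) > 1e-9)
    stop("state fractions must sum to 1")
  k <- length(state_angles)
  if (length(state_fractions) != k) stop("one fraction per state")
  margin <- vapply(state_angles, function(a)
    min(abs(.circ_diff(a, boundaries))), numeric(1))
  if (jitter_degrees >= min(margin))
    stop("jitter ", jitter_degrees, " deg would cross a bin boundary ",
         "(margin ", round(min(margin), 2), " deg)")
  # largest-remainder allocation: exact counts summing to n_frames
  raw <- state_fractions * n_frames
  counts <- floor(raw)
  rem <- n_frames - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)
  states <- sample(rep.int(seq_len(k), counts))
  jit <- stats::runif(n_frames, -jitter_degrees, jitter_degrees)
  angles <- state_angles[states] + jit
  angles <- ifelse(angles > 180, angles - 360, angles)

  atoms <- data.frame(serial = 1:4, name = c("C", "CA", "CB", "CG"),
                      element = c("C", "C", "C", "C"), res_name = "HIS",
                      res_id = 393L, chain_id = "R",
                      stringsAsFactors = FALSE)
  top <- topology(atoms, partitions = list(receptor = 1:4))
  coords <- array(NA_real_, c(n_frames, 4, 3))
  for (f in seq_len(n_frames))
    coords[f, , ] <- .torsion_quadruple(angles[f])
  list(topology = top, trajectory = trajectory(coords),
       quadruple = 1:4, states = states,
       state_fractions = counts / n_frames)
}

.circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Coordinates of a 4-point chain realising torsion phi (degrees).
.torsion_quadruple <- function(phi) {
  rad <- phi * pi / 180
  rbind(c(-0.5, 1.4, 0),
        c(0, 0, 0),
        c(1.5, 0, 0),
        c(2.0, 1.4 * cos(rad), 1.4 * sin(rad)))
}

#' Single charged sphere with a closed-form Born energy
#'
#' One-atom system whose generalized-Born energy has the analytic target
#' `-(ke/2) (1/eps_in - 1/eps_out) q^2 / radius`. The stored intrinsic
#' radius is offset-corrected so the effective radius equals `radius`.
#'
#' @param charge charge in e.
#' @param radius desired effective Born radius (Angstrom).
#' @return list with `topology` and `coords` (1 x 3 zero matrix).
#' @export
make_charged_sphere_system <- function(charge, radius) {
  if (radius <= 0) stop("radius must be > 0")
  atoms <- data.frame(serial = 1L, name = "Q", element = "C",
                      res_name = "SPH", res_id = 1L, chain_id = "S",
                      charge = charge, gb_radius = radius + .GB_OFFSET,
                      lj_rmin_half = radius, lj_epsilon = 0,
                      mass = 12.011, stringsAsFactors = FALSE)
  list(topology = topology(atoms, partitions = list(sphere = 1L)),
       coords = matrix(0, 1, 3))
}

#' Minimal salt-bridge complex with a known hot spot
#'
#' Two six-residue chains: a basic lysine-like residue (chain R, position
#' 3) forms the single dominant salt bridge to an acidic glutamate-like
#' residue (chain G, position 3) at `separation`; two flanking alanine
#' pairs provide van der Waals contacts so the complex is genuinely bound;
#' a neutral leucine-like residue at chain R position 5 sits far from the
#' interface as the null control for alanine scanning.
#'
#' @param separation tip-tip N-O distance of the salt bridge (Angstrom,
#'   default 3.0; must be below the 4.0 salt-bridge criterion).
#' @param seed integer.
#' @return list with `topology`, `coords`, and `hot_spot` /
#'   `null_residue` residue descriptors.
#' @export
make_saltbridge_complex <- function(separation = 3.0, seed = 1L) {
  if (separation >= 4.0)
    stop("separation must lie below the 4.0 A salt-bridge criterion")
  cx <- make_two_chain_complex(
    n_res_a = 6, n_res_b = 6,
    interface_spec = data.frame(res_a = c(2, 3, 4), res_b = c(2, 3, 4),
                                distance = c(3.4, separation, 3.4)),
    res_types_a = c("ALA", "ALA", "LYS", "ALA", "LEU", "ALA"),
    res_types_b = c("ALA", "ALA", "GLU", "ALA", "ALA", "ALA"),
    seed = seed)
  c(cx, list(hot_spot = list(chain_id = "R", res_id = 3L, res_name = "LYS"),
             null_residue = list(chain_id = "R", res_id = 5L,
                                 res_name = "LEU")))
}
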