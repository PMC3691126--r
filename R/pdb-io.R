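#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) into a [topology()] plus a single
#' frame of coordinates. Chains and file order are preserved; author residue
#' numbering is kept verbatim. Files using insertion codes are rejected:
#' downstream residue identity is `(chain_id, res_id, res_name)` and an
#' insertion code would make it ambiguous.
#'
#' @param path PDB file.
#' @param format only `"pdb"` is supported.
#' @return list with elements `topology` (a `Topology`) and `coords`
#'   (n_atoms x 3 matrix, Angstrom).
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported (residue identity would be ",
         "ambiguous): ", path)
  atoms <- data.frame(
    serial = at$eleno, name = at$elety,
    element = .element_from_record(at$elesy, at$elety),
    res_name = at$resid, res_id = at$resno, chain_id = at$chain,
    stringsAsFactors = FALSE)
  atoms$chain_id[is.na(atoms$chain_id)] <- " "
  coords <- cbind(at$x, at$y, at$z)
  if (any(!is.finite(coords))) stop("non-finite coordinates in ", path)
  top <- topology(atoms, partitions = .chain_partitions(atoms))
  list(topology = top, coords = coords)
}

# One partition per chain; callers typically rename/regroup these.
.chain_partitions <- function(atoms) {
  chains <- unique(atoms$chain_id)
  stats::setNames(lapply(chains, function(ch) which(atoms$chain_id == ch)),
                  paste0("chain_", chains))
}

.element_from_record <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  guess <- toupper(substr(gsub("[^A-Za-z].*", "", trimws(elety)), 1, 1))
  ifelse(el == "", guess, el)
}

# Fixed-column sanity check so parse errors carry a line number.
.validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (ln in which(rec)) {
    l <- lines[ln]
    if (nchar(l) < 54)
      stop("malformed ATOM record (too short) at line ", ln, " of ", path)
    xyz <- c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(xyz)))))
      stop("malformed ATOM record (bad coordinate field) at line ", ln,
           " of ", path)
  }
  invisible(TRUE)
}

#' Write a structure (or one trajectory frame) as PDB
#'
#' @param top a `Topology`.
#' @param coords n_atoms x 3 matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(top, coords, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_pdb_frame(con, top, coords)
  writeLines("END", con)
  invisible(path)
}

.write_pdb_frame <- function(con, top, coords) {
  a <- top$atoms
  name4 <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                  sprintf("%-4s", a$name))
  writeLines(sprintf(
    "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000L, name4, a$res_name, a$chain_id, a$res_id,
    coords[, 1], coords[, 2], coords[, 3], 1, 0, a$element), con)
  invisible(NULL)
}

#' Construct a trajectory
#'
#' @param coords n_frames x n_atoms x 3 array (Angstrom).
#' @param times frame times in ps, strictly increasing; default `0, 1, ...`.
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(coords, times = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  n_frames <- dim(coords)[1]
  if (is.null(times)) times <- as.numeric(seq_len(n_frames) - 1)
  if (length(times) != n_frames)
    stop("frame_times length ", length(times), " != n_frames ", n_frames)
  if (n_frames > 1 && any(diff(times) <= 0))
    stop("frame_times must be strictly increasing")
  if (any(!is.finite(coords))) stop("non-finite coordinates in trajectory")
  structure(list(coords = coords, times = as.numeric(times),
                 n_frames = n_frames, n_atoms = dim(coords)[2]),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", x$n_frames, "frames x", x$n_atoms, "atoms, t =",
      x$times[1], "..", x$times[x$n_frames], "ps\n")
  invisible(x)
}

#' Extract one frame of a trajectory as an n_atoms x 3 matrix
#' @param traj a `Trajectory`.
#' @param frame 1-based frame index.
#' @return n_atoms x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(frame >= 1, frame <= traj$n_frames)
  matrix(traj$coords[frame, , ], ncol = 3)
}

#' Read a trajectory from a multi-model PDB
#'
#' Frames are delimited by MODEL/ENDMDL records (a plain single-structure
#' file yields one frame). The atom count of every frame must match the
#' supplied topology. PDB files carry no time axis, so frame times are
#' assigned as `0, dt, 2 dt, ...`.
#'
#' @param path multi-model PDB file.
#' @param top the matching `Topology`.
#' @param format only `"pdb"`.
#' @param dt frame spacing in ps (default 1).
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(path, top, format = "pdb", dt = 1) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  n_expected <- nrow(top$atoms)
  n_file <- ncol(xyz) / 3
  if (n_file != n_expected)
    stop("atom-count mismatch: topology has ", n_expected,
         " atoms, file has ", n_file)
  n_frames <- nrow(xyz)
  coords <- array(NA_real_, c(n_frames, n_expected, 3))
  for (f in seq_len(n_frames))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(coords, times = dt * (seq_len(n_frames) - 1))
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a `Trajectory`.
#' @param top the matching `Topology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, top, path) {
  if (traj$n_atoms != nrow(top$atoms))
    stop("atom-count mismatch between trajectory and topology")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    .write_pdb_frame(con, top, frame_coords(traj, f))
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
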