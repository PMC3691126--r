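# Fallback parameters for the hydrogen that replaces the gamma atom.
.HB_PARAMS <- list(charge = 0, gb_radius = 1.2, lj_rmin_half = 1.487,
                   lj_epsilon = 0.0157, mass = 1.008, gb_screen = 0.85)

# Atom names that survive truncation to alanine.
.ALA_KEEP <- c("N", "H", "H1", "H2", "H3", "CA", "HA", "C", "O", "OXT",
               "CB", "HB1", "HB2", "HB3")

#' Truncate a residue's side chain to alanine
#'
#' Side-chain atoms beyond the beta carbon are removed; the beta carbon
#' keeps its wild-type coordinates and the gamma heavy atom is replaced by
#' a hydrogen placed 1.09 Angstrom from the beta carbon along the former
#' beta-gamma direction. Alanine, glycine and chain-terminal residues are
#' rejected (terminal truncation would also clip the backbone).
#'
#' By default the retained atoms keep their wild-type parameters and the
#' new hydrogen receives standard aliphatic-hydrogen values; a full alanine
#' entry table (`res_name == "ALA"` rows of the parameter schema) can be
#' supplied to remap every atom of the mutated residue.
#'
#' @param top a parameterised `Topology`.
#' @param chain,res_id residue identity.
#' @param ala_params optional data frame of alanine atom-parameter entries
#'   (`name`, `charge`, `gb_radius`, `lj_rmin_half`, `lj_epsilon`, ...).
#' @param .force_identical test hook: allow "mutating" an alanine, which
#'   must return an identical system.
#' @return object of class `AlanineMutation`: list with the mutant
#'   `topology`, `kept` (old atom indices in mutant order), `hb_row`
#'   (mutant row of the placed hydrogen or `NA`), `cb_old`, `cg_old`, and
#'   `mutant_coords(xyz)` obtained via [mutant_frame_coords()].
#' @export
alanine_mutate <- function(top, chain, res_id, ala_params = NULL,
                           .force_identical = FALSE) {
  rt <- residue_table(top)
  ri <- which(rt$chain_id == chain & rt$res_id == res_id)
  if (!length(ri)) stop("residue (", chain, ", ", res_id, ") not found")
  rn <- rt$res_name[ri]
  if (!rn %in% names(.AA3TO1))
    stop("residue ", rn, " is not a standard amino acid")
  same_chain <- which(rt$chain_id == chain)
  if (ri == min(same_chain) || ri == max(same_chain))
    stop("terminal residue (", chain, ", ", res_id,
         ") cannot be alanine-scanned")
  if (rn %in% c("ALA", "GLY") && !.force_identical)
    stop(rn, " residues are excluded from alanine scanning")

  ids <- seq.int(rt$first_atom[ri], rt$last_atom[ri])
  nm <- top$atoms$name[ids]
  if (rn == "ALA" || (rn == "GLY" && .force_identical)) {
    kept <- seq_len(nrow(top$atoms))
    return(structure(list(topology = top, kept = kept, hb_row = NA_integer_,
                          cb_old = NA_integer_, cg_old = NA_integer_),
                     class = "AlanineMutation"))
  }
  cb <- ids[nm == "CB"]
  if (length(cb) != 1) stop("residue has no unique CB atom")
  gammas <- ids[grepl("^[A-Z]G[0-9]?$", nm)]
  if (!length(gammas)) stop("residue has no gamma atom to truncate")
  cg <- gammas[1]
  drop_ <- setdiff(ids[!nm %in% .ALA_KEEP], cg)

  n <- nrow(top$atoms)
  kept <- setdiff(seq_len(n), drop_)   # cg stays, repurposed as hydrogen
  newpos <- match(seq_len(n), kept)
  a <- top$atoms[kept, , drop = FALSE]
  rownames(a) <- NULL
  hb_row <- newpos[cg]
  hb_name <- if ("HB1" %in% a$name[a$chain_id == chain & a$res_id == res_id])
    "HB9" else "HB1"
  a$name[hb_row] <- hb_name
  a$element[hb_row] <- "H"
  res_rows <- which(a$chain_id == chain & a$res_id == res_id)
  a$res_name[res_rows] <- "ALA"
  for (f in names(.HB_PARAMS)) a[[f]][hb_row] <- .HB_PARAMS[[f]]
  if (!is.null(ala_params)) {
    ala_params <- as.data.frame(ala_params, stringsAsFactors = FALSE)
    m <- match(a$name[res_rows], ala_params$name)
    for (f in intersect(names(.HB_PARAMS), names(ala_params))) {
      v <- ala_params[[f]][m]
      a[[f]][res_rows] <- ifelse(is.na(v), a[[f]][res_rows], v)
    }
  }

  remap_terms <- function(terms, cols) {
    if (!nrow(terms)) return(terms)
    keep <- rep(TRUE, nrow(terms))
    for (cn in cols) keep <- keep & !is.na(newpos[terms[[cn]]])
    terms <- terms[keep, , drop = FALSE]
    for (cn in cols) terms[[cn]] <- newpos[terms[[cn]]]
    rownames(terms) <- NULL
    terms
  }
  bonds <- remap_terms(top$bonds, c("i", "j"))
  angles <- remap_terms(top$angles, c("i", "j", "k"))
  dihedrals <- remap_terms(top$dihedrals, c("i", "j", "k", "l"))
  partitions <- lapply(top$partitions, function(p) {
    q <- newpos[p]; sort(q[!is.na(q)])
  })
  mut <- topology(a, bonds, angles, dihedrals, partitions)
  structure(list(topology = mut, kept = kept, hb_row = hb_row,
                 cb_old = cb, cg_old = cg),
            class = "AlanineMutation")
}

#' Coordinates of a mutant system for one wild-type frame
#'
#' Subsets the frame to the retained atoms and places the beta hydrogen
#' 1.09 Angstrom from CB along the wild-type CB-CG direction of that frame,
#' keeping mutant and wild type frame-matched.
#' @param mutation an `AlanineMutation`.
#' @param xyz wild-type frame coordinates.
#' @return mutant coordinate matrix.
#' @export
mutant_frame_coords <- function(mutation, xyz) {
  x <- xyz[mutation$kept, , drop = FALSE]
  if (!is.na(mutation$hb_row)) {
    v <- xyz[mutation$cg_old, ] - xyz[mutation$cb_old, ]
    x[mutation$hb_row, ] <- xyz[mutation$cb_old, ] +
      1.09 * v / sqrt(sum(v^2))
  }
  x
}

#' Computational alanine scanning
#'
#' For each requested residue, the complex is truncated to alanine and the
#' single-trajectory binding free energy recomputed on the same snapshot
#' frames; the reported change is
#' \deqn{\Delta\Delta G = \Delta G_{mutant} - \Delta G_{wildtype}}
#' aggregated frame-matched as mean and standard deviation. A positive
#' value means the wild-type side chain stabilises the complex. Alanine,
#' glycine and terminal residues are rejected by [alanine_mutate()].
#'
#' @param traj a `Trajectory`.
#' @param top a parameterised `Topology` with binding partitions.
#' @param residues data frame with `chain_id` and `res_id` columns.
#' @param config an [analysis_config()].
#' @param window frame range or `NULL`.
#' @param ala_params optional alanine parameter entries (see
#'   [alanine_mutate()]).
#' @param partition_a,partition_b partition names.
#' @return data frame of class `AlaScanResult`: residue identity,
#'   `ddG_mean`, `ddG_sd`, `n_frames`.
#' @export
alanine_scan <- function(traj, top, residues, config = analysis_config(),
                         window = NULL, ala_params = NULL,
                         partition_a = "receptor",
                         partition_b = "gprotein") {
  rt <- residue_table(top)
  frames <- snapshot_frames(traj, window, config$snapshot_stride)
  wt <- binding_free_energy(traj, top, config, window,
                            partition_a, partition_b)
  out <- vector("list", nrow(residues))
  for (r in seq_len(nrow(residues))) {
    ch <- residues$chain_id[r]; id <- residues$res_id[r]
    ri <- which(rt$chain_id == ch & rt$res_id == id)
    if (!length(ri)) stop("residue (", ch, ", ", id, ") not found")
    aidx <- seq.int(rt$first_atom[ri], rt$last_atom[ri])
    in_a <- any(aidx %in% top$partitions[[partition_a]])
    in_b <- any(aidx %in% top$partitions[[partition_b]])
    if (!in_a && !in_b)
      stop("residue (", ch, ", ", id, ") lies outside both binding ",
           "partitions")
    mut <- alanine_mutate(top, ch, id, ala_params = ala_params)
    ddg <- vapply(seq_along(frames), function(k) {
      xyz <- frame_coords(traj, frames[k])
      mx <- mutant_frame_coords(mut, xyz)
      dg_mut <- .single_frame_dg(mx, mut$topology, config,
                                 partition_a, partition_b)
      dg_mut - wt$dg[k]
    }, numeric(1))
    out[[r]] <- data.frame(
      chain_id = ch, res_id = id, res_name = rt$res_name[ri],
      generic = rt$generic[ri],
      label = residue_label(rt$res_name[ri], id, rt$generic[ri]),
      ddG_mean = mean(ddg),
      ddG_sd = if (length(ddg) > 1) stats::sd(ddg) else NA_real_,
      n_frames = length(frames), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("AlaScanResult", "data.frame")
  res
}

.single_frame_dg <- function(xyz, top, config, partition_a, partition_b) {
  ga <- top$partitions[[partition_a]]
  gb <- top$partitions[[partition_b]]
  cx <- sort(c(ga, gb))
  ec <- gbsa_frame_energy(xyz, top, cx, config)
  er <- gbsa_frame_energy(xyz, top, ga, config)
  eg <- gbsa_frame_energy(xyz, top, gb, config)
  (ec$e_vdw - er$e_vdw - eg$e_vdw) +
    (ec$e_coulomb - er$e_coulomb - eg$e_coulomb) +
    (ec$g_gb - er$g_gb - eg$g_gb) +
    (ec$g_sa - er$g_sa - eg$g_sa)
}

#' @export
print.AlaScanResult <- function(x, ...) {
  cat("Computational alanine scan (ddG = dG_mutant - dG_wildtype):\n")
  for (r in seq_len(nrow(x)))
    cat(sprintf("  %-14s %6.2f +/- %.2f kcal/mol (n = %d)\n", x$label[r],
                x$ddG_mean[r],
                ifelse(is.na(x$ddG_sd[r]), 0, x$ddG_sd[r]), x$n_frames[r]))
  invisible(x)
}

#' Write an alanine-scan table as TSV
#'
#' Columns: residue, generic number, ddG mean, ddG standard deviation,
#' snapshot count, plus a human-readable `value +/- sd` rendering.
#' @param scan an `AlaScanResult`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alascan_table <- function(scan, path) {
  out <- data.frame(
    residue = scan$label,
    generic = ifelse(is.na(scan$generic), "-", scan$generic),
    ddG_mean = sprintf("%.3f", scan$ddG_mean),
    ddG_sd = ifelse(is.na(scan$ddG_sd), "-", sprintf("%.3f", scan$ddG_sd)),
    n_frames = scan$n_frames,
    report = sprintf("%.2f ± %.2f", scan$ddG_mean,
                     ifelse(is.na(scan$ddG_sd), 0, scan$ddG_sd)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
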