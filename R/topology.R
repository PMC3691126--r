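# Standard atomic masses (g/mol) used for mass-weighted centroids; unit mass
# is substituted when the element is unknown.
.ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, FE = 55.845,
  ZN = 65.38, MG = 24.305, "NA" = 22.99, K = 39.098, CA = 40.078
)

# Pairwise-descreening screening factors by element (dimensionless).
.GB_SCREEN <- c(H = 0.85, C = 0.72, N = 0.79, O = 0.85, S = 0.96)
.GB_SCREEN_DEFAULT <- 0.8

#' Construct a molecular topology
#'
#' A `Topology` bundles the per-atom table (identity, coordinates-free
#' metadata, partial charges, intrinsic generalized-Born radii and
#' Lennard-Jones parameters), the bonded-term lists with force-field
#' constants, the nonbonded exclusion lists derived from connectivity, and
#' named atom-index partitions such as `"receptor"` and `"gprotein"`.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_id`, `chain_id` and optionally `charge` (e),
#'   `gb_radius` (Angstrom), `lj_rmin_half` (Angstrom), `lj_epsilon`
#'   (kcal/mol), `mass` (g/mol), `gb_screen`, `generic`.
#' @param bonds data frame `i, j, k, r0` (kcal/mol/A^2, Angstrom); may have
#'   zero rows.
#' @param angles data frame `i, j, k, l_k, theta0` where `l_k` is the force
#'   constant (kcal/mol/rad^2) and `theta0` the equilibrium angle (rad).
#' @param dihedrals data frame `i, j, k, l, pk, n, delta` (kcal/mol,
#'   periodicity, phase in rad).
#' @param partitions named list of integer atom-index vectors.
#' @return an object of class `Topology`.
#' @export
topology <- function(atoms, bonds = NULL, angles = NULL, dihedrals = NULL,
                     partitions = list()) {
  required <- c("serial", "name", "element", "res_name", "res_id", "chain_id")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  for (col in c("charge", "gb_radius", "lj_rmin_half", "lj_epsilon", "mass"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (is.null(atoms$gb_screen)) atoms$gb_screen <- NA_real_
  if (is.null(atoms$generic)) atoms$generic <- NA_character_
  rownames(atoms) <- NULL

  key <- paste(atoms$chain_id, atoms$res_id, atoms$name, sep = "|")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate atom name within a residue: ",
         paste(unique(key[dup]), collapse = ", "))

  n <- nrow(atoms)
  bonds <- .empty_if_null(bonds, c("i", "j", "k", "r0"))
  angles <- .empty_if_null(angles, c("i", "j", "k", "l_k", "theta0"))
  dihedrals <- .empty_if_null(dihedrals, c("i", "j", "k", "l", "pk", "n", "delta"))
  idx <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k,
           dihedrals$i, dihedrals$j, dihedrals$k, dihedrals$l,
           unlist(partitions, use.names = FALSE))
  if (length(idx) && (any(idx < 1) || any(idx > n)))
    stop("bonded/partition atom index out of range 1..", n)
  if (!is.null(partitions$receptor) && !is.null(partitions$gprotein) &&
      length(intersect(partitions$receptor, partitions$gprotein)))
    stop("partitions 'receptor' and 'gprotein' overlap")

  excl <- derive_exclusions(n, bonds)
  structure(list(atoms = atoms, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, partitions = partitions,
                 excl12_13 = excl$excl12_13, pairs14 = excl$pairs14),
            class = "Topology")
}

.empty_if_null <- function(x, cols) {
  if (is.null(x)) {
    x <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols))
    stop("bonded table lacks column(s): ", paste(missing_cols, collapse = ", "))
  x
}

#' Derive nonbonded exclusion lists from the bond graph
#'
#' 1-2 and 1-3 neighbours are fully excluded from nonbonded sums; 1-4
#' neighbours are collected separately so Coulomb and Lennard-Jones terms can
#' be scaled down. A pair connected by both a short path and a 1-4 path is
#' excluded (the stronger rule wins).
#'
#' @param n_atoms number of atoms.
#' @param bonds data frame with columns `i`, `j`.
#' @return list with integer matrices `excl12_13` and `pairs14` (2 columns,
#'   `i < j` rows, lexicographic order).
#' @export
derive_exclusions <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0)
    return(list(excl12_13 = matrix(integer(0), 0, 2),
                pairs14 = matrix(integer(0), 0, 2)))
  nb <- vector("list", n_atoms)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  p12 <- list(); p13 <- list(); p14 <- list()
  for (a in seq_len(n_atoms)) {
    one <- unique(nb[[a]])
    two <- setdiff(unique(unlist(nb[one])), c(a, one))
    three <- setdiff(unique(unlist(nb[two])), c(a, one, two))
    p12[[a]] <- one[one > a]
    p13[[a]] <- two[two > a]
    p14[[a]] <- three[three > a]
  }
  mk <- function(p) {
    lens <- lengths(p)
    if (!sum(lens)) return(matrix(integer(0), 0, 2))
    cbind(rep(seq_along(p), lens), unlist(p, use.names = FALSE))
  }
  e <- rbind(mk(p12), mk(p13))
  f <- mk(p14)
  ek <- paste(e[, 1], e[, 2])
  f <- f[!(paste(f[, 1], f[, 2]) %in% ek), , drop = FALSE]
  e <- unique(e)
  list(excl12_13 = e[order(e[, 1], e[, 2]), , drop = FALSE],
       pairs14 = f[order(f[, 1], f[, 2]), , drop = FALSE])
}

#' @export
print.Topology <- function(x, ...) {
  cat("Topology:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain_id, x$atoms$res_id))), "residues,",
      nrow(x$bonds), "bonds\n")
  if (length(x$partitions))
    cat("  partitions:",
        paste(sprintf("%s (%d)", names(x$partitions),
                      lengths(x$partitions)), collapse = ", "), "\n")
  invisible(x)
}

#' Atom indices of a named partition or selection
#'
#' @param top a `Topology`.
#' @param selection either a partition name, an integer vector of atom
#'   indices, or a list with any of `chain`, `res_id`, `name`, `elety`
#'   fields to match against the atom table.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(top, selection) {
  a <- top$atoms
  if (is.numeric(selection)) {
    sel <- as.integer(selection)
    if (any(sel < 1 | sel > nrow(a))) stop("atom index out of range")
    return(sel)
  }
  if (is.character(selection) && length(selection) == 1 &&
      selection %in% names(top$partitions))
    return(top$partitions[[selection]])
  if (is.list(selection)) {
    keep <- rep(TRUE, nrow(a))
    if (!is.null(selection$chain)) keep <- keep & a$chain_id %in% selection$chain
    if (!is.null(selection$res_id)) keep <- keep & a$res_id %in% selection$res_id
    if (!is.null(selection$name)) keep <- keep & a$name %in% selection$name
    return(which(keep))
  }
  stop("cannot interpret selection")
}

#' Masses for a set of atoms
#'
#' Uses the `mass` column when populated, otherwise standard atomic masses by
#' element, otherwise unit mass.
#' @param top a `Topology`.
#' @param idx atom indices.
#' @return numeric vector of masses.
#' @export
atom_masses <- function(top, idx = seq_len(nrow(top$atoms))) {
  m <- top$atoms$mass[idx]
  el <- toupper(top$atoms$element[idx])
  fallback <- unname(.ELEMENT_MASSES[el])
  m[is.na(m)] <- fallback[is.na(m)]
  m[is.na(m)] <- 1
  m
}

#' Residue table of a topology
#'
#' One row per residue in atom order: `chain_id`, `res_id`, `res_name`, the
#' generic-number label if assigned, and first/last atom indices.
#' @param top a `Topology`.
#' @return data frame, one row per residue.
#' @export
residue_table <- function(top) {
  a <- top$atoms
  key <- paste(a$chain_id, a$res_id, sep = "|")
  first <- !duplicated(key)
  ord <- which(first)
  data.frame(chain_id = a$chain_id[first], res_id = a$res_id[first],
             res_name = a$res_name[first], generic = a$generic[first],
             first_atom = ord,
             last_atom = c(ord[-1] - 1L, nrow(a)),
             stringsAsFactors = FALSE)
}

#' Human-readable residue label
#'
#' One-letter (when standard) or three-letter code plus author number, with
#' the generic (Ballesteros-Weinstein style) label appended as
#' `"R131^3.50"` when one is assigned.
#' @param res_name 3-letter residue names.
#' @param res_id author residue numbers.
#' @param generic generic labels or `NA`.
#' @return character vector of labels.
#' @export
residue_label <- function(res_name, res_id, generic = NA_character_) {
  one <- .AA3TO1[res_name]
  code <- ifelse(is.na(one), res_name, one)
  lab <- paste0(code, res_id)
  generic <- rep_len(generic, length(lab))
  ifelse(is.na(generic) | generic == "", lab, paste0(lab, "^", generic))
}

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
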