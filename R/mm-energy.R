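# 1-4 nonbonded scaling (ff99SB convention): electrostatics divided by 1.2,
# Lennard-Jones divided by 2.0.
.SCEE <- 1.2
.SCNB <- 2.0

#' Molecular-mechanics energy of one frame
#'
#' Evaluates harmonic bonds `k (r - r0)^2` and angles `k (theta - theta0)^2`,
#' periodic cosine dihedrals `pk (1 + cos(n phi - delta))`, 12-6
#' Lennard-Jones in the `rmin/epsilon` convention, and Coulomb
#' electrostatics with `ke = 332.0636` kcal A/(mol e^2). 1-2 and 1-3 pairs
#' are excluded from the nonbonded sums, 1-4 pairs are scaled, and no
#' distance cutoff is applied (the implicit-solvent convention). Only terms
#' whose atoms all lie inside `subset` contribute.
#'
#' @param xyz n_atoms x 3 coordinate matrix for the full topology.
#' @param top a parameterised `Topology`.
#' @param subset atom indices (or a selection for [select_atoms()]) to
#'   evaluate; defaults to all atoms.
#' @return list of class `EnergyDecomposition` with components `e_bond`,
#'   `e_angle`, `e_dihedral`, `e_vdw`, `e_coulomb`, `g_gb`, `g_sa`, `total`
#'   (kcal/mol); the solvation slots are zero here and filled by the GBSA
#'   layer.
#' @export
compute_mm_energy <- function(xyz, top, subset = NULL) {
  a <- top$atoms
  idx <- if (is.null(subset)) seq_len(nrow(a)) else select_atoms(top, subset)
  inset <- logical(nrow(a)); inset[idx] <- TRUE

  miss <- idx[is.na(a$charge[idx]) | is.na(a$lj_rmin_half[idx]) |
                is.na(a$lj_epsilon[idx])]
  if (length(miss))
    stop("missing nonbonded parameters for atom(s): ",
         paste(utils::head(paste(a$res_name[miss], a$res_id[miss],
                                 a$name[miss]), 5), collapse = ", "))

  e_bond <- 0
  b <- top$bonds
  if (nrow(b)) {
    keep <- inset[b$i] & inset[b$j]
    if (any(keep & (is.na(b$k) | is.na(b$r0))))
      stop("missing bond parameters for a bond inside the subset")
    if (any(keep)) {
      dvec <- xyz[b$i[keep], , drop = FALSE] - xyz[b$j[keep], , drop = FALSE]
      r <- sqrt(rowSums(dvec^2))
      e_bond <- sum(b$k[keep] * (r - b$r0[keep])^2)
    }
  }

  e_angle <- 0
  an <- top$angles
  if (nrow(an)) {
    keep <- inset[an$i] & inset[an$j] & inset[an$k]
    if (any(keep & (is.na(an$l_k) | is.na(an$theta0))))
      stop("missing angle parameters for an angle inside the subset")
    if (any(keep)) {
      th <- vapply(which(keep), function(t) {
        v1 <- xyz[an$i[t], ] - xyz[an$j[t], ]
        v2 <- xyz[an$k[t], ] - xyz[an$j[t], ]
        acos(pmin(1, pmax(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
      }, numeric(1))
      e_angle <- sum(an$l_k[keep] * (th - an$theta0[keep])^2)
    }
  }

  e_dihedral <- 0
  dh <- top$dihedrals
  if (nrow(dh)) {
    keep <- inset[dh$i] & inset[dh$j] & inset[dh$k] & inset[dh$l]
    if (any(keep & (is.na(dh$pk) | is.na(dh$n) | is.na(dh$delta))))
      stop("missing dihedral parameters for a torsion inside the subset")
    if (any(keep)) {
      phi <- vapply(which(keep), function(t)
        dihedral_angle(xyz[dh$i[t], ], xyz[dh$j[t], ], xyz[dh$k[t], ],
                       xyz[dh$l[t], ]) * pi / 180, numeric(1))
      e_dihedral <- sum(dh$pk[keep] *
                          (1 + cos(dh$n[keep] * phi - dh$delta[keep])))
    }
  }

  nb <- .nonbonded_energy(xyz, top, idx)
  out <- list(e_bond = e_bond, e_angle = e_angle, e_dihedral = e_dihedral,
              e_vdw = nb$e_vdw, e_coulomb = nb$e_coulomb,
              g_gb = 0, g_sa = 0)
  out$total <- out$e_bond + out$e_angle + out$e_dihedral + out$e_vdw +
    out$e_coulomb
  class(out) <- "EnergyDecomposition"
  out
}

.nonbonded_energy <- function(xyz, top, idx) {
  m <- length(idx)
  if (m < 2) return(list(e_vdw = 0, e_coulomb = 0))
  a <- top$atoms
  x <- xyz[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(x))
  pos <- match(seq_len(nrow(a)), idx)  # global -> subset position

  w_ee <- matrix(0, m, m); w_ee[upper.tri(w_ee)] <- 1
  w_lj <- w_ee
  mark <- function(pairs, vee, vlj) {
    if (!nrow(pairs)) return(invisible(NULL))
    pi_ <- pos[pairs[, 1]]; pj <- pos[pairs[, 2]]
    keep <- !is.na(pi_) & !is.na(pj)
    if (!any(keep)) return(invisible(NULL))
    lo <- pmin(pi_[keep], pj[keep]); hi <- pmax(pi_[keep], pj[keep])
    w_ee[cbind(lo, hi)] <<- vee
    w_lj[cbind(lo, hi)] <<- vlj
    invisible(NULL)
  }
  mark(top$excl12_13, 0, 0)
  mark(top$pairs14, 1 / .SCEE, 1 / .SCNB)

  if (any(d[upper.tri(d)] < 1e-8 & w_ee[upper.tri(w_ee)] > 0))
    stop("coincident atoms in a nonbonded pair")
  q <- a$charge[idx]
  qq <- outer(q, q)
  eps <- sqrt(outer(a$lj_epsilon[idx], a$lj_epsilon[idx]))
  rmin <- outer(a$lj_rmin_half[idx], a$lj_rmin_half[idx], "+")
  dd <- d; dd[dd == 0] <- Inf
  sr6 <- (rmin / dd)^6
  list(e_vdw = sum(w_lj * eps * (sr6^2 - 2 * sr6)),
       e_coulomb = sum(w_ee * KE_COULOMB * qq / dd))
}

#' @export
print.EnergyDecomposition <- function(x, ...) {
  cat(sprintf(paste0("EnergyDecomposition (kcal/mol): bond %.3f  angle %.3f",
                     "  dihedral %.3f\n  vdw %.3f  coulomb %.3f  GB %.3f",
                     "  SA %.3f  total %.3f\n"),
              x$e_bond, x$e_angle, x$e_dihedral, x$e_vdw, x$e_coulomb,
              x$g_gb, x$g_sa, x$total))
  invisible(x)
}
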