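#' Interfacial atom contacts in a single frame
#'
#' Returns every atom pair (one atom from each group) whose Euclidean
#' distance is strictly below `cutoff` ("closer than"). The default
#' cell-list finder bins atoms into cubic cells with edge >= cutoff and only
#' examines the 27 neighbouring cells of each occupied cell; it is
#' guaranteed (and property-tested) to return exactly the brute-force
#' all-pairs result.
#'
#' @param coords n_atoms x 3 coordinate matrix (Angstrom).
#' @param group_a,group_b disjoint, non-empty integer vectors of atom
#'   indices.
#' @param cutoff Angstrom, must be > 0.
#' @param method `"cell"` (default) or `"brute"`.
#' @return integer matrix with columns `i` (from `group_a`), `j` (from
#'   `group_b`) and a numeric `dist` attribute of matching length, ordered
#'   by `i` then `j`.
#' @export
atom_contacts_frame <- function(coords, group_a, group_b, cutoff,
                                method = c("cell", "brute")) {
  method <- match.arg(method)
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (!length(group_a) || !length(group_b)) stop("empty atom group")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  res <- if (method == "brute")
    .contacts_brute(coords, group_a, group_b, cutoff)
  else .contacts_cell(coords, group_a, group_b, cutoff)
  ord <- order(res$pairs[, 1], res$pairs[, 2])
  out <- res$pairs[ord, , drop = FALSE]
  colnames(out) <- c("i", "j")
  attr(out, "dist") <- res$dist[ord]
  out
}

.contacts_brute <- function(coords, ga, gb, cutoff) {
  xa <- coords[ga, , drop = FALSE]
  xb <- coords[gb, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  list(pairs = cbind(ga[hit[, 1]], gb[hit[, 2]]),
       dist = sqrt(pmax(d2[hit], 0)))
}

.contacts_cell <- function(coords, ga, gb, cutoff) {
  xa <- coords[ga, , drop = FALSE]
  xb <- coords[gb, , drop = FALSE]
  orig <- pmin(apply(xa, 2, min), apply(xb, 2, min))
  ca <- floor(sweep(xa, 2, orig) / cutoff)
  cb <- floor(sweep(xb, 2, orig) / cutoff)
  m <- max(ca, cb) + 3
  enc <- function(cells) (cells[, 1] + 1) + (cells[, 2] + 1) * m +
    (cells[, 3] + 1) * m * m
  key_a <- enc(ca)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nrow(cb)
  rep_b <- rep(seq_len(nb), each = 27)
  cb_exp <- cb[rep_b, , drop = FALSE] + offs[rep.int(seq_len(27), nb), ]
  key_b <- enc(cb_exp)
  map_b <- split(rep_b, key_b)
  by_a <- split(seq_along(ga), key_a)
  common <- intersect(names(by_a), names(map_b))
  pi_ <- list(); pj <- list(); pd <- list(); nkept <- 0L
  for (k in common) {
    ii <- by_a[[k]]; jj <- map_b[[k]]
    d2 <- outer(rowSums(xa[ii, , drop = FALSE]^2),
                rowSums(xb[jj, , drop = FALSE]^2), "+") -
      2 * tcrossprod(xa[ii, , drop = FALSE], xb[jj, , drop = FALSE])
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      nkept <- nkept + 1L
      pi_[[nkept]] <- ii[hit[, 1]]
      pj[[nkept]] <- jj[hit[, 2]]
      pd[[nkept]] <- sqrt(pmax(d2[hit], 0))
    }
  }
  if (!nkept)
    return(list(pairs = matrix(integer(0), 0, 2), dist = numeric(0)))
  list(pairs = cbind(ga[unlist(pi_)], gb[unlist(pj)]), dist = unlist(pd))
}

#' Residue-pair contact occupancy over a trajectory
#'
#' A residue pair (one residue from each partition) is "in contact" in a
#' frame when at least one atom of one residue approaches at least one atom
#' of the other closer than `config$contact_cutoff`. The occupancy of a pair
#' is the exact fraction of frames in contact. The full table reports every
#' pair observed in at least one frame; the retained set keeps pairs whose
#' occupancy strictly exceeds `config$occupancy_threshold` (more than 50%
#' of the simulation, by default).
#'
#' @param traj a `Trajectory`.
#' @param top the matching `Topology` with partitions `partition_a` and
#'   `partition_b` defined.
#' @param config an [analysis_config()].
#' @param partition_a,partition_b partition names (default `"receptor"`,
#'   `"gprotein"`).
#' @param frames optional integer vector restricting the analysis window.
#' @return an object of class `InterfaceTable`: list with `pairs` (retained
#'   pairs), `all_pairs` (pre-filter table), `residues` (per-residue degree
#'   and tier among retained pairs), `n_frames`, and the config used.
#' @export
residue_contact_occupancy <- function(traj, top, config = analysis_config(),
                                      partition_a = "receptor",
                                      partition_b = "gprotein",
                                      frames = NULL) {
  if (traj$n_frames < 1) stop("empty trajectory")
  ga <- top$partitions[[partition_a]]
  gb <- top$partitions[[partition_b]]
  if (is.null(ga) || is.null(gb))
    stop("partitions '", partition_a, "' and '", partition_b,
         "' must be defined")
  if (!isTRUE(config$include_hydrogens)) {
    hyd <- which(toupper(top$atoms$element) == "H")
    ga <- setdiff(ga, hyd); gb <- setdiff(gb, hyd)
  }
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  if (!length(frames)) stop("empty trajectory window")

  rt <- residue_table(top)
  res_of_atom <- .atom_to_residue(top, rt)
  counts <- new.env(parent = emptyenv())
  dsums <- new.env(parent = emptyenv())
  for (f in frames) {
    pr <- atom_contacts_frame(frame_coords(traj, f), ga, gb,
                              config$contact_cutoff)
    if (!nrow(pr)) next
    ra <- res_of_atom[pr[, 1]]
    rb <- res_of_atom[pr[, 2]]
    d <- attr(pr, "dist")
    key <- paste(ra, rb, sep = ":")
    mind <- tapply(d, key, min)
    for (k in names(mind)) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
      dsums[[k]] <- (if (is.null(dsums[[k]])) 0 else dsums[[k]]) + mind[[k]]
    }
  }
  keys <- ls(counts)
  n_total <- length(frames)
  if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
    ia <- as.integer(parts[, 1]); ib <- as.integer(parts[, 2])
    cnt <- vapply(keys, function(k) counts[[k]], integer(1))
    all_pairs <- data.frame(
      chain_a = rt$chain_id[ia], res_id_a = rt$res_id[ia],
      res_name_a = rt$res_name[ia], generic_a = rt$generic[ia],
      chain_b = rt$chain_id[ib], res_id_b = rt$res_id[ib],
      res_name_b = rt$res_name[ib], generic_b = rt$generic[ib],
      res_index_a = ia, res_index_b = ib,
      contact_frames = cnt, total_frames = n_total,
      occupancy = cnt / n_total,
      mean_min_distance = vapply(keys, function(k) dsums[[k]],
                                 numeric(1)) / cnt,
      ionic = FALSE, hbond = FALSE,
      stringsAsFactors = FALSE)
    ord <- order(all_pairs$chain_a, all_pairs$res_id_a, all_pairs$chain_b,
                 all_pairs$res_id_b)
    all_pairs <- all_pairs[ord, , drop = FALSE]
    rownames(all_pairs) <- NULL
  } else {
    all_pairs <- .empty_pair_table(n_total)
  }
  retained <- all_pairs[all_pairs$occupancy > config$occupancy_threshold, ,
                        drop = FALSE]
  rownames(retained) <- NULL
  tab <- structure(list(pairs = retained, all_pairs = all_pairs,
                        residues = NULL, n_frames = n_total,
                        partition_a = partition_a, partition_b = partition_b,
                        config = config, topology = top),
                   class = "InterfaceTable")
  tab$residues <- classify_contact_degree(tab)
  tab
}

.atom_to_residue <- function(top, rt = residue_table(top)) {
  key <- paste(top$atoms$chain_id, top$atoms$res_id, sep = "|")
  match(key, paste(rt$chain_id, rt$res_id, sep = "|"))
}

.empty_pair_table <- function(n_total) {
  data.frame(chain_a = character(0), res_id_a = integer(0),
             res_name_a = character(0), generic_a = character(0),
             chain_b = character(0), res_id_b = integer(0),
             res_name_b = character(0), generic_b = character(0),
             res_index_a = integer(0), res_index_b = integer(0),
             contact_frames = integer(0), total_frames = integer(0),
             occupancy = numeric(0), mean_min_distance = numeric(0),
             ionic = logical(0), hbond = logical(0),
             stringsAsFactors = FALSE)
}

#' Map a contact degree to its tier
#'
#' 0 partners: `none`; 1-2: `low`; 3-4: `mid`; 5 or more: `high` (the
#' yellow/green/blue colouring scheme of interface alignments).
#' @param degree integer vector of distinct-partner counts.
#' @return character vector of tiers.
#' @export
contact_tier <- function(degree) {
  if (any(degree < 0)) stop("negative contact degree")
  cut(degree, breaks = c(-0.5, 0.5, 2.5, 4.5, Inf),
      labels = c("none", "low", "mid", "high")) |> as.character()
}

#' Per-residue contact degree and tier
#'
#' The degree of a residue is the number of distinct partner residues among
#' the retained (post-threshold) pairs; the tier is a pure function of the
#' degree via [contact_tier()].
#' @param table an `InterfaceTable`.
#' @return data frame: residue identity, `side` (`"a"` or `"b"`), `degree`,
#'   `tier`.
#' @export
classify_contact_degree <- function(table) {
  p <- table$pairs
  mk <- function(side) {
    if (side == "a") {
      key <- paste(p$chain_a, p$res_id_a); partner <- paste(p$chain_b, p$res_id_b)
      meta <- p[c("chain_a", "res_id_a", "res_name_a", "generic_a")]
    } else {
      key <- paste(p$chain_b, p$res_id_b); partner <- paste(p$chain_a, p$res_id_a)
      meta <- p[c("chain_b", "res_id_b", "res_name_b", "generic_b")]
    }
    names(meta) <- c("chain_id", "res_id", "res_name", "generic")
    if (!nrow(p))
      return(cbind(meta[0, ], side = character(0), degree = integer(0),
                   tier = character(0)))
    first <- !duplicated(key)
    deg <- vapply(split(partner, key), function(z) length(unique(z)),
                  integer(1))
    out <- meta[first, , drop = FALSE]
    out$side <- side
    out$degree <- unname(deg[key[first]])
    out$tier <- contact_tier(out$degree)
    out
  }
  out <- rbind(mk("a"), mk("b"))
  ord <- order(out$side, out$chain_id, out$res_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.InterfaceTable <- function(x, ...) {
  cat("InterfaceTable:", nrow(x$all_pairs), "observed pairs,",
      nrow(x$pairs), "retained (occupancy >",
      x$config$occupancy_threshold, "over", x$n_frames, "frames)\n")
  if (nrow(x$pairs)) {
    p <- x$pairs
    lab <- paste0(residue_label(p$res_name_a, p$res_id_a, p$generic_a), " -- ",
                  residue_label(p$res_name_b, p$res_id_b, p$generic_b),
                  sprintf("  %5.1f%%", 100 * p$occupancy),
                  ifelse(p$ionic, " [ionic]", ""),
                  ifelse(p$hbond, " [hbond]", ""))
    cat(paste0("  ", utils::head(lab, 20), collapse = "\n"), "\n")
    if (nrow(p) > 20) cat("  ...\n")
  }
  invisible(x)
}

# Side-chain group atoms recognised by the salt-bridge rule.
.BASIC_ATOMS <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                     HIS = c("ND1", "NE2"))
.ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Flag ionic and hydrogen-bond interactions on retained pairs
#'
#' A pair is flagged `ionic` when a basic-group atom (Arg NH1/NH2/NE, Lys
#' NZ, His ND1/NE2 only if that histidine is listed as protonated in the
#' config) and an acidic-group atom (Asp OD1/OD2, Glu OE1/OE2, or any
#' C-terminal OXT) lie within `config$saltbridge_cutoff` in more than
#' `config$occupancy_threshold` of the frames. The `hbond` flag uses the
#' donor-acceptor heavy-atom criterion `config$hbond_cutoff`, and when the
#' donor carries explicit hydrogens additionally requires a
#' donor-H...acceptor angle above `config$hbond_angle_min` degrees.
#'
#' @param traj a `Trajectory`.
#' @param top the matching `Topology`.
#' @param table an `InterfaceTable` from [residue_contact_occupancy()].
#' @param config an [analysis_config()].
#' @param frames optional frame window (defaults to all frames).
#' @return the `InterfaceTable` with `ionic`/`hbond` columns filled on the
#'   retained pairs.
#' @export
annotate_interactions <- function(traj, top, table,
                                  config = table$config, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  p <- table$pairs
  if (!nrow(p)) return(table)
  rt <- residue_table(top)
  a <- top$atoms
  res_atoms <- function(ri) seq.int(rt$first_atom[ri], rt$last_atom[ri])

  charged <- function(ri, kind) {
    ids <- res_atoms(ri)
    rn <- rt$res_name[ri]
    nm <- a$name[ids]
    sel <- character(0)
    if (kind == "basic") {
      sel <- .BASIC_ATOMS[[rn]]
      if (rn == "HIS" &&
          !(paste(rt$chain_id[ri], rt$res_id[ri], sep = "|") %in%
            config$his_protonated))
        sel <- character(0)
    } else {
      sel <- c(.ACIDIC_ATOMS[[rn]], "OXT")
    }
    ids[nm %in% sel]
  }
  polar_heavy <- function(ri) {
    ids <- res_atoms(ri)
    ids[toupper(a$element[ids]) %in% c("N", "O")]
  }
  hydrogens_of <- function(heavy) {
    if (!nrow(top$bonds)) return(integer(0))
    b <- top$bonds
    h <- c(b$j[b$i == heavy], b$i[b$j == heavy])
    h[toupper(a$element[h]) == "H"]
  }

  occ_of_pairs <- function(ia, ib, cutoff, angle_check = FALSE) {
    if (!length(ia) || !length(ib)) return(0)
    hits <- 0L
    for (f in frames) {
      xyz <- frame_coords(traj, f)
      d2 <- outer(rowSums(xyz[ia, , drop = FALSE]^2),
                  rowSums(xyz[ib, , drop = FALSE]^2), "+") -
        2 * tcrossprod(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
      hit <- which(d2 < cutoff^2, arr.ind = TRUE)
      ok <- nrow(hit) > 0
      if (ok && angle_check) {
        ok <- FALSE
        for (r in seq_len(nrow(hit))) {
          don <- ia[hit[r, 1]]; acc <- ib[hit[r, 2]]
          hs <- hydrogens_of(don)
          if (!length(hs)) { ok <- TRUE; break }
          for (h in hs) {
            v1 <- xyz[don, ] - xyz[h, ]; v2 <- xyz[acc, ] - xyz[h, ]
            ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                       sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
            if (ang > config$hbond_angle_min) { ok <- TRUE; break }
          }
          if (ok) break
        }
      }
      if (ok) hits <- hits + 1L
    }
    hits / length(frames)
  }

  for (r in seq_len(nrow(p))) {
    ia <- p$res_index_a[r]; ib <- p$res_index_b[r]
    occ_ion <- max(
      occ_of_pairs(charged(ia, "basic"), charged(ib, "acidic"),
                   config$saltbridge_cutoff),
      occ_of_pairs(charged(ib, "basic"), charged(ia, "acidic"),
                   config$saltbridge_cutoff))
    p$ionic[r] <- occ_ion > config$occupancy_threshold
    occ_hb <- occ_of_pairs(polar_heavy(ia), polar_heavy(ib),
                           config$hbond_cutoff, angle_check = TRUE)
    p$hbond[r] <- occ_hb > config$occupancy_threshold
  }
  table$pairs <- p
  key_all <- paste(table$all_pairs$res_index_a, table$all_pairs$res_index_b)
  key_ret <- paste(p$res_index_a, p$res_index_b)
  m <- match(key_all, key_ret)
  table$all_pairs$ionic <- ifelse(is.na(m), FALSE, p$ionic[m])
  table$all_pairs$hbond <- ifelse(is.na(m), FALSE, p$hbond[m])
  table
}

#' Write a connection table as TSV
#'
#' One row per retained residue pair, deterministically ordered by residue
#' `a` then residue `b`. Occupancies are percentages with one decimal
#' (0.55 renders as `55.0`).
#'
#' @param table an `InterfaceTable`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_connection_table <- function(table, path) {
  p <- table$pairs
  deg <- table$residues
  dm <- match(paste("a", p$chain_a, p$res_id_a),
              paste(deg$side, deg$chain_id, deg$res_id))
  flags <- ifelse(p$ionic & p$hbond, "ionic,hbond",
                  ifelse(p$ionic, "ionic", ifelse(p$hbond, "hbond", "-")))
  out <- data.frame(
    res_a = residue_label(p$res_name_a, p$res_id_a),
    generic_a = ifelse(is.na(p$generic_a), "-", p$generic_a),
    res_b = residue_label(p$res_name_b, p$res_id_b),
    occupancy_pct = sprintf("%.1f", 100 * p$occupancy),
    mean_min_distance = sprintf("%.3f", p$mean_min_distance),
    flags = flags,
    degree_a = deg$degree[dm],
    tier_a = deg$tier[dm],
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
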