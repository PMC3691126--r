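# Shared fixtures and independent oracles, built in code at test time.

fixture_saltbridge <- function(n_frames = 3) {
  cx <- make_saltbridge_complex()
  list(cx = cx, traj = make_static_trajectory(cx, n_frames))
}

# Direct all-pairs contact search, the O(N^2) oracle.
oracle_contacts <- function(coords, ga, gb, cutoff) {
  out <- NULL
  for (i in ga) for (j in gb) {
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < cutoff)
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else
    out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# Independent single-frame Delta G: plain loops over every term, no reuse
# of the package's summation code paths beyond the per-term primitives.
oracle_frame_dg <- function(xyz, top, config) {
  ga <- top$partitions$receptor
  gb <- top$partitions$gprotein
  g_of <- function(idx) {
    a <- top$atoms
    x <- xyz[idx, , drop = FALSE]
    excl <- apply(top$excl12_13, 1, paste, collapse = "-")
    s14 <- apply(top$pairs14, 1, paste, collapse = "-")
    evdw <- 0; ecoul <- 0
    for (p in seq_along(idx)) for (q in seq_along(idx)) {
      if (p >= q) next
      i <- idx[p]; j <- idx[q]
      key <- paste(min(i, j), max(i, j), sep = "-")
      if (key %in% excl) next
      sc_ee <- if (key %in% s14) 1 / 1.2 else 1
      sc_lj <- if (key %in% s14) 1 / 2 else 1
      r <- sqrt(sum((x[p, ] - x[q, ])^2))
      rmin <- a$lj_rmin_half[i] + a$lj_rmin_half[j]
      eps <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
      evdw <- evdw + sc_lj * eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
      ecoul <- ecoul + sc_ee * 332.0636 * a$charge[i] * a$charge[j] / r
    }
    screen <- rep(0.8, length(idx))
    sfac <- c(H = 0.85, C = 0.72, N = 0.79, O = 0.85, S = 0.96)
    el <- toupper(a$element[idx])
    screen[el %in% names(sfac)] <- sfac[el[el %in% names(sfac)]]
    reff <- effective_born_radii(x, a$gb_radius[idx], screen)
    ggb <- gb_polar_energy(x, a$charge[idx], reff, config$eps_in,
                           config$eps_out)
    sas <- shrake_rupley_sasa(x, a$gb_radius[idx], config$probe_radius,
                              config$sasa_points)
    list(evdw = evdw, ecoul = ecoul, ggb = ggb,
         gsa = config$gamma * sum(sas) + config$beta)
  }
  gc_ <- g_of(sort(c(ga, gb))); gr <- g_of(ga); gg <- g_of(gb)
  (gc_$evdw - gr$evdw - gg$evdw) + (gc_$ecoul - gr$ecoul - gg$ecoul) +
    (gc_$ggb - gr$ggb - gg$ggb) + (gc_$gsa - gr$gsa - gg$gsa)
}

# 3D rotation matrix about an arbitrary axis.
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle)
  outer(a, a) * (1 - c_) + diag(3) * c_ +
    matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3) * s
}

write_fasta_alignment <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# A complete file-driven pipeline configuration over the salt-bridge study.
pipeline_fixture <- function(dir, outdir = file.path(dir, "out"),
                             analysis = list()) {
  cx <- make_saltbridge_complex()
  traj <- make_static_trajectory(cx, 3)
  files <- write_simulation_bundle(cx, traj, dir)
  aln <- file.path(dir, "receptors.fasta")
  write_fasta_alignment(c("recA", "recB"), c("AAKALA", "AARLLA"), aln)
  map <- file.path(dir, "generic.tsv")
  utils::write.table(data.frame(chain_id = "R", res_id = 3L,
                                generic = "5.71"),
                     map, sep = "\t", quote = FALSE, row.names = FALSE)
  list(structure = files$structure, trajectory = files$trajectory,
       parameters = files$parameters, generic_map = map,
       trajectory_dt = 500,
       analysis = c(analysis, list(sasa_points = 240)),
       alignment = list(path = aln, format = "fasta",
                        receptor_id = "recA", partner_id = "recB",
                        offset = 0),
       outdir = outdir, seed = 11)
}
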