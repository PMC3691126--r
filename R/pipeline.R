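#' Validate and normalise a pipeline configuration
#'
#' The configuration is a named list (or a path to a JSON file) with
#' entries: `structure` (PDB), `trajectory` (multi-model PDB),
#' `parameters` (JSON), optional `generic_map` (TSV), optional `alignment`
#' (list: `path`, `format`, `receptor_id`, `offset`, `partner_id`),
#' `partitions` (list mapping `receptor`/`gprotein` to chain ids),
#' `analysis` (overrides for [analysis_config()] fields), `window`
#' (`"stable"`, `"all"`, or `c(start, end)`), `stable_tolerance`
#' (Angstrom), `scan_residues` (`"auto"` or a data frame), `trajectory_dt`
#' (ps), `outdir`, and `seed`. All referenced paths must exist before any
#' computation starts.
#'
#' @param config list or JSON path.
#' @return validated config of class `PipelineConfig`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  defaults <- list(generic_map = NULL, alignment = NULL,
                   partitions = list(receptor = "R", gprotein = "G"),
                   analysis = list(), window = "all",
                   stable_tolerance = 0.5, scan_residues = "auto",
                   trajectory_dt = 100, seed = 1L)
  for (f in names(defaults))
    if (is.null(config[[f]])) config[[f]] <- defaults[[f]]
  for (f in c("structure", "trajectory", "parameters", "outdir"))
    if (is.null(config[[f]])) stop("pipeline config lacks '", f, "'")
  paths <- c(config$structure, config$trajectory, config$parameters,
             config$generic_map, config$alignment$path)
  missing_ <- paths[!file.exists(paths)]
  if (length(missing_))
    stop("pipeline config references missing file(s): ",
         paste(missing_, collapse = ", "))
  structure(config, class = "PipelineConfig")
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(Sys.time() - t0, units = "secs")))
  out
}

#' Run the full interface-analysis pipeline
#'
#' Reproduces the analysis chain end to end: contact occupancy screening,
#' ionic/hydrogen-bond annotation, receptor RMSD and stable-window
#' selection, single-trajectory MM-GBSA binding free energy, computational
#' alanine scanning of the retained interface residues (minus alanines,
#' glycines and chain-terminal residues), and -- when an alignment is
#' configured -- projection onto the alignment with conservation classes
#' and the selectivity report. Outputs are a pure function of (inputs,
#' config, seed); rerunning a config reproduces every file byte for byte.
#'
#' @param config a [pipeline_config()] (or list/path coercible to one).
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(unclass(config))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outs <- list()
  cfg <- do.call(analysis_config,
                 c(config$analysis, list(seed = config$seed)))

  st <- .stage("read", {
    s <- read_structure(config$structure)
    top <- load_parameters(config$parameters, s$topology)
    if (!is.null(config$generic_map))
      top <- apply_generic_numbers(top, read_generic_number_map(
        config$generic_map))
    top$partitions <- list(
      receptor = which(top$atoms$chain_id %in% config$partitions$receptor),
      gprotein = which(top$atoms$chain_id %in% config$partitions$gprotein))
    traj <- read_trajectory(config$trajectory, top,
                            dt = config$trajectory_dt)
    list(top = top, traj = traj)
  })
  top <- st$top; traj <- st$traj

  table <- .stage("contacts", {
    tab <- residue_contact_occupancy(traj, top, cfg)
    annotate_interactions(traj, top, tab, cfg)
  })
  outs$connection_table <- file.path(config$outdir, "connection_table.tsv")
  write_connection_table(table, outs$connection_table)

  geom <- .stage("geometry", {
    ca <- which(top$atoms$name == "CA" &
                  seq_len(nrow(top$atoms)) %in% top$partitions$receptor)
    if (!length(ca)) ca <- top$partitions$receptor
    rmsd_series(traj, top, ca, label = "receptor_ca_rmsd")
  })
  outs$rmsd_series <- file.path(config$outdir, "rmsd_series.tsv")
  utils::write.table(
    data.frame(time_ps = geom$times,
               rmsd = sprintf("%.4f", geom$values)),
    outs$rmsd_series, sep = "\t", quote = FALSE, row.names = FALSE)

  win <- .stage("stable_window", {
    if (identical(config$window, "stable")) {
      w <- select_stable_window(geom, config$stable_tolerance)
      if (!w$found) stop("no stable window found at tolerance ",
                         config$stable_tolerance)
      w
    } else if (is.numeric(config$window) && length(config$window) == 2) {
      list(found = TRUE, start = config$window[1], end = config$window[2],
           start_time = traj$times[config$window[1]],
           end_time = traj$times[config$window[2]])
    } else {
      list(found = TRUE, start = 1L, end = traj$n_frames,
           start_time = traj$times[1], end_time = traj$times[traj$n_frames])
    }
  })
  outs$stable_window <- file.path(config$outdir, "stable_window.tsv")
  utils::write.table(
    data.frame(start_frame = win$start, end_frame = win$end,
               start_time_ps = win$start_time, end_time_ps = win$end_time),
    outs$stable_window, sep = "\t", quote = FALSE, row.names = FALSE)
  window <- c(win$start, win$end)

  dg <- .stage("binding_energy",
               binding_free_energy(traj, top, cfg, window))
  outs$binding_energy <- file.path(config$outdir, "binding_energy.tsv")
  comp <- dg$components
  for (cn in setdiff(names(comp), c("frame")))
    comp[[cn]] <- sprintf("%.4f", comp[[cn]])
  utils::write.table(comp, outs$binding_energy, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outs$dg_summary <- file.path(config$outdir, "dg_summary.tsv")
  utils::write.table(
    data.frame(mean_dg = sprintf("%.4f", dg$mean),
               sd_dg = sprintf("%.4f", dg$sd),
               slope_kcal_per_ns = sprintf("%.6f", dg$trend$slope),
               n_snapshots = length(dg$dg)),
    outs$dg_summary, sep = "\t", quote = FALSE, row.names = FALSE)

  scan <- .stage("alanine_scan", {
    residues <- config$scan_residues
    if (identical(residues, "auto"))
      residues <- scan_candidates(table, top)
    if (is.null(residues) || !nrow(as.data.frame(residues))) NULL
    else alanine_scan(traj, top, as.data.frame(residues), cfg, window)
  })
  outs$alascan <- file.path(config$outdir, "alascan.tsv")
  if (!is.null(scan)) write_alascan_table(scan, outs$alascan)
  else writeLines(paste("residue", "generic", "ddG_mean", "ddG_sd",
                        "n_frames", "report", sep = "\t"), outs$alascan)

  if (!is.null(config$alignment)) {
    sel <- .stage("selectivity", {
      al <- config$alignment
      aln <- read_alignment(al$path, al$format %||% "fasta")
      offset <- al$offset %||% 0
      mapped <- map_interface_to_alignment(table, aln, al$receptor_id,
                                           side = "a", offset = offset)
      partner <- al$partner_id %||% setdiff(aln$ids, al$receptor_id)[1]
      cmp <- compare_complexes(mapped, .empty_interface_map(), aln,
                               al$receptor_id, partner)
      selectivity_report(cmp, mapped, .empty_interface_map(),
                         scan_a = scan, scan_b = NULL)
    })
    outs$selectivity_report <- file.path(config$outdir,
                                         "selectivity_report.tsv")
    utils::write.table(sel, outs$selectivity_report, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  outs$manifest <- file.path(config$outdir, "manifest.json")
  manifest <- list(
    package = "ternint",
    version = as.character(utils::packageVersion("ternint")),
    seed = config$seed,
    gb_variant = "HCT pairwise descreening + OBC-II rescaling (alpha 1.0, beta 0.8, gamma 4.85), offset 0.09 A",
    config = unclass(config),
    analysis = unclass(cfg),
    outputs = lapply(outs, basename))
  jsonlite::write_json(manifest, outs$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(outs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.empty_interface_map <- function() {
  data.frame(chain_id = character(0), res_id = integer(0),
             res_name = character(0), generic = character(0),
             column = integer(0), aligned_aa = character(0),
             degree = integer(0), tier = character(0),
             ionic = logical(0), hbond = logical(0),
             stringsAsFactors = FALSE)
}

#' Default alanine-scanning residue set
#'
#' The retained interface residues of both partitions, excluding alanines,
#' glycines and chain-terminal residues (which cannot be scanned).
#' @param table an `InterfaceTable`.
#' @param top the matching `Topology`.
#' @return data frame `chain_id`, `res_id`, `res_name`.
#' @export
scan_candidates <- function(table, top) {
  deg <- table$residues
  if (!nrow(deg)) return(deg[c("chain_id", "res_id", "res_name")])
  rt <- residue_table(top)
  keep <- !(deg$res_name %in% c("ALA", "GLY"))
  for (r in seq_len(nrow(deg))) {
    same <- rt$res_id[rt$chain_id == deg$chain_id[r]]
    if (deg$res_id[r] == min(same) || deg$res_id[r] == max(same))
      keep[r] <- FALSE
  }
  out <- deg[keep, c("chain_id", "res_id", "res_name")]
  out <- out[!duplicated(paste(out$chain_id, out$res_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the synthetic study bundle to disk
#'
#' Emits the files a file-driven pipeline run consumes -- structure PDB,
#' multi-model trajectory PDB, parameter JSON, generic-number map and a
#' ground-truth manifest -- for a generated complex and trajectory.
#'
#' @param complex output of [make_two_chain_complex()] (or the salt-bridge
#'   generator).
#' @param traj a `Trajectory` for the complex.
#' @param dir output directory (created).
#' @param ground_truth optional data frame recorded as
#'   `ground_truth.tsv`.
#' @return named list of file paths, invisibly.
#' @export
write_simulation_bundle <- function(complex, traj, dir,
                                    ground_truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(structure = file.path(dir, "complex.pdb"),
              trajectory = file.path(dir, "trajectory.pdb"),
              parameters = file.path(dir, "parameters.json"))
  write_structure(complex$topology, complex$coords, out$structure)
  write_trajectory(traj, complex$topology, out$trajectory)
  entries <- synthetic_parameter_entries()
  write_parameters(list(atoms = entries), out$parameters)
  if (!is.null(ground_truth)) {
    out$ground_truth <- file.path(dir, "ground_truth.tsv")
    utils::write.table(ground_truth, out$ground_truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
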