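#' Analysis configuration
#'
#' Central knobs of the analysis chain, with the defaults used throughout:
#' residue pairs are in contact when any atom pair is closer than
#' `contact_cutoff` (strict `<`), and a pair is retained when its contact
#' occupancy exceeds `occupancy_threshold` (strict `>`). Energetic snapshots
#' are taken every `snapshot_stride` ps. The generalized-Born term uses
#' `eps_in`/`eps_out`; the nonpolar term is `gamma * SASA + beta` with the
#' SASA probe radius `probe_radius`.
#'
#' @param contact_cutoff Angstrom; default 3.5.
#' @param occupancy_threshold fraction in `[0, 1)`; default 0.5.
#' @param snapshot_stride ps; default 500.
#' @param probe_radius Angstrom; default 1.4.
#' @param eps_in,eps_out interior/solvent dielectric constants (1.0, 78.5).
#' @param gamma kcal/mol/A^2; default 0.0072.
#' @param beta kcal/mol; default 0.
#' @param saltbridge_cutoff Angstrom, charged-group heavy-atom criterion;
#'   default 4.0.
#' @param hbond_cutoff Angstrom, donor-acceptor heavy-atom criterion;
#'   default 3.5.
#' @param hbond_angle_min degrees, minimum donor-H...acceptor angle applied
#'   when hydrogens are present; default 120.
#' @param include_hydrogens logical; whether hydrogens participate in the
#'   contact criterion (default TRUE: all atoms count).
#' @param his_protonated character vector of `"chain|res_id"` keys for
#'   histidines to treat as protonated (basic); default none.
#' @param sasa_points points per atom for the deterministic Shrake-Rupley
#'   lattice; default 960.
#' @param seed integer seed recorded into run manifests.
#' @return object of class `AnalysisConfig` (a named list).
#' @export
analysis_config <- function(contact_cutoff = 3.5, occupancy_threshold = 0.5,
                            snapshot_stride = 500, probe_radius = 1.4,
                            eps_in = 1.0, eps_out = 78.5,
                            gamma = 0.0072, beta = 0.0,
                            saltbridge_cutoff = 4.0, hbond_cutoff = 3.5,
                            hbond_angle_min = 120,
                            include_hydrogens = TRUE,
                            his_protonated = character(0),
                            sasa_points = 960, seed = 1L) {
  if (contact_cutoff <= 0) stop("contact_cutoff must be > 0")
  if (occupancy_threshold < 0 || occupancy_threshold >= 1)
    stop("occupancy_threshold must be in [0, 1)")
  if (snapshot_stride <= 0) stop("snapshot_stride must be > 0")
  if (eps_out <= eps_in) stop("eps_out must exceed eps_in")
  structure(list(contact_cutoff = contact_cutoff,
                 occupancy_threshold = occupancy_threshold,
                 snapshot_stride = snapshot_stride,
                 probe_radius = probe_radius,
                 eps_in = eps_in, eps_out = eps_out,
                 gamma = gamma, beta = beta,
                 saltbridge_cutoff = saltbridge_cutoff,
                 hbond_cutoff = hbond_cutoff,
                 hbond_angle_min = hbond_angle_min,
                 include_hydrogens = include_hydrogens,
                 his_protonated = his_protonated,
                 sasa_points = sasa_points,
                 seed = as.integer(seed)),
            class = "AnalysisConfig")
}

#' @export
print.AnalysisConfig <- function(x, ...) {
  cat("AnalysisConfig: cutoff", x$contact_cutoff, "A (strict <),",
      "occupancy threshold", x$occupancy_threshold, "(strict >),",
      "stride", x$snapshot_stride, "ps\n")
  cat("  GB eps", x$eps_in, "->", x$eps_out,
      "; nonpolar gamma", x$gamma, "kcal/mol/A^2, beta", x$beta, "\n")
  invisible(x)
}
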