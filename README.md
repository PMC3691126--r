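# ternint — interface analysis of ternary GPCR–G-protein complexes

`ternint` is an R toolkit for the post-simulation analysis of
protein–protein interfaces in ternary agonist–receptor–G-protein
complexes. Given a structure, a trajectory and per-atom parameters, it
answers the questions a coupling-selectivity study asks of its
simulations:

* **Which residues form the interface?** A residue pair is "in contact"
  in a frame when any atom of one residue approaches any atom of the
  other closer than 3.5 Å, and a pair belongs to the interface when that
  happens in more than 50 % of the frames (both criteria strict, and both
  configurable). Residues are tiered by their number of distinct
  partners — 1–2 (*low*), 3–4 (*mid*), ≥ 5 (*high*) — and pairs are
  flagged as ionic (salt-bridge charged-group distance < 4.0 Å) or
  hydrogen-bonded (donor–acceptor heavy-atom distance < 3.5 Å, with an
  angle term when hydrogens are present).
* **Is the complex conformationally and energetically stable?**
  Superposition-based RMSD/RMSF series (Kabsch fits, both the
  fit-on-itself and fit-on-the-partner conventions), side-chain dihedral
  series with rotamer-state occupancies, distance series, and automatic
  selection of the longest conformationally stable window of an RMSD
  trace.
* **Which residues hold the interface together?** A single-trajectory
  MM-GBSA engine built from first principles:

  ΔG = [E_vdW + E_coul + G_GB + G_SA]_complex − [·]_receptor − [·]_G-protein

  with Coulomb and 12-6 Lennard-Jones terms under ff99SB-style 1-4
  scaling, a generalized-Born polar term (Hawkins–Cramer–Truhlar
  pairwise descreening with OBC-II rescaling, ε_in = 1, ε_out = 78.5)
  and a nonpolar term γ·SASA from a deterministic Shrake–Rupley surface.
  Computational alanine scanning truncates each interface side chain at
  Cβ and reports frame-matched ΔΔG = ΔG_mutant − ΔG_wild-type, so a
  positive value marks a stabilising (hot-spot) residue. Alanines,
  glycines and chain-terminal residues are excluded.
* **Which interface residues determine selectivity?** Interface tables
  from two homologous complexes are projected onto a multiple sequence
  alignment; columns are classified *identical* / *similar* (by default
  only the Arg/Lys group) / *different* / *not applicable*, and interface
  columns that differ between the two references are nominated as
  selectivity candidates.

Because real microsecond trajectories are too large to ship, the package
includes seeded generators of synthetic two-chain complexes and
trajectories with exact ground truth — designed per-pair contact
occupancies, designed salt bridges, dihedral series with exact state
fractions, and charged spheres with closed-form Born energies — so every
stage of the pipeline can be verified end to end.

## Worked example

```r
library(ternint)

cx   <- make_saltbridge_complex()          # LYS...GLU bridge + vdW contacts
traj <- make_static_trajectory(cx, n_frames = 5)
cfg  <- analysis_config()                  # 3.5 A, >50 %, 500 ps stride

tab <- residue_contact_occupancy(traj, cx$topology, cfg)
tab <- annotate_interactions(traj, cx$topology, tab, cfg)
tab
#> InterfaceTable: 3 observed pairs, 3 retained (occupancy > 0.5 over 5 frames)
#>   A2 -- A2  100.0%
#>   K3 -- E3  100.0% [ionic] [hbond]
#>   A4 -- A4  100.0%

binding_free_energy(traj, cx$topology, cfg)
#> Binding free energy (MM-GBSA, single trajectory): -4.84 +/- 0.00 kcal/mol over 5 snapshots
#>   trend: +0.0000 kcal/mol per ns

alanine_scan(traj, cx$topology, scan_candidates(tab, cx$topology), cfg)
#> Computational alanine scan (ddG = dG_mutant - dG_wildtype):
#>   K3               4.00 +/- 0.00 kcal/mol (n = 5)
#>   E3               3.93 +/- 0.00 kcal/mol (n = 5)
```

The interface screen finds the designed salt bridge (and flags it
ionic), the complex binds with a negative mean ΔG, and the scan
identifies both charged partners as hot spots (ΔΔG ≈ +4 kcal/mol each)
while the spectator alanine contacts are excluded by the Ala/Gly rule.

`run_pipeline()` chains every stage (contacts → annotation → RMSD →
stable window → ΔG → alanine scan → alignment projection) from a single
JSON config and writes TSV tables plus a run manifest;
`inst/cli/ternary-interface` exposes the same stages as shell
subcommands.

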