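---
title: "Methods: contact mapping, MM-GBSA alanine scanning and selectivity analysis"
author: "ternint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact mapping, MM-GBSA alanine scanning and selectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternint)
```

`ternint` post-processes molecular-dynamics trajectories of ternary
agonist–GPCR–G-protein complexes to locate the coupling interface,
estimate how much each residue contributes to binding, and nominate the
residues most likely to determine receptor–G-protein selectivity. This
vignette is the package's own account of the methods: the models and
their assumptions, the tunable parameters with their defaults and units,
what the synthetic study systems do and do not emulate, and the
numerical choices made where the methodology was genuinely open.

## Contact occupancy mapping

The interface screen operates on residue pairs drawn from two named atom
partitions (`receptor`, `gprotein`). A pair is *in contact in a frame*
when at least one atom of one residue lies strictly closer than
`contact_cutoff` (default 3.5 Å) to at least one atom of the other; the
pair's *occupancy* is the exact fraction of frames in contact, and the
pair enters the reported interface when its occupancy strictly exceeds
`occupancy_threshold` (default 0.5, i.e. more than half of the
simulation). Both inequalities are deliberately strict — a pair at
exactly the cutoff, or at exactly 50 % occupancy, is excluded — because
the criteria are worded as "closer than" and "more than", and a strict
reading makes the filter reproducible at the boundary. Whether hydrogen
atoms participate in the distance criterion is exposed as a
configuration switch (`include_hydrogens`, default `TRUE`); typical
heavy-atom-only fixtures are unaffected either way.

Per-frame contacts are found with a cell-list algorithm (cubic cells
with edge ≥ cutoff, 27-neighbourhood search), which is linear in atom
count per frame. Its correctness is not assumed: a property test and an
acceptance check compare it against a brute-force O(N²) search on
hundreds of random configurations, demanding exact set equality.

Each interface residue's *degree* is its number of distinct partner
residues among retained pairs, mapped onto tiers — 1–2 `low`, 3–4 `mid`,
≥ 5 `high` — mirroring the yellow/green/blue colouring convention of
interface alignments. Retained pairs are further annotated:

* **ionic** — a basic side-chain group atom (Arg NH1/NH2/NE, Lys NZ, and
  His ND1/NE2 only when that histidine is configured as protonated) and
  an acidic group atom (Asp OD1/OD2, Glu OE1/OE2, any C-terminal OXT)
  within 4.0 Å, in more than the occupancy threshold of frames. No salt
  bridge criterion is canonical; 4.0 Å between charged-group heavy atoms
  is the common structural-biology convention and is configurable
  (`saltbridge_cutoff`).
* **hbond** — donor–acceptor heavy-atom (N/O) distance below 3.5 Å, and,
  when the donor carries explicit hydrogens in the topology, a
  donor–H···acceptor angle above 120°. Without hydrogens the heavy-atom
  distance alone decides — the honest fallback for heavy-atom-only
  trajectories.

Histidine is treated as neutral by default; protonation is declared
per residue (`his_protonated`) rather than guessed. No periodic-boundary
imaging is applied: the analysis assumes whole, centred molecules, as is
the case after solvent stripping. Water-mediated contacts are out of
scope by design.

## Geometry: RMSD, RMSF, rotamers, windows

Superpositions use the Kabsch algorithm (SVD with the determinant
correction, so reflections are never returned; collinear point sets are
rejected). `rmsd_series()` fits every frame onto the reference frame
over a *fit selection* and measures RMSD over a possibly different
*measure selection*, which covers the two conventions used for
complexes: a moiety fitted on itself reports internal mobility, a moiety
measured after fitting on its partner reports relative motion. `rmsf()`
applies the same two conventions to per-atom fluctuations about the
time-mean position.

Side-chain torsions (e.g. a His C–CA–CB–CG angle) follow the standard
signed convention, validated against two independent implementations,
with angles in (−180°, 180°]. Rotamer states are circular bins between
user boundaries; the default three bins at −120°, 0°, +120° describe the
three-state behaviour typical of a χ1-like torsion. The boundaries are a
design choice — three states are observable in such analyses but no
published bin edges exist — so they are configurable, and the
classification is exhaustive by construction (every angle lands in
exactly one bin).

Energetic post-processing should run on a conformationally settled
stretch of trajectory. `select_stable_window()` formalises the usual
by-eye selection from an RMSD trace: the longest contiguous window whose
values all stay within ± `tolerance` of the window median, subject to a
minimum length, with ties resolved to the earliest window. The
median-centred rule was chosen over a mean-centred one because it is
insensitive to the brief excursions that RMSD traces show; the search is
exact (quadratic in the worst case, which is irrelevant at the frame
counts involved).

## Single-trajectory MM-GBSA

The binding free energy of each sampled frame is

$$\Delta G = G_{\mathrm{complex}} - G_{\mathrm{receptor}} -
G_{\mathrm{gprotein}},$$

with all three terms evaluated on the *same* frame (single-trajectory
protocol) and each $G$ the sum of molecular-mechanics and implicit-
solvation terms. Entropic contributions are neglected throughout.

**Molecular mechanics.** Harmonic bonds and angles, periodic cosine
dihedrals, 12-6 Lennard-Jones in the r_min/ε convention and Coulomb
electrostatics with $k_e = 332.0636$ kcal Å mol⁻¹ e⁻². 1-2 and 1-3
pairs are excluded, 1-4 pairs scaled (electrostatics ÷ 1.2, LJ ÷ 2.0,
the ff99SB convention), and no distance cutoff is applied, as is
standard in implicit solvent. Because no bond, angle or torsion spans
the two partitions — the code verifies this and refuses covalently
linked partners — the internal bonded terms cancel identically in ΔG and
are reported as exact zeros rather than as differences of large numbers.

**Polar solvation.** The generalized Born model in Still's pairwise
form, including self terms, with
$f_{GB} = \sqrt{r^2 + R_i R_j \exp(-r^2/4R_iR_j)}$. Effective radii come
from Hawkins–Cramer–Truhlar pairwise descreening (element-dependent
screening factors, dielectric offset 0.09 Å) rescaled with the OBC
type-II coefficients (α = 1.0, β = 0.8, γ = 4.85). The underlying MM-GBSA
protocol family does not pin down one GB flavour; OBC-II was chosen as
the variant that long served as the default of the standard
implementations, and the choice is recorded in every run manifest. The
descreening integral is validated against direct numerical quadrature,
the single-atom limit reproduces the Born equation to 10⁻⁶ relative
tolerance, and the Coulomb-plus-GB interaction of two unit charges
approaches the ε_out-screened Coulomb value at large separation.
Dielectric constants default to ε_in = 1.0 and ε_out = 78.5 with no salt
screening — the conventional defaults of the method.

**Nonpolar solvation.** $G_{SA} = \gamma \cdot \mathrm{SASA} + \beta$
with γ = 0.0072 kcal mol⁻¹ Å⁻² and β = 0, the historical defaults of
the MM-GBSA protocol. SASA is computed by Shrake–Rupley point counting
on a *deterministic* Fibonacci-spiral lattice (default 960 points per
atom, probe 1.4 Å, intrinsic GB radii doubling as atomic radii).
Determinism was chosen over fidelity to any legacy implementation:
identical inputs give byte-identical outputs. The cost is a small
orientation dependence of the lattice (well below 0.1 kcal/mol on the
systems tested); MM and GB terms are exactly invariant under rigid
transforms, and the test suite treats the two classes accordingly.

**Snapshots.** Frames are sampled every `snapshot_stride` ps (default
500 ps) within the analysis window; when the frame spacing cannot
realise the stride exactly, the nearest achievable spacing is used and
reported. The per-frame ΔG series is summarised as mean ± standard
deviation plus an ordinary-least-squares trend line (kcal/mol per ns), a
drift diagnostic.

## Computational alanine scanning

For each scanned residue the side chain is truncated at Cβ: atoms beyond
Cβ are removed, Cβ keeps its wild-type coordinates, and the γ heavy atom
is replaced by a hydrogen placed 1.09 Å from Cβ along the former Cβ–Cγ
direction — so mutant and wild type remain frame-matched, and

$$\Delta\Delta G = \Delta G_{\mathrm{mutant}} -
\Delta G_{\mathrm{wild\,type}}$$

is aggregated as mean ± SD over the same snapshots. Positive ΔΔG means
the wild-type side chain stabilises the complex. Alanine and glycine
residues are excluded (there is nothing to truncate), as are
chain-terminal residues (truncation would clip the backbone); these
exclusions are enforced as errors. A test hook deliberately bypasses
the alanine rejection to confirm that an alanine-"mutated" alanine
changes nothing — the ΔΔG is exactly zero, bitwise. By default the
retained atoms keep their wild-type parameters and the new hydrogen
receives standard aliphatic-hydrogen values; a full alanine parameter
table can be supplied when the force field distinguishes alanine's
backbone charges.

## Conservation and selectivity

Interface tables are projected onto a FASTA/Clustal alignment through an
explicit per-sequence numbering offset — no automatic renumbering is
attempted, because silent off-by-one mapping errors are worse than a
required argument (a warning fires when the aligned letter disagrees
with the topology residue). Per column and non-reference sequence the
class is `identical`, `similar` (both residues in one declared
similarity group; the default is the single group {Arg, Lys}, the only
similarity the underlying colouring scheme recognises), `different`, or
`not_applicable` at gaps. Histidine in ionic positions is classified by
these literal rules only. Comparing two complexes labels each interface
column `shared`/`A_only`/`B_only`, and *selectivity candidates* are
interface columns whose two reference residues differ. Growing the
similarity groups can only shrink the candidate set (a tested
invariant). The combined report joins the comparison with the alanine
scans, marks unscanned residues `n.d.`, and derives the interaction type
(`polar` when a contact carries an ionic or hydrogen-bond flag,
`hydrophobic` otherwise).

## Synthetic study systems

The generators stand in for microsecond membrane simulations that cannot
be shipped or recomputed at desk scale. They emulate the *analysis-facing
structure* of such data with exact ground truth:

* `make_two_chain_complex()` builds two facing chains of simplified
  residues (backbone + short side chain; basic and acidic types carry
  ±1 e tips) with designed residue pairs at exact tip–tip distances, all
  force-field parameters populated. The backbone zig-zags so rigid-body
  fits are never degenerate.
* `make_contact_trajectory()` realises designed per-pair occupancies
  *exactly*: `round(occupancy × n_frames)` contact frames per pair,
  chosen by a seeded permutation rather than Bernoulli draws, so
  acceptance checks can demand exact recovery instead of statistical
  agreement.
* `make_dihedral_trajectory()` allocates rotamer-state frame counts by
  largest remainder (exact fractions), with jitter bounded away from the
  bin boundaries.
* `make_charged_sphere_system()` and `make_saltbridge_complex()` provide
  the closed-form Born fixture and a minimal bound complex with one
  dominant salt bridge, two van der Waals contact pairs (so the complex
  is genuinely bound, with mean ΔG < 0), and a distal neutral residue as
  the null control of the alanine scan.

What they do **not** emulate: physical dynamics (frames are scheduled,
not propagated), solvent and membrane, realistic side-chain rotamer
coupling, or the conformational noise of real trajectories. Passing
tests therefore demonstrate that the analysis machinery implements its
stated rules and closed forms correctly — not that any particular
biological system will show particular occupancies or ΔΔG values.

## Numerical choices and limitations

* Energies in kcal/mol, lengths in Å, times in ps (trend slopes per ns);
  frames are 1-based in all user-facing output.
* Test and acceptance problem sizes — 200-frame contact trajectories,
  1000-frame rotamer series, 100 × 500-atom contact-finder comparisons,
  a ~66-atom salt-bridge complex with 3–5 snapshots — were chosen so the
  whole suite runs in well under a minute while still exercising every
  code path at meaningful scale.
* The GB flavour, dielectric constants and γ/β used by any particular
  legacy MM-GBSA study are rarely reported; numerical agreement with
  published per-residue ΔΔG values is therefore not a goal. The engine's
  contracts are the closed-form limits, the oracle equivalences and the
  sign/ordering properties documented above.
* The nonbonded sums use no cutoff and dense matrices; systems beyond a
  few thousand atoms per partition will be slow. That is acceptable for
  the package's target use (interface-sized subsystems and synthetic
  studies).
* Binary trajectory formats (DCD/XTC) are intentionally not parsed;
  multi-model PDB is the interchange dialect, with `bio3d` handling the
  records.
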