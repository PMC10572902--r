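---
title: "Protein Block analysis of nanobody ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein Block analysis of nanobody ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbflex)
```

## The problem

Camelid single-domain antibodies (VHH, nanobodies) are humanized by point
mutations in their framework regions (FRs). Whether those mutations perturb
the domain's conformational dynamics — and whether the perturbation reaches
the antigen-binding CDR loops — is a question about *ensembles* of
conformations, not single structures. `pbflex` implements the
structural-alphabet route to that question: encode every conformation of an
ensemble into Protein Blocks, and compare systems position by position
through the statistics of the resulting letter distributions.

## The Protein Block model

Protein Blocks (PBs) are 16 prototypes of local backbone conformation, each
described by eight dihedrals over five consecutive residues,

$$(\psi_{i-2},\ \varphi_{i-1},\ \psi_{i-1},\ \varphi_i,\ \psi_i,\
\varphi_{i+1},\ \psi_{i+1},\ \varphi_{i+2}),$$

centred on residue $i$. Block *m* is the α-helix core, *d* the central
β-strand; *a*–*c* are strand N-caps, *e*–*f* strand C-caps, *g*–*j* coil,
*k*–*l* helix N-caps and *n*–*p* helix C-caps. The prototype table
(`pb_reference_table()`) is embedded as constants, in degrees.

Assignment (`assign_window()`) minimises the sum of squared *wrapped*
angular differences over the eight window angles — the RMSDA criterion of
the PB literature. Whether the sum is normalised by 8 is irrelevant to the
argmin, so the raw sum is used. Ties are broken alphabetically; they have
measure zero on continuous data. A window containing any undefined dihedral
(chain terminus, missing backbone atom) is unassignable and marked `Z`;
consequently the first two and last two positions of every chain are always
`Z`, and `Z` is excluded from all frequency statistics.

## Flexibility and comparison statistics

With $f_x$ the frequency of block $x$ at a position (over assigned frames):

* $N_{eq} = \exp(-\sum_x f_x \ln f_x)$, the equivalent number of blocks,
  in $[1, 16]$, with $0 \ln 0 = 0$. Classes (`classify_flexibility()`):
  rigid at $N_{eq} = 1$ (tolerance $10^{-6}$), *low* below 2,
  *intermediate* up to 4, *flexible* above 4 — the conventional reading of
  the scale.
* $\Delta PB = \sum_x |f^{(1)}_x - f^{(2)}_x|$, an L1 distance in $[0, 2]$;
  $\Delta PB / 2$ is the total-variation distance, i.e. the fraction of PB
  occurrences that differ (0.50 ⇔ a quarter differ; 1.25 ⇔ 62.5%).
  Positions where either system is undefined propagate `NA`, never a
  silent 0.
* $\Delta N_{eq}$ is the per-position absolute $N_{eq}$ difference.
* RMSF is computed on CA atoms after least-squares superposition of every
  frame onto the ensemble-average structure (average obtained after a first
  superposition onto frame 1, then superposed once more onto that average —
  the standard convention; superposing to frame 1 instead changes values
  only marginally but the average-structure convention is adopted).
* RMSD time series superposes every frame onto the first frame, the usual
  reference for trajectory-drift plots.
* Correlations are Pearson by default (Spearman available). Optionally a
  fixed number of positions (default 3) is dropped at each terminus, where
  fraying dominates; the width is configurable because no canonical value
  exists.
* PB logos use WebLogo-style information content
  $R = \log_2 16 - H$ (bits) with letter heights $f_x R$, without
  small-sample correction — intended frame counts are in the thousands.

Reported tables round $N_{eq}$ and $\Delta PB$ to 2 decimals and RMSF to
0.1 Å; all statistics are computed in full precision.

## Structure I/O and superposition

Multi-model PDB is the canonical interchange format (binary trajectory
formats are deliberately out of scope); parsing and formatting go through
`bio3d`. Residues are renumbered sequentially from 1 — the region scheme
and all position talk use sequential numbering — with the original numbering
kept as metadata. Where alternate locations occur the highest-occupancy
conformer is kept; insertion codes are rejected outright, because the
analysis assumes exactly one conformer per residue per frame. A residue with
a missing backbone atom is kept and flagged (its dihedral windows become
`Z`), never silently dropped.

Superposition is the Kabsch SVD solution with reflections disallowed.
TM-score uses $d_0 = 1.24\,(L-15)^{1/3} - 1.8$ (clamped at 0.5 Å),
normalised by the reference length (the standard choice), and maximises
over superpositions from iterative fragment seeding: every contiguous
fragment at lengths $L$, $L/2$, $L/4$ seeds a fit that is refined by
re-superposing on the close-residue subset, then polished by iteratively
reweighted superposition ascending the TM objective.

## Region scheme and humanization audit

The built-in `default_region_map()` is the classic 121-residue VHH layout:
FR1 1–25, CDR1 26–30, FR2 31–48, CDR2 49–56, FR3 57–93, CDR3 94–109,
FR4 110–121. Any other length requires a user scheme, validated to tile
1..L contiguously in canonical order. A mutation at a region border is
assigned strictly by the map (95 → CDR3).

The audit diffs equal-length sequences (the humanization scheme introduces
substitutions only), then flags positions against two compiled tables:
humanization *hotspots* {14, 41, 44, 76, 85, 116} and camelid *hallmark*
positions {11, 34, 41, 42, 44}, the latter carried with their Kabat
equivalents (11→11, 34→37, 41→44, 42→45, 44→47). A general Kabat
renumbering engine is deliberately not provided: the mapping is only
established here for those five positions. Proposing humanization
mutations (frequency-matrix scoring) is out of scope; the module audits
given sequence pairs. The bundled 121-residue wild-type sequence
(`vhh_synthetic_sequence()`) is synthetic: only the residues at the
mutation positions of the bundled case-study sets are meaningful.

## The synthetic-ensemble generator

The generator stands in for molecular-dynamics input so the whole pipeline
runs at desk scale. Defaults mirror a 1 µs trajectory sampled every 100 ps
— 10,000 frames per system — while tests and the bundled analyses run at
150–5,000 frames; the statistical suites state their sizes explicitly
(10,000 frames for $N_{eq}$/ΔPB convergence, 5,000 for the RMSF closed
form, 1,000 for noisy prototype recovery, 400 per system in the narrative
scripts).

Per frame, one PB letter is drawn per position (i.i.d. across frames from
the position's target profile; draws are inverse-CDF coupled between paired
systems so they differ only where profiles differ, and override windows
switch coherently per frame, as a loop changing conformation as a unit).
Every 5-residue window centred on a sampled letter proposes its prototype's
eight dihedrals for the residues it covers; each residue's φ/ψ is the
circular mean of the (up to four) proposals covering it, plus independent
wrapped-Gaussian noise (default σ = 5°, comfortably inside assignment
basins). Coordinates are rebuilt by internal-coordinate (NeRF) chain
construction with N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, ω = 180° and
standard backbone angles; rebuilding reproduces the input dihedrals to
numerical precision.

Target profiles come from `profile_for_neq()`, which inverts the $N_{eq}$
formula by bisection (to $10^{-9}$) for a dominant-mass mixture over a
2–16 letter support. `vhh_template_profiles()` ships a 121-position
template: rigid β-strand frameworks, mildly variable loops, CDRs more
variable than FRs on average, the canonical *dfbdcfb* CDR1 loop at
positions 23–29, a *kbfkipm* CDR3 motif at 102–108, and exactly three
positions above $N_{eq} = 3$ (62 and 72 in FR3, 97 in CDR3). Per-region
mean $N_{eq}$ is allocated exactly (fixed peaks plus shoulder positions
rescaled per region) to the layout values FR1 1.20, CDR1 1.45, FR2 1.04,
CDR2 1.27, FR3 1.24, CDR3 1.52, FR4 1.09 — a realistic VHH flexibility
profile chosen once as the study condition.

### What the generator does and does not emulate

It reproduces *PB occupancy statistics* and valid backbone geometry — not
physics. There are no sterics, side chains or forces, and three consequences
matter when reading results:

1. **Overlapping windows blur localized differences.** A residue's angles
   average proposals from letters at positions $i-2..i+2$, so (a) a
   homogeneous run of most letters is geometrically self-contradictory —
   only the strand and helix cores *d* and *m* re-encode exactly from runs —
   and the faithful zero-noise recovery statement is per-window:
   `prototype_window_ensemble()` builds a 5-residue chain from one
   prototype's eight dihedrals, whose central residue re-encodes to that
   letter for all 16 letters, at 0° and (≥ 99%) at 5° noise; (b) an
   *isolated single-position* profile switch is attenuated below the
   encoding's resolution, while multi-position coherent switches (the
   realistic loop-change case) survive with ±2-position edge effects. ΔPB
   convergence guarantees are therefore stated on sampled PB matrices
   (`make_pair(..., coords = FALSE)`), and coordinate-path realizations are
   reported as measured.
2. **Cartesian fluctuations are uncontrolled in dihedral space.** A small
   angle change levers the entire downstream chain, so RMSF from
   dihedral-noise ensembles is large and position-dependent in a way that
   reflects chain topology, not local mobility. RMSF studies use
   `make_rmsf_ensemble()`, which jitters a fixed conformation with
   per-residue isotropic Gaussian noise of standard deviation
   $\text{RMSF}_{target}/\sqrt{3}$ per coordinate (so raw per-residue CA
   RMSF converges to the target; `vhh_template_rmsf()` provides a VHH-like
   target layout).
3. **Passing tests show statistical correctness of the pipeline**, not that
   real trajectories would show any particular biology: thermodynamics,
   autocorrelation (an optional concern — sampling is i.i.d. per frame) and
   real loop energetics are not modelled.

## Pipeline defaults

`run_comparison()` flags positions with ΔPB ≥ 0.5 — the "quarter of
occurrences differ" level — and renders PB logos for every contiguous
flagged window; the threshold is configurable. Profiles pool all frames
given for a system (replicate pooling); per-replicate analysis is a matter
of calling the statistics per replicate. Reports are deterministic under a
fixed seed and serialise as TSV/JSON; plots are optional artifacts, never
the canonical output. Run logs always record frame counts, `Z` counts, the
seed and thresholds.

## Known limitations

* mmCIF, hydrogens and side chains are out of scope; B-factors are read
  from input only, never modelled.
* The TM-score values of any particular published model pair are not
  reproducible without those models' coordinates; the implementation is
  validated against brute-force superposition oracles on synthetic toys.
* The generator's two paths control either PB statistics or RMSF, not both
  simultaneously.
* High-$N_{eq}$ mixtures (above ≈ 3) realized through coordinates re-encode
  with some blending loss; ground-truth $N_{eq}$ recovery within 0.05 is
  guaranteed at the PB-matrix level.
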