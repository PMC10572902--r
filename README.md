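# pbflex

Structural-alphabet analysis of nanobody conformational ensembles in R.

Single-domain camelid antibodies (VHH, "nanobodies") are humanized by point
mutations in their framework regions; the question this package addresses is
whether such mutations change the domain's conformational dynamics, and
where. It works at the level of conformational ensembles (multi-model PDB,
e.g. snapshots of a molecular-dynamics trajectory) and summarises local
backbone behaviour with the 16-letter **Protein Blocks** (PB) structural
alphabet: every 5-residue window, described by the eight dihedrals
ψ(i−2), φ(i−1), ψ(i−1), φ(i), ψ(i), φ(i+1), ψ(i+1), φ(i+2), is assigned the
prototype with minimal wrapped squared angular dissimilarity (block *m* ≈
α-helix core, *d* ≈ central β-strand).

Per position over the ensemble, the PB frequency profile *f* yields

- **N_eq** = exp(−Σₓ fₓ ln fₓ) — the equivalent number of blocks: 1 means one
  conformation only (local rigidity), 16 a uniform spread; below 2 counts as
  low flexibility and above 4 as flexible;
- **ΔPB** = Σₓ |fₓ¹ − fₓ²| — the L1 distance between two systems' profiles at
  a position: 0 identical, 2 disjoint; ΔPB/2 is the fraction of occurrences
  that differ (0.50 ⇔ a quarter differ, 1.25 ⇔ 62.5% differ);
- **ΔN_eq**, per-residue **RMSF**, per-frame CA **RMSD**, Pearson/Spearman
  series correlations, FR/CDR region means, and WebLogo-style PB logo stacks
  (column information content R = log2 16 − H bits).

Around the statistics sit: a multi-model PDB reader/writer and Kabsch/TM-score
superposition (`structure_io`), a 121-residue FR/CDR region scheme with a
humanization-mutation audit against hotspot and camelid-hallmark tables
(`vhh_annotation`), a synthetic-ensemble generator with prescribed per-position
PB statistics or RMSF profiles (`synthetic_ensembles`), and an end-to-end
multi-system comparison with TSV/JSON reports (`run_comparison` /
`write_report`).

## Worked example

```r
library(pbflex)

# two synthetic 121-residue ensembles: wild type, and a variant whose CDR1
# loop (positions 24-27) switches conformation in 62.5% of frames
prof <- vhh_template_profiles()
dom <- attr(prof, "dominant")[24:27]
alt <- c("e", "h", "j", "d")
ov <- t(vapply(1:4, function(i) {
  f <- setNames(rep(0, 16), PB_LETTERS)
  f[dom[i]] <- 0.375
  f[alt[i]] <- f[alt[i]] + 0.625
  f
}, numeric(16)))
pair <- make_pair(prof, list(list(positions = 24:27, profile = ov)),
                  n_frames = 150, noise = 5, seed = 7)

rep <- run_comparison(comparison_config(
  systems = list(wt = pair$first, hum = pair$second)))
rep$pairwise$`wt vs hum`$flagged_windows
#> [[1]]
#> [1] 24 25 26 27
```

Running the bundled study (from the repository root):

```sh
Rscript analysis/01_simulate.R          # systems + ground truth
Rscript analysis/02_humanization_audit.R
Rscript analysis/03_flexibility.R
Rscript analysis/04_compare.R
```

`02_humanization_audit.R` prints, among other lines:

```
sequence-guided humanization: 15 mutations (12.4% of 121 residues)
  hotspots touched: A14P, E41G, G44W, V76L, P85A, E116L
structure-guided humanization: 12 mutations (9.9% of 121 residues)
mutations unique to the sequence-guided scenario: F34V, R42L, K84R
```

i.e. the sequence-guided scenario mutates 15 of 121 residues (12.4%), six of
them at known humanization hotspots, and touches all five camelid hallmark
positions; the structure-guided scenario carries 12 of those mutations (9.9%).
`04_compare.R` reports the realized per-position ΔPB between wild type and
humanized systems — the CDR1 override window is flagged at the ΔPB ≥ 0.5
threshold with values up to ≈ 1.25 — and writes the full report (per-position
and per-region TSVs, pairwise ΔN_eq/ΔPB, PB logos of flagged windows, the
mutation audit and a run log) under `results/comparison/`.

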