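# tcrpmhc

Structural analysis of alpha-beta T-cell receptor (TCR) complexes with
peptide–MHC (pMHC) class I ligands, and 1:1 binding kinetics for the
surface plasmon resonance (SPR) experiments that accompany such
structures.

When a TCR docks onto a pMHC ligand — for example onto a mutated
self-peptide (neoantigen) presented by HLA-A2 — the questions a
structural immunologist asks are quantitative: at what crossing angle
and tilt does the receptor sit over the peptide groove, how far is its
center shifted along the peptide, which CDR loops carry the atomic
contacts to peptide versus MHC, how much peptide surface is buried, how
complementary are the two surfaces, what moved upon binding, and how
tightly does the receptor bind. `tcrpmhc` computes all of these from
coordinates and annotation, with every computation testable offline on
a built-in synthetic-structure generator.

## What it computes

* **Docking geometry.** In the groove frame (origin at the mean helix
  Cα, z normal to the helix plane, x along the peptide toward its
  C-terminus): the crossing angle ∠(proj_xy(Vα→Vβ), +x) ∈ [0°, 180°],
  the incident angle arcsin|ẑ·(Vα→Vβ)| ∈ [0°, 90°], and the TCR-center
  projection (x_pos, y_pos). V-domain centers are means of the
  conserved-disulfide Sγ atoms (Cα fallback). Descriptors can be ranked
  against a survey table with percentile = round(100·(1 − rank/N)).
* **Interface contacts.** Non-hydrogen atom pairs at ≤ 4.0 Å, bucketed
  per CDR1/CDR2/HV4/CDR3 loop of each chain (plus a visible framework
  bucket) against peptide and MHC heavy chain; integer percentage
  tables and per-chain shares; a distance-only hydrogen-bond flag
  (donor N/O/S to acceptor N/O at ≤ 3.5 Å).
* **Surfaces.** Shrake–Rupley solvent-accessible surface areas
  (probe 1.4 Å, deterministic 960-point lattice), buried peptide
  surface ΔSASA and fraction, and the Lawrence–Colman shape
  complementarity Sc = mean of the two directional medians of
  −(n·n′)·exp(−w·d²), w = 0.5 Å⁻², on accessible dot surfaces.
* **Superposition.** Kabsch (SVD, proper rotations only), with
  separate fit-on and measure-on selections and per-residue
  displacement profiles.
* **1:1 SPR kinetics.** Closed-form Langmuir model
  R(t) = R_eq(1 − e^(−(k_on·C + k_off)·t)), R_eq = R_max·C/(C + K_D),
  K_D = k_off/k_on; steady-state K_D fits and global kinetic
  k_on/k_off fits with a resolvability flag for too-fast kinetics.
* **Synthetic structures.** Annotated toy complexes with prescribed
  docking geometry (exact to 1e-6) and per-loop contact layouts
  (verified by exhaustive enumeration), plus dot-surface fixtures with
  closed-form Sc.

## Worked example

Build a toy complex docked at a 51° crossing angle and 20° tilt, its
center 3 Å toward the peptide C-terminus, with a planted contact
layout (3 CDR3α–peptide and 61 CDR3β–peptide contacts), then analyze
it:

```r
library(tcrpmhc)

cx <- make_toy_tcr_pmhc(toy_complex_spec(
  crossing_angle = 51, incident_angle = 20, x_pos = 3, y_pos = -1.5,
  contact_layout = c("CDR3a:peptide" = 3, "CDR3b:peptide" = 61)))

analyze(cx)
#> <analysis_report> toy_tcr_pmhc
#>   geometry: crossing 51.0 deg, incident 20.0 deg, x_pos 3.0, y_pos -1.5 A
#>   contacts: peptide 64, mhc 0 (cutoff 4.0 A)
#>   buried peptide surface: 264 A^2 (39%)
#>   shape complementarity Sc: -0.41

build_contact_table(cx)
#> <contact_table> cutoff 4.0 A
#>         CDR1a CDR2a HV4a CDR3a CDR1b CDR2b HV4b CDR3b FRa FRb total
#> peptide     0     0    0     3     0     0    0    61   0   0    64
#> mhc         0     0    0     0     0     0    0     0   0   0     0
```

The measured geometry returns the generator's specification exactly,
and the contact table reproduces the planted layout: 64 TCR–peptide
contacts, 95% of them through CDR3β (`contact_percentages(...)`).
Planted-contact toys are geometric fixtures, not packed interfaces, so
their Sc is low; real TCR–pMHC interfaces score about 0.6–0.75.

Simulate a nine-concentration SPR series at published-scale rate
constants and refit it globally:

```r
p <- kinetic_params(kon = 2.5e4, koff = 0.032, rmax = 100)   # KD = 1.28 uM
conc <- c(0.19, 0.39, 0.78, 1.56, 3.12, 6.25, 12.5, 25, 50) * 1e-6
sg <- lapply(seq_along(conc), function(i)
  simulate_sensorgram(p, conc[i], t_assoc = 120, t_dissoc = 120, dt = 0.1,
                      noise_sd = 0.2, seed = i))
fit_kinetics(sg)
#> <kinetic_params> kon = 2.5e+04 1/(M s), koff = 0.032 1/s, KD = 1.28e-06 M, Rmax = 100 RU
```

Real structures follow the same path: `read_structure("6vrm.pdb")`,
`annotate_complex()` with a chain-role/loop-range config (YAML example
in `inst/extdata/toy_annotation.yaml`), then `analyze()`,
`fit_measure_rmsd()`, `compare()`. A thin command-line front end with
subcommands (`analyze`, `geometry`, `contacts`, `sasa`, `sc`,
`superpose`, `spr-simulate`, `spr-fit`, `make-toy`) ships in
`inst/cli/tcrpmhc.R`.

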