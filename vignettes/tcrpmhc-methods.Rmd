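---
title: "Methods: TCR-pMHC docking geometry, interface analysis and 1:1 binding kinetics"
author: "tcrpmhc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TCR-pMHC docking geometry, interface analysis and 1:1 binding kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrpmhc)
```

`tcrpmhc` analyses the binding geometry of alpha-beta T-cell receptors
(TCRs) on peptide-MHC class I ligands, the atomic anatomy of the
interface, and the 1:1 binding kinetics measured for such interactions
by surface plasmon resonance (SPR). This vignette explains the models
and conventions behind each computation, the tunable parameters, the
synthetic-structure generator used throughout the test suite, and the
known limitations.

## The groove reference frame

All docking descriptors are defined in a frame attached to the MHC
peptide-binding groove (`build_mhc_frame()`):

* **origin** — mean Calpha position of the two groove-flanking helices
  (alpha1, default residues 50–86; alpha2, default 138–176 on the heavy
  chain; both overridable, since published helix boundaries vary);
* **z axis** — normal of the total-least-squares plane through those
  helix Calpha atoms (smallest principal component), signed toward the
  TCR;
* **x axis** — first principal axis of the peptide Calpha trace,
  projected into the helix plane and oriented so the peptide C-terminal
  residue has the greater x coordinate;
* **y axis** — z cross x (right-handed).

A total-least-squares plane and a principal-axis peptide line were
chosen because both are deterministic, rotation-equivariant, and robust
to peptide bulging; no iterative or randomized fitting is involved, so
repeated construction is bit-identical.

## Docking descriptors

V-domain centers are the means of the two Sgamma atoms of each domain's
conserved intrachain disulfide (`domain_center()`); where a position
lacks Sgamma, its Calpha substitutes and the fallback is flagged.
Auto-detection (`detect_conserved_cys()`) accepts the unique Cys pair
with an Sgamma–Sgamma distance of at most 2.5 Å — comfortably above
disulfide bond length (≈2.05 Å) and below any non-bonded Cys pair.

* **crossing (docking) angle** — angle in [0°, 180°] between the
  groove-plane projection of the Valpha→Vbeta vector and the +x
  (peptide N→C) axis;
* **incident angle** — tilt of that vector out of the groove plane,
  arcsin of the |z| component of the unit vector, in [0°, 90°];
* **x_pos / y_pos** — frame coordinates of the TCR center (midpoint of
  the two domain centers). Positive x_pos means a shift toward the
  peptide C-terminus.

Published tilt constructions differ between surveys, so
`incident_angle()` accepts a replacement `strategy` function; the
elevation default is the one the synthetic generator inverts, making
the generator/measurement pair exactly self-consistent. Angles are
reported as magnitudes; the boolean `canonical_polarity` diagnostic
(Valpha over the alpha2 helix) records the docking polarity separately.

Descriptors can be ranked against a survey table
(`rank_percentile()`). Percentiles count the query itself:
`round(100 * (1 - rank / (n_rows + 1)))`, the convention that
reproduces the published rank/percentile pairs for a 136-complex class
I survey (rank 4 → 97th, rank 14 → 90th). A small synthetic demo table
ships in `inst/extdata/`; rebuilding a full PDB survey is out of scope.

## Interface contacts

A contact is any pair of non-hydrogen atoms from different role groups
at **4.0 Å or less** (inclusive). `build_contact_table()` buckets
TCR-side contact atoms by residue ranges into CDR1, CDR2, HV4 and CDR3
of each chain; atoms outside every range land in a visible framework
bucket rather than being dropped, so totals remain auditable. Loop
boundaries are data, not code: the defaults are IMGT-like (CDR1 27–38,
CDR2 56–65, HV4 81–86, CDR3 105–117) and should be overridden with the
author-numbering ranges of the structure at hand, because printed
contact tables are only reproducible given the ranges actually used.

The "MHC" column counts heavy-chain contacts only;
beta-2-microglobulin and water contacts are tallied separately.
Percentages (`contact_percentages()`) are nearest-integer shares of the
per-target total, and `chain_share()` sums one chain's loops plus its
framework bucket. Hydrogen bonds are flagged with a deliberately
reproducible distance-only criterion — donor-typed N/O/S against
acceptor-typed N/O at ≤3.5 Å — because crystal structures rarely carry
hydrogens; an angular term would require placing them. Published
per-bond counts obtained with unstated criteria should therefore be
treated as qualitative when compared with this flag.

## Surfaces

`compute_sasa()` is a Shrake–Rupley implementation: each atom's
probe-expanded sphere (probe 1.4 Å) is sampled with a fixed spherical
Fibonacci lattice (default 960 points) and the accessible fraction
scales the analytic sphere area. A deterministic lattice (rather than
random sampling) makes areas exactly reproducible; rotation invariance
holds to sampling noise (≈0.1%). Radii are an element-keyed, fully
overridable table in the NACCESS/Chothia tradition (C 1.87, N 1.65,
O 1.40, S 1.85 Å). Buried peptide surface is the difference between
the peptide's SASA within the pMHC alone and within the full complex,
with the fraction relative to the former.

`shape_complementarity()` computes the Lawrence–Colman statistic on
solvent-accessible dot surfaces (default 15 dots/Å²): for each
interface dot the nearest partner dot contributes
`-(n·n') exp(-w d²)` with w = 0.5 Å⁻²; Sc is the mean of the two
directional medians. Interface dots lie within 1.5 Å of the partner
surface and outside a 1.5 Å border band at the patch rim — the
parameter defaults of the original formulation. Using the accessible
surface instead of the molecular (Connolly) surface is an
approximation chosen for determinism and simplicity; on smooth test
fixtures it is exact (two parallel planes a distance d apart score
`exp(-w d²)` in closed form), while on real interfaces it shifts Sc by
a few hundredths — within the tolerance used for published values.
Which atoms constitute each side is explicit configuration; the
conventional split is TCR chains versus peptide plus MHC heavy chain.

## Superposition

`kabsch_superpose()` solves the least-squares rigid superposition by
SVD, restricted to proper rotations (reflections rejected); collinear
inputs warn, since rotation about the common axis is then arbitrary.
`fit_measure_rmsd()` separates the *fit* selection (used for the
transform) from the *measure* selection (where the RMSD is evaluated
without refitting) — the construction behind statements such as
"superpose the MHC alpha1/alpha2 domains, measure the peptide
main-chain RMSD". Residue correspondence is by author numbering within
matched chain roles; no sequence alignment is attempted, which is
appropriate when compared structures share numbering (the intended use
case) and wrong when they do not. "Main chain" means N, CA, C, O.
`displacement_profile()` reports per-residue same-atom distances after
superposition, with ties in the maximum broken toward the lower
residue number. For unbound-versus-bound TCR comparisons, the default
fit set is all matched V-domain Calpha atoms outside the CDR3 ranges,
as config.

For crystals with several complex copies in the asymmetric unit, the
copy is selected through the role map (annotate the chain ids of the
copy of interest); running two configs reports both copies.

## 1:1 binding kinetics

The SPR model is the closed-form 1:1 Langmuir scheme:
association `R(t) = Req (1 - exp(-(kon C + koff) t))` with
`Req = Rmax C / (C + KD)`, dissociation `R = R_end exp(-koff Δt)`, and
`KD = koff / kon`. No ODE integration is used — the closed form is
exact and fast. `fit_equilibrium()` fits the steady-state isotherm,
`fit_kinetics()` fits kon, koff and Rmax globally across a
concentration series (log-scale parameters, Levenberg–Marquardt via
minpack.lm), both unweighted: instrument-specific weighting and drift
terms are deliberately out of scope. Simulated noise is additive
Gaussian in RU with an optional multiplicative term, standard practice
for SPR error models. Reference-cell subtraction is an instrument
workflow step; simulated data are generated pre-subtracted.

A kinetic fit is flagged unreliable when the largest observed rate
`kobs = kon C + koff` exceeds a resolvability threshold, by default
half the sampling rate (0.5 / median time step): beyond that the
exponential rise lives between samples and the rates are no longer
determined by the data, the regime in which rates are reported as "too
fast to measure". The threshold is configurable.

## The synthetic-structure generator

`make_toy_tcr_pmhc()` builds annotated toy complexes directly in the
canonical frame: two ideal groove helices (36 residues = ten exact
100° turns, axes 18 Å apart — chosen so the helix Calpha covariance is
exactly diagonal and the constructed frame is exactly the identity), a
9-mer extended peptide along +x, a beta-2-microglobulin stub, and two
pseudo-V domains carrying synthetic conserved-disulfide Sgamma pairs
placed so that crossing angle, incident angle, x_pos and y_pos equal
the specification to numerical precision (TCR center 25 Å above the
plane, domain centers 20 Å apart). Requested per-loop contact counts
are realized by planting carbon atoms at 3.5 Å — strictly inside the
4.0 Å cutoff, so counts are insensitive to rounding — from designated
peptide or helix Calpha atoms, in tilt cones chosen so each planted
atom touches exactly its designated target; the generator verifies the
realized table by exhaustive pair enumeration and refuses infeasible
layouts.

The toys emulate what the descriptors actually depend on — anchor
atoms, frames, contact geometry — and nothing else: there is no folded
immunoglobulin topology, no side-chain packing, no crystallographic
noise, and planted contacts are geometric, not chemical. Passing the
round-trip and contact-layout tests therefore demonstrates that the
measurement code inverts its definitions exactly; it does not
demonstrate robustness to the numbering quirks, alternate
conformations and density-limited coordinates of real crystal
structures, which is why analyses of deposited entries remain a
separate, user-supplied-input pathway.

## Numerical choices and problem sizes

Sphere sampling uses 960 points per atom by default (≈1% area error on
an isolated atom; the closed-form tests bound this). The test suite
and the acceptance script run SASA at 120–960 points and Sc fixtures
at 10–30 dots/Å² on toy systems of a few hundred atoms — sizes chosen
so the whole suite completes in well under a minute while every
numerical claim stays testable. Equilibrium-fit precision is
established over 100 simulation seeds at 1% multiplicative noise on
the published nine-point concentration ladders.

Degenerate inputs are rejected with typed conditions: collinear helix
atoms (no plane), inter-domain vectors perpendicular to the groove
plane (no crossing angle), zero-response isotherms, single-phase
sensorgrams, empty Sc interfaces. Ties are broken deterministically
throughout (altloc letter order, lower residue number for displacement
maxima).

## Limitations

* Loop-range defaults are IMGT-like and **must** be overridden with
  per-structure author numbering for deposited entries; contact tables
  are only as reproducible as the ranges supplied.
* Sc uses the accessible-surface approximation described above.
* The hydrogen-bond flag is distance-only.
* No sequence-based V-domain numbering, no flexible alignment, no
  mass-transport or bivalent SPR models, and no structure downloads:
  deposited coordinates are user-supplied local files
  (`deposited_structure_path()`).
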