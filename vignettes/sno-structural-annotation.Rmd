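---
title: "Structural annotation of S-nitrosylation sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural annotation of S-nitrosylation sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snotool)
```

## The scientific problem

S-nitrosylation (SNO) attaches a nitric oxide moiety to a cysteine thiol.
When a second cysteine sits close to the SNO site in space, the
S-nitrosothiol can resolve into a disulfide bridge with it — a redox relay
in which the modification does not force a new conformation but shifts the
population of pre-existing side-chain states toward disulfide-competent
geometry. The canonical example is the mitochondrial chaperone TRAP1,
where the SNO site and a partner cysteine 26 residues away in sequence face
each other in the folded middle domain. `snotool` provides the measurement
and classification machinery for studying this mechanism at scale:

1. **discovery** — given a table of experimentally reported SNO sites and a
   directory of structure models, find every cysteine in side-chain contact
   with a site and annotate the pair;
2. **ensemble characterization** — given a multi-model structural ensemble
   of one protein (for example, from a coarse-grained flexibility sampler),
   quantify the distribution of pair geometry, accessibility and predicted
   pKa over the models;
3. **variant classification** — given ensembles of a wild type and of point
   mutants near the cysteine pair, decide whether each mutation makes the
   protein environment more or less favorable to the SNO-induced disulfide
   switch.

## Pair geometry and disulfide grading

Four observables characterize a candidate pair: the Sγ–Sγ distance, the χ1
side-chain torsions of both cysteines (N–Cα–Cβ–Sγ), and the inter-residue
Cβ–Sγ–Sγ–Cβ torsion. Canonical disulfides have Sγ–Sγ ≤ 2.5 Å and
Cβ–Sγ–Sγ–Cβ near ±90°. χ1 is reported with its rotamer state using the
standard thirds of the circle — plus `p` on (0°, 120°], minus `m` on
(−120°, 0°], trans `t` elsewhere; bins are left-open and right-closed, so a
boundary value joins the bin it closes.

`grade_disulfide()` condenses these into a four-letter stereochemical
quality class in the spirit of disulfide-database grading: `A` for a
well-formed bridge (distance within [1.8, 2.5] Å, |torsion| within 30° of
90°, both rotamers relaxed), `B` for a distance-compatible but
torsion-distorted pair, `C` for sulfurs too close to bond (< 1.8 Å), `D`
for otherwise acceptable geometry with a strained `p` rotamer, and `none`
beyond 2.5 Å. The published grading schemes are qualitative; the numeric
windows here (1.8 Å floor, ±30° torsion window, `p` → `D`) are this
package's explicit concretization and all are configurable.

Alternate conformations are first-class: `pair_geometry()` enumerates the
cross product of altloc labels on the two Sγ atoms, one row each, rather
than collapsing to the highest-occupancy conformer. Experimental structures
of the TRAP1 pair resolve the partner cysteine in two conformations —
roughly 2 Å and 4 Å from the site — and collapsing them would erase exactly
the population heterogeneity the mechanism relies on.

A note on torsion invariants: a signed torsion is invariant under rigid
motion *and under traversing the four atoms in reverse order*; it is
mirror reflection that flips its sign. The property tests assert this
(reversal invariance, mirror antisymmetry), since a sign convention error
here would silently corrupt every rotamer assignment.

## Solvent accessibility

`shrake_rupley()` implements the classic probe-sphere point-sampling
algorithm on heavy atoms with element radii C 1.70, N 1.55, O 1.52,
S 1.80 Å, probe 1.4 Å, and 960 quasi-uniform points per atom from a
golden-spiral construction (pipelines default to 240 points; the two
settings agree to well under 1% on fixtures). Relative side-chain
accessibility divides a residue's in-context side-chain area by a
*self-calibrated* reference: the same quantity measured on the central
residue of an extended Gly-X-Gly tripeptide built by the package's own
scaffold generator with identical probe and point count. Self-calibration
keeps 100% exact by construction for an extended conformation and avoids
importing a normalization table whose provenance (Gly-X-Gly vs Ala-X-Ala,
radii set) could differ from the geometry engine. Values above 100% are
possible for distorted conformations and are left as-is.

The accessibility filter used by the discovery pipeline keeps SNO sites
with relative side-chain SASA ≥ 10%. The threshold is inclusive
(`>= 10`), configurable via `sasa_min`.

## Secondary structure

`assign_ss3()` reduces hydrogen-bond-pattern assignment to three states.
Amide hydrogens are reconstructed at 1.01 Å from N, anti to the preceding
carbonyl oxygen. The Kabsch–Sander electrostatic energy
E = 27.888·(1/r~ON~ + 1/r~CH~ − 1/r~OH~ − 1/r~CN~) kcal/mol defines a
hydrogen bond at E < −0.5. Helices come from 3/4/5-turn patterns on two
consecutive residues (covering the 3-10, α and π classes), strands from
parallel and antiparallel bridge patterns; everything else is loop, and
helix wins ties. Chain breaks (peptide C–N over 2.5 Å) split contiguity for
turns while still allowing bridges between segments. On ideal fixtures
this reproduces an independent DSSP implementation's 3-state output
exactly, which the acceptance suite verifies by running that reference on
the same fixture files.

The nine-class pair taxonomy (`classify_pair_ss()`) crosses
helix/strand/loop for the SNO site (first) and the partner (second). The
class is assigned from the input model, not per ensemble member; borderline
cases genuinely flicker between classes across members, so a per-member
tabulation of `assign_ss3()` outputs is the recommended sensitivity check.

## Cysteine pKa

Thiol reactivity toward NO chemistry depends on the cysteine pKa.
`predict_cys_pka()` is a deliberately transparent three-term empirical
model around the thiol reference pKa of 9.0:

* **desolvation**: +2.0 · max(0, 1 − relSASA/100) — burial destabilizes
  the thiolate;
* **hydrogen bonds**: −0.8 per donor heavy atom (backbone amide N, or
  side-chain O–H/N–H of Ser/Thr/Tyr/Asn/Gln/Lys/Arg/His/Trp, other
  residues only) within 3.5 Å of Sγ;
* **coulomb**: ±0.5 · (7 − d)/7 per charged group center within 7 Å —
  cations (Lys NZ, Arg CZ, His ring, counted charged by default as the
  worst case) lower pKa, anions (Asp/Glu carboxylate midpoints) raise it.

When another cysteine's Sγ lies within 2.5 Å — the same ceiling the
disulfide grade uses — the thiol is treated as disulfide-locked and the
conventional sentinel 99.99 is returned with `is_unphysical = TRUE`.
Sentinel rows are kept in pipeline tables but excluded from all summary
statistics. The model's contract is its own: tests assert the stated
arithmetic, monotonicity in burial and charge sign, and sentinel behavior,
never agreement with any external predictor. A `delegate` hook passes an
installed external predictor's values through verbatim, sentinel included,
for users who want one.

## Contact searches

Partner discovery uses side-chain centers of mass (mass-weighted heavy
atoms beyond Cα) with an 8 Å cutoff, 11 Å as the standard control setting.
Glycine has no side-chain center and can be neither a query nor a hit —
the same blind spot as center-of-mass contact-network tools, stated rather
than patched. Pairs under 8 residues apart in sequence are *vicinal*
(CXXC-like motifs); spatially close pairs at ≥ 8 residues are *proximal*.
"Fewer than eight" is taken exclusive (max vicinal separation 7).
Consecutive cysteines carry an extra `sequence_adjacent` flag, and
inter-chain pairs are kept with an `interchain` flag rather than dropped.
With altlocs, a pair qualifies if *any* conformer combination is within
the cutoff (inclusive), and the qualifying combination is recorded.

## The discovery pipeline

`run_snofinder()` walks the site table, with strict bookkeeping:
`n_input_sites = n_missing_model + n_not_cysteine + n_out_of_range +
n_analyzed` holds on every run and is fuzz-tested. Sites whose model
exists and whose position is a cysteine are annotated per partner and per
altloc combination: geometry and grade, relative SASA of both residues,
secondary structure, per-residue confidence (the B-factor column read as
pLDDT for AlphaFold-style models), and pKa with sentinel flags. Sites
inside low-confidence disordered segments of ≥ 20 residues are flagged
`disordered_region` but retained — the discard decision belongs to the
analyst. Confidence-based trimming (`trim_low_confidence()`) removes
terminal low-confidence runs of any length and internal runs of ≥ 20
residues, keeping short internal loops that connect confident domains; the
"low" threshold defaults to pLDDT 50 (the AlphaFold "very low" band),
which is this package's choice of default, exposed as a parameter.

## Ensembles, fractions and pseudo-free energies

`analyze_ensemble()` computes the per-model metric table and summarizes
with means and *population* standard deviations — an ensemble is treated
as the complete set of sampled models, so a single-model ensemble has
sd 0. The headline fraction is the proportion of models with Sγ–Sγ
strictly below 6 Å, the distance band within which the `p`/`m` rotamer
states correlate with disulfide-competent approach; a value exactly at
the threshold counts in the upper bin, a stated convention since the
source analyses do not specify one.

`pmf_1d()` turns a sample into a free-energy-like profile,
F = −RT ln p per bin (R = 1.9872×10⁻³ kcal/(mol·K)), shifted to zero
minimum, with empty bins undefined rather than zero. It is a histogram
estimate for visualizing ensemble distributions — not a reconstruction
from biased sampling, which is out of scope here.

## Variant classification

`classify_variant_effect()` compares ensemble means (not per-model pairs:
wild-type and mutant ensembles are independent samples). With
Δp = mean pKa(mut) − mean pKa(WT) at the SNO site and Δd the analogous
Sγ–Sγ distance change: a large pKa increase (≥ 2.0) is destabilizing on
its own; both changes within tolerance (0.5 pKa units, 0.5 Å) is neutral;
concordant decreases beyond tolerance are stabilizing, concordant
increases destabilizing; everything discordant or borderline is uncertain.
The qualitative notions "similar" and "large" are not quantified in the
source analyses; the defaults here sit at roughly the sampling noise of a
20-model ensemble mean and live in `variant_params()`. The rule table is
anti-symmetric for strong concordant shifts (swapping WT and mutant swaps
stabilizing and destabilizing), which is tested. Ensembles whose SNO-site
pKa is sentinel in every model classify as uncertain with an explicit
reason.

## The synthetic-structure generator

Every analysis above is exercised on structures the package builds itself:

* `build_scaffold()` — ideal-geometry backbones (N–Cα 1.458, Cα–C 1.525,
  C–N 1.329, C=O 1.231 Å; N-Cα-C 111.2°, Cα-C-N 116.2°, C-N-Cα 121.7°;
  ω = 180°) at requested φ/ψ (−57/−47 helix, −139/135 strand, randomized
  coil), side chains from per-residue internal-coordinate templates at
  χ1 = −60° by default. Supported alphabet: GACSTVLIMDENQKRH.
* `place_cys_pair()` — rigid placement of a second scaffold so the
  measured Sγ–Sγ distance lands within 0.05 Å of target and Cβ–Sγ–Sγ–Cβ
  within 2°, scanning free orientation parameters for a clash-free pose.
* `build_strand_pair()` — an antiparallel two-strand sheet: the second
  strand is the first rotated 180° about the in-plane axis perpendicular
  to the strand direction at ~4 Å offset, with a small deterministic
  register refinement maximizing backbone hydrogen bonds.
* `synth_ensemble()` — n jittered copies (default 20, matching typical
  coarse-grained ensemble sizes) with cysteine χ1 resampled from a t/m/p
  weight vector. Cartesian jitter feeds back into χ1 (0.15 Å of jitter
  contributes roughly 15° of torsion noise), so rotamer targets are exact
  only at small jitter — a documented property, tested at small jitter.
* `synth_sites_table()` — a dbPTM-like site table plus matching model
  files with injected bookkeeping errors and a manifest of expected
  counts, closing the loop on the discovery pipeline.

What the generator does *not* emulate: physically realistic conformational
sampling (no energy function), side-chain rotamer correlations, crystal
contacts, or the length and disorder spectrum of real proteomes. Passing
tests therefore demonstrate that the measurement and classification
machinery is correct and self-consistent — not that any particular
biological conclusion transfers to real proteins, which requires real
models and ensembles as inputs.

## Numerical choices and problem sizes

Degenerate inputs are defined, not patched: coincident torsion points
error; glycine SASA is 0 with a warning; empty PMF bins are NA; empty
partner lists are empty tables; chains under 3 residues are all-loop.
Occupancies outside [0, 1] clamp with a warning. SASA neighbor search uses
a full distance matrix — appropriate at the tens-to-hundreds-of-residues
scale of the test fixtures and typical single-domain inputs; the point
counts (960 reference, 240 in pipelines) keep a full discovery run on a
synthetic table of half a dozen proteins under a few seconds. The test
suite's stochastic blocks (100-seed classifier recovery, 10⁵-sample PMF,
50-table bookkeeping fuzz) were sized to run in well under a minute
together.

## Known limitations

* The pKa model is a three-term surrogate with documented coefficients; it
  captures burial, donor and charge trends, not coupled titration or
  conformational pKa averaging.
* DSSP reduction is 3-state; π-helix subtleties and β-bulges are out of
  scope, as are χ2/χ3 torsions.
* The discovery pipeline trusts the model's author numbering; site tables
  must use the same numbering as the models (true for AlphaFold models and
  UniProt positions).
* Inter-chain pairs are flagged but the vicinal/proximal split is defined
  only within a chain.
* Recomputing published surveys of deposited experimental structures
  requires downloading those PDB entries; the package ships the machinery
  and synthetic stand-ins, never the data.
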