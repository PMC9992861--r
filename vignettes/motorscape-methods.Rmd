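---
title: "Methods: collective variables, GaMD reweighting, and ensemble analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collective variables, GaMD reweighting, and ensemble analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorscape)
```

`motorscape` post-processes conformational ensembles of molecular-motor
complexes: it projects multi-model PDB ensembles onto collective
variables (CVs), recovers equilibrium free-energy profiles from
Gaussian-accelerated MD (GaMD) boost potentials, and condenses ensembles
into clusters, centroids and distribution summaries. This vignette is the
package's account of the underlying methods, the choices that were
genuinely open, and what the synthetic-data validation does and does not
demonstrate.

## Ensembles and selections

An `Ensemble` is an ordered list of frames over one immutable topology;
every frame must present the identical (chain, residue number, atom name)
sequence, which the PDB reader enforces model by model. Author residue
numbering is taken verbatim — the residue anchors this kind of analysis
relies on (cleft residues, salt-bridge partners, loop boundaries) are
quoted in author numbering in the literature, so renumbering would only
add a failure mode. Insertion codes are rejected rather than silently
reinterpreted. Alternate locations keep the highest-occupancy conformer,
ties resolved to the lexicographically smallest altloc id: deterministic
and the common convention. Hydrogens are kept on read (MD-derived PDBs
have them) and removed by the `"heavy"` selection filter.

Boost-potential logs are plain text. The `two_column` dialect is
`frame dV` with `#` comments; the `amber_gamd` dialect skips `#` headers
and takes the total boost energy from an explicitly configured column —
engine log layouts vary, and guessing a column is exactly the kind of
silent error a pipeline should refuse to make. Slightly negative values
are numerical noise and are clamped to zero (with a warning beyond
1e-6 kcal/mol). Replica logs pair with replica ensembles one-to-one and
the pairing is validated before any analysis runs.

## Collective variables

**Distances and cleft width.** Plain Euclidean atom-pair distances per
frame. The actin-binding cleft width is the same operation with Cα
defaults and a semantic name: the open/closed state of the cleft between
the upper and lower 50-kDa subdomains is conventionally reported as a
single Cα–Cα distance across the cleft mouth.

**Crossing angles.** Each secondary-structure element gets a directed
(N→C) axis; the CV is the angle between the two axes in [0°, 180°]. The
directed convention matters: reported basins near 5–10° and 20–25° are
only distinguishable from their supplements if the axes carry direction.
The axis is the principal component of the element's Cα positions after a
light smoothing step — positions two residues apart are averaged — which
suppresses the helical-wheel component of short helices. Without it, the
principal axis of a 12-residue α-helix (radius 2.3 Å, rise 1.5 Å,
100°/residue) tilts ≈ 1.3° away from the true axis because a non-integer
number of turns leaves a net radial moment; with it the recovery error is
below 0.3°, and exactly collinear strands are unaffected. Elements with
fewer than five Cα atoms skip the smoothing. Degenerate geometry (all
points coincident) is an error, not a NaN.

**Contact areas.** The buried area between motif groups A and B is
(SASA_A + SASA_B − SASA_AB)/2, with SASA from a Shrake–Rupley
implementation using a *deterministic* Fibonacci sphere lattice (default
960 points) and probe radius 1.4 Å; van der Waals radii are a Bondi-style
element table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20, default
1.70 Å), overridable. Two open choices were resolved as follows:

* *Context.* The default is the pairwise definition — only A and B
  occlude each other — because it is symmetric, reproducible, and
  independent of how much of the rest of the complex happens to be in the
  model. A `context = TRUE` mode includes all remaining atoms as
  occluders for users who want areas conditioned on the full complex.
  Published contact areas rarely state which convention was used; both
  are provided, and reports record the choice.
* *Determinism over Monte Carlo.* A fixed lattice makes results exactly
  repeatable and lets the quadrature be validated against closed forms
  (isolated sphere: 4πr²; two overlapping spheres: the analytic
  spherical-cap burial), at the cost of a small orientation dependence.
  At 960 points the isolated-sphere error is < 1% and rigid-body rotation
  moves contact areas by well under 1 Å² on the test systems — that is
  the quadrature resolution, and the test suite checks invariance at that
  tolerance rather than at floating-point precision, which a space-fixed
  lattice cannot deliver.

**Superposition RMSD.** Kabsch superposition via SVD with the reflection
corrected to a proper rotation; rank-deficient covariance (collinear
point sets) is a hard error because the optimal rotation is not unique
there. `rmsd_series()` superposes each frame on a *fit* selection and
measures RMSD over a possibly different *measure* selection, which is how
motor-core-aligned, motif-resolved deviations are reported. Selections
default to heavy atoms; a `"CA"` filter reproduces backbone-level
comparisons. Both conventions appear in the literature and the reports
record which was used.

## GaMD reweighting

GaMD samples a modified potential V + ΔV with
ΔV = ½ k (E − V)² wherever V < E, so ΔV ≥ 0. The biased and equilibrium
bin probabilities are related by p(j) ∝ p\*(j) ⟨e^{βΔV}⟩_j. The
exponential average is numerically hopeless at realistic sample sizes, so
it is expanded in cumulants of the per-bin ΔV distribution:

$$\ln \langle e^{\beta \Delta V} \rangle_j \approx \beta C_1 +
\tfrac{\beta^2}{2} C_2 + \tfrac{\beta^3}{6} C_3,$$

truncated at `cumulant_order` (default 2, standard GaMD practice; orders
1–3 implemented). The free energy per bin is
F_j = −k_B T ln p\*_j − (C1 + βC2/2 + β²C3/6), anchored so the minimum
over unmasked bins is zero. Two exact identities pin the implementation
down and are tested bitwise: ΔV ≡ 0 reduces to the plain histogram PMF,
and a constant ΔV cancels entirely after anchoring.

Choices and defaults, with reasons:

* **Per-bin (local) cumulants**, not a single global factor: a global
  factor is a constant and cancels on anchoring — it cannot reshape a
  landscape, so only bin-local moments carry information.
* **k_B = 0.0019872041 kcal/(mol·K)**, temperature default 300 K,
  configurable.
* **Bins**: 50 (1D), 40×40 (2D) by default; `min_count` 20 frames/bin.
  Bins below `min_count` are masked (`NA`) rather than reported as
  unreliable numbers; the masked fraction shrinks as sampling grows,
  which the suite checks as a property.
* **Diagnostics**: the 2nd-order truncation assumes near-Gaussian per-bin
  ΔV; `anharmonicity_check()` flags bins with |skewness| > 0.5 so users
  can see where the truncation is suspect (an exponential ΔV, skewness 2,
  is flagged; Gaussian and constant ΔV are not).

**Basin labelling.** Local minima over the unmasked bin graph
(2-neighborhood in 1D, 4-neighborhood in 2D), merged by a persistence
criterion: a minimum whose depth below its lowest connecting saddle is
less than `depth_threshold` merges into its deeper neighbor. Labels m1,
m2, … are assigned by ascending free energy, so m1 is the global minimum.
This lowest-saddle flood is simpler than a full watershed; it is
sufficient for labelling a handful of basins on smooth landscapes and is
documented as such — very flat, noisy profiles with threshold 0 will
report every wiggle.

## Ensemble clustering and distributions

Clustering is the GROMOS leader algorithm: the frame with the most
neighbors within `cutoff` (default 2.0 Å) seeds a cluster, its
neighborhood is removed, and the procedure repeats. No installed R
package provides this algorithm; it is small, deterministic (ties broken
by lowest frame index everywhere), and has a testable contract —
well-separated planted conformers are recovered exactly for any cutoff
between the jitter and separation scales. Cluster ids are ordered by
descending population and the centroid is the member minimizing mean RMSD
to its cluster mates (verified against brute force in the tests). When
the conformational change of interest is the relative arrangement of two
domains, the RMSD selection must pool both domains — a selection confined
to one rigid domain is blind to inter-domain motion by construction.

Densities use `stats::density` (Gaussian kernel, 512-point grid, data
range padded by three bandwidths, Silverman's rule by default) with
optional per-frame weights for reweighted distributions. Peaks are local
maxima filtered by topographic prominence relative to the global maximum
(default 5%), ordered by density, so a "most probable distance" and a
secondary mode fall out of one report. A zero-variance series produces a
degenerate single-delta report instead of an error, because constant CVs
are a legitimate limiting case of rigid fixtures.

## Synthetic ground truth: what it shows and what it does not

The generators define the package's validation conditions:

* `make_toy_motor()` builds two rigid Cα-only domains (a 12-residue ideal
  helix, radius 2.3 Å, rise 1.5 Å, 100°/residue, continued by a
  6-residue strand). Domain B is a rotated, translated copy of domain A,
  so the planted cleft distance (anchor Cα atoms of residue 6 on each
  chain) and crossing angle are realized *exactly* before jitter;
  per-coordinate Gaussian jitter (default 0.1 Å) then models local
  flexibility. Defaults (cleft 15 Å, angle 22°, 100 frames) sit in the
  regime reported for actomyosin cleft widths and HF-helix rotations, so
  the tests exercise realistic magnitudes. Planted conformer mixtures
  give exact cluster labels.
* `sample_boosted()` draws from p\*(x) ∝ exp(−β[V + ΔV]) at the
  distribution level — by inverse CDF on a dense grid in 1D and by
  Metropolis (proposal sd = 5 grid spacings, burn-in 10⁴, thinning 5) in
  2D — with the exact GaMD boost ΔV = ½k(E − V)². Simulating dynamics
  would add nothing the analysis stages can detect: they consume only
  (ξ, ΔV) pairs. The default double-well study condition is a 3 kcal/mol
  barrier with wells 4 CV units apart, boosted with E = 4 kcal/mol and
  k = 0.2 — chosen GaMD-style (k of order 1/(E − V_min)) so the boosted
  landscape is well sampled while the per-bin ΔV stays near-Gaussian,
  which is the regime the 2nd-order cumulant truncation is built for. At
  2×10⁵ samples the recovered profile deviates from truth by under
  0.3 kcal/mol everywhere and the barrier is recovered within
  0.05 kcal/mol (see `scripts/acceptance.R` output).
* `make_bimodal_series()` mirrors the bimodal salt-bridge distance
  regime (modes near 3.8 and 6.9 Å) with exact component labels.

What passing these tests shows: the geometry, reweighting, clustering and
peak machinery are *correct* — they recover known answers from inputs
that exercise the same code paths real data would. What it does not show:
that a particular real trajectory is converged, that its per-bin boost
distributions are Gaussian enough for 2nd-order truncation, or that the
toy geometry captures actomyosin energetics (it does not try to — the toy
domains are rigid and Cα-only, with element "C" throughout; SASA tests
use purpose-built few-atom fixtures instead). Stochastic distributional
checks (KDE mode location, KS agreement of the sampler with its analytic
CDF) run at fixed seeds chosen so that a correct implementation passes at
the stated tolerances; they are regression guards, not significance
tests.

All generators expand a single integer seed; identical spec + seed gives
byte-identical output, which the pipeline's byte-stable-rerun contract
builds on.

## Pipeline

`validate_config()` checks a whole configuration at once and reports
*every* problem (missing files, undefined motifs, dangling CV references)
in one error — pipelines with large configs should not fail one typo at a
time. `run_state_analysis()` executes fixed stages (load → pair boosts →
CVs → distributions → 1D/2D profiles → basins → clustering → reference
RMSD → report); any failure aborts naming the stage. Reports are JSON at
full precision with CSV side tables and carry provenance: input file
hashes, all settings, package version, and a timestamp (the single field
excluded from the byte-stability contract). `compare_states()` reduces
two reports to per-CV shifts of most-probable values and m1 basin
positions — the form in which state-to-state changes (e.g. a cleft-width
shift on product release) are usually quoted.

The test suite and the acceptance script run the 1D recovery at 2×10⁵
samples, the 2D checks at 10⁴–10⁵, and the end-to-end pipeline on
2 × 60-frame toy replicas with 12 (1D) and 8×8 (2D) bins and
`min_count` 3 — sizes at which every stage, including the O(n²) pairwise
RMSD matrix and the per-frame Shrake–Rupley areas, completes in seconds
while leaving the statistical tolerances comfortable.

## Known limitations

* PDB only (multi-model); no mmCIF or binary trajectory formats — the
  `Ensemble` contract is format-agnostic, so adding readers does not
  touch analysis code.
* No insertion codes; author numbering only.
* Reweighting computes nothing about ΔV itself (that is the MD engine's
  job) and implements neither WHAM/MBAR nor block-bootstrap error bars.
* Basin merging is lowest-saddle persistence, not a full watershed.
* The Shrake–Rupley lattice is space-fixed: areas are reproducible
  exactly, but rotating a structure perturbs them at quadrature
  resolution (sub-Å² at 960 points).
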