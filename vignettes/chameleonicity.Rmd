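---
title: "Profiling molecular chameleonicity from conformer ensembles"
author: "molcham"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling molecular chameleonicity from conformer ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molcham)
```

## The problem

Drugs beyond the Rule of 5 (bRo5) — macrocycles, PROTACs, large flexible
scaffolds — often owe their membrane permeability to *chameleonicity*:
the ability to expose polar groups in water (open, extended conformers)
while burying them in nonpolar media (closed, compact conformers held
together by intramolecular hydrogen bonds, IMHBs). Single-conformer 2D
descriptors such as TPSA cannot see this behavior. `molcham` quantifies
it from a pair of conformer ensembles, one labeled *polar* (water) and
one *nonpolar* (chloroform/toluene-like), whatever engine generated them
(conformational sampling, molecular dynamics, distance geometry).
Ensemble generation itself is out of scope: the package ships only a thin
adapter (`generate_ensemble()`) over an external distance-geometry engine
(RDKit ETKDG + MMFF94), because the analysis, not the sampling, is its
contribution.

## Per-conformer descriptors

**3D polar surface area** (`psa_3d()`). The polar atom set is N, O and
their bonded hydrogens (`"NO"` mode; `"NOSP"` adds S and P). For each
polar atom, points are placed on its sphere of radius $r_i +
\mathrm{probe}$ using a deterministic Fibonacci lattice (default 1024
points/atom, no RNG, so results are reproducible bit-for-bit); a point is
exposed iff it lies outside every other atom's inflated sphere, and

$$\mathrm{3D\,PSA} = \sum_{i \in \mathrm{polar}} 4\pi (r_i + p)^2
  \cdot \frac{\#\mathrm{exposed}_i}{\#\mathrm{points}} .$$

The default probe is 0 Å (polar fraction of the van der Waals surface);
1.4 Å gives the solvent-accessible variant. Radii default to the Bondi
set (H 1.20, C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å) and are
configurable, since published 3D PSA implementations differ mainly in
radii and polar-atom definitions. At 1024 points/atom the lattice error
is well below 1% (doubling the lattice moves fixture values by < 1%),
and the two-sphere case agrees with the analytic spherical-cap area to
better than 1%.

**Radius of gyration** (`radius_of_gyration()`): the RMS distance of the
atoms from the center of mass,
$R_{gyr} = \sqrt{\sum_i w_i \lVert r_i - c \rVert^2 / \sum_i w_i}$, with
mass weights by default. A unit-weight option exists because some tools
weight all atoms equally; on drug-like molecules the two differ by a few
percent and move together.

**TPSA** (`tpsa()`): the conformation-independent fragment-contribution
sum of Ertl, Rohde and Selzer, implemented from the published per-atom
environment table. It serves as the upper-envelope index against which
the most polar conformers are compared: a fully exposed ensemble should
approach (and, because fragment contributions underestimate bare sphere
areas, often slightly exceed) its TPSA. The default is N/O contributions
only, matching the common 2D implementations; `"NOSP"` mode adds S/P
contributions since some commercial tools include them (both are
reported where the choice matters). Environments missing from the table
fall back to the plainest same-element contribution with a warning.

**IMHB detection** (`detect_imhbs()`). A contact is counted when a
hydrogen bonded to N/O/S sits within $d_0 + 0.4$ Å of an acceptor (N/O/S
bearing a lone pair under a formal-charge/valence rule) at a
donor–H···acceptor angle of at least $\theta_0 - 20°$. The 0.4 Å / 20°
relaxations are the widely used defaults of the Chimera H-bond engine.
That engine relaxes per-moiety ideal geometries; the exact tables are not
public, so `molcham` uses a single ideal pair — $d_0 = 2.1$ Å,
$\theta_0 = 150°$, i.e. accept H···A ≤ 2.5 Å and angle ≥ 130° — chosen so
that (i) canonical IMHBs pass comfortably and (ii) the planar
aromatic-amine → imide-carbonyl contact of pomalidomide-like scaffolds
(H···A ≈ 2.2–2.3 Å but angle ≈ 120–128°) is rejected, reproducing the
reference tool's published behavior on that compound. Both thresholds
are closed (the exact boundary is detected), detection is
superset-monotone in the relaxations, and donor–acceptor pairs closer
than 3 bonds are excluded as geometry artifacts. Each hydrogen reports
only its nearest qualifying acceptor unless the full bifurcated list is
requested.

## Ensemble statistics and the density map

`summarize_ensemble()` reports Min/Max/Average/Median of PSA and Rgyr per
solvent. Min and Max carry the ids of the conformers that realize them —
those are real structures worth inspecting — while Average and Median
are population statistics that generally correspond to no conformer.
Even-sized medians use the midpoint of the central pair; ties for an
extreme resolve to the lowest conformer id. The cross-solvent polarity
swing is `delta_max_min()` = MaxPSA(polar) − MinPSA(nonpolar), returned
unclamped.

`tile_density()` bins (Rgyr, PSA) points into a grid of half-open,
lower-inclusive tiles (top edge inclusive), by default 25 tiles per axis
over pooled two-solvent bounds so both ensembles are binned identically.
`find_modes()` finds occupied tiles not exceeded by any 8-neighbor. Two
numerical choices harden it against count noise and were verified on
seeded Gaussian mixtures: competing maxima within a Chebyshev radius of
2 tiles are collapsed by non-maximum suppression (strongest first, ties
by tile index, deterministic), and a mode only counts as *converged*
when its count is both ≥ 3× the mean occupied-tile density and at least
4 Poisson standard deviations above that mean. The significance guard
matters: a near-uniform scatter of 200 points over 400 tiles is a
Poisson(0.5) field whose maximum reaches 4 counts in a substantial
fraction of seeds, which would clear a bare 3×-mean threshold (≈ 3.75)
and fake a cluster; no plausible seed clears the combined rule, while
genuine modes of mixtures separated by ≥ 4 SD exceed both bars by an
order of magnitude (recovery ≥ 95% across 50 seeds in the test suite).
`representative_conformers()` returns the ensemble member nearest a mode
center in z-scored property space — Å and Ų are incommensurable, so
each axis is standardized by the pooled mean/SD — with ties to the
lowest id.

## The chameleonicity verdict

Three criteria are scored on the ensemble pair:

* **(a) separation** — `polarity_separation()`:
  (median(polar) − median(nonpolar)) / pooled IQR, for PSA and Rgyr.
  Positive PSA separation means the molecule is more polar in water.
  The pooled IQR makes the score scale-free; identical distributions
  score 0, and a zero IQR with unequal medians returns a signed infinite
  sentinel with a warning rather than an error.
* **(b) congruence** — `congruence_overlap()`: the overlap coefficient
  $\sum_t \min(f_t^{polar}, f_t^{nonpolar})$ of the two tile-frequency
  distributions on the shared grid; 1 for identical occupancy, 0 for
  disjoint property ranges. Chameleons need *some* congruent conformers
  in both media to interconvert through.
* **(c) TPSA attainment** — `tpsa_attainment()`: MaxPSA(polar) / TPSA.
  A chameleon exposes essentially its full topological polarity in
  water.

The field states these criteria qualitatively; the package's numeric
operating points are declared defaults, configurable in
`chameleon_thresholds()`: s_min = 0.5 (half a pooled IQR), o_min = 0.05
(5% shared occupancy), c_min = 0.9 (90% attainment). They were chosen
once so that the canonical described patterns fall on the intended
sides: a Saquinavir-like profile (clear separation, partial overlap,
TPSA reached in water) passes all three, while a polar-PROTAC-like
profile (no overlap, never exposing full polarity, solvent-independent
IMHBs) fails (b) and (c).

The IMHB pattern completes the verdict. `ensemble_imhb_profile()`
reports ΔMean = mean(IMHB, nonpolar) − mean(IMHB, polar) (positive =
more IMHBs in the nonpolar medium) and per-pair occurrence frequencies;
`classify_imhb_persistence()` classes each donor–acceptor pair as
*static* (frequent in both media), *dynamic* (nonpolar only),
*polar-only*, or *absent*, at an occupancy threshold τ = 0.2 (no
published threshold exists; 0.2 separates incidental contacts from
populated ones in the fixtures). The verdict is **chameleonic** iff (a) ∧
(b) ∧ (c) hold and the IMHB pattern is gainful and solvent-specific:
ΔMean > 0, at least one dynamic pair, and static pairs not outnumbering
dynamic ones ("majority static" is read as static > dynamic). Missing
inputs yield **indeterminate** with a reason code; failed clauses are
enumerated as reason codes rather than collapsed into a boolean.

```{r toy, eval = FALSE}
tc <- toy_chameleon_ensembles(toy_chain_spec(seed = 1))
res <- run_analysis(tc$polar, tc$nonpolar, outdir = "toy_report")
res$report
```

## Chromatographic descriptors

Retention-time tables (system, %ACN, tR, t0) feed the standard isocratic
formulas, all base-10: the capacity factor k′ = (tR − t0)/t0 (the
operative definition; one published parenthetical conflates k′ and
log k′, and the k′ form is the one consistent with the IAM workup);
BRlogD = 3.31 · log k′60 + 2.79 on the XBridge RP18 system;
log kW^IAM as the OLS intercept of log k′ vs %ACN at 0% ACN;
Δlog kW^IAM = log kW^IAM − (0.92 · BRlogD − 1.03) as the polarity excess
over lipophilicity; Δlog P(oct−tol) with the > 2.5 rule-of-thumb for
IMHB absence (strict inequality at the boundary). `plrps_deviation()`
fits the linear 50–90% ACN range of the PLRP-S series and evaluates the
excess retention at 100% ACN; the fit window default reflects the
reported slope change near 95% ACN, and both window and evaluation point
are configurable. A positive deviation beyond 2 prediction standard
errors (with a 1e-6 floor so exact lines are never flagged by rounding
noise) marks chameleon-consistent retention at high cosolvent.

## What the synthetic generators emulate — and what they do not

`toy_chameleon_ensembles()` builds an ω-hydroxy aldehyde chain
HO–(CH₂)ₖ–CHO whose two ends are donor and acceptor, with defaults
chosen once as the package's study conditions: 8 backbone carbons, fold
H···A distance 2.0 Å (0.5 Å inside the detection boundary), 80% of
nonpolar conformers folded, 30 conformers per ensemble, 0.05 Å
coordinate jitter. Folded geometries place the backbone on a circular
arc whose radius is solved (by root finding) so the donor hydrogen sits
exactly at the specified distance from the acceptor oxygen at a linear
angle; extended geometries are a standard 112° zigzag. Every expected
behavior is therefore knowable in closed form: folded conformers carry
exactly one IMHB, extended ones none; folded Rgyr < extended Rgyr;
folding buries polar surface. The polar ensemble is all-extended, the
nonpolar one mostly folded with an extended minority — those shared
extended conformers create the congruence overlap a chameleon needs.
`toy_rigid_ensembles()` is the negative control (both solvents
all-extended). `property_cloud()` provides seeded Gaussian mixtures for
the density machinery.

These fixtures emulate the *signatures* the pipeline must detect —
polarity separation, burial by folding, solvent-specific IMHBs,
congruent subpopulations — under exactly known ground truth. They do not
emulate force-field energetics, conformational entropy, solvent
structure, or the property correlations of real bRo5 ensembles; passing
tests demonstrate the machinery's correctness, not the field
transferability of any threshold. Real-structure behavior is exercised
separately on bundled drug structures and distance-geometry ensembles,
including a pomalidomide negative control (its near-planar
amine→carbonyl contact must be rejected) and a polarity-ordering check
across three profiled molecules. The bundled `cmp98_synthetic` record is
a *synthetic stand-in* for a polar VHL-based homo-PROTAC (two
thiazole-bearing VHL ligand ends on a PEG linker), constructed from the
compound class's textual description because the exact structure is not
available in machine-readable form; it reproduces the class's size and
polarity regime (TPSA ≈ 251 Ų), not the literature compound.

## Numerical and design choices

* **Indexing** is 1-based throughout the R interface; SDF/PDB 1-based
  indices pass through unchanged.
* **Aromaticity** honours explicit aromatic bond orders when present and
  otherwise applies a Hückel-style π count per smallest ring (endocyclic
  double → 1, double into a fused ring → 1, exocyclic double to an
  acyclic atom → 0, saturated N/O/S lone pair → 2, saturated carbon
  breaks the ring; aromatic iff π = 6). This resolves fused Kekulé
  structures (naphthalene, quinoline) correctly and was cross-checked
  against an independent implementation on the bundled structures.
* **Acceptor rule**: N with degree ≤ 3 and charge ≤ 0; O/S with charge
  ≤ 0. Quaternary/protonated nitrogens are excluded (no lone pair).
* **Ties** everywhere resolve to the lowest conformer id or tile index,
  so reruns are bit-for-bit reproducible; the only RNG in the package
  sits in the fixture generators and the external embedding engine, both
  seeded.
* **Problem sizes.** The validation suite runs tens of seeds of the toy
  pipeline (30 + 30 conformers each), 50-seed mode-recovery sweeps
  (n = 1000 points), a 100-conformer pomalidomide ensemble and
  12-conformer ensembles of the three profiled structures; these sizes
  give stable pass/fail behavior for every stochastic criterion while
  keeping the suite comfortably interactive.

## Known limitations

* PDB input carries no bond orders; bonds absent from CONECT records are
  inferred from covalent radii as single bonds, so aromatic-ring counts
  and TPSA on PDB-only input are unreliable. Use SDF when topology
  matters.
* Explicit hydrogens are required for IMHB and PSA work by design;
  adding hydrogens to a 3D geometry is generation, not analysis.
* The single-pair IMHB geometry is a declared surrogate for per-moiety
  ideal tables; contacts far from the canonical geometry (strong
  charge-assisted bonds, bifurcated systems) are handled only through
  the relaxations.
* The chameleonicity thresholds are operating points, not measured
  constants; they are exposed in `chameleon_thresholds()` and reported
  alongside every verdict.
* log P(MLP)-style 3D lipophilicity is deliberately absent: no reliable
  general parameterization exists for the ionizable, flexible compounds
  this package targets.
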