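---
title: "Methods: comparative structural-NMR analysis with phnmr"
author: "phnmr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative structural-NMR analysis with phnmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phnmr)
```

`phnmr` implements the quantitative analyses that accompany a solution-NMR
characterisation of a pleckstrin homology (PH) domain and its peptide
ligands: ensemble superposition and precision, region-restricted RMSD and
sequence identity, NOE-restraint bookkeeping, chemical-shift-perturbation
(CSP) mapping, heteronuclear NOE mobility analysis, and single-site ITC
simulation and fitting. This vignette records the models, the parameter
choices, and the places where a design decision was genuinely open.

## Structure ensembles and superposition

An NMR structure is deposited as a bundle of models sharing one atom
roster. `readEnsemble()` reads multi-model PDB files (coordinates parsed
by `bio3d`), keeping residue numbering verbatim, retaining hydrogens,
keeping the highest-occupancy alternate conformer (ties broken by altloc
letter) and assigning chain "A" when the file omits chains. The symbolic
atom classes are fixed: `"backbone"` is exactly N, CA, C, O; `"heavy"` is
every non-hydrogen atom.

`kabsch()` computes the least-squares rigid superposition by singular
value decomposition of the coordinate covariance matrix, with the usual
sign correction of the smallest singular direction so the rotation is
always proper (determinant +1). The test suite pins it against an
independently implemented quaternion-eigenvalue oracle on a thousand
random point sets to 1e-7 Å.

Two conventions needed fixing where standard practice varies:

* **Representative coordinates for cross-structure RMSD.** Published
  pairwise RMSDs between NMR ensembles rarely state whether model 1, a
  representative model, or the mean structure was used. `regionRMSD()`
  defaults to the mean structure of each ensemble because it is
  reproducible without an arbitrary model choice; an integer argument
  selects any single model instead.
* **Mean structure for ensemble precision.** `ensemblePrecision()`
  computes the mean structure by iterative superposition: superpose every
  model onto the current mean, recompute the mean, repeat until the mean
  moves < 1e-6 Å (cap 100 iterations — synthetic and real bundles
  converge in a handful). The reported spread is the sample (n−1)
  standard deviation of the per-model RMSDs, matching the "mean ± sd"
  convention of structure-statistics tables. No outlier rejection or
  distance-cutoff trimming is applied: the statistic is the plain RMSD
  over the stated selection.

## Sequence identity

`globalAlign()` is a Needleman–Wunsch–Gotoh global aligner with affine
gaps. A gap of length L costs `gapOpen + L*gapExtend` (default −10 −
0.5L); traceback ties are broken deterministically (diagonal, then up,
then left), so alignments are reproducible. Plain 1/0 match/mismatch
scoring is the default rather than a substitution matrix: when the goal
is to reproduce a published identity percentage over a structurally
superposed core, the correspondence should be supplied explicitly and the
aligner is only a convenience. `percentIdentity()` counts strictly
identical aligned pairs over aligned (non-gap) pairs in the region —
similar residues do not count — and rounds half-up to one decimal, the
convention of printed identity percentages.

## NOE restraints

Restraint tables classify contacts by sequence separation (|i−j| = 0
intraresidue, 1 sequential, 2–4 medium-range, ≥ 5 long-range; the four
classes partition all pairs) and assign distance bounds by NOE intensity:
lower bound always 1.8 Å, uppers 2.7/3.3/5.0/6.0 Å for
strong/medium/weak/very-weak, with 2.9 and 3.5 Å for strong and medium
NOEs involving HN protons. Pseudo-atom upper-bound corrections are
applied where a proton group is represented by one centre; magnitudes
are rarely printed in papers, so the defaults are the field's customary
+1.0 Å (methyl), +0.7 Å (non-stereospecific methylene) and +2.0 Å
(aromatic ring), all configurable. Hydrogen bonds are stored as two
distance restraints per bond (H–acceptor 1.8–2.3 Å, donor–acceptor
2.7–3.3 Å by default); side-chain rotamer dihedrals default to
centre ± 30°, while backbone φ/ψ widths come from the caller (they are
predicted from chemical shifts by external tools, out of scope here).

## CSP mapping

The combined amide shift change is
Δδ = √((Δδ_H)² + (Δδ_N/5)²); the 1/5 nitrogen scaling is fixed, not
configurable, to avoid silent divergence from the printed convention.
Perturbed residues are called at the final titration point with a strict
Δδ > 0.100 ppm rule (a value of exactly 0.100 is excluded), plus graded
bins at 1×, 2× and 4× the threshold for structure colouring.
Intermediate-ratio values are reported but not thresholded. Unassigned or
vanished peaks are carried as missing, never as zero.

`trackPeaks()` links the assigned reference peaks (ratio 0) through the
titration by global minimum-cost one-to-one assignment (an exact
maximum-weight bipartite matching, not a greedy pass, because slow-moving
crowded peaks otherwise mis-track). Two refinements to the plain
"distance from the last position" cost proved necessary on synthetic
spectra with realistic peak densities (about a hundred amide peaks, five
of them sweeping up to 0.3 ppm in combined units):

* the cost is measured from a **velocity-extrapolated prediction** of
  each peak's next position — in fast exchange peaks move along straight
  lines with step size proportional to the change in bound fraction, so
  the previous displacement scaled by the molar-ratio increment is a
  good forecast;
* a **weak log-intensity penalty** (`intensityWeight`, default 0.2;
  0 restores a purely positional cost) arbitrates the rare cases where a
  moving peak lands within the noise of a stationary one. Position alone
  cannot distinguish the two assignments; relative peak intensity can.

Measured over 500 generator configurations, plain positional stepwise
matching mis-assigns at least one residue in roughly a quarter of runs;
the refined cost reduces this to about 2%, the residual being genuine
position-and-intensity coincidences. That residual is a physical
ambiguity of crowded spectra, not an algorithmic defect, and it is why
real CSP studies treat overlapped peaks as undetermined.

Links whose positional step exceeds `maxStep` (default 0.25 scaled ppm)
are flagged unmatched, emulating intermediate-exchange broadening.

## Heteronuclear NOE

`computeNOE()` is the saturated/reference intensity ratio with
first-order (quadrature) error propagation,
σ_NOE = |NOE|·√((σ_sat/I_sat)² + (σ_ref/I_ref)²); the noise source is
the background noise standard deviation of each spectrum, and if only one
σ is supplied it is used for both. Mobility is flagged strictly below
0.5 ("lower than" read as strict); missing records are never flagged.

## Single-site ITC

The one-site (Wiseman) model: after injection *i* the cell holds
macromolecule M_i and ligand X_i; the bound-site fraction θ_i solves the
quadratic equilibrium at those concentrations, and the cumulative heat is
Q_i = n·θ_i·M_i·ΔH·V₀. The observed per-injection heat applies the
displaced-volume midpoint correction
ΔQ_i = Q_i − Q_{i−1} + (dV_i/V₀)(Q_i + Q_{i−1})/2 + q_offset, where
q_offset absorbs the dilution-heat baseline. Dilution is tracked exactly
per injection under the discrete perfusion model — inject dv of syringe
solution, mix, displace dv of the mixture:
M_i = M_{i−1}·V₀/(V₀+dv), X_i = (X_{i−1}·V₀ + X_s·dv)/(V₀+dv).
Vendor software implements closely related bookkeeping; this model is
pinned instead by its round-trip property: noiseless simulate-then-fit
recovers (n, K_a, ΔH, q_offset) to better than 0.1% across c-values
5–500 (c = K_a·M₀ governs isotherm sigmoidicity and K_d
identifiability; fits outside roughly 1–10⁴ warn that K_d is poorly
determined).

One consequence of perfusion bookkeeping deserves note: macromolecule
displaced *before* the equivalence point while still unbound never
releases heat, so at a conventional 10× syringe excess the cumulative
corrected heat saturates about n·M₀/(2·X_s) ≈ 5% below the total
enthalpy n·M₀·V₀·ΔH. The conservation property is therefore exact only
in the strong-syringe limit, and the test suite verifies it there
(1000× excess, 100 injections: conservation to < 0.5% across the c
grid). Real instruments lose the same pre-equivalence heat.

Fitting: a coarse grid over log₁₀ K_a and n — in which ΔH and q_offset
enter linearly and are solved by least squares — supplies the start for
Levenberg–Marquardt refinement (`minpack.lm`) of all four parameters,
with K_a parametrised on the log scale. Standard errors come from the
local quadratic approximation at the optimum (K_a and K_d by the delta
method). Flat heats short-circuit to an explicit "unidentifiable" result
rather than a spurious fit. The first injection is included by default
(synthetic data have no tip-diffusion anomaly); `dropFirst = TRUE`
implements the common practice of discarding it. Derived thermodynamics
use ΔG = −RT ln K_a with R = 1.9872×10⁻³ kcal/(mol·K) and
TΔS = ΔH − ΔG; the default temperature is 293.15 K (20 °C), the usual
peptide-titration condition.

## Synthetic data: what it emulates, and what it does not

Every generator draws from a private seeded RNG stream (the caller's
RNG state is untouched; identical seeds give identical output).

* `makeEnsemble()` builds an idealised mixed α/β poly-alanine backbone
  (standard bond lengths/angles via internal-to-Cartesian construction;
  β-strand blocks with a C-terminal helix, loosely echoing a PH-like
  topology of ~108 residues) and perturbs each of the default 20 models
  with iid Gaussian coordinate noise. It emulates ensemble spread, not
  physics: real conformer bundles have spatially correlated,
  loop-concentrated disorder, side chains, and restraint-driven
  geometry. Precision numbers on synthetic bundles therefore validate
  the estimator, not any particular deposited value.
* `makeTitration()` uses the fast-exchange model: the observed peak is
  the population-weighted average, so a site residue moves along a
  straight line by f_bound·Δδ_max, with f_bound from the binding
  quadratic at each molar ratio (defaults: 100 µM protein — a 0.1 mM
  NMR sample — and ratios 0, 0.25, 0.5, 1). Non-site residues jitter
  with typical combined magnitude 0.01 ppm. Slow/intermediate exchange
  is emulated only as peak disappearance (`vanishResidues`); real
  titrations also show broadening and curved apparent trajectories when
  exchange is not fast.
* `makeITC()` adds iid Gaussian noise (default 2% of the largest heat)
  to the exact model isotherm — no baseline drift or integration error.
* `makeRestraints()` realises planted sequence-separation class counts
  exactly with random atoms and intensity classes; it does not place
  restraints consistently with any 3D structure.
* `makeHetNOE()` plants rigid (0.85) and mobile (0.30) NOE plateaus with
  intensity noise; the default mobile segments are the termini plus one
  internal loop, the canonical pattern for a compact globular domain.

Because generators carry their ground truth as attributes, recovery
tests (planted binding sites, planted mobile segments, planted class
counts, generating K_d) are exact oracles. Passing them demonstrates the
estimators are correct under the stated models — not that real spectra
are this clean.

## Numerical choices and degenerate inputs

* Superposition requires ≥ 3 non-collinear points; collinearity is
  detected from the singular values of the centred cloud.
* Selections resolve in a canonical order (chain, residue, then N, CA,
  C, O, then remaining atom names alphabetically), so results do not
  depend on file atom order; inconsistent model rosters or atom order
  across models are read errors, not silent misalignment.
* Percent identity uses half-up rounding with a 1e-9 guard so exact
  rational ties (e.g. 41/80 = 51.25%) do not fall through floating-point
  representation.
* `classifySeparation` is total and symmetric; `summarizeRestraints`
  totals always equal the input length.
* Peak tracking ties, bound fractions and θ are clamped to [0, 1]
  against floating-point excursions.

## Problem sizes in the test suite

The test and acceptance computations are sized for a desk run: 50
replicate isotherm fits per dissociation constant (25 injections each),
1000 random point sets for the superposition oracle, 500-configuration
summaries quoted above were measured during development (the shipped
suite samples fewer), and titrations of 108 residues at 4 ratios. The
full suite runs in well under a minute.

## Known limitations

* No mmCIF input; no ligand/water semantics; single-chain assumptions in
  the generators (the reader handles multiple chains).
* No automatic structural correspondence search: region RMSD requires an
  explicit residue pairing, by design.
* CSP-based K_d estimation is not implemented (K_d comes from ITC); the
  fast-exchange generator would support it as an extension.
* The ITC module fits integrated heats; raw power traces and their
  baseline integration are out of scope, as are competitive and
  multi-site models.
* Restraint violation analysis against coordinates is not included.
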