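# phnmr

Comparative structural-NMR analysis of pleckstrin homology (PH) domains.

The PH domain of the TFIIH p62/Tfb1 subunit is the module through which
the general transcription machinery and nucleotide-excision-repair factors
dock onto TFIIH: acidic, intrinsically disordered segments of target
proteins bind its basic surface in extended conformation. Characterising
such a domain by solution NMR produces a recurring set of quantitative
analyses, and `phnmr` packages them for R users working with NMR
ensembles, HSQC titrations and calorimetric binding data:

- **Ensemble superposition and precision** — Kabsch least-squares rigid
  superposition, cross-structure RMSD over an explicit residue
  correspondence (backbone N, Cα, C, O or shared heavy atoms), and
  ensemble coordinate precision as the average RMSD of the models to
  their iteratively converged mean structure.
- **Region-restricted sequence identity** — global affine-gap alignment
  (Gotoh, deterministic tie-breaking) and percent identity over the
  aligned pairs of a region, the companion statistic to core-region RMSD.
- **NOE restraint bookkeeping** — sequence-separation classes
  (intraresidue, sequential |i−j| = 1, medium-range 1 < |i−j| < 5,
  long-range |i−j| ≥ 5), intensity-to-distance bins
  (strong 1.8–2.7 Å, 2.9 Å for HN; medium 1.8–3.3 Å, 3.5 Å for HN;
  weak 1.8–5.0 Å; very weak 1.8–6.0 Å), pseudo-atom upper-bound
  corrections, and Table-1-style summaries.
- **Chemical shift perturbation (CSP)** — titration peak tracking by
  global minimum-cost assignment, the combined amide shift change
  Δδ = √(Δδ_H² + (Δδ_N/5)²), and perturbed-surface calling with the
  strict Δδ > 0.100 ppm rule plus graded bins for structure colouring.
- **Heteronuclear ¹⁵N-{¹H} NOE** — intensity-ratio NOE values with
  first-order error propagation from spectral noise and mobile-residue
  flagging (NOE strictly < 0.5).
- **Single-site ITC** — simulation and Levenberg–Marquardt fitting of the
  one-site (Wiseman) isotherm. Cumulative heat after injection *i* is
  Q_i = n·θ_i·M_i·ΔH·V₀ with the bound fraction θ_i from the quadratic
  equilibrium solution at the post-injection cell concentrations; the
  observed heat applies the displaced-volume midpoint correction
  ΔQ_i = Q_i − Q_{i−1} + (dV_i/V₀)(Q_i + Q_{i−1})/2 + q_offset. Fits
  return n, K_a (K_d = 1/K_a), ΔH and the derived ΔG = −RT ln K_a,
  TΔS = ΔH − ΔG.
- **Synthetic-data generators** — seeded generators for every input
  class (coordinate ensembles with controlled jitter, fast-exchange
  titrations driven by a ground-truth K_d, noisy one-site thermograms,
  restraint lists with planted class counts, hetNOE profiles with
  planted mobile segments), so the entire pipeline is testable without
  external data.

## Worked example

Simulate a noisy peptide-into-protein ITC run at a typical VP-ITC design
(2 ml of 30 µM protein, 300 µM peptide syringe, 25 × 20 µl injections,
20 °C) with a ground-truth K_d of 52.1 nM, and fit it:

```r
library(phnmr)
run <- makeITC(params = bindingParams(n = 1, ka = 1e9 / 52.1, dh = -10),
               seed = 1)
fitSingleSite(run)
#> One-site ITC fit
#>   n       = 0.9994 +/- 0.0039
#>   Kd      = 48.17 nM (+/- 9.5)
#>   dH      = -9.983 kcal/mol (+/- 0.1)
#>   dG      = -9.815 kcal/mol;  TdS = -0.1684 kcal/mol
#>   c-value = 623; converged: TRUE
```

The fitted K_d (48.2 nM) recovers the generating 52.1 nM within its
standard error; ΔG comes from −RT ln K_a at 293.15 K and TΔS = ΔH − ΔG.

Map a binding surface from a synthetic fast-exchange titration and flag
flexible backbone segments from a hetNOE profile:

```r
tt <- makeTitration(kd = 52.1, siteResidues = c(20, 22, 45, 60, 92),
                    seed = 1)
callPerturbed(cspTable(trackPeaks(tt)))$perturbed
#> [1] 20 22 45 60 92

flagMobile(makeHetNOE(seed = 1))
#> [1]   1   2   3   4  64  65  66  67  68 104 105 106 107 108
```

Both calls recover exactly the planted ground truth: the five
binding-site residues exceed the Δδ > 0.100 ppm rule at the final 1:1
titration point, and the flexible termini plus the planted internal loop
sit below the NOE < 0.5 mobility cutoff.

Ensemble coordinate precision over a residue window, on a 20-model
synthetic bundle:

```r
ens <- makeEnsemble(nResidues = 108, nModels = 20, sigma = 0.35, seed = 1)
p <- ensemblePrecision(ens, atomSelection(resno = 4:102, atoms = "backbone"))
sprintf("%.2f +/- %.2f A", p$mean, p$sd)
#> [1] "0.59 +/- 0.01 A"
```

A command-line front end mirrors the R interface
(`inst/scripts/phnmr`, or `runPhnmr()` from R):

```sh
phnmr simulate itc --seed 1 --kd 52.1 --out runs/
phnmr itc-fit --in runs/itc.tsv --cell 30 --syringe 300 --v0 2
```

## Documentation

The methods vignette (`vignettes/phnmr-methods.Rmd`) describes the
models, the numerical choices, what the synthetic generators do and do
not emulate, and known limitations.
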