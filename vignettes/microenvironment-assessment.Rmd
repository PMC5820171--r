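---
title: "Functional assessment of predicted structures from site microenvironments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional assessment of predicted structures from site microenvironments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Structure prediction is usually scored globally: GDT_TS, TM-score and RMSD
summarize how well a model superposes onto the experimental structure as a
whole. But structures are solved to answer functional questions — does this
pocket bind its ligand, is this catalytic dyad intact, what does a mutation
do to its neighborhood — and global scores can be nearly blind to the few
residues that carry that information. `pocketsim` implements the
complementary, local view: it describes the *physicochemical
microenvironments* around functional-site centers and asks how similar the
site in a predicted model is to the site in the experimental structure,
independently of (and alongside) the global structural metrics.

## The descriptor

A **microenvironment** is the spherical region of radius 7.5 Å around a
**functional center** — a single side-chain atom or the mean of a small atom
set (e.g. `OG` for serine, the mean of `OD1`/`OD2` for aspartate, the ring
centroid for aromatics; glycine and unknown residues fall back to `CA`).
Within the sphere, 80 physicochemical properties are accumulated separately
over six concentric shells of width 1.25 Å, giving a 480-dimensional
descriptor (index = shell × 80 + property, shell-major). Shells are
half-open `[k·w, (k+1)·w)`, so every heavy atom inside the sphere is counted
exactly once; hydrogens are ignored so that experimental structures and
server models (which rarely include them) featurize comparably, and hetero
atoms are excluded so a bound ligand cannot leak into the comparison of a
holo experimental site with apo predictions.

Each property rule is a function of atom and residue identity and scalar
per-atom attributes only — never of absolute orientation — which makes the
descriptor rigid-motion invariant by construction (asserted to 1e-9 in the
tests). The default manifest (`default_manifest()`) draws its 80 rules from
documented families: residue-type counts (20), element counts C/N/O/S (4),
charge-class counts and a net formal-charge sum (4), a Kyte–Doolittle
hydropathy sum (1), hydrogen-bond donor/acceptor counts (2), aromatic-ring
atom count (1), backbone/side-chain counts (2), B-factor and occupancy means
(2), residue-class counts (8), functional-group counts (6), a
backbone-dihedral secondary-structure proxy (3), and 27 named-atom counts.
The exact composition of the original 80-property set is not public; the
manifest is therefore *data, not code* — any 80-rule manifest satisfying the
same invariants (unique names, count/sum/mean kinds, orientation-free
extractors) is admissible, and it serializes to JSON. The
secondary-structure proxy is computed from φ/ψ bins rather than an external
assignment tool so that the test path needs no binaries.

## Standardization and the similarity score

Raw descriptor dimensions live on wildly different scales, so they are
z-scored per dimension against a background pool of microenvironments
(`build_background()`), using the *population* standard deviation —
the same convention as the ensemble z-scores below. Dimensions with zero
variance in the pool carry no information and standardize to zero; they are
dropped from the retained set rather than erroring, unless the caller pins
them explicitly (a pool where *every* dimension is degenerate is an error).

Two standardized microenvironments are compared with a binary **Tanimoto**
coefficient: bit *i* is set when `z_i > 1.0` (one background SD above
typical), and `T = |A∩B| / |A∪B|`, with `T = 0` for an empty union. A
continuous min/max variant on the rectified excesses is available behind
`mode = "continuous"` for sensitivity analysis; the binary form is the
default because it is the canonical Tanimoto and robust to heavy-tailed
dimensions. The raw coefficient is then calibrated per chemistry class:
random same-class center pairs from the background pool give `μ_T` and
`σ_T`, and a pair scores

```
score = −(raw_T − μ_T) / σ_T
```

so that **more negative = more similar than background** (the sign
convention of the functional z-scores downstream). Only *same-class* pairs
are permissible — comparing a carboxylate microenvironment to an aromatic
one is chemically meaningless and would only add noise to the matching.

## Site alignment

Two sites (clusters of centers) are aligned by a greedy mutual-best-match:
all permissible pairs are scored exhaustively, the globally most negative
remaining pair is accepted while it scores at or below the significance
cutoff (default −0.5), and both centers are retired. The site similarity
(`pf score`) is the sum of accepted pair scores. Ties are broken
deterministically and symmetrically (unordered index pair, then sorted label
pair), so `align_sites(A, B)` and `align_sites(B, A)` agree. The greedy
matcher is pinned against a naive exhaustive-scan oracle on all small cases
in the test suite. Total scores are *not* normalized by site size: the
pipeline only ever compares models within one site, never across sites.

The −0.5 cutoff is a configuration surface (the original choice is not
public); the calibration guidance is to choose it so that at most ~5% of
random background pairs pass.

## Structural companions

`kabsch_superpose()` (SVD least squares with the proper-rotation
determinant fix), `gdt_ts()`, `tm_score()` and `local_rmsd()` provide the
structural side of the functional-vs-structural comparison. GDT_TS searches
superpositions seeded from contiguous fragments (lengths 3/5/7 and
full-length) with iterative distance-cutoff extension; for chains of ≤ 8
residues it seeds from *all* 3-subsets, which makes it exhaustive on the
toys the tests pin against an all-subsets oracle. TM-score uses
`d0 = 1.24·(L−15)^⅓ − 1.8` clamped below at 0.5 (the short-chain
convention) and, because its optimum is a continuous rotation problem
rather than an RMSD subset problem, polishes the best fragment-seeded
candidates directly against the TM objective. These are stand-ins for the
official assessment programs: they reproduce ranking behavior (and the
small-case oracles exactly), not archived evaluation numbers bit-for-bit.
Residue correspondence is by author numbering throughout — the convention
of prediction servers indexing the target sequence — not by sequence
alignment.

## Ensemble assessment

`score_ensemble()` aligns the experimental site against the corresponding
centers of every model; models missing more than half the site residues are
excluded and reported (the 50% tolerance is configurable; the original
procedure is silent on partially unmodeled sites). `zscore_records()`
normalizes the pf scores within an evaluation set — either **all models**,
or **model-1** only (each predictor's self-declared best) — to mean 0, SD 1
(population SD). Ranks are dense 1..N with deterministic
(source, model-index) tie-breaks, and functional-vs-structural agreement is
measured with Spearman's rank correlation (Pearson on average ranks; the
original statistic for "correlation between rankings" is unstated, and
Spearman is the conservative reading). The selection rules mirror the
published procedure literally: models are kept when global RMSD ≤ 5.0 Å
(boundary inclusive) and a site is eligible when *strictly more than* 10
predictions survive; top-30 selection takes the most negative functional
z-scores first.

Exposure classification is a total function of relative solvent
accessibility with thresholds 0.09 and 0.36: buried below 0.09,
intermediate on the half-open band `[0.09, 0.36)`, exposed at or above
0.36 — the only reading of these published thresholds that actually
partitions the range. Accessibility and secondary-structure
labels are *consumed as inputs* (`variant_site_metrics()`): computing them
is the job of established tools and out of scope here.

## What the synthetic generator emulates — and what it does not

Real inputs for this analysis are prediction-archive ensembles, which are
not redistributable at desk scale. The generator therefore builds a stated
world with the statistical structure the analysis assumes:

* a solenoidal backbone (ideal 3.8 Å Cα spacing) whose interior channel is
  a genuine concavity; site residues point their side-chain proxies into it;
* a sequence whose composition is balanced over the ten chemistry classes
  (a fixed 20-residue block cycled and seeded-shuffled), so background
  calibration always has ≥ 2 centers per class;
* optionally a 4-atom ligand placed in the channel with minimum protein
  distance in [2.5, 4.5] Å, so holo-site extraction at 5 Å is well posed;
* decoys with i.i.d. per-coordinate Gaussian noise: a global component on
  every atom plus an independent local component on site-residue atoms.
  Servers of five models each carry graded base levels, with model 1 the
  least noisy (predictors know their best model); *anti-coupled* injections
  — maximal global noise, zero local noise — are drawn from non-model-1
  slots and create the "good site in a bad model" second mode.

Defaults (60 residues, 50 models, σ_global = σ_local = 2.0 Å, site of 8,
seeded) were fixed before any acceptance outcome was observed. A green test
on this world establishes that the pipeline recovers controlled, separable
degradation — not that it reproduces archived evaluation numbers, which
would require the external prediction data, and not that Gaussian decoys
resemble template-based models (they have no rotamer structure, no
compactness constraint and no physical plausibility).

## Numerical choices

* population SD everywhere a z-score is formed; zero variance is an error,
  not a silent NaN — it surfaces degenerate ensembles;
* shell boundaries lower-inclusive; distances ≥ 7.5 Å are outside;
* empty shells contribute 0 to mean-kind properties;
* altlocs reduced to the highest-occupancy conformer (ties → 'A');
  first MODEL only of multi-model files, with a warning;
* Tanimoto of an empty union is 0 by convention;
* greedy matching tie-breaks are mirrored under argument swap;
* all generator randomness flows through one seed and never disturbs the
  caller's RNG stream.

## Known limitations

* The 80-property manifest is a documented stand-in; absolute pf values are
  not comparable to other implementations (within-ensemble *rankings* are
  the supported quantity).
* GDT/TM here are search heuristics with small-case oracle guarantees; on
  large chains they may differ from official implementations in the third
  digit.
* No mmCIF, no biological assemblies, no NMR multi-model ensembles; no
  de-novo pocket finding (sites are inputs); no conservation metrics.
* Solvent accessibility is never computed, only consumed.

## A minimal session

```{r example}
library(pocketsim)

ens <- generate_ensemble(ensemble_config(n_residues = 60, n_models = 25,
                                         anti_coupled_fraction = 0.2,
                                         with_ligand = TRUE, seed = 7))
cen <- centers_from_residues(ens$reference, residue_table(ens$reference))$centers
ap  <- atom_properties(ens$reference)
vecs <- lapply(seq_len(nrow(cen)), function(i)
  featurize(ap, c(cen$x[i], cen$y[i], cen$z[i])))
bg  <- build_background(vecs, cen$chem_class, n_pairs = 200, seed = 7)

rec <- score_ensemble(ens$reference, ens$site, ens$models, bg)
z   <- rank_by(rank_by(zscore_records(rec, "all_models"), "pf_zscore"), "gdt_ts")
spearman_rho(z$rank_functional, z$rank_structural)
```
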