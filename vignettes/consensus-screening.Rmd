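---
title: "Consensus ADMET screening: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ADMET screening: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dadmet)
```

## The model

Free chemoinformatics platforms predict overlapping but non-identical
sets of molecular descriptors and ADMET endpoints, and their predictions
disagree — slightly for molecular weight, substantially for LogP, where
fragment-based and machine-learned estimators can differ by more than a
log unit on the same molecule. The screening model implemented here
treats the platform ensemble as the predictor:

* For a **numeric descriptor**, the consensus estimate is the arithmetic
  mean over the platforms that report it. Platforms that do not compute
  a descriptor are simply absent from the average — there is no
  imputation. The underlying assumption is that platform errors are
  roughly independent and centred, so averaging cancels them; this is
  borne out by the validation tables, where consensus MW agrees with
  reference values to RMSE 0.23 g/mol over 63 approved drugs, and by the
  Monte-Carlo tests in this package, where consensus error shrinks
  monotonically with platform count. LogP is the known weak point: the
  all-platform consensus correlates with experiment at only r = 0.645,
  and the mean of the two platforms that validated best (Molinspiration
  and Molsoft) does better, r = 0.750 — hence `logp_two_platform()` and
  the `logp_mode` config switch. The assumption of neutral species is
  inherited from the platforms; no ionisation correction is attempted.

* For a **qualitative endpoint**, the consensus call is the strict
  plurality of the non-missing platform calls. On a tie, the vote is
  repeated restricted to the tie-break platforms — by default
  AdmetLab 3.0, Deep-PK and admetSAR 3.0, the platforms with the most
  recently updated models — and if still tied, the first configured
  tie-break platform wins and the result carries a `tie_broken` flag.
  Consensus calls that required any tie handling are therefore always
  identifiable downstream.

## Scoring and selection

Five category scores summarise a compound (maxima 7 / 4 / 5 / 1 / 4):
druglikeness is the sum of six rule filters (pass = 1, a single Lipinski
violation = 0.5, fail or MDDR mid-structure = 0) plus the continuous QED
value; medicinal chemistry counts passes of Leadlikeness, GSK, PAINS and
Brenk; bioavailability adds three permeability calls (high = 1,
moderate = 0.5, low = 0) to a P-gp substrate/inhibitor combination score
(no/no = 2, no/yes = yes/yes = 1, yes/no = 0 — a substrate that is not
also an inhibitor is effluxed most efficiently, so it is the worst
case); distribution passes only on a low plasma-protein-binding call
(only the unbound fraction is pharmacologically active); toxicity counts
favourable calls over Ames, carcinogenicity, hERG and hepatotoxicity.
Clearance is parsed and reported but never scored: its predictions
failed validation against experimental data (sensitivity 0.07), and
blood–brain-barrier penetration is out of scope entirely.

The minimum acceptable scores are 3.501, 2, 2.51 and 2.01, applied with
`>=`. They bracket "half the maximum" but are used exactly as published
rather than recomputed from that phrase, because the published tables
are the authority and medicinal chemistry demonstrably admits exactly
50% (compounds with 2 of 4 passes are accepted). Likewise the selection
rule is implemented as **at least** 3 of 5 criteria, because the
published selection includes 60% compounds.

Two open points in the source material were resolved as follows and are
deliberate package choices:

* The MDDR-like rule's intermediate class is not defined explicitly
  anywhere in the source tables; this package uses the three-band
  reading of the original rule set: drug-like iff nRings ≥ 3 and
  nRigidB ≥ 18 and nRB ≥ 6, nondrug-like iff nRings ≤ 2 and nRigidB < 18
  and nRB < 6, and `mid_structure` otherwise.
* The per-platform numeric cutoffs behind high/moderate/low permeability
  classes are not published; `classify_quantitative()` applies
  user-supplied two-point cutoffs from the config, and the fixture-driven
  path bypasses the mapping entirely.

## Rule filter thresholds

The rule filters follow the cited originals as implemented by the
SwissADME conventions under which the reference tables were produced:
Lipinski MW ≤ 500, LogP ≤ 5, donors ≤ 5, acceptors ≤ 10 (one failed
condition is reported as `one_violation`); Ghose 160 ≤ MW ≤ 480,
−0.4 ≤ LogP ≤ 5.6, 40 ≤ MR ≤ 130, 20 ≤ nAtoms ≤ 70; Veber nRB ≤ 10,
TPSA ≤ 140; Egan LogP ≤ 5.88, TPSA ≤ 131.6; Muegge 200 ≤ MW ≤ 600,
−2 ≤ LogP ≤ 5, TPSA ≤ 150, rings ≤ 7, carbons > 4, heteroatoms > 1,
nRB ≤ 15, acceptors ≤ 10, donors ≤ 5; Leadlikeness 250 ≤ MW ≤ 350,
LogP ≤ 3.5, nRB ≤ 7; GSK MW ≤ 400, LogP ≤ 4. All boundary comparisons
are inclusive; no boundary cases occur in the reference tables, so this
is a convention, chosen to match how these filters are usually stated.

QED is the weighted geometric mean of eight asymmetric-double-sigmoid
desirability functions with the published parameter and weight set,
normalised by the weight sum (so rescaling all weights is a no-op). The
implementation was checked against an independent implementation of the
same published parameterisation to 10⁻⁹.

Native descriptor computation (for users starting from SMILES/SDF rather
than platform exports) goes through OpenBabel via ChemmineR: Ertl
fragment TPSA, Crippen-type atom-contribution LogP — which should be
regarded as one more "platform", not a mimic of any specific server —
N+O acceptor counts, donor-atom counts, and rigid bonds defined as
heavy-atom bonds minus rotatable bonds. The atom-count convention is
all-atom by default (the Ghose window is defined on all atoms) and
switchable to heavy-only.

The shipped PAINS and Brenk catalogs are **curated subsets** of the
published catalogs (10 and 23 hand-written SMARTS for the prominent
chemotype classes), clearly labelled as such in the data files, and any
full catalog file can be supplied through the config. Screening
decisions based on the packaged subsets are conservative in one
direction only: they can miss alerts a full catalog would flag, never
invent them.

## Validation layer

The regression metrics use divisor N exactly as defined in the model
equations (a config flag exposes the N−1 variant, since commercial
statistics packages differ); RMSE of the mean-only baseline predictor
provides the reference point, and model quality is reported as the
fractional improvement 1 − RMSE/RMSE_baseline. The Pearson r and its
square are reported separately from the coefficient-of-determination R²
(which can be negative for a bad model); regression direction is
selectable because the reference analysis regressed reference-on-
predicted for MW/TPSA/MR but predicted-on-experimental for LogP.
Confusion matrices exclude and count rows lacking experimental data;
when a class is absent, the corresponding rate is `NA`, never 0/0.

Enrichment uses n_top = ⌊x·N⌋ (332 compounds at 10% give a top set of
33), with ties in the ranking score broken by stable input order — the
tie rule used by the original ranking is unknown, so the deterministic
choice is documented here. ROC-AUC is the Mann–Whitney pair probability
with ties counted ½, making it invariant under monotone score
transforms. Pose RMSD is computed over heavy atoms without
superposition, minimised over all element-preserving graph isomorphisms
(igraph VF2), so topologically equivalent atoms — a flipped phenyl, a
rotated benzene — cannot inflate the deviation; the band boundary 3.0 Å
is assigned to "shifted", reading "between 2.0 and 3.0" inclusively.

For the inferential layer, the Welch test delegates to `stats::t.test`
(equal variances not assumed) and the KS statistic is computed natively
so both signed suprema D⁺ and D⁻ are available; its two-sided p uses the
asymptotic Kolmogorov series at effective sample size n₁n₂/(n₁+n₂),
clipped to [0, 1] — matching the convention under which published
two-sample tables report p = 1.000. The degenerate case of two constant,
equal samples returns t = 0, p = 1 by convention.

## The synthetic generators

`sim_config()` / `gen_*()` emulate every input the pipeline consumes,
so all modules are testable without network access. Descriptor truth
values are drawn uniformly from the confidence intervals estimated for
screen-passing approved kinase inhibitors (e.g. MW in [416.81, 461.47]
g/mol, LogP in [2.62, 3.49]); per-platform noise is Gaussian with
standard deviations chosen once to resemble the observed cross-platform
spread (tight for MW at 0.1, loose for LogP at 0.5, integer counts left
exact — platforms rarely disagree on counts); cells go missing at a
configurable (optionally per-platform) rate. Qualitative calls equal a
latent truth with probability 1 − flip rate, else a uniform other
category. Docking sets draw active scores N(δ, 1) against decoy N(0, 1)
with the 30-active/302-decoy benchmark layout as default.

Gaussian noise and uniform flips are chosen for analyzability, not
realism: real platform errors are correlated (shared training data),
endpoint-dependent and sometimes systematic (one platform computes TPSA
differently by design). Passing the Monte-Carlo tests therefore shows
the estimators behave correctly under independent noise — it does not
certify performance on real platform outputs, which is what the packaged
reference tables are for.

## Numerical conventions

Count-valued consensus descriptors are rounded half-up (the reference
tables print integers for counts); continuous values are carried at full
precision internally and only rounded for display (CSV reports default
to 3 decimals, JSON keeps full precision). Majority votes are invariant
to platform column order except through the configured tie-break list.
Screening is exact rational arithmetic on {0, 0.5, 1, 2} plus QED, so
reproducing the reference scores is bit-exact, not approximate.

## Problem sizes in the shipped tests

The test suite exercises the reference tables at full printed size
(63 drugs, 29 studied compounds, 332-record docking sets) and uses
simulation sizes of 300–1500 compounds, 2–8 platforms, 2000 interval-
coverage replicates and 10⁴ Welch null replicates — sizes chosen so the
whole suite completes in a few minutes on one CPU while keeping
Monte-Carlo standard errors well below the asserted tolerances.

## Known limitations

* The screen never re-predicts platform endpoints from structure; it
  aggregates what the platforms said. Native descriptor computation
  covers the physicochemical layer only.
* Shipped alert catalogs are subsets (see above).
* No BBB, skin permeability/sensitisation or ecological toxicity
  endpoints; clearance is reported but unscored.
* The two-sample comparisons (Welch, KS) for real compound sets require
  the user to supply both descriptor vectors; the package does not
  reconstruct unpublished per-compound appendix data.
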