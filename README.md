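# dadmet

Consensus-based druglikeness and ADMET screening of small molecules.

## The problem

Free ADMET prediction platforms (SwissADME, AdmetLab, pkCSM-style servers,
and the like) disagree with each other — mildly on molecular weight,
wildly on LogP — and no single one is reliable across every endpoint.
`dadmet` implements a screening method that treats the platforms as an
ensemble instead of trusting any one of them:

* **numeric descriptors** (MW, TPSA, MR, LogP, rotatable bonds, ...) are
  combined as the arithmetic mean over the platforms that report them;
* **qualitative ADMET calls** (Caco-2/HIA/MDCK permeability classes,
  P-gp substrate/inhibitor, PPB, Ames, carcinogenicity, hERG,
  hepatotoxicity) are combined by majority vote, with ties resolved by a
  configurable subset of most-recently-updated platforms.

Each compound is then scored on five criteria:

| category          | ingredients                                                   | max | pass at |
|-------------------|---------------------------------------------------------------|-----|---------|
| druglikeness      | Lipinski, Ghose, Veber, Egan, Muegge, MDDR-like (+ QED value) | 7   | ≥ 3.501 |
| medicinal chem.   | Leadlikeness, GSK, PAINS, Brenk                               | 4   | ≥ 2     |
| bioavailability   | Caco-2 + HIA + MDCK + P-gp substrate/inhibitor combination    | 5   | ≥ 2.51  |
| distribution      | plasma protein binding                                        | 1   | low PPB |
| toxicity          | Ames, carcinogenicity, hERG, hepatotoxicity                   | 4   | ≥ 2.01  |

with pass = 1, fail = 0, a single Lipinski violation = 0.5, and the
P-gp pair scored as combo(no,no) = 2, combo(no,yes) = combo(yes,yes) = 1,
combo(yes,no) = 0. A compound is **selected** when it passes at least
3 of the 5 criteria (60%).

The package also carries the validation toolkit for such a screen:

* paired regression metrics — RMSE = √(Σ(yᵢ−ŷᵢ)²/N), MAE, R², and the
  baseline RMSE of the mean-only predictor, with the improvement
  fraction 1 − RMSE/RMSE_baseline;
* OLS fits with 95% coefficient confidence intervals;
* confusion-matrix metrics SE = TP/(TP+FN), SP = TN/(TN+FP), ACC, with
  rows lacking experimental data excluded and counted;
* virtual-screening enrichment factor
  EF(x%) = (actives_x%/dataset_x%) / (actives_total/dataset_total) and
  Mann–Whitney ROC-AUC;
* symmetry-aware docking pose RMSD (minimised over graph isomorphisms)
  with the usual quality bands (< 2 Å consistent, 2–3 Å shifted,
  > 3 Å inaccurate);
* mean confidence intervals, Welch t and two-sample Kolmogorov–Smirnov
  tests for comparing compound sets.

Reference tables from a published validation study on 63 FDA-approved
tyrosine kinase inhibitors and 29 literature TKI candidates ship as
plain-text fixtures (`load_fixture()`), so the whole pipeline is
reproducible offline.

## Worked example

```r
library(dadmet)

scr <- admet_screen(load_fixture("table6_druglikeness"),
                    load_fixture("table7_medchem"),
                    load_fixture("table8_bioavailability"),
                    load_fixture("table9_distribution"),
                    load_fixture("table10_toxicity"))
summary(scr)
```

```
Consensus ADMET screen of 63 compounds
Passes per category:
   druglikeness         medchem bioavailability    distribution        toxicity
             52              43              39              26              21
Hit distribution (criteria passed):
 1  2  3  4  5
 8 16 22 10  7
Selected (>= 3/5): 39
```

Of the 63 approved drugs, 52 clear the druglikeness threshold, only 26
are predicted low-PPB, and 39 pass at least three of the five criteria —
the screen keeps a comfortable majority of approved drugs while still
discriminating (distribution and toxicity are the most-violated
categories, as expected for kinase inhibitors).

Validating one endpoint model against experimental data:

```r
t14 <- load_fixture("table14_admet_expvspred")
confusion(t14$herg_exp, t14$herg_pred, positive_label = "positive")
```

```
<classification_report> n = 13 (50 excluded, no exp. data)
  TP 5  FP 2  TN 5  FN 1
  SE 0.833  SP 0.714  ACC 0.769
```

A command-line front end is installed at
`system.file("cli", "dadmet.R", package = "dadmet")` with subcommands
`screen`, `validate`, `docking-eval`, `simulate` and `stats`.

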