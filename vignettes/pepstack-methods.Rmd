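---
title: "Stacked ensemble peptide bioactivity prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensemble peptide bioactivity prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Short peptides (roughly 3–60 residues) can inhibit enzymes such as
tyrosinase, the rate-limiting enzyme of melanin synthesis; finding new
inhibitory peptides by wet-lab screening is expensive, so a classifier
that ranks candidate peptides by predicted activity is a practical
pre-filter.  `pepstack` implements a two-level *stacked ensemble* for
this binary task.

**Level one — a baseline model zoo.**  Each peptide is encoded by ten
descriptor families: six sequence descriptors — amino acid composition
(AAC, 20-D), dipeptide composition (DPC, 400-D), dipeptide deviation
from expected mean (DDE, 400-D), pseudo and amphiphilic pseudo amino
acid composition (PAAC 21-D, APAAC 22-D) and physicochemical property
means (PCP, 11-D) — and four keyed substructure fingerprints computed
on the peptide's SMILES structure (Estate 79, FP4 307, MACCS 166,
PubChem 881 bits).  Thirteen learning algorithms (AdaBoost, decision
tree, extremely randomized trees, k-nearest neighbours, leaf-wise
histogram gradient boosting, logistic regression, multilayer
perceptron, naive Bayes, PLS, random forest, linear and RBF SVMs,
depth-wise gradient boosting) are crossed with the ten encoders, giving
130 baseline models under the defaults.  Nine algorithms carry
hyperparameter grids (tree/round counts {20, 50, 100, 200, 500}; LR
cost {0.001…100}; linear-SVM cost 2^0…2^5; RBF-SVM cost 2^-4…2^4; MLP
hidden sizes {20…500}) tuned by stratified cross-validated Matthews
correlation coefficient (MCC); DT, KNN (k = 5), NB and PLS (2
components) use fixed defaults.

**Level two — probabilistic features and the PLS meta-model.**  For
the training set, every baseline produces *out-of-fold* predicted
positive-class confidences under one shared stratified k-fold
partition (default k = 10): the model scoring sample *i* never saw
*i* during fitting.  The resulting samples × baselines matrix is the
probabilistic feature vector (PFV).  A genetic algorithm
(`select_features()`) searches for a small informative subset of PFV
columns — chromosomes carry one inclusion bit per column plus a
parametric gene (the PLS component count), fitness is stratified
k-fold CV MCC, and the selected count is repaired into
[m_start, m_end] = [5, 20] with mutation probability 0.05 and
population 50.  A univariate partial-least-squares regression of the
0/1 labels on the selected columns, thresholded at 0.5 (ties
positive), is the final classifier.  For new peptides the baselines
are refitted on the full training data and their confidences feed the
same meta-model; screening ranks candidates by meta confidence after
an inclusive length filter (default 10–57 residues) and exact
deduplication.

## Assumptions

* Inputs are linear peptides over the 20 standard amino acids;
  non-standard residues (B, J, O, U, X, Z) are rejected (strict mode)
  or dropped with a warning (lenient mode).  Sequences are
  case-normalised before validation.
* Labels are binary and exact duplicate sequences are uninformative;
  duplicates with conflicting labels are removed entirely.
* Out-of-fold construction assumes samples are exchangeable within a
  class; there is no grouping structure (e.g. homologous clusters)
  that the fold assignment should respect.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 10 | folds of the OOF PFV construction and all CV scoring |
| `tune_k` | `k` | folds of the inner hyperparameter search |
| `lambda`, `w` (PAAC/APAAC) | 1, 0.05 | sequence-order rank and weight; `lambda = 1` is forced by the 21/22-D layout, `w = 0.05` is the conventional default of the descriptor family |
| GA `m_start`, `m_end` | 5, 20 | bounds on the selected PF count |
| GA `p_m`, `pop` | 0.05, 50 | per-gene mutation probability, population |
| GA `generations`, `stagnation` | 100, 20 | budget and early stop |
| `threshold` | 0.5 | meta decision threshold (ties positive) |
| screening `length_bounds` | 10–57 | inclusive candidate length window |

All seeds are explicit arguments; identical seeds reproduce fold
partitions, tuning decisions, PFV matrices and GA trajectories
exactly.

## Design choices where the design was open

* **Tuning protocol.**  Baseline grids are tuned by stratified k-fold
  CV (default 10-fold, matching the evaluation protocol), maximising
  pooled MCC; ties pick the first (smallest) grid value.
  Hyperparameters are re-tuned *inside* each PFV fold by default so no
  tuning decision sees held-out labels; `tune_per_fold = FALSE`
  trades this guarantee for speed.
* **One shared fold partition** across all baselines: PFV rows are
  only comparable if every column's out-of-fold status refers to the
  same partition.
* **Metric aggregation** is pooled over concatenated out-of-fold
  predictions (one report per model), not averaged per fold; the
  report records the protocol tag.
* **Degenerate metrics**: MCC, Sn and Sp with zero denominators are
  reported as 0, so broken models rank poorly instead of crashing; AUC
  uses midranks, so a constant scorer gets exactly 0.5.
* **Confidence mappings**: SVMs use Platt-style probability
  calibration fitted by the SVM backend within the training data; PLS
  responses are clipped to [0, 1]; boosting margins are mapped
  affinely from [-1, 1].  These are monotone, so AUC-based conclusions
  are unaffected by the mapping.
* **GA operator suite** (tournament size 3, uniform crossover, elitism
  1, repair by random flips toward the nearer bound, fitness cache
  keyed by chromosome, shared fitness folds per run): a conventional
  suite fixed once; every choice is recorded in the `ga_config`
  object.  Ties in the final selection prefer fewer features, then the
  lexicographically smaller mask.
* **PLS meta component count** is the GA's parametric gene (1–8); when
  feature selection is skipped the count is chosen by CV MCC over
  1…min(8, m).
* **PCP scales.**  The 11 shipped per-residue scales (hydrophobicity,
  hydrophilicity, side-chain mass, volume, polarity, polarizability,
  isoelectric point, net charge index, helix and sheet propensity,
  flexibility) are standard published scales; the encoder contract is
  "mean of 11 per-residue scales", and any user TSV can replace the
  default table.
* **Gradient boosting backends.**  Both boosted-tree learners run on
  the xgboost backend; the LGBM entry uses leaf-wise (lossguide)
  histogram growth — the strategy that defines light gradient
  boosting — with 31 leaves, and the XGB entry uses the default
  depth-wise growth.  AdaBoost is implemented in-package (SAMME over
  decision stumps) because no installed R package provides it.
* **PLS implementation.**  The NIPALS PLS1 core is implemented
  in-package (it is the heart of the meta-model and of the GA fitness
  loop, where it is fitted hundreds of thousands of times) and is
  verified against an independent PLS implementation to 1e-10 in the
  test suite.

## Peptide SMILES and the synthetic fingerprint key sets

SMILES are assembled from per-residue templates
(`N[C@@H](side)C(=O)` joined head-to-tail, free N-terminal amine, free
C-terminal acid), with L-configuration α-carbons (Ile/Thr also carry
their β-centre); `stereo = FALSE` strips stereocentres.  The builder
satisfies an exact mass balance — molecular weight equals the sum of
free residue masses minus (L−1) × 18.01528 Da — which the test suite
checks against the OpenBabel backend to 0.01 Da.

The reference key definitions of the four fingerprint families are
third-party data files that cannot be redistributed, so the shipped
dictionaries are **synthetic key sets**: generated in code at the
exact published dimensions from a head of genuine functional-group
SMARTS (amine, carboxylic acid, amide, thiol, guanidine, imidazole,
indole, …) followed by systematic atom-type, element-count and
bonded-path patterns.  Bit semantics (presence/absence of a named
substructure, some with count thresholds) and dimensions match the
reference families; individual bit definitions do not, so absolute
bit patterns are not comparable with CDK/PubChem fingerprints of the
same name.

## What the synthetic data generator emulates — and what it does not

`synth_peptides()` draws residues i.i.d. within each sequence:
negatives uniformly over the 20 residues, positives from a blend of
the uniform distribution with an enrichment map (Cys, Tyr, Arg, Phe
boosted ×3, Trp, Met ×2; Asp, Leu, Pro ×0.3) at signal strength `s`.
This mirrors the compositional contrast reported between tyrosinase
inhibitory and inactive peptides (Cys/Tyr/Arg/Phe and hydrophobic
residues enriched in actives, Asp/Leu/Pro depleted).  Lengths are
uniform on 5–25, inside both the typical inhibitory-peptide range and
the screening window.  An optional first-order repeat process
(`markov_order = TRUE`) adds dipeptide-level order signal so DPC/DDE
have something beyond composition to detect.

The generator is deliberately *not* a biophysical simulator: real
peptide datasets have positional motifs, length–activity confounding,
homology clusters and label noise, none of which are modelled.
Passing the property suites therefore demonstrates that the pipeline
machinery (encoders, tuning, out-of-fold stacking, selection,
evaluation) behaves correctly under a known signal — it does not
certify real-data performance, which depends on the training corpus.

`synth_planted_pfv()` emulates the stacking layer directly: uniform
pseudo-confidences with `n_informative` columns shifted by ±`shift`
toward the label, used to measure whether the GA recovers known
informative columns.

## Problem sizes used by the shipped suites

The test and acceptance runs use reduced architectures (3 sequence
encoders × 4 fast learners, 12 baselines) and synthetic tasks of
100–300 samples; the GA recovery suite runs the full published GA
parameterisation (130 columns, population 50, 60 generations, 5
seeds).  These sizes make the whole suite reproducible on a single
CPU in minutes while still exercising every code path; the package
itself scales to the full 130-baseline architecture, whose cost is
dominated by per-fold grid tuning of the slower learners (MLP,
AdaBoost, SVMs on 881-bit fingerprints).

## Known limitations

* Exact-duplicate removal is the only redundancy control; no
  clustering-based homology reduction is provided, so CV estimates on
  homology-rich data will be optimistic.
* The fingerprint key sets are synthetic stand-ins (see above).
* Cyclic, modified or D-amino-acid peptides are out of scope for the
  SMILES builder.
* No probability calibration is applied to the meta output; the 0.5
  threshold is a ranking convention, not a calibrated decision rule.
* Performance numbers published for the original tyrosinase-inhibitor
  corpus are not reproducible here because that corpus is not
  shipped; the package's own suites measure structural and behavioural
  properties on synthetic data instead.
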