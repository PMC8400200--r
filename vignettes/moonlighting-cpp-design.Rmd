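---
title: "Designing moonlighting cell-penetrating peptides with moonpep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing moonlighting cell-penetrating peptides with moonpep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moonpep)
```

## The problem

Cell-penetrating peptides (CPPs) internalize into most cell types
indiscriminately. Selectivity can be engineered by *targeting* (embedding a
receptor ligand, e.g. the yeast α-pheromone that binds the Ste2p receptor on
MATa cells) or by *activation* (appending residues that silence the CPP until
a protease — here neprilysin/CD10, which cleaves FFGFLA after the G —
removes them). Doing this by fusing whole extra domains enlarges the peptide;
the moonlighting approach instead adds a handful of residues around a fixed
motif and lets a sequence classifier decide when the composite behaves as a
CPP (or stops behaving as one). moonpep is that loop: featurize, classify,
search.

## The descriptor layer

Every peptide is represented by 27 numbers in a fixed order
(`featureNames()`):

| slots | descriptor | default machinery |
|---|---|---|
| 1–20 | residue counts, alphabetical one-letter order | raw counts (a `normalizeCounts` flag divides by length, off by default) |
| 21 | mean hydrophobicity | Eisenberg consensus scale (standardized AAindex form) |
| 22 | mean charge | Henderson–Hasselbalch net charge at pH 7 / length |
| 23 | isoelectric point | bisection on [0, 14], tolerance 1e-4 pH units |
| 24 | sliding-window range of net charge | width 11, step 1 |
| 25 | sliding-window range of hydrophobic moment | δ = 100°/residue, per-residue normalization |
| 26 | octanol–water partition sum | additive Fauchère–Pliška side-chain values |
| 27 | helical content | Chou–Fasman helix-former fraction (Pα ≥ 1) |

Assumptions and numerical choices, in the order a reviewer usually asks:

* **Charge model.** Fractional Henderson–Hasselbalch charges over the
  ionizable side chains (basic H, K, R; acidic C, D, E, Y) with the EMBOSS
  pKa set. Backbone termini are *excluded by default*: the designed peptides
  this package models are typically N-terminally conjugated to a fluorophore
  label, which removes the free α-amine; `includeTermini = TRUE` restores
  both groups.
* **Isoelectric point.** Net charge is monotone non-increasing in pH, so
  bisection is safe. Peptides with no acids (or no bases) have no root; the
  bracket endpoint with the smaller |charge| is returned with a
  `degenerate` attribute rather than an error, so featurization never fails
  on a valid sequence.
* **Hydrophobic moment.** The α-helix convention: residue *k* contributes
  its hydrophobicity at angle *k*·100°, and the modulus of the vector sum is
  divided by the window length. An 18-residue homopolymer has moment exactly
  0 (18 × 100° wraps the wheel five full turns) — a fixed point the tests
  use.
* **Windows.** Width 11 (a common helical-scan width), step 1. A sequence
  shorter than the window is a single window and its range is defined as 0;
  this keeps short peptides featurizable at the cost of a dead descriptor
  below length 12.
* **Scales.** The quantities "hydrophobicity", "partition coefficient" and
  "helical content" are scale families, not single numbers. The defaults —
  Eisenberg consensus, Fauchère–Pliška, Chou–Fasman Pα — are the standard
  companions of the moment formula, the additive logP approximation, and the
  helix-former threshold respectively, and the whole `ScaleSet` is
  replaceable per call. The numeric tables are cross-checked against the
  AAindex database (via seqinr) in the test suite. Published probabilities
  for specific peptides can shift under different scale choices, which is
  one reason exact reproduction of external numbers is not promised (below).

## The classifier

A from-scratch random forest over the 27 descriptors:

* Each tree sees a bootstrap sample of size *n* (with replacement) and a
  random feature subset. The subset **size** is drawn uniformly from 1–27
  per tree and the subset then sampled without replacement
  (`featureRule = "random_size"`); a conventional fixed-m mode
  (`"fixed_m"`, default m = ⌈√27⌉ = 6) is available because the
  uniform-size reading, while faithful to how the method is usually
  described, is nonstandard among forest implementations.
* Trees are CART with Gini impurity; candidate thresholds are midpoints
  between consecutive distinct sorted values (clamped to the lower value
  when the midpoint would round onto the upper one — ulp-adjacent values
  otherwise cause a non-partitioning split); growth stops at purity,
  `minLeaf` (default 1), or the optional depth cap. Tie-breaks are fixed
  for reproducibility: equal Gini gains resolve to the lowest feature index,
  then the lowest threshold; leaf-vote ties resolve to non-CPP.
* **P(CPP) is the mean of hard tree votes**, so with 500 trees it is always
  a multiple of 1/500 — this is what produces granular published-style
  probabilities such as 0.112, and it is asserted exactly in the tests. A
  flag-free alternative (mean of leaf class fractions) was considered and
  rejected to keep the vote-fraction invariant testable.
* Out-of-bag error uses the standard Breiman scheme. Everything —
  bootstraps, subsets, and therefore the model and all its predictions — is
  a deterministic function of (data, parameters, seed).

Model archives are JSON with doubles written at 17 significant digits, which
round-trips IEEE doubles exactly; a reloaded model is asserted to predict
bit-identically. Archives refuse to load under a different descriptor order
rather than silently reordering.

## The design search

`designPeptide()` optimizes the added flanks around an immutable motif:

* genome = (N-flank, C-flank) under the placement constraint
  (`both_termini` for targeted designs, `c_terminal_tail` for activatable
  ones — additions go where the respective strategy adds them);
* operators: per-offspring point mutation (0.1), single-residue insertion
  (0.05) and deletion (0.05), restricted to flanks; tournament selection
  (size 3) on penalized fitness; elitism 4; population 64; 200 generations;
* fitness: P(CPP) (targeted) or 1 − P(CPP) (activation), minus
  λ·(added residues) with λ = 0.01 — small enough never to override a
  threshold crossing, but encoding the motivation for moonlighting designs
  in the first place: shorter peptides are cheaper and less antigenic;
* success thresholds: P(CPP) ≥ 0.88 for targeted designs (the bound the
  designed peptides were reported to clear); activation designs default to
  P(CPP) ≤ 0.20, a value chosen to bracket the reported silenced designs,
  since no explicit cutoff is published — both are task parameters;
* candidates whose flanks recreate the motif (overlapping occurrences
  counted) are discarded, since a duplicated ligand is a different molecule;
* output: all distinct successful designs ranked by fewest added residues,
  then penalized fitness, then sequence (an invented but fixed tie-break);
  if nothing succeeds, the single best candidate with `success = FALSE`.

The underlying optimizer is not prescribed by the method description, which
defers to earlier work; a genetic algorithm was chosen *because it can be
validated*: `exhaustiveDesign()` enumerates every flank assignment in small
spaces (guarded at 10⁶ candidates) and the test suite requires the search to
attain the exhaustive optimum on at least 18 of 20 randomized scoring-stub
tasks (4-letter alphabet, flank cap 3). `evaluateDesign()` and
`verifyMotif()` expose the scoring and integrity primitives; spans are
reported 0-based, half-open.

`neprilysinCut()` models the activation event: it locates FFGFLA and returns
the fragment up to the scissile G, so a silenced Tat design reactivates to
the Tat + FFG fragment.

## The synthetic data, and what it does and does not show

No training data ships with the package; `generateSyntheticDataset()` stands
in for the external CPP/non-CPP datasets so every test runs offline.

* **`by_generator` mode** (class realism): positives are an equal mixture of
  two CPP archetypes — *polycationic* (K/R-rich, hydrophilic, Tat-like) and
  *amphipathic* (cationic plus a β-branched/aromatic hydrophobic block) —
  negatives are hydrophilic/acidic (D, E, S, T, G, N biased). Lengths are
  uniform on 10–35 residues. This encodes exactly the two class differences
  the design method exploits (charge and membrane affinity) and claims no
  distributional fidelity to curated CPP databases.
* **`by_descriptor_rule` mode** (testability): candidates are proposed from
  the pooled archetypes and the *label is assigned by a known rule* —
  positive iff mean charge > 0.25 **and** mean hydrophobicity > the scale
  median — with a ±0.05 margin band rejected around the boundary. Because
  cationic-but-hydrophilic proposals land in the negative class, residue
  composition alone cannot predict the label and the forest must recover the
  two-descriptor interaction; because of the margin, the classes are
  separable by construction. If a margin/bias combination rejects more than
  99% of proposals the generator raises an error instead of looping.

The recovery experiments define the package's verifiable claims:
`recoveryExperiment()` (held-out accuracy on rule-labeled data, n = 400,
5 folds, 500 trees) and `designRecoveryExperiment()` (an acidic tail of ≤ 8
D/E residues flips a strongly rule-positive core's predicted label; a
neutral hydrophobic 6-mer crosses the 0.88 threshold within 12 added
residues). The recovery searches run at higher insertion pressure (0.3) than
the package default because their optima sit near the addition budget and
the fitness landscape is flat below the charge threshold — with the default
insertion rate the search rarely accumulates 11–12 additions within 200
generations. The neutral motif (LILALV) is deliberately uncharged *and*
hydrophobic: under the rule geometry, a longer or more hydrophilic motif
cannot clear both rule margins within a 12-residue budget at all, so the
experiment would test arithmetic impossibility rather than the search.

Problem sizes throughout (400-peptide training sets, 500 trees, 20
oracle-equivalence tasks at flank cap 3) are the package's chosen operating
points: large enough for stable estimates, small enough that the whole suite
and the acceptance script each run in about a minute on one CPU.

## Known limitations

* **Published probabilities are only partially reproducible.** The six
  published moonlighting designs are scored in `tests` and
  `scripts/acceptance.R` against a forest trained on the synthetic stand-in.
  The targeted designs and the activated Tat fragment score as strong CPPs
  (within the documented ±0.15 of their published values), but the silenced
  TatNepNoCPP design does **not** reproduce its published 0.112: the
  stand-in's acidic negatives teach the forest that negatives are
  *globally* acidic, not that an acidic tail silences an otherwise cationic
  peptide, and the sequence's six arginines dominate the vote. Reproducing
  that number requires the original training data (an external download),
  whose bundling is out of scope by design.
* Descriptors are sequence-letter functions: D-amino-acid isomers carry a
  chirality note as metadata but featurize identically to their L
  counterparts; the small published probability difference between an all-D
  design and its L form is therefore not reproducible from these
  descriptors, and no chirality term is added.
* The additive logP and threshold helix approximations ignore conformation;
  solubility, toxicity, receptor binding and protease kinetics are not
  modeled.
* With `minLeaf = 1` and no depth cap the trees interpolate their bootstrap
  samples; the forest's regularization comes from averaging, not pruning.
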