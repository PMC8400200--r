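# moonpep

Classifier-guided design of **moonlighting cell-penetrating peptides** (CPPs)
in R.

CPPs cross biological membranes and can carry impermeable cargo into cells,
but most internalize indiscriminately. Two engineering routes add
selectivity: *targeting* (a receptor ligand steers the peptide to cells
bearing the receptor) and *activation* (the CPP is silenced by an appended
extension until a protease expressed near the target cells cleaves it off).
Both normally bolt an extra domain onto the CPP, which raises synthesis cost,
protease exposure and immunogenicity. The moonlighting alternative embeds the
second activity *inside* the CPP domain itself: starting from a fixed
functional motif, residues are added at the termini until a classifier says
the whole sequence follows CPP feature rules (or, for activatable designs,
until it stops following them). moonpep implements that computational
workflow end to end.

## What it computes

**27-descriptor featurization.** Each peptide is mapped to a fixed-order
vector: the 20 residue counts; mean hydrophobicity (Eisenberg consensus
scale); mean Henderson–Hasselbalch charge at pH 7 over the ionizable side
chains (sum over basic groups H, K, R of 1/(1+10^(pH−pKa)) minus the acidic
groups C, D, E, Y analog; EMBOSS pKa set); the isoelectric point (bisection
root of the net charge over pH 0–14); the sliding-window (width 11) ranges
of net charge and of the Eisenberg hydrophobic moment
μH = (1/N)·|Σₖ hₖ·e^(ik·100°)|; an additive Fauchère–Pliška octanol–water
partition sum; and the Chou–Fasman helix-former fraction.

**Random-forest P(CPP).** A from-scratch classification forest: each tree is
grown by CART/Gini on a bootstrap sample, restricted to a per-tree random
feature subset whose *size* is itself drawn uniformly from 1–27. The
consensus P(CPP) is the mean of hard tree votes, so it is always an exact
vote fraction. Out-of-bag error is reported; training is bit-reproducible
under a seed, and models round-trip through a JSON archive with bit-identical
predictions.

**Moonlighting design search.** A seeded genetic algorithm mutates only the
added flanks (the motif is immutable and must occur exactly once), under a
total added-residue budget, scoring candidates by P(CPP) (targeted mode) or
1−P(CPP) (activation mode) minus a small length penalty. An exhaustive
enumerator over small flank spaces serves as an oracle for the search.

**Synthetic data.** A generator with CPP-like statistical structure
(polycationic + amphipathic positive archetypes vs hydrophilic/acidic
negatives), plus a rule-labeled mode in which a known two-descriptor rule
assigns the labels, so classifier and design recovery can be verified without
any external dataset.

## Worked example

```r
library(moonpep)

ds  <- generateSyntheticDataset(synthParams(seed = 1))   # 200 CPP / 200 non-CPP
fit <- trainForest(ds, params = forestParams(seed = 2))  # 500 trees
fit
#> CPPForest with 500 trees over 27 descriptors
#>   feature rule: random_size
#>   OOB error: 0.0000

tab1 <- validateSequence(
  c("RLWHWLQLKPGQPMYWRQPKSKRKVRR", "YGRKKRRQRRRFFG",
    "YGRKKRRQRRRFFGFLADDDDEE"),
  ids = c("alphaNLSC", "TatNep", "TatNepNoCPP"))
predictPCPP(fit, tab1)
#>            id p_cpp label
#> 1   alphaNLSC 0.982     1
#> 2      TatNep 0.958     1
#> 3 TatNepNoCPP 0.862     1
```

`p_cpp` is the fraction of the 500 trees that vote "CPP". The first peptide
embeds the yeast α-pheromone (WHWLQLKPGQPMY, the Ste2p ligand) inside a
designed CPP; the second is the Tat(47–57) core plus the start of the
neprilysin recognition site; the third appends the full site and an acidic
DDDDEE tail meant to silence it. Under this synthetic-data model the first
two score as strong CPPs, as published; the silenced design drops but stays
above 0.5 — see the vignette for why the bundled stand-in training data
cannot reproduce its published 0.112.

Silencing a strongly positive core with an acidic tail, against a
rule-labeled synthetic model:

```r
dsr  <- generateSyntheticDataset(synthParams(labelRule = "by_descriptor_rule",
                                             seed = 1))
fitr <- trainForest(dsr, params = forestParams(seed = 2))
task <- designTask("KIIKIIKKIIKIIIKI", mode = "embed_noncpp",
                   alphabet = c("D", "E"), maxAdded = 8)
head(designPeptide(task, fitr, searchParams(seed = 3)), 3)
#>              sequence p_cpp added_c n_added success
#> 1 KIIKIIKKIIKIIIKIEDD 0.140     EDD       3    TRUE
#> 2 KIIKIIKKIIKIIIKIDDE 0.148     DDE       3    TRUE
#> 3 KIIKIIKKIIKIIIKIDED 0.148     DED       3    TRUE

neprilysinCut("YGRKKRRQRRRFFGFLADDDDEE")   # proteolytic re-activation
#> [1] "YGRKKRRQRRRFFG"
```

Three appended acidic residues already push the core below the non-CPP
threshold (P(CPP) ≤ 0.20); designs are ranked by fewest added residues.

A command-line interface with `featurize`, `train`, `predict`, `design`,
`crossval` and `synth` subcommands is installed at
`inst/scripts/moonpep` (see `?moonpepCLI`).

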