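# Positive-class sampling weights. CPP training sets span two canonical
# archetypes, so the positive class is a mixture: polycationic peptides
# (Tat / oligo-arginine-like: K/R-rich, hydrophilic) and amphipathic ones
# (cationic plus a beta-branched/aromatic hydrophobic block).
.POS_POLYCATIONIC <- c(
  A = 0.04, C = 0.002, D = 0.002, E = 0.002, F = 0.03,
  G = 0.06, H = 0.01, I = 0.03, K = 0.22, L = 0.06,
  M = 0.002, N = 0.02, P = 0.04, Q = 0.06, R = 0.28,
  S = 0.03, T = 0.02, V = 0.03, W = 0.05, Y = 0.01
)

.POS_AMPHIPATHIC <- c(
  A = 0.005, C = 0.0009, D = 0.0009, E = 0.0009, F = 0.09,
  G = 0.005, H = 0.0009, I = 0.30, K = 0.30, L = 0.17,
  M = 0.0009, N = 0.0009, P = 0.0009, Q = 0.0009, R = 0.03,
  S = 0.0009, T = 0.0009, V = 0.04, W = 0.05, Y = 0.0009
)

.POS_BIAS <- list(polycationic = .POS_POLYCATIONIC,
                  amphipathic = .POS_AMPHIPATHIC)

.NEG_BIAS <- c(
  A = 0.05, C = 0.07 / 11, D = 0.16, E = 0.16, F = 0.07 / 11,
  G = 0.12, H = 0.07 / 11, I = 0.07 / 11, K = 0.07 / 11, L = 0.07 / 11,
  M = 0.07 / 11, N = 0.10, P = 0.05, Q = 0.05, R = 0.07 / 11,
  S = 0.13, T = 0.11, V = 0.07 / 11, W = 0.07 / 11, Y = 0.07 / 11
)

#' Parameters for the synthetic CPP-like dataset generator
#'
#' The generator emulates the statistical structure CPP training sets rely
#' on: positives are short, cationic and membrane-seeking (sampling biased
#' toward K, R, W, L, F), negatives hydrophilic and acidic (biased toward
#' D, E, S, T, G, N). It makes no claim of distributional fidelity to any
#' curated CPP database; it encodes exactly the two class differences
#' (charge, hydrophobicity) the design method exploits.
#'
#' @param nPos,nNeg number of positive / negative records.
#' @param lengthRange inclusive residue-length range (uniform).
#' @param posBias,negBias named per-residue sampling weights (normalized
#'   internally), or a list of such vectors defining an equal-weight mixture
#'   of compositional archetypes (the default positive class mixes a
#'   polycationic and an amphipathic component).
#' @param labelRule `"by_generator"` labels records by the bias that
#'   generated them; `"by_descriptor_rule"` labels by the ground-truth
#'   descriptor rule *positive iff mean charge > 0.25 and mean
#'   hydrophobicity > the hydrophobicity scale's median*, rejection-sampling
#'   so every record sits outside `ruleMargin` of both boundaries.
#' @param ruleMargin half-width of the exclusion band around the rule
#'   boundary (descriptor-rule mode only).
#' @param seed integer RNG seed.
#' @return a list with class `"SynthParams"`.
#' @export
synthParams <- function(nPos = 200L, nNeg = 200L, lengthRange = c(10L, 35L),
                        posBias = .POS_BIAS, negBias = .NEG_BIAS,
                        labelRule = c("by_generator", "by_descriptor_rule"),
                        ruleMargin = 0.05, seed = 1L) {
  labelRule <- match.arg(labelRule)
  if (nPos < 0L || nNeg < 0L) stop("counts must be >= 0", call. = FALSE)
  if (lengthRange[1L] < 5L) stop("minimum length must be >= 5", call. = FALSE)
  normalizeBias <- function(bias) {
    if (!is.list(bias)) bias <- list(bias)
    lapply(bias, function(b) {
      stopIfNot20(b, "sampling bias")
      if (any(b[AA_ALPHABET] <= 0)) {
        stop("bias weights must be positive", call. = FALSE)
      }
      b[AA_ALPHABET] / sum(b[AA_ALPHABET])
    })
  }
  structure(
    list(nPos = as.integer(nPos), nNeg = as.integer(nNeg),
         lengthRange = as.integer(lengthRange),
         posBias = normalizeBias(posBias),
         negBias = normalizeBias(negBias),
         labelRule = labelRule, ruleMargin = ruleMargin,
         seed = as.integer(seed)),
    class = "SynthParams"
  )
}

#' The ground-truth descriptor rule used by the generator
#'
#' @param scales a [ScaleSet-class].
#' @return list with `chargeThreshold` (0.25) and `hydroThreshold` (median of
#'   the hydrophobicity scale): a peptide is rule-positive iff its mean
#'   charge exceeds the former and its mean hydrophobicity the latter.
#' @export
descriptorRule <- function(scales = defaultScales()) {
  list(chargeThreshold = 0.25,
       hydroThreshold = stats::median(scales@hydrophobicity[AA_ALPHABET]))
}

#' Generate a synthetic labeled CPP/non-CPP dataset
#'
#' Sequences are sampled residue-wise with lengths uniform in `lengthRange`.
#' In `by_generator` mode each class is drawn from its own bias and labeled
#' by the bias that generated it. In `by_descriptor_rule` mode the label is
#' assigned by the ground-truth descriptor rule instead: candidates are
#' proposed from the pooled archetype compositions (both classes' biases)
#' and kept on whichever side of the rule they fall, provided they clear the
#' `ruleMargin` band around the boundary. The rule-labeled classes are
#' therefore separable in descriptor space by construction, while residue
#' composition alone does not determine the label (cationic but hydrophilic
#' proposals land in the negative class), so a classifier has to recover the
#' rule's charge-hydrophobicity interaction rather than memorize
#' compositions. Fully reproducible under the seed.
#'
#' @param params a [synthParams()] list.
#' @param scales a [ScaleSet-class] (used by the descriptor rule).
#' @return a labeled [PeptideSet-class] with attributes `"params"` and (in
#'   descriptor-rule mode) `"rule"`.
#' @export
generateSyntheticDataset <- function(params = synthParams(),
                                     scales = defaultScales()) {
  rule <- descriptorRule(scales)
  hyd <- scales@hydrophobicity[AA_ALPHABET]
  ruleMode <- params$labelRule == "by_descriptor_rule"
  m <- params$ruleMargin

  drawClass <- function(n, bias, positive) {
    if (n == 0L) return(character())
    out <- character(0)
    attempts <- 0L
    while (length(out) < n) {
      batch <- max(n - length(out), 32L)
      lens <- sample(seq.int(params$lengthRange[1L], params$lengthRange[2L]),
                     batch, replace = TRUE)
      comp <- sample.int(length(bias), batch, replace = TRUE)
      seqs <- vapply(seq_len(batch), function(j) {
        paste(sample(AA_ALPHABET, lens[j], replace = TRUE,
                     prob = bias[[comp[j]]]),
              collapse = "")
      }, "")
      attempts <- attempts + batch
      if (ruleMode) {
        ok <- vapply(seqs, function(s) {
          chars <- seqChars(s)
          cnt <- vapply(c(.BASIC, .ACIDIC), function(r) sum(chars == r), 0L)
          mc <- .netChargeFromCounts(cnt, 7.0, scales@pka) / length(chars)
          mh <- mean(hyd[chars])
          if (positive) {
            mc > rule$chargeThreshold + m && mh > rule$hydroThreshold + m
          } else {
            mc <= rule$chargeThreshold - m || mh <= rule$hydroThreshold - m
          }
        }, TRUE)
        seqs <- seqs[ok]
      }
      out <- c(out, seqs)
      if (attempts >= 2000L && length(out) / attempts < 0.01) {
        stop("rejection rate above 99%: the rule margin is infeasible for ",
             "this sampling bias", call. = FALSE)
      }
      if (attempts > 1e6) {
        stop("synthetic generation did not converge", call. = FALSE)
      }
    }
    out[seq_len(n)]
  }

  ps <- withSeed(params$seed, {
    posBias <- if (ruleMode) c(params$posBias, params$negBias) else
      params$posBias
    negBias <- if (ruleMode) c(params$posBias, params$negBias) else
      params$negBias
    pos <- drawClass(params$nPos, posBias, TRUE)
    neg <- drawClass(params$nNeg, negBias, FALSE)
    new("PeptideSet",
      ids = c(sprintf("pos%03d", seq_len(params$nPos)),
              sprintf("neg%03d", seq_len(params$nNeg))),
      sequences = c(pos, neg),
      labels = c(rep(1L, params$nPos), rep(0L, params$nNeg)),
      chirality = rep(NA_character_, params$nPos + params$nNeg)
    )
  })
  attr(ps, "params") <- params
  if (ruleMode) attr(ps, "rule") <- rule
  ps
}

#' End-to-end classifier recovery on synthetic data
#'
#' Generates a rule-labeled synthetic dataset, trains the forest, and
#' cross-validates. Because the classes are separable in descriptor space by
#' construction, held-out accuracy is expected to clear `accuracyFloor`.
#'
#' @param synth a [synthParams()] list (must use `by_descriptor_rule`).
#' @param forest a [forestParams()] list.
#' @param kFolds cross-validation folds.
#' @param accuracyFloor the held-out accuracy the experiment checks against.
#' @param scales a [ScaleSet-class].
#' @return list: `perFold` metrics, `meanAccuracy`, `oobError`, `pass`.
#' @export
recoveryExperiment <- function(synth = synthParams(
                                 labelRule = "by_descriptor_rule"),
                               forest = forestParams(),
                               kFolds = 5L, accuracyFloor = 0.90,
                               scales = defaultScales()) {
  if (synth$labelRule != "by_descriptor_rule") {
    stop("recoveryExperiment needs labelRule = 'by_descriptor_rule'",
         call. = FALSE)
  }
  ds <- generateSyntheticDataset(synth, scales = scales)
  fit <- trainForest(ds, params = forest, scales = scales)
  cv <- crossValidate(ds, kFolds = kFolds, params = forest, scales = scales)
  list(
    perFold = cv$perFold,
    meanAccuracy = unname(cv$mean["accuracy"]),
    oobError = oobError(fit),
    accuracyFloor = accuracyFloor,
    pass = unname(cv$mean["accuracy"]) >= accuracyFloor
  )
}

# a fixed strongly rule-positive core (cationic and beta-branched
# hydrophobic) and a fixed uncharged hydrophobic motif used by the
# design-recovery run
.SYNTH_CPP_CORE <- "KIIKIIKKIIKIIIKI"
.NEUTRAL_MOTIF <- "LILALV"

#' End-to-end design recovery on synthetic data
#'
#' Trains a forest on a rule-labeled synthetic dataset, then runs the two
#' design directions against it: silencing a strongly rule-positive core
#' with an acidic C-terminal tail (`embed_noncpp`, budget 8), and pushing a
#' neutral motif over the CPP threshold (`embed_cpp`, budget 12).
#'
#' @param seed integer seed driving dataset, training and both searches.
#' @param synth,forest generator and forest settings.
#' @param population,generations genetic-search size.
#' @param scales a [ScaleSet-class].
#' @return list with elements `noncpp` and `cpp` (each: best design row,
#'   `success` against the task target, `n_added`, `p_cpp`, and
#'   `labelFlipped`, i.e. whether the hard 0.5 label changed) plus the
#'   trained model's `oobError`.
#' @export
designRecoveryExperiment <- function(seed = 1L,
                                     synth = NULL, forest = NULL,
                                     population = 64L, generations = 200L,
                                     scales = defaultScales()) {
  seed <- as.integer(seed)
  if (is.null(synth)) {
    synth <- synthParams(labelRule = "by_descriptor_rule", seed = seed)
  }
  if (is.null(forest)) forest <- forestParams(seed = seed)
  ds <- generateSyntheticDataset(synth, scales = scales)
  fit <- trainForest(ds, params = forest, scales = scales)

  # both recovery optima sit close to the addition budget, so the search
  # runs with more insertion pressure than the package-wide default
  recoverySearch <- function(s) {
    searchParams(population = population, generations = generations,
                 mutationRate = 0.2, insertionRate = 0.3,
                 deletionRate = 0.05, seed = s)
  }
  noncppTask <- designTask(.SYNTH_CPP_CORE, mode = "embed_noncpp",
                           alphabet = c("D", "E"), maxAdded = 8L)
  noncpp <- designPeptide(noncppTask, fit, recoverySearch(seed + 1L))
  cppTask <- designTask(.NEUTRAL_MOTIF, mode = "embed_cpp", maxAdded = 12L)
  cpp <- designPeptide(cppTask, fit, recoverySearch(seed + 2L))
  summarize <- function(res) {
    best <- res[1L, ]
    list(design = best, success = best$success, n_added = best$n_added,
         p_cpp = best$p_cpp, labelFlipped = best$p_cpp < 0.5)
  }
  list(noncpp = summarize(noncpp), cpp = summarize(cpp),
       oobError = oobError(fit))
}
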