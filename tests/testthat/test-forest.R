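test_that("forced and degenerate splits behave like textbook CART", {
  # two points, one feature: a single split at the midpoint, both leaves pure
  X <- matrix(c(0, 1), ncol = 1)
  tr <- moonpep:::.cppGrowTree(X, c(0L, 1L), 1:2, 1L, 1L, -1L)
  expect_equal(nrow(tr), 3L)
  expect_equal(tr[1, "feature"], 1, ignore_attr = TRUE)
  expect_equal(tr[1, "threshold"], 0.5, ignore_attr = TRUE)
  expect_equal(walkTree(tr, 0), 0L)
  expect_equal(walkTree(tr, 1), 1L)

  # identical vectors with mixed labels: no valid split, majority leaf
  Xi <- matrix(rep(1, 6), ncol = 1)
  tr2 <- moonpep:::.cppGrowTree(Xi, c(1L, 1L, 0L, 0L, 1L, 1L), 1:6, 1L, 1L, -1L)
  expect_equal(nrow(tr2), 1L)
  expect_equal(tr2[1, "vote"], 1, ignore_attr = TRUE)

  # leaf-vote tie resolves to non-CPP
  tr3 <- moonpep:::.cppGrowTree(Xi[1:4, , drop = FALSE],
                                c(1L, 1L, 0L, 0L), 1:4, 1L, 1L, -1L)
  expect_equal(tr3[1, "vote"], 0, ignore_attr = TRUE)

  # single-class bootstrap: depth-0 tree voting that class
  tr4 <- moonpep:::.cppGrowTree(matrix(runif(8), ncol = 2),
                                c(1L, 1L, 1L, 1L), 1:4, 1:2, 1L, -1L)
  expect_equal(nrow(tr4), 1L)
  expect_equal(tr4[1, "vote"], 1, ignore_attr = TRUE)
})

test_that("split choice matches exhaustive Gini enumeration on small instances", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    p <- sample(1:3, 1)
    X <- matrix(sample(0:8, n * p, replace = TRUE) / 2, ncol = p)
    y <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
    feats <- seq_len(p)
    tr <- moonpep:::.cppGrowTree(X, y, seq_len(n), feats, 1L, -1L)
    oracle <- oracleBestSplit(X, y, feats)
    if (is.na(oracle$f)) {
      expect_equal(nrow(tr), 1L)
    } else {
      expect_equal(tr[1, "feature"], oracle$f, ignore_attr = TRUE)
      expect_equal(tr[1, "threshold"], oracle$thr, ignore_attr = TRUE)
      # and the whole tree predicts like the recursive oracle everywhere
      pred <- oracleTree(X, y, feats)
      grid <- matrix(runif(20 * p, -1, 5), ncol = p)
      for (i in seq_len(nrow(grid))) {
        expect_equal(walkTree(tr, grid[i, ]), pred(grid[i, ]))
      }
    }
  }
})

test_that("consensus probability is exactly the tree-vote fraction", {
  f4 <- stubForest(c(1, 1, 1, 0))
  expect_equal(predictPCPP(f4, "KRRKRRKK")$p_cpp, 0.75)
  expect_equal(predictPCPP(f4, "KRRKRRKK")$label, 1L)

  f1 <- stubForest(1)
  expect_true(predictPCPP(f1, "KRRKRRKK")$p_cpp %in% c(0, 1))

  # vote fraction over many probes: p * nTrees is always an integer
  ds <- generateSyntheticDataset(synthParams(nPos = 30, nNeg = 30, seed = 6))
  fit <- trainForest(ds, params = forestParams(nTrees = 37, seed = 8))
  set.seed(9)
  probes <- vapply(1:20, function(i) randomPeptide(sample(8:25, 1)), "")
  p <- predictPCPP(fit, probes)$p_cpp
  expect_true(all(abs(p * 37 - round(p * 37)) < 1e-12))
  expect_true(all(p >= 0 & p <= 1))

  expect_error(predictPCPP(fit, matrix(1, ncol = 5)), "27 columns")
  expect_error(predictPCPP(fit, rep(1, 26)), "27 columns")
})

test_that("training is bit-reproducible under a fixed seed", {
  ds <- generateSyntheticDataset(synthParams(nPos = 40, nNeg = 40, seed = 2))
  fitA <- trainForest(ds, params = forestParams(nTrees = 80, seed = 21))
  fitB <- trainForest(ds, params = forestParams(nTrees = 80, seed = 21))
  expect_identical(fitA@trees, fitB@trees)
  set.seed(3)
  probes <- vapply(1:50, function(i) randomPeptide(sample(8:30, 1)), "")
  expect_identical(predictPCPP(fitA, probes)$p_cpp,
                   predictPCPP(fitB, probes)$p_cpp)
  fitC <- trainForest(ds, params = forestParams(nTrees = 80, seed = 22))
  expect_false(identical(fitA@trees, fitC@trees))
})

test_that("each tree fits its bootstrap sample where its features permit", {
  ds <- generateSyntheticDataset(
    synthParams(nPos = 30, nNeg = 30, labelRule = "by_descriptor_rule",
                seed = 14))
  X <- featurize(ds)
  y <- peptideLabels(ds)
  fit <- trainForest(ds, params = forestParams(nTrees = 25, seed = 15))
  for (b in seq_len(25)) {
    boot <- fit@inbag[[b]]
    feats <- fit@subsets[[b]]
    v <- moonpep:::.cppForestVotes(fit@trees[b], X[boot, , drop = FALSE])[, 1]
    # a tree can only separate points that differ within its feature subset:
    # in-bag fit must be perfect wherever the projected vectors are
    # conflict-free
    key <- apply(X[boot, feats, drop = FALSE], 1, paste, collapse = ",")
    conflicted <- names(which(tapply(y[boot], key,
                                     function(l) length(unique(l)) > 1L)))
    ok <- !(key %in% conflicted)
    expect_equal(v[ok], y[boot][ok])
  }
})

test_that("out-of-bag error is small on separable data, chance after shuffling", {
  ds <- generateSyntheticDataset(
    synthParams(nPos = 75, nNeg = 75, labelRule = "by_descriptor_rule",
                seed = 19))
  fit <- trainForest(ds, params = forestParams(nTrees = 200, seed = 20))
  expect_lte(oobError(fit), 0.08)

  shuffled <- withr::with_seed(77, sample(peptideLabels(ds)))
  dsShuf <- validateSequence(peptideSequences(ds), ids = peptideIds(ds),
                             labels = shuffled)
  fitShuf <- trainForest(dsShuf, params = forestParams(nTrees = 200, seed = 20))
  expect_gte(oobError(fitShuf), 0.35)
  expect_lte(oobError(fitShuf), 0.65)
})

test_that("cross-validation metrics are computed per stratified fold", {
  # all-identical feature vectors with balanced labels force a constant
  # non-CPP prediction (vote ties go to 0), pinning the metric arithmetic
  const <- validateSequence(rep("KRKRKRKR", 20),
                            ids = paste0("s", 1:20),
                            labels = rep(c(1L, 0L), each = 10))
  cv <- crossValidate(const, kFolds = 2L, params = forestParams(nTrees = 11,
                                                                seed = 5))
  expect_equal(unname(cv$mean["accuracy"]), 0.5)
  # constant prediction: sensitivity and specificity are complementary
  expect_equal(unname(cv$mean["sensitivity"] + cv$mean["specificity"]), 1)
  expect_true(all(cv$perFold$sensitivity %in% c(0, 1)))

  # separable data: near-perfect held-out accuracy
  ds <- generateSyntheticDataset(
    synthParams(nPos = 45, nNeg = 45, labelRule = "by_descriptor_rule",
                seed = 23))
  cv2 <- crossValidate(ds, kFolds = 3L,
                       params = forestParams(nTrees = 120, seed = 24))
  expect_gte(unname(cv2$mean["accuracy"]), 0.9)
  expect_true(all(cv2$perFold$accuracy >= 0 & cv2$perFold$accuracy <= 1))

  tiny <- validateSequence(c("KRRK", "KKRR", "DDEE"),
                           labels = c(1L, 1L, 0L), ids = c("a", "b", "c"))
  expect_error(crossValidate(tiny, kFolds = 2L), "kFolds members")
})

test_that("more trees reduce the seed-to-seed variance of the consensus", {
  ds <- generateSyntheticDataset(synthParams(nPos = 30, nNeg = 30, seed = 26))
  # a deliberately ambiguous probe between the two class archetypes
  probe <- "KDKDGSLLKG"
  pAt <- function(nTrees) {
    vapply(1:8, function(s) {
      fit <- trainForest(ds, params = forestParams(nTrees = nTrees, seed = s))
      predictPCPP(fit, probe)$p_cpp
    }, 0)
  }
  expect_lt(sd(pAt(200)), sd(pAt(20)))
})

test_that("forest accuracy is corroborated by an independent implementation", {
  ds <- generateSyntheticDataset(synthParams(nPos = 60, nNeg = 60, seed = 28))
  X <- featurize(ds)
  y <- factor(peptideLabels(ds))
  fit <- trainForest(ds, params = forestParams(nTrees = 150, seed = 29))
  rf <- randomForest::randomForest(x = X, y = y, ntree = 150)
  refErr <- mean(rf$predicted != y)
  expect_lt(abs(oobError(fit) - refErr), 0.1)
})
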