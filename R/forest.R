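#' Random-forest hyperparameters
#'
#' @param nTrees number of trees in the ensemble.
#' @param featureRule how each tree's feature subset is drawn:
#'   `"random_size"` draws the subset size uniformly from 1..p per tree and
#'   then samples that many features (the default, matching the method's
#'   description of selecting "a random number" of the attributes);
#'   `"fixed_m"` uses a constant subset size `m` per tree.
#' @param m subset size for `featureRule = "fixed_m"` (default
#'   `ceiling(sqrt(27)) = 6`).
#' @param minLeaf minimum samples per leaf.
#' @param maxDepth optional depth cap (`NULL` = unlimited).
#' @param seed integer RNG seed; (dataset, params, seed) fully determine the
#'   trained model.
#' @return a list with class `"ForestParams"`.
#' @export
forestParams <- function(nTrees = 500L,
                         featureRule = c("random_size", "fixed_m"),
                         m = 6L, minLeaf = 1L, maxDepth = NULL, seed = 1L) {
  featureRule <- match.arg(featureRule)
  nTrees <- as.integer(nTrees)
  if (nTrees < 1L) stop("nTrees must be >= 1", call. = FALSE)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  structure(
    list(nTrees = nTrees, featureRule = featureRule, m = as.integer(m),
         minLeaf = as.integer(minLeaf),
         maxDepth = if (is.null(maxDepth)) NULL else as.integer(maxDepth),
         seed = as.integer(seed)),
    class = "ForestParams"
  )
}

#' Random-forest CPP classifier
#'
#' An ensemble of CART trees grown on bootstrap samples, each restricted to a
#' random feature subset. The consensus prediction P(CPP) is the mean of the
#' trees' hard leaf votes, so it always equals (number of trees voting
#' CPP)/(number of trees) exactly.
#'
#' @slot trees list of node matrices (one per tree).
#' @slot params the [forestParams()] used for training.
#' @slot featureOrder descriptor names, in the order of the training matrix.
#' @slot scales the [ScaleSet-class] used to featurize the training data.
#' @slot inbag list of in-bag (bootstrap) sample indices, one per tree.
#' @slot subsets list of per-tree feature subsets (column indices).
#' @slot oobError out-of-bag misclassification estimate.
#' @export
setClass("CPPForest",
  representation(
    trees = "list",
    params = "list",
    featureOrder = "character",
    scales = "ScaleSet",
    inbag = "list",
    subsets = "list",
    oobError = "numeric"
  )
)

setValidity("CPPForest", function(object) {
  msg <- character()
  if (length(object@trees) < 1L) msg <- c(msg, "forest must contain trees")
  if (!all(vapply(object@trees, is.matrix, TRUE))) {
    msg <- c(msg, "trees must be node matrices")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CPPForest", function(object) {
  cat("CPPForest with ", length(object@trees), " trees over ",
      length(object@featureOrder), " descriptors\n", sep = "")
  cat("  feature rule: ", object@params$featureRule, "\n", sep = "")
  if (length(object@oobError) && is.finite(object@oobError)) {
    cat(sprintf("  OOB error: %.4f\n", object@oobError))
  }
})

#' @describeIn CPPForest-class number of trees
#' @param x a `CPPForest`
#' @export
nTrees <- function(x) length(x@trees)

#' @describeIn CPPForest-class out-of-bag error estimate
#' @export
oobError <- function(x) x@oobError

#' @describeIn CPPForest-class descriptor order the model expects
#' @export
featureOrder <- function(x) x@featureOrder

# featurize a PeptideSet, or pass a numeric matrix through with shape checks
.asFeatureMatrix <- function(x, featureOrder, scales,
                             params = windowParams()) {
  if (is(x, "PeptideSet") || is.character(x)) {
    return(featurize(x, scales = scales, params = params))
  }
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x) || ncol(x) != length(featureOrder)) {
    stop(sprintf("descriptor input must have %d columns (got %s)",
                 length(featureOrder),
                 if (is.matrix(x)) ncol(x) else length(x)), call. = FALSE)
  }
  x
}

#' Train the random-forest CPP classifier
#'
#' For each tree a bootstrap sample (size n, with replacement) is drawn, a
#' feature subset is selected under the `featureRule`, and a CART tree is
#' grown with Gini impurity, midpoint thresholds, and majority leaf votes
#' (ties go to non-CPP). The out-of-bag error is estimated from the samples
#' each tree did not see.
#'
#' @param x a labeled [PeptideSet-class], or a numeric descriptor matrix.
#' @param labels 0/1 labels, required when `x` is a matrix.
#' @param params a [forestParams()] list.
#' @param scales [ScaleSet-class] used for featurization.
#' @param windows [windowParams()] used for featurization.
#' @return a [CPPForest-class] model.
#' @examples
#' ds <- generateSyntheticDataset(synthParams(nPos = 30, nNeg = 30, seed = 7))
#' fit <- trainForest(ds, params = forestParams(nTrees = 50, seed = 7))
#' oobError(fit)
#' @export
trainForest <- function(x, labels = NULL, params = forestParams(),
                        scales = defaultScales(), windows = windowParams()) {
  if (is(x, "PeptideSet")) {
    .checkTrainingSet(x, allowDuplicates = TRUE)
    labels <- peptideLabels(x)
    X <- featurize(x, scales = scales, params = windows)
  } else {
    X <- x
    if (is.null(labels)) stop("matrix input needs 'labels'", call. = FALSE)
  }
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("training requires both classes",
                                   call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  maxDepth <- if (is.null(params$maxDepth)) -1L else params$maxDepth
  trees <- vector("list", params$nTrees)
  inbag <- vector("list", params$nTrees)
  subsets <- vector("list", params$nTrees)
  voteSum <- numeric(n)
  voteN <- integer(n)
  withSeed(params$seed, {
    for (b in seq_len(params$nTrees)) {
      boot <- sample.int(n, n, replace = TRUE)
      k <- if (params$featureRule == "random_size") {
        sample.int(p, 1L)
      } else {
        min(params$m, p)
      }
      feats <- sort(sample.int(p, k))
      trees[[b]] <- .cppGrowTree(X, y, boot, feats, params$minLeaf, maxDepth)
      inbag[[b]] <- boot
      subsets[[b]] <- feats
      oob <- which(tabulate(boot, nbins = n) == 0L)
      if (length(oob)) {
        v <- .cppForestVotes(trees[b], X[oob, , drop = FALSE])[, 1L]
        voteSum[oob] <- voteSum[oob] + v
        voteN[oob] <- voteN[oob] + 1L
      }
    }
  })
  seen <- voteN > 0L
  oobErr <- if (any(seen)) {
    oobLabel <- as.integer(voteSum[seen] / voteN[seen] >= 0.5)
    mean(oobLabel != y[seen])
  } else {
    NA_real_
  }
  new("CPPForest",
    trees = trees,
    params = unclass(params),
    featureOrder = colnames(X) %||% featureNames(),
    scales = scales,
    inbag = inbag,
    subsets = subsets,
    oobError = oobErr
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict P(CPP)
#'
#' The consensus probability that each input follows CPP feature rules: the
#' fraction of trees voting class 1. The hard label is 1 iff
#' `p_cpp >= 0.5`.
#'
#' @param model a [CPPForest-class].
#' @param x a `PeptideSet`, character sequences, a 27-column descriptor
#'   matrix, or a single length-27 descriptor vector.
#' @return data.frame with columns `id`, `p_cpp`, `label`.
#' @export
predictPCPP <- function(model, x) {
  stopifnot(is(model, "CPPForest"))
  ids <- if (is(x, "PeptideSet")) peptideIds(x) else NULL
  X <- .asFeatureMatrix(x, model@featureOrder, model@scales)
  votes <- .cppForestVotes(model@trees, X)
  p <- rowSums(votes) / ncol(votes)
  data.frame(
    id = ids %||% rownames(X) %||% paste0("seq", seq_len(nrow(X))),
    p_cpp = p,
    label = as.integer(p >= 0.5),
    row.names = NULL
  )
}

#' Stratified k-fold cross-validation
#'
#' Folds are assigned per class under the params seed, so the assignment is
#' reproducible. Each fold's model is trained with the same hyperparameters.
#'
#' @param x a labeled [PeptideSet-class].
#' @param kFolds number of folds (>= 2).
#' @param params a [forestParams()] list.
#' @param scales,windows featurization settings.
#' @return list with `perFold` (data.frame of accuracy, sensitivity,
#'   specificity per fold) and `mean` (named numeric vector).
#' @export
crossValidate <- function(x, kFolds = 5L, params = forestParams(),
                          scales = defaultScales(),
                          windows = windowParams()) {
  stopifnot(is(x, "PeptideSet"))
  kFolds <- as.integer(kFolds)
  if (kFolds < 2L) stop("kFolds must be >= 2", call. = FALSE)
  y <- peptideLabels(x)
  if (any(table(y) < kFolds)) {
    stop("each class needs at least kFolds members", call. = FALSE)
  }
  X <- featurize(x, scales = scales, params = windows)
  n <- length(y)
  fold <- integer(n)
  withSeed(params$seed, {
    for (cls in c(0L, 1L)) {
      i <- which(y == cls)
      fold[i] <- sample(rep_len(seq_len(kFolds), length(i)))
    }
  })
  perFold <- data.frame(fold = seq_len(kFolds), accuracy = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_)
  for (k in seq_len(kFolds)) {
    test <- fold == k
    fit <- trainForest(X[!test, , drop = FALSE], labels = y[!test],
                       params = params, scales = scales)
    pred <- predictPCPP(fit, X[test, , drop = FALSE])$label
    truth <- y[test]
    perFold$accuracy[k] <- mean(pred == truth)
    perFold$sensitivity[k] <- if (any(truth == 1L)) {
      mean(pred[truth == 1L] == 1L)
    } else NA_real_
    perFold$specificity[k] <- if (any(truth == 0L)) {
      mean(pred[truth == 0L] == 0L)
    } else NA_real_
  }
  list(
    perFold = perFold,
    mean = c(accuracy = mean(perFold$accuracy),
             sensitivity = mean(perFold$sensitivity, na.rm = TRUE),
             specificity = mean(perFold$specificity, na.rm = TRUE))
  )
}
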