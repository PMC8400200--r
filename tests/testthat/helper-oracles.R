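# Independent brute-force oracles and small fixtures shared across tests.
# Every oracle recomputes its quantity from first principles, without going
# through the package's descriptor code paths.

randomPeptide <- function(len, alphabet = AA_ALPHABET) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

.oracleScales <- defaultScales()

# per-group Henderson-Hasselbalch sum, written independently of the package
oracleNetCharge <- function(s, pH, pka = pkaScale(.oracleScales)) {
  ch <- strsplit(s, "")[[1L]]
  q <- 0
  for (r in ch) {
    if (r %in% c("H", "K", "R")) {
      q <- q + 1 / (1 + 10^(pH - pka[[r]]))
    } else if (r %in% c("C", "D", "E", "Y")) {
      q <- q - 1 / (1 + 10^(pka[[r]] - pH))
    }
  }
  q
}

# pI by scanning a 1e-4-step pH grid for the minimum |net charge|
oracleGridPI <- function(s, step = 1e-4, pka = pkaScale(.oracleScales)) {
  ch <- strsplit(s, "")[[1L]]
  grid <- seq(0, 14, by = step)
  q <- numeric(length(grid))
  for (r in c("H", "K", "R")) {
    n <- sum(ch == r)
    if (n) q <- q + n / (1 + 10^(grid - pka[[r]]))
  }
  for (r in c("C", "D", "E", "Y")) {
    n <- sum(ch == r)
    if (n) q <- q - n / (1 + 10^(pka[[r]] - grid))
  }
  grid[which.min(abs(q))]
}

# hydrophobic moment as a direct complex-exponential sum
oracleMoment <- function(s, deltaAngle = 100,
                         hyd = hydrophobicityScale(.oracleScales)) {
  h <- hyd[strsplit(s, "")[[1L]]]
  k <- seq_along(h) - 1
  Mod(sum(h * exp(1i * k * deltaAngle * pi / 180))) / length(h)
}

# window range by explicit enumeration of every window
oracleWindowRange <- function(s, statistic, width = 11L) {
  n <- nchar(s)
  if (n <= width) return(0)
  starts <- 1:(n - width + 1L)
  vals <- vapply(starts, function(i) {
    w <- substr(s, i, i + width - 1L)
    if (statistic == "charge") oracleNetCharge(w, 7.0) else oracleMoment(w)
  }, 0)
  max(vals) - min(vals)
}

# exhaustive enumeration of every (feature, midpoint-threshold) split by the
# Gini criterion, with the same tie-breaks the grower documents: features in
# ascending order, thresholds ascending, strict improvement only
oracleBestSplit <- function(X, y, feats, minLeaf = 1L) {
  n <- nrow(X)
  n1 <- sum(y)
  n0 <- n - n1
  best <- list(s = (n0^2 + n1^2) / n, f = NA_integer_, thr = NA_real_)
  for (f in feats) {
    o <- order(X[, f])
    vs <- X[o, f]
    ys <- y[o]
    l0 <- 0
    l1 <- 0
    for (i in seq_len(n - 1L)) {
      if (ys[i] == 1) l1 <- l1 + 1 else l0 <- l0 + 1
      if (vs[i] == vs[i + 1L]) next
      nl <- i
      nr <- n - i
      if (nl < minLeaf || nr < minLeaf) next
      r0 <- n0 - l0
      r1 <- n1 - l1
      s <- (l0 * l0 + l1 * l1) / nl + (r0 * r0 + r1 * r1) / nr
      if (s > best$s) {
        thr <- (vs[i] + vs[i + 1L]) / 2
        if (thr >= vs[i + 1L]) thr <- vs[i]
        best <- list(s = s, f = f, thr = thr)
      }
    }
  }
  best
}

# recursive CART oracle with the same stopping and tie rules as the grower;
# returns a prediction function
oracleTree <- function(X, y, feats, minLeaf = 1L) {
  n <- length(y)
  n1 <- sum(y)
  n0 <- n - n1
  if (n0 == 0L || n1 == 0L || n < 2L * minLeaf) {
    vote <- as.integer(n1 > n0)
    return(function(x) vote)
  }
  sp <- oracleBestSplit(X, y, feats, minLeaf)
  if (is.na(sp$f)) {
    vote <- as.integer(n1 > n0)
    return(function(x) vote)
  }
  left <- X[, sp$f] <= sp$thr
  fl <- oracleTree(X[left, , drop = FALSE], y[left], feats, minLeaf)
  fr <- oracleTree(X[!left, , drop = FALSE], y[!left], feats, minLeaf)
  function(x) if (x[sp$f] <= sp$thr) fl(x) else fr(x)
}

# predict with a single grown node-matrix tree (R-side reference walker)
walkTree <- function(tree, x) {
  node <- 1L
  while (tree[node, "feature"] > 0) {
    f <- tree[node, "feature"]
    node <- if (x[f] <= tree[node, "threshold"]) {
      as.integer(tree[node, "left"])
    } else {
      as.integer(tree[node, "right"])
    }
  }
  as.integer(tree[node, "vote"])
}

# graded scoring stubs for design-search tests: a logistic function of mean
# charge and mean hydrophobicity with task-specific coefficients
gradedStub <- function(a = 4, b = 0, c = 0) {
  force(a); force(b); force(c)
  function(seqs) {
    vapply(seqs, function(s) {
      1 / (1 + exp(-(a * meanCharge(s) + b * meanHydrophobicity(s) + c)))
    }, 0, USE.NAMES = FALSE)
  }
}

# hand-built single-leaf tree voting a fixed class
leafTree <- function(vote) {
  m <- matrix(c(0, 0, 0, 0, vote, 1, 1), nrow = 1)
  colnames(m) <- c("feature", "threshold", "left", "right", "vote", "n0", "n1")
  m
}

stubForest <- function(votes) {
  new("CPPForest",
    trees = lapply(votes, leafTree),
    params = unclass(forestParams(nTrees = length(votes))),
    featureOrder = featureNames(),
    scales = defaultScales(),
    inbag = list(),
    subsets = list(),
    oobError = NA_real_
  )
}

tinyLabeledSet <- function(seqsPos, seqsNeg) {
  validateSequence(c(seqsPos, seqsNeg),
                   ids = paste0("s", seq_len(length(seqsPos) + length(seqsNeg))),
                   labels = c(rep(1L, length(seqsPos)),
                              rep(0L, length(seqsNeg))))
}
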