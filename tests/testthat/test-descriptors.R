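tat <- "YGRKKRRQRRRFFG"
tatTail <- "YGRKKRRQRRRFFGFLADDDDEE"
sc <- defaultScales()

test_that("residue counts are exact and order-invariant", {
  cnt <- residueCounts(tat)
  expect_equal(sum(cnt), nchar(tat))
  expect_equal(unname(cnt[c("R", "K", "G", "F", "Q", "Y")]),
               c(6L, 2L, 2L, 2L, 1L, 1L))
  expect_equal(sum(cnt[setdiff(AA_ALPHABET, c("R", "K", "G", "F", "Q", "Y"))]),
               0L)
  expect_equal(unname(residueCounts("A")[["A"]]), 1L)

  set.seed(5)
  for (i in 1:10) {
    s <- randomPeptide(sample(6:40, 1))
    perm <- paste(sample(strsplit(s, "")[[1L]]), collapse = "")
    expect_identical(residueCounts(perm), residueCounts(s))
  }
})

test_that("default scale tables agree with the published AAindex entries", {
  data(aaindex, package = "seqinr", envir = environment())
  lookup <- function(id) {
    e <- aaindex[[which(vapply(aaindex, function(a) a$H[1] == id, TRUE))]]$I
    names(e) <- seqinr::a(names(e))
    e[AA_ALPHABET]
  }
  expect_equal(unname(hydrophobicityScale(sc)[AA_ALPHABET]),
               unname(lookup("EISD840101")))
  expect_equal(unname(logPScale(sc)[AA_ALPHABET]),
               unname(lookup("FAUJ830101")))
  expect_equal(unname(helixScale(sc)[AA_ALPHABET]),
               unname(lookup("CHOP780201")))
})

test_that("mean hydrophobicity is the arithmetic scale mean", {
  hyd <- hydrophobicityScale(sc)
  for (r in AA_ALPHABET) {
    expect_equal(meanHydrophobicity(strrep(r, 7)), unname(hyd[[r]]))
  }
  expect_equal(meanHydrophobicity("AG"), (hyd[["A"]] + hyd[["G"]]) / 2)
  expect_equal(meanHydrophobicity(tat),
               sum(hyd[strsplit(tat, "")[[1L]]]) / nchar(tat))
})

test_that("net charge follows the Henderson-Hasselbalch group model", {
  pka <- pkaScale(sc)
  mid <- (pka[["D"]] + pka[["K"]]) / 2
  expect_equal(netCharge("DK", pH = mid), 0, tolerance = 1e-12)
  for (pH in c(1, 5, 7, 12)) expect_equal(netCharge("GGGG", pH = pH), 0)
  expect_equal(netCharge(tat, 7.0), oracleNetCharge(tat, 7.0))
  expect_gt(netCharge(tat, 7.0), 7.9)
  expect_lt(netCharge(tat, 7.0), 8.0)
  expect_error(netCharge("KR", pH = 15), "pH")

  # termini add one basic and one acidic group
  withT <- netCharge("GGGG", 7, includeTermini = TRUE)
  expect_equal(withT,
               1 / (1 + 10^(7 - pka[["nterm"]])) -
                 1 / (1 + 10^(pka[["cterm"]] - 7)))
})

test_that("mean charge matches the per-group oracle on the worked examples", {
  expect_equal(meanCharge(tat), oracleNetCharge(tat, 7) / nchar(tat))
  expect_equal(meanCharge(tat), 0.571, tolerance = 1e-3)  # ~ +8/14
  expect_equal(meanCharge(tatTail), oracleNetCharge(tatTail, 7) / 23)
  expect_equal(meanCharge(tatTail), 0.087, tolerance = 5e-3)  # ~ (8-6)/23
  expect_equal(meanCharge("GGGG"), 0)
})

test_that("isoelectric point matches closed forms and flags degeneracy", {
  pka <- pkaScale(sc)
  expect_equal(as.numeric(isoelectricPoint("DK")),
               (pka[["D"]] + pka[["K"]]) / 2, tolerance = 2e-4)
  expect_false(attr(isoelectricPoint("DK"), "degenerate"))

  pIr <- isoelectricPoint("RRRR")
  expect_true(attr(pIr, "degenerate"))
  expect_equal(as.numeric(pIr), 14)

  pId <- isoelectricPoint("DDDD")
  expect_true(attr(pId, "degenerate"))
  expect_equal(as.numeric(pId), 0)

  expect_equal(as.numeric(isoelectricPoint(tatTail)),
               oracleGridPI(tatTail), tolerance = 2e-4)
})

test_that("isoelectric point agrees with a 1e-4 grid scan on random peptides", {
  set.seed(11)
  for (i in 1:60) {
    s <- randomPeptide(sample(5:50, 1))
    expect_equal(as.numeric(isoelectricPoint(s)), oracleGridPI(s),
                 tolerance = 2e-4)
  }
})

test_that("hydrophobic moment matches the complex-exponential oracle", {
  # 18 residues x 100 degrees wraps the helical wheel exactly five times,
  # so all unit vectors cancel for a homopolymer
  for (r in c("L", "K", "W")) {
    expect_equal(hydrophobicMoment(strrep(r, 18)), 0, tolerance = 1e-12)
  }
  # delta = 0: all vectors aligned, moment is |mean hydrophobicity|
  s <- "LKKLLKLL"
  expect_equal(hydrophobicMoment(s, deltaAngle = 0),
               abs(meanHydrophobicity(s)), tolerance = 1e-12)
  expect_equal(hydrophobicMoment(s), oracleMoment(s), tolerance = 1e-10)
  set.seed(7)
  for (i in 1:50) {
    w <- randomPeptide(sample(2:18, 1))
    expect_equal(hydrophobicMoment(w), oracleMoment(w), tolerance = 1e-10)
  }
  expect_error(hydrophobicMoment("K"), "length >= 2")
})

test_that("window ranges match exhaustive window enumeration", {
  expect_equal(windowRange(strrep("K", 30), "charge"), 0)
  expect_equal(windowRange("KRRK", "charge"), 0)  # shorter than the window

  kd <- paste0(strrep("K", 11), strrep("D", 11))
  expect_equal(windowRange(kd, "charge"), oracleWindowRange(kd, "charge"))
  # extreme windows are all-K vs all-D
  expect_equal(windowRange(kd, "charge"),
               oracleNetCharge(strrep("K", 11), 7) -
                 oracleNetCharge(strrep("D", 11), 7))

  set.seed(13)
  for (i in 1:25) {
    s <- randomPeptide(sample(12:40, 1))
    expect_equal(windowRange(s, "charge"), oracleWindowRange(s, "charge"),
                 tolerance = 1e-12)
    expect_equal(windowRange(s, "hydrophobic_moment"),
                 oracleWindowRange(s, "hydrophobic_moment"),
                 tolerance = 1e-10)
  }
})

test_that("octanol-water partition sum is additive", {
  lgp <- logPScale(sc)
  expect_equal(logPOctanol(strrep("W", 9)), 9 * lgp[["W"]])
  expect_equal(logPOctanol(tat), sum(lgp[strsplit(tat, "")[[1L]]]))
})

test_that("helical content is the helix-former fraction", {
  expect_equal(helicalContent(strrep("A", 12)), 1)
  expect_equal(helicalContent(strrep("G", 12)), 0)
  hel <- helixScale(sc)
  expect_equal(helicalContent(tat),
               mean(hel[strsplit(tat, "")[[1L]]] >= 1))
  alt <- helicalContent(tat, method = "mean_rescaled")
  expect_gte(alt, 0)
  expect_lte(alt, 1)
})

test_that("featurize is deterministic, consistent, and always finite", {
  v1 <- featurize(tat)
  v2 <- featurize(tat)
  expect_identical(v1, v2)
  expect_equal(ncol(v1), 27L)
  expect_identical(colnames(v1), featureNames())
  expect_equal(unname(v1[1, 1:20]), unname(as.numeric(residueCounts(tat))))
  expect_equal(v1[1, "mean_charge"], meanCharge(tat), ignore_attr = TRUE)
  expect_equal(v1[1, "charge_window_range"], windowRange(tat, "charge"),
               ignore_attr = TRUE)
  expect_equal(v1[1, "moment_window_range"],
               windowRange(tat, "hydrophobic_moment"), ignore_attr = TRUE)

  set.seed(17)
  seqs <- vapply(seq_len(300), function(i) randomPeptide(sample(5:50, 1)), "")
  X <- featurize(seqs)
  expect_true(all(is.finite(X)))
  expect_equal(unname(rowSums(X[, 1:20])), nchar(seqs))
  expect_true(all(X[, "helical_content"] >= 0 & X[, "helical_content"] <= 1))
  expect_true(all(X[, "charge_window_range"] >= 0))
  expect_true(all(X[, "moment_window_range"] >= 0))
  expect_true(all(X[, "isoelectric_point"] >= 0 &
                    X[, "isoelectric_point"] <= 14))
})

test_that("global descriptors are permutation-invariant; window ones are not", {
  set.seed(23)
  global <- c(1:23, 26, 27)
  for (i in 1:10) {
    s <- randomPeptide(sample(12:30, 1))
    perm <- paste(sample(strsplit(s, "")[[1L]]), collapse = "")
    expect_equal(featurize(s)[1, global], featurize(perm)[1, global])
  }
  # explicit counterexample: blocked vs alternating charge layout
  blocked <- paste0(strrep("K", 11), strrep("D", 11))
  mixed <- paste(rep(c("K", "D"), 11), collapse = "")
  expect_gt(featurize(blocked)[1, "charge_window_range"],
            featurize(mixed)[1, "charge_window_range"] + 0.5)
})

test_that("appending acidic residues strictly lowers mean charge", {
  set.seed(29)
  for (i in 1:50) {
    s <- randomPeptide(sample(5:30, 1))
    expect_lt(meanCharge(paste0(s, "D")), meanCharge(s))
    expect_lt(meanCharge(paste0(s, "E")), meanCharge(s))
  }
})
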