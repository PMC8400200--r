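#' Sliding-window parameters
#'
#' Controls the two window-based descriptors: the range across windows of the
#' net charge and of the helical-wheel hydrophobic moment.
#'
#' @param width window width in residues (default 11, a common helical-scan
#'   width). Sequences shorter than the width are treated as a single window,
#'   whose range is 0.
#' @param step window step in residues.
#' @param deltaAngle rotation per residue in degrees on the helical wheel
#'   (100 degrees is the alpha-helix convention).
#' @return a list with class `"WindowParams"`.
#' @export
windowParams <- function(width = 11L, step = 1L, deltaAngle = 100) {
  width <- as.integer(width)
  step <- as.integer(step)
  if (width < 2L) stop("window width must be >= 2", call. = FALSE)
  if (step < 1L) stop("window step must be >= 1", call. = FALSE)
  if (!(deltaAngle > 0 && deltaAngle < 360)) {
    stop("deltaAngle must be in (0, 360)", call. = FALSE)
  }
  structure(list(width = width, step = step, deltaAngle = deltaAngle),
            class = "WindowParams")
}

#' Names of the 27 descriptors, in contract order
#'
#' Slots 1--20 are residue counts in alphabetical one-letter order, followed by
#' mean hydrophobicity, mean charge, isoelectric point, sliding-window range
#' of charge, sliding-window range of hydrophobic moment, octanol--water
#' partition sum and helix-former fraction.
#' @return character vector of length 27.
#' @export
featureNames <- function() {
  c(paste0("count_", AA_ALPHABET),
    "mean_hydrophobicity", "mean_charge", "isoelectric_point",
    "charge_window_range", "moment_window_range",
    "logp_octanol", "helical_content")
}

.asSequences <- function(x) {
  if (is(x, "PeptideSet")) return(peptideSequences(x))
  if (is.character(x)) return(peptideSequences(validateSequence(x)))
  stop("expected a PeptideSet or character sequences", call. = FALSE)
}

#' Residue counts
#'
#' @param seq a peptide sequence (single string) or `PeptideSet` of length 1.
#' @return named integer vector of length 20 (alphabetical one-letter order);
#'   the counts sum to the sequence length.
#' @export
residueCounts <- function(seq) {
  s <- .asSequences(seq)[1L]
  setNames(tabulate(match(seqChars(s), AA_ALPHABET), nbins = 20L),
           AA_ALPHABET)
}

#' Mean hydrophobicity
#'
#' Arithmetic mean of the per-residue hydrophobicity values.
#' @inheritParams residueCounts
#' @param scales a [ScaleSet-class].
#' @return a number.
#' @export
meanHydrophobicity <- function(seq, scales = defaultScales()) {
  s <- .asSequences(seq)[1L]
  mean(scales@hydrophobicity[seqChars(s)])
}

# Fractional charge of each residue at the given pH (Henderson-Hasselbalch):
# +1/(1+10^(pH-pKa)) for the basic side chains (H, K, R) and
# -1/(1+10^(pKa-pH)) for the acidic ones (C, D, E, Y); 0 otherwise.
.residueCharges <- function(chars, pH, pka) {
  out <- numeric(length(chars))
  for (r in c("H", "K", "R")) {
    hit <- chars == r
    if (any(hit)) out[hit] <- 1 / (1 + 10^(pH - pka[[r]]))
  }
  for (r in c("C", "D", "E", "Y")) {
    hit <- chars == r
    if (any(hit)) out[hit] <- -1 / (1 + 10^(pka[[r]] - pH))
  }
  out
}

.BASIC <- c("H", "K", "R")
.ACIDIC <- c("C", "D", "E", "Y")

# net charge as a function of pH from counts of ionizable residues;
# vectorized over pH
.netChargeFromCounts <- function(cnt, pH, pka, includeTermini = FALSE) {
  q <- 0
  for (r in .BASIC) {
    if (cnt[[r]] > 0L) q <- q + cnt[[r]] / (1 + 10^(pH - pka[[r]]))
  }
  for (r in .ACIDIC) {
    if (cnt[[r]] > 0L) q <- q - cnt[[r]] / (1 + 10^(pka[[r]] - pH))
  }
  if (includeTermini) {
    q <- q + 1 / (1 + 10^(pH - pka[["nterm"]])) -
      1 / (1 + 10^(pka[["cterm"]] - pH))
  }
  q
}

.pIFromCounts <- function(cnt, pka, tol = 1e-4, includeTermini = FALSE) {
  lo <- 0
  hi <- 14
  flo <- .netChargeFromCounts(cnt, lo, pka, includeTermini)
  fhi <- .netChargeFromCounts(cnt, hi, pka, includeTermini)
  if (flo <= 0 || fhi >= 0) {
    # net charge is monotone non-increasing in pH, so it has constant sign
    pI <- if (abs(flo) <= abs(fhi)) lo else hi
    return(structure(pI, degenerate = TRUE))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.netChargeFromCounts(cnt, mid, pka, includeTermini) > 0) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  structure((lo + hi) / 2, degenerate = FALSE)
}

#' Net charge at a given pH
#'
#' Henderson--Hasselbalch fractional charge summed over ionizable side chains:
#' basic groups (H, K, R) contribute \eqn{1/(1+10^{pH-pKa})}, acidic groups
#' (C, D, E, Y) contribute \eqn{-1/(1+10^{pKa-pH})}. Backbone termini are
#' included only when `includeTermini = TRUE` (off by default; the designed
#' peptides this package models are typically N-terminally conjugated to a
#' fluorophore, which removes the free alpha-amine).
#'
#' @inheritParams meanHydrophobicity
#' @param pH a value in \[0, 14\].
#' @param includeTermini add the alpha-amino and alpha-carboxyl contributions.
#' @return a number.
#' @export
netCharge <- function(seq, pH = 7.0, scales = defaultScales(),
                      includeTermini = FALSE) {
  if (pH < 0 || pH > 14) stop("pH must be in [0, 14]", call. = FALSE)
  s <- .asSequences(seq)[1L]
  pka <- scales@pka
  q <- sum(.residueCharges(seqChars(s), pH, pka))
  if (includeTermini) {
    q <- q + 1 / (1 + 10^(pH - pka[["nterm"]])) -
      1 / (1 + 10^(pka[["cterm"]] - pH))
  }
  q
}

#' Mean charge
#'
#' Net charge at pH 7 divided by sequence length.
#' @inheritParams netCharge
#' @return a number.
#' @export
meanCharge <- function(seq, scales = defaultScales(), includeTermini = FALSE) {
  s <- .asSequences(seq)[1L]
  netCharge(s, pH = 7.0, scales = scales, includeTermini = includeTermini) /
    nchar(s)
}

#' Isoelectric point
#'
#' The pH at which the net charge vanishes, found by bisection over
#' \[0, 14\]. When the charge has constant sign over the whole bracket (no
#' acids, or no bases), no root exists; the bracket endpoint with the smaller
#' absolute charge is returned and flagged via the `"degenerate"` attribute.
#'
#' @inheritParams netCharge
#' @param tol bisection tolerance in pH units.
#' @return the pI, with attribute `degenerate` (logical).
#' @export
isoelectricPoint <- function(seq, scales = defaultScales(), tol = 1e-4,
                             includeTermini = FALSE) {
  s <- .asSequences(seq)[1L]
  chars <- seqChars(s)
  cnt <- vapply(c(.BASIC, .ACIDIC), function(r) sum(chars == r), 0L)
  .pIFromCounts(cnt, scales@pka, tol = tol, includeTermini = includeTermini)
}

#' Helical-wheel hydrophobic moment
#'
#' Eisenberg moment per residue for one window: residues are placed at
#' successive angles `deltaAngle` apart, each carrying its hydrophobicity as a
#' vector magnitude, and the modulus of the vector sum is divided by the
#' window length:
#' \deqn{\mu_H = \frac{1}{N}\sqrt{\left(\sum_k h_k \sin k\delta\right)^2 +
#'   \left(\sum_k h_k \cos k\delta\right)^2},\quad k = 0,\dots,N-1.}
#'
#' @inheritParams meanHydrophobicity
#' @param deltaAngle rotation per residue, degrees.
#' @return a non-negative number.
#' @export
hydrophobicMoment <- function(seq, scales = defaultScales(), deltaAngle = 100) {
  s <- .asSequences(seq)[1L]
  n <- nchar(s)
  if (n < 2L) stop("hydrophobic moment needs a window of length >= 2",
                   call. = FALSE)
  h <- scales@hydrophobicity[seqChars(s)]
  ang <- (seq_len(n) - 1L) * deltaAngle * pi / 180
  sqrt(sum(h * sin(ang))^2 + sum(h * cos(ang))^2) / n
}

#' Sliding-window range of a local statistic
#'
#' Computes the net charge (pH 7, termini off) or the hydrophobic moment on
#' every window of the given width (step `params$step`) and returns
#' `max - min` across windows. A sequence shorter than the width forms a
#' single window, whose range is 0 by definition.
#'
#' @inheritParams meanHydrophobicity
#' @param statistic `"charge"` or `"hydrophobic_moment"`.
#' @param params a [windowParams()] list.
#' @return a non-negative number.
#' @export
windowRange <- function(seq, statistic = c("charge", "hydrophobic_moment"),
                        params = windowParams(), scales = defaultScales()) {
  statistic <- match.arg(statistic)
  s <- .asSequences(seq)[1L]
  n <- nchar(s)
  w <- params$width
  if (n <= w) return(0)
  chars <- seqChars(s)
  starts <- seq.int(1L, n - w + 1L, by = params$step)
  if (length(starts) < 2L) return(0)
  if (statistic == "charge") {
    q <- .residueCharges(chars, 7.0, scales@pka)
    cs <- c(0, cumsum(q))
    vals <- cs[starts + w] - cs[starts]
  } else {
    h <- scales@hydrophobicity[chars]
    ang <- (seq_len(n) - 1L) * params$deltaAngle * pi / 180
    # the modulus of a windowed complex sum is invariant to the phase offset
    # of the window start, so one cumulative sum serves every window
    z <- complex(modulus = 1, argument = ang) * h
    cz <- c(0 + 0i, cumsum(z))
    vals <- Mod(cz[starts + w] - cz[starts]) / w
  }
  max(vals) - min(vals)
}

#' Octanol--water partition sum
#'
#' Additive side-chain partition coefficient: the sum over residues of the
#' per-residue value (Fauchere--Pliska by default). An additive approximation;
#' no backbone or conformation term.
#'
#' @inheritParams meanHydrophobicity
#' @return a number.
#' @export
logPOctanol <- function(seq, scales = defaultScales()) {
  s <- .asSequences(seq)[1L]
  sum(scales@logP[seqChars(s)])
}

#' Approximate alpha-helical content
#'
#' Default: the fraction of residues whose helix propensity is at least 1
#' (helix formers under Chou--Fasman P-alpha), a number in \[0, 1\]. The
#' alternative `"mean_rescaled"` method returns the mean propensity rescaled
#' to \[0, 1\] over the scale's own range.
#'
#' @inheritParams meanHydrophobicity
#' @param method `"former_fraction"` (default) or `"mean_rescaled"`.
#' @return a number in \[0, 1\].
#' @export
helicalContent <- function(seq, scales = defaultScales(),
                           method = c("former_fraction", "mean_rescaled")) {
  method <- match.arg(method)
  s <- .asSequences(seq)[1L]
  p <- scales@helix[seqChars(s)]
  if (method == "former_fraction") {
    mean(p >= 1.00)
  } else {
    rng <- range(scales@helix[AA_ALPHABET])
    min(max((mean(p) - rng[1L]) / (rng[2L] - rng[1L]), 0), 1)
  }
}

#' Featurize peptides into the 27-descriptor matrix
#'
#' Computes, per sequence, the fixed-order descriptor vector: 20 residue
#' counts, mean hydrophobicity, mean charge, isoelectric point, sliding-window
#' range of charge, sliding-window range of hydrophobic moment, octanol--water
#' partition sum and helix-former fraction. Deterministic: identical input
#' gives an identical matrix.
#'
#' @param x a `PeptideSet` or character vector of sequences.
#' @param scales a [ScaleSet-class].
#' @param params a [windowParams()] list.
#' @param normalizeCounts divide the 20 count slots by sequence length
#'   (default off: raw counts).
#' @param includeTermini include backbone termini in charge terms.
#' @return numeric matrix, one row per peptide, 27 named columns.
#' @examples
#' featurize("YGRKKRRQRRRFFG")[, "mean_charge"]
#' @export
featurize <- function(x, scales = defaultScales(), params = windowParams(),
                      normalizeCounts = FALSE, includeTermini = FALSE) {
  ids <- if (is(x, "PeptideSet")) peptideIds(x) else NULL
  seqs <- .asSequences(x)
  hyd <- scales@hydrophobicity
  lgp <- scales@logP
  hel <- scales@helix
  out <- matrix(NA_real_, nrow = length(seqs), ncol = 27L,
                dimnames = list(ids, featureNames()))
  pka <- scales@pka
  w <- params$width
  dAng <- params$deltaAngle
  for (i in seq_along(seqs)) {
    chars <- seqChars(seqs[i])
    n <- length(chars)
    counts <- tabulate(match(chars, AA_ALPHABET), nbins = 20L)
    ion <- vapply(c(.BASIC, .ACIDIC), function(r) sum(chars == r), 0L)
    net <- .netChargeFromCounts(ion, 7.0, pka, includeTermini)
    pI <- as.numeric(.pIFromCounts(ion, pka, includeTermini = includeTermini))
    h <- hyd[chars]
    if (n <= w) {
      qRange <- 0
      mRange <- 0
    } else {
      starts <- seq.int(1L, n - w + 1L, by = params$step)
      q <- .residueCharges(chars, 7.0, pka)
      cs <- c(0, cumsum(q))
      qw <- cs[starts + w] - cs[starts]
      qRange <- max(qw) - min(qw)
      ang <- (seq_len(n) - 1L) * dAng * pi / 180
      cz <- c(0 + 0i, cumsum(complex(modulus = 1, argument = ang) * h))
      mw <- Mod(cz[starts + w] - cz[starts]) / w
      mRange <- max(mw) - min(mw)
    }
    out[i, ] <- c(
      if (normalizeCounts) counts / n else counts,
      mean(h),
      net / n,
      pI,
      qRange,
      mRange,
      sum(lgp[chars]),
      mean(hel[chars] >= 1.00)
    )
  }
  out
}
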