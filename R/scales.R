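#' Per-residue physicochemical scales
#'
#' A `ScaleSet` bundles the four per-residue tables the descriptor layer
#' consumes: a hydrophobicity scale (used for the mean hydrophobicity and the
#' helical-wheel hydrophobic moment), side-chain acid-dissociation constants
#' (Henderson--Hasselbalch charge and isoelectric point), additive side-chain
#' octanol--water partition values, and alpha-helix propensities.
#'
#' @slot name identifier of the set, carried into model archives.
#' @slot hydrophobicity named numeric, one value per canonical residue.
#' @slot pka named numeric: side-chain pKa for the ionizable residues
#'   (C, D, E, H, K, R, Y) plus `nterm`/`cterm` for the backbone termini.
#' @slot logP named numeric, additive side-chain octanol--water partition
#'   contribution per residue.
#' @slot helix named numeric, helix propensity per residue; residues with a
#'   value >= 1 are counted as helix formers.
#'
#' @seealso [defaultScales()]
#' @export
setClass("ScaleSet",
  representation(
    name = "character",
    hydrophobicity = "numeric",
    pka = "numeric",
    logP = "numeric",
    helix = "numeric"
  )
)

setValidity("ScaleSet", function(object) {
  msg <- character()
  for (s in c("hydrophobicity", "logP", "helix")) {
    v <- slot(object, s)
    if (!all(AA_ALPHABET %in% names(v)) || !all(is.finite(v[AA_ALPHABET]))) {
      msg <- c(msg, sprintf("'%s' must be finite and cover all 20 residues", s))
    }
  }
  needed <- c("C", "D", "E", "H", "K", "R", "Y", "nterm", "cterm")
  if (!all(needed %in% names(object@pka)) ||
      !all(is.finite(object@pka[needed]))) {
    msg <- c(msg, "'pka' must cover C, D, E, H, K, R, Y, nterm, cterm")
  }
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be length 1")
  if (length(msg)) msg else TRUE
})

# Eisenberg consensus hydrophobicity (standardized form, AAindex EISD840101).
.EISENBERG <- c(
  A =  0.25, C =  0.04, D = -0.72, E = -0.62, F =  0.61,
  G =  0.16, H = -0.40, I =  0.73, K = -1.10, L =  0.53,
  M =  0.26, N = -0.64, P = -0.07, Q = -0.69, R = -1.76,
  S = -0.26, T = -0.18, V =  0.54, W =  0.37, Y =  0.02
)

# EMBOSS pKa set (iep defaults).
.EMBOSS_PKA <- c(
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1,
  nterm = 8.6, cterm = 3.6
)

# Fauchere-Pliska side-chain hydrophobic parameter pi (AAindex FAUJ830101),
# used as an additive octanol-water partition contribution.
.FAUCHERE_PLISKA <- c(
  A =  0.31, C =  1.54, D = -0.77, E = -0.64, F =  1.79,
  G =  0.00, H =  0.13, I =  1.80, K = -0.99, L =  1.70,
  M =  1.23, N = -0.60, P =  0.72, Q = -0.22, R = -1.01,
  S = -0.04, T =  0.26, V =  1.22, W =  2.25, Y =  0.96
)

# Chou-Fasman normalized alpha-helix frequency P-alpha (AAindex CHOP780201).
.CHOU_FASMAN_ALPHA <- c(
  A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13,
  G = 0.57, H = 1.00, I = 1.08, K = 1.16, L = 1.21,
  M = 1.45, N = 0.67, P = 0.57, Q = 1.11, R = 0.98,
  S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69
)

#' Default descriptor scales
#'
#' Returns the scale set the package uses unless told otherwise: Eisenberg
#' consensus hydrophobicity, the EMBOSS pKa set, Fauchere--Pliska side-chain
#' octanol--water partition values, and Chou--Fasman alpha-helix propensities.
#' Any table can be overridden, e.g. to swap in another hydrophobicity scale.
#'
#' @param name identifier stored with the set.
#' @param hydrophobicity,pka,logP,helix optional named numeric vectors
#'   replacing the corresponding default table.
#' @return a [ScaleSet-class] object.
#' @examples
#' sc <- defaultScales()
#' hydrophobicityScale(sc)[["W"]]
#' @export
defaultScales <- function(name = "default",
                          hydrophobicity = .EISENBERG,
                          pka = .EMBOSS_PKA,
                          logP = .FAUCHERE_PLISKA,
                          helix = .CHOU_FASMAN_ALPHA) {
  new("ScaleSet",
    name = name,
    hydrophobicity = hydrophobicity,
    pka = pka,
    logP = logP,
    helix = helix
  )
}

#' @describeIn ScaleSet-class hydrophobicity table accessor
#' @param x a `ScaleSet`
#' @export
hydrophobicityScale <- function(x) x@hydrophobicity

#' @describeIn ScaleSet-class pKa table accessor
#' @export
pkaScale <- function(x) x@pka

#' @describeIn ScaleSet-class octanol--water partition table accessor
#' @export
logPScale <- function(x) x@logP

#' @describeIn ScaleSet-class helix-propensity table accessor
#' @export
helixScale <- function(x) x@helix

#' @describeIn ScaleSet-class name accessor
#' @export
scaleSetName <- function(x) x@name

setMethod("show", "ScaleSet", function(object) {
  cat("ScaleSet '", object@name, "'\n", sep = "")
  cat("  hydrophobicity range: ",
      paste(range(object@hydrophobicity), collapse = " .. "), "\n", sep = "")
  cat("  ionizable groups: ",
      paste(setdiff(names(object@pka), c("nterm", "cterm")), collapse = ""),
      " (+ termini)\n", sep = "")
})
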