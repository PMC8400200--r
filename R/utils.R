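#' The 20 canonical amino acids, alphabetical one-letter order
#'
#' Order is part of the descriptor contract: the first 20 descriptor slots are
#' residue counts in this order.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so seeded package routines do not perturb user code.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

# split a sequence into its residue characters
seqChars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

stopIfNot20 <- function(x, what) {
  if (!all(AA_ALPHABET %in% names(x))) {
    stop(sprintf("%s must provide a value for all 20 canonical residues", what),
         call. = FALSE)
  }
  if (!all(is.finite(x[AA_ALPHABET]))) {
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  }
  invisible(TRUE)
}
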