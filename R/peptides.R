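#' A validated collection of peptide sequences
#'
#' `PeptideSet` is the package's container for peptide records: an identifier,
#' a validated uppercase sequence over the 20 canonical amino acids, an
#' optional binary class label (1 = CPP, 0 = non-CPP) and an optional
#' free-text chirality note (e.g. `"all-D"`). The chirality note is metadata
#' only: all descriptors are functions of the letter sequence, so an all-D
#' isomer featurizes identically to its L counterpart.
#'
#' @slot ids character vector of identifiers.
#' @slot sequences character vector of validated peptide sequences.
#' @slot labels integer vector, each element 0, 1 or `NA`.
#' @slot chirality character vector of notes, `NA` when absent.
#' @export
setClass("PeptideSet",
  representation(
    ids = "character",
    sequences = "character",
    labels = "integer",
    chirality = "character"
  )
)

setValidity("PeptideSet", function(object) {
  n <- length(object@sequences)
  msg <- character()
  if (length(object@ids) != n || length(object@labels) != n ||
      length(object@chirality) != n) {
    msg <- c(msg, "ids, sequences, labels and chirality must have equal length")
  }
  bad <- .sequenceProblem(object@sequences)
  if (!is.na(bad)) msg <- c(msg, bad)
  lab <- object@labels
  if (!all(is.na(lab) | lab %in% c(0L, 1L))) {
    msg <- c(msg, "labels must be 0, 1 or NA")
  }
  if (length(msg)) msg else TRUE
})

# first validation problem over a vector of already-normalized sequences,
# or NA if none
.sequenceProblem <- function(seqs) {
  if (any(!nzchar(seqs))) return("empty sequence")
  for (s in seqs) {
    ch <- seqChars(s)
    off <- which(!(ch %in% AA_ALPHABET))
    if (length(off)) {
      return(sprintf("non-canonical residue '%s' at position %d", ch[off[1L]],
                     off[1L]))
    }
  }
  NA_character_
}

#' Validate raw peptide input
#'
#' Strips whitespace, uppercases, and checks that every character is one of
#' the 20 canonical one-letter amino-acid codes. Validation is idempotent:
#' applying it to an already-valid sequence changes nothing.
#'
#' @param raw character vector of raw sequences.
#' @param ids identifiers (recycled default `"peptide"`, made unique).
#' @param labels optional labels in \{0, 1\} (NA allowed).
#' @param chirality optional free-text chirality notes.
#' @return a [PeptideSet-class].
#' @examples
#' validateSequence("ygrkkrrqrrrffg", ids = "TatNep")
#' @export
validateSequence <- function(raw, ids = NULL, labels = NA, chirality = NA) {
  if (!is.character(raw)) stop("'raw' must be character", call. = FALSE)
  seqs <- unname(toupper(gsub("[[:space:]]+", "", raw)))
  if (any(!nzchar(seqs))) stop("empty sequence", call. = FALSE)
  problem <- .sequenceProblem(seqs)
  if (!is.na(problem)) stop(problem, call. = FALSE)
  n <- length(seqs)
  if (is.null(ids)) {
    ids <- if (n == 1L) "peptide" else paste0("peptide", seq_len(n))
  }
  new("PeptideSet",
    ids = as.character(rep_len(ids, n)),
    sequences = seqs,
    labels = as.integer(rep_len(labels, n)),
    chirality = as.character(rep_len(chirality, n))
  )
}

#' @describeIn PeptideSet-class identifiers
#' @param x a `PeptideSet`
#' @export
peptideIds <- function(x) x@ids

#' @describeIn PeptideSet-class sequences as a character vector
#' @export
peptideSequences <- function(x) x@sequences

#' @describeIn PeptideSet-class labels (0/1/NA integer vector)
#' @export
peptideLabels <- function(x) x@labels

#' @describeIn PeptideSet-class chirality notes
#' @export
chiralityNotes <- function(x) x@chirality

#' @export
setMethod("length", "PeptideSet", function(x) length(x@sequences))

#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = TRUE) {
  new("PeptideSet",
    ids = x@ids[i], sequences = x@sequences[i],
    labels = x@labels[i], chirality = x@chirality[i]
  )
})

setMethod("show", "PeptideSet", function(object) {
  n <- length(object)
  lab <- object@labels
  cat("PeptideSet with ", n, " peptide", if (n != 1) "s", "\n", sep = "")
  if (any(!is.na(lab))) {
    cat("  labels: ", sum(lab == 1L, na.rm = TRUE), " CPP / ",
        sum(lab == 0L, na.rm = TRUE), " non-CPP\n", sep = "")
  }
  show_n <- min(n, 5L)
  for (i in seq_len(show_n)) {
    cat(sprintf("  %-12s %s%s\n", object@ids[i], object@sequences[i],
                if (!is.na(lab[i])) sprintf("  [%d]", lab[i]) else ""))
  }
  if (n > show_n) cat("  ...\n")
})

#' Read peptides from a FASTA file
#'
#' The header token before the first whitespace becomes the record id;
#' line-wrapped sequences are concatenated; all sequences are validated as
#' canonical peptides.
#'
#' @param path FASTA file.
#' @return a [PeptideSet-class].
#' @export
readPeptideFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (length(content) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(trimws(lines[content[1L]]), ">")) {
    stop(sprintf("malformed FASTA: sequence before first header at line %d",
                 content[1L]), call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "[[:space:]]+"), `[`, "", 1L)
  validateSequence(as.character(aa), ids = ids)
}

#' Write peptides to a FASTA file
#'
#' @param x a [PeptideSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePeptideFasta <- function(x, path) {
  stopifnot(is(x, "PeptideSet"))
  aa <- Biostrings::AAStringSet(setNames(x@sequences, x@ids))
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

#' Read a labeled CPP/non-CPP training dataset
#'
#' Two dialects are supported: a two-column tab-separated file
#' (`sequence<TAB>label`, label 0 or 1) or a pair of FASTA files holding
#' positives and negatives. Training requires both classes to be present.
#'
#' @param path dataset file (TSV dialect) or positives FASTA (paired dialect).
#' @param dialect `"tsv"` (default) or `"fasta_pair"`.
#' @param negatives negatives FASTA, required for `dialect = "fasta_pair"`.
#' @param allowDuplicates keep duplicated (sequence, label) pairs and
#'   sequences carrying conflicting labels instead of rejecting them.
#' @param quiet suppress the class-count message.
#' @return a labeled [PeptideSet-class].
#' @export
readLabeledDataset <- function(path, dialect = c("tsv", "fasta_pair"),
                               negatives = NULL, allowDuplicates = FALSE,
                               quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             comment.char = "")
    if (ncol(tab) < 2L) {
      stop("TSV dataset needs two columns: sequence<TAB>label", call. = FALSE)
    }
    labs <- suppressWarnings(as.numeric(tab[[2L]]))
    if (any(is.na(labs)) || !all(labs %in% c(0, 1))) {
      bad <- which(is.na(labs) | !(labs %in% c(0, 1)))[1L]
      stop(sprintf("invalid label '%s' on row %d: labels must be 0 or 1",
                   tab[[2L]][bad], bad), call. = FALSE)
    }
    ps <- validateSequence(tab[[1L]],
                           ids = paste0("seq", seq_len(nrow(tab))),
                           labels = as.integer(labs))
  } else {
    if (is.null(negatives)) {
      stop("dialect 'fasta_pair' needs a 'negatives' FASTA", call. = FALSE)
    }
    pos <- readPeptideFasta(path)
    neg <- readPeptideFasta(negatives)
    ps <- new("PeptideSet",
      ids = c(pos@ids, neg@ids),
      sequences = c(pos@sequences, neg@sequences),
      labels = c(rep(1L, length(pos)), rep(0L, length(neg))),
      chirality = rep(NA_character_, length(pos) + length(neg))
    )
  }
  .checkTrainingSet(ps, allowDuplicates = allowDuplicates)
  if (!quiet) {
    message(sprintf("labeled dataset: %d CPP, %d non-CPP",
                    sum(ps@labels == 1L), sum(ps@labels == 0L)))
  }
  ps
}

.checkTrainingSet <- function(ps, allowDuplicates = FALSE) {
  lab <- ps@labels
  if (any(is.na(lab))) stop("all training records must be labeled", call. = FALSE)
  if (length(unique(lab)) < 2L) {
    stop("training requires both classes", call. = FALSE)
  }
  if (!allowDuplicates) {
    key <- paste(ps@sequences, lab)
    if (anyDuplicated(key)) {
      stop("duplicate (sequence, label) pairs in dataset; ",
           "set allowDuplicates = TRUE to keep them", call. = FALSE)
    }
    conf <- tapply(lab, ps@sequences, function(v) length(unique(v)))
    if (any(conf > 1L)) {
      stop("sequence(s) present with conflicting labels; ",
           "set allowDuplicates = TRUE to keep them", call. = FALSE)
    }
  }
  invisible(ps)
}
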