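#' A moonlighting-design task
#'
#' Describes what the residue-addition search must achieve: a fixed motif
#' that has to stay intact and contiguous in every design, a direction
#' (`embed_cpp` pushes P(CPP) up so the motif ends up inside a working CPP;
#' `embed_noncpp` pushes P(CPP) down so a CPP core is silenced until
#' proteolytic activation), where residues may be added, a budget of added
#' residues, the residue alphabet allowed for additions, and the success
#' threshold on P(CPP).
#'
#' @slot motif fixed sequence that must appear intact in every design.
#' @slot mode `"embed_cpp"` or `"embed_noncpp"`.
#' @slot placement `"both_termini"`, `"n_terminal_tail"` or
#'   `"c_terminal_tail"`.
#' @slot maxAdded total added-residue budget.
#' @slot alphabet residues allowed for additions.
#' @slot targetP success threshold: designs succeed when P(CPP) >= targetP
#'   (`embed_cpp`) or P(CPP) <= targetP (`embed_noncpp`).
#' @export
setClass("DesignTask",
  representation(
    motif = "character",
    mode = "character",
    placement = "character",
    maxAdded = "integer",
    alphabet = "character",
    targetP = "numeric"
  )
)

setValidity("DesignTask", function(object) {
  msg <- character()
  bad <- .sequenceProblem(object@motif)
  if (!is.na(bad)) msg <- c(msg, paste("motif:", bad))
  if (!object@mode %in% c("embed_cpp", "embed_noncpp")) {
    msg <- c(msg, "mode must be embed_cpp or embed_noncpp")
  }
  if (!object@placement %in%
      c("both_termini", "n_terminal_tail", "c_terminal_tail")) {
    msg <- c(msg, "invalid placement")
  }
  if (!(object@maxAdded >= 0L && object@maxAdded <= 30L)) {
    msg <- c(msg, "maxAdded must be in [0, 30]")
  }
  if (!all(object@alphabet %in% AA_ALPHABET)) {
    msg <- c(msg, "alphabet must be canonical residues")
  }
  if (!(object@targetP >= 0 && object@targetP <= 1)) {
    msg <- c(msg, "targetP must be in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a design task
#'
#' @param motif the fixed functional sequence (ligand, or CPP core plus
#'   cleavage site) that every design must contain intact.
#' @param mode `"embed_cpp"` (default; make the design a CPP) or
#'   `"embed_noncpp"` (silence a CPP core).
#' @param placement where residues may be added. Defaults by mode:
#'   `both_termini` for `embed_cpp` (flanks on either side of the motif),
#'   `c_terminal_tail` for `embed_noncpp` (an appended inhibitory tail).
#' @param maxAdded total added-residue cap (default 12).
#' @param alphabet residues allowed in the additions (default all 20).
#' @param targetP success threshold; defaults to 0.88 for `embed_cpp` and
#'   0.20 for `embed_noncpp`.
#' @return a [DesignTask-class].
#' @examples
#' designTask("WHWLQLKPGQPMY", mode = "embed_cpp")
#' @export
designTask <- function(motif, mode = c("embed_cpp", "embed_noncpp"),
                       placement = NULL, maxAdded = 12L,
                       alphabet = AA_ALPHABET, targetP = NULL) {
  mode <- match.arg(mode)
  if (is.null(placement)) {
    placement <- if (mode == "embed_cpp") "both_termini" else "c_terminal_tail"
  }
  if (is.null(targetP)) {
    targetP <- if (mode == "embed_cpp") 0.88 else 0.20
  }
  motif <- peptideSequences(validateSequence(motif))[1L]
  new("DesignTask",
    motif = motif, mode = mode, placement = placement,
    maxAdded = as.integer(maxAdded),
    alphabet = toupper(alphabet), targetP = targetP
  )
}

setMethod("show", "DesignTask", function(object) {
  cat("DesignTask (", object@mode, ", ", object@placement, ")\n", sep = "")
  cat("  motif: ", object@motif, "\n", sep = "")
  cat("  budget: ", object@maxAdded, " added residues from {",
      paste(object@alphabet, collapse = ""), "}\n", sep = "")
  cat("  success: P(CPP) ",
      if (object@mode == "embed_cpp") ">=" else "<=", " ",
      object@targetP, "\n", sep = "")
})

#' Genetic-search parameters
#'
#' @param population population size.
#' @param generations number of generations.
#' @param mutationRate,insertionRate,deletionRate per-offspring probabilities
#'   of a point mutation, a single-residue insertion, a single-residue
#'   deletion (all restricted to the added flanks; the motif is never
#'   touched).
#' @param elitism number of top genomes copied unchanged each generation.
#' @param lambda length penalty per added residue, subtracted from the raw
#'   fitness; small by default so it breaks ties toward shorter designs
#'   without overriding a threshold crossing.
#' @param tournament tournament size for parent selection.
#' @param seed integer RNG seed.
#' @return a list with class `"SearchParams"`.
#' @export
searchParams <- function(population = 64L, generations = 200L,
                         mutationRate = 0.1, insertionRate = 0.05,
                         deletionRate = 0.05, elitism = 4L, lambda = 0.01,
                         tournament = 3L, seed = 1L) {
  if (population < 2L) stop("population must be >= 2", call. = FALSE)
  rates <- c(mutationRate, insertionRate, deletionRate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  structure(
    list(population = as.integer(population),
         generations = as.integer(generations),
         mutationRate = mutationRate, insertionRate = insertionRate,
         deletionRate = deletionRate, elitism = as.integer(elitism),
         lambda = lambda, tournament = as.integer(tournament),
         seed = as.integer(seed)),
    class = "SearchParams"
  )
}

#' Check that a motif is intact inside a design
#'
#' @param design full peptide sequence.
#' @param motif the motif to locate.
#' @return list with `found` (TRUE iff the motif occurs as a contiguous
#'   substring), `start`/`end` (0-based, half-open span of the first
#'   occurrence; `NA` when absent) and `count` (number of occurrences,
#'   counting overlapping ones).
#' @examples
#' verifyMotif("RLWHWLQLKPGQPMYWRQPKSKRKVRR", "WHWLQLKPGQPMY")
#' @export
verifyMotif <- function(design, motif) {
  # lookahead so overlapping occurrences are counted too
  hits <- gregexpr(paste0("(?=", motif, ")"), design, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) {
    return(list(found = FALSE, start = NA_integer_, end = NA_integer_,
                count = 0L))
  }
  list(found = TRUE,
       start = hits[1L] - 1L,
       end = hits[1L] - 1L + nchar(motif),
       count = length(hits))
}

# dispatch P(CPP) over either a CPPForest or a plain scoring function
# (character vector of sequences -> numeric probabilities)
.predictP <- function(model, seqs) {
  if (is.function(model)) {
    p <- model(seqs)
    if (length(p) != length(seqs)) {
      stop("scoring function must return one probability per sequence",
           call. = FALSE)
    }
    return(as.numeric(p))
  }
  predictPCPP(model, seqs)$p_cpp
}

#' Evaluate one candidate design
#'
#' Featurizes and scores the candidate, derives the mode-specific fitness
#' (raw = P(CPP) for `embed_cpp`, 1 - P(CPP) for `embed_noncpp`) and the
#' length-penalized fitness, and reports the added flanks and motif span.
#'
#' @param candidate full candidate sequence; must contain the task motif.
#' @param task a [DesignTask-class].
#' @param model a [CPPForest-class] or a scoring function.
#' @param lambda length penalty per added residue.
#' @return one-row data.frame with columns `sequence`, `p_cpp`, `raw`,
#'   `penalized`, `added_n`, `added_c`, `n_added`, `motif_start`,
#'   `motif_end`, `success`.
#' @export
evaluateDesign <- function(candidate, task, model, lambda = 0) {
  stopifnot(is(task, "DesignTask"))
  candidate <- peptideSequences(validateSequence(candidate))[1L]
  hit <- verifyMotif(candidate, task@motif)
  if (!hit$found) {
    stop("candidate does not contain the motif intact", call. = FALSE)
  }
  p <- .predictP(model, candidate)
  .designRow(candidate, p, task, lambda, hit)
}

.designRow <- function(candidate, p, task, lambda, hit) {
  nAdded <- nchar(candidate) - nchar(task@motif)
  raw <- if (task@mode == "embed_cpp") p else 1 - p
  success <- if (task@mode == "embed_cpp") p >= task@targetP else
    p <= task@targetP
  data.frame(
    sequence = candidate,
    p_cpp = p,
    raw = raw,
    penalized = raw - lambda * nAdded,
    added_n = substr(candidate, 1L, hit$start),
    added_c = substr(candidate, hit$end + 1L, nchar(candidate)),
    n_added = nAdded,
    motif_start = hit$start,
    motif_end = hit$end,
    success = success,
    stringsAsFactors = FALSE
  )
}

# comparator order for "best design": penalized fitness desc, then fewer
# added residues, then lexicographic sequence
.bestOrder <- function(df) {
  order(-df$penalized, df$n_added, df$sequence)
}

# ranking order for reported successes: fewest additions first, then fitness
.rankOrder <- function(df) {
  order(df$n_added, -df$penalized, df$sequence)
}

.assemble <- function(nf, cf, motif) paste0(nf, motif, cf)

.randomFlank <- function(len, alphabet) {
  if (len == 0L) return("")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# mutate one genome (list(nf, cf)) under the placement/budget constraints
.mutateGenome <- function(g, task, search) {
  nBoth <- nchar(g$nf) + nchar(g$cf)
  slots <- switch(task@placement,
    both_termini = c("nf", "cf"),
    n_terminal_tail = "nf",
    c_terminal_tail = "cf"
  )
  if (runif(1) < search$mutationRate && nBoth > 0L) {
    pos <- sample.int(nBoth, 1L)
    tgt <- if (pos <= nchar(g$nf)) "nf" else "cf"
    at <- if (tgt == "nf") pos else pos - nchar(g$nf)
    s <- seqChars(g[[tgt]])
    s[at] <- sample(task@alphabet, 1L)
    g[[tgt]] <- paste(s, collapse = "")
  }
  if (runif(1) < search$insertionRate && nBoth < task@maxAdded) {
    tgt <- if (length(slots) == 1L) slots else sample(slots, 1L)
    s <- seqChars(g[[tgt]])
    at <- sample.int(length(s) + 1L, 1L)
    g[[tgt]] <- paste(append(s, sample(task@alphabet, 1L), after = at - 1L),
                      collapse = "")
  }
  if (runif(1) < search$deletionRate && nBoth > 0L) {
    pos <- sample.int(nBoth, 1L)
    tgt <- if (pos <= nchar(g$nf)) "nf" else "cf"
    at <- if (tgt == "nf") pos else pos - nchar(g$nf)
    s <- seqChars(g[[tgt]])
    g[[tgt]] <- paste(s[-at], collapse = "")
  }
  g
}

#' Design a moonlighting peptide by genetic search
#'
#' Searches over added flank strings (the motif itself is immutable) with a
#' seeded genetic algorithm: tournament selection on the length-penalized
#' fitness, elitism, and point-mutation / single-residue insertion / deletion
#' operators restricted to the flanks. Candidates whose flanks accidentally
#' recreate the motif (so it occurs more than once) are discarded. Every
#' evaluated design respects the added-residue budget.
#'
#' @param task a [DesignTask-class].
#' @param model a [CPPForest-class] or a scoring function
#'   (character vector -> numeric P(CPP)).
#' @param search a [searchParams()] list.
#' @return data.frame of designs. If any candidate met the target, all
#'   distinct successful designs are returned, ranked by fewest added
#'   residues, then penalized fitness, then sequence; otherwise the single
#'   best design found with `success = FALSE`. The attribute `"audit"`
#'   carries every distinct design evaluated during the whole run, and
#'   `"n_discarded"` counts candidates rejected for motif duplication.
#' @examples
#' stub <- function(seqs) as.numeric(vapply(seqs, meanCharge, 0) > 0.3)
#' task <- designTask("WHWLQLKPGQPMY", alphabet = c("D", "E", "K", "R"),
#'                    maxAdded = 4, targetP = 1)
#' head(designPeptide(task, stub,
#'                    searchParams(generations = 30, seed = 2)))
#' @export
designPeptide <- function(task, model, search = searchParams()) {
  stopifnot(is(task, "DesignTask"))
  archive <- new.env(parent = emptyenv())
  nDiscarded <- 0L
  evalBatch <- function(genomes) {
    seqs <- vapply(genomes, function(g) .assemble(g$nf, g$cf, task@motif), "")
    fresh <- unique(seqs[!vapply(seqs, exists, TRUE, envir = archive)])
    if (length(fresh)) {
      keep <- vapply(fresh,
                     function(s) verifyMotif(s, task@motif)$count == 1L, TRUE)
      nDiscarded <<- nDiscarded + sum(!keep)
      for (s in fresh[!keep]) assign(s, NULL, envir = archive)
      valid <- fresh[keep]
      if (length(valid)) {
        p <- .predictP(model, valid)
        for (i in seq_along(valid)) {
          hit <- verifyMotif(valid[i], task@motif)
          assign(valid[i],
                 .designRow(valid[i], p[i], task, search$lambda, hit),
                 envir = archive)
        }
      }
    }
    vapply(seqs, function(s) {
      row <- get(s, envir = archive)
      if (is.null(row)) -Inf else row$penalized
    }, 0)
  }

  withSeed(search$seed, {
    pop <- list(list(nf = "", cf = ""))
    while (length(pop) < search$population) {
      maxInit <- min(4L, task@maxAdded)
      nLen <- if (task@placement == "c_terminal_tail") 0L else
        sample.int(maxInit + 1L, 1L) - 1L
      cLen <- if (task@placement == "n_terminal_tail") 0L else
        sample.int(min(maxInit, task@maxAdded - nLen) + 1L, 1L) - 1L
      pop[[length(pop) + 1L]] <- list(
        nf = .randomFlank(nLen, task@alphabet),
        cf = .randomFlank(cLen, task@alphabet)
      )
    }
    fit <- evalBatch(pop)
    for (gen in seq_len(search$generations)) {
      ord <- order(-fit)
      elite <- pop[ord[seq_len(min(search$elitism, length(pop)))]]
      offspring <- elite
      while (length(offspring) < search$population) {
        contenders <- sample.int(length(pop), search$tournament,
                                 replace = TRUE)
        parent <- pop[[contenders[which.max(fit[contenders])]]]
        offspring[[length(offspring) + 1L]] <-
          .mutateGenome(parent, task, search)
      }
      pop <- offspring
      fit <- evalBatch(pop)
    }
  })

  rows <- Filter(Negate(is.null),
                 lapply(ls(archive, sorted = TRUE),
                        function(s) get(s, envir = archive)))
  audit <- do.call(rbind, rows)
  successes <- audit[audit$success, , drop = FALSE]
  out <- if (nrow(successes)) {
    successes[.rankOrder(successes), , drop = FALSE]
  } else {
    audit[.bestOrder(audit)[1L], , drop = FALSE]
  }
  rownames(out) <- NULL
  rownames(audit) <- NULL
  attr(out, "audit") <- audit
  attr(out, "n_discarded") <- nDiscarded
  out
}

#' Exhaustive flank search (small spaces)
#'
#' Enumerates every flank assignment with total added length up to
#' `maxTotalFlank` over the alphabet, under the task's placement constraint,
#' and returns the best design by the same comparator the genetic search
#' uses (penalized fitness, then fewer additions, then sequence). Intended
#' as an oracle for validating the genetic search on small spaces.
#'
#' @param task a [DesignTask-class].
#' @param model a [CPPForest-class] or scoring function.
#' @param maxTotalFlank cap on total added residues to enumerate.
#' @param alphabet residues to enumerate (default: the task's alphabet).
#' @param lambda length penalty per added residue.
#' @param guard refuse to enumerate more than this many candidates.
#' @return one-row data.frame (same columns as [evaluateDesign()]).
#' @export
exhaustiveDesign <- function(task, model, maxTotalFlank = task@maxAdded,
                             alphabet = task@alphabet, lambda = 0.01,
                             guard = 1e6) {
  stopifnot(is(task, "DesignTask"))
  a <- length(alphabet)
  total <- 0
  for (t in 0:maxTotalFlank) {
    nSplits <- switch(task@placement,
      both_termini = t + 1,
      n_terminal_tail = 1,
      c_terminal_tail = 1
    )
    total <- total + nSplits * a^t
  }
  if (total > guard) {
    stop(sprintf(paste("exhaustive enumeration would visit %.3g candidates",
                       "(guard %.3g); shrink the alphabet or the flank cap"),
                 total, guard), call. = FALSE)
  }
  allStrings <- function(len) {
    if (len == 0L) return("")
    do.call(paste0, expand.grid(rep(list(alphabet), len),
                                stringsAsFactors = FALSE))
  }
  seqs <- character()
  for (t in 0:maxTotalFlank) {
    nLens <- switch(task@placement,
      both_termini = 0:t,
      n_terminal_tail = t,
      c_terminal_tail = 0L
    )
    for (nl in nLens) {
      cl <- t - nl
      if (task@placement == "n_terminal_tail" && cl > 0L) next
      nfs <- allStrings(nl)
      cfs <- allStrings(cl)
      grid <- expand.grid(nf = nfs, cf = cfs, stringsAsFactors = FALSE)
      seqs <- c(seqs, .assemble(grid$nf, grid$cf, task@motif))
    }
  }
  seqs <- unique(seqs)
  keep <- vapply(seqs, function(s) verifyMotif(s, task@motif)$count == 1L,
                 TRUE)
  seqs <- seqs[keep]
  p <- .predictP(model, seqs)
  rows <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    .designRow(seqs[i], p[i], task, lambda, verifyMotif(seqs[i], task@motif))
  }))
  best <- rows[.bestOrder(rows)[1L], , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Cleave a design at a protease scissile position
#'
#' Returns the N-terminal fragment produced by cutting after `pos` residues,
#' modeling proteolytic activation of a silenced CPP.
#'
#' @param seq full peptide sequence.
#' @param pos 1-based position of the last residue retained.
#' @return the activated fragment.
#' @export
cleaveAt <- function(seq, pos) {
  seq <- peptideSequences(validateSequence(seq))[1L]
  if (pos < 1L || pos >= nchar(seq)) {
    stop("cut position must satisfy 1 <= pos < nchar(seq)", call. = FALSE)
  }
  substr(seq, 1L, pos)
}

#' Neprilysin cleavage of an activatable design
#'
#' Locates the neprilysin recognition site FFGFLA and cuts after its G
#' (neprilysin's scissile position), returning the activated N-terminal
#' fragment. Applied to an activatable Tat design this recovers the
#' Tat + FFG positive-control peptide.
#'
#' @param seq full peptide sequence containing FFGFLA.
#' @return the activated fragment.
#' @examples
#' neprilysinCut("YGRKKRRQRRRFFGFLADDDDEE")
#' @export
neprilysinCut <- function(seq) {
  seq <- peptideSequences(validateSequence(seq))[1L]
  hit <- verifyMotif(seq, "FFGFLA")
  if (!hit$found) {
    stop("sequence does not contain the neprilysin site FFGFLA",
         call. = FALSE)
  }
  cleaveAt(seq, hit$start + 3L)
}
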