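.ARCHIVE_FORMAT <- "moonpep-forest"
.ARCHIVE_VERSION <- 1L

#' Save a trained forest to a JSON archive
#'
#' The archive stores the trees at full floating-point precision, the
#' descriptor order, the scale set and the training parameters, so a reloaded
#' model reproduces the in-memory model's predictions bit-exactly.
#'
#' @param model a [CPPForest-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "CPPForest"))
  sc <- model@scales
  archive <- list(
    format = .ARCHIVE_FORMAT,
    version = .ARCHIVE_VERSION,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = model@params$seed,
    params = model@params,
    feature_order = model@featureOrder,
    scale_set = list(
      name = sc@name,
      hydrophobicity = as.list(sc@hydrophobicity),
      pka = as.list(sc@pka),
      logP = as.list(sc@logP),
      helix = as.list(sc@helix)
    ),
    oob_error = model@oobError,
    inbag = model@inbag,
    subsets = model@subsets,
    trees = lapply(model@trees, function(m) unname(m))
  )
  # I(17) significant digits: doubles survive the decimal round trip exactly,
  # so a reloaded forest votes identically on every input
  jsonlite::write_json(archive, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a forest archive
#'
#' Fails loudly on a missing file, an unparseable or truncated archive, a
#' format/version mismatch, or a descriptor order that differs from this
#' package's contract (no silent reordering).
#'
#' @param path archive written by [saveModel()].
#' @return a [CPPForest-class].
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path,
                               call. = FALSE)
  archive <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      stop("failed to parse model archive (truncated or not a moonpep ",
           "archive): ", conditionMessage(e), call. = FALSE)
    }
  )
  if (!identical(archive$format, .ARCHIVE_FORMAT) ||
      !identical(as.integer(archive$version), .ARCHIVE_VERSION)) {
    stop("unsupported model archive format/version", call. = FALSE)
  }
  if (!identical(as.character(archive$feature_order), featureNames())) {
    stop("feature order in archive differs from this package's descriptor ",
         "contract; refusing to reorder silently", call. = FALSE)
  }
  sc <- defaultScales(
    name = archive$scale_set$name,
    hydrophobicity = unlist(archive$scale_set$hydrophobicity),
    pka = unlist(archive$scale_set$pka),
    logP = unlist(archive$scale_set$logP),
    helix = unlist(archive$scale_set$helix)
  )
  trees <- lapply(archive$trees, function(m) {
    m <- if (is.matrix(m)) m else matrix(m, nrow = 1L)
    colnames(m) <- c("feature", "threshold", "left", "right", "vote",
                     "n0", "n1")
    m
  })
  params <- archive$params
  params$maxDepth <- if (is.null(params$maxDepth)) NULL else
    as.integer(params$maxDepth)
  inbag <- archive$inbag
  if (is.matrix(inbag)) inbag <- lapply(seq_len(nrow(inbag)), function(i) inbag[i, ])
  subsets <- archive$subsets
  if (is.matrix(subsets)) {
    subsets <- lapply(seq_len(nrow(subsets)), function(i) subsets[i, ])
  }
  new("CPPForest",
    trees = trees,
    params = params,
    featureOrder = as.character(archive$feature_order),
    scales = sc,
    inbag = lapply(inbag, as.integer),
    subsets = lapply(subsets, as.integer),
    oobError = as.numeric(archive$oob_error %||% NA_real_)
  )
}
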