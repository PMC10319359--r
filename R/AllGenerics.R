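#' @rdname BisectedNetwork-accessors
#' @export
setGeneric("leftIds", function(x) standardGeneric("leftIds"))

#' @rdname BisectedNetwork-accessors
#' @export
setGeneric("rightIds", function(x) standardGeneric("rightIds"))

#' @rdname BisectedNetwork-accessors
#' @export
setGeneric("nLeft", function(x) standardGeneric("nLeft"))

#' @rdname BisectedNetwork-accessors
#' @export
setGeneric("nRight", function(x) standardGeneric("nRight"))

#' @rdname BisectedNetwork-accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' @rdname BisectedNetwork-accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname BisectedNetwork-accessors
#' @export
setGeneric("padIds", function(x) standardGeneric("padIds"))

#' @rdname adjacencyBlock
#' @export
setGeneric("adjacencyBlock", function(x, block, layer = 1L)
  standardGeneric("adjacencyBlock"))

#' @rdname gmView
#' @export
setGeneric("gmView", function(x) standardGeneric("gmView"))

#' @rdname Matching-accessors
#' @export
setGeneric("permutation", function(x) standardGeneric("permutation"))

#' @rdname matchedPairs
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))

#' @rdname matchFrequencies
#' @export
setGeneric("matchFrequencies", function(x) standardGeneric("matchFrequencies"))

#' Accessors for BisectedNetwork objects
#'
#' `leftIds()`/`rightIds()` return the ordered node identifiers per side
#' (matrix rows/columns are indexed by these orders); `nLeft()`, `nRight()`,
#' `nLayers()` and `layerNames()` report dimensions; `padIds()` returns the
#' sentinel ids added by [padNetwork()] (empty otherwise).
#'
#' @param x a [BisectedNetwork-class] object.
#' @return character or integer vectors as described.
#' @name BisectedNetwork-accessors
#' @aliases leftIds rightIds nLeft nRight nLayers layerNames padIds
NULL

#' @rdname BisectedNetwork-accessors
setMethod("leftIds", "BisectedNetwork", function(x) x@leftIds)
#' @rdname BisectedNetwork-accessors
setMethod("rightIds", "BisectedNetwork", function(x) x@rightIds)
#' @rdname BisectedNetwork-accessors
setMethod("nLeft", "BisectedNetwork", function(x) length(x@leftIds))
#' @rdname BisectedNetwork-accessors
setMethod("nRight", "BisectedNetwork", function(x) length(x@rightIds))
#' @rdname BisectedNetwork-accessors
setMethod("nLayers", "BisectedNetwork", function(x) length(x@layers))
#' @rdname BisectedNetwork-accessors
setMethod("layerNames", "BisectedNetwork", function(x) names(x@layers))
#' @rdname BisectedNetwork-accessors
setMethod("padIds", "BisectedNetwork", function(x) x@padIds)

#' Extract one adjacency block
#'
#' @param x a [BisectedNetwork-class].
#' @param block one of `"LL"`, `"RR"`, `"LR"`, `"RL"`.
#' @param layer layer index or name (default first layer).
#' @return the requested adjacency matrix.
#' @name adjacencyBlock
setMethod("adjacencyBlock", "BisectedNetwork", function(x, block, layer = 1L) {
  block <- match.arg(block, .BLOCK_NAMES)
  x@layers[[layer]][[block]]
})

#' Ipsilateral-only view of a network
#'
#' Returns a copy of the network with all contralateral blocks set to zero,
#' so that bisected graph matching on the view coincides with plain graph
#' matching on the ipsilateral subgraphs. The original object is not touched.
#'
#' @param x a [BisectedNetwork-class].
#' @return a [BisectedNetwork-class] with zero `LR`/`RL` blocks.
#' @name gmView
setMethod("gmView", "BisectedNetwork", function(x) {
  x@layers <- lapply(x@layers, function(ly) {
    ly$LR[] <- 0
    ly$RL[] <- 0
    ly
  })
  validObject(x)
  x
})

#' Accessors for Matching objects
#'
#' `permutation()` returns the integer permutation vector (`perm[j]` is the
#' right-side position matched to left position `j`).
#'
#' @param x a [Matching-class].
#' @name Matching-accessors
setMethod("permutation", "Matching", function(x) x@perm)

#' Matched pairs as a table
#'
#' One row per left node with its predicted right partner. Left nodes matched
#' to padding sentinels (and sentinel left nodes themselves) are reported as
#' unmatched (`NA` partner).
#'
#' @param x a [Matching-class].
#' @return data.frame with columns `left_id`, `right_id`, `matched`.
#' @name matchedPairs
setMethod("matchedPairs", "Matching", function(x) {
  right <- x@rightIds[x@perm]
  unmatched <- right %in% x@padIds | x@leftIds %in% x@padIds
  data.frame(
    left_id = x@leftIds,
    right_id = ifelse(unmatched, NA_character_, right),
    matched = !unmatched,
    stringsAsFactors = FALSE
  )
})

setMethod("show", "BisectedNetwork", function(object) {
  cat(sprintf(
    "BisectedNetwork: %d left / %d right nodes, %d layer%s, %s%s\n",
    nLeft(object), nRight(object), nLayers(object),
    if (nLayers(object) > 1L) "s" else "",
    if (object@weighted) "weighted" else "binary",
    if (length(object@padIds)) sprintf(" (%d padded)", length(object@padIds)) else ""
  ))
  dens <- vapply(object@layers, function(ly)
    mean(c(ly$LL > 0, ly$RR > 0, ly$LR > 0, ly$RL > 0)), numeric(1))
  cat(sprintf("  edge density by layer: %s\n",
              paste(sprintf("%.3f", dens), collapse = ", ")))
})

setMethod("show", "Matching", function(object) {
  cat(sprintf(
    "Matching of %d nodes: objective %.4g, restart %d/%d, %d iterations (%s)\n",
    length(object@perm), object@objective, object@restartIndex,
    ncol(object@restartPerms), object@nIterations,
    if (object@converged) "converged" else "max iterations"
  ))
})

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult over contralateral edge correlation:\n")
  print(object@summary, row.names = FALSE)
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: accuracy %.3f over %d evaluable nodes\n",
              object@accuracy, object@nEvaluable))
})

#' @rdname SweepResult-accessors
#' @export
setGeneric("sweepResults", function(x) standardGeneric("sweepResults"))
#' @rdname SweepResult-accessors
#' @export
setGeneric("sweepSummary", function(x) standardGeneric("sweepSummary"))

#' Accessors for SweepResult objects
#'
#' @param x a [SweepResult-class].
#' @return `sweepResults()` gives the per-replicate data.frame,
#'   `sweepSummary()` the per-grid-value means with 95% confidence intervals.
#' @name SweepResult-accessors
setMethod("sweepResults", "SweepResult", function(x) x@results)
#' @rdname SweepResult-accessors
setMethod("sweepSummary", "SweepResult", function(x) x@summary)
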