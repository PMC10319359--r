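# CSV input/output: node tables, edge lists, pair files.

#' Read a node table
#'
#' Expects columns `node_id`, `side` (values `L`/`R`) and optionally
#' `pair_id` marking known homolog pairs.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readNodeTable <- function(path) {
  nodes <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("node_id", "side") %in% names(nodes)))
    stop("node table ", path, " must have columns 'node_id' and 'side'")
  bad <- which(!nodes$side %in% c("L", "R"))
  if (length(bad))
    stop("invalid side label at ", path, " line ", bad[1L] + 1L,
         ": '", nodes$side[bad[1L]], "'")
  nodes
}

#' Read a directed edge list
#'
#' Expects columns `source`, `target` and optionally `weight` (default 1).
#'
#' @param path CSV file path.
#' @return data.frame with columns `source`, `target`, `weight`.
#' @export
readEdgeList <- function(path) {
  edges <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(edges)))
    stop("edge list ", path, " must have columns 'source' and 'target'")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (!"weight" %in% names(edges)) edges$weight <- 1
  edges$weight <- as.numeric(edges$weight)
  bad <- which(!is.finite(edges$weight) | edges$weight < 0)
  if (length(bad))
    stop("invalid weight at ", path, " line ", bad[1L] + 1L)
  edges
}

#' Read a network from node and edge CSV files
#'
#' @param nodesPath node table path (see [readNodeTable()]).
#' @param edgesPaths one or more edge list paths, one per layer; layer names
#'   default to file base names.
#' @param layers optional layer labels.
#' @return a [BisectedNetwork-class].
#' @export
readBisectedNetwork <- function(nodesPath, edgesPaths, layers = NULL) {
  nodes <- readNodeTable(nodesPath)
  edges <- lapply(edgesPaths, readEdgeList)
  names(edges) <- layers %||%
    sub("\\.[^.]*$", "", basename(unlist(edgesPaths)))
  bisectedNetwork(nodes, edges)
}

#' Read / write left-right pair files
#'
#' Pair files are CSVs with columns `left_id`, `right_id`. `readPairs()`
#' rejects files in which an id appears twice, naming the offender;
#' `writePairs()` writes pairs ordered by `left_id`, so a write/read round
#' trip is the identity.
#'
#' @param path CSV file path.
#' @return `readPairs()`: a [SeedSet-class]; `writePairs()`: the path,
#'   invisibly.
#' @export
readPairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("left_id", "right_id") %in% names(df)))
    stop("pair file ", path, " must have columns 'left_id' and 'right_id'")
  dupL <- unique(df$left_id[duplicated(df$left_id)])
  dupR <- unique(df$right_id[duplicated(df$right_id)])
  if (length(dupL) || length(dupR))
    stop("duplicated id(s) in ", path, ": ",
         paste(c(dupL, dupR), collapse = ", "))
  seedSet(df$left_id, df$right_id)
}

#' @param x a [SeedSet-class] or two-column data.frame of pairs.
#' @rdname readPairs
#' @export
writePairs <- function(x, path) {
  if (is(x, "SeedSet")) x <- x@pairs
  df <- data.frame(left_id = as.character(x[[1L]]),
                   right_id = as.character(x[[2L]]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$left_id), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a match report
#'
#' One row per left node: predicted partner, truth (when known), a
#' correctness flag and the across-restart selection frequency.
#'
#' @param report an [EvaluationReport-class] (see [evaluateMatching()]).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeMatchReport <- function(report, path) {
  stopifnot(is(report, "EvaluationReport"))
  df <- report@perNode
  names(df) <- c("left_id", "predicted_right_id", "truth_right_id",
                 "correct", "frequency")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
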