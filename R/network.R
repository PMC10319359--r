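# Construction and manipulation of bisected networks.

#' Low-level BisectedNetwork constructor
#'
#' Build a network directly from adjacency blocks. Either supply the four
#' blocks of a single layer (`LL`, `RR`, `LR`, `RL`) or a list of layers,
#' each a named list with those four matrices.
#'
#' @param LL,RR,LR,RL adjacency blocks of a single-layer network. `LL` is the
#'   left-to-left (ipsilateral) block, `LR` the left-to-right (contralateral)
#'   block, and so on; rows are sources, columns are targets.
#' @param layers alternatively, a list of layers (each a named list with
#'   elements `LL`, `RR`, `LR`, `RL`); overrides the four matrix arguments.
#' @param leftIds,rightIds node identifiers; defaults `L1..LnL` / `R1..RnR`.
#' @param weighted logical; inferred from the entries when `NA`.
#' @return a validated [BisectedNetwork-class].
#' @examples
#' A <- matrix(rbinom(9, 1, 0.4), 3, 3)
#' net <- BisectedNetwork(LL = A, RR = A, LR = matrix(0, 3, 3),
#'                        RL = matrix(0, 3, 3))
#' nLeft(net)
#' @export
BisectedNetwork <- function(LL = NULL, RR = NULL, LR = NULL, RL = NULL,
                            layers = NULL, leftIds = NULL, rightIds = NULL,
                            weighted = NA) {
  if (is.null(layers)) {
    if (is.null(LL) || is.null(RR) || is.null(LR) || is.null(RL))
      stop("supply either 'layers' or all four blocks LL, RR, LR, RL")
    layers <- list(list(LL = LL, RR = RR, LR = LR, RL = RL))
  }
  layers <- lapply(layers, function(ly) {
    ly <- ly[.BLOCK_NAMES]
    lapply(ly, function(m) {
      m <- as.matrix(m)
      storage.mode(m) <- "double"
      dimnames(m) <- NULL
      m
    })
  })
  nL <- nrow(layers[[1L]]$LL)
  nR <- nrow(layers[[1L]]$RR)
  if (is.null(leftIds)) leftIds <- paste0("L", seq_len(nL))
  if (is.null(rightIds)) rightIds <- paste0("R", seq_len(nR))
  if (is.na(weighted)) {
    weighted <- !all(vapply(layers, function(ly)
      all(unlist(ly, use.names = FALSE) %in% c(0, 1)), logical(1)))
  }
  new("BisectedNetwork", layers = layers, leftIds = as.character(leftIds),
      rightIds = as.character(rightIds), weighted = weighted,
      padIds = character())
}

#' Build a bisected network from node and edge tables
#'
#' Routes directed edges into the four adjacency blocks according to the
#' side labels of their endpoints: an edge from a left node to a left node
#' lands in `LL`, left-to-right in `LR`, and so on. Node order is the order
#' of first appearance in the node table; absent edges are zero. Multiple
#' records for the same (layer, source, target) triple have their weights
#' summed.
#'
#' @param nodes data.frame with columns `node_id` and `side` (`"L"`/`"R"`);
#'   an optional `pair_id` column marking known homolog pairs is preserved
#'   as the `"pairing"` attribute of the result.
#' @param edges either one data.frame with columns `source`, `target` and
#'   optionally `weight` (default 1), or a named list of such data.frames,
#'   one per layer.
#' @param layers optional layer labels when `edges` is a list.
#' @return a [BisectedNetwork-class].
#' @examples
#' nodes <- data.frame(node_id = c("a", "b", "c", "d"),
#'                     side = c("L", "L", "R", "R"))
#' edges <- data.frame(source = c("a", "a", "c"),
#'                     target = c("b", "c", "a"), weight = c(1, 2, 1))
#' net <- bisectedNetwork(nodes, edges)
#' adjacencyBlock(net, "LR")
#' @export
bisectedNetwork <- function(nodes, edges, layers = NULL) {
  if (!all(c("node_id", "side") %in% names(nodes)))
    stop("node table must have columns 'node_id' and 'side'")
  nodes$node_id <- as.character(nodes$node_id)
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node ids: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "))
  if (!all(nodes$side %in% c("L", "R")))
    stop("side labels must be 'L' or 'R'; found: ",
         paste(setdiff(unique(nodes$side), c("L", "R")), collapse = ", "))
  leftIds <- nodes$node_id[nodes$side == "L"]
  rightIds <- nodes$node_id[nodes$side == "R"]

  if (is.data.frame(edges)) edges <- list(edges)
  if (!is.null(layers)) names(edges) <- layers
  if (is.null(names(edges)) && length(edges) > 1L)
    names(edges) <- paste0("layer", seq_along(edges))

  side <- stats::setNames(nodes$side, nodes$node_id)
  posL <- stats::setNames(seq_along(leftIds), leftIds)
  posR <- stats::setNames(seq_along(rightIds), rightIds)
  nL <- length(leftIds); nR <- length(rightIds)

  lys <- lapply(edges, function(ed) {
    if (!all(c("source", "target") %in% names(ed)))
      stop("edge table must have columns 'source' and 'target'")
    src <- as.character(ed$source); tgt <- as.character(ed$target)
    w <- if ("weight" %in% names(ed)) as.numeric(ed$weight) else rep(1, nrow(ed))
    unknown <- setdiff(c(src, tgt), nodes$node_id)
    if (length(unknown))
      stop("edge endpoint(s) not in node table: ", paste(unknown, collapse = ", "))
    if (any(!is.finite(w)) || any(w < 0))
      stop("edge weights must be finite and non-negative")
    blocks <- list(LL = matrix(0, nL, nL), RR = matrix(0, nR, nR),
                   LR = matrix(0, nL, nR), RL = matrix(0, nR, nL))
    sig <- paste0(side[src], side[tgt])
    for (b in .BLOCK_NAMES) {
      sel <- sig == b
      if (!any(sel)) next
      i <- if (substr(b, 1, 1) == "L") posL[src[sel]] else posR[src[sel]]
      j <- if (substr(b, 2, 2) == "L") posL[tgt[sel]] else posR[tgt[sel]]
      # accumulate: duplicated (source, target) records sum
      m <- blocks[[b]]
      for (e in seq_along(i)) m[i[e], j[e]] <- m[i[e], j[e]] + w[sel][e]
      blocks[[b]] <- m
    }
    blocks
  })

  net <- BisectedNetwork(layers = lys, leftIds = leftIds, rightIds = rightIds)
  if ("pair_id" %in% names(nodes))
    attr(net, "pairing") <- nodes[, c("node_id", "side", "pair_id")]
  net
}

#' Serialize a network back to edge records
#'
#' Inverse of [bisectedNetwork()]: emits one record per nonzero adjacency
#' entry. Building a network from tables and serializing it reproduces the
#' multiset of input edges (with duplicate records merged by weight).
#'
#' @param net a [BisectedNetwork-class].
#' @return data.frame with columns `layer`, `source`, `target`, `weight`.
#' @export
asEdgeList <- function(net) {
  stopifnot(is(net, "BisectedNetwork"))
  ids <- list(L = leftIds(net), R = rightIds(net))
  lyNames <- layerNames(net)
  if (is.null(lyNames)) lyNames <- as.character(seq_len(nLayers(net)))
  out <- lapply(seq_len(nLayers(net)), function(k) {
    recs <- lapply(.BLOCK_NAMES, function(b) {
      m <- net@layers[[k]][[b]]
      nz <- which(m != 0, arr.ind = TRUE)
      if (!nrow(nz)) return(NULL)
      data.frame(
        layer = lyNames[k],
        source = ids[[substr(b, 1, 1)]][nz[, 1]],
        target = ids[[substr(b, 2, 2)]][nz[, 2]],
        weight = m[nz],
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, recs)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(layer = character(), source = character(),
                      target = character(), weight = numeric())
  out[order(out$layer, out$source, out$target), , drop = FALSE]
}

#' Restrict a network to its largest weakly connected component
#'
#' All layers are summed into one full adjacency matrix over left and right
#' nodes; nodes outside the largest weakly connected component are dropped
#' (node orders otherwise preserved). Ties between equally large components
#' go to the one containing the earliest node.
#'
#' @param net a [BisectedNetwork-class].
#' @return the induced [BisectedNetwork-class] sub-network.
#' @export
largestComponent <- function(net) {
  stopifnot(is(net, "BisectedNetwork"))
  nL <- nLeft(net); nR <- nRight(net)
  n <- nL + nR
  if (n == 0L) stop("empty network")
  full <- matrix(0, n, n)
  for (ly in net@layers) {
    full[seq_len(nL), seq_len(nL)] <- full[seq_len(nL), seq_len(nL)] + ly$LL
    full[seq_len(nL), nL + seq_len(nR)] <- full[seq_len(nL), nL + seq_len(nR)] + ly$LR
    full[nL + seq_len(nR), seq_len(nL)] <- full[nL + seq_len(nR), seq_len(nL)] + ly$RL
    full[nL + seq_len(nR), nL + seq_len(nR)] <- full[nL + seq_len(nR), nL + seq_len(nR)] + ly$RR
  }
  g <- igraph::graph_from_adjacency_matrix(full, mode = "directed", weighted = TRUE)
  comp <- igraph::components(g, mode = "weak")
  keep <- which(comp$membership == which.max(comp$csize))
  keepL <- keep[keep <= nL]
  keepR <- keep[keep > nL] - nL
  net@layers <- lapply(net@layers, function(ly) list(
    LL = ly$LL[keepL, keepL, drop = FALSE],
    RR = ly$RR[keepR, keepR, drop = FALSE],
    LR = ly$LR[keepL, keepR, drop = FALSE],
    RL = ly$RL[keepR, keepL, drop = FALSE]
  ))
  net@leftIds <- net@leftIds[keepL]
  net@rightIds <- net@rightIds[keepR]
  net@padIds <- intersect(net@padIds, c(net@leftIds, net@rightIds))
  validObject(net)
  net
}

#' Zero-pad the smaller side of an unequal network
#'
#' Naive padding for matching sides of unequal size: the smaller side's
#' ipsilateral block is embedded in the top-left of a square zero matrix of
#' the larger size, and the contralateral blocks get zero columns/rows
#' appended, so that all blocks become square. The synthetic nodes added are
#' recorded in `padIds()` and reported as "unmatched" downstream. Networks
#' with equal sides are returned unchanged.
#'
#' @param net a [BisectedNetwork-class].
#' @return a square [BisectedNetwork-class].
#' @export
padNetwork <- function(net) {
  stopifnot(is(net, "BisectedNetwork"))
  nL <- nLeft(net); nR <- nRight(net)
  if (nL == nR) return(net)
  d <- abs(nL - nR)
  sent <- paste0("__pad", seq_len(d))
  padRight <- nR < nL
  n <- max(nL, nR)
  grow <- function(m, rows, cols) {
    out <- matrix(0, rows, cols)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  net@layers <- lapply(net@layers, function(ly) {
    if (padRight) {
      list(LL = ly$LL, RR = grow(ly$RR, n, n),
           LR = grow(ly$LR, n, n), RL = grow(ly$RL, n, n))
    } else {
      list(LL = grow(ly$LL, n, n), RR = ly$RR,
           LR = grow(ly$LR, n, n), RL = grow(ly$RL, n, n))
    }
  })
  if (padRight) net@rightIds <- c(net@rightIds, sent)
  else net@leftIds <- c(net@leftIds, sent)
  net@padIds <- c(net@padIds, sent)
  validObject(net)
  net
}

#' Optional edge-weight transforms
#'
#' Weights are matched raw by default (synapse counts); `transformWeights()`
#' offers the common alternatives as an explicit opt-in.
#'
#' @param net a [BisectedNetwork-class].
#' @param method `"binarize"` (indicator of a nonzero entry) or `"log1p"`.
#' @return the transformed [BisectedNetwork-class].
#' @export
transformWeights <- function(net, method = c("binarize", "log1p")) {
  method <- match.arg(method)
  f <- switch(method, binarize = function(m) (m > 0) * 1, log1p = log1p)
  net@layers <- lapply(net@layers, function(ly) lapply(ly, f))
  net@weighted <- method != "binarize"
  validObject(net)
  net
}

#' Construct a seed set
#'
#' @param left,right character vectors of paired node ids, or `left` may be
#'   a two-column data.frame/matrix of pairs.
#' @return a [SeedSet-class].
#' @examples
#' seedSet(c("L1", "L2"), c("R1", "R2"))
#' @export
seedSet <- function(left, right = NULL) {
  if (is.null(right)) {
    stopifnot(ncol(left) >= 2L)
    right <- left[[2L]]
    left <- left[[1L]]
  }
  new("SeedSet", pairs = data.frame(left = as.character(left),
                                    right = as.character(right),
                                    stringsAsFactors = FALSE))
}

#' Construct solver options
#'
#' Defaults follow common Frank-Wolfe graph-matching practice: at most 30
#' iterations, stopping when the Frobenius norm of the change in the doubly
#' stochastic iterate drops below 0.03, one restart from the barycenter.
#'
#' @param maxIter maximum Frank-Wolfe iterations.
#' @param tol stopping threshold on \eqn{\|P_i - P_{i-1}\|_F / \sqrt{n}}.
#' @param nRestarts number of restarts; lowest discrete objective wins.
#' @param init `"barycenter"` or `"randomized-barycenter"`.
#' @param seed optional integer seed; all solver randomness (assignment
#'   tie-breaking and randomized initialization) flows from it.
#' @param useContralateral `TRUE` for bisected graph matching (BGM),
#'   `FALSE` for plain graph matching (GM).
#' @param project final projection onto permutations: `"solution"` (linear
#'   assignment on the final iterate itself, the default) or `"gradient"`
#'   (linear assignment on the gradient at the final iterate).
#' @return a [SolverOptions-class].
#' @export
solverOptions <- function(maxIter = 30L, tol = 0.03, nRestarts = 1L,
                          init = c("barycenter", "randomized-barycenter"),
                          seed = NULL, useContralateral = TRUE,
                          project = c("solution", "gradient")) {
  new("SolverOptions",
      maxIter = as.integer(maxIter), tol = as.numeric(tol),
      nRestarts = as.integer(nRestarts), init = match.arg(init),
      seed = as.integer(seed %||% integer()),
      useContralateral = isTRUE(useContralateral), project = match.arg(project))
}

#' Construct simulation parameters
#'
#' Defaults are the bilateral simulation conditions used throughout the
#' package's experiments: 10 nodes per side, ipsilateral density 0.3 with
#' edge correlation 0.8, contralateral density 0.2.
#'
#' @param n nodes per side.
#' @param pIpsi,rhoIpsi ipsilateral density and edge correlation.
#' @param pContra,rhoContra contralateral density and edge correlation.
#' @return a [SimulationParams-class].
#' @export
simulationParams <- function(n = 10L, pIpsi = 0.3, rhoIpsi = 0.8,
                             pContra = 0.2, rhoContra = 0.8) {
  new("SimulationParams", n = as.integer(n), pIpsi = pIpsi, rhoIpsi = rhoIpsi,
      pContra = pContra, rhoContra = rhoContra)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Permutation helpers --------------------------------------------------------

.permMatrix <- function(perm) {
  n <- length(perm)
  P <- matrix(0, n, n)
  P[cbind(seq_len(n), perm)] <- 1
  P
}

.invPerm <- function(perm) {
  out <- integer(length(perm))
  out[perm] <- seq_along(perm)
  out
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards; a NULL seed leaves the RNG stream untouched.
.localSeed <- function(seed, code) {
  if (is.null(seed) || length(seed) == 0L) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# Deterministically derive k child seeds from one parent seed (kept below
# 2^31 so they remain valid R integers).
.childSeeds <- function(seed, k) {
  .localSeed(seed, sample.int(.Machine$integer.max - 1L, k))
}
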