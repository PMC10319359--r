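#' @import methods
NULL

.BLOCK_NAMES <- c("LL", "RR", "LR", "RL")

#' Class for a bisected (two-sided) directed network
#'
#' A `BisectedNetwork` holds one directed network whose nodes are partitioned
#' into a left and a right side, stored as the four adjacency blocks of the
#' full adjacency matrix: the ipsilateral subgraphs `LL` (left-to-left) and
#' `RR` (right-to-right), and the contralateral subgraphs `LR` (left-to-right)
#' and `RL` (right-to-left). Multiplex networks (several edge types over the
#' same nodes) are stored as multiple layers, each with its own four blocks.
#'
#' Matrices are indexed positionally by `leftIds()` / `rightIds()`; all
#' permutations produced by the solver are over right-side positions.
#' Self-loops (diagonal of `LL`/`RR`) are carried through unchanged; diagonal
#' entries of `LR`/`RL` are ordinary contralateral edges between index-matched
#' nodes, not loops.
#'
#' @slot layers list of layers; each layer is a named list with matrices
#'   `LL` (nL x nL), `RR` (nR x nR), `LR` (nL x nR), `RL` (nR x nL).
#' @slot leftIds,rightIds character vectors of node identifiers (disjoint,
#'   no duplicates).
#' @slot weighted logical; `FALSE` means all entries are 0/1.
#' @slot padIds character vector of synthetic sentinel ids introduced by
#'   [padNetwork()]; empty for unpadded networks.
#'
#' @seealso [bisectedNetwork()], [padNetwork()], [gmView()], [matchBisected()]
#' @export
setClass("BisectedNetwork",
  slots = c(
    layers = "list",
    leftIds = "character",
    rightIds = "character",
    weighted = "logical",
    padIds = "character"
  ),
  prototype = prototype(padIds = character())
)

.validBisectedNetwork <- function(object) {
  msgs <- character()
  nL <- length(object@leftIds)
  nR <- length(object@rightIds)
  if (length(object@layers) < 1L) msgs <- c(msgs, "at least one layer required")
  if (anyDuplicated(object@leftIds)) msgs <- c(msgs, "duplicate left node ids")
  if (anyDuplicated(object@rightIds)) msgs <- c(msgs, "duplicate right node ids")
  if (length(intersect(object@leftIds, object@rightIds)) > 0L)
    msgs <- c(msgs, "left and right node ids must be disjoint")
  dims <- list(LL = c(nL, nL), RR = c(nR, nR), LR = c(nL, nR), RL = c(nR, nL))
  for (k in seq_along(object@layers)) {
    ly <- object@layers[[k]]
    if (!is.list(ly) || !all(.BLOCK_NAMES %in% names(ly))) {
      msgs <- c(msgs, sprintf("layer %d must contain matrices LL, RR, LR, RL", k))
      next
    }
    for (b in .BLOCK_NAMES) {
      m <- ly[[b]]
      if (!is.matrix(m) || !is.numeric(m)) {
        msgs <- c(msgs, sprintf("layer %d block %s is not a numeric matrix", k, b))
        next
      }
      if (!identical(dim(m), as.integer(dims[[b]])))
        msgs <- c(msgs, sprintf("layer %d block %s has wrong dimensions", k, b))
      if (any(!is.finite(m)))
        msgs <- c(msgs, sprintf("layer %d block %s has non-finite entries", k, b))
      else if (any(m < 0))
        msgs <- c(msgs, sprintf("layer %d block %s has negative entries", k, b))
    }
  }
  if (!all(object@padIds %in% c(object@leftIds, object@rightIds)))
    msgs <- c(msgs, "padIds must be existing node ids")
  if (length(msgs)) msgs else TRUE
}
setValidity("BisectedNetwork", .validBisectedNetwork)

#' Class for a recovered left/right matching
#'
#' The result of [matchBisected()]: a bijection from left-side positions to
#' right-side positions (the permutation \eqn{P}), together with provenance
#' (discrete objective value, iteration count, convergence flag, which
#' restart won) and the per-restart permutations needed for match-frequency
#' confidence estimates.
#'
#' @slot perm integer vector; `perm[j]` is the right-side position matched to
#'   left position `j`.
#' @slot leftIds,rightIds node identifiers of the matched network.
#' @slot padIds sentinel ids from padding; matches to these are "unmatched".
#' @slot objective discrete edge-disagreement objective at `perm`
#'   (recomputable via [bgmObjective()]).
#' @slot nIterations Frank-Wolfe iterations used by the winning restart.
#' @slot converged did the winning restart stop on the tolerance criterion?
#' @slot restartIndex index (1-based) of the winning restart.
#' @slot restartPerms n x nRestarts integer matrix of all restart solutions.
#' @slot restartObjectives discrete objectives, one per restart.
#' @slot objectiveTrace relaxed-objective trace of the winning restart.
#' @slot useContralateral was the contralateral term included (BGM vs GM)?
#' @seealso [matchedPairs()], [matchFrequencies()], [matchingAccuracy()]
#' @export
setClass("Matching",
  slots = c(
    perm = "integer",
    leftIds = "character",
    rightIds = "character",
    padIds = "character",
    objective = "numeric",
    nIterations = "integer",
    converged = "logical",
    restartIndex = "integer",
    restartPerms = "matrix",
    restartObjectives = "numeric",
    objectiveTrace = "numeric",
    useContralateral = "logical"
  )
)

setValidity("Matching", function(object) {
  n <- length(object@perm)
  msgs <- character()
  if (!identical(sort(object@perm), seq_len(n)))
    msgs <- c(msgs, "perm is not a permutation of 1..n")
  if (length(object@leftIds) != n || length(object@rightIds) != n)
    msgs <- c(msgs, "id vectors must have length n")
  if (nrow(object@restartPerms) != n)
    msgs <- c(msgs, "restartPerms must have n rows")
  if (ncol(object@restartPerms) != length(object@restartObjectives))
    msgs <- c(msgs, "one objective per restart required")
  if (length(msgs)) msgs else TRUE
})

#' Class for a set of seed (known) pairings
#'
#' Seeds are left/right node pairs whose correspondence is known ahead of
#' time and honored exactly by the solver: only the non-seed block of the
#' permutation is optimized, with gradient terms coupling seeds to non-seeds.
#'
#' @slot pairs data.frame with character columns `left` and `right`.
#' @seealso [seedSet()], [matchBisected()]
#' @export
setClass("SeedSet", slots = c(pairs = "data.frame"))

setValidity("SeedSet", function(object) {
  p <- object@pairs
  msgs <- character()
  if (!all(c("left", "right") %in% names(p)))
    return("pairs must have columns 'left' and 'right'")
  if (anyDuplicated(p$left)) msgs <- c(msgs, "duplicate left ids in seed set")
  if (anyDuplicated(p$right)) msgs <- c(msgs, "duplicate right ids in seed set")
  if (length(msgs)) msgs else TRUE
})

#' Class for solver options
#'
#' @slot maxIter maximum Frank-Wolfe iterations (default 30).
#' @slot tol stopping threshold on the Frobenius norm of the change in the
#'   doubly stochastic iterate between iterations, scaled by \eqn{\sqrt{n}}
#'   so the criterion is size-independent (default 0.03).
#' @slot nRestarts number of restarts; the solution with the lowest discrete
#'   objective wins, ties going to the lowest restart index.
#' @slot init `"barycenter"` (the flat matrix 1/n, the centroid of the
#'   doubly stochastic set) or `"randomized-barycenter"` (barycenter averaged
#'   with a random doubly stochastic matrix).
#' @slot seed optional integer seed making the whole solve reproducible;
#'   length 0 means use the current RNG state.
#' @slot useContralateral include the contralateral disagreement term (BGM);
#'   `FALSE` gives plain graph matching (GM) on the ipsilateral blocks.
#' @slot project `"solution"` (default) projects the final doubly stochastic
#'   iterate onto the permutations via linear assignment; `"gradient"`
#'   instead solves the assignment on the gradient at the final iterate (the
#'   direction one further Frank-Wolfe step would take). The two are not
#'   always equivalent.
#' @seealso [solverOptions()]
#' @export
setClass("SolverOptions",
  slots = c(
    maxIter = "integer", tol = "numeric", nRestarts = "integer",
    init = "character", seed = "integer",
    useContralateral = "logical", project = "character"
  )
)

setValidity("SolverOptions", function(object) {
  msgs <- character()
  if (object@maxIter < 1L) msgs <- c(msgs, "maxIter must be >= 1")
  if (object@tol < 0) msgs <- c(msgs, "tol must be >= 0")
  if (object@nRestarts < 1L) msgs <- c(msgs, "nRestarts must be >= 1")
  if (!object@init %in% c("barycenter", "randomized-barycenter"))
    msgs <- c(msgs, "unknown init")
  if (!object@project %in% c("gradient", "solution"))
    msgs <- c(msgs, "unknown projection method")
  if (length(msgs)) msgs else TRUE
})

#' Class for correlated Erdos-Renyi bilateral simulation parameters
#'
#' Parameters of the bilateral network simulator: each side has `n` nodes;
#' the ipsilateral subgraphs form a correlated Erdos-Renyi pair with density
#' `pIpsi` and edge correlation `rhoIpsi`; independently, the contralateral
#' subgraphs form a correlated pair with density `pContra` and correlation
#' `rhoContra`.
#'
#' @slot n nodes per side.
#' @slot pIpsi,rhoIpsi ipsilateral density and edge correlation, in [0, 1].
#' @slot pContra,rhoContra contralateral density and edge correlation.
#' @seealso [simulationParams()], [simulateBilateral()]
#' @export
setClass("SimulationParams",
  slots = c(n = "integer", pIpsi = "numeric", rhoIpsi = "numeric",
            pContra = "numeric", rhoContra = "numeric")
)

setValidity("SimulationParams", function(object) {
  probs <- c(object@pIpsi, object@rhoIpsi, object@pContra, object@rhoContra)
  msgs <- character()
  if (object@n < 1L) msgs <- c(msgs, "n must be >= 1")
  if (any(probs < 0 | probs > 1))
    msgs <- c(msgs, "densities and correlations must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Class for a sweep over contralateral edge correlation
#'
#' Result of [runRhoSweep()]: per-replicate matching accuracies for GM and
#' BGM at each grid value of the contralateral edge correlation, plus a
#' per-grid-value summary (mean accuracy and normal-approximation 95%
#' confidence interval, mean +/- 1.96 SEM).
#'
#' @slot results data.frame with columns `rhoContra`, `replicate`, `method`,
#'   `accuracy` (one row per replicate and method).
#' @slot summary data.frame with columns `rhoContra`, `method`, `mean`,
#'   `lower`, `upper`, `nReps`.
#' @export
setClass("SweepResult", slots = c(results = "data.frame", summary = "data.frame"))

setValidity("SweepResult", function(object) {
  need <- c("rhoContra", "replicate", "method", "accuracy")
  if (!all(need %in% names(object@results))) return("missing results columns")
  TRUE
})

#' Class for a matching evaluation report
#'
#' @slot accuracy proportion of evaluable left nodes matched to their true
#'   partner (seeds and padding sentinels excluded).
#' @slot nEvaluable number of left nodes entering the denominator.
#' @slot perNode data.frame with columns `left_id`, `predicted_right_id`,
#'   `truth_right_id`, `correct`, `frequency`.
#' @slot frequencies data.frame of match frequencies across restarts
#'   (columns `left_id`, `right_id`, `frequency`, `highConfidence`).
#' @seealso [evaluateMatching()], [matchFrequencies()]
#' @export
setClass("EvaluationReport",
  slots = c(accuracy = "numeric", nEvaluable = "integer",
            perNode = "data.frame", frequencies = "data.frame")
)
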