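# Correlated Erdos-Renyi simulation of bilateral networks.

#' Sample a correlated Erdos-Renyi matrix pair
#'
#' Draws a pair of binary matrices `(A, B)` such that each is marginally
#' Erdos-Renyi with density `p` and the index-aligned entries have Pearson
#' correlation `rho`: every entry of `A` is Bernoulli(`p`), and conditionally
#' `B[i,j]` is Bernoulli(`p + rho (1 - p)`) where `A[i,j] = 1` and
#' Bernoulli(`p (1 - rho)`) where `A[i,j] = 0`. With `loops = FALSE` (the
#' convention for square ipsilateral subgraphs, where a diagonal entry would
#' be a self-synapse) the diagonal of both matrices is zeroed; contralateral
#' sampling uses `loops = TRUE` since a diagonal entry there is an ordinary
#' edge between index-matched nodes on opposite sides.
#'
#' @param nRow,nCol matrix dimensions (`nCol` defaults to `nRow`).
#' @param p marginal edge density in [0, 1].
#' @param rho Pearson edge correlation in [0, 1].
#' @param loops keep diagonal entries? Ignored for non-square dimensions.
#' @return list with binary matrices `A` and `B`.
#' @examples
#' pair <- sampleCorrER(50, p = 0.2, rho = 0.6)
#' cor(as.vector(pair$A), as.vector(pair$B))  # close to 0.6
#' @export
sampleCorrER <- function(nRow, nCol = nRow, p, rho, loops = FALSE) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  A <- matrix(stats::rbinom(nRow * nCol, 1L, p), nRow, nCol)
  pCond <- ifelse(A == 1L, p + rho * (1 - p), p * (1 - rho))
  B <- matrix(stats::rbinom(nRow * nCol, 1L, as.vector(pCond)), nRow, nCol)
  if (!loops && nRow == nCol) {
    diag(A) <- 0L
    diag(B) <- 0L
  }
  storage.mode(A) <- "double"
  storage.mode(B) <- "double"
  list(A = A, B = B)
}

#' Permute the right side of a network
#'
#' Applies a permutation to the right-side node order: the right ipsilateral
#' block has its rows and columns permuted, the left-to-right block its
#' columns, and the right-to-left block its rows (a permutation of the right
#' nodes touches only one index of each contralateral block). Applying
#' `sigma` and then its inverse restores the network exactly.
#'
#' @param net a [BisectedNetwork-class].
#' @param sigma integer permutation of `1..nRight(net)`; shuffled position
#'   `t` holds the node formerly at position `sigma[t]`.
#' @return the shuffled [BisectedNetwork-class].
#' @export
applyShuffle <- function(net, sigma) {
  stopifnot(is(net, "BisectedNetwork"))
  sigma <- as.integer(sigma)
  if (!identical(sort(sigma), seq_len(nRight(net))))
    stop("sigma must be a permutation of 1..", nRight(net))
  net@layers <- lapply(net@layers, function(ly) list(
    LL = ly$LL,
    RR = ly$RR[sigma, sigma, drop = FALSE],
    LR = ly$LR[, sigma, drop = FALSE],
    RL = ly$RL[sigma, , drop = FALSE]
  ))
  net@rightIds <- net@rightIds[sigma]
  validObject(net)
  net
}

#' Simulate a bilateral network with a hidden correspondence
#'
#' Builds one synthetic bilateral network: the ipsilateral subgraph pair is
#' drawn from CorrER(`n`, `pIpsi`, `rhoIpsi`) (loop-free), and independently
#' the contralateral pair from CorrER(`n`, `pContra`, `rhoContra`) (diagonal
#' kept). The four blocks are assembled into one network whose index-aligned
#' pairing is the truth, and a uniformly random permutation is then applied
#' to the right side to hide that correspondence from the matcher.
#'
#' When `seed` is given, three child seeds are derived from it for the
#' ipsilateral draw, the contralateral draw and the shuffle, so that varying
#' one correlation parameter alone reuses comparable draws for the others.
#'
#' @param params a [SimulationParams-class], see [simulationParams()].
#' @param seed optional integer seed.
#' @param shuffle set `FALSE` to skip the hiding permutation (truth is then
#'   the identity).
#' @return list with elements `network` (the shuffled
#'   [BisectedNetwork-class]), `truth` (integer vector: `truth[j]` is the
#'   shuffled right position homologous to left position `j`), `sigma` (the
#'   permutation applied to the right side), and `unshuffled` (the network
#'   before shuffling).
#' @examples
#' sim <- simulateBilateral(simulationParams(n = 10, rhoContra = 0.9), seed = 3)
#' m <- matchBisected(sim$network, options = solverOptions(seed = 4))
#' matchingAccuracy(m, sim$truth)
#' @export
simulateBilateral <- function(params = simulationParams(), seed = NULL,
                              shuffle = TRUE) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  n <- params@n
  sub <- if (is.null(seed)) list(NULL, NULL, NULL) else
    as.list(.childSeeds(seed, 3L))
  ipsi <- .localSeed(sub[[1L]],
    sampleCorrER(n, n, params@pIpsi, params@rhoIpsi, loops = FALSE))
  contra <- .localSeed(sub[[2L]],
    sampleCorrER(n, n, params@pContra, params@rhoContra, loops = TRUE))
  net <- BisectedNetwork(LL = ipsi$A, RR = ipsi$B,
                         LR = contra$A, RL = contra$B, weighted = FALSE)
  sigma <- if (shuffle) .localSeed(sub[[3L]], sample.int(n)) else seq_len(n)
  shuffled <- applyShuffle(net, sigma)
  list(network = shuffled, truth = .invPerm(sigma), sigma = sigma,
       unshuffled = net)
}
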