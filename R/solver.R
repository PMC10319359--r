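# Frank-Wolfe solver for bisected graph matching.
#
# The discrete objective being minimized over permutation matrices P is
#   sum_k || A_LL^k - P A_RR^k P' ||_F^2  +  || A_LR^k P' - P A_RL^k ||_F^2
# (the contralateral term only when useContralateral = TRUE). On the doubly
# stochastic relaxation the solver works with the indefinite trace form
#   f(P) = -sum_k [ tr(A_LL^k' P A_RR^k P') + tr(A_RL^k P A_LR^k' P) ]
# whose gradient is the one used for the search direction; on permutation
# matrices the discrete objective equals a constant plus twice f(P), so both
# forms share their minimizers. With seeds, only the nonseed-by-nonseed block
# of P is free and the trace form gains linear seed-interaction terms.

# Assemble the internal problem representation: nonseed blocks per layer,
# the constant seed-interaction matrix K, and the index bookkeeping needed
# to re-embed the solved block into a full permutation.
.problem <- function(net, seeds = NULL, useContralateral = TRUE) {
  nL <- nLeft(net); nR <- nRight(net)
  if (nL != nR)
    stop("sides have unequal size (", nL, " vs ", nR,
         "); apply padNetwork() first")
  n <- nL
  if (is.null(seeds) || nrow(seeds@pairs) == 0L) {
    sL <- integer(); sR <- integer()
  } else {
    sL <- match(seeds@pairs$left, leftIds(net))
    sR <- match(seeds@pairs$right, rightIds(net))
    if (anyNA(sL) || anyNA(sR))
      stop("seed ids not present in the network: ",
           paste(c(seeds@pairs$left[is.na(sL)], seeds@pairs$right[is.na(sR)]),
                 collapse = ", "))
    if (length(sL) >= n) stop("seed count must be smaller than n")
  }
  nsL <- setdiff(seq_len(n), sL)
  nsR <- setdiff(seq_len(n), sR)
  m <- length(sL)
  nn <- n - m
  K <- matrix(0, nn, nn)
  layers <- lapply(net@layers, function(ly) {
    A <- ly$LL[nsL, nsL, drop = FALSE]; B <- ly$RR[nsR, nsR, drop = FALSE]
    C <- ly$LR[nsL, nsR, drop = FALSE]; D <- ly$RL[nsR, nsL, drop = FALSE]
    if (m > 0L) {
      K <<- K + ly$LL[nsL, sL, drop = FALSE] %*% t(ly$RR[nsR, sR, drop = FALSE]) +
        t(ly$LL[sL, nsL, drop = FALSE]) %*% ly$RR[sR, nsR, drop = FALSE]
      if (useContralateral)
        K <<- K + ly$LR[nsL, sR, drop = FALSE] %*% t(ly$RL[nsR, sL, drop = FALSE]) +
          t(ly$RL[sR, nsL, drop = FALSE]) %*% ly$LR[sL, nsR, drop = FALSE]
    }
    list(A = A, B = B, C = C, D = D)
  })
  list(layers = layers, K = K, contra = isTRUE(useContralateral),
       n = n, nn = nn, m = m, sL = sL, sR = sR, nsL = nsL, nsR = nsR)
}

.relaxedObj <- function(prob, P) {
  val <- -sum(P * prob$K)
  for (ly in prob$layers) {
    val <- val - sum(ly$A * (P %*% ly$B %*% t(P)))
    if (prob$contra)
      val <- val - sum(t(ly$D) * (P %*% t(ly$C) %*% P))
  }
  val
}

.relaxedGrad <- function(prob, P) {
  G <- -prob$K
  for (ly in prob$layers) {
    G <- G - ly$A %*% P %*% t(ly$B) - t(ly$A) %*% P %*% ly$B
    if (prob$contra)
      G <- G - ly$C %*% t(P) %*% t(ly$D) - t(ly$D) %*% t(P) %*% ly$C
  }
  G
}

# Coefficients (c0, c1, c2) of the relaxed objective along the segment
# P(alpha) = alpha * P + (1 - alpha) * Q, a quadratic in alpha.
.segmentCoef <- function(prob, P, Q) {
  R <- P - Q
  c0 <- -sum(Q * prob$K)
  c1 <- -sum(R * prob$K)
  c2 <- 0
  for (ly in prob$layers) {
    tQ <- t(Q); tR <- t(R)
    BQ <- ly$B %*% tQ; BR <- ly$B %*% tR
    c0 <- c0 - sum(ly$A * (Q %*% BQ))
    c1 <- c1 - sum(ly$A * (R %*% BQ + Q %*% BR))
    c2 <- c2 - sum(ly$A * (R %*% BR))
    if (prob$contra) {
      tD <- t(ly$D); Ct <- t(ly$C)
      CQ <- Ct %*% Q; CR <- Ct %*% R
      c0 <- c0 - sum(tD * (Q %*% CQ))
      c1 <- c1 - sum(tD * (R %*% CQ + Q %*% CR))
      c2 <- c2 - sum(tD * (R %*% CR))
    }
  }
  c(c0, c1, c2)
}

.stepFromCoef <- function(coef) {
  a <- coef[3L]; b <- coef[2L]
  if (a > 0) return(min(max(-b / (2 * a), 0), 1))
  # concave/linear along the segment: an endpoint minimizes; ties (including
  # the degenerate P == Q segment) return 1, i.e. stay at P
  f0 <- coef[1L]
  f1 <- coef[1L] + coef[2L] + coef[3L]
  if (f1 <= f0) 1 else 0
}

# Minimize sum_i G[i, perm[i]] over permutations, with ties broken by a
# random symmetric relabeling of rows and columns. Consumes one sample.int(n)
# draw from the RNG per call.
.lapDirection <- function(G) {
  n <- nrow(G)
  s <- sample.int(n)
  a <- lap_solve(G[s, s, drop = FALSE])
  perm <- integer(n)
  perm[s] <- s[a]
  perm
}

# Embed a solved nonseed-block permutation into a full right-for-left
# permutation that maps every seed to its partner.
.embedPerm <- function(prob, blockPerm) {
  full <- integer(prob$n)
  full[prob$sL] <- prob$sR
  full[prob$nsL] <- prob$nsR[blockPerm]
  full
}

#' Edge-disagreement objective
#'
#' The discrete objective of bisected graph matching: the squared Frobenius
#' norm of the ipsilateral disagreement \eqn{A_{LL} - P A_{RR} P'} plus,
#' when `useContralateral = TRUE`, the contralateral disagreement
#' \eqn{A_{LR} P' - P A_{RL}}, summed over layers. For an unweighted network
#' this counts edge disagreements. With contralateral blocks all zero (or
#' `useContralateral = FALSE`) it reduces to the classic graph matching
#' objective on the ipsilateral blocks alone.
#'
#' @param net a [BisectedNetwork-class] with equal sides.
#' @param perm either an integer permutation (`perm[j]` = right position for
#'   left position `j`) of length `n`, or an `n x n` relaxed (doubly
#'   stochastic) matrix. With seeds, an integer `perm` must map every seed to
#'   its partner, and a matrix must be the free nonseed block.
#' @param seeds optional [SeedSet-class]; the seed block of \eqn{P} is fixed
#'   to the seed pairing.
#' @param useContralateral include the contralateral term?
#' @return the objective value (a non-negative scalar).
#' @seealso [relaxedObjective()] for the trace form the solver optimizes.
#' @export
bgmObjective <- function(net, perm, seeds = NULL, useContralateral = TRUE) {
  stopifnot(is(net, "BisectedNetwork"))
  prob <- .problem(net, seeds, useContralateral)
  if (is.matrix(perm)) {
    if (!all(dim(perm) == prob$nn))
      stop("relaxed matrix must be ", prob$nn, " x ", prob$nn)
    n <- prob$n
    P <- matrix(0, n, n)
    P[cbind(prob$sL, prob$sR)] <- 1
    P[prob$nsL, prob$nsR] <- perm
  } else {
    perm <- as.integer(perm)
    if (length(perm) != prob$n || !identical(sort(perm), seq_len(prob$n)))
      stop("perm must be a permutation of 1..", prob$n)
    if (prob$m > 0L && !identical(perm[prob$sL], prob$sR))
      stop("perm must honor the seed pairing")
    P <- .permMatrix(perm)
  }
  val <- 0
  for (ly in net@layers) {
    val <- val + sum((ly$LL - P %*% ly$RR %*% t(P))^2)
    if (useContralateral)
      val <- val + sum((ly$LR %*% t(P) - P %*% ly$RL)^2)
  }
  val
}

#' Relaxed (trace-form) objective
#'
#' The indefinite relaxation optimized by the Frank-Wolfe solver:
#' \eqn{f(P) = -\sum_k tr(A_{LL}^{k\prime} P A_{RR}^k P') +
#' tr(A_{RL}^k P A_{LR}^{k\prime} P)} (contralateral trace only when
#' `useContralateral = TRUE`), plus linear seed-interaction terms when seeds
#' are present. On permutation matrices the discrete [bgmObjective()] equals
#' a data-dependent constant plus twice this value, so the two share their
#' minimizers; along a Frank-Wolfe segment this form is an exact quadratic,
#' which is what makes the exact line search possible.
#'
#' @inheritParams bgmObjective
#' @param P the free block of the relaxed solution: an `n x n` matrix without
#'   seeds, or `(n - m) x (n - m)` with `m` seeds.
#' @return the relaxed objective value.
#' @export
relaxedObjective <- function(net, P, seeds = NULL, useContralateral = TRUE) {
  prob <- .problem(net, seeds, useContralateral)
  if (!is.matrix(P) || !all(dim(P) == prob$nn))
    stop("P must be ", prob$nn, " x ", prob$nn)
  .relaxedObj(prob, P)
}

#' Gradient of the relaxed objective
#'
#' Returns the gradient of [relaxedObjective()] with respect to the free
#' block of \eqn{P}: without seeds,
#' \eqn{-\sum_k (A_{LL} P A_{RR}' + A_{LL}' P A_{RR} + A_{LR} P' A_{RL}' +
#' A_{RL}' P' A_{LR})}; with seeds, the nonseed-block gradient including the
#' constant seed-interaction terms.
#'
#' @inheritParams relaxedObjective
#' @return a matrix of the same shape as `P`.
#' @export
bgmGradient <- function(net, P, seeds = NULL, useContralateral = TRUE) {
  prob <- .problem(net, seeds, useContralateral)
  if (!is.matrix(P) || !all(dim(P) == prob$nn))
    stop("P must be ", prob$nn, " x ", prob$nn)
  .relaxedGrad(prob, P)
}

#' Frank-Wolfe search direction
#'
#' Finds the permutation matrix \eqn{Q} minimizing \eqn{tr(Q' G)} for a
#' gradient matrix \eqn{G} by solving a linear assignment problem. Ties are
#' broken by applying a random symmetric relabeling of rows and columns
#' before the assignment solve and undoing it afterwards (this consumes one
#' draw from the RNG).
#'
#' @param grad a finite square numeric matrix.
#' @return a permutation matrix with attribute `"perm"` holding the
#'   permutation vector.
#' @export
frankWolfeDirection <- function(grad) {
  if (!is.matrix(grad) || nrow(grad) != ncol(grad))
    stop("grad must be a square matrix")
  if (any(!is.finite(grad))) stop("grad must be finite")
  perm <- .lapDirection(grad)
  Q <- .permMatrix(perm)
  attr(Q, "perm") <- perm
  Q
}

#' Exact line search along a Frank-Wolfe segment
#'
#' The relaxed objective restricted to the segment
#' \eqn{\alpha P + (1 - \alpha) Q} is an exact quadratic in \eqn{\alpha};
#' this returns its minimizer over \eqn{[0, 1]}. When the quadratic is
#' concave or linear the better endpoint is returned; the degenerate
#' `P == Q` segment returns 1 by convention.
#'
#' @inheritParams relaxedObjective
#' @param P,Q same-shape matrices (the current iterate and the direction).
#' @return the step size \eqn{\alpha \in [0, 1]}.
#' @export
exactStepSize <- function(net, P, Q, seeds = NULL, useContralateral = TRUE) {
  prob <- .problem(net, seeds, useContralateral)
  stopifnot(is.matrix(P), is.matrix(Q), all(dim(P) == dim(Q)),
            all(dim(P) == prob$nn))
  .stepFromCoef(.segmentCoef(prob, P, Q))
}

#' Project a relaxed solution onto the permutations
#'
#' `method = "gradient"` solves the linear assignment problem on the gradient
#' at `P` (the direction a further Frank-Wolfe step would take);
#' `method = "solution"` solves it on `-P`, i.e. finds the permutation
#' closest to the relaxed solution itself. Both consume one RNG draw for
#' tie-breaking.
#'
#' @inheritParams relaxedObjective
#' @param method projection variant.
#' @return an integer permutation over the full node set (seeds included,
#'   mapped to their partners).
#' @export
projectToPermutation <- function(net, P, seeds = NULL, useContralateral = TRUE,
                                 method = c("solution", "gradient")) {
  method <- match.arg(method)
  prob <- .problem(net, seeds, useContralateral)
  stopifnot(is.matrix(P), all(dim(P) == prob$nn))
  target <- if (method == "gradient") .relaxedGrad(prob, P) else -P
  .embedPerm(prob, .lapDirection(target))
}

.initMatrix <- function(nn, init) {
  J <- matrix(1 / nn, nn, nn)
  if (init == "barycenter") return(J)
  # randomized barycenter: average the barycenter with a random doubly
  # stochastic matrix obtained by Sinkhorn-normalizing uniform noise
  D <- matrix(stats::runif(nn * nn), nn, nn)
  for (i in seq_len(10L)) {
    D <- D / rowSums(D)
    D <- sweep(D, 2L, colSums(D), "/")
  }
  (J + D) / 2
}

.fwRun <- function(prob, P0, maxIter, tol) {
  P <- P0
  trace <- .relaxedObj(prob, P)
  converged <- FALSE
  iter <- 0L
  for (i in seq_len(maxIter)) {
    iter <- i
    G <- .relaxedGrad(prob, P)
    q <- .lapDirection(G)
    Q <- .permMatrix(q)
    coef <- .segmentCoef(prob, P, Q)
    alpha <- .stepFromCoef(coef)
    Pnew <- alpha * P + (1 - alpha) * Q
    trace <- c(trace, coef[1L] + coef[2L] * alpha + coef[3L] * alpha^2)
    # size-independent criterion: Frobenius change scaled by sqrt(n), as in
    # the field's standard Frank-Wolfe matchers
    delta <- sqrt(sum((Pnew - P)^2)) / sqrt(nrow(P))
    P <- Pnew
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(P = P, iterations = iter, converged = converged, trace = trace)
}

#' Match the two sides of a bisected network
#'
#' Runs the Frank-Wolfe graph matcher on the doubly stochastic relaxation,
#' restarting `nRestarts` times, and returns the matching whose discrete
#' edge-disagreement objective is lowest (ties to the lowest restart index).
#' With `useContralateral = TRUE` (the default) the contralateral subgraphs
#' participate in the objective (bisected graph matching, BGM); with `FALSE`
#' only the ipsilateral subgraphs are used (classic graph matching, GM).
#' Seeded pairs are honored exactly. All randomness (assignment tie-breaking
#' and any randomized initialization) is determined by `options@seed` when
#' set.
#'
#' @param net a [BisectedNetwork-class] with equally sized sides (use
#'   [padNetwork()] first otherwise).
#' @param seeds optional [SeedSet-class] of known pairings.
#' @param options a [SolverOptions-class], see [solverOptions()].
#' @return a [Matching-class].
#' @examples
#' sim <- simulateBilateral(simulationParams(n = 8, rhoContra = 1,
#'                                           rhoIpsi = 1), seed = 7)
#' m <- matchBisected(sim$network, options = solverOptions(nRestarts = 5,
#'                                                         seed = 1))
#' matchingAccuracy(m, sim$truth)
#' @export
matchBisected <- function(net, seeds = NULL, options = solverOptions()) {
  stopifnot(is(net, "BisectedNetwork"))
  if (!is.null(seeds)) stopifnot(is(seeds, "SeedSet"))
  validObject(options)
  prob <- .problem(net, seeds, options@useContralateral)
  nR <- options@nRestarts
  .localSeed(if (length(options@seed)) options@seed else NULL, {
    perms <- matrix(0L, prob$n, nR)
    objs <- numeric(nR)
    runs <- vector("list", nR)
    for (r in seq_len(nR)) {
      P0 <- .initMatrix(prob$nn, options@init)
      run <- .fwRun(prob, P0, options@maxIter, options@tol)
      target <- if (options@project == "gradient")
        .relaxedGrad(prob, run$P) else -run$P
      full <- .embedPerm(prob, .lapDirection(target))
      perms[, r] <- full
      objs[r] <- bgmObjective(net, full, seeds, options@useContralateral)
      runs[[r]] <- run
    }
    best <- which(objs == min(objs))[1L]
    new("Matching",
        perm = perms[, best],
        leftIds = leftIds(net), rightIds = rightIds(net),
        padIds = net@padIds,
        objective = objs[best],
        nIterations = as.integer(runs[[best]]$iterations),
        converged = runs[[best]]$converged,
        restartIndex = as.integer(best),
        restartPerms = perms,
        restartObjectives = objs,
        objectiveTrace = runs[[best]]$trace,
        useContralateral = options@useContralateral)
  })
}
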