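# Independent oracles and fixture builders, deliberately written with naive
# loops so they share no code path with the package internals they check.

# all n! permutations of 1..n, one per row
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

# brute-force discrete objective by explicit double loops over entries
bruteObjective <- function(net, perm, useContralateral = TRUE) {
  total <- 0
  n <- length(perm)
  for (k in seq_len(nLayers(net))) {
    LL <- adjacencyBlock(net, "LL", k); RR <- adjacencyBlock(net, "RR", k)
    LR <- adjacencyBlock(net, "LR", k); RL <- adjacencyBlock(net, "RL", k)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      total <- total + (LL[i, j] - RR[perm[i], perm[j]])^2
      if (useContralateral)
        total <- total + (LR[i, perm[j]] - RL[perm[i], j])^2
    }
  }
  total
}

exhaustiveMin <- function(net, useContralateral = TRUE) {
  perms <- allPerms(nLeft(net))
  vals <- apply(perms, 1L, function(p) bruteObjective(net, p, useContralateral))
  list(value = min(vals), perm = perms[which.min(vals), ])
}

# weakly connected component labels by hand-rolled BFS on the summed
# adjacency (union of out- and in-neighbors)
bfsComponents <- function(adj) {
  n <- nrow(adj)
  lab <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(lab[s])) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which((adj[v, ] != 0 | adj[, v] != 0) & is.na(lab))
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

# random doubly stochastic matrix via long Sinkhorn balancing
randomDS <- function(n) {
  M <- matrix(stats::runif(n * n) + 0.1, n, n)
  for (i in seq_len(200L)) {
    M <- M / rowSums(M)
    M <- sweep(M, 2L, colSums(M), "/")
  }
  M
}

randomNet <- function(n, layers = 1L, weighted = TRUE, contraZero = FALSE) {
  mk <- function() {
    m <- matrix(stats::runif(n * n), n, n)
    if (!weighted) m <- round(m * 3)
    m
  }
  lys <- lapply(seq_len(layers), function(k) {
    list(LL = mk(), RR = mk(),
         LR = if (contraZero) matrix(0, n, n) else mk(),
         RL = if (contraZero) matrix(0, n, n) else mk())
  })
  BisectedNetwork(layers = lys)
}

# a network whose right side is an exactly relabeled copy of the left
# (rho = 1 planted isomorphism): the unshuffled instance from the simulator
plantedNet <- function(n, seed) {
  simulateBilateral(simulationParams(n = n, rhoIpsi = 1, rhoContra = 1),
                    seed = seed)
}
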