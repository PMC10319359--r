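# Objective, gradient, line search, projection and the full Frank-Wolfe solve.

test_that("discrete objective matches a brute-force entrywise oracle", {
  # perfectly mirrored halves score zero at the identity
  set.seed(21)
  A <- matrix(rbinom(36, 1, 0.4), 6); diag(A) <- 0
  C <- matrix(rbinom(36, 1, 0.3), 6)
  sym <- BisectedNetwork(LL = A, RR = A, LR = C, RL = C)
  expect_equal(bgmObjective(sym, 1:6), 0)

  # dropping the contralateral term reduces to the ipsilateral-only objective
  net <- randomNet(5)
  for (r in 1:5) {
    p <- sample(5)
    expect_equal(bgmObjective(net, p, useContralateral = FALSE),
                 bgmObjective(gmView(net), p))
    expect_equal(bgmObjective(net, p), bruteObjective(net, p))
    expect_equal(bgmObjective(net, p, useContralateral = FALSE),
                 bruteObjective(net, p, useContralateral = FALSE))
  }

  # 3-node integer blocks at a fixed non-identity permutation
  set.seed(4)
  ints <- BisectedNetwork(LL = matrix(sample(0:4, 9, TRUE), 3),
                          RR = matrix(sample(0:4, 9, TRUE), 3),
                          LR = matrix(sample(0:4, 9, TRUE), 3),
                          RL = matrix(sample(0:4, 9, TRUE), 3))
  expect_equal(bgmObjective(ints, c(3L, 1L, 2L)),
               bruteObjective(ints, c(3L, 1L, 2L)))
})

test_that("discrete objective is an affine function of the relaxed trace form on permutations", {
  set.seed(33)
  for (layers in 1:2) {
    net <- randomNet(5, layers = layers)
    cst <- sum(vapply(seq_len(layers), function(k)
      sum(adjacencyBlock(net, "LL", k)^2) + sum(adjacencyBlock(net, "RR", k)^2) +
        sum(adjacencyBlock(net, "LR", k)^2) + sum(adjacencyBlock(net, "RL", k)^2),
      numeric(1)))
    for (r in 1:5) {
      p <- sample(5)
      P <- matrix(0, 5, 5); P[cbind(1:5, p)] <- 1
      expect_equal(bgmObjective(net, p), cst + 2 * relaxedObjective(net, P))
    }
  }
})

test_that("gradient matches central finite differences of the relaxed objective", {
  set.seed(12)
  h <- 1e-5
  fdGrad <- function(f, P) {
    G <- matrix(0, nrow(P), ncol(P))
    for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
      E <- matrix(0, nrow(P), ncol(P)); E[i, j] <- h
      G[i, j] <- (f(P + E) - f(P - E)) / (2 * h)
    }
    G
  }
  # unseeded, single layer and multiplex K = 2
  for (layers in 1:2) {
    net <- randomNet(4, layers = layers)
    P <- randomDS(4)
    expect_equal(bgmGradient(net, P),
                 fdGrad(function(X) relaxedObjective(net, X), P),
                 tolerance = 1e-6)
  }
  # all-zero network: zero gradient
  z <- matrix(0, 4, 4)
  zero <- BisectedNetwork(LL = z, RR = z, LR = z, RL = z)
  expect_equal(bgmGradient(zero, randomDS(4)), z)
  # zero contralateral blocks: classic ipsilateral-only gradient
  gmnet <- randomNet(4, contraZero = TRUE)
  P <- randomDS(4)
  A <- adjacencyBlock(gmnet, "LL"); B <- adjacencyBlock(gmnet, "RR")
  expect_equal(bgmGradient(gmnet, P),
               -(A %*% P %*% t(B) + t(A) %*% P %*% B))
})

test_that("seeded gradient matches finite differences and honors the seed algebra", {
  set.seed(13)
  net <- randomNet(6)
  seeds <- seedSet(c("L2", "L5"), c("R1", "R4"))
  P <- randomDS(4)
  h <- 1e-5
  fd <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    E <- matrix(0, 4, 4); E[i, j] <- h
    fd[i, j] <- (relaxedObjective(net, P + E, seeds) -
                   relaxedObjective(net, P - E, seeds)) / (2 * h)
  }
  expect_equal(bgmGradient(net, P, seeds), fd, tolerance = 1e-6)

  # the seeded relaxed form stays affinely tied to the seed-respecting
  # discrete objective over all free-block permutations, so both rank
  # candidate permutations identically
  perms <- allPerms(4)
  disc <- apply(perms, 1, function(bp) {
    full <- integer(6)
    full[c(2L, 5L)] <- c(1L, 4L)
    full[c(1L, 3L, 4L, 6L)] <- c(2L, 3L, 5L, 6L)[bp]
    bgmObjective(net, full, seeds)
  })
  rel <- apply(perms, 1, function(bp) {
    Pm <- matrix(0, 4, 4); Pm[cbind(1:4, bp)] <- 1
    relaxedObjective(net, Pm, seeds)
  })
  expect_equal(disc - 2 * rel, rep(disc[1] - 2 * rel[1], length(disc)),
               tolerance = 1e-8)
})

test_that("the Frank-Wolfe direction solves the assignment exactly", {
  expect_equal(attr(frankWolfeDirection(-diag(5)), "perm"), 1:5)
  # a unique minimal entry per row forming a permutation pattern
  G <- matrix(10, 4, 4)
  pat <- c(3L, 1L, 4L, 2L)
  G[cbind(1:4, pat)] <- -1
  expect_equal(attr(frankWolfeDirection(G), "perm"), pat)
  # random matrices against exhaustive enumeration over all 120 permutations
  set.seed(77)
  perms <- allPerms(5)
  for (r in 1:10) {
    G <- matrix(rnorm(25), 5)
    q <- attr(frankWolfeDirection(G), "perm")
    vals <- apply(perms, 1, function(p) sum(G[cbind(1:5, p)]))
    expect_equal(sum(G[cbind(1:5, q)]), min(vals))
  }
  expect_error(frankWolfeDirection(matrix(c(1, NA, 0, 1), 2)), "finite")
})

test_that("exact step size minimizes the segment objective", {
  set.seed(9)
  net <- randomNet(5)
  P <- randomDS(5)
  # degenerate segment: convention alpha = 1
  expect_equal(exactStepSize(net, P, P), 1)
  for (r in 1:10) {
    q <- sample(5)
    Q <- matrix(0, 5, 5); Q[cbind(1:5, q)] <- 1
    a <- exactStepSize(net, P, Q)
    seg <- function(al) relaxedObjective(net, al * P + (1 - al) * Q)
    # minimizer property against endpoints and local perturbations
    expect_lte(seg(a), seg(0) + 1e-10)
    expect_lte(seg(a), seg(1) + 1e-10)
    if (a > 0.01 && a < 0.99) {
      expect_lte(seg(a), seg(a + 0.01) + 1e-10)
      expect_lte(seg(a), seg(a - 0.01) + 1e-10)
    }
    # dense grid-search oracle
    grid <- seq(0, 1, length.out = 10001)
    best <- grid[which.min(vapply(grid, seg, numeric(1)))]
    expect_equal(seg(a), seg(best), tolerance = 1e-6)
    expect_lt(abs(a - best), 1e-3)
  }
})

test_that("projection onto permutations matches enumeration and fixes solved optima", {
  set.seed(41)
  # n = 1: the only permutation
  one <- randomNet(1)
  expect_equal(projectToPermutation(one, matrix(1, 1, 1)), 1L)
  # random relaxed points: assignment value equals the exhaustive minimum
  net <- randomNet(5)
  perms <- allPerms(5)
  for (r in 1:5) {
    P <- randomDS(5)
    for (method in c("solution", "gradient")) {
      perm <- projectToPermutation(net, P, method = method)
      target <- if (method == "gradient") bgmGradient(net, P) else -P
      vals <- apply(perms, 1, function(p) sum(target[cbind(1:5, p)]))
      expect_equal(sum(target[cbind(1:5, perm)]), min(vals))
    }
  }
  # a permutation matrix at a strict local optimum projects to itself
  sim <- plantedNet(5, seed = 19)
  truthPerm <- sim$truth
  Pstar <- matrix(0, 5, 5); Pstar[cbind(1:5, truthPerm)] <- 1
  expect_equal(bgmObjective(sim$network, truthPerm), 0)
  expect_equal(projectToPermutation(sim$network, Pstar, method = "solution"),
               truthPerm)
})

test_that("solve recovers planted relabelings and never beats exhaustive search", {
  # planted isomorphism: objective 0 and the planted permutation recovered
  sim <- plantedNet(6, seed = 5)
  m <- matchBisected(sim$network,
                     options = solverOptions(nRestarts = 5, seed = 2))
  expect_equal(m@objective, 0)
  expect_equal(m@perm, sim$truth)

  # random weighted instances: returned objective is bounded below by the
  # exhaustive minimum over all permutations
  set.seed(64)
  for (r in 1:5) {
    net <- randomNet(5)
    m <- matchBisected(net, options = solverOptions(nRestarts = 3, seed = r))
    ex <- exhaustiveMin(net)
    expect_gte(m@objective + 1e-9, ex$value)
    expect_equal(m@objective, bgmObjective(net, m@perm))
  }
})

test_that("GM and BGM coincide exactly when contralateral blocks are zero", {
  set.seed(17)
  net <- randomNet(6, contraZero = TRUE)
  for (r in 1:8) {
    p <- sample(6)
    expect_equal(bgmObjective(net, p, useContralateral = TRUE),
                 bgmObjective(net, p, useContralateral = FALSE))
  }
  mG <- matchBisected(net, options = solverOptions(seed = 99, nRestarts = 3,
                                                   useContralateral = FALSE))
  mB <- matchBisected(net, options = solverOptions(seed = 99, nRestarts = 3,
                                                   useContralateral = TRUE))
  expect_identical(mG@perm, mB@perm)
  expect_identical(mG@restartPerms, mB@restartPerms)
  expect_equal(mG@objectiveTrace, mB@objectiveTrace)
  expect_equal(mG@objective, mB@objective)
})

test_that("the relaxed objective trace is non-increasing and iterates stay doubly stochastic", {
  set.seed(26)
  for (r in 1:5) {
    net <- randomNet(8, weighted = (r %% 2 == 0))
    m <- matchBisected(net, options = solverOptions(seed = r))
    expect_true(all(diff(m@objectiveTrace) <= 1e-9))
    # re-run the internal loop to inspect the final iterate
    prob <- bgmatch:::.problem(net, NULL, TRUE)
    set.seed(r)
    run <- bgmatch:::.fwRun(prob, matrix(1 / 8, 8, 8), 30L, 0.03)
    expect_equal(rowSums(run$P), rep(1, 8), tolerance = 1e-8)
    expect_equal(colSums(run$P), rep(1, 8), tolerance = 1e-8)
    expect_true(all(run$P >= -1e-12 & run$P <= 1 + 1e-12))
  }
})

test_that("relabeling the right side transforms the recovered matching accordingly", {
  sim <- plantedNet(6, seed = 23)
  net <- sim$network
  m0 <- matchBisected(net, options = solverOptions(nRestarts = 5, seed = 3))
  expect_equal(m0@objective, 0)  # unique optimum instance
  sigma <- c(4L, 1L, 6L, 2L, 5L, 3L)
  m1 <- matchBisected(applyShuffle(net, sigma),
                      options = solverOptions(nRestarts = 5, seed = 3))
  expect_equal(m1@objective, 0)
  # right node formerly at position p now sits where sigma maps it
  inv <- integer(6); inv[sigma] <- 1:6
  expect_equal(m1@perm, inv[m0@perm])
})

test_that("seeded solves honor the seed pairing exactly", {
  set.seed(47)
  for (r in 1:4) {
    sim <- simulateBilateral(simulationParams(n = 8, rhoContra = 0.6),
                             seed = 100 + r)
    net <- sim$network
    sl <- sample(leftIds(net), 3)
    sr <- rightIds(net)[sim$truth[match(sl, leftIds(net))]]
    seeds <- seedSet(sl, sr)
    m <- matchBisected(net, seeds = seeds,
                       options = solverOptions(seed = r, nRestarts = 2))
    got <- rightIds(net)[m@perm[match(sl, leftIds(net))]]
    expect_identical(got, sr)
    # every restart honors the seeds, not just the winner
    for (k in seq_len(ncol(m@restartPerms)))
      expect_identical(rightIds(net)[m@restartPerms[match(sl, leftIds(net)), k]], sr)
  }
})

test_that("unequal sides are rejected with a pointer to padNetwork, and padded solves report unmatched nodes", {
  set.seed(58)
  net <- BisectedNetwork(LL = matrix(runif(36), 6), RR = matrix(runif(16), 4),
                         LR = matrix(runif(24), 6, 4), RL = matrix(runif(24), 4, 6))
  expect_error(matchBisected(net), "padNetwork")
  padded <- padNetwork(net)
  m <- matchBisected(padded, options = solverOptions(seed = 6))
  mp <- matchedPairs(m)
  expect_equal(sum(!mp$matched), 2)
  expect_true(all(is.na(mp$right_id[!mp$matched])))
})

test_that("solves are reproducible from the seed and select the best restart", {
  sim <- simulateBilateral(simulationParams(n = 9, rhoContra = 0.5), seed = 77)
  a <- matchBisected(sim$network, options = solverOptions(nRestarts = 4, seed = 5))
  b <- matchBisected(sim$network, options = solverOptions(nRestarts = 4, seed = 5))
  expect_identical(a@perm, b@perm)
  expect_identical(a@restartPerms, b@restartPerms)
  expect_equal(a@objective, min(a@restartObjectives))
  expect_equal(a@restartIndex, which(a@restartObjectives == a@objective)[1])
  # randomized-barycenter initialization is also seed-reproducible
  c1 <- matchBisected(sim$network, options = solverOptions(
    nRestarts = 2, seed = 8, init = "randomized-barycenter"))
  c2 <- matchBisected(sim$network, options = solverOptions(
    nRestarts = 2, seed = 8, init = "randomized-barycenter"))
  expect_identical(c1@restartPerms, c2@restartPerms)
})

test_that("multiplex solves run over all layers and recover planted structure", {
  sim <- simulateBilateral(simulationParams(n = 7, rhoIpsi = 1, rhoContra = 1),
                           seed = 31)
  un <- sim$unshuffled
  two <- BisectedNetwork(layers = list(un@layers[[1]], un@layers[[1]]))
  two <- applyShuffle(two, sim$sigma)
  m <- matchBisected(two, options = solverOptions(nRestarts = 3, seed = 4))
  expect_equal(m@objective, 0)
  expect_equal(m@perm, sim$truth)
})
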