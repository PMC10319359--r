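# Scripted simulation experiments: the contralateral-correlation sweep,
# restart-based method comparison, and seeded cross-validation.

#' Sweep matching accuracy over the contralateral edge correlation
#'
#' For each grid value of the contralateral edge correlation, simulates
#' `nReps` bilateral networks and runs graph matching (GM) and bisected
#' graph matching (BGM) once each, from the barycenter, on the identical
#' instance with the same tie-breaking randomness. Replicate seeds are
#' shared across grid values (common random numbers), so the ipsilateral
#' draws at a given replicate are identical along the grid.
#'
#' @param params a [SimulationParams-class]; its `rhoContra` is ignored in
#'   favor of `grid`.
#' @param grid contralateral correlation values in [0, 1].
#' @param nReps replicates per grid value.
#' @param seed integer seed; identical seeds give identical results.
#' @param options solver options applied to both methods (the
#'   `useContralateral` flag is overridden per method).
#' @return a [SweepResult-class].
#' @examples
#' sw <- runRhoSweep(grid = c(0, 1), nReps = 20, seed = 1)
#' sweepSummary(sw)
#' @export
runRhoSweep <- function(params = simulationParams(), grid = seq(0, 1, by = 0.1),
                        nReps = 1000L, seed = NULL,
                        options = solverOptions()) {
  stopifnot(all(grid >= 0 & grid <= 1), nReps >= 1L)
  seeds <- .childSeeds(seed %||% sample.int(.Machine$integer.max - 1L, 1L), 2L)
  instSeeds <- .childSeeds(seeds[1L], nReps)
  solveSeeds <- .childSeeds(seeds[2L], nReps)
  rows <- vector("list", length(grid) * nReps)
  idx <- 0L
  for (g in seq_along(grid)) {
    params@rhoContra <- grid[g]
    for (r in seq_len(nReps)) {
      sim <- simulateBilateral(params, seed = instSeeds[r])
      accs <- vapply(c(gm = FALSE, bgm = TRUE), function(contra) {
        opts <- options
        opts@useContralateral <- contra
        opts@seed <- solveSeeds[r]
        matchingAccuracy(matchBisected(sim$network, options = opts)@perm,
                         sim$truth)
      }, numeric(1))
      idx <- idx + 1L
      rows[[idx]] <- data.frame(rhoContra = grid[g], replicate = r,
                                method = c("gm", "bgm"), accuracy = accs,
                                stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  new("SweepResult", results = results, summary = .sweepSummary(results))
}

.sweepSummary <- function(results) {
  agg <- stats::aggregate(accuracy ~ rhoContra + method, data = results,
                          FUN = function(x) c(mean = mean(x),
                                              sem = stats::sd(x) / sqrt(length(x)),
                                              n = length(x)))
  out <- data.frame(rhoContra = agg$rhoContra, method = agg$method,
                    mean = agg$accuracy[, "mean"],
                    lower = agg$accuracy[, "mean"] - 1.96 * agg$accuracy[, "sem"],
                    upper = agg$accuracy[, "mean"] + 1.96 * agg$accuracy[, "sem"],
                    nReps = agg$accuracy[, "n"],
                    stringsAsFactors = FALSE)
  out[order(out$rhoContra, out$method), ]
}

#' Compare GM and BGM across shared restarts
#'
#' Runs both methods once per restart seed on the same network, so each
#' restart pair shares its initialization and tie-breaking randomness, and
#' summarizes the paired per-restart accuracies with a two-sided
#' Mann-Whitney U test.
#'
#' @param net a [BisectedNetwork-class] with equal sides.
#' @param truth as in [matchingAccuracy()].
#' @param nRestarts number of restarts per method.
#' @param seed integer seed.
#' @param options base solver options.
#' @return list with `results` (data.frame: `restart`, `method`, `accuracy`),
#'   `test` (see [compareMethods()], GM as sample A), and `meanAccuracy`.
#' @export
runRestartComparison <- function(net, truth, nRestarts = 50L, seed = NULL,
                                 options = solverOptions()) {
  stopifnot(is(net, "BisectedNetwork"), nRestarts >= 1L)
  restartSeeds <- .childSeeds(seed %||% sample.int(.Machine$integer.max - 1L, 1L),
                              nRestarts)
  acc <- sapply(c(gm = FALSE, bgm = TRUE), function(contra) {
    vapply(seq_len(nRestarts), function(r) {
      opts <- options
      opts@useContralateral <- contra
      opts@seed <- restartSeeds[r]
      opts@nRestarts <- 1L
      matchingAccuracy(matchBisected(net, options = opts), truth)
    }, numeric(1))
  })
  acc <- matrix(acc, ncol = 2, dimnames = list(NULL, c("gm", "bgm")))
  results <- data.frame(
    restart = rep(seq_len(nRestarts), 2L),
    method = rep(c("gm", "bgm"), each = nRestarts),
    accuracy = c(acc[, "gm"], acc[, "bgm"]),
    stringsAsFactors = FALSE
  )
  test <- if (nRestarts >= 2L) compareMethods(acc[, "gm"], acc[, "bgm"]) else NULL
  list(results = results, test = test,
       meanAccuracy = c(gm = mean(acc[, "gm"]), bgm = mean(acc[, "bgm"])))
}

#' Seeded-matching cross-validation
#'
#' Emulates the design used to study the value of seeds: in each fold, a
#' fraction (`holdoutFrac`, default 20%) of the known pairs is held out for
#' evaluation; for each requested seed count, that many of the remaining
#' pairs are given to both GM and BGM as seeds, and accuracy is computed on
#' the held-out pairs only. Holdout pairs never enter the seed set, and the
#' holdout is re-randomized per fold.
#'
#' @param net a [BisectedNetwork-class] with equal sides.
#' @param knownPairs two-column data.frame of (left_id, right_id) known
#'   pairs, or a [SeedSet-class].
#' @param seedCounts integer vector of seed-set sizes to test; each must fit
#'   within the non-holdout pairs.
#' @param holdoutFrac fraction of pairs held out for evaluation per fold.
#' @param nFolds number of folds.
#' @param seed integer seed.
#' @param options base solver options.
#' @return data.frame with columns `fold`, `nSeeds`, `method`, `accuracy`.
#' @export
runSeedCV <- function(net, knownPairs, seedCounts, holdoutFrac = 0.2,
                      nFolds = 5L, seed = NULL, options = solverOptions()) {
  stopifnot(is(net, "BisectedNetwork"))
  if (is(knownPairs, "SeedSet")) knownPairs <- knownPairs@pairs
  pairs <- data.frame(left = as.character(knownPairs[[1L]]),
                      right = as.character(knownPairs[[2L]]),
                      stringsAsFactors = FALSE)
  nPairs <- nrow(pairs)
  nHold <- max(1L, round(holdoutFrac * nPairs))
  if (max(seedCounts) > nPairs - nHold)
    stop("seedCounts exceed the available non-holdout pairs (",
         nPairs - nHold, ")")
  foldSeeds <- .childSeeds(seed %||% sample.int(.Machine$integer.max - 1L, 1L),
                           nFolds)
  rows <- list()
  for (f in seq_len(nFolds)) {
    sub <- .childSeeds(foldSeeds[f], 2L + 2L * length(seedCounts))
    hold <- .localSeed(sub[1L], sample.int(nPairs, nHold))
    avail <- setdiff(seq_len(nPairs), hold)
    truthDf <- pairs[hold, ]
    for (ci in seq_along(seedCounts)) {
      cnt <- seedCounts[ci]
      pick <- .localSeed(sub[2L + ci], sample(avail, cnt))
      sd <- seedSet(pairs$left[pick], pairs$right[pick])
      for (contra in c(gm = FALSE, bgm = TRUE)) {
        opts <- options
        opts@useContralateral <- contra
        opts@seed <- sub[2L + length(seedCounts) + ci]
        m <- matchBisected(net, seeds = if (cnt > 0L) sd else NULL,
                           options = opts)
        rows[[length(rows) + 1L]] <- data.frame(
          fold = f, nSeeds = cnt, method = if (contra) "bgm" else "gm",
          accuracy = matchingAccuracy(m, truthDf, evalIds = truthDf$left),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
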