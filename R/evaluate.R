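# Accuracy and diagnostic metrics for recovered matchings.

.truthToPerm <- function(truth, matching) {
  if (is.atomic(truth)) return(as.integer(truth))
  # data.frame of (left_id, right_id) pairs
  stopifnot(is.data.frame(truth), ncol(truth) >= 2L)
  perm <- rep(NA_integer_, length(matching@leftIds))
  i <- match(as.character(truth[[1L]]), matching@leftIds)
  j <- match(as.character(truth[[2L]]), matching@rightIds)
  if (anyNA(i) || anyNA(j)) stop("truth pairing references unknown node ids")
  perm[i] <- j
  perm
}

#' Matching accuracy
#'
#' The proportion of evaluable left nodes whose predicted right partner
#' equals the true partner. Seeds (when supplied) are excluded from both
#' numerator and denominator, as are padding sentinels and any left node
#' without truth information.
#'
#' @param predicted a [Matching-class], or an integer permutation vector
#'   (then `exclude` must be `NULL` or index-based information is
#'   unavailable and only a numeric truth is accepted).
#' @param truth integer vector (`truth[j]` = true right position for left
#'   position `j`, `NA` where unknown) or a two-column data.frame of
#'   (left_id, right_id) pairs.
#' @param exclude optional [SeedSet-class] whose left nodes are excluded
#'   from the evaluation.
#' @param evalIds optional character vector restricting evaluation to these
#'   left ids (used e.g. for held-out seed pairs in cross-validation).
#' @return accuracy in [0, 1].
#' @export
matchingAccuracy <- function(predicted, truth, exclude = NULL, evalIds = NULL) {
  if (is(predicted, "Matching")) {
    perm <- predicted@perm
    truthPerm <- .truthToPerm(truth, predicted)
    keep <- !is.na(truthPerm)
    # padding sentinels: left sentinels and left nodes assigned to a
    # sentinel ("unmatched") are excluded from the denominator
    keep[predicted@leftIds %in% predicted@padIds] <- FALSE
    keep[predicted@rightIds[perm] %in% predicted@padIds] <- FALSE
    if (!is.null(exclude)) {
      stopifnot(is(exclude, "SeedSet"))
      keep[predicted@leftIds %in% exclude@pairs$left] <- FALSE
    }
    if (!is.null(evalIds))
      keep <- keep & predicted@leftIds %in% evalIds
  } else {
    perm <- as.integer(predicted)
    truthPerm <- as.integer(truth)
    keep <- !is.na(truthPerm)
    if (!is.null(exclude) || !is.null(evalIds))
      stop("id-based exclusion requires a Matching object")
  }
  if (!any(keep)) stop("no evaluable nodes")
  mean(perm[keep] == truthPerm[keep])
}

#' Alignment correlations of a paired network
#'
#' Pearson correlations between the two ipsilateral subgraphs and between
#' the two contralateral subgraphs once the right side is aligned by a
#' pairing: the ipsilateral correlation compares the off-diagonal entries of
#' `A_LL` with those of `A_RR[perm, perm]` (diagonal, i.e. self-loop,
#' positions excluded); the contralateral correlation compares all entries
#' of `A_LR[, perm]` with `A_RL[perm, ]` (the convention under which mirror
#' symmetry maps the edge Li->Rj onto Ri->Lj, and the one the bisected
#' matching objective itself uses). For multiplex networks entries are
#' pooled across layers.
#'
#' @param net a [BisectedNetwork-class] with equal sides.
#' @param pairing a full bijection: integer permutation vector or a
#'   [Matching-class].
#' @return named numeric vector with elements `ipsi` and `contra`.
#' @export
alignmentCorrelation <- function(net, pairing) {
  stopifnot(is(net, "BisectedNetwork"))
  if (is(pairing, "Matching")) pairing <- pairing@perm
  perm <- as.integer(pairing)
  n <- nLeft(net)
  if (n != nRight(net)) stop("sides must have equal size")
  if (!identical(sort(perm), seq_len(n)))
    stop("pairing must be a full bijection")
  off <- row(diag(n)) != col(diag(n))
  ipsiX <- unlist(lapply(net@layers, function(ly) ly$LL[off]))
  ipsiY <- unlist(lapply(net@layers, function(ly)
    ly$RR[perm, perm, drop = FALSE][off]))
  contraX <- unlist(lapply(net@layers, function(ly) ly$LR[, perm, drop = FALSE]))
  contraY <- unlist(lapply(net@layers, function(ly) ly$RL[perm, , drop = FALSE]))
  if (stats::sd(ipsiX) == 0 || stats::sd(ipsiY) == 0 ||
      stats::sd(contraX) == 0 || stats::sd(contraY) == 0)
    stop("correlation undefined: a vectorized subgraph has zero variance")
  c(ipsi = stats::cor(ipsiX, ipsiY), contra = stats::cor(contraX, contraY))
}

#' Edge disagreement of a matching
#'
#' The discrete matching objective evaluated at a permutation; for a binary
#' network the ipsilateral term counts mismatched edges (each disagreement
#' contributing 1 as a squared 0/1 difference).
#'
#' @inheritParams bgmObjective
#' @return the edge-disagreement value.
#' @export
edgeDisagreement <- function(net, perm, useContralateral = TRUE) {
  bgmObjective(net, perm, seeds = NULL, useContralateral = useContralateral)
}

#' Match frequencies across restarts
#'
#' How often each (left, right) pair was selected across restarts. Pairs at
#' frequency 1.0 (selected by every restart) are flagged high-confidence;
#' low frequencies indicate unstable, lower-confidence matches.
#'
#' @param x a [Matching-class] (its per-restart solutions are used) or a
#'   list of [Matching-class] objects over the same node sets.
#' @return data.frame with columns `left_id`, `right_id`, `frequency`,
#'   `highConfidence`, ordered by `left_id` then decreasing frequency.
#' @name matchFrequencies
setMethod("matchFrequencies", "Matching", function(x) {
  .freqFromPerms(x@restartPerms, x@leftIds, x@rightIds)
})

#' @rdname matchFrequencies
setMethod("matchFrequencies", "list", function(x) {
  stopifnot(length(x) > 0L, all(vapply(x, is, logical(1), "Matching")))
  ref <- x[[1L]]
  for (m in x[-1L])
    if (!identical(m@leftIds, ref@leftIds) || !identical(m@rightIds, ref@rightIds))
      stop("all matchings must share the same node sets")
  perms <- vapply(x, function(m) m@perm, integer(length(ref@perm)))
  .freqFromPerms(matrix(perms, nrow = length(ref@perm)), ref@leftIds, ref@rightIds)
})

.freqFromPerms <- function(perms, leftIds, rightIds) {
  nRestart <- ncol(perms)
  pairs <- data.frame(
    left_id = rep(leftIds, nRestart),
    right_id = rightIds[as.vector(perms)],
    stringsAsFactors = FALSE
  )
  tab <- stats::aggregate(cnt ~ left_id + right_id,
                          data = cbind(pairs, cnt = 1), FUN = sum)
  tab$frequency <- tab$cnt / nRestart
  tab$cnt <- NULL
  tab$highConfidence <- tab$frequency == 1
  tab <- tab[order(tab$left_id, -tab$frequency, tab$right_id), ]
  rownames(tab) <- NULL
  tab
}

#' Evaluate a matching against a known pairing
#'
#' Convenience wrapper bundling [matchingAccuracy()], per-node correctness
#' flags and [matchFrequencies()] into one report.
#'
#' @param matching a [Matching-class].
#' @param truth as in [matchingAccuracy()].
#' @param seeds optional [SeedSet-class] excluded from evaluation.
#' @return an [EvaluationReport-class].
#' @export
evaluateMatching <- function(matching, truth, seeds = NULL) {
  stopifnot(is(matching, "Matching"))
  truthPerm <- .truthToPerm(truth, matching)
  freq <- matchFrequencies(matching)
  predRight <- matching@rightIds[matching@perm]
  key <- paste(matching@leftIds, predRight, sep = "\r")
  fmap <- stats::setNames(freq$frequency, paste(freq$left_id, freq$right_id, sep = "\r"))
  perNode <- data.frame(
    left_id = matching@leftIds,
    predicted_right_id = predRight,
    truth_right_id = ifelse(is.na(truthPerm), NA_character_,
                            matching@rightIds[truthPerm]),
    correct = matching@perm == truthPerm,
    frequency = unname(fmap[key]),
    stringsAsFactors = FALSE
  )
  keep <- !is.na(truthPerm) &
    !(matching@leftIds %in% matching@padIds) &
    !(predRight %in% matching@padIds)
  if (!is.null(seeds)) keep[matching@leftIds %in% seeds@pairs$left] <- FALSE
  acc <- matchingAccuracy(matching, truth, exclude = seeds)
  new("EvaluationReport", accuracy = acc, nEvaluable = sum(keep),
      perNode = perNode, frequencies = freq)
}

#' Compare two accuracy samples
#'
#' Two-sided Mann-Whitney U test (via [stats::wilcox.test()]) between two
#' sets of per-restart accuracies, as used when comparing GM against BGM.
#'
#' @param accA,accB numeric vectors of accuracies (at least 2 each).
#' @return list with elements `U` (the statistic for `accA`), `pValue`,
#'   `nA`, `nB` and `method`.
#' @export
compareMethods <- function(accA, accB) {
  if (length(accA) < 2L || length(accB) < 2L)
    stop("need at least two observations per sample")
  wt <- suppressWarnings(stats::wilcox.test(accA, accB, alternative = "two.sided"))
  list(U = unname(wt$statistic), pValue = wt$p.value,
       nA = length(accA), nB = length(accB),
       method = "two-sided Mann-Whitney U")
}
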