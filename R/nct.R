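#' Permutation-based comparison of two cross-sectional networks
#'
#' Re-estimates both networks under random relabelings of the pooled
#' subjects (group sizes preserved) and tests: network structure (M = the
#' maximum absolute edge difference), global strength (S = the absolute
#' difference of the summed absolute edge weights) and centrality
#' (per-metric maximum absolute node difference, with per-node Holm
#' post-hoc when the omnibus test is significant). Post-hoc edge tests are
#' run only when the structure test is significant at `alpha`, with
#' Holm-Bonferroni adjustment. P-values use the add-one convention
#' \eqn{p = (1 + \#\{perm \ge obs\})/(1 + n_{perm})}.
#'
#' @param dataA,dataB Subject x item matrices (same items), or
#'   [panelData()] objects together with `wave`.
#' @param estimator Deterministic recipe `X -> weight matrix`
#'   ([ggmEstimator()] by default).
#' @param nPerm Number of permutations.
#' @param seed Integer seed.
#' @param tests Which statistics to test.
#' @param alpha Significance gate for the post-hoc stages.
#' @param centralityMode `"omnibus"` (default: max-over-nodes statistic,
#'   then per-node post-hoc) or `"direct"` (per-node p-values, Holm
#'   adjusted, without the omnibus gate).
#' @param wave Wave label when panels are given.
#' @return An `nctResult`.
#' @export
nctTest <- function(dataA, dataB, estimator = ggmEstimator(), nPerm = 1000,
                    seed = 1L,
                    tests = c("structure", "global_strength", "centrality"),
                    alpha = 0.05,
                    centralityMode = c("omnibus", "direct"), wave = NULL) {
  centralityMode <- match.arg(centralityMode)
  tests <- match.arg(tests, several.ok = TRUE)
  XA <- if (inherits(dataA, "panelData")) waveMatrix(dataA, wave) else
    as.matrix(dataA)
  XB <- if (inherits(dataB, "panelData")) waveMatrix(dataB, wave) else
    as.matrix(dataB)
  if (ncol(XA) != ncol(XB) ||
      !identical(colnames(XA), colnames(XB)))
    stopf("both groups must share the same item set")
  p <- ncol(XA)
  if (min(nrow(XA), nrow(XB)) < p / 2)
    warnf("smallest group (n = %d) is below p/2; permutation estimates may be unstable",
          min(nrow(XA), nrow(XB)))
  # canonical order (larger group first) so the test is invariant under
  # swapping the roles of A and B
  swapped <- nrow(XB) > nrow(XA)
  X1 <- if (swapped) XB else XA
  X2 <- if (swapped) XA else XB
  n1 <- nrow(X1)
  pooled <- rbind(X1, X2)
  n <- nrow(pooled)

  W1 <- estimator(X1)
  W2 <- estimator(X2)
  edgeDiffObs <- abs(upperTri(W1) - upperTri(W2))
  obsM <- max(edgeDiffObs)
  obsS <- abs(globalStrength(W1) - globalStrength(W2))
  centObs <- list(
    strength = abs(strengthCentrality(W1) - strengthCentrality(W2)),
    expectedInfluence = abs(expectedInfluence(W1) - expectedInfluence(W2)))

  nEdge <- length(edgeDiffObs)
  permM <- numeric(nPerm)
  permS <- numeric(nPerm)
  permEdge <- matrix(NA_real_, nPerm, nEdge)
  permCent <- list(strength = matrix(NA_real_, nPerm, p),
                   expectedInfluence = matrix(NA_real_, nPerm, p))
  withSeed(seed, {
    for (b in seq_len(nPerm)) {
      ok <- FALSE
      for (try in 1:10) {
        idx <- sample.int(n)
        fit <- tryCatch({
          Wp1 <- estimator(pooled[idx[seq_len(n1)], , drop = FALSE])
          Wp2 <- estimator(pooled[idx[-seq_len(n1)], , drop = FALSE])
          list(Wp1, Wp2)
        }, error = function(e) NULL)
        if (!is.null(fit)) { ok <- TRUE; break }
      }
      if (!ok) stopf("network estimation failed on 10 consecutive redraws of permutation %d", b)
      d <- abs(upperTri(fit[[1]]) - upperTri(fit[[2]]))
      permEdge[b, ] <- d
      permM[b] <- max(d)
      permS[b] <- abs(globalStrength(fit[[1]]) - globalStrength(fit[[2]]))
      permCent$strength[b, ] <-
        abs(strengthCentrality(fit[[1]]) - strengthCentrality(fit[[2]]))
      permCent$expectedInfluence[b, ] <-
        abs(expectedInfluence(fit[[1]]) - expectedInfluence(fit[[2]]))
    }
  })
  addOneP <- function(perm, obs) (1 + sum(perm >= obs)) / (1 + length(perm))

  res <- list(M = obsM, pM = NA_real_, S = obsS, pS = NA_real_,
              centrality = NULL, postHocEdges = NULL,
              postHocCentrality = NULL, nPerm = nPerm, tests = tests,
              alpha = alpha, nodes = colnames(XA),
              weightsA = if (swapped) W2 else W1,
              weightsB = if (swapped) W1 else W2)
  if ("structure" %in% tests) {
    res$pM <- addOneP(permM, obsM)
    if (res$pM <= alpha) {
      en <- edgeNames(colnames(XA) %||% paste0("V", seq_len(p)))
      praw <- vapply(seq_len(nEdge), function(e)
        addOneP(permEdge[, e], edgeDiffObs[e]), 0)
      res$postHocEdges <- data.frame(
        edge = en, obsDiff = edgeDiffObs, p = praw,
        pAdj = p.adjust(praw, method = "holm"), stringsAsFactors = FALSE)
    }
  }
  if ("global_strength" %in% tests) res$pS <- addOneP(permS, obsS)
  if ("centrality" %in% tests) {
    metrics <- names(centObs)
    if (centralityMode == "omnibus") {
      stat <- vapply(metrics, function(m) max(centObs[[m]]), 0)
      pv <- vapply(metrics, function(m)
        addOneP(apply(permCent[[m]], 1, max), stat[m]), 0)
      res$centrality <- data.frame(metric = metrics, stat = stat, p = pv,
                                   stringsAsFactors = FALSE)
      sig <- metrics[pv <= alpha]
      if (length(sig)) {
        ph <- lapply(sig, function(m) {
          praw <- vapply(seq_len(p), function(i)
            addOneP(permCent[[m]][, i], centObs[[m]][i]), 0)
          data.frame(metric = m, node = colnames(XA),
                     obsDiff = unname(centObs[[m]]), p = praw,
                     pAdj = p.adjust(praw, method = "holm"),
                     stringsAsFactors = FALSE)
        })
        res$postHocCentrality <- do.call(rbind, ph)
      }
    } else {
      ph <- lapply(metrics, function(m) {
        praw <- vapply(seq_len(p), function(i)
          addOneP(permCent[[m]][, i], centObs[[m]][i]), 0)
        data.frame(metric = m, node = colnames(XA),
                   obsDiff = unname(centObs[[m]]), p = praw,
                   pAdj = p.adjust(praw, method = "holm"),
                   stringsAsFactors = FALSE)
      })
      res$postHocCentrality <- do.call(rbind, ph)
      res$centrality <- data.frame(
        metric = metrics,
        stat = vapply(metrics, function(m) max(centObs[[m]]), 0),
        p = NA_real_, stringsAsFactors = FALSE)
    }
  }
  structure(res, class = "nctResult")
}

#' @export
print.nctResult <- function(x, ...) {
  cat(sprintf("Network comparison test (%d permutations)\n", x$nPerm))
  if ("structure" %in% x$tests)
    cat(sprintf("  structure:       M = %.3f, p = %.3f\n", x$M, x$pM))
  if ("global_strength" %in% x$tests)
    cat(sprintf("  global strength: S = %.3f, p = %.3f\n", x$S, x$pS))
  if (!is.null(x$centrality) && !all(is.na(x$centrality$p)))
    for (i in seq_len(nrow(x$centrality)))
      cat(sprintf("  centrality (%s): max|diff| = %.3f, p = %.3f\n",
                  x$centrality$metric[i], x$centrality$stat[i],
                  x$centrality$p[i]))
  if (!is.null(x$postHocEdges))
    cat(sprintf("  post-hoc edges: %d tested, %d significant after Holm\n",
                nrow(x$postHocEdges), sum(x$postHocEdges$pAdj <= x$alpha)))
  invisible(x)
}
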