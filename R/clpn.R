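# Cross-Lagged Panel Network estimation: regularized support selection on
# wave-to-wave regressions, then non-regularized refits on the selected
# support.

# The temporal estimators accept either a panelData or a plain subject x
# item x wave numeric array (e.g. latent scores); this normalizes both.
panelWaveList <- function(data) {
  if (inherits(data, "panelData"))
    return(list(waves = data$waves,
                get = function(w) waveMatrix(data, w)))
  stopifnot(is.array(data), length(dim(data)) == 3)
  waves <- dimnames(data)[[3]] %||% paste0("T", seq_len(dim(data)[3]) - 1)
  list(waves = waves, get = function(w) {
    m <- data[, , match(w, waves), drop = FALSE]
    dim(m) <- dim(m)[1:2]
    dimnames(m) <- dimnames(data)[1:2]
    m
  })
}

# Complete-case, within-wave z-standardized predictor/outcome matrices for
# one interval. `interval` is either an index k (waves k -> k+1) or a pair
# of wave labels.
intervalMatrices <- function(data, interval) {
  pw <- panelWaveList(data)
  if (length(pw$waves) < 2) stopf("need at least 2 waves")
  wv <- if (is.numeric(interval)) {
    stopifnot(length(interval) == 1, interval >= 1,
              interval < length(pw$waves))
    pw$waves[c(interval, interval + 1)]
  } else {
    stopifnot(length(interval) == 2, all(interval %in% pw$waves))
    as.character(interval)
  }
  X0 <- pw$get(wv[1])
  X1 <- pw$get(wv[2])
  cc <- complete.cases(X0) & complete.cases(X1)
  if (sum(cc) < ncol(X0) + 2)
    stopf("too few complete cases (%d) for interval %s -> %s", sum(cc),
          wv[1], wv[2])
  list(X = zstandardize(X0[cc, , drop = FALSE]),
       Y = zstandardize(X1[cc, , drop = FALSE]),
       n = sum(cc), waves = wv)
}

#' LASSO support selection for one cross-lagged interval
#'
#' One LASSO regression per outcome item at wave t+1 on all items at wave
#' t (variables z-standardized within wave, complete cases for the
#' interval), with the penalty chosen at minimal 10-fold cross-validated
#' mean squared error under a fixed, seeded fold assignment shared across
#' outcomes.
#'
#' @param data A [panelData()] or a subject x item x wave numeric array.
#' @param interval Interval index (1 = first wave pair) or a pair of wave
#'   labels.
#' @param folds Number of CV folds.
#' @param seed Integer seed fixing the fold assignment.
#' @param lambdaRule `"min"` (default) keeps the penalty at minimal CV
#'   error, retaining many small paths (and, inevitably, false-positive
#'   connections); `"1se"` uses the conservative one-standard-error rule,
#'   appropriate when sparse support recovery matters more than
#'   sensitivity.
#' @param returnCoefs Also return the penalized coefficients themselves
#'   (attribute `"coefs"`), useful for comparing the biased LASSO weights
#'   against the two-step refit.
#' @return Logical p x p support matrix: entry `[j, i]` is `TRUE` when the
#'   path from item i at t to item j at t+1 is selected (diagonal =
#'   autoregressive paths).
#' @export
fitLassoStep <- function(data, interval = 1, folds = 10, seed = 1L,
                         lambdaRule = c("min", "1se"),
                         returnCoefs = FALSE) {
  lambdaRule <- match.arg(lambdaRule)
  im <- intervalMatrices(data, interval)
  if (im$n < folds)
    stopf("fewer complete cases (%d) than folds (%d)", im$n, folds)
  p <- ncol(im$X)
  foldid <- makeFolds(im$n, folds, seed)
  support <- matrix(FALSE, p, p,
                    dimnames = list(colnames(im$X), colnames(im$X)))
  coefs <- matrix(0, p, p, dimnames = dimnames(support))
  s <- paste0("lambda.", lambdaRule)
  for (j in seq_len(p)) {
    cvfit <- glmnet::cv.glmnet(im$X, im$Y[, j], foldid = foldid,
                               standardize = FALSE)
    b <- as.numeric(coef(cvfit, s = s))[-1]
    support[j, ] <- b != 0
    coefs[j, ] <- b
  }
  if (returnCoefs) attr(support, "coefs") <- coefs
  support
}

#' Non-regularized refit on a fixed support
#'
#' Per-outcome ordinary least squares restricted to the selected
#' predictors; paths outside the support are exactly zero. Coefficients,
#' standard errors and two-sided p-values are returned.
#'
#' @param data A [panelData()].
#' @param interval Interval index or pair of wave labels.
#' @param support Logical p x p matrix (rows = outcomes at t+1) from
#'   [fitLassoStep()] or user-supplied.
#' @return A `clpnNetwork`: list with `B` (coefficients, `B[j, i]` =
#'   effect of item i at t on item j at t+1; diagonal autoregressive),
#'   `se`, `pvals`, `support`, `r2` (per outcome), `interval`, `n`.
#' @export
refitSupport <- function(data, interval = 1, support) {
  im <- intervalMatrices(data, interval)
  p <- ncol(im$X)
  stopifnot(is.matrix(support), nrow(support) == p, ncol(support) == p)
  nodes <- colnames(im$X)
  B <- SE <- PV <- matrix(0, p, p, dimnames = list(nodes, nodes))
  PV[] <- NA_real_
  r2 <- setNames(numeric(p), nodes)
  for (j in seq_len(p)) {
    sel <- which(support[j, ])
    y <- im$Y[, j]
    if (!length(sel)) { r2[j] <- 0; next }
    Xj <- im$X[, sel, drop = FALSE]
    if (qr(cbind(1, Xj))$rank < length(sel) + 1)
      stopf("rank-deficient restricted design for outcome %s", nodes[j])
    fit <- lm(y ~ Xj)
    sm <- summary(fit)
    B[j, sel] <- coef(fit)[-1]
    SE[j, sel] <- sm$coefficients[-1, "Std. Error"]
    PV[j, sel] <- sm$coefficients[-1, "Pr(>|t|)"]
    r2[j] <- sm$r.squared
  }
  structure(list(B = B, se = SE, pvals = PV, support = support != 0,
                 r2 = r2, interval = im$waves, n = im$n, nodes = nodes),
            class = "clpnNetwork")
}

#' @export
print.clpnNetwork <- function(x, ...) {
  p <- ncol(x$B)
  nCross <- sum(x$B[row(x$B) != col(x$B)] != 0)
  cat(sprintf("clpnNetwork %s -> %s: %d nodes, %d cross-lagged paths, %d autoregressive (n = %d)\n",
              x$interval[1], x$interval[2], p, nCross,
              sum(diag(x$B) != 0), x$n))
  cat(sprintf("  mean |autoregressive| = %.2f\n", mean(abs(diag(x$B)))))
  invisible(x)
}

#' In- and out-prediction of a cross-lagged network
#'
#' In-prediction of an item is the share of its variance at t+1 explained
#' by the *other* items at t beyond its own autoregression: the R-squared
#' of the full supported regression minus the R-squared of the
#' autoregressive-only refit. Out-prediction of an item is the mean (over
#' the other items) drop in R-squared when its outgoing path is removed
#' and the outcome model refit. Both are clipped to [0, 1].
#'
#' @param net A `clpnNetwork` from [refitSupport()].
#' @param data The [panelData()] the network was fit on.
#' @return Data frame: `node`, `inPrediction`, `outPrediction`.
#' @export
predictionIndices <- function(net, data) {
  im <- intervalMatrices(data, net$interval)
  p <- ncol(im$X)
  support <- net$support
  r2sub <- function(j, sel) {
    if (!length(sel)) return(0)
    fit <- lm(im$Y[, j] ~ im$X[, sel, drop = FALSE])
    summary(fit)$r.squared
  }
  r2full <- vapply(seq_len(p), function(j) r2sub(j, which(support[j, ])), 0)
  inPred <- vapply(seq_len(p), function(j) {
    arSel <- intersect(j, which(support[j, ]))
    max(0, min(1, r2full[j] - r2sub(j, arSel)))
  }, 0)
  outPred <- vapply(seq_len(p), function(i) {
    drops <- vapply(setdiff(seq_len(p), i), function(j) {
      sel <- which(support[j, ])
      if (!(i %in% sel)) return(0)
      r2full[j] - r2sub(j, setdiff(sel, i))
    }, 0)
    max(0, min(1, mean(drops)))
  }, 0)
  data.frame(node = net$nodes, inPrediction = inPred,
             outPrediction = outPred, stringsAsFactors = FALSE)
}

directedEdges <- function(B, includeAutoregressive = FALSE) {
  keep <- B != 0
  if (!includeAutoregressive) diag(keep) <- FALSE
  keep
}

#' Similarity of two directed networks
#'
#' Jaccard index of edge presence and Pearson correlation of edge weights
#' over the union of non-zero edges (edges absent from one network
#' contribute weight 0 there), with a two-sided p-value from the t
#' distribution on |union| - 2 degrees of freedom. Autoregressive
#' (diagonal) paths are excluded by default.
#'
#' @param netA,netB `clpnNetwork` objects or coefficient matrices with the
#'   same node set.
#' @param includeAutoregressive Include diagonal paths in the comparison.
#' @return A `similarityResult`: list with `jaccard`, `r`, `p`,
#'   `nIntersection`, `nUnion`.
#' @export
compareDirected <- function(netA, netB, includeAutoregressive = FALSE) {
  BA <- if (inherits(netA, "clpnNetwork")) netA$B else as.matrix(netA)
  BB <- if (inherits(netB, "clpnNetwork")) netB$B else as.matrix(netB)
  if (!all(dim(BA) == dim(BB)))
    stopf("networks must share the same node set")
  EA <- directedEdges(BA, includeAutoregressive)
  EB <- directedEdges(BB, includeAutoregressive)
  uni <- EA | EB
  if (!any(uni)) stopf("both edge sets are empty; Jaccard index undefined")
  ji <- sum(EA & EB) / sum(uni)
  wA <- BA[uni]
  wB <- BB[uni]
  m <- sum(uni)
  if (m >= 3 && sd(wA) > 0 && sd(wB) > 0) {
    r <- cor(wA, wB)
    tt <- r * sqrt((m - 2) / max(1 - r^2, .Machine$double.eps))
    pv <- 2 * pt(-abs(tt), df = m - 2)
  } else {
    r <- if (m >= 2 && sd(wA) > 0 && sd(wB) > 0) cor(wA, wB) else NA_real_
    pv <- NA_real_
  }
  structure(list(jaccard = ji, r = r, p = pv, nIntersection = sum(EA & EB),
                 nUnion = m, includeAutoregressive = includeAutoregressive),
            class = "similarityResult")
}

#' @export
print.similarityResult <- function(x, ...) {
  cat(sprintf("similarityResult: JI = %.3f (%d/%d edges shared), r = %.3f (p = %.3g)\n",
              x$jaccard, x$nIntersection, x$nUnion, x$r, x$p))
  invisible(x)
}

#' Directed network edge list
#' @param net A `clpnNetwork`.
#' @param dropZero Omit zero paths.
#' @return data.frame `from`, `to`, `weight`, `se`, `p`.
#' @export
directedEdgeList <- function(net, dropZero = TRUE) {
  stopifnot(inherits(net, "clpnNetwork"))
  out <- do.call(rbind, lapply(seq_along(net$nodes), function(j) {
    data.frame(from = net$nodes, to = net$nodes[j], weight = net$B[j, ],
               se = net$se[j, ], p = net$pvals[j, ],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (dropZero) out <- out[out$weight != 0, , drop = FALSE]
  out
}
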