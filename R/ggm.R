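#' Spearman correlation matrix at one wave
#'
#' Pairwise-complete Spearman rank correlations (average ranks for ties)
#' over the items of a panel at one wave. If the resulting matrix is not
#' positive semi-definite it is repaired by clipping eigenvalues at 1e-8
#' and rescaling to unit diagonal; the repair is flagged.
#'
#' @param data A [panelData()] or a numeric subject x item matrix.
#' @param wave Wave label (ignored for matrix input).
#' @return A `corMatrix`: list with `R`, `n` (subjects), `repaired`.
#' @export
spearmanMatrix <- function(data, wave = NULL) {
  X <- if (inherits(data, "panelData")) waveMatrix(data, wave) else
    as.matrix(data)
  p <- ncol(X)
  constant <- vapply(seq_len(p), function(j) {
    v <- X[, j][!is.na(X[, j])]
    length(unique(v)) <= 1
  }, TRUE)
  if (any(constant))
    stopf("constant item(s) (zero rank variance): %s",
          paste(colnames(X)[constant], collapse = ", "))
  nPair <- crossprod(!is.na(X))
  if (any(nPair < 3))
    stopf("fewer than 3 complete observations for some item pair")
  R <- if (anyNA(X))
    cor(X, method = "spearman", use = "pairwise.complete.obs")
  else  # complete data: rank once, then Pearson (identical, much faster)
    cor(vapply(seq_len(p), function(j) rank(X[, j]), numeric(nrow(X))))
  if (!anyNA(X)) dimnames(R) <- list(colnames(X), colnames(X))
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 0) {
    vals <- pmax(ev$values, 1e-8)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    R <- stats::cov2cor(R)
    dimnames(R) <- list(colnames(X), colnames(X))
    repaired <- TRUE
  }
  structure(list(R = R, n = nrow(X), repaired = repaired),
            class = "corMatrix")
}

asCorMatrix <- function(R, n = NULL) {
  if (inherits(R, "corMatrix")) return(R)
  structure(list(R = as.matrix(R), n = n, repaired = FALSE),
            class = "corMatrix")
}

#' Graphical lasso at a fixed penalty
#'
#' Maximizes \eqn{\log\det\Theta - tr(R\Theta) - \lambda\sum_{i\ne j}
#' |\Theta_{ij}|} (off-diagonal penalty only) by block coordinate descent.
#'
#' @param R A `corMatrix` from [spearmanMatrix()] or a PD symmetric matrix.
#' @param lambda Penalty, >= 0.
#' @param maxit,tol Outer iteration cap and convergence threshold on the
#'   working covariance.
#' @param kktTol Solutions must satisfy the stationarity (KKT) conditions
#'   to this residual; otherwise an error reports the residual.
#' @return List with `Theta` (precision estimate), `W` (its inverse),
#'   `lambda`, `iterations`, `kkt` (residual).
#' @export
glassoFit <- function(R, lambda, maxit = 500, tol = 1e-9, kktTol = 1e-5) {
  cm <- asCorMatrix(R)
  stopifnot(lambda >= 0)
  fit <- glasso_cpp(cm$R, lambda, maxit = maxit, tol = tol)
  kkt <- kktResidual(fit$Theta, cm$R, lambda)
  if (kkt > kktTol)
    stopf("graphical lasso did not converge (KKT residual %.2e > %.0e at lambda = %.4g)",
          kkt, kktTol, lambda)
  dimnames(fit$Theta) <- dimnames(cm$R)
  list(Theta = fit$Theta, W = fit$W, lambda = lambda,
       iterations = fit$iterations, kkt = kkt)
}

#' KKT stationarity residual of a graphical lasso solution
#'
#' For the off-diagonal-penalized problem the optimum satisfies
#' \eqn{\Theta^{-1} = R + \lambda\Gamma} with \eqn{\Gamma_{ij} \in
#' \partial|\Theta_{ij}|}, \eqn{\Gamma_{ii} = 0}. Returns the maximum
#' violation of these conditions.
#'
#' @param Theta Precision estimate.
#' @param R Input matrix.
#' @param lambda Penalty.
#' @return Non-negative scalar residual.
#' @export
kktResidual <- function(Theta, R, lambda) {
  W <- solve(Theta)
  D <- W - R
  p <- nrow(R)
  resid <- max(abs(diag(D)))
  off <- upper.tri(D)
  nz <- off & Theta != 0
  z <- off & Theta == 0
  if (any(nz))
    resid <- max(resid, max(abs(D[nz] - lambda * sign(Theta[nz]))))
  if (any(z))
    resid <- max(resid, max(pmax(0, abs(D[z]) - lambda)))
  resid
}

#' Precision matrix to partial correlations
#'
#' \eqn{\rho_{ij} = -\Theta_{ij} / \sqrt{\Theta_{ii}\Theta_{jj}}}, zero
#' diagonal.
#'
#' @param Theta Positive-definite precision matrix.
#' @return Symmetric partial-correlation matrix.
#' @export
precisionToPcor <- function(Theta) {
  d <- diag(Theta)
  if (any(d <= 0)) stopf("non-positive diagonal in precision matrix")
  P <- -Theta / sqrt(outer(d, d))
  diag(P) <- 0
  P
}

#' EBIC graphical lasso network selection
#'
#' Fits the graphical lasso along a log-spaced penalty path from
#' \eqn{\lambda_{max}} (= max off-diagonal |R|) down to
#' \eqn{\lambda_{max}\cdot ratio} and selects the penalty minimizing the
#' extended BIC \eqn{-2\ell(\hat\Theta) + E\log n + 4E\gamma\log p}, where
#' \eqn{\ell} is the Gaussian log-likelihood (see `likelihood` for where it
#' is evaluated) and \eqn{E} the number of selected (upper-triangle) edges.
#'
#' @param R A `corMatrix` or symmetric matrix.
#' @param n Sample size (taken from the `corMatrix` when present).
#' @param gamma EBIC hyperparameter; 0.5 by default (conservative).
#' @param nLambda Grid size.
#' @param lambdaMinRatio Smallest penalty as a fraction of
#'   \eqn{\lambda_{max}}.
#' @param likelihood Where the EBIC likelihood is evaluated: `"refit"`
#'   (default) uses the unpenalized MLE restricted to each candidate
#'   support, the convention under which EBIC model selection is
#'   consistent; `"penalized"` evaluates it at the shrunk estimate
#'   itself, which over-selects at large n because the shrinkage bias on
#'   strong edges keeps shrinking along the path.
#' @return A `ggmNetwork`: list with `weights` (partial-correlation matrix
#'   of the selected penalized model), `lambda`, `gamma`, `ebic`,
#'   `lambdas`, `nEdges` (per grid point), `n`.
#' @export
ebicGlasso <- function(R, n = NULL, gamma = 0.5, nLambda = 100,
                       lambdaMinRatio = 0.01,
                       likelihood = c("refit", "penalized")) {
  likelihood <- match.arg(likelihood)
  cm <- asCorMatrix(R, n)
  n <- n %||% cm$n
  if (is.null(n)) stopf("sample size n required")
  S <- cm$R
  p <- ncol(S)
  if (n <= p) warnf("n (%d) <= p (%d): network estimation may be unstable", n, p)
  lmax <- max(abs(S[upper.tri(S)]))
  if (!is.finite(lmax) || lmax <= 0) stopf("empty penalty grid (no off-diagonal signal)")
  lambdas <- exp(seq(log(lmax), log(lmax * lambdaMinRatio),
                     length.out = nLambda))
  path <- glasso_path_cpp(S, lambdas)
  E <- numeric(nLambda)
  ll2 <- numeric(nLambda)  # 2 * loglik up to constants
  supKey <- character(nLambda)
  for (k in seq_len(nLambda)) {
    Th <- path$Thetas[, , k]
    nz <- which(Th[upper.tri(Th)] != 0)
    E[k] <- length(nz)
    supKey[k] <- paste0("s", paste(nz, collapse = ","))
    if (likelihood == "penalized")
      ll2[k] <- n * (ldet(Th) - sum(S * Th))
  }
  if (likelihood == "refit") {
    refitLl <- new.env()
    for (k in seq_len(nLambda)) {
      key <- supKey[k]
      if (is.null(refitLl[[key]])) {
        sup <- matrix(0L, p, p)
        sup[upper.tri(sup)][as.integer(strsplit(substring(key, 2), ",")[[1]])] <- 1L
        sup <- sup + t(sup)
        fit <- glasso_restricted_cpp(S, sup)
        refitLl[[key]] <- n * (ldet(fit$Theta) - sum(S * fit$Theta))
      }
      ll2[k] <- refitLl[[key]]
    }
  }
  ebic <- -ll2 + E * log(n) + 4 * E * gamma * log(p)
  # under the refit likelihood every lambda sharing a support ties exactly;
  # take the smallest such lambda so reported weights are least shrunk
  best <- max(which(ebic == min(ebic)))
  Theta <- path$Thetas[, , best]
  dimnames(Theta) <- dimnames(S)
  W <- precisionToPcor(Theta)
  structure(list(weights = W, Theta = Theta, lambda = lambdas[best],
                 gamma = gamma, ebic = ebic, lambdas = lambdas,
                 nEdges = E, n = n, repaired = cm$repaired,
                 likelihood = likelihood),
            class = "ggmNetwork")
}

#' Estimate a cross-sectional symptom network
#'
#' Convenience wrapper: Spearman correlations at one wave, then
#' [ebicGlasso()].
#'
#' @param data A [panelData()] or subject x item matrix.
#' @param wave Wave label (for panel input).
#' @param ... Passed to [ebicGlasso()].
#' @return A `ggmNetwork`.
#' @export
estimateGGM <- function(data, wave = NULL, ...) {
  cm <- spearmanMatrix(data, wave)
  ebicGlasso(cm, ...)
}

#' A reusable network-estimation recipe
#'
#' Returns a deterministic function mapping a subject x item matrix to a
#' partial-correlation weight matrix, for use with [bootstrapEdges()],
#' [caseDropCS()] and [nctTest()].
#'
#' @param gamma,nLambda,lambdaMinRatio,likelihood Passed to [ebicGlasso()].
#' @return A function `X -> weight matrix`.
#' @export
ggmEstimator <- function(gamma = 0.5, nLambda = 100, lambdaMinRatio = 0.01,
                         likelihood = "refit") {
  force(gamma); force(nLambda); force(lambdaMinRatio); force(likelihood)
  function(X) {
    net <- ebicGlasso(spearmanMatrix(X), gamma = gamma, nLambda = nLambda,
                      lambdaMinRatio = lambdaMinRatio,
                      likelihood = likelihood)
    net$weights
  }
}

#' @export
print.ggmNetwork <- function(x, ...) {
  p <- ncol(x$weights)
  E <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("ggmNetwork: %d nodes, %d edges (lambda = %.4f, gamma = %.2f, n = %d)\n",
              p, E, x$lambda, x$gamma, x$n))
  cat(sprintf("  global strength = %.3f\n", globalStrength(x)))
  invisible(x)
}

netWeights <- function(net) {
  if (inherits(net, "ggmNetwork")) net$weights
  else if (inherits(net, "mixedNetwork")) net$weights
  else as.matrix(net)
}

#' Strength centrality
#'
#' Per-node sum of absolute incident edge weights.
#' @param net A `ggmNetwork`, `mixedNetwork` or symmetric weight matrix.
#' @return Named numeric vector.
#' @export
strengthCentrality <- function(net) {
  W <- netWeights(net)
  rowSums(abs(W))
}

#' One-step expected influence
#'
#' Per-node signed sum of incident edge weights: positive edges add,
#' negative edges subtract.
#' @inheritParams strengthCentrality
#' @return Named numeric vector.
#' @export
expectedInfluence <- function(net) {
  W <- netWeights(net)
  rowSums(W)
}

#' Strength and expected-influence table
#'
#' @inheritParams strengthCentrality
#' @param zscore Also include z-scored columns.
#' @return A data.frame with one row per node.
#' @export
centralityTable <- function(net, zscore = TRUE) {
  s <- strengthCentrality(net)
  ei <- expectedInfluence(net)
  out <- data.frame(node = names(s) %||% seq_along(s), strength = unname(s),
                    expectedInfluence = unname(ei),
                    stringsAsFactors = FALSE)
  if (zscore) {
    zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
    out$strength.z <- zs(out$strength)
    out$expectedInfluence.z <- zs(out$expectedInfluence)
  }
  out
}

#' Global strength of a network
#'
#' Sum of absolute weights over unique (upper-triangle) edges.
#' @inheritParams strengthCentrality
#' @return Scalar.
#' @export
globalStrength <- function(net) {
  W <- netWeights(net)
  sum(abs(W[upper.tri(W)]))
}

#' Edge list of a symmetric network
#' @inheritParams strengthCentrality
#' @param dropZero Omit zero-weight pairs.
#' @return data.frame with `node_i`, `node_j`, `weight`.
#' @export
asEdgeList <- function(net, dropZero = TRUE) {
  W <- netWeights(net)
  nodes <- colnames(W) %||% paste0("V", seq_len(ncol(W)))
  idx <- which(upper.tri(W), arr.ind = TRUE)
  out <- data.frame(node_i = nodes[idx[, 1]], node_j = nodes[idx[, 2]],
                    weight = W[idx], stringsAsFactors = FALSE)
  if (dropZero) out <- out[out$weight != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
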