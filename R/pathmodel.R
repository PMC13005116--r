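# Gaussian path model for the three-wave cross-lagged design, fit by
# maximum likelihood. The model factorizes recursively:
#   X0 ~ N(0, Phi)                      (covariance free)
#   X1 = B1 X0 + e1,   e1 ~ N(0, Psi1) (Psi1 free, B1 support-restricted)
#   X2 = B2 X1 + C X0 + e2             (Psi2 free; C = optional lag-2 block)
# so the discrepancy F_ML decomposes into independent terms, each a
# restricted multivariate ("seemingly unrelated") regression with free
# residual covariance, solved by iterated feasible GLS. The fully free
# model (all lag-1 and lag-2 paths) is saturated: F_ML = 0, df = 0.

# One ML term: outcomes Y on predictors Z with per-cell free/zero map.
# Czz, Czy, Syy are the relevant blocks of the sample covariance; map is a
# q x p integer matrix giving the global parameter index of each (local
# predictor, outcome) coefficient, 0 = fixed at zero.
mlSurTerms <- function(terms, nFree, maxit = 500, ftol = 1e-12) {
  if (nFree == 0) {
    G <- lapply(terms, function(tm) tm$Syy)
    return(list(theta = numeric(0), G = G,
                value = sum(vapply(G, ldet, 0)), iterations = 0))
  }
  Psi <- lapply(terms, function(tm) diag(ncol(tm$Syy)))
  valOld <- Inf
  theta <- numeric(nFree)
  for (it in seq_len(maxit)) {
    A <- matrix(0, nFree, nFree)
    rhs <- numeric(nFree)
    for (tm in terms) {
      Pinv <- chol2inv(chol(Psi[[tm$id]]))
      sel <- which(tm$map != 0)          # column-major (a, j) order
      gi <- tm$map[sel]
      K <- kronecker(Pinv, tm$Czz)       # [(j-1)q + a, (k-1)q + b]
      A[gi, gi] <- A[gi, gi] + K[sel, sel]
      R <- tm$Czy %*% Pinv               # rhs[a, j]
      rhs[gi] <- rhs[gi] + R[sel]
    }
    theta <- solve(A, rhs)
    val <- 0
    G <- vector("list", length(terms))
    for (tm in terms) {
      Bloc <- matrix(0, nrow(tm$map), ncol(tm$map))
      Bloc[tm$map != 0] <- theta[tm$map[tm$map != 0]]
      Gt <- tm$Syy - t(Bloc) %*% tm$Czy - t(tm$Czy) %*% Bloc +
        t(Bloc) %*% tm$Czz %*% Bloc
      Gt <- (Gt + t(Gt)) / 2
      Psi[[tm$id]] <- Gt
      G[[tm$id]] <- Gt
      val <- val + ldet(Gt)
    }
    if (abs(valOld - val) < ftol) break
    valOld <- val
  }
  list(theta = theta, G = G, value = val, iterations = it)
}

ldet <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)

#' Fit the three-wave cross-lagged path model
#'
#' Maximum-likelihood covariance-structure fit of the cross-lagged panel
#' model over three equally spaced waves (variables z-standardized within
#' wave, complete cases across all waves): first-wave covariances free,
#' wave-to-wave regressions restricted to the given supports, same-wave
#' residual covariances free. With `constrained = TRUE` the two lag-1
#' coefficient matrices are constrained equal on the union of the two
#' supports. An optional lag-2 (first to third wave) support block is
#' available; with all lag-1 and lag-2 paths free the model is saturated
#' (chi-square 0 on 0 degrees of freedom).
#'
#' @param data A [panelData()] with at least three waves, or a subject x
#'   item x wave numeric array (e.g. latent scores).
#' @param supports List of two logical p x p matrices (rows = outcome at
#'   t+1) selecting lag-1 paths per interval, e.g. from [fitLassoStep()].
#' @param constrained Impose equality of the two interval coefficient
#'   matrices (union support, pooled values).
#' @param lag2Support Optional logical p x p matrix of first-to-third-wave
#'   paths; default none (the cross-lagged panel restriction).
#' @param waves Three wave labels; defaults to the panel's first three.
#' @param standardize Z-standardize the variables within wave before
#'   fitting. Off by default: the model is fit on the covariance (raw,
#'   centered) scale, because cross-time equality constraints are not
#'   invariant to per-wave rescaling, and analyzing standardized data as
#'   if it were raw distorts the chi-square of constrained models. Enable
#'   only for unconstrained descriptive fits on a standardized scale.
#' @return A `clpnModel`: list with `B` (list of the two fitted interval
#'   matrices), `lag2`, `fit` (chi-square, df, p, RMSEA with 90% CI,
#'   CFI, TLI, log-likelihood, n), `constrained`, `supports`, `nFree`.
#' @export
fitPathModel <- function(data, supports, constrained = FALSE,
                         lag2Support = NULL, waves = NULL,
                         standardize = FALSE) {
  pw <- panelWaveList(data)
  waves <- waves %||% pw$waves[1:3]
  if (length(waves) != 3 || !all(waves %in% pw$waves))
    stopf("need three waves present in the panel")
  X <- lapply(waves, pw$get)
  cc <- Reduce(`&`, lapply(X, complete.cases))
  n <- sum(cc)
  p <- ncol(X[[1]])
  if (n < 3 * p) warnf("only %d complete cases for a %d-variable model", n, p)
  Z <- lapply(X, function(x) {
    x <- x[cc, , drop = FALSE]
    if (standardize) zstandardize(x) else scale(x, scale = FALSE)
  })
  nodes <- colnames(Z[[1]])
  stopifnot(is.list(supports), length(supports) == 2)
  supports <- lapply(supports, function(s) {
    stopifnot(is.matrix(s), nrow(s) == p, ncol(s) == p)
    s != 0
  })
  if (is.null(lag2Support)) lag2Support <- matrix(FALSE, p, p)
  lag2Support <- lag2Support != 0

  S <- cov(do.call(cbind, Z))
  i0 <- seq_len(p); i1 <- p + i0; i2 <- 2 * p + i0

  # global parameter numbering
  if (constrained) {
    uni <- supports[[1]] | supports[[2]]
    nB <- sum(uni)
    bIndex <- matrix(0L, p, p)
    bIndex[uni] <- seq_len(nB)
    nC <- sum(lag2Support)
    cIndex <- matrix(0L, p, p)
    cIndex[lag2Support] <- nB + seq_len(nC)
    nFree <- nB + nC
    # term 1: X1 on X0; map[a, j] = coef of predictor a for outcome j
    map1 <- t(bIndex)
    # term 2: X2 on (X1, X0)
    map2 <- rbind(t(bIndex), t(cIndex))
    terms <- list(
      list(id = 1L, Czz = S[i0, i0], Czy = S[i0, i1], Syy = S[i1, i1],
           map = map1),
      list(id = 2L, Czz = S[c(i1, i0), c(i1, i0)],
           Czy = S[c(i1, i0), i2], Syy = S[i2, i2], map = map2))
    fitted <- mlSurTerms(terms, nFree)
    B1 <- matrix(0, p, p, dimnames = list(nodes, nodes))
    B1[uni] <- fitted$theta[bIndex[uni]]
    B2 <- B1
    C <- matrix(0, p, p, dimnames = list(nodes, nodes))
    if (nC) C[lag2Support] <- fitted$theta[cIndex[lag2Support]]
    nPaths <- nB + nC
  } else {
    n1 <- sum(supports[[1]])
    b1Index <- matrix(0L, p, p)
    b1Index[supports[[1]]] <- seq_len(n1)
    n2 <- sum(supports[[2]])
    b2Index <- matrix(0L, p, p)
    b2Index[supports[[2]]] <- n1 + seq_len(n2)
    nC <- sum(lag2Support)
    cIndex <- matrix(0L, p, p)
    cIndex[lag2Support] <- n1 + n2 + seq_len(nC)
    nFree <- n1 + n2 + nC
    terms <- list(
      list(id = 1L, Czz = S[i0, i0], Czy = S[i0, i1], Syy = S[i1, i1],
           map = t(b1Index)),
      list(id = 2L, Czz = S[c(i1, i0), c(i1, i0)],
           Czy = S[c(i1, i0), i2], Syy = S[i2, i2],
           map = rbind(t(b2Index), t(cIndex))))
    fitted <- mlSurTerms(terms, nFree)
    B1 <- matrix(0, p, p, dimnames = list(nodes, nodes))
    B1[supports[[1]]] <- fitted$theta[b1Index[supports[[1]]]]
    B2 <- matrix(0, p, p, dimnames = list(nodes, nodes))
    B2[supports[[2]]] <- fitted$theta[b2Index[supports[[2]]]]
    C <- matrix(0, p, p, dimnames = list(nodes, nodes))
    if (nC) C[lag2Support] <- fitted$theta[cIndex[lag2Support]]
    nPaths <- nFree
  }

  q <- 3 * p
  Fml <- ldet(S[i0, i0]) + fitted$value - ldet(S)
  Fml <- max(Fml, 0)
  freeParams <- 3 * p * (p + 1) / 2 + nPaths
  df <- q * (q + 1) / 2 - freeParams
  if (df < 0) stopf("negative degrees of freedom (%d): model over-parameterized", df)
  fit <- fitStatsFromF(Fml, df, n, S)
  structure(list(B = list(B1, B2), lag2 = C, constrained = constrained,
                 supports = supports, lag2Support = lag2Support,
                 fit = fit, n = n, waves = waves, nodes = nodes,
                 nFree = nPaths, iterations = fitted$iterations),
            class = "clpnModel")
}

# chi-square, RMSEA (with 90% noncentrality-inversion CI), CFI/TLI against
# the independence baseline, from the minimized ML discrepancy.
fitStatsFromF <- function(Fml, df, n, S) {
  q <- ncol(S)
  chisq <- (n - 1) * Fml
  pval <- if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else
    as.numeric(chisq <= 1e-8)
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * (n - 1))) else 0
  ci <- c(0, 0)
  if (df > 0) {
    pAt <- function(l) pchisq(chisq, df, ncp = l)
    searchNcp <- function(target) {  # pAt is decreasing in the ncp
      if (pAt(0) <= target) return(0)
      ub <- max(chisq * 2, df, 10)
      while (pAt(ub) > target && ub < 1e9) ub <- ub * 2
      uniroot(function(l) pAt(l) - target, c(0, ub))$root
    }
    ci <- sqrt(c(searchNcp(0.95), searchNcp(0.05)) / (df * (n - 1)))
  }
  Fb <- -ldet(stats::cov2cor(S))  # independence baseline on unit variances
  chisqB <- (n - 1) * Fb
  dfB <- q * (q + 1) / 2 - q
  cfi <- 1 - max(chisq - df, 0) / max(chisqB - dfB, chisq - df, 0)
  tli <- if (df > 0) ((chisqB / dfB) - (chisq / df)) / ((chisqB / dfB) - 1)
  else NA_real_
  ll <- -(n - 1) / 2 * (ldet(S) + Fml + q + q * log(2 * pi))
  list(chisq = chisq, df = df, p = pval, rmsea = rmsea,
       rmsea.ci = ci, cfi = cfi, tli = tli, logLik = ll, n = n)
}

#' @export
print.clpnModel <- function(x, ...) {
  f <- x$fit
  cat(sprintf("clpnModel (%s): %d free paths, n = %d\n",
              if (x$constrained) "constrained" else "unconstrained",
              x$nFree, x$n))
  cat(sprintf("  chi-square(df = %d) = %.2f, p = %.3g\n", f$df, f$chisq, f$p))
  cat(sprintf("  RMSEA = %.3f (%.3f, %.3f); CFI = %.3f, TLI = %.3f\n",
              f$rmsea, f$rmsea.ci[1], f$rmsea.ci[2], f$cfi, f$tli))
  invisible(x)
}

#' Nested chi-square difference test for temporal constraints
#'
#' Compares the unconstrained cross-lagged model against the model with
#' cross-time equality constraints. The constrained model is kept
#' (parsimony) when the test is non-significant.
#'
#' @param unconstrained,constrained `clpnModel` fits on the same data.
#' @return List: `dChisq`, `dDf`, `p`, `keepConstrained` (at the 0.05
#'   level).
#' @export
chi2Difference <- function(unconstrained, constrained) {
  stopifnot(inherits(unconstrained, "clpnModel"),
            inherits(constrained, "clpnModel"))
  if (unconstrained$n != constrained$n)
    stopf("models were fit on different sample sizes")
  dChisq <- constrained$fit$chisq - unconstrained$fit$chisq
  dDf <- constrained$fit$df - unconstrained$fit$df
  if (dDf < 0) stopf("models are not nested (df difference %d < 0)", dDf)
  if (dDf == 0) {
    if (abs(dChisq) > 1e-6)
      stopf("models are not nested (df difference 0 but chi-square differs)")
    return(list(dChisq = 0, dDf = 0L, p = 1, keepConstrained = TRUE))
  }
  p <- pchisq(max(dChisq, 0), dDf, lower.tail = FALSE)
  list(dChisq = dChisq, dDf = as.integer(dDf), p = p,
       keepConstrained = p >= 0.05)
}

#' Two-step cross-lagged panel network analysis
#'
#' The full temporal workflow for one group: LASSO support selection per
#' interval ([fitLassoStep()]), non-regularized refits ([refitSupport()]),
#' unconstrained and constrained path-model fits with the nested
#' chi-square constraint test, and in-/out-prediction indices.
#'
#' @param data A [panelData()] with (at least) three waves.
#' @param folds CV folds for the LASSO step.
#' @param seed Integer seed (fold assignment).
#' @param waves Three wave labels (defaults to the first three).
#' @return A list with `supports`, `networks` (refit `clpnNetwork` per
#'   interval), `unconstrained`, `constrained` (`clpnModel`s),
#'   `constraintTest`, and `prediction` (per-interval index tables).
#' @export
fitCLPN <- function(data, folds = 10, seed = 1L, waves = NULL) {
  waves <- waves %||% data$waves[1:3]
  sub <- data
  ints <- list(waves[1:2], waves[2:3])
  supports <- lapply(seq_along(ints), function(k)
    fitLassoStep(sub, interval = ints[[k]], folds = folds,
                 seed = childSeed(seed, paste0("lasso", k))))
  networks <- lapply(seq_along(ints), function(k)
    refitSupport(sub, interval = ints[[k]], support = supports[[k]]))
  unconstrained <- fitPathModel(sub, supports, constrained = FALSE,
                                waves = waves)
  constrained <- fitPathModel(sub, supports, constrained = TRUE,
                              waves = waves)
  test <- chi2Difference(unconstrained, constrained)
  prediction <- lapply(networks, predictionIndices, data = sub)
  list(supports = supports, networks = networks,
       unconstrained = unconstrained, constrained = constrained,
       constraintTest = test, prediction = prediction, waves = waves)
}
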