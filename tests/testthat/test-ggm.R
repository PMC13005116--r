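test_that("Spearman matrix matches hand-computed rank correlations", {
  X <- cbind(a = c(1, 2, 3), b = c(3, 1, 2), c = c(1, 2, 4))
  cm <- spearmanMatrix(X)
  expect_equal(cm$R["a", "b"], -0.5)   # ranks (1,2,3) vs (3,1,2), sum d^2 = 6
  expect_equal(cm$R["a", "c"], 1)      # strictly monotone pair
  expect_equal(diag(cm$R), c(a = 1, b = 1, c = 1))
  expect_error(spearmanMatrix(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "constant item")
})

test_that("pairwise-complete Spearman handles missing cells and repairs non-PD", {
  set.seed(1)
  X <- matrix(sample(1:7, 200, TRUE), 40, 5)
  X[sample(length(X), 30)] <- NA
  cm <- spearmanMatrix(X)
  ref <- cor(X, method = "spearman", use = "pairwise.complete.obs")
  expect_equal(unname(cm$R), unname(ref),
               tolerance = if (cm$repaired) 0.05 else 1e-12)
  ev <- eigen(cm$R, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
})

test_that("graphical lasso satisfies KKT conditions across random problems and penalties", {
  set.seed(7)
  for (rep in 1:5) {
    p <- sample(5:10, 1)
    A <- matrix(rnorm(p * p), p)
    S <- cov2cor(crossprod(A) / p + diag(p) * 0.5)
    lmax <- max(abs(S[upper.tri(S)]))
    for (lam in lmax * c(0.9, 0.5, 0.2, 0.05)) {
      fit <- glassoFit(S, lam)
      expect_lte(fit$kkt, 1e-5)
      ev <- eigen(fit$Theta, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), 0)
    }
    # lam = 0: unpenalized MLE equals the matrix inverse
    expect_lt(max(abs(glassoFit(S, 0)$Theta - solve(S))), 1e-6)
    # full shrinkage: lam >= max off-diagonal gives a diagonal estimate
    fitD <- glassoFit(S, lmax + 0.01)
    expect_equal(sum(fitD$Theta[upper.tri(fitD$Theta)] != 0), 0)
  }
})

test_that("precision-to-partial-correlation transform is exact", {
  expect_equal(precisionToPcor(diag(3)), matrix(0, 3, 3))
  Th <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(precisionToPcor(Th)[1, 2], 0.5)
  expect_error(precisionToPcor(matrix(c(-1, 0, 0, 1), 2)), "diagonal")
  # 3-node case equals the residual correlation controlling the third node
  set.seed(11)
  X <- matrix(rnorm(4000 * 3), ncol = 3) %*% chol(solve(chainTheta(3, -0.35)))
  S <- cov(X)
  pc <- precisionToPcor(solve(S))
  r12.3 <- cor(resid(lm(X[, 1] ~ X[, 3])), resid(lm(X[, 2] ~ X[, 3])))
  expect_equal(pc[1, 2], r12.3, tolerance = 1e-10)
})

test_that("lasso path sparsity is monotone in the penalty", {
  set.seed(3)
  X <- rmvnPrec(400, chainTheta(7), seed = 3)
  net <- ebicGlasso(spearmanMatrix(X), n = 400)
  ord <- order(net$lambdas, decreasing = TRUE)
  expect_true(all(diff(net$nEdges[ord]) >= 0))
})

test_that("EBIC with no edges reduces to the pure likelihood term", {
  set.seed(5)
  X <- matrix(rnorm(500 * 6), ncol = 6)
  net <- ebicGlasso(spearmanMatrix(X), n = 500)
  k <- which(net$nEdges == 0)[1]
  S <- spearmanMatrix(X)$R
  ThDiag <- diag(1 / diag(S))
  ll2 <- 500 * (determinant(ThDiag)$modulus[1] - sum(S * ThDiag))
  expect_equal(net$ebic[k], -ll2, ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("centrality indices follow their definitions and identities", {
  W <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  W["a", "b"] <- W["b", "a"] <- 0.3
  W["a", "c"] <- W["c", "a"] <- -0.2
  expect_equal(strengthCentrality(W)[["a"]], 0.5)
  expect_equal(expectedInfluence(W)[["a"]], 0.1)
  expect_equal(globalStrength(W), 0.5)
  # identities: gs = sum(strength)/2; EI = strength for all-positive nets
  expect_equal(globalStrength(W), sum(strengthCentrality(W)) / 2)
  Wp <- abs(W)
  expect_equal(strengthCentrality(Wp), expectedInfluence(Wp))
  expect_true(all(strengthCentrality(W) >= abs(expectedInfluence(W))))
  # sign flip negates EI
  expect_equal(expectedInfluence(-W), -expectedInfluence(W))
  # node permutation permutes strengths
  perm <- c(3, 1, 2)
  expect_equal(unname(strengthCentrality(W[perm, perm])),
               unname(strengthCentrality(W)[perm]))
  # empty network
  expect_equal(unname(strengthCentrality(matrix(0, 4, 4))), rep(0, 4))
  expect_equal(globalStrength(matrix(0, 4, 4)), 0)
})

test_that("edge lists mirror the weight matrix", {
  W <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  W["a", "b"] <- W["b", "a"] <- 0.3
  el <- asEdgeList(W)
  expect_equal(nrow(el), 1)
  expect_equal(el$weight, 0.3)
  expect_equal(nrow(asEdgeList(W, dropZero = FALSE)), 3)
})
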