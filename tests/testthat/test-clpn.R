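test_that("lasso support selection is deterministic and finds a dominant predictor", {
  p <- 6
  B <- diag(0.4, p)
  B[2, 1] <- 0.8
  cfg <- synthConfig(items = paste0("V", 1:p), waves = c("T0", "T1"),
                     nPerGroup = c(g = 1000), B = B, seed = 17)
  sim <- simulatePanel(cfg)
  s1 <- fitLassoStep(sim$data, interval = 1, seed = 5)
  s2 <- fitLassoStep(sim$data, interval = 1, seed = 5)
  expect_identical(s1, s2)
  expect_true(s1["V2", "V1"])     # the dominant cross-lagged path
  expect_true(all(diag(s1)))      # autoregressions survive
})

test_that("refit on a fixed support matches the normal-equations solution", {
  cfg <- synthConfig(items = c("A", "B", "C"), waves = c("T0", "T1"),
                     nPerGroup = c(g = 300),
                     B = matrix(c(0.5, 0, 0, 0.3, 0.5, 0, 0, 0, 0.5), 3,
                                byrow = TRUE),
                     seed = 23)
  sim <- simulatePanel(cfg)
  sup <- matrix(FALSE, 3, 3)
  sup[1, 2] <- TRUE               # single path B -> A
  net <- refitSupport(sim$data, 1, sup)
  im <- panelnet:::intervalMatrices(sim$data, 1)
  Xd <- cbind(1, im$X[, 2])
  beta <- solve(crossprod(Xd), crossprod(Xd, im$Y[, 1]))  # independent oracle
  expect_equal(net$B[1, 2], beta[2], ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(sum(net$B != 0), 1)
  # full support equals ordinary least squares on all predictors
  full <- refitSupport(sim$data, 1, matrix(TRUE, 3, 3))
  ols <- coef(lm(im$Y[, 1] ~ im$X))[-1]
  expect_equal(unname(full$B[1, ]), unname(ols), tolerance = 1e-10)
  # empty support: all-zero coefficients, zero R2
  none <- refitSupport(sim$data, 1, matrix(FALSE, 3, 3))
  expect_true(all(none$B == 0))
  expect_true(all(none$r2 == 0))
})

test_that("two-step refit is less biased than the raw LASSO coefficients", {
  p <- 8
  B <- diag(0.45, p)
  B[2, 1] <- 0.3; B[4, 3] <- -0.3; B[6, 5] <- 0.3
  truthStd <- NULL
  wins <- 0
  for (s in 1:10) {
    cfg <- synthConfig(items = paste0("V", 1:p), waves = c("T0", "T1"),
                       nPerGroup = c(g = 1500), B = B,
                       initial = "stationary", seed = 400 + s)
    sim <- simulatePanel(cfg)
    sup <- fitLassoStep(sim$data, 1, seed = s, returnCoefs = TRUE)
    lasso <- attr(sup, "coefs")
    refit <- refitSupport(sim$data, 1, sup)$B
    # compare on the true nonzero paths (standardization attenuates the
    # latent truth identically for both estimators)
    nz <- B != 0
    rmseL <- sqrt(mean((lasso[nz] - B[nz])^2))
    rmseR <- sqrt(mean((refit[nz] - B[nz])^2))
    if (rmseR < rmseL) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("prediction indices match the closed form in the orthogonal single-path case", {
  # X standardized orthogonal predictors, single cross-lagged path i -> j
  set.seed(61)
  n <- 4000
  p <- 4
  X0 <- matrix(rnorm(n * p), n, p)
  beta <- 0.5
  X1 <- matrix(rnorm(n * p) * 0.2, n, p)
  X1[, 2] <- beta * X0[, 1] + rnorm(n) * sqrt(1 - beta^2)
  arr <- array(c(X0, X1), c(n, p, 2),
               dimnames = list(NULL, paste0("V", 1:p), c("T0", "T1")))
  sup <- matrix(FALSE, p, p)
  sup[2, 1] <- TRUE
  net <- refitSupport(arr, 1, sup)
  pi <- predictionIndices(net, arr)
  bhat <- net$B[2, 1]
  expect_equal(pi$inPrediction[2], bhat^2, tolerance = 1e-10)
  expect_equal(pi$outPrediction[1], bhat^2 / (p - 1), tolerance = 1e-10)
  expect_equal(pi$inPrediction[-2], rep(0, p - 1))
  expect_equal(pi$outPrediction[-1], rep(0, p - 1))
  expect_equal(bhat, beta, tolerance = 0.05)
})

test_that("prediction indices agree with a brute-force leave-path-out oracle", {
  cfg <- synthConfig(items = paste0("V", 1:5), waves = c("T0", "T1"),
                     nPerGroup = c(g = 400),
                     B = {
                       M <- diag(0.4, 5)
                       M[2, 1] <- 0.25; M[3, 1] <- -0.2; M[5, 4] <- 0.3
                       M
                     }, seed = 71)
  sim <- simulatePanel(cfg)
  sup <- fitLassoStep(sim$data, 1, seed = 2)
  net <- refitSupport(sim$data, 1, sup)
  got <- predictionIndices(net, sim$data)
  # oracle: literal lm() refits for every leave-one-path-out model
  im <- panelnet:::intervalMatrices(sim$data, 1)
  r2 <- function(j, sel) {
    if (!length(sel)) return(0)
    summary(lm(im$Y[, j] ~ im$X[, sel, drop = FALSE]))$r.squared
  }
  p <- 5
  for (j in 1:p) {
    sel <- which(sup[j, ])
    inOracle <- r2(j, sel) - r2(j, intersect(sel, j))
    expect_equal(got$inPrediction[j], max(0, min(1, inOracle)),
                 tolerance = 1e-8)
  }
  for (i in 1:p) {
    drops <- vapply(setdiff(1:p, i), function(j) {
      sel <- which(sup[j, ])
      if (!(i %in% sel)) return(0)
      r2(j, sel) - r2(j, setdiff(sel, i))
    }, 0)
    expect_equal(got$outPrediction[i], max(0, min(1, mean(drops))),
                 tolerance = 1e-8)
  }
  # in-prediction is zero whenever no incoming cross-lagged path exists
  noCross <- diag(TRUE, 5)
  netAr <- refitSupport(sim$data, 1, noCross)
  expect_equal(predictionIndices(netAr, sim$data)$inPrediction, rep(0, 5))
})

test_that("directed-network similarity statistics are exact on fixtures", {
  mk <- function(edges, nodes = 4) {
    B <- matrix(0, nodes, nodes)
    for (e in edges) B[e[2], e[1]] <- e[3]
    B
  }
  A <- mk(list(c(1, 2, 0.5), c(2, 3, -0.2), c(3, 1, 0.1)))
  expect_equal(compareDirected(A, A)$jaccard, 1)
  expect_equal(compareDirected(A, A)$r, 1)
  B <- mk(list(c(1, 3, 0.4), c(3, 2, 0.2)))
  expect_equal(compareDirected(A, B)$jaccard, 0)
  # {e1,e2,e3} vs {e3,e4}: one shared of four in the union
  C <- mk(list(c(3, 1, 0.3), c(1, 4, 0.25)))
  A2 <- mk(list(c(1, 2, 0.5), c(2, 3, -0.2), c(3, 1, 0.1)))
  expect_equal(compareDirected(A2, C)$jaccard, 1 / 4)
  # sign-flipped weights correlate at -1
  expect_equal(compareDirected(A, -A)$r, -1)
  # autoregressive paths are excluded unless requested
  D <- mk(list(c(1, 1, 0.5)))
  expect_error(compareDirected(D, D), "empty")
  expect_equal(compareDirected(D, D, includeAutoregressive = TRUE)$jaccard, 1)
  # symmetry
  s1 <- compareDirected(A, C)
  s2 <- compareDirected(C, A)
  expect_equal(s1$jaccard, s2$jaccard)
  expect_equal(s1$r, s2$r)
})
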