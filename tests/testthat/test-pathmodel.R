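test_that("the fully free path model is saturated: chi-square 0 on 0 df", {
  cfg <- synthConfig(items = paste0("V", 1:4), waves = c("T0", "T1", "T2"),
                     nPerGroup = c(g = 200), B = diag(0.4, 4), seed = 44)
  sim <- simulatePanel(cfg)
  full <- matrix(TRUE, 4, 4)
  m <- fitPathModel(sim$data, list(full, full), lag2Support = full)
  expect_equal(m$fit$chisq, 0, tolerance = 1e-7)
  expect_identical(m$fit$df, 0)
  expect_equal(m$fit$rmsea, 0)
})

test_that("degrees of freedom count free parameters exactly", {
  p <- 4
  cfg <- synthConfig(items = paste0("V", 1:p), waves = c("T0", "T1", "T2"),
                     nPerGroup = c(g = 300), B = diag(0.4, p), seed = 45)
  sim <- simulatePanel(cfg)
  s1 <- matrix(FALSE, p, p); diag(s1) <- TRUE; s1[2, 1] <- TRUE
  s2 <- matrix(FALSE, p, p); diag(s2) <- TRUE; s2[3, 1] <- TRUE
  q <- 3 * p
  sat <- q * (q + 1) / 2
  u <- fitPathModel(sim$data, list(s1, s2))
  expect_equal(u$fit$df, sat - (3 * p * (p + 1) / 2 + sum(s1) + sum(s2)))
  cm <- fitPathModel(sim$data, list(s1, s2), constrained = TRUE)
  uni <- s1 | s2
  expect_equal(cm$fit$df, sat - (3 * p * (p + 1) / 2 + sum(uni)))
  # df difference = number of genuinely tied paths (shared support cells)
  expect_equal(cm$fit$df - u$fit$df, sum(s1 & s2))
  # with identical supports the difference is the full support size
  u2 <- fitPathModel(sim$data, list(s1, s1))
  c2 <- fitPathModel(sim$data, list(s1, s1), constrained = TRUE)
  expect_equal(c2$fit$df - u2$fit$df, sum(s1))
})

test_that("restricted ML equals per-equation OLS when the support is full", {
  # with every regression unrestricted, GLS = OLS regardless of the
  # residual covariance, giving a closed-form oracle
  p <- 3
  cfg <- synthConfig(items = paste0("V", 1:p), waves = c("T0", "T1", "T2"),
                     nPerGroup = c(g = 250), B = diag(0.5, p), seed = 46)
  sim <- simulatePanel(cfg)
  full <- matrix(TRUE, p, p)
  m <- fitPathModel(sim$data, list(full, full), lag2Support = NULL)
  X <- lapply(c("T0", "T1", "T2"), function(w) waveMatrix(sim$data, w))
  Z <- lapply(X, scale, scale = FALSE)
  B1ols <- t(solve(crossprod(Z[[1]]), crossprod(Z[[1]], Z[[2]])))
  expect_equal(unname(m$B[[1]]), unname(B1ols), tolerance = 1e-8)
})

test_that("the chi-square difference test behaves on fixtures and the reported tail", {
  p <- 4
  cfg <- synthConfig(items = paste0("V", 1:p), waves = c("T0", "T1", "T2"),
                     nPerGroup = c(g = 500), B = diag(0.45, p),
                     initial = "stationary", seed = 47)
  sim <- simulatePanel(cfg)
  s <- diag(TRUE, p)
  u <- fitPathModel(sim$data, list(s, s))
  cm <- fitPathModel(sim$data, list(s, s), constrained = TRUE)
  tst <- chi2Difference(u, cm)
  expect_equal(tst$dDf, sum(s))
  expect_gte(tst$dChisq, 0)
  # identical models: zero difference, p = 1
  same <- chi2Difference(u, u)
  expect_equal(same$dChisq, 0)
  expect_equal(same$p, 1)
  # reversed nesting errors
  expect_error(chi2Difference(cm, u), "not nested")
  # tail computation at a published-scale value: 439.7 on 232 df is
  # overwhelmingly significant
  expect_lt(pchisq(439.7, 232, lower.tail = FALSE), 0.001)
})

test_that("time-varying dynamics are detected and power grows with n", {
  p <- 4
  B1 <- diag(0.5, p); B1[2, 1] <- 0.4
  B2 <- diag(0.5, p); B2[2, 1] <- -0.4
  rejAt <- function(n) {
    cfg <- synthConfig(items = paste0("V", 1:p), waves = c("T0", "T1", "T2"),
                       nPerGroup = c(g = n), B = list(B1, B2), seed = 48)
    sim <- simulatePanel(cfg)
    s <- B1 != 0 | B2 != 0
    u <- fitPathModel(sim$data, list(s, s))
    cm <- fitPathModel(sim$data, list(s, s), constrained = TRUE)
    chi2Difference(u, cm)
  }
  big <- rejAt(800)
  expect_lt(big$p, 0.001)
  expect_false(big$keepConstrained)
})

test_that("fit indices are coherent: good fit for true models, poor for the baseline", {
  p <- 5
  B <- diag(0.5, p); B[2, 1] <- 0.3; B[4, 3] <- -0.3
  cfg <- synthConfig(items = paste0("V", 1:p), waves = c("T0", "T1", "T2"),
                     nPerGroup = c(g = 600), B = B,
                     initial = "stationary", seed = 49)
  lat <- simulatePanel(cfg, returnLatent = TRUE)$truth$latent
  sup <- B != 0
  m <- fitPathModel(lat, list(sup, sup))
  expect_gt(m$fit$p, 0.001)
  expect_lt(m$fit$rmsea, 0.05)
  expect_gt(m$fit$cfi, 0.95)
  expect_gt(m$fit$tli, 0.9)
  expect_lte(m$fit$rmsea.ci[1], m$fit$rmsea + 1e-12)
  expect_gte(m$fit$rmsea.ci[2], m$fit$rmsea - 1e-12)
  # a badly wrong (empty lag-1) model fits poorly
  none <- matrix(FALSE, p, p)
  bad <- fitPathModel(lat, list(none, none))
  expect_lt(bad$fit$p, 0.01)
  expect_gt(bad$fit$rmsea, m$fit$rmsea)
})

test_that("fitCLPN runs the full two-step workflow end to end", {
  cfg <- synthConfig(items = paste0("V", 1:5), waves = c("T0", "T1", "T2"),
                     nPerGroup = c(g = 250),
                     B = {
                       M <- diag(0.5, 5); M[2, 1] <- 0.3; M
                     }, seed = 50)
  sim <- simulatePanel(cfg)
  cl <- fitCLPN(sim$data, seed = 4)
  expect_length(cl$networks, 2)
  expect_s3_class(cl$networks[[1]], "clpnNetwork")
  expect_true(all(cl$networks[[1]]$B[!cl$supports[[1]]] == 0))
  expect_true(is.list(cl$constraintTest))
  expect_length(cl$prediction, 2)
  expect_true(all(cl$prediction[[1]]$inPrediction >= 0 &
                    cl$prediction[[1]]$inPrediction <= 1))
})
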