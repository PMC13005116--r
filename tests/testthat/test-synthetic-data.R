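test_that("the generator is reproducible and validates its inputs", {
  cfg <- xsectConfig(p = 4, n = 30, seed = 9)
  a <- simulatePanel(cfg)
  b <- simulatePanel(cfg)
  expect_identical(a$data$ratings, b$data$ratings)
  # non-PD Theta rejected
  badTheta <- matrix(1, 3, 3)
  expect_error(synthConfig(items = c("A", "B", "C"), waves = c("T0", "T1"),
                           nPerGroup = c(g = 10), Theta = badTheta),
               "positive definite")
  # non-increasing thresholds rejected
  expect_error(synthConfig(items = c("A", "B"), waves = c("T0", "T1"),
                           nPerGroup = c(g = 10),
                           thresholds = c(0, 0, 1, 2, 3, 4)),
               "strictly increasing")
  # explosive dynamics warn
  expect_warning(synthConfig(items = c("A", "B"), waves = c("T0", "T1"),
                             nPerGroup = c(g = 10), B = diag(1.2, 2)),
                 "spectral radius")
})

test_that("extreme thresholds give a flagged degenerate constant panel", {
  expect_warning(
    simulatePanel(synthConfig(items = c("A", "B"), waves = c("T0", "T1"),
                              nPerGroup = c(g = 20),
                              thresholds = c(50, 60, 70, 80, 90, 100),
                              seed = 3)),
    "degenerate")
})

test_that("independent items (B diagonal, Theta = I) show near-zero Spearman correlations", {
  cfg <- synthConfig(items = paste0("V", 1:10), waves = c("T0", "T1"),
                     nPerGroup = c(g = 5000), B = diag(0.3, 10),
                     Theta = diag(10), seed = 21)
  sim <- simulatePanel(cfg)
  R <- spearmanMatrix(sim$data, "T0")$R
  # Monte-Carlo bound: sd(rho) ~ 1/sqrt(n); 45 pairs, 4.5 sd margin
  expect_lt(max(abs(R[upper.tri(R)])), 4.5 / sqrt(5000))
})

test_that("two-arm simulation randomizes reproducibly and injects the latent shift", {
  codes <- paste0("V", 1:6)
  base <- synthConfig(items = codes, waves = c("W0", "W1"),
                      nPerGroup = c(g = 800), B = diag(0.4, 6),
                      treatmentEffect = c(V3 = -1.5), seed = 12)
  a <- simulateTwoArm(base)
  b <- simulateTwoArm(base)
  expect_identical(a$data$arm, b$data$arm)
  expect_equal(sum(a$data$arm), 400)
  # standardized mean difference on the targeted item is detectable
  x <- waveMatrix(a$data, "W1")[, "V3"]
  d <- (mean(x[a$data$arm == 0]) - mean(x[a$data$arm == 1])) /
    sd(x)
  expect_gt(abs(d), 0.5)
  # untargeted item shows no such shift
  y <- waveMatrix(a$data, "W1")[, "V5"]
  d0 <- (mean(y[a$data$arm == 0]) - mean(y[a$data$arm == 1])) / sd(y)
  expect_lt(abs(d0), 0.25)
})

test_that("empty treatment effect leaves arms exchangeable", {
  codes <- paste0("V", 1:5)
  cfg <- synthConfig(items = codes, waves = c("W0", "W1"),
                     nPerGroup = c(g = 1000), B = diag(0.4, 5), seed = 6)
  sim <- simulateTwoArm(cfg)
  x <- waveMatrix(sim$data, "W1")
  pv <- vapply(seq_len(ncol(x)), function(j)
    t.test(x[sim$data$arm == 0, j], x[sim$data$arm == 1, j])$p.value, 0)
  # no item shows a multiplicity-adjusted arm difference
  expect_gt(min(p.adjust(pv, "bonferroni")), 0.05)
})

test_that("MCAR masking hits roughly the requested fraction and round-trips", {
  cfg <- xsectConfig(p = 5, n = 200, seed = 2)
  pd <- simulatePanel(cfg)$data
  masked <- maskMCAR(pd, 0.2, seed = 8)
  frac <- mean(is.na(masked$ratings))
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.25)
  expect_identical(maskMCAR(pd, 0.2, seed = 8)$ratings, masked$ratings)
})

test_that("default study configs produce plausible two-group panels", {
  sim <- simulatePanel(phase1Config(seed = 30))
  expect_equal(dim(sim$data$ratings), c(446L, 21L, 3L))
  expect_equal(unname(table(sim$data$group)["remitter"]), 250L)
  ts <- totalScore(sim$data, "T0")
  expect_gt(mean(ts), 45)   # 21-item totals around the mid-50s at baseline
  expect_lt(mean(ts), 65)
  lab <- classifyRemission(sim$data, "T2", missing = "na")
  # remission labelling is non-degenerate and concentrated in remitters
  rate <- vapply(split(lab, sim$data$group), function(v) mean(v, na.rm = TRUE), 0)
  expect_gt(rate[["remitter"]], 0.5)
  expect_lt(rate[["nonremitter"]], 0.25)
  sim2 <- simulateTwoArm(phase2Config(seed = 30))
  expect_equal(dim(sim2$data$ratings)[1], 85L)
  expect_equal(sort(as.integer(table(sim2$data$arm))), c(42L, 43L))
})
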