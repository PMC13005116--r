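# Shared fixtures: small deterministic panels and generator configs.

# tiny 2-subject x 3-item x 3-wave panel with known values
tinyPanel <- function() {
  r <- array(NA_real_, c(2, 3, 3),
             dimnames = list(c("a", "b"), c("P1", "N1", "G5"),
                             c("T0", "T1", "T2")))
  r["a", , ] <- matrix(c(4, 3, 2,
                         5, 4, 3,
                         3, 2, 1), 3, 3, byrow = TRUE)
  r["b", , ] <- matrix(c(2, 2, 1,
                         3, 3, 2,
                         2, 1, 1), 3, 3, byrow = TRUE)
  panelData(r, group = c("remitter", "nonremitter"))
}

# chain-structured precision matrix
chainTheta <- function(p, rho = -0.3) {
  Th <- diag(p)
  for (k in seq_len(p - 1)) {
    Th[k, k + 1] <- rho
    Th[k + 1, k] <- rho
  }
  Th
}

# draw a Gaussian sample with given precision
rmvnPrec <- function(n, Theta, seed) {
  U <- chol(solve(Theta))
  withr::with_seed(seed, matrix(rnorm(n * nrow(Theta)), n) %*% U)
}

# small ordinal two-wave config for cross-sectional simulations
xsectConfig <- function(p = 8, n = 300, seed = 1, Theta = chainTheta(p),
                        ar = 0.3) {
  synthConfig(items = paste0("V", seq_len(p)), waves = c("T0", "T1"),
              nPerGroup = c(g = n), B = diag(ar, p), Theta = Theta,
              seed = seed)
}

# fast GGM estimator used where many re-estimations are needed
fastEstimator <- function() ggmEstimator(nLambda = 40)

# small end-to-end pipeline inputs shared by pipeline and acceptance tests
smallPhase1Inputs <- function(seed = 1) {
  items <- itemSet(paste0("V", 1:8),
                   remissionItems = paste0("V", 1:4))
  p <- 8
  B1 <- diag(0.5, p); B1[2, 1] <- 0.25; B1[4, 3] <- 0.2
  B2 <- diag(0.5, p); B2[6, 5] <- 0.25
  C1 <- diag(0.5, p); C1[8, 7] <- 0.25
  C2 <- diag(0.5, p); C2[3, 2] <- 0.2; C2[5, 6] <- -0.2
  synthConfig(items = items, waves = c("T0", "T1", "T2"),
              nPerGroup = c(remitter = 120, nonremitter = 100),
              B = list(remitter = list(B1, B2), nonremitter = list(C1, C2)),
              Theta = chainTheta(p, -0.3),
              drift = list(remitter = c(0, -0.9, -0.8),
                           nonremitter = c(0, -0.1, 0.1)),
              subjectSigma = 0.4, seed = seed)
}

smallConfig <- function(outDir, seed = 5) {
  pipelineConfig(outDir = outDir, seed = seed, nBoot = 12, nPerm = 12,
                 csB = 8, csGrid = c(0.1, 0.3), folds = 5, nLambda = 40)
}
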