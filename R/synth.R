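#' Configuration for the latent-VAR ordinal panel simulator
#'
#' Panels are generated from a group-specific latent first-order
#' vector-autoregression, then discretized onto the 1-7 rating scale by
#' fixed per-item thresholds (a Gaussian copula mechanism, matching the
#' rank-correlation assumption of the estimators):
#' \deqn{X_0 = d_0 + \epsilon_0,\quad
#'       X_{t+1} = d_{t+1} + B_t X_t + \epsilon_{t+1},\quad
#'       \epsilon_t \sim N(0, \Theta^{-1})}
#' with observed rating \eqn{1 + \#\{cutpoints < X + u\}}, where \eqn{u} is
#' an optional stable per-subject severity intercept shared across items
#' and waves.
#'
#' @param items An [itemSet()] or character vector of item codes.
#' @param waves Ordered wave labels (>= 2).
#' @param nPerGroup Named integer vector: subjects per group.
#' @param B Cross-lagged coefficient matrices (rows = target at t+1,
#'   columns = source at t; diagonal = autoregressive). Either a single
#'   p x p matrix (shared), a list of `length(waves) - 1` matrices (shared
#'   across groups), or a list per group of such lists.
#' @param Theta Positive-definite p x p innovation precision matrix (shared
#'   across groups), identity by default.
#' @param thresholds Either a length-6 increasing vector (shared across
#'   items) or a p x 6 matrix of strictly increasing per-item cutpoints.
#' @param drift Latent mean shifts: a waves x p matrix, a length-`waves`
#'   vector (replicated across items), or a list per group of either.
#'   Negative values model symptom improvement.
#' @param treatmentEffect Named numeric vector, item -> latent shift added
#'   for treatment-arm subjects at all post-baseline waves (used by
#'   [simulateTwoArm()]).
#' @param subjectSigma SD of the per-subject severity intercept (0 = none).
#' @param initial Baseline latent distribution: `"innovation"` (default)
#'   draws the first wave from the innovation covariance
#'   \eqn{\Theta^{-1}}; `"stationary"` solves the discrete Lyapunov
#'   equation of the first interval's dynamics so every wave shares the
#'   same latent variance (a time-invariant process on any scale).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A validated `synthConfig`.
#' @export
synthConfig <- function(items, waves, nPerGroup, B = NULL, Theta = NULL,
                        thresholds = c(-1.0, 0.0, 0.9, 1.8, 2.6, 3.4),
                        drift = 0, treatmentEffect = NULL,
                        subjectSigma = 0, initial = c("innovation", "stationary"),
                        seed = 1L) {
  initial <- match.arg(initial)
  set <- if (inherits(items, "itemSet")) items else itemSet(items)
  p <- length(set$codes)
  waves <- as.character(waves)
  W <- length(waves)
  stopifnot(W >= 2, length(nPerGroup) >= 1, !is.null(names(nPerGroup)))
  groups <- names(nPerGroup)

  if (is.null(Theta)) Theta <- diag(p)
  stopifnot(is.matrix(Theta), nrow(Theta) == p, ncol(Theta) == p)
  ev <- eigen(Theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stopf("Theta is not positive definite (min eigenvalue %.3g)",
                          min(ev))

  if (is.null(B)) B <- diag(0.5, p)
  B <- normalizeByGroup(B, groups, W - 1, p, "B")
  for (g in groups) for (k in seq_len(W - 1)) {
    sr <- max(Mod(eigen(B[[g]][[k]], only.values = TRUE)$values))
    if (sr >= 1)
      warnf("autoregressive system for group '%s', interval %d has spectral radius %.2f >= 1 (non-stationary)",
            g, k, sr)
  }

  if (is.vector(thresholds)) {
    stopifnot(length(thresholds) == 6)
    thresholds <- matrix(thresholds, p, 6, byrow = TRUE)
  }
  stopifnot(nrow(thresholds) == p, ncol(thresholds) == 6)
  if (any(apply(thresholds, 1, function(r) any(diff(r) <= 0))))
    stopf("thresholds must be strictly increasing for every item")
  rownames(thresholds) <- set$codes

  drift <- normalizeDrift(drift, groups, W, p)
  if (!is.null(treatmentEffect)) {
    stopifnot(!is.null(names(treatmentEffect)),
              all(names(treatmentEffect) %in% set$codes))
  }
  structure(list(items = set, waves = waves, nPerGroup = nPerGroup,
                 B = B, Theta = Theta, thresholds = thresholds,
                 drift = drift, treatmentEffect = treatmentEffect,
                 subjectSigma = subjectSigma, initial = initial,
                 seed = as.integer(seed)),
            class = "synthConfig")
}

normalizeByGroup <- function(B, groups, nInt, p, what) {
  asIntervalList <- function(x) {
    if (is.matrix(x)) x <- rep(list(x), nInt)
    stopifnot(length(x) == nInt)
    lapply(x, function(m) {
      stopifnot(is.matrix(m), nrow(m) == p, ncol(m) == p)
      m
    })
  }
  if (is.matrix(B) || (is.list(B) && is.null(names(B))))
    return(setNames(rep(list(asIntervalList(B)), length(groups)), groups))
  stopifnot(all(groups %in% names(B)))
  lapply(B[groups], asIntervalList)
}

normalizeDrift <- function(drift, groups, W, p) {
  asMat <- function(x) {
    if (is.vector(x) && length(x) %in% c(1, W))
      x <- matrix(rep(x, length.out = W), W, p)
    stopifnot(is.matrix(x), nrow(x) == W, ncol(x) == p)
    x
  }
  if (!is.list(drift))
    return(setNames(rep(list(asMat(drift)), length(groups)), groups))
  stopifnot(all(groups %in% names(drift)))
  lapply(drift[groups], asMat)
}

#' Simulate an ordinal symptom panel with known ground truth
#'
#' @param config A [synthConfig()].
#' @param returnLatent Keep the latent (pre-threshold) scores in the
#'   ground-truth record.
#' @return A list with `data` (a [panelData()] whose `group` labels are the
#'   generating groups) and `truth` (the generating `B`, `Theta`,
#'   thresholds, drift and, optionally, latent scores).
#' @export
simulatePanel <- function(config, returnLatent = FALSE) {
  stopifnot(inherits(config, "synthConfig"))
  withSeed(config$seed, simulatePanelImpl(config, returnLatent,
                                          armOffsets = NULL, arm = NULL))
}

simulatePanelImpl <- function(config, returnLatent, armOffsets, arm) {
  set <- config$items
  p <- length(set$codes)
  W <- length(config$waves)
  Sigma <- solve(config$Theta)
  U <- chol(Sigma)
  groups <- names(config$nPerGroup)
  ratingList <- list()
  latentList <- list()
  groupLab <- character()
  for (g in groups) {
    n <- config$nPerGroup[[g]]
    X <- array(0, c(n, p, W))
    dr <- config$drift[[g]]
    U0 <- U
    if ((config$initial %||% "innovation") == "stationary") {
      B1 <- config$B[[g]][[1]]
      V <- Sigma  # solve V = B V B' + Sigma by fixed-point iteration
      for (i in 1:200) {
        Vn <- B1 %*% V %*% t(B1) + Sigma
        if (max(abs(Vn - V)) < 1e-12) { V <- Vn; break }
        V <- Vn
      }
      U0 <- chol(V)
    }
    X[, , 1] <- matrix(dr[1, ], n, p, byrow = TRUE) +
      matrix(rnorm(n * p), n, p) %*% U0
    for (t in 2:W) {
      X[, , t] <- matrix(dr[t, ], n, p, byrow = TRUE) +
        X[, , t - 1] %*% t(config$B[[g]][[t - 1]]) +
        matrix(rnorm(n * p), n, p) %*% U
      if (!is.null(armOffsets))
        X[, , t] <- X[, , t] + armOffsets[[g]][, , t]
    }
    if (config$subjectSigma > 0) {
      u <- rnorm(n, 0, config$subjectSigma)
      X <- X + array(u, c(n, p, W))
    }
    ratings <- array(NA_real_, c(n, p, W))
    for (j in seq_len(p))
      for (t in seq_len(W))
        ratings[, j, t] <- 1 + findInterval(X[, j, t], config$thresholds[j, ])
    ratingList[[g]] <- ratings
    latentList[[g]] <- X
    groupLab <- c(groupLab, rep(g, n))
  }
  ratings <- do.call(abind3, ratingList)
  latent <- do.call(abind3, latentList)
  ntot <- dim(ratings)[1]
  subjects <- sprintf("S%04d", seq_len(ntot))
  dimnames(ratings) <- list(subjects, set$codes, config$waves)
  constant <- apply(ratings, 2, function(m) length(unique(as.vector(m))) == 1)
  if (any(constant))
    warnf("degenerate item(s) with constant ratings: %s",
          paste(set$codes[constant], collapse = ", "))
  data <- panelData(ratings, waves = config$waves, group = groupLab,
                    arm = arm, items = set, subjects = subjects)
  truth <- list(B = config$B, Theta = config$Theta,
                thresholds = config$thresholds, drift = config$drift,
                treatmentEffect = config$treatmentEffect,
                subjectSigma = config$subjectSigma, groups = groupLab)
  if (returnLatent) {
    dimnames(latent) <- list(subjects, set$codes, config$waves)
    truth$latent <- latent
  }
  list(data = data, truth = truth)
}

# stack 3-d arrays along the first (subject) dimension
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(NA_real_, c(sum(vapply(xs, function(x) dim(x)[1], 0)),
                           d[2], d[3]))
  at <- 0
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' Simulate a two-arm treatment panel
#'
#' Subjects are randomized 0/1 to two arms (near-balanced); arm-1 subjects
#' receive the configured latent shift on the targeted items at every
#' post-baseline wave (the shift enters the latent dynamics, so it also
#' propagates through the cross-lagged structure).
#'
#' @param config A [synthConfig()]; `treatmentEffect` may be `NULL` or
#'   empty, in which case the arms are statistically exchangeable.
#' @param returnLatent Keep latent scores in the ground truth.
#' @return As [simulatePanel()]; the `panelData` carries the `arm` codes.
#' @export
simulateTwoArm <- function(config, returnLatent = FALSE) {
  stopifnot(inherits(config, "synthConfig"))
  withSeed(config$seed, {
    p <- length(config$items$codes)
    W <- length(config$waves)
    groups <- names(config$nPerGroup)
    armByGroup <- lapply(config$nPerGroup,
                         function(n) sample(rep(0:1, length.out = n)))
    offsets <- lapply(groups, function(g) {
      n <- config$nPerGroup[[g]]
      off <- array(0, c(n, p, W))
      eff <- config$treatmentEffect
      if (length(eff)) {
        jj <- match(names(eff), config$items$codes)
        for (t in 2:W)
          off[armByGroup[[g]] == 1, jj, t] <-
            matrix(eff, sum(armByGroup[[g]] == 1), length(eff), byrow = TRUE)
      }
      off
    })
    names(offsets) <- groups
    simulatePanelImpl(config, returnLatent, armOffsets = offsets,
                      arm = unlist(armByGroup, use.names = FALSE))
  })
}

#' Mask ratings completely at random
#'
#' Utility to inject MCAR missingness into a simulated panel.
#' @param data A [panelData()].
#' @param prob Probability that any observed cell is set to missing.
#' @param seed Integer seed.
#' @return A `panelData` with masked cells.
#' @export
maskMCAR <- function(data, prob, seed = 1L) {
  stopifnot(prob >= 0, prob < 1)
  r <- data$ratings
  mask <- withSeed(seed, runif(length(r)) < prob)
  r[mask] <- NA_real_
  panelData(r, waves = data$waves, group = data$group, arm = data$arm,
            items = data$items, subjects = data$subjects)
}

#' Default phase-I study configuration
#'
#' The shipped study conditions: 21 items over three equally spaced waves,
#' two outcome groups (250 remitters, 196 non-remitters) sharing the same
#' contemporaneous structure and autoregression (0.5) but with distinct,
#' largely disjoint cross-lagged dynamics; remitters improve strongly early
#' (latent drift -1.1 then -0.9), non-remitters improve little with
#' renewed worsening of negative-domain items at the last wave.
#'
#' @param seed Integer seed.
#' @param nPerGroup Named vector of group sizes.
#' @param items Item set (default [panss21ItemSet()]).
#' @return A [synthConfig()].
#' @export
phase1Config <- function(seed = 1L,
                         nPerGroup = c(remitter = 250, nonremitter = 196),
                         items = panss21ItemSet()) {
  codes <- if (inherits(items, "itemSet")) items$codes else items
  p <- length(codes)
  path <- function(pairs, value) {
    # pairs: list of c(source, target); B[target, source] = value
    M <- diag(0.5, p)
    dimnames(M) <- list(codes, codes)
    for (k in seq_along(pairs))
      M[pairs[[k]][2], pairs[[k]][1]] <- value[min(k, length(value))]
    M
  }
  remB1 <- path(list(c("P6", "P1"), c("N3", "P1"), c("G14", "P1"),
                     c("N5", "P1"), c("G13", "P1"), c("G15", "P1"),
                     c("G14", "P6"), c("G14", "G9"), c("G14", "G8"),
                     c("G14", "P7")),
                c(0.15, 0.12, 0.12, 0.10, 0.10, 0.10, 0.12, 0.10, 0.12, 0.10))
  remB2 <- path(list(c("N3", "G8"), c("N3", "N7"), c("N3", "P3"),
                     c("G8", "G13")),
                c(0.18, 0.12, 0.10, 0.10))
  nonB1 <- path(list(c("N4", "G10"), c("G13", "G10"), c("G13", "N6")),
                c(0.15, 0.12, 0.10))
  nonB2 <- path(list(c("N1", "G7"), c("N2", "G7"), c("N3", "G7"),
                     c("P6", "G7"), c("G9", "G7"), c("N5", "P6"),
                     c("N5", "G10"), c("P1", "N2")),
                c(0.12, 0.12, 0.10, -0.12, -0.10, -0.12, 0.12, -0.10))
  drift <- list(
    remitter = matrix(c(0, -1.1, -0.9), 3, p),
    nonremitter = {
      d <- matrix(c(0, -0.1, 0.15), 3, p)
      colnames(d) <- codes
      d[3, c("N1", "N2", "N6", "G5", "G7")] <-
        d[3, c("N1", "N2", "N6", "G5", "G7")] + 0.3
      d
    })
  names(drift) <- names(nPerGroup)
  synthConfig(items = items, waves = c("T0", "T1", "T2"),
              nPerGroup = nPerGroup,
              B = setNames(list(list(remB1, remB2), list(nonB1, nonB2)),
                           names(nPerGroup)),
              Theta = domainPrecision(items),
              drift = drift, subjectSigma = 0.5, seed = seed)
}

#' Default phase-II (two-arm) study configuration
#'
#' 85 initial non-remitters randomized to two active arms across three
#' post-randomization assessments, with a differential latent effect of
#' -0.6 on poor rapport (N3) for arm 1 at post-baseline waves.
#'
#' @param seed Integer seed.
#' @param n Total subjects.
#' @param items Item set.
#' @param treatmentEffect Named latent shifts applied to arm 1.
#' @return A [synthConfig()].
#' @export
phase2Config <- function(seed = 1L, n = 85, items = panss21ItemSet(),
                         treatmentEffect = c(N3 = -0.6)) {
  codes <- if (inherits(items, "itemSet")) items$codes else items
  p <- length(codes)
  synthConfig(items = items, waves = c("W6", "W8", "W10"),
              nPerGroup = c(phase2 = n),
              B = diag(0.5, p),
              Theta = domainPrecision(items),
              drift = c(0, -0.15, -0.1),
              treatmentEffect = treatmentEffect,
              subjectSigma = 0.5, seed = seed)
}

# Contemporaneous precision: chain within each symptom domain (partial
# correlations ~ 0.3, the magnitude typical of within-domain PANSS item
# pairs) plus weak bridges between consecutive domains; diagonally
# dominant, hence positive definite.
domainPrecision <- function(items, within = -0.3, bridge = -0.12) {
  set <- if (inherits(items, "itemSet")) items else itemSet(items)
  p <- length(set$codes)
  Theta <- diag(p)
  dimnames(Theta) <- list(set$codes, set$codes)
  doms <- unique(set$domains)
  first <- character(0)
  for (d in doms) {
    mem <- set$codes[set$domains[set$codes] == d]
    if (length(mem) >= 2)
      for (k in seq_len(length(mem) - 1)) {
        Theta[mem[k], mem[k + 1]] <- within
        Theta[mem[k + 1], mem[k]] <- within
      }
    first <- c(first, mem[1])
  }
  if (length(first) >= 2)
    for (k in seq_len(length(first) - 1)) {
      Theta[first[k], first[k + 1]] <- bridge
      Theta[first[k + 1], first[k]] <- bridge
    }
  Theta
}
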