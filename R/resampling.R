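#' Nonparametric bootstrap of edge weights
#'
#' Resamples subjects with replacement, re-runs the estimation recipe with
#' identical settings on every replicate, and summarizes each edge by its
#' point estimate, 95% quantile confidence interval and inclusion
#' proportion (share of replicates where the edge is non-zero).
#'
#' @param data A [panelData()] (with `wave`) or a subject x item matrix.
#' @param estimator Function mapping a subject x item matrix to a symmetric
#'   weight matrix, e.g. [ggmEstimator()].
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param wave Wave label for panel input.
#' @param indices Optional list of `B` row-index vectors overriding the
#'   random draws (for exact reproduction).
#' @return An `edgeBootstrap`: list with `edges` (data.frame: `edge`,
#'   `point`, `lower`, `upper`, `inclusion`), `B`, `nFailed`, and the
#'   replicate x edge `samples` matrix. Note the quantile interval is not
#'   forced to contain the point estimate for edges absent from the
#'   full-sample network.
#' @export
bootstrapEdges <- function(data, estimator, B = 1000, seed = 1L,
                           wave = NULL, indices = NULL) {
  X <- if (inherits(data, "panelData")) waveMatrix(data, wave) else
    as.matrix(data)
  n <- nrow(X)
  W0 <- estimator(X)
  en <- edgeNames(colnames(W0) %||% paste0("V", seq_len(ncol(W0))))
  point <- upperTri(W0)
  if (is.null(indices))
    indices <- withSeed(seed, lapply(seq_len(B), function(b)
      sample.int(n, n, replace = TRUE)))
  B <- length(indices)
  samples <- matrix(NA_real_, B, length(en))
  nFailed <- 0
  for (b in seq_len(B)) {
    Wb <- tryCatch(estimator(X[indices[[b]], , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(Wb)) { nFailed <- nFailed + 1; next }
    samples[b, ] <- upperTri(Wb)
  }
  if (nFailed > 0.05 * B)
    stopf("estimation failed on %d of %d bootstrap replicates (> 5%%)",
          nFailed, B)
  ok <- !is.na(samples[, 1])
  qs <- apply(samples[ok, , drop = FALSE], 2, quantile,
              probs = c(0.025, 0.975))
  edges <- data.frame(edge = en, point = point,
                      lower = qs[1, ], upper = qs[2, ],
                      inclusion = colMeans(samples[ok, , drop = FALSE] != 0),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(edges = edges, B = B, nFailed = nFailed,
                 samples = samples),
            class = "edgeBootstrap")
}

#' @export
print.edgeBootstrap <- function(x, ...) {
  cat(sprintf("edgeBootstrap: %d edges, B = %d (%d failed)\n",
              nrow(x$edges), x$B, x$nFailed))
  cat(sprintf("  mean CI width = %.3f\n",
              mean(x$edges$upper - x$edges$lower)))
  invisible(x)
}

#' Case-dropping centrality stability (CS) coefficient
#'
#' For each drop proportion, draws subsamples without replacement,
#' recomputes centrality, and correlates it with the full-sample
#' centrality. The CS-coefficient is the largest drop proportion whose
#' correlation stays at or above `threshold` in at least a `prob` share of
#' subsamples (0 if none). Networks with CS >= 0.25 are conventionally
#' labelled stable; CS >= 0.5 is preferred.
#'
#' @param data A [panelData()] (with `wave`) or a subject x item matrix.
#' @param centralityFn Function mapping a subject x item matrix to a named
#'   centrality vector, or to a node x metric matrix for several metrics
#'   at once (see [ggmCentrality()]).
#' @param dropGrid Proportions of cases to drop.
#' @param B Subsamples per proportion.
#' @param threshold Correlation threshold (0.70 by convention).
#' @param prob Required share of subsamples meeting the threshold.
#' @param seed Integer seed.
#' @param wave Wave label for panel input.
#' @param indexSets Optional list (one element per drop proportion, in
#'   `dropGrid` order) of lists of row-index vectors, overriding the
#'   random draws.
#' @return A `csResult`: list with `cs` (named per metric), `table`
#'   (data.frame: drop proportion, metric, mean correlation, share above
#'   threshold, replicates used), `threshold`, `prob`, `dropGrid`, `B`.
#' @export
caseDropCS <- function(data, centralityFn, dropGrid = seq(0.1, 0.75, by = 0.05),
                       B = 1000, threshold = 0.70, prob = 0.95, seed = 1L,
                       wave = NULL, indexSets = NULL) {
  X <- if (inherits(data, "panelData")) waveMatrix(data, wave) else
    as.matrix(data)
  n <- nrow(X)
  p <- ncol(X)
  if ((1 - max(dropGrid)) * n < 3 * p)
    warnf("largest drop proportion leaves %d subjects (< 3p = %d)",
          floor((1 - max(dropGrid)) * n), 3 * p)
  full <- asMetricMatrix(centralityFn(X))
  metrics <- colnames(full)
  if (is.null(indexSets))
    indexSets <- withSeed(seed, lapply(dropGrid, function(q) {
      m <- max(3, round((1 - q) * n))
      lapply(seq_len(B), function(b) sample.int(n, m, replace = FALSE))
    }))
  stopifnot(length(indexSets) == length(dropGrid))
  tab <- NULL
  skipped <- 0
  cors <- array(NA_real_, c(length(dropGrid), length(indexSets[[1]]),
                            length(metrics)))
  for (qi in seq_along(dropGrid)) {
    for (b in seq_along(indexSets[[qi]])) {
      sub <- tryCatch(
        asMetricMatrix(centralityFn(X[indexSets[[qi]][[b]], , drop = FALSE])),
        error = function(e) NULL)
      if (is.null(sub)) { skipped <- skipped + 1; next }
      for (m in seq_along(metrics)) {
        if (sd(sub[, m]) == 0 || sd(full[, m]) == 0) {
          skipped <- skipped + 1
          next
        }
        cors[qi, b, m] <- cor(full[, m], sub[, m])
      }
    }
  }
  if (skipped > 0)
    warnf("%d subsample replicate(s) skipped (estimation failure or constant centrality)", skipped)
  cs <- setNames(numeric(length(metrics)), metrics)
  rows <- list()
  for (m in seq_along(metrics)) {
    shares <- numeric(length(dropGrid))
    for (qi in seq_along(dropGrid)) {
      v <- cors[qi, , m]
      v <- v[!is.na(v)]
      shares[qi] <- if (length(v)) mean(v >= threshold) else 0
      rows[[length(rows) + 1]] <- data.frame(
        drop = dropGrid[qi], metric = metrics[m],
        meanCor = if (length(v)) mean(v) else NA_real_,
        shareAbove = shares[qi], used = length(v),
        stringsAsFactors = FALSE)
    }
    okq <- dropGrid[shares >= prob]
    cs[m] <- if (length(okq)) max(okq) else 0
  }
  structure(list(cs = cs, table = do.call(rbind, rows),
                 threshold = threshold, prob = prob, dropGrid = dropGrid,
                 B = length(indexSets[[1]]), skipped = skipped),
            class = "csResult")
}

asMetricMatrix <- function(v) {
  if (is.matrix(v)) return(v)
  matrix(v, ncol = 1, dimnames = list(names(v), "centrality"))
}

#' @export
print.csResult <- function(x, ...) {
  cat("csResult (case-dropping bootstrap, B =", x$B, ")\n")
  for (m in names(x$cs))
    cat(sprintf("  CS(%s) = %.2f [%s]\n", m, x$cs[m],
                if (x$cs[m] >= 0.25) "stable" else "unstable"))
  invisible(x)
}

#' Strength + expected-influence centrality recipe
#'
#' Builds a centrality function for [caseDropCS()]: estimates a network on
#' the given matrix and returns both strength and expected influence.
#'
#' @param estimator A network-estimation recipe, e.g. [ggmEstimator()].
#' @return Function `X -> node x metric matrix`.
#' @export
ggmCentrality <- function(estimator = ggmEstimator()) {
  force(estimator)
  function(X) {
    W <- estimator(X)
    cbind(strength = strengthCentrality(W),
          expectedInfluence = expectedInfluence(W))
  }
}
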