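# Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic fold assignment for cross-validation. Uses a private RNG
# stream so callers' seeds are not disturbed.
makeFolds <- function(n, k, seed) {
  stopifnot(n >= k, k >= 2)
  withSeed(seed, sample(rep(seq_len(k), length.out = n)))
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stage label; stays < 2^31.
childSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}

upperTri <- function(M) M[upper.tri(M)]

edgeNames <- function(nodes) {
  idx <- which(upper.tri(diag(length(nodes))), arr.ind = TRUE)
  paste(nodes[idx[, 1]], nodes[idx[, 2]], sep = "--")
}

isWholeNumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

zstandardize <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  if (any(s == 0)) stopf("constant column(s): %s",
                         paste(colnames(X)[s == 0], collapse = ", "))
  scale(X, center = mu, scale = s)
}
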