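# Independent oracles used across the suite. These deliberately use the
# slowest, most transparent formulation of each quantity (recursion, dense
# linear algebra) and never call the code paths they check.

# Random sorted pedigree: first n_founders have unknown parents, every later
# animal draws two distinct earlier animals as parents.
rand_pedigree <- function(n, n_founders = 10L, seed = 1L) {
  set.seed(seed)
  sire <- dam <- integer(n)
  for (i in (n_founders + 1L):n) {
    p <- sample.int(i - 1L, 2L)
    sire[i] <- p[1L]; dam[i] <- p[2L]
  }
  list(sire = sire, dam = dam)
}

# Recursive coancestry with memoisation; A_ij = 2 f(i, j).
kinship_oracle_A <- function(sire, dam) {
  n <- length(sire)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    key <- paste0(i, "_", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) 0.5 * (1 + f(sire[i], dam[i]))
           else 0.5 * (f(sire[i], j) + f(dam[i], j))
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    A[i, j] <- A[j, i] <- 2 * f(i, j)
  }
  A
}

# Dense multi-trait GLS/BLUP oracle. y is n x t with NA for missing records;
# K the (any) relationship matrix; G0/R0 trait covariance matrices. Fixed
# effects are per-trait means. Returns beta and the full n x t matrix of
# BLUPs (animals without records predicted through relationships).
gls_blup_oracle <- function(y, K, G0, R0) {
  n <- nrow(y); t_ <- ncol(y)
  obs <- which(!is.na(y), arr.ind = TRUE)
  no <- nrow(obs)
  yv <- y[obs]
  V <- matrix(0, no, no)
  for (a in seq_len(no)) for (b in seq_len(no)) {
    ia <- obs[a, 1L]; ta <- obs[a, 2L]
    ib <- obs[b, 1L]; tb <- obs[b, 2L]
    V[a, b] <- G0[ta, tb] * K[ia, ib] + (if (ia == ib) R0[ta, tb] else 0)
  }
  X <- matrix(0, no, t_)
  X[cbind(seq_len(no), obs[, 2L])] <- 1
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% yv)
  resid <- yv - X %*% beta
  # Cov(u[i, t], y_obs[b]) = G0[t, tb] * K[i, ib]
  U <- matrix(0, n, t_)
  for (tr in seq_len(t_)) {
    C <- matrix(0, n, no)
    for (b in seq_len(no))
      C[, b] <- G0[tr, obs[b, 2L]] * K[, obs[b, 1L]]
    U[, tr] <- C %*% Vi %*% resid
  }
  list(beta = drop(beta), u = U)
}

# Small flock fixture shared across files (built once per test run).
tiny_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_test_population(seed = 42L)
    cache
  }
})
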