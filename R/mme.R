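#' Solve the multi-trait mixed-model equations
#'
#' Best linear unbiased prediction for the animal model
#' `y_t = mu_t + u_t + e_t` with per-trait means as the only fixed effects
#' and the animal effect covariance `K (x) G0` (Kronecker), where K is the
#' relationship matrix whose inverse is supplied (pedigree A-inverse for
#' PBLUP, H-inverse for single-step GBLUP). Residual covariance `R0` is
#' diagonal (residuals uncorrelated across traits). Animals without records
#' receive breeding values through relationships. The system is solved with
#' a Jacobi-preconditioned conjugate-gradient iteration on the full MME.
#'
#' @param y n x t matrix of phenotypes, `NA` for missing records; rows in the
#'   order of `K_inv`.
#' @param K_inv Sparse inverse relationship matrix (n x n), e.g. from
#'   [build_A_inverse()] or [build_H_inverse()].
#' @param G0 t x t additive genetic covariance matrix between traits.
#' @param R0 t x t diagonal residual covariance matrix.
#' @param correction Optional dense genomic correction
#'   (`G_blended^-1 - A22^-1`) applied on `geno_idx` (the single-step
#'   sparse-plus-dense form from `build_H_inverse(..., parts = TRUE)`).
#' @param geno_idx Positions of the genotyped animals for `correction`.
#' @param tol Relative-residual convergence tolerance (default 1e-8).
#' @param maxit Maximum conjugate-gradient iterations (default 5000).
#' @return List with `beta` (per-trait means), `u` (n x t matrix of EBVs),
#'   `iterations`, and `converged`.
#' @export
solve_mme <- function(y, K_inv, G0, R0, correction = NULL,
                      geno_idx = integer(0), tol = 1e-8, maxit = 5000L) {
  y <- as.matrix(y)
  n <- nrow(y); t_ <- ncol(y)
  stopifnot(nrow(K_inv) == n, nrow(G0) == t_, nrow(R0) == t_)
  obs <- !is.na(y)
  n_obs <- colSums(obs)
  if (any(n_obs == 0L))
    stop("no phenotypes for at least one trait: fixed means undefined")
  G0i <- solve(G0)
  r <- diag(R0)
  if (any(r <= 0)) stop("residual variances must be positive")
  # unknown ordering: beta (t), then u with trait index fastest:
  # position of u[i, tr] = t_ + (i - 1) * t_ + tr
  ntot <- t_ + n * t_
  u_pos <- function(i, tr) t_ + (i - 1L) * t_ + tr
  rhs <- numeric(ntot)
  for (tr in seq_len(t_)) {
    o <- which(obs[, tr])
    rhs[tr] <- sum(y[o, tr]) / r[tr]
    rhs[u_pos(o, tr)] <- y[o, tr] / r[tr]
  }
  obs_num <- lapply(seq_len(t_), function(tr) which(obs[, tr]))
  has_corr <- !is.null(correction) && length(geno_idx) > 0L
  mul <- function(v) {
    out <- numeric(ntot)
    U <- matrix(v[-seq_len(t_)], n, t_, byrow = TRUE)
    # data part
    for (tr in seq_len(t_)) {
      o <- obs_num[[tr]]
      out[tr] <- (n_obs[tr] * v[tr] + sum(U[o, tr])) / r[tr]
      out[u_pos(o, tr)] <- out[u_pos(o, tr)] + (v[tr] + U[o, tr]) / r[tr]
    }
    # polygenic part: (K_inv (x) G0i) u  =  vec_t(G0i U' K_inv)
    KU <- as.matrix(K_inv %*% U) %*% G0i
    if (has_corr)
      KU[geno_idx, ] <- KU[geno_idx, ] +
        correction %*% U[geno_idx, , drop = FALSE] %*% G0i
    out[-seq_len(t_)] <- out[-seq_len(t_)] + as.numeric(t(KU))
    out
  }
  # block preconditioner: the per-animal t x t diagonal block of the LHS
  # (data diagonal + d_i * G0^-1), inverted in closed form for t = 2;
  # falls back to the plain Jacobi diagonal otherwise
  dK <- Matrix::diag(K_inv)
  if (has_corr) dK[geno_idx] <- dK[geno_idx] + diag(correction)
  dg <- numeric(ntot)
  dg[seq_len(t_)] <- n_obs / r
  for (tr in seq_len(t_)) {
    di <- dK * G0i[tr, tr]
    di[obs_num[[tr]]] <- di[obs_num[[tr]]] + 1 / r[tr]
    dg[u_pos(seq_len(n), tr)] <- di
  }
  dg[dg <= 0] <- 1
  if (t_ == 2L) {
    # closed-form 2x2 block inverse applied inside the preconditioner
    b11 <- dg[u_pos(seq_len(n), 1L)]
    b22 <- dg[u_pos(seq_len(n), 2L)]
    b12 <- dK * G0i[1L, 2L]
    det <- b11 * b22 - b12 * b12
    bad <- !is.finite(det) | det <= 0
    if (any(bad)) { b12[bad] <- 0; det[bad] <- b11[bad] * b22[bad] }
    i1 <- u_pos(seq_len(n), 1L); i2 <- u_pos(seq_len(n), 2L)
    dbeta <- dg[seq_len(t_)]
    precond <- function(res) {
      z <- numeric(ntot)
      z[seq_len(t_)] <- res[seq_len(t_)] / dbeta
      r1 <- res[i1]; r2 <- res[i2]
      z[i1] <- (b22 * r1 - b12 * r2) / det
      z[i2] <- (b11 * r2 - b12 * r1) / det
      z
    }
    sol <- pcg_solve(mul, rhs, precond, tol = tol, maxit = maxit)
  } else {
    sol <- pcg_solve(mul, rhs, dg, tol = tol, maxit = maxit)
  }
  U <- matrix(sol$x[-seq_len(t_)], n, t_, byrow = TRUE)
  list(beta = sol$x[seq_len(t_)], u = U,
       iterations = sol$iterations, converged = sol$converged)
}

## Preconditioned conjugate gradient for SPD operators. The preconditioner
## is either a positive diagonal or a function applying M^-1 to a residual.
pcg_solve <- function(mul, b, precond, tol = 1e-8, maxit = 5000L) {
  apply_prec <- if (is.function(precond)) precond else function(r) r / precond
  x <- numeric(length(b))
  r <- b
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(list(x = x, iterations = 0L, converged = TRUE))
  z <- apply_prec(r)
  p <- z
  rz <- sum(r * z)
  for (k in seq_len(maxit)) {
    Ap <- mul(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) <= tol * bnorm)
      return(list(x = x, iterations = k, converged = TRUE))
    z <- apply_prec(r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("conjugate-gradient solver did not converge in ", maxit,
       " iterations (relative residual ",
       format(sqrt(sum(r * r)) / bnorm, digits = 3), ")")
}

#' Total merit index
#'
#' Equal-weight sum of the two trait EBVs. Both traits are simulated with
#' the same genetic variance, so the raw sum is an equal-emphasis index.
#'
#' @param ebv An n x 2 matrix of EBVs, or a `solve_mme()` result.
#' @return Numeric vector of index values.
#' @export
tmi <- function(ebv) {
  if (is.list(ebv) && !is.null(ebv$u)) ebv <- ebv$u
  rowSums(ebv)
}

#' Accuracy of estimated breeding values
#'
#' Pearson correlation of true and estimated breeding values within a
#' cohort, per trait. Returns `NA` for a trait whose EBVs have zero variance
#' within the cohort.
#'
#' @param tbv,ebv Matrices (cohort x traits) of true and estimated breeding
#'   values, rows aligned.
#' @return Numeric vector of per-trait correlations.
#' @export
ebv_accuracy <- function(tbv, ebv) {
  tbv <- as.matrix(tbv); ebv <- as.matrix(ebv)
  if (nrow(tbv) < 3L) stop("cohort too small for a correlation")
  vapply(seq_len(ncol(tbv)), function(tr) {
    if (stats::sd(ebv[, tr]) == 0 || stats::sd(tbv[, tr]) == 0)
      return(NA_real_)
    stats::cor(tbv[, tr], ebv[, tr])
  }, numeric(1L))
}
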