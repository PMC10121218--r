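# Internal linear-algebra helpers shared by the phylogenetic modules.

# Symmetric inverse square root of an SPD matrix via eigendecomposition.
# Basis-stable: eigenvectors of a symmetric matrix with distinct eigenvalues
# are unique up to sign, and the symmetric square root is unique regardless.
mat_inv_sqrt <- function(C, tol = 1e-12) {
  e <- eigen(C, symmetric = TRUE)
  if (any(e$values < -tol * max(abs(e$values)))) {
    stop("matrix is not positive semi-definite")
  }
  vals <- pmax(e$values, tol * max(e$values))
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

# Solve C x = b through the Cholesky factor; errors on singular C.
chol_solve <- function(C, b) {
  U <- tryCatch(chol(C), error = function(e) stop("singular phylogenetic covariance"))
  backsolve(U, backsolve(U, b, transpose = TRUE))
}

# log determinant of an SPD matrix via Cholesky
chol_logdet <- function(C) {
  2 * sum(log(diag(chol(C))))
}

# GLS (phylogenetic) mean of each column of Y under covariance C:
# a = (1' C^-1 1)^-1 1' C^-1 Y
phylo_mean <- function(Y, C) {
  Y <- as.matrix(Y)
  one <- matrix(1, nrow(Y), 1)
  Ci1 <- chol_solve(C, one)
  drop(crossprod(Ci1, Y)) / drop(crossprod(one, Ci1))
}

# Permutation p-value with the observed statistic included in the reference set.
perm_pvalue <- function(observed, permuted) {
  (1 + sum(permuted >= observed)) / (length(permuted) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
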