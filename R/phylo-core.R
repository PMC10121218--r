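# Phylogenetic covariance machinery: Brownian-motion tip covariance,
# Pagel's lambda transformation and fitting, phylogenetic PCA, and
# multivariate phylogenetic signal (K-mult).

#' Brownian-motion tip covariance of a tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip depths (constant for an ultrametric tree).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return symmetric PSD matrix with tip labels on both margins.
#' @export
phylo_covariance <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged. `lambda = 1` is Brownian motion; `lambda = 0` removes all
#' phylogenetic covariance.
#'
#' @param C tip covariance matrix.
#' @param lambda value in `[0, 1]`.
#' @return transformed covariance matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Pagel's lambda transform of the tree itself
#'
#' Edge-wise equivalent of [lambda_transform()] for an ultrametric tree:
#' every edge is scaled by `lambda` and each terminal edge is extended so
#' tip depths (the covariance diagonal) are preserved. Used to transform
#' branch lengths before rate analyses.
#'
#' @param tree rooted ultrametric `phylo`.
#' @param lambda value in `[0, 1]`.
#' @return transformed `phylo`.
#' @export
lambda_tree <- function(tree, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  out <- tree
  out$edge.length <- tree$edge.length * lambda
  term <- match(seq_along(tree$tip.label), tree$edge[, 2])
  out$edge.length[term] <- out$edge.length[term] + (1 - lambda) * depths
  out
}

# Profiled multivariate Gaussian log-likelihood at a given lambda: traits
# independent given the tree, per-trait rates profiled out analytically.
lambda_loglik <- function(Y, C, lambda) {
  Cl <- lambda_transform(C, lambda)
  n <- nrow(Y)
  p <- ncol(Y)
  ld <- chol_logdet(Cl)
  a <- phylo_mean(Y, Cl)
  Y0 <- sweep(Y, 2, a)
  Q <- colSums(Y0 * chol_solve(Cl, Y0))
  sig <- Q / n
  sum(-0.5 * (n * log(2 * pi * sig) + ld + n))
}

#' Fit Pagel's lambda to multivariate trait data
#'
#' Maximizes the phylogenetic Gaussian likelihood over `lambda` in
#' `[1e-10, 1]` with all traits sharing one lambda and per-trait Brownian
#' rates profiled out (traits treated as independent given the tree; see
#' the methods vignette for why the full trait covariance is not estimated
#' at p close to n). The fitted model is compared with Brownian motion
#' (`lambda = 1`) by AIC on the same restricted likelihood.
#'
#' @param Y species x traits matrix, rows aligned with `tree$tip.label`.
#' @param tree rooted `phylo`.
#' @param tol optimization tolerance on lambda (default 1e-8).
#' @return list of class `lambda_fit`: `lambda`, `loglik`, `aic`,
#'   `loglik_bm`, `aic_bm`, `best_model` (`"BM"` or `"lambda"`).
#' @export
fit_lambda <- function(Y, tree, tol = 1e-8) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 4) stop("at least 4 species required")
  C <- phylo_covariance(tree)[rownames(Y), rownames(Y)]
  p <- ncol(Y)
  n <- nrow(Y)
  opt <- optimize(function(l) lambda_loglik(Y, C, l),
                  interval = c(1e-10, 1), maximum = TRUE, tol = tol)
  lam <- max(opt$maximum, 1e-10)
  ll <- opt$objective
  ll_bm <- lambda_loglik(Y, C, 1)
  # boundary check: the optimizer never evaluates the exact endpoints
  if (ll_bm > ll) {
    lam <- 1
    ll <- ll_bm
  }
  k <- 2 * p       # per-trait mean + rate
  aic_bm <- -2 * ll_bm + 2 * k
  aic <- -2 * ll + 2 * (k + 1)
  structure(list(
    lambda = lam, loglik = ll, aic = aic,
    loglik_bm = ll_bm, aic_bm = aic_bm,
    best_model = if (aic < aic_bm) "lambda" else "BM",
    n = n, p = p
  ), class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("Pagel's lambda fit: lambda = %.4f, logLik = %.2f, AIC = %.2f (BM AIC = %.2f); best: %s\n",
              x$lambda, x$loglik, x$aic, x$aic_bm, x$best_model))
  invisible(x)
}

#' Phylogenetic principal components analysis
#'
#' pPCA on the evolutionary covariance matrix: with phylogenetic mean
#' `a = (1'C^-1 1)^-1 1'C^-1 Y` and
#' `R = (Y - 1a)' C^-1 (Y - 1a) / (n - 1)` (optionally ridge-regularized),
#' scores are the centered data projected on the eigenvectors of R.
#' `mode = "ordinary"` sets `C = I`, giving standard covariance-matrix PCA.
#'
#' @param Y species x traits matrix with species rownames.
#' @param tree rooted `phylo` (ignored for `mode = "ordinary"`).
#' @param lambda Pagel's lambda applied to C before the analysis (default 1).
#' @param mode `"phylo"` or `"ordinary"`.
#' @param ridge ridge coefficient delta in `R + delta * trace(R)/p * I`
#'   expressed as a fraction (default 1e-8); 0 disables.
#' @return list of class `ppca`: `scores`, `loadings`, `eigenvalues`,
#'   `center`, `mode`.
#' @export
ppca <- function(Y, tree = NULL, lambda = 1, mode = c("phylo", "ordinary"),
                 ridge = 1e-8) {
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 3) stop("at least 3 species required")
  if (mode == "phylo") {
    C <- lambda_transform(phylo_covariance(tree)[rownames(Y), rownames(Y)], lambda)
  } else {
    C <- diag(n)
    rownames(C) <- colnames(C) <- rownames(Y)
  }
  a <- phylo_mean(Y, C)
  Y0 <- sweep(Y, 2, a)
  R <- crossprod(Y0, chol_solve(C, Y0)) / (n - 1)
  if (ridge > 0) R <- R + diag(ridge * sum(diag(R)) / ncol(R), ncol(R))
  e <- eigen(R, symmetric = TRUE)
  scores <- Y0 %*% e$vectors
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  colnames(e$vectors) <- colnames(scores)
  rownames(e$vectors) <- colnames(Y)
  structure(list(scores = scores, loadings = e$vectors,
                 eigenvalues = e$values, center = a, mode = mode),
            class = "ppca")
}

#' Multivariate phylogenetic signal (K-mult)
#'
#' Multivariate generalization of Blomberg's K: the ratio of raw to
#' phylogenetically corrected mean squared deviations from the phylogenetic
#' mean, scaled by its Brownian-motion expectation, summed across traits.
#' K is about 1 for data evolved by Brownian motion on the tree and falls
#' toward 0 when trait similarity is decoupled from the phylogeny.
#' Significance comes from permuting species across the tips.
#'
#' @param Y species x traits matrix (a single trait may be a vector) with
#'   species names, rows aligned to `tree$tip.label`.
#' @param tree rooted `phylo`.
#' @param nperm number of tip permutations (default 999).
#' @return list of class `kmult`: `K`, `p`, `nperm`, `K_perm`.
#' @export
phylo_signal_kmult <- function(Y, tree, nperm = 999) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 4) stop("at least 4 species required")
  if (all(apply(Y, 2, var) == 0)) stop("zero-variance trait data")
  C <- phylo_covariance(tree)[rownames(Y), rownames(Y)]
  Cinv_one <- chol_solve(C, matrix(1, n, 1))
  denom_expect <- (sum(diag(C)) - n / sum(Cinv_one)) / (n - 1)
  kstat <- function(Ym) {
    a <- phylo_mean(Ym, C)
    Y0 <- sweep(Ym, 2, a)
    num <- sum(Y0^2)
    den <- sum(Y0 * chol_solve(C, Y0))
    (num / den) / denom_expect
  }
  K_obs <- kstat(Y)
  K_perm <- vapply(seq_len(nperm), function(i) kstat(Y[sample(n), , drop = FALSE]),
                   numeric(1))
  structure(list(K = K_obs, p = perm_pvalue(K_obs, K_perm),
                 nperm = nperm, K_perm = K_perm),
            class = "kmult")
}

#' @export
print.kmult <- function(x, ...) {
  cat(sprintf("K-mult = %.3f, p = %.4f (%d permutations)\n", x$K, x$p, x$nperm))
  invisible(x)
}
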