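# Multivariate Brownian-motion rate estimation, group rate-ratio
# permutation tests, and branch-specific rates by phylogenetic ridge
# regression.

#' Multivariate Brownian-motion rate
#'
#' The net evolutionary rate across traits:
#' `sigma2_mult = sum_j (y_j - a_j 1)' C^-1 (y_j - a_j 1) / (N p)`, with
#' `a` the phylogenetic mean — the mean of the per-trait univariate GLS
#' rate estimates for independent traits. The covariance can be
#' lambda-transformed first (rate analyses in this package transform branch
#' lengths by the fitted lambda before estimating rates).
#'
#' @param Y species x traits matrix (vector accepted) with species
#'   rownames aligned to the tree tips.
#' @param tree rooted `phylo`.
#' @param lambda Pagel's lambda applied to the covariance (default 1).
#' @return scalar rate (JND^2 per unit branch length for color data).
#' @export
sigma2_mult <- function(Y, tree, lambda = 1) {
  Y <- as.matrix(Y)
  C <- lambda_transform(phylo_covariance(tree)[rownames(Y), rownames(Y)], lambda)
  a <- phylo_mean(Y, C)
  Y0 <- sweep(Y, 2, a)
  sum(Y0 * chol_solve(C, Y0)) / (nrow(Y) * ncol(Y))
}

#' Rate-ratio permutation test between groups
#'
#' Compares multivariate Brownian rates between groups of tips (for example
#' island vs continental species, or high- vs low-complexity species).
#' Tip deviations from the common phylogenetic mean are whitened by the
#' symmetric inverse square root of the (lambda-transformed) covariance;
#' each group's rate is its share of the whitened squared deviations
#' divided by `N_group * p`. The observed max/min rate ratio is compared
#' with a null built by permuting group labels across tips.
#'
#' @param Y species x traits matrix with species rownames.
#' @param tree rooted `phylo`.
#' @param groups factor/character vector of group labels named by species
#'   (2 or more groups, each with at least 3 tips).
#' @param nperm permutations (default 999).
#' @param lambda Pagel's lambda applied to the covariance (default 1).
#' @return list of class `rate_report`: `sigma2_overall`, `sigma2_by_group`,
#'   `ratio`, `p_perm`, `nperm`, `n_traits`.
#' @export
rate_ratio_test <- function(Y, tree, groups, nperm = 999, lambda = 1) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  p <- ncol(Y)
  groups <- groups[rownames(Y)]
  if (anyNA(groups)) stop("groups must be named by species and cover all tips")
  groups <- factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 3)) stop("every group needs at least 3 tips")
  C <- lambda_transform(phylo_covariance(tree)[rownames(Y), rownames(Y)], lambda)
  a <- phylo_mean(Y, C)
  D <- mat_inv_sqrt(C) %*% sweep(Y, 2, a)
  d2 <- rowSums(D^2)        # per-tip whitened squared deviation
  group_rates <- function(g) {
    tapply(d2, g, sum) / (table(g) * p)
  }
  obs_rates <- group_rates(groups)
  obs_ratio <- max(obs_rates) / min(obs_rates)
  perm_ratio <- vapply(seq_len(nperm), function(i) {
    r <- group_rates(groups[sample(n)])
    max(r) / min(r)
  }, numeric(1))
  structure(list(
    sigma2_overall = sum(d2) / (n * p),
    sigma2_by_group = as.numeric(obs_rates) |> setNames(names(obs_rates)),
    ratio = obs_ratio,
    p_perm = perm_pvalue(obs_ratio, perm_ratio),
    nperm = nperm,
    n_traits = p
  ), class = "rate_report")
}

#' @export
print.rate_report <- function(x, ...) {
  cat(sprintf("rate ratio test (%d traits): ratio = %.3f, p = %.4f (%d permutations)\n",
              x$n_traits, x$ratio, x$p_perm, x$nperm))
  print(round(x$sigma2_by_group, 4))
  invisible(x)
}

# tips x edges path matrix: entry = edge length when the edge lies on the
# root-to-tip path.
path_matrix <- function(tree) {
  n <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  L <- matrix(0, n, ne, dimnames = list(tree$tip.label, NULL))
  # walk rootward from each tip
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  for (i in seq_len(n)) {
    node <- i
    repeat {
      e <- match(node, child)
      if (is.na(e)) break
      L[i, e] <- tree$edge.length[e]
      node <- parent[e]
    }
  }
  L
}

#' Branch-specific rates by phylogenetic ridge regression
#'
#' Models each tip value as the sum of per-branch contributions along its
#' root-to-tip path (design matrix `L`, entries = branch lengths) and
#' solves, per trait, the ridge problem
#' `min || y - a - L b ||^2 + penalty * ||b||^2` with `a` the phylogenetic
#' mean. The scalar rate of a branch is the L2 norm of its coefficients
#' across traits, and the species-specific rate is the rate of the
#' species' terminal branch. The penalty, when not supplied, is chosen by
#' generalized cross-validation (summed across traits) on a log-spaced
#' grid.
#'
#' @param Y species x traits matrix with species rownames.
#' @param tree rooted `phylo` (lambda-transform it first if desired, see
#'   [lambda_tree()]).
#' @param penalty ridge penalty; `NULL` (default) selects by GCV.
#' @return list of class `branch_rates`: `beta` (edges x traits),
#'   `branch_rate` (per edge), `species_rate` (named per tip), `penalty`.
#' @export
species_rates_ridge <- function(Y, tree, penalty = NULL) {
  Y <- as.matrix(Y)
  ord <- tree$tip.label
  Y <- Y[ord, , drop = FALSE]
  term_edge <- match(seq_along(ord), tree$edge[, 2])
  if (any(tree$edge.length[term_edge] <= 0)) stop("zero-length terminal branch")
  C <- phylo_covariance(tree)
  a <- phylo_mean(Y, C[ord, ord])
  Y0 <- sweep(Y, 2, a)
  L <- path_matrix(tree)
  sv <- svd(L)
  UtY <- crossprod(sv$u, Y0)
  n <- nrow(Y)
  if (is.null(penalty)) {
    grid <- 10^seq(-6, 4, length.out = 60) * mean(sv$d^2)
    gcv <- vapply(grid, function(lam) {
      shrink <- sv$d^2 / (sv$d^2 + lam)
      df <- sum(shrink)
      fitted_norm2 <- colSums((shrink * UtY)^2)
      resid2 <- colSums(Y0^2) - 2 * colSums(shrink * UtY^2) + fitted_norm2
      sum(n * resid2 / (n - df)^2)
    }, numeric(1))
    penalty <- grid[which.min(gcv)]
  }
  coefs <- sv$v %*% ((sv$d / (sv$d^2 + penalty)) * UtY)
  branch_rate <- sqrt(rowSums(coefs^2))
  species_rate <- setNames(branch_rate[term_edge], ord)
  structure(list(beta = coefs, branch_rate = branch_rate,
                 species_rate = species_rate, penalty = penalty),
            class = "branch_rates")
}

#' @export
print.branch_rates <- function(x, ...) {
  cat(sprintf("branch_rates: %d branches, penalty = %.4g\n",
              length(x$branch_rate), x$penalty))
  print(summary(x$species_rate))
  invisible(x)
}
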