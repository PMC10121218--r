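# Univariate PGLS with Pagel's lambda (ML), bidirectional stepwise AIC,
# VIF diagnostics, distance-based multivariate PGLS with residual
# randomization (RRPP), and two-block phylogenetic integration (r-PLS).

# ML machinery shared by pgls_fit and fit-free callers: profile
# log-likelihood of a GLS fit at a given lambda.
pgls_profile <- function(y, X, C, lambda) {
  Cl <- lambda_transform(C, lambda)
  n <- length(y)
  U <- chol(Cl)
  Xt <- backsolve(U, X, transpose = TRUE)
  yt <- backsolve(U, y, transpose = TRUE)
  qrX <- qr(Xt)
  beta <- qr.coef(qrX, yt)
  res <- yt - Xt %*% beta
  rss <- sum(res^2)
  sig2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sig2) + chol_logdet(Cl) + n)
  list(beta = beta, rss = rss, sig2 = sig2, loglik = ll, U = U,
       Xt = Xt, yt = yt, qrX = qrX, lambda = lambda)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * C_lambda)`, with lambda
#' estimated by maximum likelihood on `[1e-10, 1]` (or fixed). Variables
#' should be z-scored beforehand when coefficients are to be read as
#' standardized effect sizes (see [zscore()]). The likelihood-based R^2 is
#' `1 - exp((2/n) (ll_null - ll_model))` with the null the intercept-only
#' PGLS (its own lambda).
#'
#' @param formula model formula.
#' @param data data frame with species rownames matching the tree tips.
#' @param tree rooted `phylo`.
#' @param lambda `NULL` (default) to estimate by ML, or a fixed value.
#' @return object of class `pgls_fit` with coefficients, SEs, t/p values,
#'   `lambda`, `loglik`, `aic`, `r2`, `n`.
#' @export
pgls_fit <- function(formula, data, tree, lambda = NULL) {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  species <- rownames(data)
  C <- phylo_covariance(tree)[species, species]
  est_lambda <- is.null(lambda)
  if (est_lambda) {
    opt <- optimize(function(l) pgls_profile(y, X, C, l)$loglik,
                    interval = c(1e-10, 1), maximum = TRUE, tol = 1e-8)
    lambda <- opt$maximum
    # the optimizer stays off the boundary; admit an interior-vs-BM tie
    if (pgls_profile(y, X, C, 1)$loglik > opt$objective) lambda <- 1
  }
  fit <- pgls_profile(y, X, C, lambda)
  n <- length(y)
  p <- ncol(X)
  XtXi <- chol2inv(qr.R(fit$qrX))
  sig2_unb <- fit$rss / (n - p)
  se <- sqrt(diag(XtXi) * sig2_unb)
  tval <- drop(fit$beta) / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  k <- p + 1 + if (est_lambda) 1 else 0    # + sigma2 (+ lambda)
  null_ll <- if (est_lambda) {
    opt0 <- optimize(function(l) pgls_profile(y, matrix(1, n, 1), C, l)$loglik,
                     interval = c(1e-10, 1), maximum = TRUE, tol = 1e-8)
    max(opt0$objective, pgls_profile(y, matrix(1, n, 1), C, 1)$loglik)
  } else {
    pgls_profile(y, matrix(1, n, 1), C, lambda)$loglik
  }
  structure(list(
    coefficients = setNames(drop(fit$beta), colnames(X)),
    se = setNames(se, colnames(X)),
    t = tval, p = setNames(pval, colnames(X)),
    lambda = lambda, lambda_estimated = est_lambda,
    loglik = fit$loglik, aic = -2 * fit$loglik + 2 * k,
    r2 = 1 - exp((2 / n) * (null_ll - fit$loglik)),
    sigma2 = fit$sig2, n = n, formula = formula,
    data = data, tree = tree
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS (lambda = %.3f%s): AIC = %.2f, R2 = %.3f, n = %d\n",
              x$lambda, if (x$lambda_estimated) ", ML" else ", fixed",
              x$aic, x$r2, x$n))
  tab <- cbind(Effect = x$coefficients, SE = x$se, t = x$t, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Sequential (type-I) F table for a PGLS fit at fixed lambda
#'
#' Terms are added in formula order on the whitened data; each F uses the
#' full-model residual mean square. With one response trait this equals the
#' single-trait distance-based PGLS F of [dpgls()].
#'
#' @param formula,data,tree as in [pgls_fit()].
#' @param lambda fixed lambda for the covariance (default 1).
#' @return data frame with df, SS, F per term.
#' @export
pgls_anova <- function(formula, data, tree, lambda = 1) {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(formula, mf)
  species <- rownames(data)
  C <- lambda_transform(phylo_covariance(tree)[species, species], lambda)
  P <- mat_inv_sqrt(C)
  seq_ss_table(P %*% matrix(y), P %*% X, attr(X, "assign"))
}

# Sequential SS decomposition of (already whitened) responses on a design,
# following the assign vector (0 = intercept).
seq_ss_table <- function(Yt, Xt, assign) {
  terms_idx <- unique(assign[assign > 0])
  n <- nrow(Yt)
  rss <- numeric(length(terms_idx) + 1)
  dfs <- numeric(length(terms_idx) + 1)
  for (k in 0:length(terms_idx)) {
    keep <- assign %in% c(0, head(terms_idx, k))
    q <- qr(Xt[, keep, drop = FALSE])
    fitted <- qr.fitted(q, Yt)
    rss[k + 1] <- sum((Yt - fitted)^2)
    dfs[k + 1] <- q$rank
  }
  ss <- -diff(rss)
  df_terms <- diff(dfs)
  df_res <- n - dfs[length(dfs)]
  ss_res <- rss[length(rss)]
  data.frame(
    term = terms_idx, df = df_terms, ss = ss,
    F = (ss / df_terms) / (ss_res / df_res),
    row.names = NULL
  )
}

#' Standardize variables to zero mean and unit variance
#'
#' @param x numeric vector or data frame (numeric columns scaled in place).
#' @return object of the same shape.
#' @export
zscore <- function(x) {
  if (is.data.frame(x)) {
    x[] <- lapply(x, function(v) if (is.numeric(v)) drop(scale(v)) else v)
    x
  } else {
    drop(scale(x))
  }
}

#' Bidirectional stepwise model selection by AIC for PGLS
#'
#' Starts from the full model over `candidates` and repeatedly applies the
#' single-term addition or deletion with the largest AIC decrease, until no
#' move lowers the AIC. Deterministic given the data; may return the
#' intercept-only model. Terms whose addition would make the design
#' rank-deficient are never added.
#'
#' @param response name of the response column in `data`.
#' @param candidates character vector of candidate predictor columns.
#' @param data data frame with species rownames.
#' @param tree rooted `phylo`.
#' @return the selected [pgls_fit()], with the move log in `$steps`.
#' @export
stepwise_aic <- function(response, candidates, data, tree) {
  if (length(candidates) < 1) stop("at least one candidate predictor required")
  make_formula <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    stats::as.formula(paste(response, "~", rhs))
  }
  fit_terms <- function(terms) {
    X <- model.matrix(make_formula(terms), data)
    if (qr(X)$rank < ncol(X)) return(NULL)   # rank guard
    pgls_fit(make_formula(terms), data, tree)
  }
  current <- candidates
  fit <- fit_terms(current)
  if (is.null(fit)) {
    # full design is rank-deficient (e.g. duplicated columns): start from a
    # maximal full-rank subset in candidate order
    current <- character(0)
    for (tm in candidates) {
      X <- model.matrix(make_formula(c(current, tm)), data)
      if (qr(X)$rank == ncol(X)) current <- c(current, tm)
    }
    fit <- fit_terms(current)
  }
  steps <- sprintf("start: AIC = %.2f", fit$aic)
  repeat {
    moves <- c(
      lapply(current, function(tm) setdiff(current, tm)),
      lapply(setdiff(candidates, current), function(tm) c(current, tm))
    )
    fits <- lapply(moves, fit_terms)
    aics <- vapply(fits, function(f) if (is.null(f)) Inf else f$aic, numeric(1))
    if (!length(aics) || min(aics) >= fit$aic) break
    best <- which.min(aics)
    current <- moves[[best]]
    fit <- fits[[best]]
    steps <- c(steps, sprintf("-> {%s}: AIC = %.2f",
                              paste(current, collapse = ", "), fit$aic))
  }
  fit$steps <- steps
  fit$terms_selected <- current
  fit
}

#' Variance inflation factors under PGLS
#'
#' For each predictor, fits a PGLS of that predictor on the remaining ones,
#' takes the likelihood-based R^2, and reports `VIF = 1 / (1 - R^2)`.
#' Perfect collinearity yields `Inf` with a warning. The conventional
#' screening threshold in comparative analyses is VIF < 5.
#'
#' @param predictors character vector (2 or more) of columns of `data`.
#' @param data data frame with species rownames.
#' @param tree rooted `phylo`.
#' @return named numeric vector of VIFs.
#' @export
vif_pgls <- function(predictors, data, tree) {
  if (length(predictors) < 2) stop("at least 2 predictors required")
  vapply(predictors, function(pj) {
    # full-rank subset of the remaining predictors, in order
    others <- character(0)
    for (tm in setdiff(predictors, pj)) {
      X <- model.matrix(stats::as.formula(paste("~", paste(c(others, tm), collapse = " + "))), data)
      if (qr(X)$rank == ncol(X)) others <- c(others, tm)
    }
    f <- stats::as.formula(paste(pj, "~", paste(others, collapse = " + ")))
    X <- model.matrix(f, data)
    if (qr(cbind(X, data[[pj]]))$rank <= qr(X)$rank) {
      warning(sprintf("predictor '%s' is perfectly collinear; VIF infinite", pj))
      return(Inf)
    }
    r2 <- pgls_fit(f, data, tree)$r2
    if (r2 >= 1 - 1e-12) {
      warning(sprintf("predictor '%s' is perfectly collinear; VIF infinite", pj))
      return(Inf)
    }
    1 / (1 - r2)
  }, numeric(1))
}

#' Distance-based phylogenetic regression (d-PGLS) with RRPP
#'
#' Multivariate regression of a species x traits block on predictors under
#' phylogenetic covariance: responses and design are whitened by the
#' symmetric inverse square root of `C_lambda`, sums of squares are
#' sequential (type-I) in formula order with SS summed across traits, and
#' `F = (SS_term / df_term) / (SS_resid / df_resid)` with the full-model
#' residual. Significance comes from randomizing reduced-model residuals
#' (RRPP): for each term, residuals of the model with all preceding terms
#' are row-permuted, added back to the reduced fitted values, and the term's
#' F recomputed; `p = (1 + #{F* >= F}) / (nperm + 1)`.
#'
#' @param formula predictors-only right side, e.g. `~ insularity + n_sympatric`.
#' @param Y species x traits matrix with species rownames.
#' @param data data frame of predictors with species rownames.
#' @param tree rooted `phylo`.
#' @param nperm permutations (default 999).
#' @param lambda Pagel's lambda for the covariance (default 1).
#' @return object of class `dpgls` with the per-term table (`df`, `SS`,
#'   `F`, `p`), `nperm`, `n_traits`, `n_species`.
#' @export
dpgls <- function(formula, Y, data, tree, nperm = 999, lambda = 1) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  X <- model.matrix(formula, data)
  assign <- attr(X, "assign")
  if (ncol(X) >= n) stop("more predictors than species")
  if (any(apply(X[, assign > 0, drop = FALSE], 2, var) == 0)) {
    stop("constant predictor")
  }
  species <- rownames(Y)
  C <- lambda_transform(phylo_covariance(tree)[species, species], lambda)
  P <- mat_inv_sqrt(C)
  Yt <- P %*% Y
  Xt <- P %*% X
  terms_idx <- unique(assign[assign > 0])
  K <- length(terms_idx)

  # nested QR fits: model k contains intercept + first k terms
  qrs <- lapply(0:K, function(k) qr(Xt[, assign %in% c(0, head(terms_idx, k)), drop = FALSE]))
  rss <- vapply(qrs, function(q) sum((Yt - qr.fitted(q, Yt))^2), numeric(1))
  dfs <- vapply(qrs, `[[`, numeric(1), "rank")
  ss <- -diff(rss)
  df_terms <- diff(dfs)
  df_res <- n - dfs[K + 1]
  F_obs <- (ss / df_terms) / (rss[K + 1] / df_res)

  term_labels <- attr(stats::terms(formula), "term.labels")
  F_perm <- matrix(NA_real_, nperm, K)
  for (it in seq_len(nperm)) {
    idx <- sample(n)
    for (k in seq_len(K)) {
      fit_red <- qr.fitted(qrs[[k]], Yt)
      Ystar <- fit_red + (Yt - fit_red)[idx, , drop = FALSE]
      rss_red <- sum((Ystar - qr.fitted(qrs[[k]], Ystar))^2)
      rss_k <- sum((Ystar - qr.fitted(qrs[[k + 1]], Ystar))^2)
      rss_full <- sum((Ystar - qr.fitted(qrs[[K + 1]], Ystar))^2)
      F_perm[it, k] <- ((rss_red - rss_k) / df_terms[k]) / (rss_full / df_res)
    }
  }
  pvals <- vapply(seq_len(K), function(k) perm_pvalue(F_obs[k], F_perm[, k]),
                  numeric(1))
  structure(list(
    table = data.frame(term = term_labels, df = df_terms, SS = ss,
                       F = F_obs, p = pvals, row.names = NULL),
    nperm = nperm, n_traits = ncol(Y), n_species = n, lambda = lambda
  ), class = "dpgls")
}

#' @export
print.dpgls <- function(x, ...) {
  cat(sprintf("d-PGLS: %d species, %d traits, %d permutations (lambda = %.3f)\n",
              x$n_species, x$n_traits, x$nperm, x$lambda))
  print(transform(x$table, SS = round(SS, 4), F = round(F, 4)))
  invisible(x)
}

#' Two-block phylogenetic integration (r-PLS)
#'
#' Measures evolutionary integration between two trait blocks measured on
#' the same species (for example male vs female plumage color): both blocks
#' are centered on their phylogenetic means and whitened by the symmetric
#' inverse square root of C, the cross-block covariance is decomposed by
#' SVD, and r-PLS is the absolute correlation of the first pair of
#' projection scores. Significance comes from permuting the species rows of
#' the second block.
#'
#' @param Y1,Y2 species x traits matrices with identical species rownames.
#' @param tree rooted `phylo`.
#' @param nperm permutations (default 999).
#' @return list of class `rpls`: `r_pls`, `p_perm`, `nperm`, `n`.
#' @export
integration_rpls <- function(Y1, Y2, tree, nperm = 999) {
  Y1 <- as.matrix(Y1); Y2 <- as.matrix(Y2)
  if (!identical(rownames(Y1), rownames(Y2))) stop("blocks must share species order")
  if (all(apply(Y1, 2, var) == 0) || all(apply(Y2, 2, var) == 0)) {
    stop("a block has zero variance")
  }
  species <- rownames(Y1)
  C <- phylo_covariance(tree)[species, species]
  P <- mat_inv_sqrt(C)
  n <- nrow(Y1)
  transform_block <- function(Y) {
    a <- phylo_mean(Y, C)
    P %*% sweep(Y, 2, a)
  }
  E1 <- transform_block(Y1)
  E2 <- transform_block(Y2)
  rstat <- function(E2m) {
    sv <- svd(crossprod(E1, E2m) / (n - 1), nu = 1, nv = 1)
    abs(drop(cor(E1 %*% sv$u, E2m %*% sv$v)))
  }
  r_obs <- rstat(E2)
  # permute rows of the whitened block: whitened residual rows are
  # exchangeable under the null, raw tip rows are not
  r_perm <- vapply(seq_len(nperm), function(i) {
    rstat(E2[sample(n), , drop = FALSE])
  }, numeric(1))
  structure(list(r_pls = r_obs, p_perm = perm_pvalue(r_obs, r_perm),
                 nperm = nperm, n = n),
            class = "rpls")
}

#' @export
print.rpls <- function(x, ...) {
  cat(sprintf("r-PLS = %.3f, p = %.4f (%d permutations, n = %d)\n",
              x$r_pls, x$p_perm, x$nperm, x$n))
  invisible(x)
}
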