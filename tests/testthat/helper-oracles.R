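# Shared fixtures and independent oracles, all built in code.

# Brownian-motion traits on a tree through the covariance Cholesky;
# independent of the package's edge-wise simulator.
sim_bm <- function(tree, p, sigma2 = 1) {
  C <- ape::vcv.phylo(tree)
  Y <- t(chol(C)) %*% matrix(rnorm(nrow(C) * p, sd = sqrt(sigma2)), nrow(C), p)
  rownames(Y) <- rownames(C)
  Y
}

# small named layouts for complexity tests
chain_layout <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  patch_layout(sprintf("p%d", seq_len(n)), A)
}

star_layout <- function(n) {
  A <- matrix(0, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1
  patch_layout(sprintf("p%d", seq_len(n)), A)
}

complete_layout <- function(n) {
  A <- matrix(1, n, n) - diag(n)
  patch_layout(sprintf("p%d", seq_len(n)), A)
}

# brute-force connected components by depth-first search on an adjacency
# matrix; independent of igraph
dfs_components <- function(A) {
  n <- nrow(A)
  seen <- rep(FALSE, n)
  comps <- 0L
  for (start in seq_len(n)) {
    if (seen[start]) next
    comps <- comps + 1L
    stack <- start
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, which(A[v, ] == 1 & !seen))
    }
  }
  comps
}

# closed-form receptor-noise-limited distance for a tetrachromat
# (numerator over receptor pairs, denominator over triples)
vo_tetra_distance <- function(Qa, Qb, e) {
  df <- log(Qa / Qb)
  pairs <- utils::combn(4, 2)
  num <- 0
  for (k in seq_len(ncol(pairs))) {
    ij <- pairs[, k]
    rest <- setdiff(1:4, ij)
    num <- num + prod(e[rest])^2 * (df[ij[2]] - df[ij[1]])^2
  }
  trips <- utils::combn(4, 3)
  den <- sum(apply(trips, 2, function(tr) prod(e[tr])^2))
  unname(sqrt(num / den))
}

# random positive quantum catches
rand_catch <- function() setNames(exp(rnorm(4, 0, 0.5)), c("u", "s", "m", "l"))

# write a long-form spectra CSV for the given patch spectra (one specimen)
write_toy_spectra_csv <- function(path, wl, patch_values, specimen = "spec1",
                                  species = "spA", sex = "male", replicate = 1) {
  df <- do.call(rbind, lapply(names(patch_values), function(p) {
    data.frame(specimen = specimen, species = species, sex = sex, patch = p,
               replicate = replicate, wavelength = wl,
               reflectance = patch_values[[p]])
  }))
  write.csv(df, path, row.names = FALSE)
  path
}

# balanced patch x species x sex dataset with known variance components
# (per coordinate)
sim_varpart_data <- function(n_patch = 12, n_species = 10, n_rep = 3,
                             v_patch = 4, v_species = 1, v_sex = 0.25,
                             v_resid = 0.5) {
  d <- expand.grid(patch = sprintf("p%02d", 1:n_patch),
                   species = sprintf("s%02d", 1:n_species),
                   sex = c("male", "female"), rep = seq_len(n_rep),
                   stringsAsFactors = FALSE)
  for (co in c("x", "y", "z")) {
    pe <- rnorm(n_patch, 0, sqrt(v_patch))
    se <- rnorm(n_species, 0, sqrt(v_species))
    xe <- rnorm(2, 0, sqrt(v_sex))
    d[[co]] <- pe[match(d$patch, unique(d$patch))] +
      se[match(d$species, unique(d$species))] +
      xe[match(d$sex, c("male", "female"))] +
      rnorm(nrow(d), 0, sqrt(v_resid))
  }
  d
}

# 3-D rigid rotation from a QR decomposition (deterministic given seed state)
random_rotation <- function(d) {
  Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
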