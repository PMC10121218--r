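# Synthetic-data generator: pure-birth trees, island-colonization regimes,
# and plumage color data with the statistical structure the analyses
# assume, plus ground truth for every recovery test.

#' Simulation configuration
#'
#' Defaults emulate the empirical study design this package is built
#' around: 22 patches, 72 species, 1-3 specimens per species, two sexes,
#' island and continental regimes with an island rate multiplier near the
#' empirically observed chromatic rate ratio (about 1.8), and sympatric
#' species counts of 1-9 on islands and 6-38 on the mainland.
#'
#' @param n_species,n_patches tree tips and plumage patches.
#' @param seed RNG seed used by [simulate_plumage_dataset()].
#' @param birth_rate pure-birth speciation rate.
#' @param island_q island/continental transition rate (symmetric, per unit
#'   branch length on the depth-1 tree).
#' @param base_rate Brownian rate sigma^2 per trait per unit time (JND^2).
#' @param island_rate_mult rate multiplier on island branch segments.
#' @param lambda Pagel's lambda used to distort the tree before simulating.
#' @param patch_offset_scale sd (JND) of fixed per-species, per-patch mean
#'   offsets; controls true intraspecific complexity.
#' @param sex_offset_sd sd (JND) of per-patch sex (dichromatism) offsets.
#' @param replicate_noise_sd sd (JND) of specimen replicate noise.
#' @param specimens_per_species range of specimens sampled per species.
#' @param sympatric_island,sympatric_mainland inclusive count ranges.
#' @param complexity_rate_coupling slope linking a species' realized c1
#'   (z-scored) to its terminal-branch rate multiplier; 0 (default)
#'   disables the coupling mode.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 72, n_patches = 22, seed = 1,
                       birth_rate = 1, island_q = 0.5,
                       base_rate = 0.2, island_rate_mult = 1.8,
                       lambda = 1, patch_offset_scale = 3,
                       sex_offset_sd = 0.5, replicate_noise_sd = 0.3,
                       specimens_per_species = c(1, 3),
                       sympatric_island = c(1, 9),
                       sympatric_mainland = c(6, 38),
                       complexity_rate_coupling = 0) {
  stopifnot(n_species >= 3, n_patches >= 2, birth_rate > 0, island_q > 0,
            base_rate > 0, island_rate_mult > 0, lambda >= 0, lambda <= 1,
            patch_offset_scale >= 0, replicate_noise_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a pure-birth ultrametric tree
#'
#' @param n number of tips (>= 3).
#' @param birth_rate speciation rate.
#' @param seed optional RNG seed.
#' @return ultrametric `phylo`, depth rescaled to 1, tips `sp01`, `sp02`, ...
#' @export
simulate_tree <- function(n, birth_rate = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 3) stop("need at least 3 tips")
  tree <- ape::rphylo(n, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%02d", seq_len(n))
  tree
}

#' Simulate island/continental regimes along a tree
#'
#' A symmetric two-state Markov chain (continental = 0, island = 1) evolves
#' along the branches from a continental root, with full jump histories so
#' each edge knows the fraction of its length spent in the island state.
#'
#' @param tree rooted `phylo`.
#' @param q transition rate (> 0, each direction).
#' @param seed optional RNG seed.
#' @return list of class `regimes`: `tip_state` (named 0/1),
#'   `edge_island_frac`, `edge_end_state`, `q`.
#' @export
simulate_regimes <- function(tree, q, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (q <= 0) stop("q must be positive")
  ntip <- length(tree$tip.label)
  node_state <- rep(NA_integer_, ntip + tree$Nnode)
  node_state[ntip + 1] <- 0L   # continental root
  edge_frac <- numeric(nrow(tree$edge))
  edge_end <- integer(nrow(tree$edge))
  for (e in edges_preorder(tree)) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    s <- node_state[parent]
    len <- tree$edge.length[e]
    t_in_island <- 0
    t <- 0
    repeat {
      wait <- rexp(1, q)
      if (t + wait >= len) {
        if (s == 1L) t_in_island <- t_in_island + (len - t)
        break
      }
      if (s == 1L) t_in_island <- t_in_island + wait
      t <- t + wait
      s <- 1L - s
    }
    node_state[child] <- s
    edge_frac[e] <- t_in_island / len
    edge_end[e] <- s
  }
  structure(list(
    tip_state = setNames(node_state[seq_len(ntip)], tree$tip.label),
    edge_island_frac = edge_frac,
    edge_end_state = edge_end,
    q = q
  ), class = "regimes")
}

# Edge indices ordered so every parent node is visited before its children.
edges_preorder <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  order(depth[tree$edge[, 1]])
}

# Simulate one BM trait along the tree with per-edge rates.
bm_along_tree <- function(tree, edge_rate) {
  ntip <- length(tree$tip.label)
  vals <- rep(NA_real_, ntip + tree$Nnode)
  vals[ntip + 1] <- 0
  for (e in edges_preorder(tree)) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    vals[child] <- vals[parent] +
      rnorm(1, 0, sqrt(edge_rate[e] * tree$edge.length[e]))
  }
  setNames(vals[seq_len(ntip)], tree$tip.label)
}

#' Simulate plumage colors with known ground truth
#'
#' Species-level chromatic coloration follows a shared 3-D Brownian process
#' on the (lambda-distorted) tree with rate `base_rate` per coordinate,
#' multiplied on island branch segments by `island_rate_mult`; luminance is
#' a 1-D analog. Each patch adds a fixed mean offset drawn once and shared
#' across species (scaled by `patch_offset_scale`; with scale 0 every patch
#' shares the species process and a single plumage region dominates), each
#' sex a per-patch
#' dichromatism offset, and each specimen replicate Gaussian measurement
#' noise. When `complexity_rate_coupling` is nonzero, per-species offset
#' scales are drawn and the terminal-branch rate is a linear function of
#' the species' realized c1, giving a known complexity-rate effect.
#'
#' @param tree `phylo` from [simulate_tree()].
#' @param regimes from [simulate_regimes()].
#' @param cfg a [sim_config()].
#' @param seed optional RNG seed.
#' @return list: `profile` (specimen x patch color table with columns
#'   specimen, species, sex, patch, x, y, z, lum), `species_colors` (true
#'   species x patch values), `truth` (tree, regimes, per-edge rates, patch
#'   offsets, config).
#' @export
simulate_colors <- function(tree, regimes, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  sp <- tree$tip.label
  tr <- lambda_tree(tree, cfg$lambda)
  edge_mult <- 1 + (cfg$island_rate_mult - 1) * regimes$edge_island_frac

  # Patch structure: unit offset directions are drawn once and shared by
  # every species (a patch main effect: the same patch tends toward the
  # same color family across the clade). A species' offsets are the shared
  # directions times its offset scale; by default all scales are equal, in
  # coupling mode they vary and drive the terminal-branch rate.
  patches <- sprintf("patch%02d", seq_len(cfg$n_patches))
  u_chrom <- matrix(rnorm(cfg$n_patches * 3), cfg$n_patches, 3,
                    dimnames = list(patches, c("x", "y", "z")))
  u_lum <- rnorm(cfg$n_patches)
  if (cfg$complexity_rate_coupling != 0) {
    offset_scale <- setNames(runif(ntip, 0.5 * cfg$patch_offset_scale,
                                   1.5 * cfg$patch_offset_scale), sp)
  } else {
    offset_scale <- setNames(rep(cfg$patch_offset_scale, ntip), sp)
  }
  offsets <- array(
    rep(u_chrom, each = ntip),
    dim = c(ntip, cfg$n_patches, 3),
    dimnames = list(sp, patches, c("x", "y", "z"))
  ) * offset_scale
  lum_offsets <- outer(offset_scale, u_lum)
  dimnames(lum_offsets) <- list(sp, patches)

  # realized per-species c1 of the offsets drives the terminal rate in
  # coupling mode
  term_edge <- match(seq_len(ntip), tr$edge[, 2])
  term_mult <- setNames(rep(1, ntip), sp)
  if (cfg$complexity_rate_coupling != 0) {
    c1_true <- vapply(sp, function(s) {
      mean(dist(offsets[s, , ]))
    }, numeric(1))
    term_mult <- 1 + cfg$complexity_rate_coupling * drop(scale(c1_true))
    term_mult <- pmax(term_mult, 0.05)
  }
  edge_rate <- cfg$base_rate * edge_mult
  edge_rate[term_edge] <- edge_rate[term_edge] * term_mult

  # shared species-level processes
  X <- vapply(1:3, function(k) bm_along_tree(tr, edge_rate), numeric(ntip))
  Lsp <- bm_along_tree(tr, edge_rate)

  sex_off <- matrix(rnorm(cfg$n_patches * 3, 0, cfg$sex_offset_sd),
                    cfg$n_patches, 3, dimnames = list(patches, c("x", "y", "z")))
  sex_off_lum <- rnorm(cfg$n_patches, 0, cfg$sex_offset_sd)

  species_colors <- do.call(rbind, lapply(sp, function(s) {
    data.frame(species = s, patch = patches,
               x = X[s, 1] + offsets[s, , "x"],
               y = X[s, 2] + offsets[s, , "y"],
               z = X[s, 3] + offsets[s, , "z"],
               lum = Lsp[s] + lum_offsets[s, ])
  }))

  n_spec <- sample(cfg$specimens_per_species[1]:cfg$specimens_per_species[2],
                   ntip, replace = TRUE)
  rows <- list()
  for (s in sp) {
    base <- species_colors[species_colors$species == s, ]
    for (i in seq_len(n_spec[match(s, sp)])) {
      sex <- if (i %% 2 == 1) "male" else "female"
      sgn <- if (sex == "male") 1 else -1
      np <- cfg$n_patches
      rows[[length(rows) + 1]] <- data.frame(
        specimen = sprintf("%s_%02d", s, i),
        species = s, sex = sex, patch = patches,
        x = base$x + sgn * sex_off[, "x"] + rnorm(np, 0, cfg$replicate_noise_sd),
        y = base$y + sgn * sex_off[, "y"] + rnorm(np, 0, cfg$replicate_noise_sd),
        z = base$z + sgn * sex_off[, "z"] + rnorm(np, 0, cfg$replicate_noise_sd),
        lum = base$lum + sgn * sex_off_lum + rnorm(np, 0, cfg$replicate_noise_sd)
      )
    }
  }
  profile <- do.call(rbind, rows)
  class(profile) <- c("color_profile", class(profile))
  list(
    profile = profile,
    species_colors = species_colors,
    truth = list(tree = tree, regimes = regimes, edge_rate = edge_rate,
                 terminal_mult = term_mult, offsets = offsets,
                 offset_scale = offset_scale, sex_offsets = sex_off,
                 config = cfg)
  )
}

#' Simulate a complete analysis-ready dataset
#'
#' One call producing everything the pipeline consumes: a tree, regimes, a
#' specimen-level color profile, and a metadata table (insularity = tip
#' regime; ln body mass; sympatric counts drawn from the regime-specific
#' ranges), all under a single RNG stream seeded from `cfg$seed` (identical
#' configurations give identical output).
#'
#' @param cfg a [sim_config()].
#' @return list: `tree`, `regimes`, `profile`, `species_colors`,
#'   `metadata`, `truth`.
#' @export
simulate_plumage_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  tree <- simulate_tree(cfg$n_species, cfg$birth_rate)
  regimes <- simulate_regimes(tree, cfg$island_q)
  colors <- simulate_colors(tree, regimes, cfg)
  island <- regimes$tip_state
  n_symp <- ifelse(
    island == 1,
    sample(cfg$sympatric_island[1]:cfg$sympatric_island[2],
           cfg$n_species, replace = TRUE),
    sample(cfg$sympatric_mainland[1]:cfg$sympatric_mainland[2],
           cfg$n_species, replace = TRUE)
  )
  metadata <- data.frame(
    species = tree$tip.label,
    insularity = as.integer(island),
    ln_body_mass = rnorm(cfg$n_species, 3.5, 0.8),  # ln grams, kingfisher-like
    n_sympatric = n_symp
  )
  c(list(tree = tree, regimes = regimes, metadata = metadata), colors)
}

#' Reconstruct reflectance spectra from target color coordinates
#'
#' Builds, for every specimen x patch in a color profile, a smooth
#' non-negative reflectance curve (a flat term plus Gaussian bumps) whose
#' visual-model image approximates the target `(x, y, z, lum)`. Used to
#' create end-to-end fixtures whose ground truth is known. Out-of-gamut
#' targets return the nearest achievable spectrum with a warning.
#'
#' @param profile a color profile data frame (columns specimen, species,
#'   sex, patch, x, y, z, lum).
#' @param vs a [visual_system()].
#' @param tol JND residual above which a target is flagged out-of-gamut
#'   (default 0.5).
#' @return list of `spectrum_set` objects (one per specimen, replicate 1)
#'   with attribute `residuals` (per-row JND round-trip error).
#' @export
colors_to_spectra <- function(profile, vs, tol = 0.5) {
  wl <- vs$wavelengths
  basis <- cbind(
    flat = rep(1, length(wl)),
    vapply(seq(320, 680, length.out = 6),
           function(p) exp(-0.5 * ((wl - p) / 60)^2), numeric(length(wl)))
  )
  solve_one <- function(target) {
    objective <- function(w) {
      R <- drop(basis %*% w)
      Q <- quantum_catch(R, vs)
      xyz <- to_xyz(Q, vs)
      sum((xyz - target[1:3])^2) + (luminance_jnd(Q[["dbl"]], vs) - target[4])^2
    }
    w0 <- c(0.3, rep(0.01, ncol(basis) - 1))
    fit <- optim(w0, objective, method = "L-BFGS-B",
                 lower = rep(1e-6, ncol(basis)), upper = rep(20, ncol(basis)))
    list(R = drop(basis %*% fit$par), resid = sqrt(fit$value))
  }
  resids <- numeric(nrow(profile))
  specs <- lapply(split(seq_len(nrow(profile)), profile$specimen), function(idx) {
    R <- t(vapply(idx, function(i) {
      sol <- solve_one(as.numeric(profile[i, c("x", "y", "z", "lum")]))
      resids[i] <<- sol$resid
      sol$R
    }, numeric(length(wl))))
    rownames(R) <- profile$patch[idx]
    new_spectrum_set(profile$specimen[idx[1]], profile$species[idx[1]],
                     profile$sex[idx[1]], R, 1L)
  })
  if (any(resids > tol)) {
    warning(sprintf("%d target(s) out of gamut (residual > %g JND); nearest achievable returned",
                    sum(resids > tol), tol))
  }
  attr(specs, "residuals") <- resids
  specs
}
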