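# Synthetic-data generator: trees, regimes, colors, spectra inversion.

test_that("simulated trees are ultrametric, depth-1, and seed-deterministic", {
  t1 <- simulate_tree(72, 1, seed = 7)
  expect_identical(ape::Ntip(t1), 72L)
  depths <- ape::node.depth.edgelength(t1)[1:72]
  expect_lt(diff(range(depths)), 1e-9)
  expect_equal(max(depths), 1, tolerance = 1e-12)
  t2 <- simulate_tree(72, 1, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(simulate_tree(2, 1), "at least 3")
})

test_that("regimes follow the two-state Markov chain limits", {
  tr <- simulate_tree(40, 1, seed = 8)
  # vanishing transition rate: everything stays continental
  r0 <- simulate_regimes(tr, q = 1e-9, seed = 1)
  expect_true(all(r0$tip_state == 0))
  expect_true(all(r0$edge_island_frac == 0))
  # large rate: tip island fraction near the stationary 1/2
  set.seed(9)
  frac <- mean(replicate(60, mean(simulate_regimes(tr, q = 60)$tip_state)))
  expect_equal(frac, 0.5, tolerance = 0.05)
  # island fraction of each edge lies in [0, 1]
  r <- simulate_regimes(tr, q = 2, seed = 10)
  expect_true(all(r$edge_island_frac >= 0 & r$edge_island_frac <= 1))
  expect_error(simulate_regimes(tr, q = 0), "positive")
})

test_that("color generator honours its degenerate configurations", {
  cfg0 <- sim_config(n_species = 10, n_patches = 6, seed = 3,
                     replicate_noise_sd = 0, sex_offset_sd = 0)
  sim0 <- simulate_plumage_dataset(cfg0)
  # replicate noise 0 and no sex effect: all specimens of a species identical
  sp1 <- sim0$profile[sim0$profile$species == sim0$tree$tip.label[1], ]
  for (co in c("x", "y", "z", "lum")) {
    spread <- tapply(sp1[[co]], sp1$patch, function(v) diff(range(v)))
    expect_true(all(spread == 0))
  }

  # offset scale 0: every patch shares the species process; c3 = 1
  cfgc <- sim_config(n_species = 8, n_patches = 6, seed = 4,
                     patch_offset_scale = 0, replicate_noise_sd = 0,
                     sex_offset_sd = 0)
  simc <- simulate_plumage_dataset(cfgc)
  lay <- chain_layout(6)
  lay$patch_names <- sprintf("patch%02d", 1:6)
  dimnames(lay$adjacency) <- list(lay$patch_names, lay$patch_names)
  cx <- plumage_complexity(simc$profile, lay)
  expect_true(all(cx$c3 == 1))
  expect_true(all(cx$c1 == 0))
})

test_that("identical configurations give identical datasets", {
  cfg <- sim_config(n_species = 10, n_patches = 5, seed = 11)
  s1 <- simulate_plumage_dataset(cfg)
  s2 <- simulate_plumage_dataset(cfg)
  expect_identical(s1$profile, s2$profile)
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
})

test_that("metadata matches the stated study design", {
  cfg <- sim_config(n_species = 40, seed = 12)
  sim <- simulate_plumage_dataset(cfg)
  md <- sim$metadata
  isl <- md$insularity == 1
  expect_true(all(md$n_sympatric[isl] >= 1 & md$n_sympatric[isl] <= 9))
  expect_true(all(md$n_sympatric[!isl] >= 6 & md$n_sympatric[!isl] <= 38))
  expect_identical(md$species, sim$tree$tip.label)
  expect_identical(md$insularity, as.integer(sim$regimes$tip_state))
})

test_that("complexity-rate coupling raises terminal rates of complex species", {
  cfg <- sim_config(n_species = 30, n_patches = 8, seed = 13,
                    complexity_rate_coupling = 0.5)
  sim <- simulate_plumage_dataset(cfg)
  tm <- sim$truth$terminal_mult
  sc <- sim$truth$offset_scale
  expect_gt(cor(tm, sc), 0.3)  # larger offsets -> faster terminal branches
})

test_that("spectra reconstructed from colors round-trip through the visual model", {
  vs <- visual_system()
  # in-gamut targets: images of actual non-negative basis combinations
  set.seed(14)
  wl <- vs$wavelengths
  basis <- cbind(rep(1, length(wl)),
                 vapply(seq(320, 680, length.out = 6),
                        function(p) exp(-0.5 * ((wl - p) / 60)^2), numeric(length(wl))))
  targets <- t(replicate(4, {
    w <- runif(7, 0.01, 0.6)
    Q <- quantum_catch(drop(basis %*% w), vs)
    c(to_xyz(Q, vs), luminance_jnd(Q[["dbl"]], vs))
  }))
  prof <- data.frame(specimen = "s1", species = "spA", sex = "male",
                     patch = sprintf("patch%02d", 1:4),
                     x = targets[, 1], y = targets[, 2], z = targets[, 3],
                     lum = targets[, 4])
  specs <- colors_to_spectra(prof, vs)
  expect_true(all(attr(specs, "residuals") < 0.5))
  expect_true(all(specs[[1]]$reflectance >= 0))
  # flat-spectrum target recovers a near-flat reflectance
  Qf <- quantum_catch(rep(0.4, length(wl)), vs)
  pf <- data.frame(specimen = "s2", species = "spA", sex = "male", patch = "patch01",
                   x = to_xyz(Qf, vs)[1], y = to_xyz(Qf, vs)[2], z = to_xyz(Qf, vs)[3],
                   lum = luminance_jnd(Qf[["dbl"]], vs))
  sf <- colors_to_spectra(pf, vs)
  expect_lt(attr(sf, "residuals")[1], 0.5)
})

test_that("generated data pass the full pipeline end-to-end", {
  cfg <- sim_config(n_species = 16, n_patches = 6, seed = 15)
  sim <- simulate_plumage_dataset(cfg)
  lay <- chain_layout(6)
  lay$patch_names <- sprintf("patch%02d", 1:6)
  dimnames(lay$adjacency) <- list(lay$patch_names, lay$patch_names)
  cx <- plumage_complexity(sim$profile, lay)
  expect_identical(nrow(cx), 16L)
  # species-level trait block: per-patch coordinates flattened
  sc <- sim$species_colors
  Y <- do.call(rbind, lapply(split(sc, sc$species), function(d) {
    as.numeric(t(as.matrix(d[c("x", "y", "z")])))
  }))
  Y <- Y[sim$tree$tip.label, ]
  g <- setNames(ifelse(sim$regimes$tip_state == 1, "island", "continent"),
                sim$tree$tip.label)
  if (min(table(g)) >= 3) {
    rr <- rate_ratio_test(Y, sim$tree, g, nperm = 49)
    expect_gte(rr$ratio, 1)
  }
  d <- data.frame(c1 = cx$c1[match(sim$tree$tip.label, cx$species)],
                  insularity = sim$metadata$insularity,
                  ln_mass = sim$metadata$ln_body_mass,
                  rate = drop(scale(species_rates_ridge(Y, sim$tree)$species_rate)))
  rownames(d) <- sim$tree$tip.label
  d[c("c1", "insularity", "ln_mass")] <- zscore(d[c("c1", "insularity", "ln_mass")])
  fit <- pgls_fit(rate ~ c1 + insularity + ln_mass, d, sim$tree)
  expect_true(is.finite(fit$aic))
  expect_identical(fit$n, 16L)
})
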