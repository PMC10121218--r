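# Plumage-complexity metrics c1, c2, c3 and binary complexity groups.

test_that("mean interpatch distance averages the lower triangle", {
  same <- matrix(0, 3, 3)
  expect_equal(mean_interpatch_distance(same), 0)
  two <- matrix(c(0, 3, 3, 0), 2)
  expect_equal(mean_interpatch_distance(two), 3)
  # three collinear points at 0, 1, 2: pairwise distances 1, 2, 1
  pts <- cbind(c(0, 1, 2), 0, 0)
  expect_equal(mean_interpatch_distance(jnd_matrix(pts)), 4 / 3)
  expect_error(mean_interpatch_distance(matrix(0, 1, 1)), "2 patches")
})

test_that("color volume: convex hull in 3-D, range in 1-D, degenerate cases 0", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(color_volume(tet, "chromatic"), 1 / 6, tolerance = 1e-12)
  coplanar <- cbind(runif(8), runif(8), 1)
  expect_equal(color_volume(coplanar, "chromatic"), 0)
  expect_equal(color_volume(c(2, 5, 9), "achromatic"), 7)
  expect_equal(color_volume(rbind(tet, tet), "chromatic"), 1 / 6, tolerance = 1e-12)
})

test_that("convex hull volume matches a Monte Carlo oracle on random clouds", {
  set.seed(31)
  for (i in 1:5) {
    pts <- matrix(rnorm(3 * 15), ncol = 3)
    vol <- color_volume(pts, "chromatic")
    # membership oracle: a point is in the hull iff adding it leaves the
    # volume unchanged; integrate over the bounding box
    lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
    box <- prod(hi - lo)
    probe <- matrix(runif(3 * 4000, lo, hi), ncol = 3, byrow = TRUE)
    inside <- vapply(seq_len(nrow(probe)), function(k) {
      isTRUE(all.equal(color_volume(rbind(pts, probe[k, ]), "chromatic"), vol,
                       tolerance = 1e-9))
    }, logical(1))
    expect_equal(vol, box * mean(inside), tolerance = 0.15)
  }
})

test_that("contiguous patch count merges adjacent indistinguishable patches", {
  lay <- chain_layout(4)
  # only (1,2) and (3,4) below threshold: two regions
  D <- matrix(5, 4, 4, dimnames = list(lay$patch_names, lay$patch_names))
  diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0.5
  D[3, 4] <- D[4, 3] <- 0.5
  expect_identical(contiguous_patch_count(D, lay), 2L)

  # all pairs indistinguishable on a connected layout: one region
  D1 <- matrix(0.1, 4, 4, dimnames = dimnames(D)); diag(D1) <- 0
  expect_identical(contiguous_patch_count(D1, lay), 1L)

  # everything distinct: one region per patch (22 on the default layout)
  lay22 <- default_patch_layout()
  D22 <- matrix(5, 22, 22, dimnames = list(lay22$patch_names, lay22$patch_names))
  diag(D22) <- 0
  expect_identical(contiguous_patch_count(D22, lay22), 22L)

  # tie at exactly JND = 1 counts as distinguishable
  Dt <- matrix(1, 4, 4, dimnames = dimnames(D)); diag(Dt) <- 0
  expect_identical(contiguous_patch_count(Dt, lay, threshold = 1), 4L)
})

test_that("c3 is monotone non-increasing in the threshold", {
  set.seed(32)
  lay <- chain_layout(6)
  D <- as.matrix(dist(matrix(rnorm(6 * 3), 6)))
  dimnames(D) <- list(lay$patch_names, lay$patch_names)
  counts <- vapply(c(0.25, 0.5, 1, 2, 4, 8),
                   function(th) contiguous_patch_count(D, lay, th), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("c1 and c2 are invariant to rigid rotation of the coordinates", {
  set.seed(33)
  pts <- matrix(rnorm(3 * 10), ncol = 3)
  R <- random_rotation(3)
  expect_equal(mean_interpatch_distance(jnd_matrix(pts)),
               mean_interpatch_distance(jnd_matrix(pts %*% R)), tolerance = 1e-10)
  expect_equal(color_volume(pts, "chromatic"), color_volume(pts %*% R, "chromatic"),
               tolerance = 1e-9)
})

test_that("folded vs spread wing differ only through the adjacency", {
  set.seed(34)
  folded <- default_patch_layout("folded")
  spread <- default_patch_layout("spread")
  pts <- matrix(rnorm(22 * 3, sd = 0.6), ncol = 3)
  rownames(pts) <- folded$patch_names
  D <- jnd_matrix(pts)
  c3_f <- contiguous_patch_count(D, folded)
  c3_s <- contiguous_patch_count(D, spread)
  expect_gte(c3_s, c3_f)  # fewer contacts can only split regions
  # with the folded adjacency substituted in, counts coincide
  relabeled <- patch_layout(spread$patch_names, folded$adjacency, wing = "spread")
  expect_identical(contiguous_patch_count(D, relabeled), c3_f)
})

test_that("binary complexity is the exhaustive 1-D two-means split", {
  x <- setNames(c(1, 1, 1, 10, 10), letters[1:5])
  g <- binary_complexity(x)
  expect_identical(as.character(g), c("low", "low", "low", "high", "high"))
  g2 <- binary_complexity(c(a = 0, b = 10))
  expect_identical(as.character(g2), c("low", "high"))
  expect_error(binary_complexity(rep(3, 4)), "identical")
  # agreement with an exhaustive split search on random data
  set.seed(35)
  for (i in 1:10) {
    v <- rnorm(12)
    g3 <- binary_complexity(v)
    # oracle: best of all 2-partitions respecting sorted order
    ord <- order(v); vs <- v[ord]
    wss <- vapply(1:11, function(k) {
      sum((vs[1:k] - mean(vs[1:k]))^2) + sum((vs[(k + 1):12] - mean(vs[(k + 1):12]))^2)
    }, numeric(1))
    k <- which.min(wss)
    expect_identical(sum(g3 == "high"), 12L - k)
    expect_true(min(v[g3 == "high"]) > max(v[g3 == "low"]))
  }
})

test_that("species matrices average specimens and drive the complexity table", {
  set.seed(36)
  lay <- chain_layout(4)
  # two specimens of one species with different patch colors
  mk <- function(id, shift) data.frame(
    specimen = id, species = "spA", sex = "male",
    patch = lay$patch_names,
    x = c(0, 0.1, 3, 3.1) + shift, y = 0, z = 0,
    lum = c(10, 10.2, 20, 20.2) + shift
  )
  prof <- rbind(mk("s1", 0), mk("s2", 0.2))
  mats <- species_jnd_matrices(prof, lay)
  D1 <- jnd_matrix(`rownames<-`(as.matrix(mk("s1", 0)[c("x", "y", "z")]), lay$patch_names))
  D2 <- jnd_matrix(`rownames<-`(as.matrix(mk("s2", 0.2)[c("x", "y", "z")]), lay$patch_names))
  expect_equal(mats$spA, (D1 + D2) / 2, tolerance = 1e-12)

  tab <- plumage_complexity(prof, lay, variant = "chromatic")
  expect_identical(tab$c3, 2L)           # two regions: {p1,p2}, {p3,p4}
  tab_a <- plumage_complexity(prof, lay, variant = "achromatic")
  expect_equal(tab_a$c2, 20.3 - 10.1, tolerance = 1e-9)  # range of patch mean lum
})
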