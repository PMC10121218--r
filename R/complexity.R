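# Intraspecific plumage-complexity metrics. Working currency is a
# patch x patch perceptual-distance matrix (JND): c1 = mean interpatch
# distance; c2 = colorspace convex-hull volume (chromatic) or luminance
# range (achromatic); c3 = number of contiguous perceptually uniform
# plumage regions on the patch adjacency graph.

#' Patch-by-patch JND distance matrix
#'
#' Chromatic variant: Euclidean distances between per-patch `xyz`
#' coordinates (equal to the receptor-noise chromatic distance). Achromatic
#' variant: absolute differences of luminance JND values.
#'
#' @param coords chromatic: patches x 3 coordinate matrix with patch
#'   rownames; achromatic: named numeric vector of luminance JNDs.
#' @param variant `"chromatic"` or `"achromatic"`.
#' @return symmetric matrix with zero diagonal, patch names on both margins.
#' @export
jnd_matrix <- function(coords, variant = c("chromatic", "achromatic")) {
  variant <- match.arg(variant)
  if (variant == "chromatic") {
    m <- as.matrix(dist(as.matrix(coords)))
  } else {
    v <- as.numeric(coords)
    m <- abs(outer(v, v, "-"))
    dimnames(m) <- list(names(coords), names(coords))
  }
  m
}

#' Average per-specimen JND matrices within species
#'
#' Builds one distance matrix per specimen from a [color_profile()] and
#' averages them by species (combined sexes by default, or a single sex).
#'
#' @param profile a [color_profile()] data frame.
#' @param layout a [patch_layout()] fixing the patch order.
#' @param variant `"chromatic"` or `"achromatic"`.
#' @param sex `"both"`, `"male"` or `"female"`.
#' @return named list of patch x patch matrices, one per species.
#' @export
species_jnd_matrices <- function(profile, layout = default_patch_layout(),
                                 variant = c("chromatic", "achromatic"),
                                 sex = c("both", "male", "female")) {
  variant <- match.arg(variant)
  sex <- match.arg(sex)
  if (sex != "both") profile <- profile[profile$sex == sex, ]
  patches <- layout$patch_names
  out <- lapply(split(profile, profile$species), function(sp) {
    mats <- lapply(split(sp, sp$specimen), function(d) {
      d <- d[match(patches, d$patch), ]
      if (anyNA(d$patch)) stop("profile is missing patches present in the layout")
      if (variant == "chromatic") {
        jnd_matrix(`rownames<-`(as.matrix(d[c("x", "y", "z")]), patches), variant)
      } else {
        jnd_matrix(setNames(d$lum, patches), variant)
      }
    })
    Reduce(`+`, mats) / length(mats)
  })
  out
}

#' Mean interpatch distance (complexity metric c1)
#'
#' Mean of the strictly-lower-triangle entries of a patch distance matrix.
#'
#' @param jnd symmetric patch x patch JND matrix.
#' @return scalar c1 (JND).
#' @export
mean_interpatch_distance <- function(jnd) {
  jnd <- as.matrix(jnd)
  if (nrow(jnd) < 2) stop("at least 2 patches required")
  mean(jnd[lower.tri(jnd)])
}

#' Colorspace volume or lightness range (complexity metric c2)
#'
#' Chromatic: volume of the 3-D convex hull of the per-patch coordinates
#' (JND^3); degenerate (coplanar or fewer than 4 distinct) configurations
#' return 0. Achromatic: range (max - min) of luminance JND values.
#'
#' @param points chromatic: patches x 3 coordinate matrix; achromatic:
#'   numeric vector of luminance JNDs.
#' @param variant `"chromatic"` or `"achromatic"`.
#' @return scalar c2.
#' @export
color_volume <- function(points, variant = c("chromatic", "achromatic")) {
  variant <- match.arg(variant)
  if (variant == "achromatic") {
    v <- as.numeric(points)
    if (length(v) < 2) stop("at least 2 luminance values required")
    return(max(v) - min(v))
  }
  pts <- as.matrix(points)
  if (ncol(pts) != 3) stop("chromatic points must be 3-D")
  if (nrow(pts) < 4) return(0)
  convex_hull_volume(pts)
}

# Volume of the convex hull of 3-D points by randomized incremental
# construction (no external hull library in this stack). Degenerate inputs
# (all points within eps of a common plane) return 0. Coordinates are in
# JND, so tolerances are absolute at machine-precision scale relative to
# the point cloud's extent.
convex_hull_volume <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 4) return(0)
  scale <- max(apply(pts, 2, function(x) diff(range(x))), 1)
  eps <- 1e-10 * scale       # face-visibility tolerance
  eps_deg <- 1e-7 * scale    # degeneracy tolerance (cancellation-prone)

  # initial tetrahedron: a point pair far apart, a third far from the line,
  # a fourth far from the plane
  d01 <- as.matrix(dist(pts))
  ij <- which(d01 == max(d01), arr.ind = TRUE)[1, ]
  i1 <- ij[1]; i2 <- ij[2]
  ab <- pts[i2, ] - pts[i1, ]
  line_d <- apply(pts, 1, function(p) {
    v <- p - pts[i1, ]
    sqrt(max(sum(v * v) - sum(v * ab)^2 / sum(ab * ab), 0))
  })
  i3 <- which.max(line_d)
  if (line_d[i3] < eps_deg) return(0)  # collinear
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  nn <- sqrt(sum(nrm^2))
  if (!is.finite(nn) || nn < eps_deg^2) return(0)
  plane_d <- abs(as.vector((pts - rep(pts[i1, ], each = n)) %*% nrm)) / nn
  i4 <- which.max(plane_d)
  if (length(i4) == 0 || plane_d[i4] < eps_deg) return(0)  # coplanar

  # faces stored as vertex index triples with outward orientation relative
  # to the interior point
  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- lapply(faces, orient_face, pts = pts, interior = interior)

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    visible <- vapply(faces, function(f) {
      signed_dist(pts[p, ], pts[f[1], ], pts[f[2], ], pts[f[3], ]) > eps
    }, logical(1))
    if (!any(visible)) next
    # horizon = edges shared by exactly one visible face
    vis_faces <- faces[visible]
    edges <- do.call(rbind, lapply(vis_faces, function(f) {
      rbind(sort(f[1:2]), sort(f[2:3]), sort(f[c(1, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    faces <- faces[!visible]
    for (k in seq_len(nrow(horizon))) {
      f <- orient_face(c(horizon[k, 1], horizon[k, 2], p), pts, interior)
      faces[[length(faces) + 1]] <- f
    }
  }

  # volume as the sum of tetrahedra from the interior point
  vol <- 0
  for (f in faces) {
    vol <- vol + abs(det(rbind(
      pts[f[1], ] - interior, pts[f[2], ] - interior, pts[f[3], ] - interior
    ))) / 6
  }
  vol
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# signed distance of point x from the plane of face (a, b, c)
signed_dist <- function(x, a, b, c) {
  nrm <- cross3(b - a, c - a)
  sum(nrm * (x - a)) / sqrt(sum(nrm^2))
}

# orient a face triple so its normal points away from the interior point
orient_face <- function(f, pts, interior) {
  if (signed_dist(interior, pts[f[1], ], pts[f[2], ], pts[f[3], ]) > 0) f[c(1, 3, 2)] else f
}

#' Number of contiguous plumage regions (complexity metric c3)
#'
#' Patches are merged into one plumage region when they are both adjacent
#' on the body (`M_adj[i, j] = 1`) and perceptually indistinguishable
#' (distance strictly below `threshold` JND; a tie at exactly the threshold
#' counts as distinguishable). c3 is the number of connected components of
#' the resulting graph over all patches; isolated patches count as their
#' own region.
#'
#' @param jnd symmetric patch x patch JND matrix, same patch order as
#'   `layout`.
#' @param layout a [patch_layout()].
#' @param threshold JND threshold (default 1).
#' @return integer count in `[1, n_patches]`.
#' @export
contiguous_patch_count <- function(jnd, layout, threshold = 1) {
  jnd <- as.matrix(jnd)
  n <- length(layout$patch_names)
  if (nrow(jnd) != n) stop("distance matrix and layout patch counts differ")
  if (!is.null(rownames(jnd)) && !identical(rownames(jnd), layout$patch_names)) {
    stop("distance matrix patch order does not match the layout")
  }
  m_jnd <- (jnd < threshold) * 1      # 1 = indistinguishable
  merged <- m_jnd * layout$adjacency  # elementwise: adjacent AND indistinguishable
  diag(merged) <- 0
  g <- igraph::graph_from_adjacency_matrix(merged, mode = "undirected")
  as.integer(igraph::components(g)$no)
}

#' Binary complexity groups by exhaustive 1-D 2-means
#'
#' Deterministic two-cluster k-means in one dimension: all n-1 ordered
#' splits of the sorted values are scored by within-cluster sum of squares
#' and the global optimum taken. The cluster with the larger centroid is
#' labelled `"high"`.
#'
#' @param scores named numeric vector of per-species complexity values.
#' @return factor with levels `low`, `high`, named like `scores`.
#' @export
binary_complexity <- function(scores) {
  x <- as.numeric(scores)
  if (length(unique(x)) < 2) stop("all complexity values identical; cannot split")
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  wss <- vapply(seq_len(n - 1), function(k) {
    sum((xs[1:k] - mean(xs[1:k]))^2) + sum((xs[(k + 1):n] - mean(xs[(k + 1):n]))^2)
  }, numeric(1))
  k <- which.min(wss)
  lab <- rep("low", n)
  lab[ord[(k + 1):n]] <- "high"
  factor(setNames(lab, names(scores)), levels = c("low", "high"))
}

#' Per-species plumage complexity table
#'
#' Convenience wrapper computing c1, c2 and c3 for every species in a
#' [color_profile()], for one variant and wing configuration. Species mean
#' coordinates (for c2) use the specimen mean per patch; distance matrices
#' (c1, c3) are averaged across specimens per species before thresholding.
#'
#' @param profile a [color_profile()].
#' @param layout a [patch_layout()].
#' @param variant `"chromatic"` or `"achromatic"`.
#' @param sex `"both"`, `"male"` or `"female"`.
#' @param threshold JND threshold for c3.
#' @return data frame: species, variant, wing, c1, c2, c3.
#' @export
plumage_complexity <- function(profile, layout = default_patch_layout(),
                               variant = c("chromatic", "achromatic"),
                               sex = c("both", "male", "female"),
                               threshold = 1) {
  variant <- match.arg(variant)
  sex <- match.arg(sex)
  mats <- species_jnd_matrices(profile, layout, variant, sex)
  prof <- if (sex == "both") profile else profile[profile$sex == sex, ]
  rows <- lapply(names(mats), function(sp) {
    d <- prof[prof$species == sp, ]
    if (variant == "chromatic") {
      pts <- do.call(rbind, lapply(split(d, d$patch), function(p) {
        colMeans(as.matrix(p[c("x", "y", "z")]))
      }))
      c2 <- color_volume(pts[layout$patch_names, , drop = FALSE], variant)
    } else {
      lums <- vapply(split(d, d$patch), function(p) mean(p$lum), numeric(1))
      c2 <- color_volume(lums[layout$patch_names], variant)
    }
    data.frame(
      species = sp, variant = variant, wing = layout$wing,
      c1 = mean_interpatch_distance(mats[[sp]]),
      c2 = c2,
      c3 = contiguous_patch_count(mats[[sp]], layout, threshold)
    )
  })
  do.call(rbind, rows)
}
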