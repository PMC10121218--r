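# Readers/writers for the external formats: long/wide spectra CSV, patch
# adjacency CSV, Newick trees, species metadata; plus alignment of trees
# with trait tables.

#' Patch layout: ordered patch names plus adjacency
#'
#' @param patch_names character vector of patch names.
#' @param adjacency square symmetric 0/1 matrix, zero diagonal, rows/cols
#'   in `patch_names` order.
#' @param wing layout variant label, `"folded"` or `"spread"`.
#' @return object of class `patch_layout`.
#' @export
patch_layout <- function(patch_names, adjacency, wing = "folded") {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  n <- length(patch_names)
  stopifnot(nrow(adjacency) == n, ncol(adjacency) == n)
  if (!all(adjacency %in% c(0, 1))) stop("adjacency entries must be 0/1")
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  dimnames(adjacency) <- list(patch_names, patch_names)
  structure(list(patch_names = patch_names, adjacency = adjacency, wing = wing),
            class = "patch_layout")
}

#' @export
print.patch_layout <- function(x, ...) {
  cat(sprintf("patch_layout (%s wing): %d patches, %d adjacencies\n",
              x$wing, length(x$patch_names), sum(x$adjacency) / 2))
  invisible(x)
}

#' Default 22-patch plumage layout
#'
#' The standard 22 plumage regions scored on study skins, with body
#' adjacency for a folded-wing configuration (the wing lies over the flanks
#' and scapulars) or a spread-wing configuration (wing surfaces contact the
#' body only through the scapulars). The folded-wing graph is connected.
#'
#' @param wing `"folded"` (default) or `"spread"`.
#' @return a [patch_layout()].
#' @export
default_patch_layout <- function(wing = c("folded", "spread")) {
  wing <- match.arg(wing)
  patches <- c(
    "forehead", "lores", "crown", "ear_coverts", "nape", "chin", "throat",
    "breast", "belly", "flanks", "thigh", "vent", "undertail_coverts",
    "mantle", "scapulars", "back", "rump", "uppertail_coverts", "tail",
    "wing_coverts", "secondaries", "primaries"
  )
  edges <- list(
    c("forehead", "crown"), c("forehead", "lores"), c("lores", "ear_coverts"),
    c("lores", "chin"), c("crown", "nape"), c("crown", "ear_coverts"),
    c("ear_coverts", "throat"), c("ear_coverts", "nape"), c("chin", "throat"),
    c("throat", "breast"), c("breast", "belly"), c("breast", "flanks"),
    c("belly", "flanks"), c("belly", "vent"), c("flanks", "thigh"),
    c("thigh", "vent"), c("vent", "undertail_coverts"),
    c("undertail_coverts", "tail"), c("nape", "mantle"), c("mantle", "back"),
    c("mantle", "scapulars"), c("back", "rump"), c("back", "scapulars"),
    c("rump", "uppertail_coverts"), c("uppertail_coverts", "tail"),
    c("scapulars", "wing_coverts"), c("wing_coverts", "secondaries"),
    c("secondaries", "primaries")
  )
  folded_extra <- list(
    # the closed wing rests against the body and the tail base
    c("flanks", "wing_coverts"), c("breast", "wing_coverts"),
    c("flanks", "secondaries"), c("primaries", "uppertail_coverts")
  )
  if (wing == "folded") edges <- c(edges, folded_extra)
  A <- matrix(0, 22, 22, dimnames = list(patches, patches))
  for (e in edges) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  patch_layout(patches, A, wing = wing)
}

#' Read a patch adjacency matrix from CSV
#'
#' Square CSV with a header row and first column of patch names, cells 0/1.
#'
#' @param path CSV file.
#' @param wing layout variant label.
#' @return a [patch_layout()].
#' @export
read_adjacency <- function(path, wing = "folded") {
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  if (!identical(rownames(m), colnames(m))) {
    stop("adjacency CSV row and column names must match")
  }
  patch_layout(rownames(m), m, wing = wing)
}

#' @rdname read_adjacency
#' @param layout a [patch_layout()] to write.
#' @export
write_adjacency <- function(layout, path) {
  write.csv(layout$adjacency, path)
  invisible(path)
}

# The common wavelength grid all spectra are resampled to.
grid_nm <- function() 300:700

new_spectrum_set <- function(specimen_id, species, sex, reflectance, replicate) {
  structure(list(
    specimen_id = specimen_id,
    species = species,
    sex = sex,
    wavelengths = grid_nm(),
    reflectance = reflectance,
    replicate_index = replicate
  ), class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: specimen %s (%s, %s), replicate %d, %d patches x %d nm\n",
              x$specimen_id, x$species, x$sex, x$replicate_index,
              nrow(x$reflectance), ncol(x$reflectance)))
  invisible(x)
}

#' Read reflectance spectra from CSV
#'
#' Accepts a long table (columns specimen, species, sex, patch, replicate,
#' wavelength, reflectance) or a wide table (a `wavelength` column plus one
#' column per `specimen:patch:replicate`). Spectra are linearly interpolated
#' onto the common 1-nm 300-700 nm grid; input wavelengths outside that
#' range are dropped. Replicates are retained as separate `spectrum_set`
#' objects (averaging, when wanted, happens on reflectance in
#' [color_profile()]).
#'
#' @param path CSV file.
#' @param layout a [patch_layout()]; every patch in the file must be listed
#'   in it.
#' @return list of `spectrum_set` objects, one per specimen x replicate.
#' @export
read_spectra <- function(path, layout = default_patch_layout()) {
  df <- read.csv(path, check.names = FALSE)
  long_cols <- c("specimen", "species", "sex", "patch", "replicate",
                 "wavelength", "reflectance")
  if (all(long_cols %in% names(df))) {
    refl <- df$reflectance
    if (!is.numeric(refl)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(refl)))))
      stop(sprintf("non-numeric reflectance at row %d", bad[1]))
    }
  } else if ("wavelength" %in% names(df)) {
    # wide form: melt into the long layout; species/sex unknown
    value_cols <- setdiff(names(df), "wavelength")
    parts <- strsplit(value_cols, ":", fixed = TRUE)
    if (any(lengths(parts) != 3L)) {
      stop("wide-form columns must be named specimen:patch:replicate")
    }
    df <- do.call(rbind, lapply(seq_along(value_cols), function(i) {
      v <- df[[value_cols[i]]]
      if (!is.numeric(v)) {
        bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
        stop(sprintf("non-numeric reflectance at row %d", bad[1]))
      }
      data.frame(specimen = parts[[i]][1], species = NA_character_,
                 sex = "unknown", patch = parts[[i]][2],
                 replicate = as.integer(parts[[i]][3]),
                 wavelength = df$wavelength, reflectance = v)
    }))
  } else {
    stop("unrecognized spectra CSV layout")
  }

  unknown <- setdiff(unique(df$patch), layout$patch_names)
  if (length(unknown)) {
    stop(sprintf("unknown patch name(s): %s", paste(unknown, collapse = ", ")))
  }
  if (any(df$reflectance < 0, na.rm = TRUE)) stop("negative reflectance values")
  df <- df[df$wavelength >= 300 & df$wavelength <= 700, ]

  grid <- grid_nm()
  keys <- unique(df[c("specimen", "species", "sex", "replicate")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- df[df$specimen == k$specimen & df$replicate == k$replicate &
                (is.na(k$species) | df$species %in% k$species), ]
    patches <- intersect(layout$patch_names, unique(sub$patch))
    R <- t(vapply(patches, function(p) {
      s <- sub[sub$patch == p, ]
      if (min(s$wavelength) > 300 || max(s$wavelength) < 700) {
        stop(sprintf("spectrum for patch '%s' does not cover 300-700 nm", p))
      }
      approx(s$wavelength, s$reflectance, xout = grid, rule = 1)$y
    }, numeric(length(grid))))
    rownames(R) <- patches
    new_spectrum_set(as.character(k$specimen), as.character(k$species),
                     as.character(k$sex), R, as.integer(k$replicate))
  })
  out
}

#' Write spectra to long-form CSV
#'
#' Inverse of [read_spectra()]; values on the common grid round-trip
#' exactly.
#'
#' @param spectra list of `spectrum_set` objects.
#' @param path output CSV.
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "spectrum_set")) spectra <- list(spectra)
  rows <- lapply(spectra, function(s) {
    data.frame(
      specimen = s$specimen_id, species = s$species, sex = s$sex,
      patch = rep(rownames(s$reflectance), each = length(s$wavelengths)),
      replicate = s$replicate_index,
      wavelength = rep(s$wavelengths, nrow(s$reflectance)),
      reflectance = as.vector(t(s$reflectance))
    )
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a rooted time-calibrated tree from Newick
#'
#' Checks for branch lengths, unique tip labels, and ultrametricity within a
#' relative tolerance of 1e-6. A non-ultrametric tree is admitted with a
#' warning and `attr(tree, "ultrametric") = FALSE` (downstream analyses are
#' still permitted).
#'
#' @param path Newick file.
#' @return an [ape::read.tree()] `phylo` object, rooted.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree must have branch lengths")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  ultra <- diff(range(depths)) <= 1e-6 * max(depths)
  if (!ultra) warning("tree is not ultrametric within tolerance; flagging")
  attr(tree, "ultrametric") <- ultra
  tree
}

#' Read a species metadata table from CSV
#'
#' Columns: species, insularity (0/1), ln_body_mass, n_sympatric, and an
#' optional island_system.
#'
#' @param path CSV file.
#' @return data frame, one row per species.
#' @export
read_metadata <- function(path) {
  df <- read.csv(path)
  needed <- c("species", "insularity", "ln_body_mass", "n_sympatric")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("metadata missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$species)) stop("metadata must have one row per species")
  if (!all(df$insularity %in% c(0, 1))) stop("insularity must be 0/1")
  if (any(df$n_sympatric < 1)) stop("n_sympatric must be >= 1")
  df
}

#' Align a tree, a species trait table, and metadata
#'
#' Prunes everything to the common set of species and imposes a single
#' species ordering (the pruned tree's tip order) on all matrices handed to
#' the analysis modules. Dropped species are reported via `message()` and in
#' the returned object.
#'
#' @param tree a rooted `phylo`.
#' @param profiles species-level trait table: a matrix/data frame with
#'   species rownames, or a data frame with a `species` column.
#' @param metadata optional metadata table with a `species` column.
#' @return list of class `aligned_bundle` with elements `tree`, `Y`
#'   (species x traits matrix), `metadata`, `species`, `dropped`.
#' @export
match_data <- function(tree, profiles, metadata = NULL) {
  if (is.data.frame(profiles) && "species" %in% names(profiles)) {
    rn <- profiles$species
    Y <- as.matrix(profiles[setdiff(names(profiles), "species")])
    rownames(Y) <- rn
  } else {
    Y <- as.matrix(profiles)
    if (is.null(rownames(Y))) stop("profiles must carry species names")
  }
  sets <- list(tree = tree$tip.label, profiles = rownames(Y))
  if (!is.null(metadata)) sets$metadata <- metadata$species
  common <- Reduce(intersect, sets)
  if (length(common) == 0) stop("no species shared between tree and data")
  if (length(common) < 3) {
    message(sprintf("match_data: only %d species in the intersection; most analyses need more",
                    length(common)))
  }
  dropped <- lapply(sets, setdiff, y = common)
  n_drop <- sum(lengths(dropped))
  if (n_drop > 0) {
    message(sprintf("match_data: dropped %d name(s): %s", n_drop,
                    paste(unique(unlist(dropped)), collapse = ", ")))
  }
  tree <- ape::keep.tip(tree, common)
  ord <- tree$tip.label
  out <- list(
    tree = tree,
    Y = Y[ord, , drop = FALSE],
    metadata = if (!is.null(metadata)) metadata[match(ord, metadata$species), , drop = FALSE],
    species = ord,
    dropped = dropped
  )
  class(out) <- "aligned_bundle"
  out
}

#' @export
print.aligned_bundle <- function(x, ...) {
  cat(sprintf("aligned_bundle: %d species, %d traits, %d dropped\n",
              length(x$species), ncol(x$Y), sum(lengths(x$dropped))))
  invisible(x)
}
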