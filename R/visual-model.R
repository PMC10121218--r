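# Receptor-noise-limited avian visual model: quantum catches, chromatic
# (tetrachromatic) JND distances, perceptually uniform 3-D coordinates, and
# achromatic (double-cone) luminance JNDs.

#' Construct an avian visual system
#'
#' Bundles the spectral sensitivities of the four single cones (u, s, m, l)
#' and the double cone, an illuminant, relative cone densities, and Weber
#' fractions into a `visual_system` object used by [quantum_catch()],
#' [chromatic_distance()], [to_xyz()] and [luminance_jnd()].
#'
#' The default sensitivities are Gaussian templates for a UV-type visual
#' system (peaks at 372, 456, 544 and 609 nm for u, s, m and l, and a
#' broadband double cone), each normalized to unit area on the wavelength
#' grid so that a flat unit reflectance under a flat unit illuminant yields
#' quantum catch 1 in every channel. Users with measured sensitivity curves
#' can pass them directly via `sensitivities`.
#'
#' Channel noise follows the receptor-noise model: the standard deviation of
#' the log-catch signal in channel i is `e_i = omega_c / sqrt(eta_i)`, where
#' `eta_i` is the relative density of cone class i.
#'
#' @param wavelengths integer/numeric grid in nm, strictly increasing
#'   (default 300:700, 1-nm steps).
#' @param sensitivities optional matrix (length(wavelengths) x 4, columns
#'   u, s, m, l) of single-cone sensitivities; defaults to Gaussian templates.
#' @param dbl optional double-cone sensitivity vector; defaults to a
#'   broadband Gaussian template (peak 560 nm).
#' @param illuminant irradiance spectrum on the grid; default flat (ideal
#'   white). Chromatic and achromatic *differences* are invariant to its
#'   overall scale.
#' @param eta relative cone densities for u, s, m, l (default `c(1, 2, 2, 4)`).
#' @param omega_c chromatic Weber fraction (default 0.1).
#' @param omega_a achromatic Weber fraction (default 0.1).
#' @param lum_floor luminance floor constant subtracted on the log scale
#'   (default 0.01), so a catch equal to the floor maps to 0 luminance JND.
#' @param peaks,widths peak positions and Gaussian widths (nm) used when
#'   building default sensitivities.
#' @return an object of class `visual_system`.
#' @export
visual_system <- function(wavelengths = 300:700,
                          sensitivities = NULL,
                          dbl = NULL,
                          illuminant = NULL,
                          eta = c(u = 1, s = 2, m = 2, l = 4),
                          omega_c = 0.1,
                          omega_a = 0.1,
                          lum_floor = 0.01,
                          peaks = c(u = 372, s = 456, m = 544, l = 609),
                          widths = c(u = 30, s = 35, m = 40, l = 45)) {
  wavelengths <- as.numeric(wavelengths)
  stopifnot(length(wavelengths) > 1, all(diff(wavelengths) > 0))
  nw <- length(wavelengths)
  if (is.null(sensitivities)) {
    sensitivities <- vapply(seq_along(peaks), function(i) {
      gauss_curve(wavelengths, peaks[[i]], widths[[i]])
    }, numeric(nw))
    colnames(sensitivities) <- names(peaks)
  }
  sensitivities <- as.matrix(sensitivities)
  if (ncol(sensitivities) != 4L) stop("exactly four single-cone channels required")
  if (nrow(sensitivities) != nw) stop("sensitivities must match the wavelength grid")
  if (any(sensitivities < 0)) stop("sensitivities must be non-negative")
  if (is.null(colnames(sensitivities))) colnames(sensitivities) <- c("u", "s", "m", "l")
  if (is.null(dbl)) dbl <- gauss_curve(wavelengths, 560, 90)
  if (length(dbl) != nw || any(dbl < 0)) stop("invalid double-cone sensitivity")
  if (is.null(illuminant)) illuminant <- rep(1, nw)
  if (length(illuminant) != nw || any(illuminant < 0)) stop("invalid illuminant")
  eta <- as.numeric(eta)
  if (length(eta) != 4L || any(eta <= 0)) stop("eta must be four positive densities")
  if (omega_c <= 0 || omega_a <= 0) stop("Weber fractions must be positive")

  vs <- structure(list(
    wavelengths = wavelengths,
    S = sensitivities,
    S_dbl = as.numeric(dbl),
    illuminant = as.numeric(illuminant),
    eta = eta,
    omega_c = omega_c,
    omega_a = omega_a,
    lum_floor = lum_floor,
    # channel noise e_i = omega_c / sqrt(eta_i)
    e = omega_c / sqrt(eta)
  ), class = "visual_system")
  vs$basis <- chromatic_basis(vs)
  vs
}

# Gaussian sensitivity template normalized to unit area under the 1-step
# rectangle rule used by quantum_catch (sum over grid points * delta).
gauss_curve <- function(wl, peak, width) {
  s <- exp(-0.5 * ((wl - peak) / width)^2)
  dl <- mean(diff(wl))
  s / (sum(s) * dl)
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf(
    "visual_system: %d-point grid %g-%g nm; eta = (%s); omega_c = %g, omega_a = %g\n",
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    paste(x$eta, collapse = ", "), x$omega_c, x$omega_a
  ))
  invisible(x)
}

#' Read sensitivity or illuminant curves from CSV
#'
#' Expects a `wavelength` column plus one column per channel; curves are
#' linearly interpolated onto the target grid.
#'
#' @param path CSV file path.
#' @param wavelengths target grid (default 300:700).
#' @return matrix with one column per channel on the target grid.
#' @export
read_curves <- function(path, wavelengths = 300:700) {
  df <- read.csv(path, check.names = FALSE)
  if (!"wavelength" %in% names(df)) stop("curve CSV needs a 'wavelength' column")
  chans <- setdiff(names(df), "wavelength")
  out <- vapply(chans, function(ch) {
    approx(df$wavelength, df[[ch]], xout = wavelengths, rule = 1)$y
  }, numeric(length(wavelengths)))
  if (anyNA(out)) stop("curves do not cover the full wavelength grid")
  colnames(out) <- chans
  out
}

#' Quantum catches of a reflectance spectrum
#'
#' Integrates reflectance x illuminant x sensitivity over the wavelength grid
#' (rectangle rule, 1-nm default step):
#' `Q_i = sum_lambda R(lambda) I(lambda) S_i(lambda) dlambda`,
#' for the four single cones and the double cone.
#'
#' @param reflectance numeric vector on the grid, or a patches x wavelengths
#'   matrix (rows are spectra).
#' @param vs a [visual_system()].
#' @return named vector `(u, s, m, l, dbl)`, or a matrix with those columns
#'   when `reflectance` is a matrix.
#' @export
quantum_catch <- function(reflectance, vs) {
  stopifnot(inherits(vs, "visual_system"))
  R <- if (is.matrix(reflectance)) reflectance else matrix(reflectance, nrow = 1)
  if (ncol(R) != length(vs$wavelengths)) {
    stop("reflectance must be sampled on the visual system's wavelength grid")
  }
  if (any(R < 0)) stop("reflectance must be non-negative")
  if (any(rowSums(R) == 0)) stop("all-zero reflectance: quantum catch would be zero")
  dl <- mean(diff(vs$wavelengths))
  W <- R * rep(vs$illuminant, each = nrow(R))
  Q <- cbind(W %*% vs$S, dbl = drop(W %*% vs$S_dbl)) * dl
  colnames(Q) <- c(colnames(vs$S), "dbl")
  rownames(Q) <- rownames(R)
  if (is.matrix(reflectance)) Q else drop(Q)
}

# Noise-metric-orthonormal basis of the 3-D chromatic subspace.
# Work in whitened log-catch space g = diag(1/e_i) %*% ln Q, where the
# receptor-noise metric is Euclidean. The achromatic direction is
# w = (1/e_1, ..., 1/e_4); the chromatic subspace is its orthogonal
# complement. Basis fixed by Gram-Schmidt on the channel-difference
# directions l - m, s - (l + m)/2, u - (s + m + l)/3 (in that order), with
# signs chosen so that increasing l-catch increases the first coordinate.
chromatic_basis <- function(vs) {
  w <- 1 / vs$e
  seeds <- rbind(
    c(0, 0, -1, 1),        # l - m
    c(0, 1, -0.5, -0.5),   # s vs l/m average
    c(1, -1 / 3, -1 / 3, -1 / 3) # u vs rest
  )
  basis <- matrix(0, 4, 3)
  prev <- w / sqrt(sum(w^2))
  for (k in 1:3) {
    v <- seeds[k, ] / vs$e  # map channel direction into whitened space
    v <- v - prev %*% crossprod(prev, v)
    v <- drop(v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("degenerate chromatic basis")
    v <- v / nv
    prev <- cbind(prev, v)
    basis[, k] <- v
  }
  # sign convention: d xyz_1 / d lnQ_l > 0, d xyz_2 / d lnQ_s > 0,
  # d xyz_3 / d lnQ_u > 0
  ref <- c(4L, 2L, 1L)
  for (k in 1:3) {
    if (basis[ref[k], k] < 0) basis[, k] <- -basis[, k]
  }
  basis
}

#' Receptor-noise-limited chromatic distance (JND)
#'
#' Distance between two stimuli given their single-cone quantum catches,
#' under the receptor-noise-limited model: the log-catch contrast
#' `df_i = ln(Qa_i / Qb_i)` is projected onto the chromatic subspace (the
#' complement of the achromatic direction `(1,1,1,1)` under the noise metric
#' `diag(e_i^2)^-1`), and its norm under that metric is the distance in JND.
#'
#' @param Qa,Qb catches for the four single cones (named or in u, s, m, l
#'   order; a `dbl` entry, if present, is ignored).
#' @param vs a [visual_system()].
#' @return chromatic distance in JND units.
#' @export
chromatic_distance <- function(Qa, Qb, vs) {
  stopifnot(inherits(vs, "visual_system"))
  qa <- single_cone(Qa); qb <- single_cone(Qb)
  if (any(qa <= 0) || any(qb <= 0)) stop("quantum catches must be positive")
  df <- log(qa / qb)
  g <- df / vs$e                  # whitened contrast
  w <- 1 / vs$e
  w <- w / sqrt(sum(w^2))
  g_chrom <- g - w * sum(w * g)   # project out the achromatic direction
  sqrt(sum(g_chrom^2))
}

single_cone <- function(Q) {
  if (!is.null(names(Q)) && all(c("u", "s", "m", "l") %in% names(Q))) {
    as.numeric(Q[c("u", "s", "m", "l")])
  } else {
    as.numeric(Q)[1:4]
  }
}

#' Perceptually uniform chromatic coordinates
#'
#' Maps quantum catches to 3-D coordinates such that Euclidean distance
#' between coordinates equals [chromatic_distance()] between the stimuli
#' (both in JND units). The map projects the noise-whitened log catches onto
#' a fixed orthonormal basis of the chromatic subspace (see
#' [visual_system()] for the basis convention); coordinates are therefore
#' reproducible bit-for-bit, and any alternative valid basis differs only by
#' a rigid rotation/reflection.
#'
#' @param Q catches for the four single cones, or a matrix with columns
#'   u, s, m, l (a `dbl` column is ignored).
#' @param vs a [visual_system()].
#' @return 3-vector `(x, y, z)`, or an n x 3 matrix for matrix input.
#' @export
to_xyz <- function(Q, vs) {
  stopifnot(inherits(vs, "visual_system"))
  Qm <- if (is.matrix(Q)) Q else matrix(Q, nrow = 1, dimnames = list(NULL, names(Q)))
  if (!is.null(colnames(Qm)) && all(c("u", "s", "m", "l") %in% colnames(Qm))) {
    Qm <- Qm[, c("u", "s", "m", "l"), drop = FALSE]
  } else {
    Qm <- Qm[, 1:4, drop = FALSE]
  }
  if (any(Qm <= 0)) stop("quantum catches must be positive")
  G <- sweep(log(Qm), 2, vs$e, "/")
  out <- G %*% vs$basis
  colnames(out) <- c("x", "y", "z")
  if (is.matrix(Q)) out else setNames(drop(out), c("x", "y", "z"))
}

#' Luminance on the achromatic JND scale
#'
#' Converts a double-cone quantum catch to a scale where differences between
#' values are achromatic JNDs: `(ln Q - ln floor) / omega_a`, with the floor
#' defaulting to 0.01 and the achromatic Weber fraction to 0.1. A catch equal
#' to the floor maps to 0.
#'
#' @param Q_dbl positive double-cone catch (vectorized).
#' @param vs a [visual_system()].
#' @return luminance in JND units.
#' @export
luminance_jnd <- function(Q_dbl, vs) {
  stopifnot(inherits(vs, "visual_system"))
  if (any(Q_dbl <= 0)) stop("luminance catch must be positive")
  (log(Q_dbl) - log(vs$lum_floor)) / vs$omega_a
}

#' Per-patch color profile of spectra
#'
#' Runs the full visual model over a list of spectrum sets: replicate
#' reflectance spectra are averaged per patch per specimen *before* the
#' visual model is applied, then quantum catches, chromatic `xyz`
#' coordinates and luminance JND are computed per patch.
#'
#' @param spectra list of `spectrum_set` objects (see [read_spectra()]).
#' @param vs a [visual_system()].
#' @return data frame of class `color_profile` with columns specimen,
#'   species, sex, patch, x, y, z, lum, and the five quantum catches.
#' @export
color_profile <- function(spectra, vs) {
  if (inherits(spectra, "spectrum_set")) spectra <- list(spectra)
  key <- vapply(spectra, function(s) paste(s$specimen_id, s$species, s$sex), "")
  rows <- lapply(unique(key), function(k) {
    reps <- spectra[key == k]
    patches <- rownames(reps[[1]]$reflectance)
    R <- Reduce(`+`, lapply(reps, `[[`, "reflectance")) / length(reps)
    Q <- quantum_catch(R, vs)
    xyz <- to_xyz(Q, vs)
    data.frame(
      specimen = reps[[1]]$specimen_id,
      species = reps[[1]]$species,
      sex = reps[[1]]$sex,
      patch = patches,
      xyz,
      lum = luminance_jnd(Q[, "dbl"], vs),
      Q,
      row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("color_profile", class(out))
  out
}

#' Write a color profile to CSV
#' @param profile a [color_profile()] data frame.
#' @param path output file.
#' @export
write_color_profile <- function(profile, path) {
  write.csv(profile[c("species", "sex", "patch", "x", "y", "z", "lum")],
            path, row.names = FALSE)
  invisible(path)
}
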