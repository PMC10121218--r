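# Taxonomic variance partitioning: how much color variance lies among
# patches, between sexes, among species, and in the residual (within
# species/specimen), per clade.

#' Partition color variance among patches, sexes, and species
#'
#' Fits, per chromatic coordinate (or for a single luminance column), a
#' crossed random-effects model `value ~ 1 + (1|patch) + (1|sex) +
#' (1|species)` by REML, sums each variance component across coordinates,
#' and reports components and proportions of the total. A factor with a
#' single level within a clade has its component fixed at 0 with a warning.
#'
#' @param points data frame with columns `patch`, `sex`, `species`, and the
#'   coordinate columns in `coords` (patch-level observations, one row per
#'   specimen x patch).
#' @param coords names of the coordinate columns (default `c("x","y","z")`;
#'   use `"lum"` for the achromatic analysis).
#' @param clades optional named vector mapping species to clades; when
#'   given, the partition runs per clade.
#' @return data frame of class `variance_partition`: clade, component
#'   (patch, sex, species, residual), variance, proportion.
#' @export
partition_variance <- function(points, coords = c("x", "y", "z"), clades = NULL) {
  if (is.null(clades)) {
    clades <- setNames(rep("all", length(unique(points$species))),
                       unique(points$species))
  }
  points$clade <- clades[points$species]
  if (anyNA(points$clade)) stop("clade map does not cover all species")
  out <- do.call(rbind, lapply(split(points, points$clade), function(d) {
    factors <- c("patch", "sex", "species")
    usable <- factors[vapply(factors, function(f) length(unique(d[[f]])) > 1,
                             logical(1))]
    dropped <- setdiff(factors, usable)
    if (length(dropped)) {
      warning(sprintf("clade %s: factor(s) with one level fixed at 0: %s",
                      d$clade[1], paste(dropped, collapse = ", ")))
    }
    comps <- c(patch = 0, sex = 0, species = 0, residual = 0)
    for (co in coords) {
      comps <- comps + varcomp_one(d, co, usable)
    }
    data.frame(clade = d$clade[1],
               component = names(comps),
               variance = as.numeric(comps),
               proportion = as.numeric(comps) / sum(comps),
               row.names = NULL)
  }))
  class(out) <- c("variance_partition", class(out))
  out
}

# REML variance components of one coordinate; factors not in `usable` are
# fixed at 0.
varcomp_one <- function(d, coord, usable = c("patch", "sex", "species")) {
  usable <- usable[vapply(usable, function(f) length(unique(d[[f]])) > 1,
                          logical(1))]
  out <- c(patch = 0, sex = 0, species = 0, residual = 0)
  if (!length(usable)) {
    out["residual"] <- var(d[[coord]])
    return(out)
  }
  fml <- stats::as.formula(paste(
    coord, "~ 1 +", paste(sprintf("(1 | %s)", usable), collapse = " + ")
  ))
  fit <- suppressMessages(lme4::lmer(fml, data = d, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  for (i in seq_len(nrow(vc))) {
    grp <- vc$grp[i]
    if (grp == "Residual") out["residual"] <- out["residual"] + vc$vcov[i]
    else out[grp] <- out[grp] + vc$vcov[i]
  }
  out
}
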