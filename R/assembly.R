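#' Flora assembly analysis
#'
#' The central analysis of the package: given a dated regional phylogeny, a
#' taxonomy, a genus-to-distribution-type table and (optionally) occurrence
#' data, computes the divergence table for families, genera and species,
#' per-bin divergence counts on a fixed-width and a geological timescale,
#' the floristic-element trajectory with its HT ratio and
#' tropical-to-temperate crossover, and the endemism statistics.
#'
#' @param tree a [dated_tree()] (already pruned to the focal species list if
#'   desired; see [prune_to_taxa()]).
#' @param taxonomy a [taxonomy_map()] covering the tips.
#' @param type_table data frame `genus`, `type` (Wu types 1-15).
#' @param overrides optional override data frame (see [load_overrides()]).
#' @param occurrences optional occurrence table (`species`, `county`).
#' @param region optional [region_definition()]; required with
#'   `occurrences`.
#' @param bin_width width (My) of the fixed timescale; default 5 as in
#'   per-five-million-year divergence tables.
#' @param trajectory_width width (My) of the fixed timescale used for the
#'   element trajectory; default 10.
#' @param oldest oldest bound of the fixed scales (Mya); default 145 (base
#'   of the Cretaceous), automatically extended when the tree is older.
#' @param endemic_threshold range fraction defining endemism; default 0.9.
#' @param temperate_includes_type15 see [element_trajectory()].
#' @param skip_unclassified drop genera without a distribution type.
#' @param include_root include taxa whose stem node is missing (age taken
#'   at the root).
#' @return an object of class `flora_assembly`; see [print.flora_assembly()]
#'   and [summary.flora_assembly()]. Components: `divergence`,
#'   `assignments`, `scales` (list `fixed`, `trajectory`, `geological`),
#'   `bins` (per rank x scale), `trajectory` (list `fixed`, `geological`),
#'   `crossover_mya`, `endemism` (or NULL).
#' @export
flora_assembly <- function(tree, taxonomy, type_table, overrides = NULL,
                           occurrences = NULL, region = NULL,
                           bin_width = 5, trajectory_width = 10,
                           oldest = 145, endemic_threshold = 0.9,
                           temperate_includes_type15 = TRUE,
                           skip_unclassified = FALSE, include_root = TRUE) {
  tree <- as_dated_tree(tree)
  div <- divergence_table(tree, taxonomy)
  genera <- unique(div$name[div$rank == "genus"])
  assignments <- classify_genera(type_table, genera = genera,
                                 overrides = overrides,
                                 skip_unclassified = skip_unclassified)

  top <- max(oldest, ceiling(max(div$age_mya) / bin_width) * bin_width,
             ceiling(max(div$age_mya) / trajectory_width) * trajectory_width)
  fixed <- make_timescale("fixed", width = bin_width,
                          start = ceiling(top / bin_width) * bin_width)
  traj_scale <- make_timescale("fixed", width = trajectory_width,
                               start = ceiling(top / trajectory_width) *
                                 trajectory_width)
  geo <- extend_timescale(make_timescale("geological"),
                          oldest = ceiling(max(div$age_mya, 145)),
                          name = "Pre-Cretaceous")

  bins <- list()
  for (rk in c("family", "genus", "species")) {
    bins[[rk]] <- list(fixed = bin_counts(div, fixed, rank = rk,
                                          include_root = include_root),
                       geological = bin_counts(div, geo, rank = rk,
                                               include_root = include_root))
  }
  trajectory <- list(
    fixed = element_trajectory(div, assignments, traj_scale,
                               temperate_includes_type15 =
                                 temperate_includes_type15,
                               skip_unclassified = skip_unclassified,
                               include_root = include_root),
    geological = element_trajectory(div, assignments, geo,
                                    temperate_includes_type15 =
                                      temperate_includes_type15,
                                    skip_unclassified = skip_unclassified,
                                    include_root = include_root))
  crossover <- crossover_time(trajectory$fixed)

  endemism <- NULL
  if (!is.null(occurrences)) {
    if (is.null(region)) stop("'region' is required with 'occurrences'")
    es <- endemic_species(occurrences, region, threshold = endemic_threshold)
    conf <- genus_confinement(occurrences, taxonomy, region,
                              threshold = endemic_threshold)
    eg <- endemic_genera(assignments, conf)
    endemism <- list(
      species = es,
      genera = eg,
      species_stats = list(
        fixed = endemic_divergence_stats(div, es$species[es$endemic], fixed,
                                         rank = "species",
                                         include_root = include_root),
        geological = endemic_divergence_stats(div, es$species[es$endemic],
                                              geo, rank = "species",
                                              include_root = include_root)),
      genus_stats = if (length(eg)) list(
        fixed = endemic_divergence_stats(div, eg, fixed, rank = "genus",
                                         include_root = include_root),
        geological = endemic_divergence_stats(div, eg, geo, rank = "genus",
                                              include_root = include_root))
        else NULL)
  }

  structure(list(tree = tree, divergence = div, assignments = assignments,
                 scales = list(fixed = fixed, trajectory = traj_scale,
                               geological = geo),
                 bins = bins, trajectory = trajectory,
                 crossover_mya = crossover, endemism = endemism,
                 settings = list(bin_width = bin_width,
                                 trajectory_width = trajectory_width,
                                 endemic_threshold = endemic_threshold,
                                 temperate_includes_type15 =
                                   temperate_includes_type15,
                                 include_root = include_root)),
            class = "flora_assembly")
}

#' @export
print.flora_assembly <- function(x, ...) {
  d <- x$divergence
  cat("Flora assembly analysis\n")
  cat("  tree: ", ape::Ntip(x$tree$phylo), " species, height ",
      format(round(x$tree$height, 2)), " Mya\n", sep = "")
  cat("  taxa: ", sum(d$rank == "family"), " families, ",
      sum(d$rank == "genus"), " genera, ",
      sum(d$rank == "species"), " species\n", sep = "")
  cat("  classified genera: ", nrow(x$assignments), "\n", sep = "")
  co <- x$crossover_mya
  cat("  tropical->temperate crossover: ",
      if (is.na(co)) "none detected" else paste(format(co), "Mya"),
      "\n", sep = "")
  if (!is.null(x$endemism)) {
    cat("  endemics: ", sum(x$endemism$species$endemic), " species, ",
        length(x$endemism$genera), " genera\n", sep = "")
  }
  invisible(x)
}

#' Summarize a flora assembly analysis
#'
#' Per-geological-period divergence percentages per rank, the element
#' trajectory on the geological scale, and endemism counts.
#'
#' @param object a [flora_assembly()] result.
#' @param ... unused.
#' @return a list of class `summary.flora_assembly` with `periods` (wide
#'   table of per-period divergence percentages by rank), `trajectory`
#'   (geological element trajectory), `crossover_mya`, `endemics`.
#' @export
summary.flora_assembly <- function(object, ...) {
  keep <- object$bins$family$geological$bin != "total"
  tab <- data.frame(period = object$bins$family$geological$bin[keep])
  for (rk in c("family", "genus", "species")) {
    b <- object$bins[[rk]]$geological
    tab[[paste0(rk, "_count")]] <- b$count[keep]
    tab[[paste0(rk, "_pct")]] <- round(b$percentage[keep], 1)
  }
  out <- list(periods = tab,
              trajectory = object$trajectory$geological,
              crossover_mya = object$crossover_mya,
              endemics = if (is.null(object$endemism)) NULL else
                list(n_species = sum(object$endemism$species$endemic),
                     n_genera = length(object$endemism$genera)))
  class(out) <- "summary.flora_assembly"
  out
}

#' @export
print.summary.flora_assembly <- function(x, ...) {
  cat("Divergence by geological period (counts and % of rank total):\n")
  print(x$periods, row.names = FALSE)
  cat("\nElement trajectory (geological periods):\n")
  tr <- x$trajectory
  show <- data.frame(period = tr$bin, n = tr$n_classified,
                     H = tr$H, T = tr$T,
                     ht_ratio = round(tr$ht_ratio, 3))
  print(show, row.names = FALSE)
  cat("\nTropical->temperate crossover: ",
      if (is.na(x$crossover_mya)) "none detected"
      else paste(format(x$crossover_mya), "Mya"), "\n", sep = "")
  if (!is.null(x$endemics)) {
    cat("Endemics: ", x$endemics$n_species, " species, ",
        x$endemics$n_genera, " genera\n", sep = "")
  }
  invisible(x)
}

#' Plot a flora assembly analysis
#'
#' Two stacked panels: per-bin divergence percentage per rank on the
#' fixed-width timescale (lines), and the element trajectory with the HT
#' ratio.
#'
#' @param x a [flora_assembly()] result.
#' @param ... further arguments passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.flora_assembly <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ranks <- c("family", "genus", "species")
  b <- lapply(ranks, function(rk) {
    d <- x$bins[[rk]]$fixed
    d[d$bin != "total", ]
  })
  mid <- (b[[1]]$old_bound + b[[1]]$young_bound) / 2
  pct <- sapply(b, `[[`, "percentage")
  graphics::matplot(mid, pct, type = "l", lty = 1, lwd = 2,
                    col = c("steelblue", "grey40", "goldenrod"),
                    xlim = rev(range(mid)), xlab = "Age (Mya)",
                    ylab = "% of rank diverging", main = "Divergence", ...)
  graphics::legend("topleft", legend = ranks, lty = 1, lwd = 2,
                   col = c("steelblue", "grey40", "goldenrod"), bty = "n")
  tr <- x$trajectory$fixed
  midt <- (tr$old_bound + tr$young_bound) / 2
  graphics::plot(midt, tr$ht_ratio, type = "b", pch = 16,
                 xlim = rev(range(midt)), ylim = c(-1, 1),
                 xlab = "Age (Mya)", ylab = "HT ratio",
                 main = "Tropical vs temperate elements")
  graphics::abline(h = 0, lty = 2)
  if (!is.na(x$crossover_mya)) {
    graphics::abline(v = x$crossover_mya, col = "red3", lty = 3)
  }
  invisible(x)
}
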