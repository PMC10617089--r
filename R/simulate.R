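#' Simulate an ultrametric birth-death tree
#'
#' Constant-rate birth-death process, conditioned either on the number of
#' extant tips (via [ape::rphylo()]) or on the crown age (via
#' [ape::rbdtree()]). Draws come from the current R random stream; seed the
#' stream with `set.seed()` (or use [simulate_flora()], which seeds once
#' per run) for reproducibility.
#'
#' @param n_tips number of extant tips (mutually exclusive with
#'   `crown_age`).
#' @param crown_age crown age in Mya.
#' @param birth speciation rate, events/My/lineage.
#' @param death extinction rate; must be `< birth`.
#' @return a [dated_tree()] with tips labeled `t1, t2, ...` (relabel with
#'   [paint_taxonomy()]).
#' @export
simulate_bd_tree <- function(n_tips = NULL, crown_age = NULL,
                             birth = 0.06, death = 0.02) {
  if (death >= birth) stop("death rate must be smaller than birth rate")
  if (death < 0) stop("death rate must be >= 0")
  if (is.null(n_tips) == is.null(crown_age)) {
    stop("give exactly one of 'n_tips' or 'crown_age'")
  }
  if (!is.null(n_tips)) {
    if (n_tips < 2) stop("n_tips must be >= 2")
    phy <- ape::rphylo(n_tips, birth = birth, death = death, fossils = FALSE)
  } else {
    if (crown_age <= 0) stop("crown_age must be > 0")
    phy <- ape::rbdtree(birth = birth, death = death, Tmax = crown_age)
  }
  dated_tree(phy, allow_nonultrametric = TRUE)
}

#' Paint a nested taxonomy onto a simulated tree
#'
#' Cuts the tree at an age threshold chosen so that exactly `n_genera`
#' lineages cross it; the tips below each crossing lineage form one genus
#' (monophyletic by construction). Families are painted the same way at an
#' older threshold with `n_families` crossing lineages, so every genus
#' nests inside one family. Tips are relabeled as synthetic binomials
#' `"Genus### sp####"`. Optionally a fraction of multi-species genera are
#' made non-monophyletic by swapping one tip between paired genera, to
#' exercise the maximum-stem-age rule.
#'
#' The returned ground truth records, for every family and genus, the true
#' maximum stem age computed by brute force over all tree nodes
#' (independent of [stem_age()]'s traversal), plus monophyly status.
#'
#' @param tree a [dated_tree()] from [simulate_bd_tree()].
#' @param n_genera number of genera, `1 <= n_genera <= n_tips`.
#' @param n_families number of families, `1 <= n_families <= n_genera`.
#' @param nonmono_fraction fraction of genera to force non-monophyletic by
#'   pairwise tip swaps (approximate: a swap can leave a donor genus
#'   monophyletic when the moved tip was sister to the rest).
#' @return a list with `tree` (relabeled [dated_tree()]), `taxonomy`
#'   (a [taxonomy_map()]), and `truth` (data frame `rank`, `name`,
#'   `age_mya`, `monophyletic`, `n_lineages`).
#' @export
paint_taxonomy <- function(tree, n_genera, n_families,
                           nonmono_fraction = 0) {
  tree <- as_dated_tree(tree)
  phy <- tree$phylo
  n <- ape::Ntip(phy)
  if (n_genera < 1 || n_genera > n) stop("need 1 <= n_genera <= n_tips")
  if (n_families < 1 || n_families > n_genera) {
    stop("need 1 <= n_families <= n_genera")
  }
  if (nonmono_fraction < 0 || nonmono_fraction > 1) {
    stop("nonmono_fraction must be in [0, 1]")
  }
  genus_id <- .cut_groups(tree, n_genera)
  family_id <- .cut_groups(tree, n_families)
  # nesting: all tips of a genus share one family clade
  fam_of_genus <- vapply(seq_len(n_genera), function(g) {
    f <- unique(family_id[genus_id == g])
    stopifnot(length(f) == 1L)
    f
  }, integer(1))

  genus_names <- sprintf("Genus%03d", seq_len(n_genera))
  family_names <- sprintf("Familia%02d", seq_len(n_families))
  epithet <- sprintf("sp%04d", seq_len(n))

  # force non-monophyly by swapping one tip between paired genera
  n_swap_pairs <- floor(round(nonmono_fraction * n_genera) / 2)
  if (n_swap_pairs > 0) {
    sizes <- tabulate(genus_id, nbins = n_genera)
    eligible <- which(sizes >= 2)
    # swaps may cross family boundaries, making families non-monophyletic
    # too; the truth table is computed after the swaps, so it stays exact
    if (length(eligible) < 2) {
      warning("too few multi-species genera; no non-monophyly injected")
    } else {
      pool <- sample(eligible)
      n_swap_pairs <- min(n_swap_pairs, floor(length(pool) / 2))
      for (p in seq_len(n_swap_pairs)) {
        a <- pool[2 * p - 1]; b <- pool[2 * p]
        ta <- sample(which(genus_id == a), 1L)
        tb <- sample(which(genus_id == b), 1L)
        genus_id[ta] <- b; genus_id[tb] <- a
      }
    }
  }

  labels <- paste(genus_names[genus_id], epithet)
  phy$tip.label <- labels
  tree$phylo <- phy
  taxonomy <- taxonomy_map(
    labels,
    family_of = data.frame(genus = genus_names,
                           family = family_names[fam_of_genus],
                           stringsAsFactors = FALSE))

  truth_rows <- function(rank, ids, nms) {
    do.call(rbind, lapply(sort(unique(ids)), function(k) {
      bf <- .bf_stem_age(tree, labels[ids == k])
      data.frame(rank = rank, name = nms[k], age_mya = bf$age,
                 monophyletic = bf$monophyletic, n_lineages = bf$n_lineages,
                 stringsAsFactors = FALSE)
    }))
  }
  fam_id_of_tip <- fam_of_genus[genus_id]
  truth <- rbind(truth_rows("family", fam_id_of_tip, family_names),
                 truth_rows("genus", genus_id, genus_names))
  list(tree = tree, taxonomy = taxonomy, truth = truth)
}

# tip group ids (1..n_groups) from cutting the tree where exactly n_groups
# lineages cross: cut just below the (n_groups - 1)-th oldest internal node
.cut_groups <- function(tree, n_groups) {
  phy <- tree$phylo
  n <- ape::Ntip(phy)
  if (n_groups == n) return(seq_len(n))
  int_age <- sort(tree$node_age[(n + 1L):(n + phy$Nnode)], decreasing = TRUE)
  if (n_groups == 1L) {
    t_cut <- tree$height + 1
  } else {
    # with the k oldest nodes above the cut there are k + 1 crossing lineages
    a_hi <- int_age[n_groups - 1L]
    a_lo <- if (n_groups <= phy$Nnode) int_age[n_groups] else 0
    if (a_hi <= a_lo) stop("tied node ages; cannot cut ", n_groups, " groups")
    t_cut <- (a_hi + a_lo) / 2
  }
  # group = crossing edge below which the tip sits; walk up from each tip
  parent <- integer(n + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  top <- vapply(seq_len(n), function(t) {
    node <- t
    while (parent[node] != 0L && tree$node_age[parent[node]] <= t_cut) {
      node <- parent[node]
    }
    node
  }, integer(1))
  match(top, sort(unique(top)))
}

# brute-force max-stem-age oracle used for simulator ground truth: test every
# node's clade for purity via prop.part, keep the maximal pure nodes
.bf_stem_age <- function(tree, tipset) {
  phy <- tree$phylo
  n <- ape::Ntip(phy)
  idx <- match(tipset, phy$tip.label)
  stopifnot(!anyNA(idx))
  parts <- ape::prop.part(phy)
  clade_tips <- c(as.list(seq_len(n)), lapply(parts, as.integer))
  pure <- vapply(clade_tips, function(tp) all(tp %in% idx), logical(1)) &
    vapply(clade_tips, length, integer(1)) > 0
  pure[seq_len(n)] <- pure[seq_len(n)] & seq_len(n) %in% idx
  is_maximal <- function(k) {
    if (!pure[k]) return(FALSE)
    sup <- which(pure & vapply(clade_tips, function(tp)
      length(tp) > length(clade_tips[[k]]) && all(clade_tips[[k]] %in% tp),
      logical(1)))
    length(sup) == 0
  }
  maximal <- which(vapply(seq_along(clade_tips), is_maximal, logical(1)))
  parent <- integer(n + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  ages <- vapply(maximal, function(k) {
    if (parent[k] == 0L) tree$node_age[k] else tree$node_age[parent[k]]
  }, numeric(1))
  list(age = max(ages), monophyletic = length(maximal) == 1L,
       n_lineages = length(maximal))
}

#' Simulate era-dependent floristic-element labels
#'
#' Each genus is labeled temperate with probability
#' `P(temperate | age a) = 1 / (1 + exp(-k (c - a)))` — a logistic in its
#' stem age with crossover `c` (where tropical and temperate are equally
#' likely) and steepness `k` — otherwise tropical; independently, a small
#' fraction is relabeled widespread. Wu types are drawn uniformly within
#' the chosen group (tropical: 2-7, temperate: 8-15, widespread: 1). This
#' emulates a flora in which temperate elements progressively overtake
#' tropical ones toward the present.
#'
#' @param div a [divergence_table()] (genus rows used), or a data frame
#'   with columns `name`, `age_mya` (one row per genus).
#' @param crossover `c`, Mya: the age at which P(temperate) = 1/2.
#' @param steepness `k`, per My; `Inf` gives a step function (ages exactly
#'   at `c` are temperate with probability 1/2).
#' @param widespread_fraction fraction of genera relabeled widespread.
#' @return a list with `type_table` (data frame `genus`, `type` — the
#'   pipeline input) and `truth` (data frame `genus`, `age_mya`,
#'   `p_temperate`, `group`).
#' @export
simulate_element_labels <- function(div, crossover = 10, steepness = 0.5,
                                    widespread_fraction = 0.05) {
  if (widespread_fraction < 0 || widespread_fraction > 1) {
    stop("widespread_fraction must be in [0, 1]")
  }
  if (steepness < 0) stop("steepness must be >= 0")
  g <- if ("rank" %in% names(div)) div[div$rank == "genus", ] else div
  age <- g$age_mya
  p_temp <- stats::plogis(steepness * (crossover - age))
  p_temp[is.nan(p_temp)] <- 0.5        # Inf * 0 at age == crossover
  stopifnot(all(p_temp >= 0 & p_temp <= 1))
  grp <- ifelse(stats::runif(length(age)) < p_temp, "temperate", "tropical")
  grp[stats::runif(length(age)) < widespread_fraction] <- "widespread"
  type <- vapply(grp, function(x) switch(x,
    widespread = 1L,
    tropical = sample(2:7, 1L),
    temperate = sample(8:15, 1L)), integer(1))
  list(type_table = data.frame(genus = g$name, type = unname(type),
                               stringsAsFactors = FALSE),
       truth = data.frame(genus = g$name, age_mya = age,
                          p_temperate = p_temp, group = unname(grp),
                          stringsAsFactors = FALSE))
}

#' Simulate a county-level occurrence table with a known endemic set
#'
#' A pool of `n_counties` counties is split into the focal region (the
#' first `region_fraction` share) and the outside. A designated fraction of
#' species is made endemic: each receives `m` counties (uniform on
#' `county_range`) of which at most `floor((1 - threshold) * m)` fall
#' outside the region, so its in-region fraction is `>= threshold`
#' (including exact-boundary cases). Non-endemics get at least one county
#' more than that outside, so their fraction is `< threshold`.
#'
#' @param species character vector of species names.
#' @param endemic_fraction fraction of species designated endemic (ignored
#'   when `endemic` is given).
#' @param endemic optional character vector naming the species to construct
#'   as endemic (must be a subset of `species`); when `NULL`, a random
#'   `endemic_fraction` of species is designated.
#' @param n_counties total number of counties (`>= 2`).
#' @param region_fraction fraction of counties inside the region, in (0,1).
#' @param county_range integer range (min, max) of counties per species.
#' @param threshold the endemism threshold the construction respects.
#' @return a list with `occurrences` (data frame `species`, `county`),
#'   `region` (a [region_definition()]), and `endemic_truth` (character
#'   vector of the species constructed as endemic).
#' @export
simulate_occurrences <- function(species, endemic_fraction = 0.3,
                                 endemic = NULL,
                                 n_counties = 50, region_fraction = 0.4,
                                 county_range = c(1L, 10L), threshold = 0.9) {
  if (n_counties < 2) stop("need at least 2 counties")
  if (region_fraction <= 0 || region_fraction >= 1) {
    stop("region_fraction must be in (0, 1)")
  }
  species <- normalize_names(species)
  counties <- sprintf("county%03d", seq_len(n_counties))
  n_in <- max(1L, round(region_fraction * n_counties))
  if (n_in >= n_counties) n_in <- n_counties - 1L
  inside <- counties[seq_len(n_in)]
  outside <- counties[-seq_len(n_in)]
  m_max <- min(county_range[2L], n_in, length(outside))
  if (m_max < county_range[1L]) stop("county pools too small for county_range")
  if (is.null(endemic)) {
    endemic <- sort(sample(species, round(endemic_fraction * length(species))))
  } else {
    endemic <- sort(normalize_names(endemic))
    if (!all(endemic %in% species)) {
      stop("'endemic' contains names not in 'species'")
    }
  }
  recs <- lapply(species, function(sp) {
    m <- sample(seq(county_range[1L], m_max), 1L)
    # tolerance so that e.g. (1 - 0.9) * 10 floors to 1, not 0
    slack <- floor((1 - threshold) * m + 1e-9)
    n_out <- if (sp %in% endemic) {
      sample(0:slack, 1L)
    } else {
      if (slack + 1L > m) m else sample((slack + 1L):m, 1L)
    }
    data.frame(species = sp,
               county = c(sample(inside, m - n_out), sample(outside, n_out)),
               stringsAsFactors = FALSE)
  })
  list(occurrences = do.call(rbind, recs),
       region = region_definition("focal region", inside),
       endemic_truth = endemic)
}

#' Generate a complete synthetic flora dataset
#'
#' One call producing every input the pipeline consumes, with ground truth:
#' a dated birth-death tree with painted taxonomy (optionally including
#' non-monophyletic genera), era-dependent element labels whose temperate
#' probability follows a logistic in genus stem age, and an occurrence
#' table with a known endemic species set. All randomness flows from a
#' single `set.seed(seed)` at entry, so equal configurations give
#' byte-identical datasets.
#'
#' The defaults emulate, at desk scale, a Cretaceous-rooted angiosperm
#' flora: 400 species in 100 genera and 25 families from a birth-death
#' process (birth 0.06, death 0.02 per My per lineage, tree height
#' typically ~100-140 My), a tropical-to-temperate transition centered at
#' 10 Mya, and 30% endemic species. Endemic species are designated by
#' whole genera (endemism is phylogenetically clustered in real floras),
#' so confined type-14/15 genera — endemic genera — arise as well.
#'
#' @param seed integer seed (mandatory).
#' @param n_tips,n_genera,n_families taxonomy targets.
#' @param birth,death birth-death rates (events/My/lineage).
#' @param nonmono_fraction fraction of genera forced non-monophyletic.
#' @param crossover,steepness logistic element-label model (Mya, 1/My).
#' @param widespread_fraction fraction of widespread genera.
#' @param endemic_fraction,n_counties,region_fraction occurrence model.
#' @return a list of class `synthetic_flora` with `tree`, `taxonomy`,
#'   `truth` (taxon ages), `type_table`, `element_truth`, `occurrences`,
#'   `region`, `endemic_truth`, and `config`.
#' @export
simulate_flora <- function(seed, n_tips = 400, n_genera = 100,
                           n_families = 25, birth = 0.06, death = 0.02,
                           nonmono_fraction = 0.2, crossover = 10,
                           steepness = 0.5, widespread_fraction = 0.05,
                           endemic_fraction = 0.3, n_counties = 50,
                           region_fraction = 0.4) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  set.seed(seed)
  tree <- simulate_bd_tree(n_tips = n_tips, birth = birth, death = death)
  painted <- paint_taxonomy(tree, n_genera = n_genera,
                            n_families = n_families,
                            nonmono_fraction = nonmono_fraction)
  div <- divergence_table(painted$tree, painted$taxonomy)
  labels <- simulate_element_labels(div, crossover = crossover,
                                    steepness = steepness,
                                    widespread_fraction = widespread_fraction)
  # endemism is phylogenetically clustered: designate whole genera as
  # endemic (in random order) until the species budget is met, so endemic
  # genera (confined type-14/15 genera) arise alongside endemic species
  budget <- round(endemic_fraction * n_tips)
  endemic <- character(0)
  for (g in sample(unique(painted$taxonomy$genus))) {
    if (length(endemic) >= budget) break
    sp <- painted$taxonomy$species[painted$taxonomy$genus == g]
    endemic <- c(endemic, sp[seq_len(min(length(sp),
                                         budget - length(endemic)))])
  }
  occ <- simulate_occurrences(painted$taxonomy$species,
                              endemic = endemic,
                              n_counties = n_counties,
                              region_fraction = region_fraction)
  structure(list(tree = painted$tree, taxonomy = painted$taxonomy,
                 truth = painted$truth, type_table = labels$type_table,
                 element_truth = labels$truth,
                 occurrences = occ$occurrences, region = occ$region,
                 endemic_truth = occ$endemic_truth,
                 config = list(seed = seed, n_tips = n_tips,
                               n_genera = n_genera, n_families = n_families,
                               birth = birth, death = death,
                               nonmono_fraction = nonmono_fraction,
                               crossover = crossover, steepness = steepness,
                               widespread_fraction = widespread_fraction,
                               endemic_fraction = endemic_fraction,
                               n_counties = n_counties,
                               region_fraction = region_fraction)),
            class = "synthetic_flora")
}

#' Write a synthetic flora dataset to disk in pipeline formats
#'
#' Emits exactly the file formats the pipeline consumes: `tree.nwk`
#' (Newick), `taxonomy.tsv` (species/genus/family), `type_table.tsv`
#' (genus/type), `occurrences.csv`, `region.yaml`, plus `truth.json` with
#' the ground-truth taxon ages, element labels, and endemic set.
#'
#' @param flora a [simulate_flora()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_flora_dataset <- function(flora, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dated_tree(flora$tree, file.path(dir, "tree.nwk"))
  utils::write.table(as.data.frame(flora$taxonomy),
                     file.path(dir, "taxonomy.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(flora$type_table, file.path(dir, "type_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(flora$occurrences, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(name = flora$region$name,
                        counties = flora$region$counties),
                   file.path(dir, "region.yaml"))
  jsonlite::write_json(list(taxon_ages = flora$truth,
                            element_truth = flora$element_truth,
                            endemic_species = flora$endemic_truth,
                            config = flora$config),
                       file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.synthetic_flora <- function(x, ...) {
  cat("Synthetic flora (seed ", x$config$seed, "): ",
      nrow(x$taxonomy), " species, ",
      length(unique(x$taxonomy$genus)), " genera, ",
      length(unique(x$taxonomy$family)), " families; tree height ",
      format(round(x$tree$height, 2)), " Mya; ",
      length(x$endemic_truth), " endemic species\n", sep = "")
  invisible(x)
}
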