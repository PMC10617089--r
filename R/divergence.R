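#' Maximal monophyletic lineages of a set of tips
#'
#' Partitions `tipset` into the unique minimal set of clades such that each
#' clade's MRCA subtends no tips outside `tipset`, and no two clades can be
#' merged while preserving that property. A single tip counts as a lineage.
#' A monophyletic taxon yields exactly one lineage; a para- or polyphyletic
#' taxon decomposes into several.
#'
#' Internally this is a single post-order pass: a node is "pure" when all
#' tips it subtends belong to `tipset`; the lineages are the pure nodes
#' whose parent is not pure.
#'
#' @param tree a [dated_tree] or `phylo`.
#' @param tipset character vector of tip labels (normalized before matching).
#' @return a list with one element per lineage, each a list with `node`
#'   (ape node index of the lineage's MRCA, or the tip index for a
#'   singleton), `tips` (tip labels), and `at_root` (is the MRCA the tree
#'   root?).
#' @export
maximal_monophyletic_lineages <- function(tree, tipset) {
  tree <- as_dated_tree(tree)
  phy <- tree$phylo
  idx <- .tipset_index(phy, tipset)
  n <- ape::Ntip(phy)
  root <- n + 1L
  in_set <- logical(n)
  in_set[idx] <- TRUE

  e <- ape::reorder.phylo(phy, "postorder")$edge
  n_in <- c(as.numeric(in_set), numeric(phy$Nnode))
  n_tot <- c(rep(1, n), numeric(phy$Nnode))
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]; ch <- e[i, 2L]
    n_in[p] <- n_in[p] + n_in[ch]
    n_tot[p] <- n_tot[p] + n_tot[ch]
  }
  pure <- n_in > 0 & n_in == n_tot

  parent <- integer(n + phy$Nnode)
  parent[e[, 2L]] <- e[, 1L]           # parent[root] stays 0
  # climb from each member tip to its highest pure ancestor
  top <- vapply(idx, function(t) {
    node <- t
    while (parent[node] != 0L && pure[parent[node]]) node <- parent[node]
    node
  }, integer(1))
  lin_nodes <- sort(unique(top))
  lapply(lin_nodes, function(nd) {
    list(node = nd,
         tips = phy$tip.label[idx[top == nd]],
         at_root = nd == root)
  })
}

#' Stem age of a taxon under the maximum-stem-age rule
#'
#' For each maximal monophyletic lineage of `tipset` the stem age is the
#' age of the parent of the lineage's MRCA (for a singleton, the parent of
#' the tip). The taxon's age is the oldest such stem age — the earliest
#' possible time the taxon's lineage was present. If a lineage's MRCA is
#' the tree root there is no stem node; the root age is used and `at_root`
#' is set, so the caller can exclude such taxa if desired.
#'
#' @inheritParams maximal_monophyletic_lineages
#' @return a list with `age` (Mya), `monophyletic` (single lineage?),
#'   `n_lineages`, and `at_root` (TRUE when some lineage's MRCA is the
#'   root, in which case the reported age is the root age).
#' @examples
#' tr <- dated_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' stem_age(tr, c("A", "B"))   # age 2, monophyletic
#' stem_age(tr, c("A", "C"))   # age 2, two lineages
#' @export
stem_age <- function(tree, tipset) {
  tree <- as_dated_tree(tree)
  phy <- tree$phylo
  n <- ape::Ntip(phy)
  root <- n + 1L
  lin <- maximal_monophyletic_lineages(tree, tipset)
  parent <- integer(n + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  ages <- vapply(lin, function(l) {
    if (l$at_root) tree$node_age[root] else tree$node_age[parent[l$node]]
  }, numeric(1))
  list(age = max(ages),
       monophyletic = length(lin) == 1L,
       n_lineages = length(lin),
       at_root = any(vapply(lin, `[[`, logical(1), "at_root")))
}

#' Divergence age of a species
#'
#' The age of the parent node of the species' tip; on an ultrametric tree
#' this equals the terminal branch length.
#'
#' @param tree a [dated_tree] or `phylo`.
#' @param tip a tip label.
#' @return age in Mya.
#' @export
species_age <- function(tree, tip) {
  tree <- as_dated_tree(tree)
  phy <- tree$phylo
  i <- match(normalize_names(tip), phy$tip.label)
  if (anyNA(i)) {
    stop("unknown tip: ", paste(normalize_names(tip)[is.na(i)], collapse = ", "))
  }
  parent <- integer(ape::Ntip(phy) + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  unname(tree$node_age[parent[i]])
}

#' Divergence table for all taxa in a dated tree
#'
#' One row per family, genus, and species present in the tree. Family and
#' genus ages come from [stem_age()] (maximum stem age over maximal
#' monophyletic lineages); species ages from [species_age()]. Rows are
#' sorted by rank (family, genus, species) then age descending. Ages are
#' never rounded internally.
#'
#' @param tree a [dated_tree].
#' @param taxonomy a [taxonomy_map()] covering every tip of the tree.
#' @return a data frame of class `divergence_table` with columns `rank`,
#'   `name`, `age_mya`, `monophyletic`, `n_lineages`, `at_root`.
#' @export
divergence_table <- function(tree, taxonomy) {
  tree <- as_dated_tree(tree)
  phy <- tree$phylo
  tips <- phy$tip.label
  i <- match(tips, taxonomy$species)
  if (anyNA(i)) {
    stop("tips not covered by the taxonomy: ",
         paste(tips[is.na(i)], collapse = ", "))
  }
  genus <- taxonomy$genus[i]
  family <- taxonomy$family[i]
  if (anyNA(family)) {
    stop("tips with no family assignment: ",
         paste(tips[is.na(family)], collapse = ", "))
  }
  rank_rows <- function(rank, groups) {
    nm <- sort(unique(groups))
    rows <- lapply(nm, function(g) {
      s <- stem_age(tree, tips[groups == g])
      data.frame(rank = rank, name = g, age_mya = s$age,
                 monophyletic = s$monophyletic, n_lineages = s$n_lineages,
                 at_root = s$at_root, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  parent <- integer(ape::Ntip(phy) + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  sp <- data.frame(rank = "species", name = tips,
                   age_mya = unname(tree$node_age[parent[seq_along(tips)]]),
                   monophyletic = TRUE, n_lineages = 1L, at_root = FALSE,
                   stringsAsFactors = FALSE)
  out <- rbind(rank_rows("family", family), rank_rows("genus", genus), sp)
  out <- out[order(match(out$rank, c("family", "genus", "species")),
                   -out$age_mya, out$name), ]
  rownames(out) <- NULL
  class(out) <- c("divergence_table", "data.frame")
  out
}

#' Write a divergence table as CSV
#'
#' Columns `rank,name,age_mya,monophyletic,n_lineages,at_root`.
#'
#' @param x a [divergence_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_divergence_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# resolve + validate a tipset against the tree, returning tip indices
.tipset_index <- function(phy, tipset) {
  tipset <- unique(normalize_names(tipset))
  if (length(tipset) == 0) stop("tipset is empty")
  idx <- match(tipset, phy$tip.label)
  if (anyNA(idx)) {
    stop("unknown tip name(s): ", paste(tipset[is.na(idx)], collapse = ", "))
  }
  idx
}
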