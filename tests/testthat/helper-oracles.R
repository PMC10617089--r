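# Independent brute-force oracles and small generators used across tests.
# The oracles enumerate every node of the tree and never share code with the
# package's post-order implementation.

# all clades of the tree as tip-index sets, indexed by ape node id
all_clades <- function(phy) {
  n <- ape::Ntip(phy)
  c(as.list(seq_len(n)), lapply(ape::prop.part(phy), as.integer))
}

# brute force: every node whose clade lies inside the tipset is "pure";
# the partition is the set of pure nodes with no pure strict superset
oracle_lineage_partition <- function(phy, tipset_idx) {
  clades <- all_clades(phy)
  pure <- vapply(clades, function(tp) all(tp %in% tipset_idx), logical(1))
  maximal <- vapply(seq_along(clades), function(k) {
    if (!pure[k]) return(FALSE)
    !any(vapply(which(pure), function(j) {
      length(clades[[j]]) > length(clades[[k]]) &&
        all(clades[[k]] %in% clades[[j]])
    }, logical(1)))
  }, logical(1))
  nodes <- which(maximal)
  lapply(nodes, function(k) sort(clades[[k]]))
}

oracle_stem_age <- function(tree, tipset_idx) {
  phy <- tree$phylo
  part <- oracle_lineage_partition(phy, tipset_idx)
  clades <- all_clades(phy)
  node_of <- vapply(part, function(tp) {
    which(vapply(clades, function(c2) identical(sort(c2), tp), logical(1)))[1L]
  }, integer(1))
  parent <- integer(ape::Ntip(phy) + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  ages <- vapply(node_of, function(k) {
    if (parent[k] == 0L) tree$node_age[k] else tree$node_age[parent[k]]
  }, numeric(1))
  list(age = max(ages), n_lineages = length(part))
}

# a random ultrametric tree with untouched ape tip labels
random_tree <- function(n, birth = 0.1, death = 0) {
  floristics::simulate_bd_tree(n_tips = n, birth = birth, death = death)
}

# lineage partition from the package, normalized for comparison
pkg_partition <- function(tree, tipset_idx) {
  tips <- tree$phylo$tip.label[tipset_idx]
  lin <- floristics::maximal_monophyletic_lineages(tree, tips)
  lapply(lin, function(l) sort(match(l$tips, tree$phylo$tip.label)))
}

sort_partition <- function(p) p[order(vapply(p, min, numeric(1)))]
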