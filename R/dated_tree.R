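#' Dated phylogenetic trees
#'
#' A `dated_tree` wraps an [ape::read.tree()]-style `phylo` object together
#' with node ages on the "millions of years before present" axis (present
#' = 0, increasing into the past). Ages are derived from branch lengths as
#' `tree height - root-to-node depth`, so for an ultrametric tree every tip
#' has age 0 and the root has age equal to the tree height.
#'
#' @param phy a rooted `phylo` object with branch lengths in Mya.
#' @param allow_nonultrametric logical; if `FALSE` (default) a tree whose
#'   root-to-tip path lengths differ by more than `rel_tol` times the tree
#'   height is rejected. If `TRUE`, tips may have positive ages.
#' @param rel_tol relative tolerance used for the ultrametricity check.
#' @return an object of class `dated_tree`: a list with elements `phylo`
#'   (tip labels normalized), `node_age` (numeric, indexed like ape nodes:
#'   tips `1..n`, internals `n+1..n+m`), and `height` (root age, Mya).
#' @seealso [read_dated_tree()], [prune_to_taxa()], [validate_ultrametric()]
#' @export
dated_tree <- function(phy, allow_nonultrametric = FALSE, rel_tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("'phy' must be a 'phylo' object")
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths; a dated tree requires lengths in Mya")
  }
  if (anyNA(phy$edge.length)) {
    bad <- phy$edge[is.na(phy$edge.length), 2L]
    bad_lab <- .node_label(phy, bad)
    stop("missing branch length on the edge leading to: ",
         paste(bad_lab, collapse = ", "))
  }
  if (!ape::is.rooted(phy)) {
    stop("tree is unrooted; root it (e.g. with an outgroup or ape::root) ",
         "before dating analyses")
  }
  if (any(phy$edge.length < 0)) stop("negative branch lengths are not allowed")
  phy$tip.label <- normalize_names(phy$tip.label)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicated tip labels after normalization: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth)
  age <- height - depth
  x <- structure(list(phylo = phy, node_age = age, height = height),
                 class = "dated_tree")
  if (!allow_nonultrametric) {
    v <- validate_ultrametric(x, rel_tol = rel_tol)
    if (!v$ultrametric) {
      stop("tree is not ultrametric (max root-to-tip deviation ",
           format(v$max_deviation), " Mya, relative ",
           format(v$relative_deviation), "); pass allow_nonultrametric = TRUE ",
           "to accept tips with positive ages")
    }
  }
  x
}

#' Read a dated phylogeny from Newick or Nexus
#'
#' Parses a time-calibrated tree whose branch lengths are in millions of
#' years, computes node ages (present = 0), and normalizes tip labels
#' (underscores become spaces, surrounding whitespace is trimmed).
#'
#' @param path path to the tree file.
#' @param format `"newick"` or `"nexus"` (a TREES block).
#' @inheritParams dated_tree
#' @return a [dated_tree] object.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' tr <- read_dated_tree(tf)
#' tr$height            # 2
#' @export
read_dated_tree <- function(path, format = c("newick", "nexus"),
                            allow_nonultrametric = FALSE, rel_tol = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (file.size(path) == 0) stop("tree file is empty: ", path)
  phy <- switch(format,
    newick = tryCatch(ape::read.tree(path),
                      error = function(e) stop("failed to parse Newick file '",
                                               path, "': ", conditionMessage(e))),
    nexus = tryCatch(ape::read.nexus(path),
                     error = function(e) stop("failed to parse Nexus file '",
                                              path, "': ", conditionMessage(e)))
  )
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) == 0) stop("no trees found in ", path)
    if (length(phy) > 1) message("file contains ", length(phy),
                                 " trees; using the first")
    phy <- phy[[1L]]
  }
  if (is.null(phy)) stop("no tree could be parsed from ", path)
  dated_tree(phy, allow_nonultrametric = allow_nonultrametric,
             rel_tol = rel_tol)
}

#' Write a dated tree as Newick
#'
#' @param tree a [dated_tree].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dated_tree <- function(tree, path) {
  tree <- as_dated_tree(tree)
  ape::write.tree(tree$phylo, file = path, digits = 15)
  invisible(path)
}

#' @export
print.dated_tree <- function(x, ...) {
  n <- ape::Ntip(x$phylo)
  cat("Dated phylogeny: ", n, " tips, ", x$phylo$Nnode,
      " internal nodes, height ", format(round(x$height, 3)), " Mya\n", sep = "")
  tip_age <- x$node_age[seq_len(n)]
  if (max(tip_age) > 1e-6 * max(x$height, 1)) {
    cat("Non-ultrametric: tip ages up to ", format(round(max(tip_age), 3)),
        " Mya\n", sep = "")
  }
  invisible(x)
}

#' Coerce to a dated tree
#'
#' @param x a `dated_tree` or rooted `phylo` with branch lengths.
#' @param ... passed to [dated_tree()] when coercing a `phylo`.
#' @return a [dated_tree].
#' @export
as_dated_tree <- function(x, ...) {
  if (inherits(x, "dated_tree")) return(x)
  if (inherits(x, "phylo")) return(dated_tree(x, ...))
  stop("cannot coerce object of class '", paste(class(x), collapse = "/"),
       "' to a dated_tree")
}

#' Check ultrametricity of a dated tree
#'
#' Reports the maximum deviation of root-to-tip path lengths from the tree
#' height, plus pass/fail flags for the structural invariants of a dated
#' tree (single root, non-negative branch lengths, child ages not exceeding
#' parent ages). This is a reporting operation and never throws.
#'
#' @param tree a [dated_tree] or `phylo`.
#' @param rel_tol relative tolerance: the tree passes if the maximum
#'   deviation is at most `rel_tol` times the tree height.
#' @return a list of class `tree_validation` with elements `ultrametric`,
#'   `max_deviation`, `relative_deviation`, `height`, `nonneg_lengths`,
#'   `ages_monotone`, and `pass` (all checks combined).
#' @export
validate_ultrametric <- function(tree, rel_tol = 1e-6) {
  if (inherits(tree, "phylo")) {
    # bypass the constructor's own check: validation must not throw
    tree <- dated_tree(tree, allow_nonultrametric = TRUE)
  }
  phy <- tree$phylo
  n <- ape::Ntip(phy)
  if (n < 2) stop("validation requires a tree with at least 2 tips")
  tip_depth <- ape::node.depth.edgelength(phy)[seq_len(n)]
  dev <- max(abs(tip_depth - tree$height))
  rel <- if (tree$height > 0) dev / tree$height else 0
  parent <- phy$edge[, 1L]
  child <- phy$edge[, 2L]
  out <- list(
    ultrametric = rel <= rel_tol,
    max_deviation = dev,
    relative_deviation = rel,
    rel_tol = rel_tol,
    height = tree$height,
    nonneg_lengths = all(phy$edge.length >= 0),
    ages_monotone = all(tree$node_age[child] <= tree$node_age[parent] +
                          rel_tol * max(tree$height, 1))
  )
  out$pass <- out$ultrametric && out$nonneg_lengths && out$ages_monotone
  class(out) <- "tree_validation"
  out
}

#' @export
print.tree_validation <- function(x, ...) {
  cat("Dated-tree validation\n")
  cat("  height:                ", format(x$height), "Mya\n")
  cat("  max root-tip deviation:", format(x$max_deviation),
      sprintf("(relative %s, tolerance %s)\n",
              format(x$relative_deviation), format(x$rel_tol)))
  for (f in c("ultrametric", "nonneg_lengths", "ages_monotone", "pass")) {
    cat(sprintf("  %-22s %s\n", paste0(f, ":"), if (x[[f]]) "PASS" else "FAIL"))
  }
  invisible(x)
}

#' Prune a dated tree to a species list
#'
#' Restricts the tree to the tips present in `keep`. Degree-two nodes
#' created by the pruning are suppressed; surviving internal nodes keep
#' their ages from the input tree exactly (each pruned node is matched to
#' the most recent common ancestor of its retained tips in the original
#' tree, and edge lengths are rebuilt as age differences). Requested names
#' missing from the tree are counted and reported via a message.
#'
#' @param tree a [dated_tree].
#' @param keep character vector of species names to retain (normalized with
#'   [normalize_names()] before matching).
#' @return a [dated_tree] containing exactly `keep` intersected with the
#'   tree's tips.
#' @export
prune_to_taxa <- function(tree, keep) {
  tree <- as_dated_tree(tree)
  phy <- tree$phylo
  keep <- unique(normalize_names(keep))
  hit <- keep %in% phy$tip.label
  if (sum(!hit) > 0) {
    message(sum(!hit), " of ", length(keep),
            " requested names absent from the tree; dropped")
  }
  keep <- keep[hit]
  if (length(keep) == 0) stop("no requested species occur in the tree")
  if (length(keep) == 1) {
    stop("only one requested species occurs in the tree; cannot form a tree")
  }
  if (length(keep) == ape::Ntip(phy)) return(tree)
  pruned <- ape::keep.tip(phy, keep)
  n <- ape::Ntip(pruned)
  age <- numeric(n + pruned$Nnode)
  age[seq_len(n)] <- tree$node_age[match(pruned$tip.label, phy$tip.label)]
  # internal nodes: carry the age of the matching node in the input tree
  parts <- ape::prop.part(pruned)
  labs <- attr(parts, "labels")
  for (i in seq_along(parts)) {
    orig <- ape::getMRCA(phy, labs[parts[[i]]])
    age[n + i] <- tree$node_age[orig]
  }
  pruned$edge.length <- age[pruned$edge[, 1L]] - age[pruned$edge[, 2L]]
  structure(list(phylo = pruned, node_age = age, height = age[n + 1L]),
            class = "dated_tree")
}

#' Normalize taxon names
#'
#' Replaces underscores with spaces, collapses repeated whitespace and
#' trims; case is preserved. Matching throughout the package is exact
#' after this normalization.
#'
#' @param x character vector of names.
#' @return normalized character vector.
#' @export
normalize_names <- function(x) {
  x <- gsub("_", " ", as.character(x), fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# label for error messages: tip label or node number
.node_label <- function(phy, node) {
  n <- ape::Ntip(phy)
  ifelse(node <= n, phy$tip.label[node], paste0("node #", node))
}
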