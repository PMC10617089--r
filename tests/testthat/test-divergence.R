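toy3 <- function() dated_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))

test_that("maximal monophyletic lineages: hand-checked cases", {
  tr <- toy3()
  lin <- maximal_monophyletic_lineages(tr, c("A", "B"))
  expect_length(lin, 1L)
  expect_setequal(lin[[1]]$tips, c("A", "B"))

  # caterpillar (((A,B),C),D), tipset {A,B,D} -> clade {A,B} + singleton {D}
  cat4 <- dated_tree(ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);"))
  lin <- maximal_monophyletic_lineages(cat4, c("A", "B", "D"))
  tipsets <- lapply(lin, function(l) sort(l$tips))
  expect_length(lin, 2L)
  expect_true(list(c("A", "B")) %in% tipsets && list("D") %in% tipsets)

  # whole tree is one lineage rooted at the root
  lin <- maximal_monophyletic_lineages(cat4, c("A", "B", "C", "D"))
  expect_length(lin, 1L)
  expect_true(lin[[1]]$at_root)

  expect_error(maximal_monophyletic_lineages(tr, character(0)), "empty")
  expect_error(maximal_monophyletic_lineages(tr, c("A", "Zz")), "Zz")
})

test_that("stem ages follow the maximum-stem rule", {
  tr <- toy3()
  s <- stem_age(tr, c("A", "B"))
  expect_equal(s$age, 2)            # parent of the AB ancestor is the root
  expect_true(s$monophyletic)
  expect_false(s$at_root)

  s <- stem_age(tr, c("A", "C"))    # lineages {A} (stem 1) and {C} (stem 2)
  expect_equal(s$age, 2)
  expect_false(s$monophyletic)
  expect_equal(s$n_lineages, 2L)

  s <- stem_age(tr, c("A", "B", "C"))
  expect_true(s$at_root)
  expect_equal(s$age, 2)            # no stem node: root age used
})

test_that("species age equals the terminal branch length on ultrametric trees", {
  tr <- toy3()
  expect_equal(species_age(tr, "A"), 1)
  expect_equal(species_age(tr, "C"), 2)
  expect_error(species_age(tr, "nope"), "unknown tip")

  set.seed(7)
  sim <- random_tree(40)
  phy <- sim$phylo
  term <- phy$edge.length[match(seq_len(ape::Ntip(phy)), phy$edge[, 2L])]
  expect_equal(species_age(sim, phy$tip.label), unname(term))
})

test_that("lineage partition and stem age match the brute-force oracle", {
  set.seed(123)
  for (rep in 1:40) {
    tr <- random_tree(sample(8:64, 1))
    n <- ape::Ntip(tr$phylo)
    tipset <- sort(sample(n, sample(1:n, 1)))
    expect_identical(sort_partition(pkg_partition(tr, tipset)),
                     sort_partition(oracle_lineage_partition(tr$phylo, tipset)))
    o <- oracle_stem_age(tr, tipset)
    s <- stem_age(tr, tr$phylo$tip.label[tipset])
    expect_identical(s$age, o$age)
    expect_identical(s$n_lineages, o$n_lineages)
  }
})

test_that("divergence table covers every taxon with correct structure", {
  # three monotypic genera in one family
  tr <- toy3()
  tax <- taxonomy_map(c("A", "B", "C"),
                      family_of = data.frame(genus = c("A", "B", "C"),
                                             family = "Fam"))
  div <- divergence_table(tr, tax)
  expect_equal(sum(div$rank == "family"), 1L)
  expect_equal(sum(div$rank == "genus"), 3L)
  expect_equal(sum(div$rank == "species"), 3L)
  fam <- div[div$rank == "family", ]
  expect_equal(fam$age_mya, 2)
  expect_true(fam$at_root)
  expect_true(all(div$n_lineages[div$rank == "species"] == 1L))

  # paraphyletic genus on a 6-tip tree: age equals the oracle max-stem value
  phy <- ape::read.tree(
    text = "(((a1:1,a2:1):1,(b1:1.5,a3:1.5):0.5):1,(b2:2,c1:2):1);")
  tr6 <- dated_tree(phy)
  tax6 <- taxonomy_map(phy$tip.label,
                       family_of = data.frame(genus = c("a", "b", "c"),
                                              family = "F"),
                       genus_of = data.frame(
                         species = phy$tip.label,
                         genus = sub("[0-9]+$", "", phy$tip.label)))
  div6 <- divergence_table(tr6, tax6)
  arow <- div6[div6$rank == "genus" & div6$name == "a", ]
  idx <- match(c("a1", "a2", "a3"), phy$tip.label)
  o <- oracle_stem_age(tr6, idx)
  expect_equal(arow$age_mya, o$age)
  expect_false(arow$monophyletic)

  expect_error(divergence_table(tr, taxonomy_map(c("A", "B", "C"))),
               "no family")
})

test_that("divergence table row counts match simulator bookkeeping", {
  flora <- simulate_flora(seed = 99, n_tips = 200, n_genera = 40,
                          n_families = 10)
  div <- divergence_table(flora$tree, flora$taxonomy)
  expect_equal(sum(div$rank == "family"),
               length(unique(flora$taxonomy$family)))
  expect_equal(sum(div$rank == "genus"),
               length(unique(flora$taxonomy$genus)))
  expect_equal(sum(div$rank == "species"), 200L)
  # sorted by rank then age descending
  expect_false(is.unsorted(match(div$rank, c("family", "genus", "species"))))
  for (rk in unique(div$rank)) {
    expect_false(is.unsorted(rev(div$age_mya[div$rank == rk])))
  }
})

test_that("genus stems are at least as old as member species ages, families nest", {
  flora <- simulate_flora(seed = 17, n_tips = 150, n_genera = 30,
                          n_families = 8, nonmono_fraction = 0)
  div <- divergence_table(flora$tree, flora$taxonomy)
  tax <- flora$taxonomy
  ga <- setNames(div$age_mya[div$rank == "genus"],
                 div$name[div$rank == "genus"])
  sa <- setNames(div$age_mya[div$rank == "species"],
                 div$name[div$rank == "species"])
  expect_true(all(ga[tax$genus] >= sa[tax$species]))
  # painted taxonomy is fully monophyletic: strict nesting holds
  fa <- setNames(div$age_mya[div$rank == "family"],
                 div$name[div$rank == "family"])
  expect_true(all(fa[tax$family] >= ga[tax$genus]))
  expect_true(all(div$monophyletic[div$rank != "species"]))
})
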