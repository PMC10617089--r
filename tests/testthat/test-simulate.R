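test_that("birth-death simulator: minimal case, guards, determinism", {
  set.seed(1)
  t2 <- simulate_bd_tree(n_tips = 2, birth = 1, death = 0)
  expect_equal(ape::Ntip(t2$phylo), 2L)
  expect_equal(t2$phylo$Nnode, 1L)

  expect_error(simulate_bd_tree(n_tips = 5, birth = 1, death = 1), "death")
  expect_error(simulate_bd_tree(n_tips = 1, birth = 1), "n_tips")
  expect_error(simulate_bd_tree(n_tips = 5, crown_age = 3), "exactly one")

  set.seed(10); a <- simulate_bd_tree(n_tips = 30)
  set.seed(10); b <- simulate_bd_tree(n_tips = 30)
  expect_identical(ape::write.tree(a$phylo), ape::write.tree(b$phylo))
})

test_that("crown-age Yule trees match the expected lineage count 2*exp(lambda*t)", {
  set.seed(202)
  lambda <- 0.3; tmax <- 5; nrep <- 500
  n <- replicate(nrep, ape::Ntip(simulate_bd_tree(crown_age = tmax,
                                                  birth = lambda,
                                                  death = 0)$phylo))
  mu <- 2 * exp(lambda * tmax)
  # each crown lineage is an independent Yule process: Var N = e^2lt - e^lt
  sd3 <- 3 * sqrt(2 * (exp(2 * lambda * tmax) - exp(lambda * tmax)) / nrep)
  expect_lt(abs(mean(n) - mu), sd3)
})

test_that("painted taxonomy: group counts, monotypic limit, monophyly control", {
  set.seed(3)
  tr <- simulate_bd_tree(n_tips = 80)
  p <- paint_taxonomy(tr, n_genera = 20, n_families = 5)
  expect_equal(length(unique(p$taxonomy$genus)), 20L)
  expect_equal(length(unique(p$taxonomy$family)), 5L)
  div <- divergence_table(p$tree, p$taxonomy)
  expect_true(all(div$monophyletic[div$rank != "species"]))

  # every genus monotypic when n_genera equals the tip count
  pm <- paint_taxonomy(tr, n_genera = 80, n_families = 10)
  expect_equal(length(unique(pm$taxonomy$genus)), 80L)
  expect_true(all(table(pm$taxonomy$genus) == 1L))

  # forced non-monophyly: truth table flags it, ages stay exact
  set.seed(4)
  pn <- paint_taxonomy(tr, n_genera = 20, n_families = 5,
                       nonmono_fraction = 0.4)
  expect_gt(sum(!pn$truth$monophyletic[pn$truth$rank == "genus"]), 0L)
  divn <- divergence_table(pn$tree, pn$taxonomy)
  m <- merge(pn$truth, as.data.frame(divn), by = c("rank", "name"))
  expect_equal(nrow(m), nrow(pn$truth))
  expect_identical(m$age_mya.x, m$age_mya.y)
  expect_identical(m$monophyletic.x, m$monophyletic.y)
  expect_identical(m$n_lineages.x, m$n_lineages.y)
})

test_that("element labels: step-function limit and determinism", {
  div <- data.frame(rank = "genus", name = paste0("g", 1:100),
                    age_mya = seq(0.5, 50, length.out = 100),
                    monophyletic = TRUE, n_lineages = 1L, at_root = FALSE)
  set.seed(6)
  lab <- simulate_element_labels(div, crossover = 10, steepness = Inf,
                                 widespread_fraction = 0)
  old <- lab$truth$age_mya > 10
  expect_true(all(lab$truth$group[old] == "tropical"))
  expect_true(all(lab$truth$group[!old & lab$truth$age_mya < 10] ==
                    "temperate"))
  # types drawn within the labeled group
  tt <- merge(lab$type_table, lab$truth, by = "genus")
  expect_true(all(tt$type[tt$group == "tropical"] %in% 2:7))
  expect_true(all(tt$type[tt$group == "temperate"] %in% 8:15))

  set.seed(9); l1 <- simulate_element_labels(div)
  set.seed(9); l2 <- simulate_element_labels(div)
  expect_identical(l1, l2)
})

test_that("occurrence simulator respects the construction rules and seed", {
  set.seed(15)
  sim <- simulate_occurrences(sprintf("S%03d x", 1:60),
                              endemic_fraction = 0.25, n_counties = 40,
                              region_fraction = 0.5)
  tot <- tapply(sim$occurrences$county, sim$occurrences$species,
                function(x) length(unique(x)))
  inr <- tapply(sim$occurrences$county, sim$occurrences$species,
                function(x) sum(unique(x) %in% sim$region$counties))
  f <- inr / tot
  end <- names(f) %in% sim$endemic_truth
  expect_true(all(f[end] >= 0.9))
  expect_true(all(f[!end] < 0.9))

  set.seed(15)
  sim2 <- simulate_occurrences(sprintf("S%03d x", 1:60),
                               endemic_fraction = 0.25, n_counties = 40,
                               region_fraction = 0.5)
  expect_identical(sim$occurrences, sim2$occurrences)
  expect_identical(sim$endemic_truth, sim2$endemic_truth)
})

test_that("simulate_flora is fully deterministic under a fixed seed", {
  f1 <- simulate_flora(seed = 123, n_tips = 60, n_genera = 15, n_families = 4)
  f2 <- simulate_flora(seed = 123, n_tips = 60, n_genera = 15, n_families = 4)
  expect_identical(ape::write.tree(f1$tree$phylo),
                   ape::write.tree(f2$tree$phylo))
  expect_identical(f1$type_table, f2$type_table)
  expect_identical(f1$occurrences, f2$occurrences)
  expect_identical(f1$endemic_truth, f2$endemic_truth)
  expect_error(simulate_flora(), "seed")

  d <- withr::local_tempdir()
  write_flora_dataset(f1, d)
  expect_true(all(file.exists(file.path(d, c("tree.nwk", "taxonomy.tsv",
                                             "type_table.tsv",
                                             "occurrences.csv",
                                             "region.yaml", "truth.json")))))
  reread <- read_dated_tree(file.path(d, "tree.nwk"),
                            allow_nonultrametric = TRUE)
  expect_true(ape::all.equal.phylo(reread$phylo, f1$tree$phylo))
})
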