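test_that("fixed and geological timescales have the stated structure", {
  fx <- make_timescale("fixed", width = 5, start = 145)
  expect_equal(nrow(fx), 29L)
  expect_equal(fx$old_bound[1], 145)
  expect_equal(fx$young_bound[nrow(fx)], 0)

  geo <- make_timescale("geological")
  mio <- geo[geo$name == "Miocene", ]
  expect_equal(c(mio$old_bound, mio$young_bound), c(23.03, 5.333))
  expect_equal(geo$old_bound[1], 145)

  # 145 is not a multiple of 10: start raised with a warning
  expect_warning(fx10 <- make_timescale("fixed", width = 10, start = 145),
                 "raised to 150")
  expect_equal(nrow(fx10), 15L)
  expect_equal(fx10$old_bound[1], 150)

  expect_error(make_timescale("fixed", width = 0), "width")
  expect_error(make_timescale("custom",
                              bins = data.frame(name = c("a", "b"),
                                                old_bound = c(10, 4),
                                                young_bound = c(5, 0))),
               "contiguous")
})

test_that("bin assignment: boundaries belong to the bin they bound as old", {
  geo <- make_timescale("geological")
  expect_equal(as.character(assign_bin(66, geo)), "Paleocene")
  expect_equal(as.character(assign_bin(0, geo)), "Quaternary")
  expect_equal(as.character(assign_bin(145, geo)), "Early Cretaceous")
  expect_equal(as.character(assign_bin(23.03, geo)), "Miocene")
  expect_error(assign_bin(200, geo, names = "Oldtaxon"), "Oldtaxon")
  expect_error(assign_bin(-1, geo), ">= 0")

  # partition: 1000 uniform random ages each land in exactly one bin
  set.seed(31)
  ages <- runif(1000, 0, 145)
  b <- assign_bin(ages, geo)
  expect_false(anyNA(b))
  for (i in seq_len(nrow(geo))) {
    in_bin <- ages <= geo$old_bound[i] & (ages > geo$young_bound[i] |
                                            (i == nrow(geo) & ages == 0))
    expect_equal(unname(table(b)[geo$name[i]]), sum(in_bin))
  }
})

test_that("bin counts, percentages and rates are direct tallies", {
  div <- data.frame(rank = "species", name = c("s1", "s2", "s3"),
                    age_mya = c(1, 2, 12), monophyletic = TRUE,
                    n_lineages = 1L, at_root = FALSE)
  fx <- make_timescale("fixed", width = 5, start = 15)
  bc <- bin_counts(div, fx, rank = "species")
  expect_equal(bc$count[bc$bin == "5-0"], 2L)
  expect_equal(bc$percentage[bc$bin == "5-0"], 200 / 3)
  expect_equal(bc$count[bc$bin == "15-10"], 1L)
  expect_equal(bc$percentage[bc$bin == "15-10"], 100 / 3)
  expect_equal(bc$rate[bc$bin == "15-10"], 0.2)
  expect_equal(bc$count[bc$bin == "total"], 3L)

  one <- bin_counts(div[div$age_mya < 5, ], fx, rank = "species")
  expect_equal(one$percentage[one$bin == "5-0"], 100)
  expect_error(bin_counts(div[0, ], fx, rank = "species"), "no rows")
})

test_that("HT ratio algebra: bounds, antisymmetry, scale invariance, NA", {
  expect_equal(ht_ratio(50, 50), 0)
  expect_equal(ht_ratio(75, 25), 0.5)
  expect_true(is.na(ht_ratio(0, 0)))
  expect_error(ht_ratio(-1, 2), "non-negative")

  set.seed(8)
  H <- c(0, 0, rexp(200, 1 / 50))
  T <- c(0, 5, rexp(200, 1 / 50))
  r <- ht_ratio(H, T)
  defined <- !is.na(r)
  expect_true(all(abs(r[defined]) <= 1))
  expect_equal(ht_ratio(T, H), -r)
  for (k in c(0.01, 1, 7)) expect_equal(ht_ratio(k * H, k * T), r)
  expect_equal(ht_ratio(H, H), ifelse(H == 0, NA_real_, 0))
})

test_that("element trajectory: hand count on four genera", {
  div <- data.frame(rank = "genus",
                    name = c("tr1", "tr2", "te1", "te2"),
                    age_mya = c(30, 40, 8, 12), monophyletic = TRUE,
                    n_lineages = 1L, at_root = FALSE)
  tt <- data.frame(genus = div$name, type = c(2L, 7L, 8L, 14L))
  asg <- classify_genera(tt)
  fx <- make_timescale("fixed", width = 10, start = 50)
  tr <- element_trajectory(div, asg, fx)
  # boundary ages fall in the bin they bound as old: 40 -> (40,30], 30 -> (30,20]
  expect_equal(tr$ht_ratio[tr$bin == "40-30"], 1)
  expect_equal(tr$ht_ratio[tr$bin == "30-20"], 1)
  expect_equal(tr$ht_ratio[tr$bin == "20-10"], -1)
  expect_equal(tr$ht_ratio[tr$bin == "10-0"], -1)
  expect_true(is.na(tr$ht_ratio[tr$bin == "50-40"]))
  expect_equal(sum(tr$n_classified), 4L)
  expect_equal(crossover_time(tr), 20)

  # all widespread: H + T = 0 everywhere, every ratio missing
  ttw <- data.frame(genus = div$name, type = 1L)
  trw <- element_trajectory(div, classify_genera(ttw), fx)
  expect_true(all(is.na(trw$ht_ratio)))
  expect_true(is.na(crossover_time(trw)))

  expect_error(element_trajectory(div, asg[-1, ], fx), "unclassified")
})

test_that("type 15 can be excluded from the temperate count", {
  div <- data.frame(rank = "genus", name = c("g1", "g2", "g3"),
                    age_mya = c(4, 4, 4), monophyletic = TRUE,
                    n_lineages = 1L, at_root = FALSE)
  tt <- data.frame(genus = div$name, type = c(2L, 8L, 15L))
  asg <- classify_genera(tt)
  fx <- make_timescale("fixed", width = 5, start = 10)
  incl <- element_trajectory(div, asg, fx)
  excl <- element_trajectory(div, asg, fx, temperate_includes_type15 = FALSE)
  expect_equal(incl$T[incl$bin == "5-0"], 2L)
  expect_equal(excl$T[excl$bin == "5-0"], 1L)
  expect_equal(incl$ht_ratio[incl$bin == "5-0"], (1 - 2) / 3)
  expect_equal(excl$ht_ratio[excl$bin == "5-0"], 0)
})

test_that("crossover scanning old to young finds the youngest sign change", {
  fake <- data.frame(bin = c("40-30", "30-20", "20-10", "10-0"),
                     old_bound = c(40, 30, 20, 10),
                     young_bound = c(30, 20, 10, 0),
                     ht_ratio = c(0.4, 0.1, -0.2, -0.5))
  expect_equal(crossover_time(fake), 20)
  fake$ht_ratio <- c(0.4, 0.3, 0.2, 0.1)           # monotone positive
  expect_true(is.na(crossover_time(fake)))
  fake$ht_ratio <- c(0.4, -0.1, 0.3, -0.2)         # two changes: youngest wins
  expect_equal(crossover_time(fake), 10)
  fake$ht_ratio <- c(0.4, 0, NA, -0.2)             # zeros/NA skipped
  expect_equal(crossover_time(fake), 10)
})

test_that("simulated era-dependent labels land within binomial bounds per bin", {
  set.seed(77)
  tr <- simulate_bd_tree(n_tips = 500, birth = 0.1, death = 0)
  phy <- tr$phylo
  ages <- tr$node_age[phy$edge[match(seq_len(500), phy$edge[, 2L]), 1L]]
  div <- data.frame(rank = "genus", name = sprintf("g%03d", 1:500),
                    age_mya = ages, monophyletic = TRUE, n_lineages = 1L,
                    at_root = FALSE)
  lab <- simulate_element_labels(div, crossover = 10, steepness = 0.5,
                                 widespread_fraction = 0)
  asg <- classify_genera(lab$type_table)
  fx <- make_timescale("fixed", width = 5,
                       start = ceiling(max(ages) / 5) * 5)
  traj <- element_trajectory(div, asg, fx)
  # per-bin temperate share vs the mean logistic probability of that bin
  truth <- lab$truth
  truth$bin <- assign_bin(truth$age_mya, fx)
  for (b in levels(truth$bin)) {
    n <- sum(truth$bin == b)
    if (n < 10) next
    p <- mean(truth$p_temperate[truth$bin == b])
    obs <- traj$T[traj$bin == b]
    expect_lt(abs(obs - n * p), 3 * sqrt(n * p * (1 - p)) + 1e-9)
  }
  # conservation within the trajectory
  expect_equal(sum(traj$n_classified), 500L)
  expect_equal(traj$H + traj$T, traj$n_classified)
})
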