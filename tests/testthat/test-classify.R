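test_that("clutch classification implements the pure/mixed criteria", {
  expect_equal(classify_clutch(c("L1", "L1", "L2"), c("L", "L", "L")),
               "larviparous")
  expect_equal(classify_clutch(c("P2", "P2"), c("P", "P")), "pueriparous")
  # criterion 2: pure larvae and pure juveniles co-occurring
  expect_equal(classify_clutch(c("L1", "P2"), c("L", "P")), "mixed")
  # criterion 1: any member with transitional development
  expect_equal(classify_clutch(c("L1", "L1"), c("LP", "LP")), "mixed")
  expect_error(classify_clutch(character(0), character(0)), "empty")
})

test_that("clutch classification is permutation-invariant and mixed-absorbing", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    g <- sample(gill_stages(), n, replace = TRUE)
    p <- sample(pigment_stages(), n, replace = TRUE)
    m0 <- classify_clutch(g, p)
    perm <- sample(n)
    expect_equal(classify_clutch(g[perm], p[perm]), m0)
    # appending a mixed-phenotype member forces the clutch mixed
    expect_equal(classify_clutch(c(g, "L1"), c(p, "LP")), "mixed")
  }
})

test_that("partial clutches classify from staged members with a warning", {
  expect_warning(m <- classify_clutch(c("L1", "", "L2"), c("L", "", "L")),
                 "unstaged")
  expect_equal(m, "larviparous")
  expect_warning(m2 <- classify_clutch("", ""), "unstaged")
  expect_true(is.na(m2))
})

test_that("population mode aggregates clutch modes hierarchically", {
  expect_equal(classify_population(c("larviparous", "larviparous")), "larviparous")
  expect_equal(classify_population(c("pueriparous", "pueriparous")), "pueriparous")
  expect_equal(classify_population(c("larviparous", "pueriparous")), "mixed")
  expect_equal(classify_population(c("mixed", "larviparous")), "mixed")
  expect_true(is.na(classify_population(character(0))))
})

test_that("population purity propagates down to every offspring", {
  sim <- make_sim_dataset(seed = 17)
  cl <- clutch_summaries(sim$offspring)
  pops <- population_summaries(cl)
  for (i in seq_len(nrow(pops))) {
    if (is.na(pops$mode[i])) next
    sub <- cl[cl$population == pops$population[i], ]
    if (pops$mode[i] == "larviparous") {
      expect_true(all(sub$mode == "larviparous"))
      expect_true(all(sub$n_mixed == 0 & sub$n_juvenile == 0))
    }
    if (pops$mode[i] == "pueriparous") {
      expect_true(all(sub$mode == "pueriparous"))
      expect_true(all(sub$n_mixed == 0 & sub$n_larva == 0))
    }
  }
})

test_that("proportion rows sum to one at both levels", {
  sim <- make_sim_dataset(seed = 3)
  pc <- mode_proportions(sim$offspring, "clutch")
  expect_true(all(abs(pc$larva + pc$mixed + pc$juvenile - 1) < 1e-12))
  pp <- mode_proportions(sim$offspring, "population")
  expect_true(all(abs(pp$larviparous + pp$mixed + pp$pueriparous - 1) < 1e-12))
})

test_that("clutch-mode proportions reproduce the published population patterns", {
  # all-mixed clutches: fractions (0, 1, 0) in (larviparous, mixed, pueriparous)
  off_cervo <- data.frame(
    offspring_id = paste0("o", 1:4), female_id = rep(c("f1", "f2"), each = 2),
    population = "CER",
    gill_stage = c("L1", "L2", "L2", "P1"),
    pigment_stage = c("LP", "P", "L", "LP")
  )
  pp <- mode_proportions(off_cervo, "population")
  expect_equal(unlist(pp[1, c("larviparous", "mixed", "pueriparous")],
                      use.names = FALSE), c(0, 1, 0))
  # one larviparous + one pueriparous clutch: mixed population, (0.5, 0, 0.5)
  off_bel <- data.frame(
    offspring_id = paste0("o", 1:4), female_id = rep(c("f1", "f2"), each = 2),
    population = "BEL",
    gill_stage = c("L1", "L1", "P2", "P2"),
    pigment_stage = c("L", "L", "P", "P")
  )
  cl <- clutch_summaries(off_bel)
  expect_equal(classify_population(cl$mode), "mixed")
  pp2 <- mode_proportions(off_bel, "population")
  expect_equal(unlist(pp2[1, c("larviparous", "mixed", "pueriparous")],
                      use.names = FALSE), c(0.5, 0, 0.5))
})

test_that("success rates pool clutches over females within mode groups", {
  t1 <- table1_sampling()
  sr <- success_rates(t1)
  expect_equal(sr$overall, 27)
  rates <- setNames(sr$by_mode$rate_pct, sr$by_mode$group)
  expect_equal(unname(rates["pueriparous"]), 10)
  expect_equal(unname(rates["larviparous"]), 53)
  expect_equal(unname(rates["mixed"]), 43)
  # overall equals the clutch-weighted combination of groups when they
  # partition the populations with births
  with_births <- t1[t1$n_clutches > 0, ]
  expect_equal(sum(sr$by_mode$n_clutches), sum(with_births$n_clutches))
  # a group with females but no clutches has rate 0
  z <- data.frame(n_females_collected = 10, n_clutches = 0, mode = "larviparous")
  expect_equal(success_rates(z)$by_mode$rate_pct[1], 0)
})

test_that("transect profile sorts canonically by position then name", {
  ps <- data.frame(population = c("B", "A", "C"),
                   transect_position_km = c(10, 10, 0))
  out <- transect_profile(ps)
  expect_equal(out$population, c("C", "A", "B"))
  shuffled <- ps[c(3, 1, 2), ]
  expect_equal(transect_profile(shuffled), out)
  ps$transect_position_km[2] <- NA
  expect_error(transect_profile(ps), "position")
})
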