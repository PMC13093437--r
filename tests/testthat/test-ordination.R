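random_table <- function(nr, nc) {
  matrix(rpois(nr * nc, lambda = runif(1, 2, 15)) + 1, nr, nc,
         dimnames = list(paste0("r", seq_len(nr)), paste0("c", seq_len(nc))))
}

test_that("contingency construction matches direct counting in all variants", {
  off <- data.frame(
    offspring_id = paste0("o", 1:5),
    female_id = c("fA", "fA", "fA", "fB", "fB"),
    population = c("A", "A", "A", "B", "B"),
    gill_stage = c("L1", "L1", "L1", "P2", "P2"),
    pigment_stage = c("L", "L", "L", "P", "P")
  )
  comb <- suppressWarnings(build_contingency(off, "combined"))
  expect_equal(unname(comb), matrix(c(3L, 0L, 0L, 2L), 2, 2))
  expect_equal(colnames(comb), c("L1_L", "P2_P"))
  stk <- suppressWarnings(build_contingency(off, "stacked"))
  # zero columns (L2, P1, LP) dropped; remaining gill block then pigment block
  expect_equal(colnames(stk), c("L1", "P2", "L", "P"))
  expect_equal(unname(stk["A", ]), c(3L, 0L, 3L, 0L))
  expect_true(all(rowSums(suppressWarnings(build_contingency(off, "gill"))) ==
                    c(3, 2)))
  # population with only unstaged offspring is dropped with a warning
  off2 <- rbind(off, data.frame(offspring_id = "o6", female_id = "fC",
                                population = "C", gill_stage = "",
                                pigment_stage = ""))
  w <- capture_warnings(build_contingency(off2, "gill"))
  expect_true(any(grepl("no staged offspring: C", w)))
})

test_that("chi-square statistic matches hand computation and exact independence", {
  res <- chi_square_independence(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(res$statistic, 20)  # all expected counts are 5
  expect_equal(res$df, 1)
  # proportional rows: statistic 0
  ind <- outer(c(10, 20, 30), c(1, 2, 4))
  expect_equal(chi_square_independence(ind)$statistic, 0, tolerance = 1e-12)
})

test_that("total inertia equals chi-square over n on random tables", {
  set.seed(7)
  for (rep in 1:20) {
    tab <- random_table(sample(3:12, 1), sample(3:7, 1))
    ca <- correspondence_analysis(tab)
    chi <- chi_square_independence(tab)
    expect_equal(ca$total_inertia, chi$statistic / sum(tab), tolerance = 1e-9)
    if (length(ca$pct_variance)) {
      expect_equal(sum(ca$pct_variance), 100, tolerance = 1e-9)
    }
  }
})

test_that("association structure sets the CA rank", {
  # any associated 2x2 table: one axis carrying 100%
  ca2 <- correspondence_analysis(matrix(c(8, 2, 3, 9), 2, 2))
  expect_equal(length(ca2$principal_inertias), 1L)
  expect_equal(unname(ca2$pct_variance), 100)
  # exactly independent table: no non-trivial dimension, zero inertia
  ind <- outer(c(5, 10), c(2, 3, 5))
  cai <- correspondence_analysis(ind)
  expect_equal(length(cai$principal_inertias), 0L)
  expect_equal(cai$total_inertia, 0, tolerance = 1e-12)
})

test_that("CA satisfies the transition formula and centering", {
  set.seed(99)
  for (rep in 1:10) {
    tab <- random_table(6, 5)
    ca <- correspondence_analysis(tab)
    # transition formula: row principal coords are the row-profile averages
    # of the standard column coordinates (equivalently, row standard coords
    # scaled by sigma_k per axis)
    P <- tab / sum(tab)
    profiles <- sweep(P, 1, rowSums(P), "/")
    trans <- profiles %*% ca$col_coords_standard
    expect_equal(unname(ca$row_coords_principal), unname(trans),
                 tolerance = 1e-9)
    # mass-weighted row coordinates centre at zero on every axis
    ctr <- drop(ca$row_masses %*% ca$row_coords_principal)
    expect_true(all(abs(ctr) < 1e-9))
    # scaling all counts by an integer changes nothing
    ca3 <- correspondence_analysis(tab * 3L)
    expect_equal(ca3$row_coords_principal, ca$row_coords_principal,
                 tolerance = 1e-9)
    expect_equal(ca3$total_inertia, ca$total_inertia, tolerance = 1e-12)
  }
})

test_that("principal inertias agree with an independent CA implementation", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (rep in 1:5) {
    tab <- random_table(8, 6)
    ca <- correspondence_analysis(tab)
    ref <- vegan::cca(as.data.frame(tab))
    ev <- ref$CA$eig
    expect_equal(unname(ca$principal_inertias),
                 unname(ev[seq_along(ca$principal_inertias)]),
                 tolerance = 1e-8)
  }
})

test_that("biplot export styles share rows and differ in column scaling", {
  tab <- random_table(5, 4)
  ca <- correspondence_analysis(tab)
  sym <- biplot_export(ca, "symmetric")
  asym <- biplot_export(ca, "asymmetric")
  expect_equal(sym[sym$set == "row", ], asym[asym$set == "row", ])
  expect_false(isTRUE(all.equal(sym[sym$set == "column", "Dim1"],
                                asym[asym$set == "column", "Dim1"])))
  expect_error(biplot_export(ca, ndim = 10), "dimensions")
  ca2 <- correspondence_analysis(matrix(c(8, 2, 3, 9), 2, 2))
  expect_equal(attr(biplot_export(ca2), "pct_variance"),
               c(Dim1 = 100))
})

test_that("dimension-1 scores track the transect on steep-cline data", {
  sim <- simulate_transect(cline_params(width = 5, seed = 19))
  tab <- suppressWarnings(build_contingency(sim$offspring, "stacked"))
  ca <- correspondence_analysis(tab)
  pos <- sim$populations$transect_position_km[
    match(rownames(ca$row_coords_principal), sim$populations$population)]
  rho <- cor(ca$row_coords_principal[, 1], pos, method = "spearman")
  expect_gt(abs(rho), 0.8)
})
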