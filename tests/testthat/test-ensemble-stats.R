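RT310 <- 1.987204259e-3 * 310.15

test_that("Boltzmann percentages sum to 100 and follow the energy order", {
  rel <- relative_energy_table("only", 0)
  expect_equal(boltzmann_percentages(rel)$table$bp_percent, 100)

  rel4 <- relative_energy_table(letters[1:4], rep(0, 4))
  expect_equal(boltzmann_percentages(rel4)$table$bp_percent, rep(25, 4))

  # dG = RT ln 2 -> exactly 2:1 population
  rel2 <- relative_energy_table(c("a", "b"), c(0, RT310 * log(2)))
  bp <- boltzmann_percentages(rel2, T = 310.15)
  expect_equal(bp$table$bp_percent, c(200 / 3, 100 / 3), tolerance = 1e-10)

  set.seed(6)
  relr <- relative_energy_table(sprintf("c%d", 1:30), runif(30, 0, 8))
  pop <- boltzmann_percentages(relr)
  expect_equal(sum(pop$table$bp_percent), 100, tolerance = 1e-8)
  # monotone: bp decreasing in dG
  expect_true(all(diff(pop$table$dg_kcal[order(-pop$table$bp_percent)])
                  >= -1e-12))

  expect_error(boltzmann_percentages(relr, complete = FALSE),
               "incomplete")
})

test_that("populations flatten as temperature rises", {
  rel <- relative_energy_table(c("a", "b", "c"), c(0, 1, 3))
  lo <- boltzmann_percentages(rel, T = 310.15)$table
  hi <- boltzmann_percentages(rel, T = 620.3)$table
  for (id in c("b", "c")) {
    expect_gt(hi$bp_percent[hi$conformer_id == id],
              lo$bp_percent[lo$conformer_id == id])
  }
})

test_that("stabilization correction matches its closed forms", {
  expect_equal(stabilization_correction(
    relative_energy_table("a", 0))$dg_stab, 0)
  expect_equal(stabilization_correction(
    relative_energy_table(c("a", "b"), c(0, 0)))$dg_stab,
    -RT310 * log(2), tolerance = 1e-12)
  expect_equal(stabilization_correction(
    relative_energy_table(c("a", "b"), c(0, 0.5)))$dg_stab,
    -RT310 * log(1 + exp(-0.5 / RT310)), tolerance = 1e-12)
  # n degenerate conformers -> -RT ln n
  for (n in c(3, 7, 20)) {
    expect_equal(stabilization_correction(
      relative_energy_table(sprintf("c%d", 1:n), rep(0, n)))$dg_stab,
      -RT310 * log(n), tolerance = 1e-10)
  }
})

test_that("stabilization and populations are mutually consistent", {
  set.seed(99)
  for (k in 1:20) {
    n <- sample(2:40, 1)
    rel <- relative_energy_table(sprintf("c%d", 1:n),
                                 c(0, runif(n - 1, 0, 8)))
    st <- stabilization_correction(rel)
    expect_lte(st$dg_stab, 0)
    lhs <- exp(-st$dg_stab / RT310)
    rhs <- sum(exp(-rel$table$dg_kcal / RT310))
    expect_equal(lhs, rhs, tolerance = 1e-9)
    # adding a conformer can only stabilize further
    rel_plus <- relative_energy_table(c(rel$table$conformer_id, "extra"),
                                      c(rel$table$dg_kcal, 5))
    expect_lte(stabilization_correction(rel_plus)$dg_stab, st$dg_stab)
  }
})

test_that("population subsets use strict 'above-cutoff' comparison", {
  pop <- structure(list(
    table = data.frame(conformer_id = c("a", "b", "c"),
                       dg_kcal = c(0, 0.3, 0.55),
                       bp_percent = c(50, 30, 20),
                       stringsAsFactors = FALSE),
    temperature = 310.15, level_label = "CBS(DTQ)", complete_flag = TRUE),
    class = "population_table")
  expect_identical(population_subset(pop, 25), c("a", "b"))
  # conformer exactly at the cutoff is excluded
  expect_identical(population_subset(pop, 20), c("a", "b"))
  expect_identical(population_subset(pop, 0), c("a", "b", "c"))
  expect_error(population_subset(pop, 100), "\\[0, 100\\)")
})

test_that("the census counts classes over the population subset", {
  rel <- relative_energy_table(sprintf("c%d", 1:4), c(0, 0.2, 0.4, 6))
  pop <- boltzmann_percentages(rel)
  labs <- c(c1 = "cis", c2 = "gauche", c3 = "cis", c4 = "trans")
  cen <- conformer_type_census(labs, pop, cutoff = 0.5)
  expect_equal(unname(cen$counts), c(2L, 0L, 1L))
  expect_equal(cen$n_total, 3L)
  # cutoff above the maximum population -> empty census
  cen0 <- conformer_type_census(labs, pop, cutoff = 99)
  expect_equal(sum(cen0$counts), 0L)
  expect_error(conformer_type_census(labs[1:2], pop, cutoff = 0.1),
               "no conformation label")
})

test_that("pharmacology correlations recover monotone relationships", {
  x <- setNames(seq(-1.2, -0.1, length.out = 8), sprintf("%d", 1:8))
  pharm <- data.frame(analog_id = sprintf("%d", 1:8),
                      ki_nM = exp(seq(0, 3.5, length.out = 8)),
                      ec50_nM = as.character(10^seq(0, 3.5,
                                                    length.out = 8)),
                      stringsAsFactors = FALSE)
  rep <- pharmacology_correlation(x, pharm)
  sp_ki <- rep$report$coefficient[rep$report$endpoint == "ki" &
                                    rep$report$method == "spearman"]
  expect_equal(sp_ki, 1, tolerance = 1e-12)
  rev_rep <- pharmacology_correlation(-x, pharm)
  expect_equal(rev_rep$report$coefficient[rev_rep$report$endpoint == "ki" &
    rev_rep$report$method == "spearman"], -1, tolerance = 1e-12)

  expect_error(pharmacology_correlation(x[1:2], pharm), "at least 3")
})

test_that("published stabilization energies show no correlation with potency", {
  summ <- analog_funnel_summary()
  pharm <- fentanyl_pharmacology()
  per_analog <- setNames(summ$dg_stab_kcal, summ$analog_id)
  rep <- pharmacology_correlation(per_analog, pharm)

  # independent oracle for the Ki rank correlation
  ki <- pharm$ki_nM
  rho_oracle <- {
    rx <- rank(unname(per_analog)); ry <- rank(ki)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  sp_ki <- rep$report$coefficient[rep$report$endpoint == "ki" &
                                    rep$report$method == "spearman"]
  expect_equal(sp_ki, rho_oracle, tolerance = 1e-10)
  # the published negative finding: no meaningful correlation
  expect_lt(abs(sp_ki), 0.5)
  pe <- rep$report$coefficient[rep$report$endpoint == "ec50" &
                                 rep$report$method == "pearson_log10"]
  expect_lt(abs(pe), 0.5)
})
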