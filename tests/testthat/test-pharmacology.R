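test_that("target inhibition follows the Hill model in internal units", {
  d <- drug("d", c(X = 1, Y = 4), hill_h = 1, K_primary = 1)
  expect_equal(target_inhibition(d, 1, "X", units = "internal"), 0.5)
  expect_equal(target_inhibition(d, 0, "X"), 0)
  expect_equal(target_inhibition(d, 4, "Y", units = "internal"), 0.5)
  expect_error(target_inhibition(d, 1, "Z"), "unknown target")
  expect_error(target_inhibition(d, -1), "dose")
  expect_error(drug("bad", c(X = 2, Y = 3)), "potency_fold = 1")
})

test_that("inhibition is strictly increasing and bounded below one", {
  d <- drug("d", c(X = 1), hill_h = 2, K_primary = 0.5)
  doses <- c(0.01, 0.1, 0.5, 1, 5, 50)
  inh <- target_inhibition(d, doses, "X")
  expect_true(all(diff(inh) > 0))
  expect_true(all(inh < 1))
})

test_that("the reference dose C yields 60% primary-target inhibition", {
  expect_equal(calibrate_C(drug("a", c(X = 1), hill_h = 1, K_primary = 1)), 1.5)
  expect_equal(calibrate_C(drug("b", c(X = 1), hill_h = 2, K_primary = 1)),
               sqrt(1.5))
  for (dr in load_fixture("drug_library")) {
    expect_equal(target_inhibition(dr, 1, units = "C"), 0.6, tolerance = 1e-9)
  }
})

test_that("selectivity rankings expand to cumulative potency folds", {
  expect_equal(selectivity_from_profile("A>B"), c(A = 1, B = 5))
  expect_equal(selectivity_from_profile("Jak2>Jak3>>Jak1>>>Tyk2"),
               c(Jak2 = 1, Jak3 = 5, Jak1 = 125, Tyk2 = 15625))
  expect_equal(selectivity_from_profile("Solo"), c(Solo = 1))
  expect_equal(selectivity_from_profile("A>B", fold_base = 2), c(A = 1, B = 2))
  expect_error(selectivity_from_profile("A>>"), "malformed")
})

test_that("the IC finder inverts a known synthetic curve", {
  doses <- exp(seq(log(0.01), log(10), length.out = 25))
  curve <- tibble::tibble(dose_c = doses,
                          reduction_pct = 100 * doses / (doses + 1))
  attr(curve, "evaluator") <- function(d) 100 * d / (d + 1)
  # analytic inversion: R(d) = 50 at d = 1
  expect_equal(find_IC(curve, 50), 1, tolerance = 2e-3)
  expect_equal(find_IC(curve, 0), doses[1])

  flat <- tibble::tibble(dose_c = doses, reduction_pct = 40 * doses / (doses + 1))
  expect_error(find_IC(flat, 50), "level not reached")
})

test_that("combination index arithmetic and verdicts match Loewe", {
  expect_equal(combination_index(2, 0, 2, 3)$ci, 1)
  expect_identical(combination_index(2, 0, 2, 3)$verdict, "additive")
  res <- combination_index(0.5 * 2, (1 / 3) * 3, 2, 3)
  expect_equal(res$ci, 5 / 6)
  expect_identical(res$verdict, "synergy")
  res2 <- combination_index((1 / 3) * 2, 0.5 * 3, 2, 3)
  expect_equal(res2$ci, 5 / 6)
  expect_error(combination_index(1, 1, 0, 1), "IC50s must be > 0")
})

test_that("an exactly Loewe-additive surface yields CI = 1 contours", {
  grid <- loewe_surface(2, 3, seq(0, 2.4, by = 0.1), seq(0, 3.6, by = 0.15))
  iso <- isobologram(grid, 50)
  expect_equal(iso$ic50_a, 2, tolerance = 0.01)
  expect_equal(iso$ic50_b, 3, tolerance = 0.01)
  expect_true(all(abs(iso$pairs$ci - 1) <= 0.02))
})

test_that("a sham self-combination surface traces the dose-addition line", {
  # same agent on both axes: response depends only on the summed dose
  doses <- seq(0, 2.4, by = 0.1)
  grid <- expand.grid(dose_a = doses, dose_b = doses)
  tot <- (grid$dose_a + grid$dose_b) / 2
  grid$reduction_pct <- 100 * tot / (tot + 1)
  iso <- isobologram(tibble::as_tibble(grid), 50)
  expect_true(all(abs(iso$pairs$dose_a + iso$pairs$dose_b - 2) <= 0.05))
  expect_true(all(abs(iso$pairs$ci - 1) <= 0.05))
})

test_that("default dose grid spans C/1000 to 10C in 25 log steps", {
  g <- default_dose_grid()
  expect_length(g, 25)
  expect_equal(g[1], 1e-3)
  expect_equal(g[25], 10)
  expect_true(all(diff(log(g)) - diff(log(g))[1] < 1e-12))
})

test_that("combination grid margins reproduce single-agent runs bitwise", {
  av <- hel_avatar()
  g6 <- load_fixture("G6")
  abt <- load_fixture("ABT737")
  doses <- c(0, 1, 3)
  grid <- combination_grid(av, g6, abt, doses, doses)
  single_a <- dose_response(av, g6, doses[-1])
  margin_a <- dplyr::arrange(dplyr::filter(grid, dose_b == 0, dose_a > 0), dose_a)
  expect_identical(margin_a$reduction_pct, single_a$reduction_pct)
  single_b <- dose_response(av, abt, doses[-1])
  margin_b <- dplyr::arrange(dplyr::filter(grid, dose_a == 0, dose_b > 0), dose_b)
  expect_identical(margin_b$reduction_pct, single_b$reduction_pct)
})

test_that("drug files round-trip through the YAML library format", {
  lib <- load_fixture("drug_library")
  g6 <- lib$G6
  expect_equal(g6$targets,
               c(JAK2 = 1, JAK3 = 5, JAK1 = 125, TYK2 = 15625))
  expect_identical(primary_target <- names(g6$targets)[g6$targets == 1], "JAK2")
  expect_equal(lib$ABT737$targets, c(BCL2 = 1, BCL2L1 = 5))
})
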