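toy_state <- function(...) {
  vals <- c(...)
  base <- stats::setNames(rep(0.5, 14), c(
    "CDK4_CCND1", "CDK2_CCNE1", "CDK2_CCNA2", "CDK1_CCNB1",
    "AKT1", "BCL2", "MCL1", "BIRC5", "BIRC2", "XIAP",
    "BAX", "CASP3", "NOXA", "CASP8"
  ))
  base[names(vals)] <- vals
  base
}

test_that("proliferation index is the weighted complex average", {
  st <- toy_state(CDK4_CCND1 = 0.2, CDK2_CCNE1 = 0.4, CDK2_CCNA2 = 0.6,
                  CDK1_CCNB1 = 0.8)
  expect_equal(proliferation_index(st), 0.5)
  def <- index_definition(proliferation = c(CDK4_CCND1 = 1, CDK2_CCNE1 = 0,
                                            CDK2_CCNA2 = 0, CDK1_CCNB1 = 0))
  expect_equal(proliferation_index(st, def), 0.2)
  st0 <- toy_state(CDK4_CCND1 = 0, CDK2_CCNE1 = 0, CDK2_CCNA2 = 0,
                   CDK1_CCNB1 = 0)
  expect_equal(proliferation_index(st0), 0)
  expect_error(proliferation_index(c(A = 1)), "missing")
})

test_that("viability is survival over apoptosis with an epsilon guard", {
  st <- toy_state(AKT1 = 0.5, BCL2 = 0.5, MCL1 = 0.5, BIRC5 = 0.5,
                  BIRC2 = 0.5, XIAP = 0.5,
                  BAX = 0.25, CASP3 = 0.25, NOXA = 0.25, CASP8 = 0.25)
  v <- viability_index(st)
  expect_equal(v$ratio, 2)
  expect_false(v$guarded)

  st_sym <- toy_state()
  expect_equal(viability_index(st_sym)$ratio, 1)

  st0 <- toy_state(BAX = 0, CASP3 = 0, NOXA = 0, CASP8 = 0)
  v0 <- viability_index(st0)
  expect_true(is.finite(v0$ratio))
  expect_true(v0$guarded)
})

test_that("viability is invariant to a common activity rescaling", {
  st <- toy_state(AKT1 = 0.6, BCL2 = 0.3, BAX = 0.2, CASP3 = 0.1)
  for (k in c(0.2, 0.5, 2)) {
    expect_equal(viability_index(st * k)$ratio, viability_index(st)$ratio,
                 tolerance = 1e-12)
  }
})

test_that("viability normalization pins the baseline at exactly 100", {
  expect_identical(normalize_viability(2, 2), 100)
  expect_equal(normalize_viability(1, 2), 50)
  expect_equal(normalize_viability(0, 2), 0)
  expect_error(normalize_viability(1, 0), "baseline")
})

test_that("index weights must be a normalized simplex point", {
  expect_error(index_definition(apoptosis = c(BAX = 0.5, CASP3 = 0.4)),
               "sum to 1")
  expect_error(index_definition(apoptosis = c(BAX = 1.5, CASP3 = -0.5)),
               ">= 0")
  w <- uniform_weights(c("a", "b", "c"))
  expect_equal(sum(w), 1)
})

test_that("calibration recovers hidden weights from synthetic trends", {
  # marker-only toy network: each perturbation hits a distinct index member
  nodes <- data.frame(id = names(toy_state()),
                      basal_drive = c(rep(0.5, 4), rep(0.6, 6), rep(0.3, 4)))
  net <- network_spec(nodes)
  hidden <- index_definition(
    proliferation = c(CDK4_CCND1 = 0.7, CDK2_CCNE1 = 0.3, CDK2_CCNA2 = 0,
                      CDK1_CCNB1 = 0),
    survival = c(AKT1 = 0.5, BCL2 = 0.5, MCL1 = 0, BIRC5 = 0, BIRC2 = 0,
                 XIAP = 0),
    apoptosis = c(BAX = 0.6, CASP3 = 0.4, NOXA = 0, CASP8 = 0)
  )
  perturb <- list(
    hit_prolif = modifier_set(activity_multiplier = c(CDK4_CCND1 = 0.2)),
    hit_surv = modifier_set(activity_multiplier = c(AKT1 = 0.3)),
    hit_apop = modifier_set(production_scaler = c(BAX = 2, CASP3 = 1.5)),
    hit_other = modifier_set(activity_multiplier = c(NOXA = 0.1, BIRC5 = 0.1))
  )
  fix <- generate_trend_fixture(net, hidden, perturb,
                                schedule = stage_schedule(15000, 30000, 45000))
  cal <- calibrate_weights(fix$cases, fix$trends)
  expect_equal(cal$agreement, 1)
  expect_true(all(cal$details$match))
  # calibrated weights stay on the simplex
  for (w in unclass(cal$definition)) expect_equal(sum(w), 1)
})

test_that("an all-unchanged trend table falls back to uniform weights", {
  nodes <- data.frame(id = names(toy_state()), basal_drive = 0.5)
  net <- network_spec(nodes)
  fix <- generate_trend_fixture(net, index_definition(), list(
    nothing = modifier_set()
  ), schedule = stage_schedule(15000, 30000, 45000))
  expect_true(all(fix$trends$direction == "unchanged"))
  cal <- calibrate_weights(fix$cases, fix$trends)
  expect_equal(cal$agreement, 1)
  expect_equal(cal$definition$survival, uniform_weights(names(index_definition()$survival)))
  expect_equal(cal$definition$apoptosis, uniform_weights(names(index_definition()$apoptosis)))
})

test_that("calibration is deterministic for a fixed lattice", {
  nodes <- data.frame(id = names(toy_state()), basal_drive = 0.4)
  net <- network_spec(nodes)
  fix <- generate_trend_fixture(net, index_definition(), list(
    p = modifier_set(activity_multiplier = c(BCL2 = 0.2, BAX = 0.9))
  ), schedule = stage_schedule(15000, 30000, 45000))
  c1 <- calibrate_weights(fix$cases, fix$trends)
  c2 <- calibrate_weights(fix$cases, fix$trends)
  expect_identical(c1$definition, c2$definition)
  expect_identical(c1$agreement, c2$agreement)
})
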