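test_that("stage schedules enforce the ordering invariant", {
  s <- stage_schedule()
  expect_equal(s$control_end, 50000)
  expect_equal(s$disease_end, 125000)
  expect_equal(s$treatment_end, 200000)
  expect_error(stage_schedule(100, 50, 200), "control_end < disease_end")
})

test_that("percent change is epsilon-guarded and signed as expected", {
  expect_equal(percent_change(2, 1), 100)
  expect_equal(percent_change(0.5, 1), -50)
  pc <- percent_change(1, 0)
  expect_true(is.finite(pc))
  expect_gt(pc, 1e6)
})

test_that("an all-zero-drive network is steady at zero activity", {
  net <- network_spec(data.frame(id = c("A", "B"), basal_drive = 0))
  ctrl <- run_control(net)
  expect_true(ctrl$steady$is_steady)
  expect_equal(unname(ctrl$state), c(0, 0))
})

test_that("an unsettled control stage raises with the worst-drift nodes", {
  slow <- network_spec(data.frame(id = "S", basal_drive = 0.5, tau = 40000))
  expect_error(run_control(slow, stage_schedule(50000, 125000, 200000)),
               "not steady.*S")
})

test_that("empty profile, condition and treatment are identities", {
  net <- chain_network()
  av <- build_avatar(net, schedule = stage_schedule(20000, 40000, 60000),
                     definition = chain_definition())
  expect_lt(max(abs(av$disease_state - av$control_state)), 1e-9)

  run <- simulate_treatment(av, list())
  expect_lt(max(abs(run$treated_state - av$disease_state)), 1e-9)
  expect_equal(run$phenotypes$normalized_viability_percent, 100)

  fake <- drug("null", c(B = 1))
  run0 <- simulate_treatment(av, list(list(drug = fake, dose_c = 0)))
  expect_lt(max(abs(run0$treated_state - av$disease_state)), 1e-9)
})

test_that("cytokine conditions validate their ligand ids", {
  net <- load_fixture("mpn_network")
  expect_error(
    build_avatar(net, load_fixture("HEL"),
                 cytokines = cytokine_condition(NOPE = 1)),
    "boundary ligand"
  )
  expect_error(cytokine_condition(IL6 = 2), "x >= 0 & x <= 1")
})

test_that("same-drug doses add while distinct drugs compose multiplicatively", {
  net <- chain_network()
  av <- build_avatar(net, schedule = stage_schedule(20000, 40000, 60000),
                     definition = chain_definition())
  d1 <- drug("d1", c(B = 1))
  split_dose <- simulate_treatment(av, list(list(drug = d1, dose_c = 0.5),
                                            list(drug = d1, dose_c = 0.5)))
  whole_dose <- simulate_treatment(av, list(list(drug = d1, dose_c = 1)))
  expect_identical(split_dose$treated_state, whole_dose$treated_state)

  d2 <- drug("d2", c(B = 1))
  both <- simulate_treatment(av, list(list(drug = d1, dose_c = 1),
                                      list(drug = d2, dose_c = 1)))
  # shared target: survivals multiply, (1 - 0.6)^2 = 0.16 effective activity
  i <- target_inhibition(d1, 1)
  expected <- compose_modifiers(drug_modifiers(d1, 1), drug_modifiers(d2, 1))
  expect_equal(expected$activity_multiplier[["B"]], (1 - i)^2)
  expect_lt(both$treated_state[["B"]], whole_dose$treated_state[["B"]])
})

test_that("staging composes: disease then drug equals pre-composed modifiers", {
  net <- chain_network()
  sched <- stage_schedule(20000, 40000, 60000)
  prof <- genomic_profile("p", data.frame(gene = "A", kind = "mutation",
                                          functional_call = "gof"))
  av <- build_avatar(net, prof, schedule = sched, definition = chain_definition())
  d <- drug("d", c(B = 1))
  run <- simulate_treatment(av, list(list(drug = d, dose_c = 1)))

  pre <- compose_modifiers(av$disease_mods, drug_modifiers(d, 1))
  direct <- final_state(simulate_network(net, pre, y_init = av$disease_state,
                                         t0 = sched$disease_end,
                                         t1 = sched$treatment_end))
  expect_identical(run$treated_state, direct)
})

test_that("readouts cover all non-ligand nodes plus the four indices", {
  av <- hel_avatar()
  run <- simulate_treatment(av, list(list(drug = load_fixture("G6"), dose_c = 1)))
  tab <- readouts(run)
  n_nodes <- nrow(av$network$nodes) - length(av$network$boundary_ligands)
  expect_identical(nrow(tab), n_nodes + 4L)
  expect_true(all(is.finite(tab$pct_change)))
  expect_false(any(av$network$boundary_ligands %in% tab$marker))
})

test_that("a clamped cytokine with a silenced receptor changes no readout", {
  av <- hel_avatar() # IL6R production is zeroed by the HEL profile
  av_il6 <- apply_microenvironment(av, cytokine_condition(IL6 = 1))
  r0 <- readouts(simulate_treatment(av))
  r1 <- readouts(simulate_treatment(av_il6))
  expect_lt(max(abs(r1$pct_change - r0$pct_change)), 1e-6)
  node_markers <- setdiff(node_ids <- av$network$nodes$id,
                          av$network$boundary_ligands)
  expect_lt(max(abs(av_il6$disease_state[node_markers] -
                      av$disease_state[node_markers])), 1e-6)
})

test_that("tidy and glance methods expose runs as tables", {
  av <- hel_avatar()
  run <- simulate_treatment(av, list(list(drug = load_fixture("G6"), dose_c = 1)))
  expect_identical(tidy(run), readouts(run))
  g <- glance(run)
  expect_identical(g$treatment, "G6@1C")
  expect_lt(g$normalized_viability_percent, 100)
  expect_identical(glance(av)$profile, "HEL")
  expect_true(glance(av)$control_steady)
  td <- tidy(av)
  expect_identical(nrow(td), nrow(av$network$nodes))
})
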