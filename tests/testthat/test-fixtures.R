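test_that("the curated MPN network contains the documented pathway arms", {
  net <- load_fixture("mpn_network")
  expect_identical(nrow(validate_network(net)), 0L)
  expected <- c(
    "JAK2", "STAT5", "STAT3", "STAT1", "PI3K", "AKT1", "SHC1", "ERK", "NFKB",
    "BCL2", "MCL1", "BIM", "CASP3", "CASP7", "CASP8", "CASP9", "PARPc",
    "BAX", "NOXA", "BIRC5", "BIRC2", "XIAP", "TP53", "RB1", "E2F1", "CDKN2A",
    "CDK4_CCND1", "CDK2_CCNE1", "CDK2_CCNA2", "CDK1_CCNB1",
    "IL6", "IL6R", "TNFA", "TNFR", "IFNG", "IFNGR"
  )
  expect_true(all(expected %in% net$nodes$id))
  expect_setequal(net$boundary_ligands, c("IL6", "TNFA", "IFNG"))
  # every index marker resolves to a node
  def <- index_definition()
  expect_true(all(c(names(def$proliferation), names(def$survival),
                    names(def$apoptosis)) %in% net$nodes$id))
})

test_that("cell-line profiles carry their documented aberrations", {
  hel <- load_fixture("HEL")
  expect_setequal(
    paste(hel$aberrations$gene, hel$aberrations$kind),
    c("JAK2 mutation", "TP53 mutation", "CDKN2A deletion",
      "RB1 deletion", "E2F1 amplification")
  )
  set2 <- load_fixture("SET2")
  expect_setequal(
    set2$aberrations$gene,
    c("JAK2", "RPTOR", "TP53", "CCNA2", "NOTCH2", "EGF", "MAP2K1")
  )
  expect_true(all(set2$aberrations$kind == "mutation"))
  for (p in list(hel, set2)) {
    expect_identical(p$receptor_expression[["IL6R"]], "absent")
  }
})

test_that("every bundled drug target and trend marker is in-network", {
  net <- load_fixture("mpn_network")
  for (dr in load_fixture("drug_library")) {
    expect_true(all(names(dr$targets) %in% net$nodes$id))
  }
  for (tt in list(load_fixture("trend_set2_jaki"), load_fixture("trend_hel_jaki1"))) {
    expect_true(all(tt$marker %in% net$nodes$id))
  }
  expect_identical(nrow(load_fixture("trend_set2_jaki")), 8L)
  expect_identical(nrow(load_fixture("trend_hel_jaki1")), 4L)
})

test_that("fixture content is pinned by hash", {
  fx <- list_fixtures()
  expect_true(all(nchar(fx$md5) == 32))
  pinned <- c(
    mpn_network = "3752d9bdc77935c378a7e58ccc11eacf", HEL = "202ec67951430f5d1d5901ff6f64065b", SET2 = "d571266dd49389ad12a214e4b50a5667",
    drug_library = "a5d69ae9b784c37305ab5bf541b9474b"
  )
  expect_identical(fx$md5[match(names(pinned), fx$name)], unname(pinned))
})

test_that("unknown fixture names are rejected", {
  expect_error(load_fixture("nope"), "unknown fixture")
})

test_that("random network generation is seed-deterministic and valid", {
  n1 <- generate_random_network(5, density = 0.3, seed = 1)
  n2 <- generate_random_network(5, density = 0.3, seed = 1)
  expect_identical(n1, n2)
  n3 <- generate_random_network(5, density = 0.3, seed = 2)
  expect_false(identical(n1$interactions, n3$interactions))
  for (seed in 1:5) {
    net <- generate_random_network(7, density = 0.25, seed = seed)
    expect_identical(nrow(validate_network(net)), 0L)
    expect_false(any(net$interactions$source == net$interactions$target))
  }
})

test_that("minimal random networks respect combinatorial bounds and connectivity", {
  tiny <- generate_random_network(2, density = 1, seed = 3)
  expect_lte(nrow(tiny$interactions), 2)
  # the spanning chain guarantees weak connectivity even at minimal density
  for (seed in 1:3) {
    net <- generate_random_network(8, density = 0.02, seed = seed)
    g <- igraph::graph_from_data_frame(as.data.frame(net$interactions),
                                       vertices = as.data.frame(net$nodes))
    expect_true(igraph::is_connected(g, mode = "weak"))
  }
})

test_that("trend fixtures close the loop from hidden perturbations", {
  net <- chain_network()
  fix <- generate_trend_fixture(
    net,
    hidden_definition = index_definition(
      proliferation = c(A = 1), survival = c(A = 0.5, B = 0.5),
      apoptosis = c(B = 1)
    ),
    perturbations = list(none = modifier_set(),
                         kill_a = modifier_set(activity_multiplier = c(A = 0.1))),
    schedule = stage_schedule(15000, 30000, 45000)
  )
  none_rows <- fix$trends[fix$trends$condition == "none", ]
  expect_true(all(none_rows$direction == "unchanged"))
  kill <- fix$trends[fix$trends$condition == "kill_a", ]
  expect_identical(
    kill$direction[kill$marker == "proliferation_index"], "down")
})
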