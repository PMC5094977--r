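# Fixed-step explicit-Euler reference integrator, independent of the
# adaptive solver path it cross-checks. Uses the package's derivative()
# contract directly.
euler_integrate <- function(net, mods = modifier_set(), y_init = NULL,
                            t0 = 0, t1 = 10000, step = NULL) {
  ids <- net$nodes$id
  if (is.null(step)) step <- min(net$nodes$tau) / 100
  y <- if (is.null(y_init)) stats::setNames(net$nodes$y0, ids) else y_init[ids]
  clamp <- NULL
  if (length(mods$ligand_clamp) > 0) {
    clamp <- mods$ligand_clamp
    y[names(clamp)] <- clamp
  }
  t <- t0
  while (t < t1 - 1e-9) {
    h <- min(step, t1 - t)
    y <- y + h * derivative(y, net, mods)
    if (!is.null(clamp)) y[names(clamp)] <- clamp
    t <- t + h
  }
  y
}

# Two-node chain with one activating edge; handy minimal network.
chain_network <- function(basal_a = 0.5, w = 0.8) {
  network_spec(
    data.frame(id = c("A", "B"), basal_drive = c(basal_a, 0), tau = 500),
    data.frame(source = "A", target = "B", sign = "activating", weight = w)
  )
}

# Index definition over the two-node chain, for protocol tests on
# networks that lack the canonical marker nodes.
chain_definition <- function() {
  index_definition(proliferation = c(A = 1), survival = c(A = 1),
                   apoptosis = c(B = 1))
}

# Memoized heavy fixtures so multiple test files share one protocol run.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
hel_avatar <- function() {
  cached("hel", build_avatar(load_fixture("mpn_network"), load_fixture("HEL")))
}
set2_avatar <- function() {
  cached("set2", build_avatar(load_fixture("mpn_network"), load_fixture("SET2")))
}
hel_g6_curve <- function() {
  cached("hel_g6_curve", dose_response(hel_avatar(), load_fixture("G6")))
}
hel_g6_ic50 <- function() {
  cached("hel_g6_ic50", find_IC(hel_g6_curve(), 50))
}
hel_abt_ic50 <- function() {
  cached("hel_abt_ic50", find_IC(dose_response(hel_avatar(), load_fixture("ABT737")), 50))
}
viability_reduction <- function(avatar, treatments) {
  run <- simulate_treatment(avatar, treatments)
  100 - run$phenotypes$normalized_viability_percent
}

# Loewe-additive analytic response surface: single agents follow
# R(d) = 100 * (d/ic50) / (d/ic50 + 1); the combination responds to the
# summed normalized dose. Exact CI = 1 everywhere by construction.
loewe_surface <- function(ic50_a, ic50_b, doses_a, doses_b) {
  grid <- expand.grid(dose_a = doses_a, dose_b = doses_b)
  u <- grid$dose_a / ic50_a + grid$dose_b / ic50_b
  grid$reduction_pct <- 100 * u / (u + 1) # single agents hit 50% at their ic50
  tibble::as_tibble(grid)
}
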