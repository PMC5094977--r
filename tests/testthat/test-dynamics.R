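test_that("edge transfer is anchored at f(0)=0 and f(1)=w", {
  expect_equal(edge_transfer(0, w = 0.8, K = 0.3, n = 2), 0)
  expect_equal(edge_transfer(1, w = 0.8, K = 0.3, n = 2), 0.8)
  # midpoint value from the closed form: 1 * (1 + 0.5) * 0.5 / (0.5 + 0.5)
  expect_equal(edge_transfer(0.5, w = 1, K = 0.5, n = 1), 0.75)
  expect_error(edge_transfer(1.2), "outside")
  expect_error(edge_transfer(-0.2), "outside")
})

test_that("edge transfer is monotone non-decreasing for varied parameters", {
  x <- seq(0, 1, length.out = 101)
  for (w in c(0.3, 0.9)) {
    for (K in c(0.2, 0.5, 0.8)) {
      for (n in c(1, 1.4, 3)) {
        f <- edge_transfer(x, w, K, n)
        expect_true(all(diff(f) >= -1e-12))
        expect_true(all(f >= 0 & f <= w + 1e-12))
      }
    }
  }
})

test_that("input combination follows noisy-OR with multiplicative inhibition", {
  expect_equal(combine_inputs(basal = 0.3), 0.3)
  expect_equal(combine_inputs(c(0.5, 0.5)), 0.75)
  expect_equal(combine_inputs(1, 1), 0)
  # AND-gated contributions multiply before pooling
  expect_equal(combine_inputs(c(0.5, 0.5), gates = c("AND", "AND")), 0.25)
  expect_equal(combine_inputs(c(0.5, 0.5, 0.5), gates = c("AND", "AND", "OR")),
               1 - (1 - 0.25) * (1 - 0.5))
})

test_that("drive is monotone in activations and antitone in inhibitions", {
  a <- seq(0, 1, by = 0.1)
  u_act <- vapply(a, function(v) combine_inputs(c(v, 0.3), c(0.2), 0.1), numeric(1))
  u_inh <- vapply(a, function(v) combine_inputs(c(0.3), c(v), 0.1), numeric(1))
  expect_true(all(diff(u_act) >= 0))
  expect_true(all(diff(u_inh) <= 0))
  expect_true(all(u_act >= 0 & u_act <= 1))
})

test_that("derivative honors the relaxation law and modifier semantics", {
  iso <- network_spec(data.frame(id = "A", basal_drive = 0, tau = 100))
  expect_equal(derivative(c(A = 0), iso), c(A = 0))

  iso1 <- network_spec(data.frame(id = "A", basal_drive = 1, tau = 100))
  expect_equal(derivative(c(A = 0), iso1), c(A = 0.01))

  # full target inhibition pushes activity toward 0
  rate <- derivative(c(A = 0.5), iso1,
                     modifier_set(activity_multiplier = c(A = 0)))
  expect_lt(rate[["A"]], 0)

  expect_error(derivative(c(B = 0), iso1), "dimensions")
})

test_that("rates are forward-invariant at the state bounds", {
  net <- chain_network()
  lo <- stats::setNames(rep(0, 2), c("A", "B"))
  hi <- stats::setNames(rep(1, 2), c("A", "B"))
  expect_true(all(derivative(lo, net) >= 0))
  expect_true(all(derivative(hi, net) <= 0))
})

test_that("a single basal-driven node matches the analytic relaxation", {
  net <- network_spec(data.frame(id = "A", basal_drive = 0.4, tau = 500))
  traj <- simulate_network(net, t1 = 4000, n_out = 81)
  analytic <- 0.4 * (1 - exp(-traj$time_s / 500))
  expect_lt(max(abs(traj$A - analytic)), 1e-6)
})

test_that("zero-drive networks stay identically zero and runs are deterministic", {
  net <- network_spec(
    data.frame(id = c("A", "B"), basal_drive = 0),
    data.frame(source = "A", target = "B", sign = "activating")
  )
  traj <- simulate_network(net, t1 = 5000)
  expect_true(all(as.matrix(traj[, c("A", "B")]) == 0))

  t1 <- simulate_network(chain_network(), t1 = 8000)
  t2 <- simulate_network(chain_network(), t1 = 8000)
  expect_identical(final_state(t1), final_state(t2))
})

test_that("clamped ligand nodes hold their clamp for the whole span", {
  net <- network_spec(
    data.frame(id = c("L", "X"), basal_drive = c(0, 0.2)),
    data.frame(source = "L", target = "X", sign = "activating"),
    boundary_ligands = "L"
  )
  traj <- simulate_network(net, modifier_set(ligand_clamp = c(L = 0.7)),
                           t1 = 10000)
  expect_true(all(traj$L == 0.7))
  expect_gt(final_state(traj)[["X"]], 0.2)
})

test_that("activities stay within bounds on random networks", {
  for (seed in 1:5) {
    net <- generate_random_network(n_nodes = 6, density = 0.4, seed = seed)
    traj <- simulate_network(net, t1 = 20000)
    vals <- as.matrix(traj[, net$nodes$id])
    expect_true(all(vals >= -1e-8 & vals <= 1 + 1e-8))
  }
})

test_that("adaptive integration agrees with the explicit-Euler oracle", {
  for (seed in 1:4) {
    net <- generate_random_network(n_nodes = 5, density = 0.35, seed = seed)
    adaptive <- final_state(simulate_network(net, t1 = 8000))
    euler <- euler_integrate(net, t1 = 8000)
    expect_lt(max(abs(adaptive - euler[names(adaptive)])), 1e-3)
  }
})

test_that("raising an activating weight cannot lower its target at steady state", {
  steady_b <- function(w) {
    final_state(simulate_network(chain_network(w = w), t1 = 20000))[["B"]]
  }
  vals <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), steady_b, numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("steady-state detection separates settled from drifting trajectories", {
  const <- tibble::tibble(time_s = seq(0, 1000, 100), A = 0.5)
  class(const) <- c("avatar_trajectory", class(const))
  ss <- detect_steady_state(const)
  expect_true(ss$is_steady)
  expect_equal(ss$max_drift, 0)

  ramp <- tibble::tibble(time_s = seq(0, 1000, 100),
                         A = seq(0.1, 0.9, length.out = 11))
  class(ramp) <- c("avatar_trajectory", class(ramp))
  ss2 <- detect_steady_state(ramp)
  expect_false(ss2$is_steady)
  expect_gt(ss2$max_drift, 0)

  expect_error(detect_steady_state(const[1, ]), "fewer than 2")
})

test_that("exponential relaxation is steady long after ten time constants", {
  net <- network_spec(data.frame(id = "A", basal_drive = 0.6, tau = 1000))
  traj <- simulate_network(net, t1 = 20000, n_out = 201)
  # trailing window sits at 18-20 tau: analytic residual e^-18 << 1e-6
  expect_true(detect_steady_state(traj, rel_tol = 1e-6)$is_steady)
  tts <- time_to_steady(traj, rel_tol = 1e-6)
  expect_false(is.na(tts))
  expect_lt(tts, 20000)
})
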