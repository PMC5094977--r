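#' Normalized-Hill edge transfer function
#'
#' The contribution a source node passes down one edge. The Hill curve is
#' rescaled so that `f(0) = 0` and `f(1) = w` exactly:
#' `f(x) = w * (1 + K^n) * x^n / (x^n + K^n)`.
#' Sources whose production is amplified can transiently exceed activity 1;
#' their contribution is evaluated on the same curve and capped at 1 when
#' pooled (see [combine_inputs()]).
#'
#' @param x Source activity, normalized to the source's `y_max`; must lie in
#'   `[0, 1]` (up to `tol`) when called directly.
#' @param w Edge weight in (0, 1]; the contribution at full source activity.
#' @param K Activation midpoint in (0, 1).
#' @param n Hill cooperativity, `>= 1`.
#' @param tol Domain tolerance for `x`.
#' @return Contribution in `[0, w]`, monotone non-decreasing in `x`.
#' @export
#' @examples
#' edge_transfer(0.5, w = 1, K = 0.5, n = 1) # 0.75
edge_transfer <- function(x, w = 0.9, K = 0.5, n = 1.4, tol = 1e-9) {
  if (any(x < -tol | x > 1 + tol)) {
    stop("source activity outside [0,1]", call. = FALSE)
  }
  x <- pmin(pmax(x, 0), 1)
  w * (1 + K^n) * x^n / (x^n + K^n)
}

#' Combine edge contributions into a node's net drive
#'
#' Independent activating inputs pool by noisy-OR, `a = 1 - prod(1 - f_i)`;
#' contributions gated `AND` (obligate co-regulators, e.g. a kinase and its
#' cyclin) multiply into a single contribution before pooling. The basal
#' constitutive drive OR-pools with the activators, and inhibiting
#' contributions attenuate multiplicatively:
#' `u = [1 - (1 - basal) * (1 - a)] * prod(1 - g_j)`.
#' The result always stays in `[0, 1]`.
#'
#' @param activations Numeric vector of activating contributions in `[0,1]`.
#' @param inhibitions Numeric vector of inhibiting contributions in `[0,1]`.
#' @param basal Constitutive drive in `[0,1]`.
#' @param gates Optional character vector parallel to `activations`
#'   (`"OR"`/`"AND"`); all `AND` entries form one product group. Default all
#'   `"OR"`.
#' @return Net drive `u` in `[0, 1]`.
#' @export
#' @examples
#' combine_inputs(c(0.5, 0.5)) # 0.75
combine_inputs <- function(activations = numeric(), inhibitions = numeric(),
                           basal = 0, gates = NULL) {
  stopifnot(all(activations >= 0 & activations <= 1),
            all(inhibitions >= 0 & inhibitions <= 1),
            basal >= 0, basal <= 1)
  if (is.null(gates)) gates <- rep("OR", length(activations))
  stopifnot(length(gates) == length(activations))
  or_part <- activations[gates == "OR"]
  and_part <- activations[gates == "AND"]
  contribs <- or_part
  if (length(and_part) > 0) contribs <- c(contribs, prod(and_part))
  a <- 1 - prod(1 - contribs)
  (1 - (1 - basal) * (1 - a)) * prod(1 - inhibitions)
}

# Precompile the network into index vectors so the ODE right-hand side is
# fully vectorized. Activating AND edges into one target form a single
# product group; each node's basal drive comes from the resolved modifiers.
compile_network <- function(net, mods = modifier_set()) {
  nodes <- net$nodes
  ids <- nodes$id
  rm_ <- resolve_modifiers(net, mods)
  e <- net$interactions
  act <- e[e$sign == "activating", , drop = FALSE]
  inh <- e[e$sign == "inhibiting", , drop = FALSE]
  idx <- function(x) match(x, ids)
  n_nodes <- length(ids)
  clamp_idx <- idx(names(rm_$clamp))

  list(
    ids = ids,
    n = n_nodes,
    y_max = nodes$y_max,
    tau = nodes$tau,
    basal = unname(rm_$basal),
    mult = unname(rm_$mult),
    prod = unname(rm_$prod),
    clamp_idx = clamp_idx,
    clamp_val = unname(rm_$clamp),
    act_src = idx(act$source), act_tgt = idx(act$target),
    act_w = act$weight, act_Kn = act$half_max^act$hill, act_n = act$hill,
    act_scale = 1 + act$half_max^act$hill,
    act_and = act$gate == "AND",
    inh_src = idx(inh$source), inh_tgt = idx(inh$target),
    inh_w = inh$weight, inh_Kn = inh$half_max^inh$hill, inh_n = inh$hill,
    inh_scale = 1 + inh$half_max^inh$hill,
    y_max_src_act = nodes$y_max[idx(act$source)],
    y_max_src_inh = nodes$y_max[idx(inh$source)]
  )
}

# Net drive u for every node, given current activities. Vectorized over
# edges; contributions are capped at 1 so amplified sources stay closed
# under noisy-OR pooling.
node_drives <- function(cn, y) {
  log_keep <- numeric(cn$n) # log prod(1 - OR contributions)
  if (length(cn$act_src) > 0) {
    xn <- pmax(y[cn$act_src] / cn$y_max_src_act, 0)
    xnn <- xn^cn$act_n
    f <- pmin(cn$act_w * cn$act_scale * xnn / (xnn + cn$act_Kn), 1)
    is_and <- cn$act_and
    if (any(is_and)) {
      and_log <- rowsum(log(pmax(f[is_and], 1e-300)), cn$act_tgt[is_and])
      and_tgt <- as.integer(rownames(and_log))
      log_keep[and_tgt] <- log_keep[and_tgt] + log1p(-pmin(exp(and_log[, 1]), 1))
    }
    if (any(!is_and)) {
      or_log <- rowsum(log1p(-f[!is_and]), cn$act_tgt[!is_and])
      or_tgt <- as.integer(rownames(or_log))
      log_keep[or_tgt] <- log_keep[or_tgt] + or_log[, 1]
    }
  }
  a <- 1 - exp(log_keep)
  inh_keep <- numeric(cn$n)
  if (length(cn$inh_src) > 0) {
    xn <- pmax(y[cn$inh_src] / cn$y_max_src_inh, 0)
    xnn <- xn^cn$inh_n
    g <- pmin(cn$inh_w * cn$inh_scale * xnn / (xnn + cn$inh_Kn), 1)
    gl <- rowsum(log1p(-g), cn$inh_tgt)
    inh_keep[as.integer(rownames(gl))] <- gl[, 1]
  }
  (1 - (1 - cn$basal) * (1 - a)) * exp(inh_keep)
}

rhs_rates <- function(cn, y) {
  u <- node_drives(cn, y)
  dy <- (cn$y_max * cn$prod * u * cn$mult - y) / cn$tau
  if (length(cn$clamp_idx) > 0) dy[cn$clamp_idx] <- 0
  dy
}

#' Evaluate the network's rate vector at a state
#'
#' The logic-ODE right-hand side:
#' `dx_i/dt = (y_max_i * p_i * u_i * m_i - x_i) / tau_i`, where `u_i` is the
#' node's net drive ([combine_inputs()] over its incoming edges), `p_i` its
#' production scaler and `m_i` its activity multiplier. Clamped ligand nodes
#' have rate 0. Bounds are forward-invariant: the rate is `>= 0` at
#' `x_i = 0` and `<= 0` at `x_i = y_max_i * p_i * m_i`.
#'
#' @param state Named numeric vector of activities (all network nodes).
#' @param net An `avatar_network`.
#' @param mods A `modifier_set` (default: none).
#' @return Named numeric vector of rates, same order as `net$nodes$id`.
#' @export
derivative <- function(state, net, mods = modifier_set()) {
  ids <- node_ids(net)
  if (length(state) != length(ids) || !all(ids %in% names(state))) {
    stop("state dimensions do not match the network", call. = FALSE)
  }
  cn <- compile_network(net, mods)
  y <- unname(state[ids])
  dy <- rhs_rates(cn, y)
  names(dy) <- ids
  dy
}

#' Integrate network dynamics over a time span
#'
#' Deterministic integration of the logic-ODE system with a stiff-capable
#' adaptive solver (deSolve's `lsoda` by default). Clamped ligand nodes are
#' pinned to their clamp values for the whole span.
#'
#' @param net An `avatar_network`.
#' @param mods A `modifier_set`.
#' @param y_init Named initial state; defaults to the nodes' `y0`.
#' @param t0,t1 Start and end of the span in simulation seconds (`t1 > t0`).
#' @param n_out Number of equally spaced output times (including both ends).
#' @param rtol,atol Solver tolerances.
#' @param method deSolve integration method.
#' @return A tibble of class `avatar_trajectory`: column `time_s` then one
#'   column per node id. The final state is available via [final_state()].
#' @export
simulate_network <- function(net, mods = modifier_set(), y_init = NULL,
                             t0 = 0, t1 = 50000, n_out = 201,
                             rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(t1 > t0, n_out >= 2)
  ids <- node_ids(net)
  cn <- compile_network(net, mods)
  if (is.null(y_init)) {
    y <- net$nodes$y0
    names(y) <- ids
  } else {
    if (!all(ids %in% names(y_init))) {
      stop("y_init must name every network node", call. = FALSE)
    }
    y <- y_init[ids]
  }
  if (length(cn$clamp_idx) > 0) y[cn$clamp_idx] <- cn$clamp_val
  times <- seq(t0, t1, length.out = n_out)
  sol <- deSolve::ode(
    y = unname(y), times = times, method = method,
    func = function(t, y, p) list(rhs_rates(cn, y)),
    rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0) {
    worst <- ids[which.max(abs(rhs_rates(cn, sol[nrow(sol), -1])))]
    stop("solver failure (step-size collapse); worst node: ", worst, call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(unclass(sol)))
  names(out) <- c("time_s", ids)
  # activities can undershoot 0 by ~atol; snap for downstream invariants
  out[ids] <- lapply(out[ids], function(col) pmax(col, 0))
  class(out) <- c("avatar_trajectory", class(out))
  out
}

#' Extract the final state of a trajectory
#'
#' @param traj An `avatar_trajectory` from [simulate_network()].
#' @return Named numeric state vector at the last output time.
#' @export
final_state <- function(traj) {
  stopifnot(inherits(traj, "avatar_trajectory") || "time_s" %in% names(traj))
  last <- as.data.frame(traj[nrow(traj), setdiff(names(traj), "time_s")])
  out <- as.numeric(last)
  names(out) <- names(last)
  out
}

#' Steady-state detection over a trailing window
#'
#' A trajectory is steady when, across the trailing fraction of its span,
#' every node's relative change is at most `rel_tol`. Nodes whose scale is
#' near zero (below `abs_floor`) are compared by absolute change instead, so
#' silent nodes cannot fail on roundoff ratios.
#'
#' @param traj An `avatar_trajectory`.
#' @param trailing_window_fraction Fraction of the time span forming the
#'   assessment window (default 0.1).
#' @param rel_tol Maximum tolerated relative drift (default 1e-6).
#' @param abs_floor Scale below which drift is assessed absolutely.
#' @return A list with `is_steady` (flag), `max_drift` (worst relative
#'   drift), and `drift` (per-node tibble sorted worst-first).
#' @export
detect_steady_state <- function(traj, trailing_window_fraction = 0.1,
                                rel_tol = 1e-6, abs_floor = 1e-3) {
  stopifnot(trailing_window_fraction > 0, trailing_window_fraction <= 1)
  t <- traj$time_s
  cut <- t[length(t)] - trailing_window_fraction * (t[length(t)] - t[1])
  win <- traj[t >= cut, , drop = FALSE]
  if (nrow(win) < 2) stop("trailing window holds fewer than 2 samples", call. = FALSE)
  ids <- setdiff(names(traj), "time_s")
  drift <- vapply(ids, function(id) {
    v <- win[[id]]
    rng <- max(v) - min(v)
    sc <- max(abs(v))
    if (sc < abs_floor) rng else rng / sc
  }, numeric(1))
  ord <- order(drift, decreasing = TRUE)
  list(
    is_steady = max(drift) <= rel_tol,
    max_drift = unname(max(drift)),
    drift = tibble::tibble(node = ids[ord], drift = unname(drift[ord]))
  )
}

#' First time at which a trajectory satisfies the steady-state criterion
#'
#' Scans the output grid and reports the earliest time `t` such that the
#' trailing window of `[t_0, t]` passes [detect_steady_state()]. Useful for
#' asking how much of a protocol stage's horizon a network actually needs.
#'
#' @inheritParams detect_steady_state
#' @return The first qualifying output time, or `NA` if none qualifies.
#' @export
time_to_steady <- function(traj, trailing_window_fraction = 0.1,
                           rel_tol = 1e-6, abs_floor = 1e-3) {
  t <- traj$time_s
  for (i in seq(3, length(t))) {
    sub <- traj[seq_len(i), , drop = FALSE]
    cut <- t[i] - trailing_window_fraction * (t[i] - t[1])
    if (sum(sub$time_s >= cut) < 2) next
    ss <- detect_steady_state(sub, trailing_window_fraction, rel_tol, abs_floor)
    if (ss$is_steady) return(t[i])
  }
  NA_real_
}
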