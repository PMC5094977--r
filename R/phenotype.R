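#' Phenotype index definition
#'
#' Indices summarize a state vector into tumor phenotypes:
#' * proliferation — weighted average of the active CDK-cyclin complex
#'   activities (CDK4-CCND1, CDK2-CCNE, CDK2-CCNA, CDK1-CCNB1);
#' * survival — weighted average of AKT1, BCL2, MCL1, BIRC5, BIRC2, XIAP;
#' * apoptosis — weighted average of BAX, CASP3, NOXA, CASP8;
#' * viability — the ratio survival / apoptosis.
#'
#' Weights within each index are non-negative and sum to 1. Uniform weights
#' are the shipped default; [calibrate_weights()] reproduces the procedure
#' of tuning them against qualitative experimental trends.
#'
#' @param proliferation,survival,apoptosis Named numeric weight vectors
#'   (marker node id to weight). Defaults: uniform over the canonical
#'   marker sets.
#' @return An object of class `index_definition`.
#' @export
index_definition <- function(
    proliferation = uniform_weights(c("CDK4_CCND1", "CDK2_CCNE1", "CDK2_CCNA2", "CDK1_CCNB1")),
    survival = uniform_weights(c("AKT1", "BCL2", "MCL1", "BIRC5", "BIRC2", "XIAP")),
    apoptosis = uniform_weights(c("BAX", "CASP3", "NOXA", "CASP8"))) {
  chk <- function(w, nm) {
    if (is.null(names(w)) || any(names(w) == "")) {
      stop(nm, " weights must be named by marker node id", call. = FALSE)
    }
    if (any(w < 0)) stop(nm, " weights must be >= 0", call. = FALSE)
    if (abs(sum(w) - 1) > 1e-8) stop(nm, " weights must sum to 1", call. = FALSE)
    w
  }
  structure(list(proliferation = chk(proliferation, "proliferation"),
                 survival = chk(survival, "survival"),
                 apoptosis = chk(apoptosis, "apoptosis")),
            class = "index_definition")
}

#' Uniform weights over a marker set
#' @param markers Character vector of marker node ids.
#' @return Named numeric vector summing to 1.
#' @export
uniform_weights <- function(markers) {
  stats::setNames(rep(1 / length(markers), length(markers)), markers)
}

weighted_marker_mean <- function(state, weights) {
  missing <- setdiff(names(weights), names(state))
  if (length(missing) > 0) {
    stop("marker node(s) missing from state: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sum(weights * state[names(weights)])
}

#' Proliferation index of a state
#'
#' Weighted average of the active CDK-cyclin complex activities.
#'
#' @param state Named state vector.
#' @param definition An [index_definition()].
#' @return Scalar index, `>= 0`.
#' @export
proliferation_index <- function(state, definition = index_definition()) {
  weighted_marker_mean(state, definition$proliferation)
}

#' Survival, apoptosis and viability indices of a state
#'
#' The viability index is the ratio of the survival sub-index over the
#' apoptosis sub-index, with an epsilon guard (`1e-6`) against a silent
#' apoptosis arm; when the guard engages, `guarded` is flagged.
#'
#' @param state Named state vector.
#' @param definition An [index_definition()].
#' @param eps Denominator guard (default 1e-6).
#' @return A list with `survival`, `apoptosis`, `ratio`, `guarded`.
#' @export
viability_index <- function(state, definition = index_definition(), eps = 1e-6) {
  s <- weighted_marker_mean(state, definition$survival)
  a <- weighted_marker_mean(state, definition$apoptosis)
  list(survival = s, apoptosis = a, ratio = s / max(a, eps), guarded = a < eps)
}

#' Normalize a viability ratio against an untreated baseline
#'
#' The untreated (vehicle) baseline defines 100% viability; treated
#' readouts are expressed relative to it.
#'
#' @param treated_ratio Treated viability index.
#' @param baseline_ratio Untreated baseline viability index (> 0).
#' @return Percentage; `baseline -> 100` exactly.
#' @export
normalize_viability <- function(treated_ratio, baseline_ratio) {
  if (any(baseline_ratio <= 0)) stop("baseline viability must be > 0", call. = FALSE)
  100 * treated_ratio / baseline_ratio
}

#' Full phenotype readout of a state
#'
#' @param state Named state vector.
#' @param definition An [index_definition()].
#' @param baseline_state Optional untreated baseline state; when given,
#'   `normalized_viability_percent` is reported against it.
#' @return A one-row tibble with the four indices (and the normalized
#'   viability percentage when a baseline is supplied).
#' @export
phenotype_readout <- function(state, definition = index_definition(),
                              baseline_state = NULL) {
  v <- viability_index(state, definition)
  out <- tibble::tibble(
    proliferation_index = proliferation_index(state, definition),
    survival_index = v$survival,
    apoptosis_index = v$apoptosis,
    viability_index = v$ratio
  )
  if (!is.null(baseline_state)) {
    vb <- viability_index(baseline_state, definition)
    out$normalized_viability_percent <- normalize_viability(v$ratio, vb$ratio)
  }
  out
}

#' Direction of a percentage change
#'
#' @param pct Percent change.
#' @param tol Dead band in percentage points within which the change counts
#'   as `unchanged` (default 0.5).
#' @return `"up"`, `"down"` or `"unchanged"`.
#' @export
trend_direction <- function(pct, tol = 0.5) {
  dplyr::case_when(pct > tol ~ "up", pct < -tol ~ "down", TRUE ~ "unchanged")
}

# All weight vectors on the k-simplex with entries that are multiples of
# `step` (a lattice; step = 0.1 gives the decile grid).
simplex_lattice <- function(k, step = 0.1) {
  m <- round(1 / step)
  if (abs(m * step - 1) > 1e-9) stop("1/step must be an integer", call. = FALSE)
  compose <- function(total, parts) {
    if (parts == 1) return(matrix(total, ncol = 1))
    out <- list()
    for (first in 0:total) {
      rest <- compose(total - first, parts - 1)
      out[[length(out) + 1]] <- cbind(first, rest)
    }
    do.call(rbind, out)
  }
  compose(m, k) / m
}

# lattice plus the exact uniform point, so the spec'd tie-break toward
# uniform weights can land on it even when 1/k is not a lattice multiple
lattice_with_uniform <- function(k, step) {
  rbind(simplex_lattice(k, step), rep(1 / k, k))
}

#' Calibrate index weights against qualitative trends
#'
#' Reproduces the weight-selection procedure: a grid search over a simplex
#' lattice (default step 0.1) per index, scoring each candidate by how many
#' trend-table rows it signs correctly, with ties broken toward uniform
#' weights. Marker-level rows do not depend on the weights but still enter
#' the reported agreement; survival and apoptosis weights are searched
#' jointly so that viability-index rows (which involve both) can be scored.
#'
#' @param cases Named list of conditions; each element a list with `baseline`
#'   and `treated` state vectors. Names match the trend table's `condition`.
#' @param trends A trend table: tibble with columns `condition`, `marker`
#'   (a node id or one of `proliferation_index`, `survival_index`,
#'   `apoptosis_index`, `viability_index`), `direction`.
#' @param step Lattice step (default 0.1).
#' @param direction_tol Dead band for [trend_direction()].
#' @param definition Template [index_definition()] supplying the marker sets.
#' @return A list with `definition` (calibrated weights), `agreement`
#'   (fraction of rows signed correctly), and `details` (per-row tibble).
#' @export
calibrate_weights <- function(cases, trends, step = 0.1, direction_tol = 0.5,
                              definition = index_definition()) {
  stopifnot(nrow(trends) > 0)
  missing_cond <- setdiff(unique(trends$condition), names(cases))
  if (length(missing_cond) > 0) {
    stop("conditions without cases: ", paste(missing_cond, collapse = ", "),
         call. = FALSE)
  }
  idx_names <- c("proliferation_index", "survival_index", "apoptosis_index",
                 "viability_index")
  marker_rows <- trends[!trends$marker %in% idx_names, , drop = FALSE]
  index_rows <- trends[trends$marker %in% idx_names, , drop = FALSE]

  pct_of <- function(cond, marker) {
    st <- cases[[cond]]
    percent_change(st$treated[[marker]], st$baseline[[marker]])
  }
  marker_ok <- if (nrow(marker_rows) > 0) {
    vapply(seq_len(nrow(marker_rows)), function(i) {
      pred <- trend_direction(pct_of(marker_rows$condition[i], marker_rows$marker[i]),
                              direction_tol)
      pred == marker_rows$direction[i]
    }, logical(1))
  } else {
    logical(0)
  }

  # activity matrices: conditions x markers, baseline and treated
  mat_of <- function(markers, slot) {
    out <- matrix(NA_real_, nrow = length(cases), ncol = length(markers),
                  dimnames = list(names(cases), markers))
    for (i in seq_along(cases)) out[i, ] <- unname(cases[[i]][[slot]][markers])
    out
  }
  # fast signed-direction code: 1 up, -1 down, 0 unchanged
  dir_code <- function(pct) (pct > direction_tol) - (pct < -direction_tol)
  code_of <- c(up = 1, down = -1, unchanged = 0)
  tie_break_pick <- function(lattice, score) {
    best <- which(score == max(score))
    k <- ncol(lattice)
    dist <- rowSums((lattice[best, , drop = FALSE] - 1 / k)^2)
    best[order(dist, seq_along(best))][1]
  }
  # proliferation: independent search
  pm <- names(definition$proliferation)
  prolif_rows <- index_rows[index_rows$marker == "proliferation_index", , drop = FALSE]
  if (nrow(prolif_rows) > 0) {
    lat_p <- lattice_with_uniform(length(pm), step)
    base_p <- mat_of(pm, "baseline"); trt_p <- mat_of(pm, "treated")
    p_base_all <- base_p %*% t(lat_p); p_trt_all <- trt_p %*% t(lat_p)
    dir_p <- dir_code(100 * (p_trt_all - p_base_all) / pmax(p_base_all, 1e-9))
    cond_idx_p <- match(prolif_rows$condition, names(cases))
    want_p <- code_of[prolif_rows$direction]
    score_p <- integer(nrow(lat_p))
    for (i in seq_len(nrow(prolif_rows))) {
      score_p <- score_p + (dir_p[cond_idx_p[i], ] == want_p[i])
    }
    w_p <- stats::setNames(lat_p[tie_break_pick(lat_p, score_p), ], pm)
  } else {
    w_p <- uniform_weights(pm)
  }

  # survival + apoptosis: joint search over the two lattices. For each
  # apoptosis candidate the score of every survival candidate is computed
  # in one vectorized pass, so the full cross-product stays tractable.
  sm <- names(definition$survival); am <- names(definition$apoptosis)
  sa_rows <- index_rows[index_rows$marker != "proliferation_index", , drop = FALSE]
  if (nrow(sa_rows) > 0) {
    lat_s <- lattice_with_uniform(length(sm), step)
    lat_a <- lattice_with_uniform(length(am), step)
    base_s <- mat_of(sm, "baseline"); trt_s <- mat_of(sm, "treated")
    base_a <- mat_of(am, "baseline"); trt_a <- mat_of(am, "treated")
    eps <- 1e-6
    n_js <- nrow(lat_s)
    s_base_all <- base_s %*% t(lat_s); s_trt_all <- trt_s %*% t(lat_s)
    a_base_all <- base_a %*% t(lat_a); a_trt_all <- trt_a %*% t(lat_a)
    dir_s_mat <- dir_code(100 * (s_trt_all - s_base_all) / pmax(s_base_all, 1e-9))
    dist_s <- rowSums((lat_s - 1 / length(sm))^2)
    dist_a <- rowSums((lat_a - 1 / length(am))^2)
    cond_idx <- match(sa_rows$condition, names(cases))
    want <- code_of[sa_rows$direction]
    best_score <- -1L; best_js <- 1L; best_ja <- 1L; best_dist <- Inf
    for (ja in seq_len(nrow(lat_a))) {
      ab <- pmax(a_base_all[, ja], eps); at <- pmax(a_trt_all[, ja], eps)
      dir_a <- dir_code(percent_change(a_trt_all[, ja], a_base_all[, ja]))
      vb <- s_base_all / ab; vt <- s_trt_all / at # vectors recycle down columns
      dir_v_mat <- dir_code(100 * (vt - vb) / pmax(vb, 1e-9))
      score <- integer(n_js)
      for (i in seq_len(nrow(sa_rows))) {
        hit <- switch(sa_rows$marker[i],
                      survival_index = dir_s_mat[cond_idx[i], ] == want[i],
                      apoptosis_index = rep(dir_a[cond_idx[i]] == want[i], n_js),
                      viability_index = dir_v_mat[cond_idx[i], ] == want[i])
        score <- score + hit
      }
      tot_dist <- dist_s + dist_a[ja]
      j <- order(-score, tot_dist)[1]
      if (score[j] > best_score ||
          (score[j] == best_score && tot_dist[j] < best_dist)) {
        best_score <- score[j]; best_js <- j; best_ja <- ja
        best_dist <- tot_dist[j]
      }
    }
    w_s <- stats::setNames(lat_s[best_js, ], sm)
    w_a <- stats::setNames(lat_a[best_ja, ], am)
  } else {
    w_s <- uniform_weights(sm)
    w_a <- uniform_weights(am)
  }

  def <- index_definition(proliferation = w_p, survival = w_s, apoptosis = w_a)

  # final per-row report under the calibrated definition
  details <- dplyr::bind_rows(lapply(seq_len(nrow(trends)), function(i) {
    cond <- trends$condition[i]; marker <- trends$marker[i]
    st <- cases[[cond]]
    pct <- if (marker %in% idx_names) {
      pb <- phenotype_readout(st$baseline, def)
      pt <- phenotype_readout(st$treated, def)
      percent_change(pt[[marker]], pb[[marker]])
    } else {
      pct_of(cond, marker)
    }
    tibble::tibble(condition = cond, marker = marker,
                   expected = trends$direction[i],
                   pct_change = pct,
                   predicted = trend_direction(pct, direction_tol))
  }))
  details$match <- details$predicted == details$expected
  list(definition = def, agreement = mean(details$match), details = details)
}
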