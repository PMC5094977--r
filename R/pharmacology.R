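#' Define a drug by its targets and inhibition model
#'
#' A drug inhibits each of its target nodes with a Hill dose-inhibition
#' curve `I(d) = d^h / (d^h + K_t^h)`, where the per-target half-inhibition
#' dose is `K_t = K_primary * potency_fold`. Exactly one target (the primary
#' one) has `potency_fold = 1`; secondary targets need proportionally higher
#' doses.
#'
#' @param id Drug identifier.
#' @param targets Named numeric vector: node id to potency fold (`>= 1`),
#'   with exactly one entry equal to 1.
#' @param hill_h Inhibition cooperativity (> 0, default 1).
#' @param K_primary Half-inhibition dose of the primary target in internal
#'   dose units (> 0, default 1).
#' @return An object of class `avatar_drug`.
#' @seealso [calibrate_C()], [target_inhibition()], [dose_response()]
#' @export
#' @examples
#' g6 <- drug("G6", selectivity_from_profile("JAK2>JAK3>>JAK1>>>TYK2"))
#' calibrate_C(g6) # 1.5: the dose giving 60% JAK2 inhibition
drug <- function(id, targets, hill_h = 1, K_primary = 1) {
  stopifnot(is.numeric(targets), !is.null(names(targets)),
            all(targets >= 1), hill_h > 0, K_primary > 0)
  if (sum(targets == 1) != 1) {
    stop("exactly one target must have potency_fold = 1 (the primary target)",
         call. = FALSE)
  }
  structure(list(id = id, targets = targets, hill_h = hill_h,
                 K_primary = K_primary),
            class = "avatar_drug")
}

#' @export
print.avatar_drug <- function(x, ...) {
  cat("<avatar_drug> ", x$id, ": targets ",
      paste0(names(x$targets), " (x", x$targets, ")", collapse = ", "),
      "; h=", x$hill_h, ", K=", x$K_primary, "\n", sep = "")
  invisible(x)
}

primary_target <- function(drug) names(drug$targets)[drug$targets == 1][1]

#' Calibrate the reference dose C
#'
#' `C` is the dose at which the drug inhibits its primary target by exactly
#' 60%; all public dose scales are expressed as multiples of `C`. Closed
#' form: `C = K_primary * (0.6 / 0.4)^(1 / h)`.
#'
#' @param drug An [drug()] object.
#' @return The reference dose in internal units.
#' @export
calibrate_C <- function(drug) {
  drug$K_primary * (0.6 / 0.4)^(1 / drug$hill_h)
}

#' Fractional inhibition of a drug target at a dose
#'
#' @param drug An [drug()] object.
#' @param dose Dose, in multiples of the calibrated reference dose `C`
#'   (`units = "C"`, default) or in internal units (`units = "internal"`).
#' @param target Target node id (default: the primary target).
#' @param units Dose units.
#' @return Inhibited fraction in `[0, 1)`: 0 at dose 0, strictly increasing.
#' @export
target_inhibition <- function(drug, dose, target = primary_target(drug),
                              units = c("C", "internal")) {
  units <- match.arg(units)
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  if (!target %in% names(drug$targets)) {
    stop("unknown target '", target, "' for drug ", drug$id, call. = FALSE)
  }
  d <- if (units == "C") dose * calibrate_C(drug) else dose
  Kt <- drug$K_primary * drug$targets[[target]]
  h <- drug$hill_h
  ifelse(d == 0, 0, d^h / (d^h + Kt^h))
}

#' Expand a selectivity ranking string into potency folds
#'
#' Rankings such as `"JAK2>JAK3>>JAK1>>>TYK2"` state ordinal selectivity
#' only; each `>` multiplies the half-inhibition dose by `fold_base`, `>>`
#' by `fold_base^2` and `>>>` by `fold_base^3`, cumulatively left to right.
#'
#' @param ranking Ranking string using `>`, `>>`, `>>>` separators.
#' @param fold_base Fold increase per single `>` (default 5).
#' @return Named numeric vector of potency folds, first-listed target = 1.
#' @export
selectivity_from_profile <- function(ranking, fold_base = 5) {
  ranking <- gsub("\\s", "", ranking)
  names_ <- strsplit(ranking, ">{1,3}")[[1]]
  seps <- regmatches(ranking, gregexpr(">{1,3}", ranking))[[1]]
  if (any(names_ == "") || length(names_) != length(seps) + 1) {
    stop("malformed selectivity ranking: ", ranking, call. = FALSE)
  }
  folds <- cumprod(c(1, fold_base^nchar(seps)))
  stats::setNames(folds, names_)
}

#' Translate a treatment into network modifiers
#'
#' Each target node receives an activity multiplier `1 - I_t(dose)`. Several
#' drugs compose multiplicatively on shared targets (see
#' [compose_modifiers()]).
#'
#' @param drug An [drug()] object.
#' @param dose_c Dose in multiples of `C`.
#' @return A [modifier_set()].
#' @export
drug_modifiers <- function(drug, dose_c) {
  stopifnot(dose_c >= 0)
  inh <- vapply(names(drug$targets), function(tg) {
    target_inhibition(drug, dose_c, target = tg, units = "C")
  }, numeric(1))
  modifier_set(activity_multiplier = 1 - inh)
}

#' Default dose grid for sweeps
#'
#' 25 log-spaced doses from `C/1000` to `10 C`, the span used for
#' single-agent viability sweeps.
#'
#' @param n Number of doses (default 25).
#' @param lo,hi Grid endpoints in C units.
#' @return Increasing numeric vector of doses in C units.
#' @export
default_dose_grid <- function(n = 25, lo = 1e-3, hi = 10) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Single-agent dose-response sweep
#'
#' Runs one full treatment-stage simulation per dose on a prepared avatar
#' and records the viability readout: `viability_pct` is the treated
#' viability index as a percentage of the untreated disease baseline
#' (untreated = 100%), `reduction_pct = 100 - viability_pct`.
#'
#' @param avatar A prepared avatar from [build_avatar()].
#' @param drug An [drug()] object.
#' @param doses Increasing dose grid in C units.
#' @return A tibble of class `dose_response_curve` with columns `dose_c`,
#'   `viability_pct`, `reduction_pct`, carrying an evaluator attribute used
#'   by [find_IC()] for bisection refinement on re-simulated doses.
#' @export
dose_response <- function(avatar, drug, doses = default_dose_grid()) {
  stopifnot(length(doses) >= 1, !is.unsorted(doses, strictly = TRUE))
  evaluate <- function(d) {
    run <- simulate_treatment(avatar, list(list(drug = drug, dose_c = d)))
    100 - run$phenotypes$normalized_viability_percent
  }
  red <- vapply(doses, evaluate, numeric(1))
  out <- tibble::tibble(dose_c = doses, viability_pct = 100 - red,
                        reduction_pct = red)
  attr(out, "evaluator") <- evaluate
  attr(out, "drug_id") <- drug$id
  attr(out, "avatar_name") <- avatar$profile$name
  class(out) <- c("dose_response_curve", class(out))
  out
}

curve_evaluator <- function(curve) {
  ev <- attr(curve, "evaluator")
  if (!is.null(ev)) return(ev)
  # fall back to linear interpolation on the monotone-processed curve
  mono <- cummax(curve$reduction_pct)
  function(d) stats::approx(curve$dose_c, mono, xout = d, rule = 2)$y
}

#' Minimal dose achieving a viability-reduction level
#'
#' Scans the monotone-processed curve for the smallest grid dose whose
#' reduction reaches `level`, then refines by bisection between the
#' bracketing grid points — re-simulating candidate doses when the curve
#' carries its evaluator — down to a relative dose tolerance.
#'
#' @param curve A `dose_response_curve` (or any tibble with `dose_c` and
#'   `reduction_pct`).
#' @param level Target reduction percentage (default 50, i.e. the viability
#'   IC50).
#' @param rel_tol Relative dose tolerance of the bisection (default 1e-3).
#' @return The minimal dose in C units.
#' @export
find_IC <- function(curve, level = 50, rel_tol = 1e-3) {
  mono <- cummax(curve$reduction_pct)
  idx <- which(mono >= level)
  if (length(idx) == 0) {
    stop("level not reached on grid (max reduction ",
         round(max(mono), 2), "% < ", level, "%)", call. = FALSE)
  }
  i <- idx[1]
  if (i == 1) return(curve$dose_c[1])
  evaluate <- curve_evaluator(curve)
  lo <- curve$dose_c[i - 1]
  hi <- curve$dose_c[i]
  while ((hi - lo) / hi > rel_tol) {
    mid <- sqrt(lo * hi)
    if (evaluate(mid) >= level) hi <- mid else lo <- mid
  }
  hi
}

#' Full-factorial combination grid
#'
#' One treatment-stage simulation per dose pair. Rows or columns at dose 0
#' reproduce the corresponding single-agent sweep exactly.
#'
#' @param avatar A prepared avatar from [build_avatar()].
#' @param drug_a,drug_b [drug()] objects.
#' @param doses_a,doses_b Dose grids in C units (typically starting at 0).
#' @return A tibble of class `combination_grid` with columns `dose_a`,
#'   `dose_b`, `viability_pct`, `reduction_pct`.
#' @export
combination_grid <- function(avatar, drug_a, drug_b, doses_a, doses_b) {
  evaluate <- function(da, db) {
    run <- simulate_treatment(avatar, list(
      list(drug = drug_a, dose_c = da),
      list(drug = drug_b, dose_c = db)
    ))
    100 - run$phenotypes$normalized_viability_percent
  }
  grid <- tidyr::expand_grid(dose_a = doses_a, dose_b = doses_b)
  grid$reduction_pct <- purrr::map2_dbl(grid$dose_a, grid$dose_b, evaluate)
  grid$viability_pct <- 100 - grid$reduction_pct
  attr(grid, "evaluator") <- evaluate
  attr(grid, "drug_ids") <- c(drug_a$id, drug_b$id)
  class(grid) <- c("combination_grid", class(grid))
  grid
}

#' Loewe combination index
#'
#' `CI = d_A / IC50_A + d_B / IC50_B` at an iso-effect dose pair. Verdicts:
#' synergy below 1, additivity within `1 +/- additivity_band`, antagonism
#' above.
#'
#' @param dose_a,dose_b Doses of the two agents at the iso-effect point.
#' @param ic50_a,ic50_b Single-agent IC50s (> 0), same units as the doses.
#' @param additivity_band Half-width of the additivity call (default 0.05).
#' @return A tibble with columns `ci` and `verdict`.
#' @export
combination_index <- function(dose_a, dose_b, ic50_a, ic50_b,
                              additivity_band = 0.05) {
  if (any(c(ic50_a, ic50_b) <= 0)) stop("IC50s must be > 0", call. = FALSE)
  ci <- dose_a / ic50_a + dose_b / ic50_b
  verdict <- dplyr::case_when(
    abs(ci - 1) <= additivity_band ~ "additive",
    ci < 1 ~ "synergy",
    TRUE ~ "antagonism"
  )
  tibble::tibble(ci = ci, verdict = verdict)
}

#' Isobologram at a fixed effect level
#'
#' Traces the iso-effect contour of a combination grid at `level` percent
#' viability reduction: for each dose of agent A, the dose of agent B whose
#' combined effect crosses the level is found by linear interpolation along
#' the grid row. Single-agent IC50s come from the grid margins. Each contour
#' pair gets a Loewe [combination_index()]; pairs strictly inside the
#' straight IC50-IC50 line indicate synergy.
#'
#' @param grid A `combination_grid` (or tibble with `dose_a`, `dose_b`,
#'   `reduction_pct` whose margins include dose 0).
#' @param level Effect level in percent reduction (default 50).
#' @return An object of class `isobologram_result`: list with `level`,
#'   `ic50_a`, `ic50_b`, and `pairs` (tibble `dose_a`, `dose_b`, `ci`,
#'   `verdict`).
#' @export
isobologram <- function(grid, level = 50) {
  margin_curve <- function(doses, reductions) {
    tibble::tibble(dose_c = doses, reduction_pct = reductions)
  }
  a_margin <- dplyr::arrange(dplyr::filter(grid, .data$dose_b == 0), .data$dose_a)
  b_margin <- dplyr::arrange(dplyr::filter(grid, .data$dose_a == 0), .data$dose_b)
  if (nrow(a_margin) == 0 || nrow(b_margin) == 0) {
    stop("grid margins must include dose 0 for both agents", call. = FALSE)
  }
  ic50_a <- find_IC(margin_curve(a_margin$dose_a, a_margin$reduction_pct), level)
  ic50_b <- find_IC(margin_curve(b_margin$dose_b, b_margin$reduction_pct), level)

  pairs <- list()
  for (da in sort(unique(grid$dose_a))) {
    row <- dplyr::arrange(dplyr::filter(grid, .data$dose_a == da), .data$dose_b)
    mono <- cummax(row$reduction_pct)
    hit <- which(mono >= level)
    if (length(hit) == 0) next
    i <- hit[1]
    if (i == 1) {
      # the level is met before agent B contributes: past the agent-A axis
      # intercept there is no genuine iso-effect crossing on this row
      if (row$dose_b[1] == 0 && mono[1] > level) next
      db <- row$dose_b[1]
    } else {
      r0 <- mono[i - 1]; r1 <- mono[i]
      frac <- if (r1 > r0) (level - r0) / (r1 - r0) else 0
      db <- row$dose_b[i - 1] + frac * (row$dose_b[i] - row$dose_b[i - 1])
    }
    pairs[[length(pairs) + 1]] <- tibble::tibble(dose_a = da, dose_b = db)
  }
  if (length(pairs) == 0) stop("level not reached anywhere on the grid", call. = FALSE)
  pairs <- dplyr::bind_rows(pairs)
  pairs <- dplyr::bind_cols(
    pairs, combination_index(pairs$dose_a, pairs$dose_b, ic50_a, ic50_b)
  )
  structure(
    list(level = level, ic50_a = ic50_a, ic50_b = ic50_b, pairs = pairs,
         drug_ids = attr(grid, "drug_ids") %||% c("A", "B")),
    class = "isobologram_result"
  )
}

#' @export
print.isobologram_result <- function(x, ...) {
  cat("<isobologram_result> level ", x$level, "%: IC50_A=", signif(x$ic50_a, 4),
      ", IC50_B=", signif(x$ic50_b, 4), " (C units); ", nrow(x$pairs),
      " contour pair(s), min CI=", signif(min(x$pairs$ci), 4), "\n", sep = "")
  invisible(x)
}
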