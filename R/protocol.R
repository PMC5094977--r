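#' Stage schedule of the simulation protocol
#'
#' The staged protocol runs an untriggered control to `control_end` (the
#' species settle to the control baseline), overlays the genomic profile and
#' any cytokine condition and integrates to `disease_end` (the disease
#' baseline), then introduces drugs and integrates to `treatment_end`.
#'
#' @param control_end,disease_end,treatment_end Stage horizons in simulation
#'   seconds; defaults 50000, 125000, 200000.
#' @return An object of class `stage_schedule`.
#' @export
stage_schedule <- function(control_end = 50000, disease_end = 125000,
                           treatment_end = 200000) {
  if (!(0 < control_end && control_end < disease_end && disease_end < treatment_end)) {
    stop("need 0 < control_end < disease_end < treatment_end", call. = FALSE)
  }
  structure(list(control_end = control_end, disease_end = disease_end,
                 treatment_end = treatment_end),
            class = "stage_schedule")
}

#' Cytokine micro-environment condition
#'
#' Clamps boundary-ligand nodes (IL6, TNFA, IFNG, ...) at fixed activities,
#' representing paracrine inputs from the micro-environment. Conditions can
#' be applied individually or cumulatively (several ligands at once).
#'
#' @param ... Named clamp levels in `[0,1]`, e.g. `TNFA = 1`.
#' @return An object of class `cytokine_condition` (named numeric vector).
#' @export
cytokine_condition <- function(...) {
  x <- c(...)
  if (length(x) > 0) {
    stopifnot(!is.null(names(x)), all(names(x) != ""), all(x >= 0 & x <= 1))
  }
  structure(as.numeric(x), names = names(x), class = "cytokine_condition")
}

#' Percentage change against a baseline
#'
#' `100 * (treated - baseline) / max(baseline, eps)`; the epsilon guard
#' keeps changes of near-zero biomarkers finite.
#'
#' @param treated,baseline Non-negative values (vectorized).
#' @param eps Denominator guard (default 1e-9).
#' @return Percent change, always finite.
#' @export
percent_change <- function(treated, baseline, eps = 1e-9) {
  100 * (treated - baseline) / pmax(baseline, eps)
}

#' Run the control stage
#'
#' Integrates the unperturbed network from its declared initial state to the
#' control horizon and enforces the steady-state criterion there.
#'
#' @param net An `avatar_network`.
#' @param schedule A [stage_schedule()].
#' @param n_out Trajectory output resolution.
#' @param rel_tol Steady-state drift tolerance (default 1e-6 over the
#'   trailing 10% window).
#' @return A list with `state` (control baseline), `steady` (diagnostics
#'   from [detect_steady_state()]) and `trajectory`.
#' @export
run_control <- function(net, schedule = stage_schedule(), n_out = 201,
                        rel_tol = 1e-6) {
  traj <- simulate_network(net, t0 = 0, t1 = schedule$control_end, n_out = n_out)
  ss <- detect_steady_state(traj, rel_tol = rel_tol)
  if (!ss$is_steady) {
    worst <- utils::head(ss$drift$node[ss$drift$drift > rel_tol], 5)
    stop("control baseline not steady at ", schedule$control_end,
         " s (max drift ", signif(ss$max_drift, 3), "); worst nodes: ",
         paste(worst, collapse = ", "), call. = FALSE)
  }
  list(state = final_state(traj), steady = ss, trajectory = traj)
}

#' Build a cell-line avatar
#'
#' Overlays a genomic profile (and optionally a cytokine condition) on a
#' control network and simulates through the disease stage, producing the
#' disease baseline against which treatments are read out. Cytokine clamps
#' are applied together with the aberrations at the start of the disease
#' stage, so the "disease baseline variant with the micro-environment" is
#' itself steady before any drug is introduced; treatment percent changes
#' are then computed against that variant, keeping drug and cytokine effects
#' separable.
#'
#' @param net An `avatar_network`.
#' @param profile A [genomic_profile()] (or `NULL` for a profile-free run).
#' @param schedule A [stage_schedule()].
#' @param cytokines A [cytokine_condition()] (or `NULL`).
#' @param params [overlay_params()].
#' @param definition [index_definition()] used for phenotype readouts.
#' @param annotation Gene annotation for `auto` mutation calls.
#' @param n_out Per-stage trajectory resolution.
#' @return An object of class `avatar`: the prepared context caching the
#'   control and disease baselines, the composed disease-stage modifiers and
#'   the overlay report.
#' @seealso [simulate_treatment()], [dose_response()], [readouts()]
#' @export
build_avatar <- function(net, profile = NULL, schedule = stage_schedule(),
                         cytokines = NULL, params = overlay_params(),
                         definition = index_definition(),
                         annotation = default_gene_annotation(),
                         n_out = 201) {
  ctrl <- run_control(net, schedule, n_out = n_out)
  if (is.null(profile)) profile <- genomic_profile("control")
  overlay <- apply_aberrations(net, profile, params, annotation)
  mods <- overlay$modifiers
  if (!is.null(cytokines) && length(cytokines) > 0) {
    bad <- setdiff(names(cytokines), net$boundary_ligands)
    if (length(bad) > 0) {
      stop("not declared boundary ligand(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    clamp <- stats::setNames(as.numeric(cytokines), names(cytokines))
    mods <- compose_modifiers(mods, modifier_set(ligand_clamp = clamp))
  }
  traj <- simulate_network(net, mods, y_init = ctrl$state,
                           t0 = schedule$control_end, t1 = schedule$disease_end,
                           n_out = n_out)
  dis_state <- final_state(traj)
  structure(
    list(network = net, profile = profile, schedule = schedule,
         cytokines = cytokines, params = params, definition = definition,
         control_state = ctrl$state, control_steady = ctrl$steady,
         disease_state = dis_state,
         disease_steady = detect_steady_state(traj),
         disease_mods = mods, overlay_report = overlay$report,
         n_out = n_out),
    class = "avatar"
  )
}

#' @export
print.avatar <- function(x, ...) {
  v <- viability_index(x$disease_state, x$definition)
  cat("<avatar> ", x$profile$name,
      if (!is.null(x$cytokines) && length(x$cytokines) > 0) {
        paste0(" + ", paste0(names(x$cytokines), "=", x$cytokines, collapse = ","))
      } else "",
      ": disease viability index ", signif(v$ratio, 4),
      " (survival ", signif(v$survival, 3), " / apoptosis ", signif(v$apoptosis, 3),
      ")\n", sep = "")
  invisible(x)
}

#' Apply a cytokine micro-environment condition to an avatar
#'
#' Returns a new avatar whose disease baseline is re-equilibrated with the
#' given ligand clamps layered onto the existing condition (cumulative
#' application). Receptor gating holds: a clamped ligand whose receptor
#' production is zeroed changes no downstream readout.
#'
#' @param avatar A prepared [build_avatar()] object.
#' @param condition A [cytokine_condition()].
#' @return A new `avatar`.
#' @export
apply_microenvironment <- function(avatar, condition) {
  combined <- c(avatar$cytokines)
  combined <- combined[!names(combined) %in% names(condition)]
  combined <- cytokine_condition(c(combined, condition))
  build_avatar(avatar$network, avatar$profile, avatar$schedule,
               cytokines = combined, params = avatar$params,
               definition = avatar$definition, n_out = avatar$n_out)
}

#' Simulate a treatment stage on an avatar
#'
#' Composes the drug modifiers for each `(drug, dose)` onto the avatar's
#' disease-stage modifiers and integrates from the disease baseline to the
#' treatment horizon. Doses of the *same* drug are summed before conversion
#' to modifiers (aliquots of one compound obey dose addition, so a sham
#' combination of a drug with itself is exactly Loewe-additive); distinct
#' drugs compose multiplicatively on shared targets (independent binding).
#'
#' @param avatar A prepared [build_avatar()] object.
#' @param treatments List of `list(drug = <drug>, dose_c = <dose in C units>)`;
#'   an empty list is the vehicle run.
#' @return An object of class `avatar_run` with the treated state, phenotype
#'   readout (normalized viability vs. the avatar's disease baseline) and
#'   treatment metadata.
#' @export
simulate_treatment <- function(avatar, treatments = list()) {
  stopifnot(inherits(avatar, "avatar"))
  for (tr in treatments) {
    if (tr$dose_c < 0) stop("dose must be >= 0", call. = FALSE)
  }
  if (length(treatments) > 1) {
    ids <- vapply(treatments, function(tr) tr$drug$id, character(1))
    treatments <- lapply(unique(ids), function(i) {
      trs <- treatments[ids == i]
      list(drug = trs[[1]]$drug,
           dose_c = sum(vapply(trs, function(tr) tr$dose_c, numeric(1))))
    })
  }
  mods <- avatar$disease_mods
  for (tr in treatments) {
    mods <- compose_modifiers(mods, drug_modifiers(tr$drug, tr$dose_c))
  }
  traj <- simulate_network(avatar$network, mods, y_init = avatar$disease_state,
                           t0 = avatar$schedule$disease_end,
                           t1 = avatar$schedule$treatment_end,
                           n_out = avatar$n_out)
  state <- final_state(traj)
  structure(
    list(avatar = avatar, treatments = treatments,
         treated_state = state,
         steady = detect_steady_state(traj),
         phenotypes = phenotype_readout(state, avatar$definition,
                                        baseline_state = avatar$disease_state)),
    class = "avatar_run"
  )
}

#' @export
print.avatar_run <- function(x, ...) {
  lab <- if (length(x$treatments) == 0) "vehicle" else {
    paste0(vapply(x$treatments, function(tr) paste0(tr$drug$id, "@", signif(tr$dose_c, 3), "C"),
                  character(1)), collapse = " + ")
  }
  cat("<avatar_run> ", x$avatar$profile$name, " | ", lab,
      ": normalized viability ",
      signif(x$phenotypes$normalized_viability_percent, 4), "%\n", sep = "")
  invisible(x)
}

#' Readout table of a treated run
#'
#' Percent change of every biomarker (all non-ligand network nodes) and of
#' the four phenotype indices, treated vs. the avatar's disease baseline.
#'
#' @param run An [simulate_treatment()] result.
#' @param markers Optional character vector restricting the biomarker rows.
#' @return A tibble with columns `marker`, `baseline`, `treated`,
#'   `pct_change`.
#' @export
readouts <- function(run, markers = NULL) {
  stopifnot(inherits(run, "avatar_run"))
  av <- run$avatar
  ids <- setdiff(node_ids(av$network), av$network$boundary_ligands)
  if (!is.null(markers)) ids <- intersect(markers, ids)
  base <- av$disease_state[ids]
  trt <- run$treated_state[ids]
  node_rows <- tibble::tibble(
    marker = ids, baseline = unname(base), treated = unname(trt),
    pct_change = percent_change(unname(trt), unname(base))
  )
  pb <- phenotype_readout(av$disease_state, av$definition)
  pt <- run$phenotypes
  idx <- c("proliferation_index", "survival_index", "apoptosis_index",
           "viability_index")
  idx_rows <- tibble::tibble(
    marker = idx,
    baseline = as.numeric(pb[1, idx]),
    treated = as.numeric(pt[1, idx]),
    pct_change = percent_change(as.numeric(pt[1, idx]), as.numeric(pb[1, idx]))
  )
  dplyr::bind_rows(node_rows, idx_rows)
}

#' Evaluate predicted trends against an expected trend table
#'
#' For each trend-table row, the predicted direction of the marker's percent
#' change under the named condition is compared with the expected direction.
#'
#' @param runs Named list of [simulate_treatment()] results; names match the
#'   trend table's `condition` column.
#' @param trends Trend table (`condition`, `marker`, `direction`).
#' @param tol Dead band for [trend_direction()] in percentage points.
#' @return A tibble with per-row `pct_change`, `predicted`, `expected`,
#'   `match`, plus an `agreement` attribute (fraction matched).
#' @export
evaluate_trends <- function(runs, trends, tol = 0.5) {
  missing_cond <- setdiff(unique(trends$condition), names(runs))
  if (length(missing_cond) > 0) {
    stop("no run supplied for condition(s): ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(trends)), function(i) {
    run <- runs[[trends$condition[i]]]
    tab <- readouts(run)
    hit <- tab[tab$marker == trends$marker[i], , drop = FALSE]
    if (nrow(hit) == 0) {
      stop("marker '", trends$marker[i], "' not resolvable in condition '",
           trends$condition[i], "'", call. = FALSE)
    }
    tibble::tibble(condition = trends$condition[i], marker = trends$marker[i],
                   pct_change = hit$pct_change[1],
                   predicted = trend_direction(hit$pct_change[1], tol),
                   expected = trends$direction[i])
  })
  out <- dplyr::bind_rows(rows)
  out$match <- out$predicted == out$expected
  attr(out, "agreement") <- if (nrow(out) > 0) mean(out$match) else NA_real_
  out
}
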