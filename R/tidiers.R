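#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an avatar into a per-node baseline table
#'
#' One row per network node: control and disease-baseline activity plus the
#' disease-induction percent change.
#'
#' @param x An [build_avatar()] object.
#' @param ... Unused.
#' @return A tibble with columns `node`, `control`, `disease`, `pct_change`.
#' @export
tidy.avatar <- function(x, ...) {
  ids <- node_ids(x$network)
  tibble::tibble(
    node = ids,
    control = unname(x$control_state[ids]),
    disease = unname(x$disease_state[ids]),
    pct_change = percent_change(unname(x$disease_state[ids]),
                                unname(x$control_state[ids]))
  )
}

#' One-row summary of an avatar
#'
#' @param x An [build_avatar()] object.
#' @param ... Unused.
#' @return A tibble with the profile name, cytokine condition, stage
#'   steadiness and disease-baseline phenotype indices.
#' @export
glance.avatar <- function(x, ...) {
  ph <- phenotype_readout(x$disease_state, x$definition)
  tibble::tibble(
    profile = x$profile$name,
    cytokines = if (is.null(x$cytokines) || length(x$cytokines) == 0) "" else {
      paste0(names(x$cytokines), "=", as.numeric(x$cytokines), collapse = ",")
    },
    control_steady = x$control_steady$is_steady,
    disease_steady = x$disease_steady$is_steady,
    proliferation_index = ph$proliferation_index,
    survival_index = ph$survival_index,
    apoptosis_index = ph$apoptosis_index,
    viability_index = ph$viability_index
  )
}

#' Tidy a treated run into its readout table
#'
#' @param x An [simulate_treatment()] result.
#' @param ... Passed to [readouts()].
#' @return The readout tibble (`marker`, `baseline`, `treated`,
#'   `pct_change`).
#' @export
tidy.avatar_run <- function(x, ...) readouts(x, ...)

#' One-row summary of a treated run
#'
#' @param x An [simulate_treatment()] result.
#' @param ... Unused.
#' @return A tibble with the treatment label, phenotype indices and
#'   normalized viability.
#' @export
glance.avatar_run <- function(x, ...) {
  lab <- if (length(x$treatments) == 0) "vehicle" else {
    paste0(vapply(x$treatments,
                  function(tr) paste0(tr$drug$id, "@", signif(tr$dose_c, 4), "C"),
                  character(1)), collapse = "+")
  }
  dplyr::bind_cols(
    tibble::tibble(profile = x$avatar$profile$name, treatment = lab),
    x$phenotypes
  )
}

#' Tidy an isobologram result into its contour pairs
#'
#' @param x An [isobologram()] result.
#' @param ... Unused.
#' @return The `pairs` tibble (`dose_a`, `dose_b`, `ci`, `verdict`).
#' @export
tidy.isobologram_result <- function(x, ...) x$pairs

#' One-row summary of an isobologram
#'
#' @param x An [isobologram()] result.
#' @param ... Unused.
#' @return A tibble with the effect level, both IC50s, the minimum
#'   combination index and the overall verdict.
#' @export
glance.isobologram_result <- function(x, ...) {
  tibble::tibble(
    level = x$level, ic50_a = x$ic50_a, ic50_b = x$ic50_b,
    min_ci = min(x$pairs$ci),
    verdict = x$pairs$verdict[which.min(x$pairs$ci)]
  )
}

#' Plot a dose-response curve
#'
#' Normalized viability (% of the untreated disease baseline) against dose
#' on a log axis.
#'
#' @param object A `dose_response_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_response_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_c, y = .data$viability_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "dose (multiples of C)", y = "viability (% of untreated)",
      title = paste0(attr(object, "drug_id") %||% "drug", " on ",
                     attr(object, "avatar_name") %||% "avatar")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a combination grid as a response surface
#'
#' @param object A `combination_grid`.
#' @param ... Unused.
#' @return A ggplot object (tile heat map of percent viability reduction).
#' @export
autoplot.combination_grid <- function(object, ...) {
  ids <- attr(object, "drug_ids") %||% c("drug A", "drug B")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_a, y = .data$dose_b,
                                       fill = .data$reduction_pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% reduction") +
    ggplot2::labs(x = paste0(ids[1], " dose (C)"), y = paste0(ids[2], " dose (C)")) +
    ggplot2::theme_minimal()
}

#' Plot an isobologram
#'
#' The straight line joins the two single-agent IC50s (Loewe additivity);
#' contour points falling inside it indicate synergy.
#'
#' @param object An `isobologram_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isobologram_result <- function(object, ...) {
  line <- tibble::tibble(dose_a = c(object$ic50_a, 0), dose_b = c(0, object$ic50_b))
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$dose_a, y = .data$dose_b)) +
    ggplot2::geom_line(data = line, colour = "red") +
    ggplot2::geom_point(shape = 4, size = 3) +
    ggplot2::labs(
      x = paste0(object$drug_ids[1], " dose (C)"),
      y = paste0(object$drug_ids[2], " dose (C)"),
      title = paste0("Iso-effect contour at ", object$level, "% reduction")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a trajectory
#'
#' @param object An `avatar_trajectory`.
#' @param nodes Optional node ids to show (default: all).
#' @param ... Unused.
#' @return A ggplot object of activity against simulation time.
#' @export
autoplot.avatar_trajectory <- function(object, nodes = NULL, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_s",
                            names_to = "node", values_to = "activity")
  if (!is.null(nodes)) df <- dplyr::filter(df, .data$node %in% nodes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$activity,
                                   colour = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "simulation time (s)", y = "normalized activity") +
    ggplot2::theme_minimal()
}
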