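#' Construct a set of network modifiers
#'
#' Modifiers are the mechanism through which everything that perturbs a
#' network — genomic aberrations, drugs, cytokine conditions — is expressed:
#'
#' * `activity_multiplier`: per-node factor in `[0,1]` scaling effective
#'   production of active protein (drug target inhibition, loss-of-function).
#' * `production_scaler`: per-node factor `>= 0` scaling expression at the
#'   transcription level (copy-number amplification/deletion, absent
#'   receptor).
#' * `basal_override`: replaces a node's constitutive drive with a value in
#'   `[0,1]` (gain-of-function mutation, making the node ligand-independent).
#' * `ligand_clamp`: holds a boundary-ligand node at a fixed activity in
#'   `[0,1]` (cytokine micro-environment condition).
#'
#' @param activity_multiplier,production_scaler,basal_override,ligand_clamp
#'   Named numeric vectors keyed by node id. All optional.
#' @return An object of class `modifier_set`.
#' @seealso [compose_modifiers()], [apply_aberrations()], [drug_modifiers()]
#' @export
modifier_set <- function(activity_multiplier = numeric(),
                         production_scaler = numeric(),
                         basal_override = numeric(),
                         ligand_clamp = numeric()) {
  chk <- function(x, lo, hi, nm) {
    if (length(x) > 0) {
      if (is.null(names(x)) || any(names(x) == "")) {
        stop(nm, " must be a named vector of node ids", call. = FALSE)
      }
      if (any(x < lo | x > hi)) {
        stop(nm, " values must lie in [", lo, ", ", hi, "]", call. = FALSE)
      }
    }
    x
  }
  structure(
    list(
      activity_multiplier = chk(activity_multiplier, 0, 1, "activity_multiplier"),
      production_scaler = chk(production_scaler, 0, Inf, "production_scaler"),
      basal_override = chk(basal_override, 0, 1, "basal_override"),
      ligand_clamp = chk(ligand_clamp, 0, 1, "ligand_clamp")
    ),
    class = "modifier_set"
  )
}

#' Compose modifier sets
#'
#' Later stages layer on earlier ones: multipliers and scalers multiply on
#' shared nodes; basal overrides and ligand clamps from the later set replace
#' earlier ones (later-stage precedence). Composition is associative, and the
#' empty set is the identity.
#'
#' @param ... `modifier_set` objects, earliest stage first.
#' @return A single composed `modifier_set`.
#' @export
compose_modifiers <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  mult <- function(a, b) {
    ids <- union(names(a), names(b))
    out <- rep(1, length(ids))
    names(out) <- ids
    out[names(a)] <- out[names(a)] * a
    out[names(b)] <- out[names(b)] * b
    out
  }
  override <- function(a, b) {
    out <- a
    out[names(b)] <- b
    out
  }
  Reduce(function(x, y) {
    modifier_set(
      activity_multiplier = mult(x$activity_multiplier, y$activity_multiplier),
      production_scaler = mult(x$production_scaler, y$production_scaler),
      basal_override = override(x$basal_override, y$basal_override),
      ligand_clamp = override(x$ligand_clamp, y$ligand_clamp)
    )
  }, sets, modifier_set())
}

#' @export
print.modifier_set <- function(x, ...) {
  cat("<modifier_set>\n")
  for (slot in names(x)) {
    if (length(x[[slot]]) > 0) {
      cat("  ", slot, ": ",
          paste0(names(x[[slot]]), "=", signif(x[[slot]], 4), collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}

# Expand a modifier set to per-node vectors aligned with the network's node
# order; errors on references to unknown nodes.
resolve_modifiers <- function(net, mods) {
  ids <- node_ids(net)
  for (slot in names(mods)) {
    assert_nodes_exist(net, names(mods[[slot]]), paste0(slot, " node"))
  }
  m <- rep(1, length(ids)); names(m) <- ids
  p <- rep(1, length(ids)); names(p) <- ids
  basal <- net$nodes$basal_drive; names(basal) <- ids
  m[names(mods$activity_multiplier)] <- mods$activity_multiplier
  p[names(mods$production_scaler)] <- mods$production_scaler
  basal[names(mods$basal_override)] <- mods$basal_override
  clamp <- mods$ligand_clamp
  list(mult = m, prod = p, basal = basal, clamp = clamp)
}
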