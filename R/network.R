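#' Construct a signaling-network specification
#'
#' A network is the mechanistic substrate of an avatar: a set of species
#' nodes (genes, proteins, complexes, ligands) carrying normalized activities
#' in `[0, y_max]`, and signed, weighted interactions between them. Dynamics
#' on the network follow normalized-Hill logic-based ODEs (see
#' [simulate_network()]).
#'
#' @param nodes A data frame with one row per species. Required column `id`
#'   (unique symbol). Optional columns (defaults in parentheses): `label`
#'   (= id), `roles` (`""`; comma-separated tags from ligand, receptor,
#'   kinase, transcription_factor, complex, effector, readout), `y_max` (1),
#'   `tau` (1000, relaxation time constant in simulation seconds),
#'   `basal_drive` (0, constitutive input in `[0,1]`), `y0` (0, initial
#'   activity).
#' @param interactions A data frame with one row per directed edge. Required
#'   columns `source`, `target`, `sign` (`"activating"` or `"inhibiting"`).
#'   Optional: `weight` (0.9, effect strength in (0,1]), `half_max` (0.5,
#'   activation midpoint), `hill` (1.4, cooperativity >= 1), `gate` (`"OR"`;
#'   `"AND"` edges into the same target multiply before OR-pooling).
#' @param boundary_ligands Character vector of node ids whose activities are
#'   externally clamped (cytokines, growth factors). Clamped nodes hold fixed
#'   values instead of relaxing.
#' @param validate If `TRUE` (default), stop on an invalid network.
#'
#' @return An object of class `avatar_network`: a list with tibbles `nodes`
#'   and `interactions` plus `boundary_ligands`.
#' @seealso [validate_network()], [read_network()], [simulate_network()]
#' @export
#' @examples
#' net <- network_spec(
#'   nodes = data.frame(id = c("L", "R", "OUT"), basal_drive = c(0, 0.1, 0)),
#'   interactions = data.frame(
#'     source = c("L", "R"), target = c("R", "OUT"), sign = "activating"
#'   ),
#'   boundary_ligands = "L"
#' )
#' net
network_spec <- function(nodes, interactions = NULL, boundary_ligands = character(),
                         validate = TRUE) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot("id" %in% names(nodes))
  node_defaults <- list(label = nodes$id, roles = "", y_max = 1, tau = 1000,
                        basal_drive = 0, y0 = 0)
  for (col in names(node_defaults)) {
    if (!col %in% names(nodes)) nodes[[col]] <- node_defaults[[col]]
  }
  nodes <- nodes[, c("id", "label", "roles", "y_max", "tau", "basal_drive", "y0")]

  if (is.null(interactions) || nrow(as.data.frame(interactions)) == 0) {
    interactions <- tibble::tibble(
      source = character(), target = character(), sign = character(),
      weight = numeric(), half_max = numeric(), hill = numeric(),
      gate = character()
    )
  } else {
    interactions <- tibble::as_tibble(interactions)
    stopifnot(all(c("source", "target", "sign") %in% names(interactions)))
    edge_defaults <- list(weight = 0.9, half_max = 0.5, hill = 1.4, gate = "OR")
    for (col in names(edge_defaults)) {
      if (!col %in% names(interactions)) interactions[[col]] <- edge_defaults[[col]]
    }
    interactions <- interactions[, c("source", "target", "sign", "weight",
                                     "half_max", "hill", "gate")]
  }

  net <- structure(
    list(nodes = nodes, interactions = interactions,
         boundary_ligands = as.character(boundary_ligands)),
    class = "avatar_network"
  )
  if (validate) {
    report <- validate_network(net)
    if (nrow(report) > 0) {
      stop("invalid network:\n", paste0("  - ", report$message, collapse = "\n"),
           call. = FALSE)
    }
  }
  net
}

#' Validate a network specification
#'
#' Checks referential integrity and parameter ranges. Unlike
#' [network_spec()]'s constructor-time check this never throws: all
#' violations are collected into a report so a curator can fix a file in one
#' pass.
#'
#' @param net An `avatar_network` (possibly malformed).
#' @return A tibble with columns `kind` (violation class) and `message`;
#'   zero rows if and only if the network is valid.
#' @export
validate_network <- function(net) {
  nodes <- net$nodes
  edges <- net$interactions
  out <- list()
  add <- function(kind, message) {
    out[[length(out) + 1]] <<- tibble::tibble(kind = kind, message = message)
  }

  if (nrow(nodes) < 1) add("empty", "network has no nodes")
  dup <- nodes$id[duplicated(nodes$id)]
  for (d in unique(dup)) add("duplicate_node", paste0("duplicate node id '", d, "'"))

  bad <- nodes$id[nodes$tau <= 0]
  for (b in bad) add("out_of_range", paste0("node '", b, "': tau must be > 0"))
  bad <- nodes$id[nodes$basal_drive < 0 | nodes$basal_drive > 1]
  for (b in bad) add("out_of_range", paste0("node '", b, "': basal_drive outside [0,1]"))
  bad <- nodes$id[nodes$y0 < 0 | nodes$y0 > nodes$y_max]
  for (b in bad) add("out_of_range", paste0("node '", b, "': y0 outside [0, y_max]"))
  bad <- nodes$id[nodes$y_max <= 0]
  for (b in bad) add("out_of_range", paste0("node '", b, "': y_max must be > 0"))

  if (nrow(edges) > 0) {
    dangling <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
    for (d in dangling) add("dangling_endpoint", paste0("dangling endpoint '", d, "'"))
    key <- paste(edges$source, edges$target, edges$sign)
    for (k in unique(key[duplicated(key)])) {
      add("duplicate_interaction", paste0("duplicate interaction (", gsub(" ", ",", k), ")"))
    }
    bad <- which(!edges$sign %in% c("activating", "inhibiting"))
    for (i in bad) add("bad_sign", paste0("edge ", edges$source[i], "->", edges$target[i],
                                          ": sign '", edges$sign[i], "' unknown"))
    bad <- which(edges$weight <= 0 | edges$weight > 1)
    for (i in bad) add("out_of_range", paste0("edge ", edges$source[i], "->", edges$target[i],
                                              ": weight outside (0,1]"))
    bad <- which(edges$half_max <= 0 | edges$half_max >= 1)
    for (i in bad) add("out_of_range", paste0("edge ", edges$source[i], "->", edges$target[i],
                                              ": half_max outside (0,1)"))
    bad <- which(edges$hill < 1)
    for (i in bad) add("out_of_range", paste0("edge ", edges$source[i], "->", edges$target[i],
                                              ": hill must be >= 1"))
    bad <- which(!edges$gate %in% c("OR", "AND"))
    for (i in bad) add("bad_gate", paste0("edge ", edges$source[i], "->", edges$target[i],
                                          ": gate '", edges$gate[i], "' unknown"))
  }
  unknown_bl <- setdiff(net$boundary_ligands, nodes$id)
  for (b in unknown_bl) add("dangling_endpoint", paste0("boundary ligand '", b, "' not a node"))

  if (length(out) == 0) {
    tibble::tibble(kind = character(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' @export
print.avatar_network <- function(x, ...) {
  cat("<avatar_network> ", nrow(x$nodes), " nodes, ", nrow(x$interactions),
      " interactions, ", length(x$boundary_ligands), " boundary ligand(s)\n", sep = "")
  invisible(x)
}

#' @export
format.avatar_network <- function(x, ...) {
  paste0("<avatar_network: ", nrow(x$nodes), " nodes, ",
         nrow(x$interactions), " edges>")
}

node_ids <- function(net) net$nodes$id

assert_nodes_exist <- function(net, ids, what = "node") {
  missing <- setdiff(ids, node_ids(net))
  if (length(missing) > 0) {
    stop("unknown ", what, "(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
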