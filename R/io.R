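# Split a structured-text document into bracketed [section] blocks.
parse_sections <- function(lines) {
  lines <- lines[!grepl("^\\s*#", lines)]
  hdr <- grep("^\\s*\\[[A-Za-z_]+\\]\\s*$", lines)
  out <- list()
  if (length(hdr) == 0) return(out)
  bounds <- c(hdr, length(lines) + 1)
  for (i in seq_along(hdr)) {
    nm <- gsub("[][ ]", "", lines[hdr[i]])
    body <- lines[seq(hdr[i] + 1, bounds[i + 1] - 1)]
    body <- body[nzchar(trimws(body))]
    out[[nm]] <- body
  }
  out
}

# Read a tab-separated block (first line = header) into a tibble.
read_tsv_block <- function(lines) {
  if (length(lines) == 0) stop("empty table block", call. = FALSE)
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.delim(con, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  ncol_hdr <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  for (i in seq_along(lines)[-1]) {
    n <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (n > ncol_hdr) {
      stop("row ", i, " has ", n, " fields, header has ", ncol_hdr, call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

fmt_tsv_block <- function(df) {
  df <- as.data.frame(df)
  hdr <- paste(names(df), collapse = "\t")
  if (nrow(df) == 0) return(hdr)
  body <- apply(df, 1, function(r) paste(trimws(format(r, scientific = FALSE)),
                                         collapse = "\t"))
  c(hdr, unname(body))
}

#' Read a network specification file
#'
#' The `avatarnet-v1` format is plain text: a `format:` header line, then
#' `[nodes]` and `[interactions]` tab-separated tables mirroring the
#' [network_spec()] fields, and an optional `[boundary_ligands]` section
#' listing one node id per line. Lines starting with `#` are comments.
#'
#' @param path Path to the network file.
#' @param validate Stop on an invalid network (default `TRUE`).
#' @return An `avatar_network`.
#' @export
read_network <- function(path, validate = TRUE) {
  lines <- readLines(path)
  fmt <- grep("^\\s*format\\s*:", lines, value = TRUE)
  if (length(fmt) == 0 || !grepl("avatarnet-v1", fmt[1])) {
    stop("not an avatarnet-v1 file: ", path, call. = FALSE)
  }
  sec <- parse_sections(lines)
  if (is.null(sec$nodes)) stop("network file lacks a [nodes] section", call. = FALSE)
  nodes <- read_tsv_block(sec$nodes)
  edges <- if (!is.null(sec$interactions)) read_tsv_block(sec$interactions) else NULL
  bl <- if (!is.null(sec$boundary_ligands)) trimws(sec$boundary_ligands) else character()
  network_spec(nodes, edges, bl, validate = validate)
}

#' Write a network specification file
#'
#' @param net An `avatar_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  lines <- c(
    "format: avatarnet-v1",
    "",
    "[nodes]",
    fmt_tsv_block(net$nodes),
    "",
    "[interactions]",
    fmt_tsv_block(net$interactions)
  )
  if (length(net$boundary_ligands) > 0) {
    lines <- c(lines, "", "[boundary_ligands]", net$boundary_ligands)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export a network to GraphML for visualization
#'
#' Read-only convenience export (via igraph); the `avatarnet-v1` text format
#' remains the authoritative representation.
#'
#' @param net An `avatar_network`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(net$interactions),
    directed = TRUE,
    vertices = as.data.frame(net$nodes)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a trajectory as a tab-separated table
#'
#' First column `time_s`, one column per node id.
#'
#' @param traj An `avatar_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a genomic profile file
#'
#' @param profile A [genomic_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  lines <- c(
    paste0("# profile: ", profile$name),
    "[aberrations]",
    fmt_tsv_block(profile$aberrations)
  )
  if (length(profile$receptor_expression) > 0) {
    lines <- c(lines, "", "[receptors]",
               fmt_tsv_block(data.frame(receptor = names(profile$receptor_expression),
                                        status = unname(profile$receptor_expression))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a drug definition file
#'
#' Drug files are YAML: one document per drug with fields `id`, `hill_h`,
#' `K_primary` and either `targets` (map of node id to potency fold) or
#' `selectivity` (a ranking string such as `"JAK2>JAK3>>JAK1>>>TYK2"`, see
#' [selectivity_from_profile()]) plus `fold_base`.
#'
#' @param path Path to a YAML drug library.
#' @return A named list of [drug()] objects.
#' @export
read_drug_library <- function(path) {
  docs <- yaml::read_yaml(path)
  if (!is.null(docs$id)) docs <- list(docs)
  drugs <- lapply(docs, function(d) {
    if (!is.null(d$selectivity)) {
      folds <- selectivity_from_profile(d$selectivity,
                                        fold_base = d$fold_base %||% 5)
    } else {
      folds <- unlist(d$targets)
    }
    drug(id = d$id, targets = folds,
         hill_h = d$hill_h %||% 1, K_primary = d$K_primary %||% 1)
  })
  stats::setNames(drugs, vapply(drugs, function(d) d$id, character(1)))
}

#' Write a readout table as tab-separated text
#'
#' Includes a comment-prefixed metadata header so each table is traceable to
#' the run that produced it.
#'
#' @param readouts A readout tibble (see [readouts()]).
#' @param path Output path.
#' @param meta Optional named character vector written as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_readouts <- function(readouts, path, meta = character()) {
  lines <- character()
  if (length(meta) > 0) lines <- paste0("# ", names(meta), ": ", unname(meta))
  lines <- c(lines, fmt_tsv_block(readouts))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trend table
#'
#' Trend tables are tab-separated with columns `condition`, `marker`,
#' `direction` (`up`, `down` or `unchanged`).
#'
#' @param path Path to the table.
#' @return A validated tibble.
#' @export
read_trend_table <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                            comment.char = "#"))
  stopifnot(all(c("condition", "marker", "direction") %in% names(df)))
  bad <- setdiff(unique(df$direction), c("up", "down", "unchanged"))
  if (length(bad) > 0) stop("unknown trend direction(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
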