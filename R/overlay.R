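#' Construct a genomic profile
#'
#' A profile is the genomic identity of an avatar: the per-gene aberrations
#' (mutations and copy-number changes) plus receptor-expression calls that
#' gate cytokine signaling.
#'
#' @param name Profile (cell line / biopsy) identifier.
#' @param aberrations Data frame with columns `gene`, `kind` (one of
#'   `mutation`, `amplification`, `deletion`), optional `functional_call`
#'   (`gof`, `lof` or `auto`; default `auto`) and optional `magnitude`
#'   (positive override of the default effect size).
#' @param receptor_expression Named character vector, receptor node id to
#'   `"present"` or `"absent"`.
#' @return An object of class `genomic_profile`.
#' @export
genomic_profile <- function(name, aberrations = NULL, receptor_expression = character()) {
  if (is.null(aberrations) || nrow(as.data.frame(aberrations)) == 0) {
    aberrations <- tibble::tibble(gene = character(), kind = character(),
                                  functional_call = character(), magnitude = numeric())
  } else {
    aberrations <- tibble::as_tibble(aberrations)
    stopifnot(all(c("gene", "kind") %in% names(aberrations)))
    if (!"functional_call" %in% names(aberrations)) aberrations$functional_call <- "auto"
    if (!"magnitude" %in% names(aberrations)) aberrations$magnitude <- NA_real_
    aberrations$functional_call[is.na(aberrations$functional_call) |
                                  aberrations$functional_call == ""] <- "auto"
    aberrations <- aberrations[, c("gene", "kind", "functional_call", "magnitude")]
  }
  bad <- setdiff(unique(aberrations$kind), c("mutation", "amplification", "deletion"))
  if (length(bad) > 0) {
    stop("unknown aberration kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(aberrations$functional_call), c("gof", "lof", "auto"))
  if (length(bad) > 0) {
    stop("unknown functional_call value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(aberrations$magnitude) & aberrations$magnitude <= 0)) {
    stop("magnitude overrides must be > 0", call. = FALSE)
  }
  if (any(aberrations$gene == "")) stop("gene symbols must be non-empty", call. = FALSE)
  key <- paste(aberrations$gene, aberrations$kind)
  if (anyDuplicated(key)) {
    stop("duplicate (gene, kind) pair: ", key[duplicated(key)][1], call. = FALSE)
  }
  if (length(receptor_expression) > 0) {
    stopifnot(!is.null(names(receptor_expression)),
              all(receptor_expression %in% c("present", "absent")))
  }
  structure(list(name = name, aberrations = aberrations,
                 receptor_expression = receptor_expression),
            class = "genomic_profile")
}

#' @export
print.genomic_profile <- function(x, ...) {
  cat("<genomic_profile> ", x$name, ": ", nrow(x$aberrations), " aberration(s)",
      sep = "")
  absent <- names(x$receptor_expression)[x$receptor_expression == "absent"]
  if (length(absent) > 0) cat("; absent receptors: ", paste(absent, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Parse a genomic profile file
#'
#' Profiles are plain tab-separated text with an `[aberrations]` table
#' (columns `gene`, `kind`, `functional_call`, `magnitude`) and an optional
#' `[receptors]` table (columns `receptor`, `status`). Lines starting with
#' `#` are comments; a `# profile:` comment names the profile.
#'
#' @param path Path to the profile file.
#' @return A validated [genomic_profile()].
#' @export
parse_profile <- function(path) {
  lines <- readLines(path)
  name <- tools::file_path_sans_ext(basename(path))
  m <- grep("^#\\s*profile\\s*:", lines, value = TRUE)
  if (length(m) > 0) name <- trimws(sub("^#\\s*profile\\s*:", "", m[1]))
  sec <- parse_sections(lines)
  ab <- NULL
  if (!is.null(sec$aberrations)) {
    ab <- tryCatch(
      read_tsv_block(sec$aberrations),
      error = function(e) stop("malformed [aberrations] table in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    need <- c("gene", "kind")
    if (!all(need %in% names(ab))) {
      stop("profile ", path, " lacks required columns gene/kind", call. = FALSE)
    }
    if ("magnitude" %in% names(ab)) ab$magnitude <- as.numeric(ab$magnitude)
  }
  rec <- character()
  if (!is.null(sec$receptors)) {
    rc <- read_tsv_block(sec$receptors)
    if (!all(c("receptor", "status") %in% names(rc))) {
      stop("profile ", path, ": [receptors] block needs receptor/status columns",
           call. = FALSE)
    }
    rec <- stats::setNames(rc$status, rc$receptor)
  }
  genomic_profile(name, ab, rec)
}

#' Curated oncogene / tumor-suppressor annotation
#'
#' Covers the genes appearing in the bundled HEL and SET2 fixtures. Any gene
#' outside this table needs an explicit `functional_call` in the profile.
#'
#' @return A tibble with columns `gene` and `class`
#'   (`oncogene`/`tumor_suppressor`).
#' @export
default_gene_annotation <- function() {
  tibble::tribble(
    ~gene,     ~class,
    "JAK2",    "oncogene",
    "MAP2K1",  "oncogene",
    "EGF",     "oncogene",
    "CCNA2",   "oncogene",
    "NOTCH2",  "oncogene",
    "RPTOR",   "oncogene",
    "E2F1",    "oncogene",
    "TP53",    "tumor_suppressor",
    "CDKN2A",  "tumor_suppressor",
    "RB1",     "tumor_suppressor"
  )
}

#' Classify a mutation as gain- or loss-of-function
#'
#' Oncogenic mutations act as gain of function at the protein-activity
#' level; tumor-suppressor mutations as loss of function. An explicit
#' `functional_call` in the profile always wins over the annotation.
#'
#' @param gene Gene symbol.
#' @param functional_call `"gof"`, `"lof"` or `"auto"`.
#' @param annotation Annotation table as in [default_gene_annotation()].
#' @return `"gof"` or `"lof"`.
#' @export
classify_mutation <- function(gene, functional_call = "auto",
                              annotation = default_gene_annotation()) {
  if (functional_call %in% c("gof", "lof")) return(functional_call)
  cls <- annotation$class[annotation$gene == gene]
  if (length(cls) == 0) {
    stop("gene '", gene, "' is unannotated; give an explicit functional_call",
         call. = FALSE)
  }
  if (cls[1] == "oncogene") "gof" else "lof"
}

#' Overlay effect magnitudes
#'
#' The conventions by which qualitative aberration calls become quantitative
#' modifiers. None of these magnitudes is measured; they are exposed so a
#' curator can express e.g. heterozygous deletion via a magnitude override.
#'
#' @param alpha_gof Basal override installed by a gain-of-function mutation
#'   (default 0.9): the node becomes constitutively driven and hence
#'   ligand-independent.
#' @param lambda_lof Activity multiplier installed by a loss-of-function
#'   mutation (default 0.1).
#' @param kappa_amp Production scaler for an amplification (default 2.0).
#' @param kappa_del Production scaler for a deletion (default 0.0).
#' @return A list of class `overlay_params`.
#' @export
overlay_params <- function(alpha_gof = 0.9, lambda_lof = 0.1,
                           kappa_amp = 2.0, kappa_del = 0.0) {
  stopifnot(alpha_gof >= 0, alpha_gof <= 1, lambda_lof >= 0, lambda_lof <= 1,
            kappa_amp >= 0, kappa_del >= 0)
  structure(list(alpha_gof = alpha_gof, lambda_lof = lambda_lof,
                 kappa_amp = kappa_amp, kappa_del = kappa_del),
            class = "overlay_params")
}

#' Map a genomic profile onto network modifiers
#'
#' Applies the overlay rules gene by gene: gain-of-function mutations set a
#' basal override (`alpha_gof`), loss-of-function mutations an activity
#' multiplier (`lambda_lof`), amplifications/deletions scale production
#' (`kappa_amp` / `kappa_del`), and absent receptors zero the receptor
#' node's production. A mutation and a CNV on the same gene compose
#' (activity and production are independent axes). Genes absent from the
#' network are skipped, never fatal; every aberration lands in the report
#' exactly once.
#'
#' @param net An `avatar_network`.
#' @param profile A [genomic_profile()].
#' @param params [overlay_params()].
#' @param annotation Gene annotation for `auto` calls.
#' @return A list with `modifiers` (a [modifier_set()]) and `report` (tibble
#'   with columns `gene`, `kind`, `status` applied/skipped, `detail`).
#' @export
apply_aberrations <- function(net, profile, params = overlay_params(),
                              annotation = default_gene_annotation()) {
  stopifnot(inherits(profile, "genomic_profile"))
  ids <- node_ids(net)
  act_mult <- numeric()
  prod_scale <- numeric()
  basal_over <- numeric()
  rows <- list()
  note <- function(gene, kind, status, detail) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      gene = gene, kind = kind, status = status, detail = detail
    )
  }
  ab <- profile$aberrations
  for (i in seq_len(nrow(ab))) {
    gene <- ab$gene[i]; kind <- ab$kind[i]
    mag <- ab$magnitude[i]
    if (!gene %in% ids) {
      note(gene, kind, "skipped", "not in network")
      next
    }
    if (kind == "mutation") {
      call <- classify_mutation(gene, ab$functional_call[i], annotation)
      if (call == "gof") {
        val <- if (is.na(mag)) params$alpha_gof else min(mag, 1)
        basal_over[gene] <- val
        note(gene, kind, "applied", paste0("gof: basal_override=", val))
      } else {
        val <- if (is.na(mag)) params$lambda_lof else min(mag, 1)
        act_mult[gene] <- min(act_mult[gene], val, 1, na.rm = TRUE)
        note(gene, kind, "applied", paste0("lof: activity_multiplier=", val))
      }
    } else if (kind == "amplification") {
      val <- if (is.na(mag)) params$kappa_amp else mag
      prod_scale[gene] <- ifelse(is.na(prod_scale[gene]), 1, prod_scale[gene]) * val
      note(gene, kind, "applied", paste0("production_scaler x", val))
    } else if (kind == "deletion") {
      val <- if (is.na(mag)) params$kappa_del else mag
      prod_scale[gene] <- ifelse(is.na(prod_scale[gene]), 1, prod_scale[gene]) * val
      note(gene, kind, "applied", paste0("production_scaler x", val))
    }
  }
  for (rec in names(profile$receptor_expression)) {
    if (profile$receptor_expression[[rec]] == "absent") {
      if (rec %in% ids) {
        prod_scale[rec] <- 0
        note(rec, "receptor_absent", "applied", "production_scaler=0")
      } else {
        note(rec, "receptor_absent", "skipped", "not in network")
      }
    }
  }
  report <- if (length(rows) == 0) {
    tibble::tibble(gene = character(), kind = character(),
                   status = character(), detail = character())
  } else {
    dplyr::bind_rows(rows)
  }
  mods <- modifier_set(
    activity_multiplier = act_mult,
    production_scaler = prod_scale,
    basal_override = basal_over
  )
  list(modifiers = mods, report = report)
}
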