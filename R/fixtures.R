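fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "cellavatar")
  if (p == "") {
    # during development the package may not be installed yet
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p)) stop("fixture file missing: ", file, call. = FALSE)
  p
}

fixture_files <- c(
  mpn_network = "mpn_network.avatarnet",
  HEL = "hel_profile.tsv",
  SET2 = "set2_profile.tsv",
  drug_library = "drugs.yaml",
  cytokines = "cytokine_conditions.yaml",
  trend_set2_jaki = "trend_set2_jaki.tsv",
  trend_hel_jaki1 = "trend_hel_jaki1.tsv"
)

#' List the bundled fixtures
#'
#' @return A tibble with fixture `name`, `file` and `md5` content hash.
#' @export
list_fixtures <- function() {
  paths <- vapply(fixture_files, fixture_path, character(1))
  tibble::tibble(
    name = names(fixture_files),
    file = unname(fixture_files),
    md5 = unname(tools::md5sum(paths))
  )
}

#' Load a bundled fixture
#'
#' The bundle is the curated myeloproliferative-neoplasm (MPN) study set: a
#' ~50-node JAK2-V617F signaling network, the HEL and SET2 cell-line
#' profiles, a drug library (G6, ABT737, a generic JAK inhibitor), standard
#' cytokine conditions (IL6, TNFA, IFNG at full clamp) and the qualitative
#' trend tables used for retrospective validation. Profiles carry only the
#' aberrations documented for these lines in the public record and are
#' deliberately partial.
#'
#' @param name One of `"mpn_network"`, `"HEL"`, `"SET2"`, `"G6"`,
#'   `"ABT737"`, `"JAKi"`, `"drug_library"`, `"cytokines"`,
#'   `"trend_set2_jaki"`, `"trend_hel_jaki1"`.
#' @return The corresponding validated object (network, profile, drug,
#'   drug list, condition list, or trend tibble).
#' @export
#' @examples
#' net <- load_fixture("mpn_network")
#' hel <- load_fixture("HEL")
load_fixture <- function(name) {
  drug_names <- c("G6", "ABT737", "JAKi")
  if (!name %in% c(names(fixture_files), drug_names)) {
    stop("unknown fixture '", name, "'; see list_fixtures()", call. = FALSE)
  }
  if (name %in% drug_names) {
    lib <- read_drug_library(fixture_path(fixture_files[["drug_library"]]))
    return(lib[[name]])
  }
  path <- fixture_path(fixture_files[[name]])
  switch(name,
    mpn_network = read_network(path),
    HEL = parse_profile(path),
    SET2 = parse_profile(path),
    drug_library = read_drug_library(path),
    cytokines = lapply(yaml::read_yaml(path), function(x) {
      do.call(cytokine_condition, as.list(unlist(x)))
    }),
    read_trend_table(path)
  )
}

#' Generate a random valid network (property-test substrate)
#'
#' Deterministic per seed: draws a random DAG-plus-feedback topology with
#' the requested edge density, excludes self-loops and duplicate
#' (source, target, sign) triples, and guarantees weak connectivity by
#' first threading a random spanning chain.
#'
#' @param n_nodes Number of nodes (`>= 2`).
#' @param density Fraction of possible ordered pairs carrying an edge, in
#'   (0, 1].
#' @param frac_inhibiting Fraction of edges drawn inhibiting.
#' @param feedback If `FALSE`, edges only go from lower to higher node
#'   index (acyclic).
#' @param seed RNG seed.
#' @return An `avatar_network`.
#' @export
generate_random_network <- function(n_nodes, density = 0.2,
                                    frac_inhibiting = 0.25, feedback = TRUE,
                                    seed = 1) {
  stopifnot(n_nodes >= 2, density > 0, density <= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  ids <- sprintf("N%02d", seq_len(n_nodes))
  nodes <- data.frame(id = ids, basal_drive = round(stats::runif(n_nodes, 0, 0.5), 3),
                      tau = 1000, y_max = 1, y0 = 0)
  pairs <- expand.grid(s = seq_len(n_nodes), t = seq_len(n_nodes))
  pairs <- pairs[pairs$s != pairs$t, ]
  if (!feedback) pairs <- pairs[pairs$s < pairs$t, ]
  # spanning chain first, then fill to the requested density
  perm <- sample(n_nodes)
  chain <- data.frame(s = perm[-n_nodes], t = perm[-1])
  if (!feedback) chain <- data.frame(s = pmin(chain$s, chain$t), t = pmax(chain$s, chain$t))
  n_target <- max(nrow(chain), round(density * nrow(pairs)))
  key <- function(df) paste(df$s, df$t)
  pool <- pairs[!key(pairs) %in% key(chain), ]
  extra <- pool[sample(nrow(pool), min(n_target - nrow(chain), nrow(pool))), ]
  sel <- unique(rbind(chain, extra))
  edges <- data.frame(
    source = ids[sel$s], target = ids[sel$t],
    sign = ifelse(stats::runif(nrow(sel)) < frac_inhibiting, "inhibiting", "activating"),
    weight = round(stats::runif(nrow(sel), 0.3, 0.9), 3),
    half_max = 0.5, hill = round(stats::runif(nrow(sel), 1, 2), 2), gate = "OR"
  )
  network_spec(nodes, edges)
}

#' Generate a synthetic trend table from hidden index weights
#'
#' Closed-loop oracle for [calibrate_weights()]: simulates each listed
#' perturbation on a network, computes index percent changes under a hidden
#' weight vector, and emits the resulting trend directions. Recovery means
#' calibration finds weights reproducing every direction.
#'
#' @param net An `avatar_network`.
#' @param hidden_definition The hidden [index_definition()].
#' @param perturbations Named list of [modifier_set()]s (condition name to
#'   perturbation); applied one at a time against the unperturbed baseline.
#' @param schedule A [stage_schedule()]; baselines at `control_end`,
#'   perturbed states at `disease_end`.
#' @param direction_tol Dead band for [trend_direction()].
#' @return A list with `trends` (tibble), `cases` (the per-condition
#'   baseline/treated states for calibration) and `hidden_definition`.
#' @export
generate_trend_fixture <- function(net, hidden_definition,
                                   perturbations,
                                   schedule = stage_schedule(),
                                   direction_tol = 0.5) {
  base_traj <- simulate_network(net, t0 = 0, t1 = schedule$control_end)
  base <- final_state(base_traj)
  idx <- c("proliferation_index", "survival_index", "apoptosis_index",
           "viability_index")
  cases <- list()
  rows <- list()
  for (cond in names(perturbations)) {
    traj <- simulate_network(net, perturbations[[cond]], y_init = base,
                             t0 = schedule$control_end, t1 = schedule$disease_end)
    treated <- final_state(traj)
    cases[[cond]] <- list(baseline = base, treated = treated)
    pb <- phenotype_readout(base, hidden_definition)
    pt <- phenotype_readout(treated, hidden_definition)
    for (m in idx) {
      pct <- percent_change(pt[[m]], pb[[m]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        condition = cond, marker = m,
        direction = trend_direction(pct, direction_tol)
      )
    }
  }
  list(trends = dplyr::bind_rows(rows), cases = cases,
       hidden_definition = hidden_definition)
}
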