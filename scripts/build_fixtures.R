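#!/usr/bin/env Rscript
# Regenerates the bundled fixtures under inst/extdata/ from the curation
# tables below. The network is the smallest closure containing the phenotype
# index biomarkers, the trend-table readouts, the JAK2-V617F driver arms and
# the three cytokine receptor axes; edge weights were calibrated once with
# this script (see scratch runs) and are frozen here. Run from the repo root:
#   Rscript scripts/build_fixtures.R

suppressMessages(devtools::load_all(".", quiet = TRUE))

out_dir <- "inst/extdata"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

# ---- curated MPN avatar network (JAK2-V617F signaling closure) ----------

N <- function(id, roles, basal = 0, tau = 1000) {
  data.frame(id = id, label = id, roles = roles, y_max = 1, tau = tau,
             basal_drive = basal, y0 = 0)
}

nodes <- rbind(
  # micro-environment ligands (boundary, clamped by cytokine conditions)
  N("IL6",   "ligand"), N("TNFA", "ligand"), N("IFNG", "ligand"),
  N("EGF",   "ligand"),
  # receptors
  N("IL6R",  "receptor", 0.10), N("TNFR", "receptor", 0.10),
  N("IFNGR", "receptor", 0.10),
  # JAK-family kinases
  N("JAK2", "kinase", 0.30), N("JAK1", "kinase", 0.20),
  N("JAK3", "kinase", 0.10), N("TYK2", "kinase", 0.10),
  # transcription factors and cytosolic transducers
  N("STAT5", "transcription_factor", 0.05),
  N("STAT3", "transcription_factor", 0.05),
  N("STAT1", "transcription_factor", 0.05),
  N("NFKB",  "transcription_factor", 0.10),
  N("PI3K",  "kinase", 0.10), N("AKT1", "kinase", 0.05),
  N("RPTOR", "effector", 0.30), N("SHC1", "effector", 0.10),
  N("MAP2K1", "kinase", 0.05), N("ERK", "kinase", 0.05),
  # tumor suppressors / cell-cycle control
  N("TP53", "transcription_factor", 0.40),
  N("CDKN2A", "effector", 0.35),
  N("RB1", "effector", 0.60),
  N("E2F1", "transcription_factor", 0.30),
  N("NOTCH2", "receptor", 0.20),
  # cyclins and CDKs
  N("CCND1", "effector", 0.10), N("CCNE1", "effector", 0.05),
  N("CCNA2", "effector", 0.05), N("CCNB1", "effector", 0.10),
  N("CDK4", "kinase", 0.60), N("CDK2", "kinase", 0.60), N("CDK1", "kinase", 0.60),
  # active CDK-cyclin complexes (AND-gated; proliferation index markers)
  N("CDK4_CCND1", "complex,readout"), N("CDK2_CCNE1", "complex,readout"),
  N("CDK2_CCNA2", "complex,readout"), N("CDK1_CCNB1", "complex,readout"),
  # survival arm
  N("BCL2", "effector,readout", 0.10), N("BCL2L1", "effector", 0.10),
  N("MCL1", "effector,readout", 0.10), N("BIRC5", "effector,readout", 0.05),
  N("BIRC2", "effector,readout", 0.10), N("XIAP", "effector,readout", 0.10),
  # apoptosis arm
  N("BIM", "effector,readout", 0.30), N("BAX", "effector,readout", 0.35),
  N("NOXA", "effector,readout", 0.05), N("CASP8", "effector,readout", 0.20),
  N("CASP9", "effector,readout", 0.15), N("CASP3", "effector,readout", 0.10),
  N("CASP7", "effector,readout", 0.10), N("PARPc", "effector,readout", 0.05)
)

E <- function(source, target, sign, weight, gate = "OR",
              half_max = 0.5, hill = 1.4) {
  data.frame(source = source, target = target, sign = sign, weight = weight,
             half_max = half_max, hill = hill, gate = gate)
}
A <- function(s, t, w, ...) E(s, t, "activating", w, ...)
I <- function(s, t, w, ...) E(s, t, "inhibiting", w, ...)

edges <- rbind(
  # cytokine axes
  A("IL6", "IL6R", 0.9), A("TNFA", "TNFR", 0.9), A("IFNG", "IFNGR", 0.9),
  A("IL6R", "JAK1", 0.5), A("IL6R", "JAK2", 0.3),
  A("IFNGR", "JAK1", 0.5), A("IFNGR", "JAK2", 0.3),
  A("TNFR", "NFKB", 0.35), A("TNFR", "CASP8", 0.55),
  # JAK2-driven core
  A("JAK2", "STAT5", 0.9), A("JAK2", "STAT3", 0.6), A("JAK2", "STAT1", 0.3),
  A("JAK2", "PI3K", 0.6), A("JAK2", "SHC1", 0.6),
  A("JAK1", "STAT3", 0.4), A("JAK1", "STAT1", 0.5),
  A("JAK3", "STAT5", 0.2), A("TYK2", "STAT1", 0.2),
  A("EGF", "SHC1", 0.5),
  A("PI3K", "AKT1", 0.85),
  A("SHC1", "MAP2K1", 0.8), A("MAP2K1", "ERK", 0.85),
  A("AKT1", "RPTOR", 0.4),
  # transcriptional outputs: survival and cyclins
  A("STAT5", "BCL2", 0.6), A("STAT5", "MCL1", 0.6), A("STAT5", "BCL2L1", 0.5),
  A("STAT5", "BIRC5", 0.5), A("STAT5", "BIRC2", 0.5), A("STAT5", "CCND1", 0.5),
  A("STAT3", "MCL1", 0.4), A("STAT3", "BCL2", 0.3), A("STAT3", "CCND1", 0.3),
  A("STAT3", "BIRC5", 0.3),
  A("STAT1", "MCL1", 0.2),
  A("NFKB", "XIAP", 0.15), A("NFKB", "BIRC2", 0.15), A("NFKB", "BCL2", 0.15),
  A("NFKB", "CCND1", 0.2),
  A("AKT1", "XIAP", 0.5), A("STAT5", "XIAP", 0.25),
  A("ERK", "CCND1", 0.5), A("RPTOR", "CCND1", 0.3), A("NOTCH2", "CCND1", 0.2),
  # AKT/ERK repression of the intrinsic apoptosis trigger
  I("AKT1", "BIM", 0.5), I("ERK", "BIM", 0.6), I("AKT1", "CASP9", 0.35),
  # p53 / cell-cycle tumor-suppressor arm
  A("CDKN2A", "TP53", 0.4),
  A("TP53", "BAX", 0.5), A("TP53", "NOXA", 0.6),
  I("RB1", "E2F1", 0.75),
  A("E2F1", "CCNE1", 0.6), A("E2F1", "CCNA2", 0.6), A("E2F1", "CCNB1", 0.4),
  # CDK-cyclin complexes (obligate pairs: AND gates)
  A("CDK4", "CDK4_CCND1", 0.95, gate = "AND"), A("CCND1", "CDK4_CCND1", 0.95, gate = "AND"),
  A("CDK2", "CDK2_CCNE1", 0.95, gate = "AND"), A("CCNE1", "CDK2_CCNE1", 0.95, gate = "AND"),
  A("CDK2", "CDK2_CCNA2", 0.95, gate = "AND"), A("CCNA2", "CDK2_CCNA2", 0.95, gate = "AND"),
  A("CDK1", "CDK1_CCNB1", 0.95, gate = "AND"), A("CCNB1", "CDK1_CCNB1", 0.95, gate = "AND"),
  I("CDKN2A", "CDK4_CCND1", 0.5),
  I("CDK4_CCND1", "RB1", 0.5), I("CDK2_CCNE1", "RB1", 0.3),
  # apoptotic cascade and its survival-arm brakes
  A("BIM", "BAX", 0.5), A("CASP8", "BAX", 0.5, half_max = 0.4),
  I("BCL2", "BAX", 0.75, half_max = 0.35), I("BCL2L1", "BAX", 0.5, half_max = 0.35),
  I("MCL1", "BAX", 0.55, half_max = 0.35),
  I("NOXA", "MCL1", 0.45),
  A("BAX", "CASP9", 0.9, half_max = 0.35),
  I("XIAP", "CASP9", 0.5, half_max = 0.4), I("BIRC5", "CASP9", 0.35),
  A("CASP9", "CASP3", 0.85, half_max = 0.4), A("CASP8", "CASP3", 0.55),
  I("XIAP", "CASP3", 0.9, half_max = 0.35, hill = 2),
  A("CASP3", "CASP7", 0.6), I("XIAP", "CASP7", 0.3),
  A("CASP3", "PARPc", 0.85), A("CASP7", "PARPc", 0.3),
  I("BIRC2", "CASP8", 0.97, half_max = 0.3, hill = 2)
)

net <- network_spec(nodes, edges, boundary_ligands = c("IL6", "TNFA", "IFNG"))
write_network(net, file.path(out_dir, "mpn_network.avatarnet"))

# ---- cell-line profiles --------------------------------------------------

hel <- genomic_profile(
  "HEL",
  aberrations = data.frame(
    gene = c("JAK2", "TP53", "CDKN2A", "RB1", "E2F1"),
    kind = c("mutation", "mutation", "deletion", "deletion", "amplification")
  ),
  receptor_expression = c(IL6R = "absent", TNFR = "present", IFNGR = "present")
)
write_profile(hel, file.path(out_dir, "hel_profile.tsv"))

set2 <- genomic_profile(
  "SET2",
  aberrations = data.frame(
    gene = c("JAK2", "RPTOR", "TP53", "CCNA2", "NOTCH2", "EGF", "MAP2K1"),
    kind = "mutation"
  ),
  receptor_expression = c(IL6R = "absent", TNFR = "present", IFNGR = "present")
)
write_profile(set2, file.path(out_dir, "set2_profile.tsv"))

# ---- drug library --------------------------------------------------------

drugs <- list(
  list(id = "G6", selectivity = "JAK2>JAK3>>JAK1>>>TYK2", fold_base = 5,
       hill_h = 1, K_primary = 1),
  list(id = "ABT737", selectivity = "BCL2>BCL2L1", fold_base = 5,
       hill_h = 1, K_primary = 1),
  list(id = "JAKi", selectivity = "JAK2>JAK1>>TYK2", fold_base = 5,
       hill_h = 1, K_primary = 1)
)
yaml::write_yaml(drugs, file.path(out_dir, "drugs.yaml"))

# ---- cytokine conditions -------------------------------------------------

yaml::write_yaml(list(IL6 = list(IL6 = 1.0), TNFA = list(TNFA = 1.0),
                      IFNG = list(IFNG = 1.0)),
                 file.path(out_dir, "cytokine_conditions.yaml"))

# ---- qualitative trend tables (drug at dose C on each avatar) ------------

writeLines(c(
  "condition\tmarker\tdirection",
  "SET2+JAKi\tPARPc\tup",
  "SET2+JAKi\tCASP3\tup",
  "SET2+JAKi\tCASP7\tup",
  "SET2+JAKi\tCASP8\tup",
  "SET2+JAKi\tCASP9\tup",
  "SET2+JAKi\tBIM\tup",
  "SET2+JAKi\tSTAT5\tdown",
  "SET2+JAKi\tMCL1\tdown"
), file.path(out_dir, "trend_set2_jaki.tsv"))

writeLines(c(
  "condition\tmarker\tdirection",
  "HEL+JAKi\tSTAT5\tdown",
  "HEL+JAKi\tAKT1\tdown",
  "HEL+JAKi\tERK\tdown",
  "HEL+JAKi\tPARPc\tup"
), file.path(out_dir, "trend_hel_jaki1.tsv"))

cat("fixtures written to", out_dir, "\n")
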