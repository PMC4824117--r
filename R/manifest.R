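# Feature manifest and shared amino-acid tables.
#
# The 106-feature layout is fixed package-wide: 5 sequence features, 17
# ddg_monomer features, 83 FastRelax features and 1 PROBE surface feature.
# All code addresses features by these names; the order below is canonical.

#' @keywords internal
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# PSIBLAST column order (differs from alphabetical)
PSSM_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# Broad chemical classes used by aminochange()
AA_CLASS <- c(A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
              M = "nonpolar", F = "nonpolar", W = "nonpolar", P = "nonpolar",
              G = "nonpolar",
              S = "polar", T = "polar", C = "polar", Y = "polar",
              N = "polar", Q = "polar",
              K = "positive", R = "positive", H = "positive",
              D = "negative", E = "negative")

# Score terms read from ddg_monomer score tables: 16 components + total.
DDG_TERMS <- c("fa_atr", "fa_rep", "fa_sol", "fa_intra_rep", "fa_elec",
               "pro_close", "hbond_sr_bb", "hbond_lr_bb", "hbond_bb_sc",
               "hbond_sc", "dslf_fa13", "rama", "omega", "fa_dun",
               "p_aa_pp", "ref", "total_score")

# Score terms read from FastRelax score tables: 19 components + total.
RELAX_TERMS <- c("fa_atr", "fa_rep", "fa_sol", "fa_intra_rep", "fa_intra_sol",
                 "fa_elec", "lk_ball_wtd", "pro_close", "hbond_sr_bb",
                 "hbond_lr_bb", "hbond_bb_sc", "hbond_sc", "dslf_fa13",
                 "rama", "omega", "fa_dun", "p_aa_pp", "ref",
                 "yhh_planarity", "total_score")

# Per-term ensemble statistics emitted for FastRelax
RELAX_STATS <- c("mean", "min", "quant", "overlap")

SEQ_FEATURES <- c("pssm_nat", "pssm_mut", "pssm_diff", "info_cont", "aminochange")

DDG_FEATURES <- paste0("ddg_", DDG_TERMS)

RELAX_FEATURES <- c(
  as.vector(t(outer(RELAX_TERMS, RELAX_STATS, function(a, b) paste0("relax_", a, "_", b)))),
  "relax_total_score_sdratio", "relax_total_score_range", "relax_total_score_median"
)

SURFACE_FEATURES <- "probe_sasa"

#' Canonical feature manifest
#'
#' Returns the fixed, ordered names of the 106 features used to characterize
#' one missense variant: 5 sequence features from a PSSM, 17 normalized
#' ddg_monomer score deltas, 83 FastRelax ensemble statistics and 1 PROBE
#' accessible-surface feature.
#'
#' @param block one of `"all"`, `"sequence"`, `"structure"`, `"ddg"`,
#'   `"relax"`, `"surface"`.
#' @return character vector of feature names.
#' @examples
#' length(feature_manifest())          # 106
#' feature_manifest("sequence")
#' @export
feature_manifest <- function(block = c("all", "sequence", "structure",
                                       "ddg", "relax", "surface")) {
  block <- match.arg(block)
  switch(block,
    all       = c(SEQ_FEATURES, DDG_FEATURES, RELAX_FEATURES, SURFACE_FEATURES),
    sequence  = SEQ_FEATURES,
    structure = c(DDG_FEATURES, RELAX_FEATURES, SURFACE_FEATURES),
    ddg       = DDG_FEATURES,
    relax     = RELAX_FEATURES,
    surface   = SURFACE_FEATURES)
}

# ---- physical interpretation categories -------------------------------------

# Each Rosetta score term maps to exactly one physical category; feature names
# are resolved to their underlying term, so the table is total over the
# structure block of the manifest (checked in category_table()).
TERM_CATEGORY <- c(
  hbond_sr_bb = "hydrogen bonding", hbond_lr_bb = "hydrogen bonding",
  hbond_bb_sc = "hydrogen bonding", hbond_sc = "hydrogen bonding",
  fa_rep = "packing", fa_atr = "packing", fa_dun = "packing",
  fa_intra_rep = "packing",
  dslf_fa13 = "disulfide",
  rama = "backbone", omega = "backbone", pro_close = "backbone",
  p_aa_pp = "backbone",
  fa_sol = "solvation", fa_intra_sol = "solvation", lk_ball_wtd = "solvation",
  fa_elec = "electrostatics",
  ref = "global", yhh_planarity = "global", total_score = "global"
)

#' Feature-to-category table for physical interpretation
#'
#' Maps every structure feature in the manifest to one physical category
#' (hydrogen bonding, packing, disulfide, backbone, solvation,
#' electrostatics, surface, global).
#'
#' @return named character vector: names are structure feature names, values
#'   are categories.
#' @export
category_table <- function() {
  feats <- feature_manifest("structure")
  cat <- vapply(feats, function(f) {
    if (f == "probe_sasa") return("surface")
    term <- sub("^(ddg|relax)_", "", f)
    term <- sub("_(mean|min|quant|overlap|sdratio|range|median)$", "", term)
    if (!term %in% names(TERM_CATEGORY))
      stop("feature '", f, "' has no physical category", call. = FALSE)
    TERM_CATEGORY[[term]]
  }, character(1))
  cat
}

is_standard_aa <- function(x) x %in% AA1
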