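# Structure-based features from matched native/variant refinement
# ensembles, expressed relative to the native ensemble's spread so that
# score terms of very different magnitudes become comparable.

new_ensemble_pair <- function(native, variant,
                              protocol = c("ddg_monomer", "fast_relax")) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(native, "score_table"), inherits(variant, "score_table"))
  if (!setequal(names(native$scores), names(variant$scores)))
    stop("native and variant score tables carry different term sets", call. = FALSE)
  if (nrow(native$scores) < 2)
    stop("native ensemble needs at least 2 decoys for normalization", call. = FALSE)
  structure(list(native = native, variant = variant, protocol = protocol),
            class = "ensemble_pair")
}

#' Pair matched native and variant score tables
#'
#' @param native,variant `score_table` objects sharing a term set; the
#'   native side needs at least two decoys (a spread is required for
#'   normalization).
#' @param protocol `"ddg_monomer"` or `"fast_relax"`.
#' @return object of class `ensemble_pair`.
#' @export
ensemble_pair <- function(native, variant, protocol) {
  new_ensemble_pair(native, variant, protocol)
}

# cap applied when the native ensemble has zero spread
NORMALIZE_CAP <- 10

#' Native-ensemble normalization of a score term
#'
#' The workhorse of the structural feature set: a variant's scores for one
#' term are expressed as the shift of their mean from the native ensemble's
#' mean, in units of the native ensemble's sample standard deviation,
#' `(mean(variant) - mean(native)) / sd(native)`.  When the native spread
#' is exactly zero the value is the signed cap (+/-10), or 0 when the means
#' also agree.
#'
#' @param variant_values,native_values numeric vectors of per-decoy scores.
#' @return a single normalized shift.
#' @examples
#' ensemble_normalize(c(6, 8), c(1, 3))  # (7 - 2) / sqrt(2) = 3.5355...
#' @export
ensemble_normalize <- function(variant_values, native_values) {
  if (!length(variant_values) || !length(native_values))
    stop("ensemble_normalize() requires non-empty score vectors", call. = FALSE)
  d <- mean(variant_values) - mean(native_values)
  s <- stats::sd(native_values)
  if (is.na(s) || s == 0) {
    if (d == 0) return(0)
    return(sign(d) * NORMALIZE_CAP)
  }
  d / s
}

# min-shift uses the same sentinel convention
normalized_min_shift <- function(variant_values, native_values) {
  d <- min(variant_values) - min(native_values)
  s <- stats::sd(native_values)
  if (is.na(s) || s == 0) {
    if (d == 0) return(0)
    return(sign(d) * NORMALIZE_CAP)
  }
  d / s
}

best_k_rows <- function(tab, k) {
  if (!"total_score" %in% names(tab$scores))
    stop("manifest error: score table lacks required term 'total_score'",
         call. = FALSE)
  ord <- order(tab$scores$total_score)
  tab$scores[ord[seq_len(min(k, nrow(tab$scores)))], , drop = FALSE]
}

check_manifest_terms <- function(tab, terms) {
  missing <- setdiff(terms, names(tab$scores))
  if (length(missing))
    stop("manifest error: score table lacks required term(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Compute the 17 ddg_monomer features
#'
#' For each term in the fixed 17-term manifest (16 Rosetta components plus
#' `total_score`), the lowest-`total_score` decoys on each side (`best_k`
#' per side, default 3) are compared with [ensemble_normalize()].
#'
#' @param pair an `ensemble_pair` with protocol `"ddg_monomer"`.
#' @param best_k decoys retained per side, ranked by `total_score`.
#' @return named numeric vector of the 17 `ddg_*` features.
#' @export
compute_ddg_features <- function(pair, best_k = 3) {
  stopifnot(inherits(pair, "ensemble_pair"))
  if (pair$protocol != "ddg_monomer")
    stop("compute_ddg_features() expects a ddg_monomer ensemble pair", call. = FALSE)
  check_manifest_terms(pair$native, DDG_TERMS)
  check_manifest_terms(pair$variant, DDG_TERMS)
  nat <- best_k_rows(pair$native, best_k)
  var <- best_k_rows(pair$variant, best_k)
  if (nrow(nat) < 2)
    stop("ensemble-size error: need >= 2 native decoys", call. = FALSE)
  out <- vapply(DDG_TERMS, function(t) ensemble_normalize(var[[t]], nat[[t]]),
                numeric(1))
  stats::setNames(out, DDG_FEATURES)
}

#' Compute the 83 FastRelax features
#'
#' For each term in the fixed 20-term manifest, four ensemble statistics
#' are emitted: the normalized mean shift ([ensemble_normalize()]), the
#' normalized minimum shift `(min_var - min_nat)/sd_nat`, the native-
#' ensemble quantile of the variant mean (fraction of native decoys at or
#' below it) and the overlap fraction (fraction of variant decoys inside
#' the native range).  Three whole-ensemble statistics on `total_score`
#' (sd ratio, range ratio, normalized median shift) complete the 83.
#'
#' @param pair an `ensemble_pair` with protocol `"fast_relax"`.
#' @return named numeric vector of the 83 `relax_*` features.
#' @export
compute_relax_features <- function(pair) {
  stopifnot(inherits(pair, "ensemble_pair"))
  if (pair$protocol != "fast_relax")
    stop("compute_relax_features() expects a fast_relax ensemble pair", call. = FALSE)
  check_manifest_terms(pair$native, RELAX_TERMS)
  check_manifest_terms(pair$variant, RELAX_TERMS)
  nat <- pair$native$scores; var <- pair$variant$scores
  if (nrow(nat) < 2 || nrow(var) < 2)
    stop("ensemble-size error: need >= 2 decoys on each side", call. = FALSE)
  out <- numeric(0)
  for (t in RELAX_TERMS) {
    nv <- nat[[t]]; vv <- var[[t]]
    stats_t <- c(
      mean = ensemble_normalize(vv, nv),
      min = normalized_min_shift(vv, nv),
      quant = mean(nv <= mean(vv)),
      overlap = mean(vv >= min(nv) & vv <= max(nv))
    )
    names(stats_t) <- paste0("relax_", t, "_", RELAX_STATS)
    out <- c(out, stats_t)
  }
  nv <- nat$total_score; vv <- var$total_score
  sd_n <- stats::sd(nv); rng_n <- max(nv) - min(nv)
  out <- c(out,
    relax_total_score_sdratio = ratio_or_cap(stats::sd(vv), sd_n),
    relax_total_score_range = ratio_or_cap(max(vv) - min(vv), rng_n),
    relax_total_score_median = if (sd_n == 0) {
      d <- stats::median(vv) - stats::median(nv)
      if (d == 0) 0 else sign(d) * NORMALIZE_CAP
    } else (stats::median(vv) - stats::median(nv)) / sd_n)
  out[RELAX_FEATURES]
}

ratio_or_cap <- function(num, den) {
  if (den == 0) {
    if (num == 0) return(1)
    return(NORMALIZE_CAP)
  }
  num / den
}

#' Accessible-surface feature at the variant position
#'
#' Looks up the PROBE-reported accessible surface value for the mapped
#' model residue; no recomputation is performed.
#'
#' @param probe_output PROBE text, lines, path, or a data.frame from
#'   [parse_probe()].
#' @param model_residue model residue number.
#' @return the accessible surface value (numeric scalar).
#' @export
surface_area_feature <- function(probe_output, model_residue) {
  tab <- if (is.data.frame(probe_output)) probe_output else parse_probe(probe_output)
  i <- match(as.integer(model_residue), tab$resno)
  if (is.na(i))
    stop("lookup error: residue ", model_residue,
         " absent from PROBE output", call. = FALSE)
  tab$area[i]
}

#' Assemble the 106-feature vector of one variant
#'
#' Concatenates the sequence, ddg_monomer, FastRelax and surface blocks in
#' canonical manifest order.  When no structural model is available
#' (`structure_available = FALSE`) the 101 structure features are `NA`
#' (masked, not imputed); supplying only part of the structure blocks with
#' `structure_available = TRUE` is an error.
#'
#' @param seq named numeric vector of the 5 sequence features.
#' @param ddg,relax,surface structure blocks, or `NULL` when unavailable.
#' @param structure_available logical.
#' @return named numeric vector of length 106 with attribute
#'   `structure_available`.
#' @export
assemble_feature_vector <- function(seq, ddg = NULL, relax = NULL,
                                    surface = NULL,
                                    structure_available = !is.null(ddg)) {
  if (!setequal(names(seq), SEQ_FEATURES))
    stop("sequence block must carry exactly the 5 sequence features", call. = FALSE)
  if (structure_available) {
    if (is.null(ddg) || is.null(relax) || is.null(surface))
      stop("assembly error: structure_available = TRUE but structure blocks are incomplete",
           call. = FALSE)
    if (!setequal(names(ddg), DDG_FEATURES) || !setequal(names(relax), RELAX_FEATURES))
      stop("assembly error: structure blocks do not match the feature manifest",
           call. = FALSE)
    v <- c(seq[SEQ_FEATURES], ddg[DDG_FEATURES], relax[RELAX_FEATURES],
           stats::setNames(as.numeric(surface), SURFACE_FEATURES))
  } else {
    if (!is.null(ddg) || !is.null(relax) || !is.null(surface))
      stop("assembly error: structure blocks supplied but structure_available = FALSE",
           call. = FALSE)
    v <- c(seq[SEQ_FEATURES],
           stats::setNames(rep(NA_real_, 101), feature_manifest("structure")))
  }
  names(v) <- feature_manifest("all")
  attr(v, "structure_available") <- structure_available
  v
}
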