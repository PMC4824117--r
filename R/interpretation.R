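# Automated physical interpretation: roll per-feature contributions up
# into physical categories (packing, hydrogen bonding, disulfide, ...) and
# render a one-line structural hypothesis for each deleterious call.

#' Categorize a prediction's feature contributions
#'
#' Sums the per-feature logit contributions of a prediction into physical
#' categories via the fixed term-to-category table ([category_table()]).
#' Categories whose deleterious-direction (positive-logit) contribution
#' exceeds `threshold` times the total absolute structure contribution are
#' reported, largest first.  Attribution is conserved: the category sums
#' add up to the summed structure contributions exactly.
#'
#' @param contributions named numeric vector of per-feature contribution
#'   terms (weight x standardized value), e.g. one row of the
#'   `"contributions"` attribute from [classify_variants()].
#' @param score the prediction's deleterious probability.
#' @param variant optional one-row variant data.frame carried through.
#' @param threshold reporting cutoff as a fraction of the total absolute
#'   structure contribution (default 0.1).
#' @return object of class `interpretation_report`: list with
#'   `category_scores`, `top_categories`, `score`, `label`, `narrative`.
#' @export
categorize_contributions <- function(contributions, score, variant = NULL,
                                     threshold = 0.1) {
  stopifnot(is.numeric(contributions), !is.null(names(contributions)))
  tab <- category_table()
  struct <- contributions[names(contributions) %in% names(tab)]
  unmapped <- setdiff(names(contributions),
                      c(names(tab), feature_manifest("sequence")))
  if (length(unmapped))
    stop("category-table error: no physical category for feature(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  cats <- tab[names(struct)]
  category_scores <- vapply(split(struct, cats), sum, numeric(1))
  total_abs <- sum(abs(struct))
  deleterious_dir <- category_scores[category_scores > 0]
  top <- deleterious_dir[deleterious_dir > threshold * total_abs]
  top <- sort(top, decreasing = TRUE)
  label <- if (score > 0.5) "deleterious" else "neutral"
  rep <- structure(list(variant = variant, score = score, label = label,
                        category_scores = category_scores,
                        top_categories = top,
                        sequence_only = length(struct) == 0),
                   class = "interpretation_report")
  rep$narrative <- render_narrative(rep)
  rep
}

#' Render the one-line narrative of an interpretation report
#'
#' Deterministic template: for a deleterious call with structural evidence,
#' `"predicted deleterious (<score>); evidence: <categories>"`; a neutral
#' call makes no category claims; a sequence-only prediction cites
#' conservation instead of physical categories.
#'
#' @param report an `interpretation_report`.
#' @return single string.
#' @export
render_narrative <- function(report) {
  stopifnot(inherits(report, "interpretation_report"))
  head_txt <- sprintf("predicted %s (%.3f)", report$label, report$score)
  if (report$label == "neutral")
    return(paste0(head_txt, "; no disruption evidence reported"))
  if (isTRUE(report$sequence_only))
    return(paste0(head_txt, "; sequence conservation evidence only (no structural model)"))
  if (!length(report$top_categories))
    return(paste0(head_txt, "; no single physical category dominates"))
  paste0(head_txt, "; evidence: ",
         paste(names(report$top_categories), collapse = ", "))
}

#' @export
print.interpretation_report <- function(x, ...) {
  cat(x$narrative, "\n")
  invisible(x)
}

#' Interpret every row of a classified variant table
#'
#' @param predictions output of [classify_variants()] (its
#'   `"contributions"` attribute supplies the per-feature terms).
#' @param threshold see [categorize_contributions()].
#' @return list of `interpretation_report`, one per row.
#' @export
interpret_predictions <- function(predictions, threshold = 0.1) {
  contrib <- attr(predictions, "contributions")
  if (is.null(contrib))
    stop("predictions carry no 'contributions' attribute; use classify_variants()",
         call. = FALSE)
  lapply(seq_len(nrow(predictions)), function(i) {
    categorize_contributions(contrib[i, ], predictions$score[i],
                             variant = predictions[i, , drop = FALSE],
                             threshold = threshold)
  })
}
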