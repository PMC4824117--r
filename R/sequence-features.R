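# The five sequence features of a variant, read straight off its PSSM.

#' Broad chemical-change score between two amino acids
#'
#' Encodes how chemically different the substitution is: `0` when both
#' residues fall in the same class, `2` when they carry opposite charges,
#' `1` for any other class change.  Classes: nonpolar (A,V,L,I,M,F,W,P,G),
#' polar uncharged (S,T,C,Y,N,Q), positive (K,R,H), negative (D,E).
#' Symmetric in its arguments.
#'
#' @param native_aa,variant_aa one-letter amino-acid codes.
#' @return integer 0, 1 or 2.
#' @examples
#' aminochange("L", "I")  # 0, both nonpolar
#' aminochange("D", "K")  # 2, charge reversal
#' aminochange("S", "P")  # 1
#' @export
aminochange <- function(native_aa, variant_aa) {
  if (!is_standard_aa(native_aa) || !is_standard_aa(variant_aa))
    stop("aminochange() requires standard one-letter amino acids", call. = FALSE)
  c1 <- AA_CLASS[[native_aa]]; c2 <- AA_CLASS[[variant_aa]]
  if (c1 == c2) return(0L)
  if (all(c(c1, c2) %in% c("positive", "negative"))) return(2L)
  1L
}

#' Compute the five sequence features for a variant
#'
#' Looks up the PSSM log-odds of the native and variant amino acid at the
#' variant position (`pssm_nat`, `pssm_mut`), their difference
#' (`pssm_diff = pssm_nat - pssm_mut`), the position's information content
#' in bits (`info_cont`) and the chemical-change score (`aminochange`).
#' No normalization is applied: these are the raw profile values.
#'
#' @param profile a `seq_profile` from [parse_pssm()] or
#'   [generate_profile()].
#' @param variant one-row data.frame (or list) with `position`, `native`,
#'   `variant`.
#' @return named numeric vector of length 5 in manifest order.
#' @export
compute_sequence_features <- function(profile, variant) {
  stopifnot(inherits(profile, "seq_profile"))
  pos <- as.integer(variant$position)
  n <- nchar(profile$sequence)
  if (is.na(pos) || pos < 1 || pos > n)
    stop(sprintf("position %s outside profile range 1..%d", variant$position, n),
         call. = FALSE)
  nat <- as.character(variant$native); mut <- as.character(variant$variant)
  prof_aa <- substr(profile$sequence, pos, pos)
  if (prof_aa != nat)
    warning(sprintf(
      "profile sequence has %s at position %d but variant declares native %s; using profile values",
      prof_aa, pos, nat), call. = FALSE)
  pssm_nat <- profile$log_odds[pos, nat]
  pssm_mut <- profile$log_odds[pos, mut]
  c(pssm_nat = unname(pssm_nat),
    pssm_mut = unname(pssm_mut),
    pssm_diff = unname(pssm_nat - pssm_mut),
    info_cont = profile$info_content[pos],
    aminochange = as.numeric(aminochange(nat, mut)))
}
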