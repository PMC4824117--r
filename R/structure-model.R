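# PDB model standardization and variant-to-model residue mapping.
#
# Models arriving from the PDB or comparative-modelling servers carry
# duplicate chains, ligands, metals, waters and occasionally non-standard
# residues; all are stripped before structural analysis, and author
# numbering is reconciled with reference (UniProt-style) numbering through
# an ungapped sliding-window alignment.

#' Standardize a PDB model
#'
#' Retains exactly one protein chain (the requested chain, else the
#' alphabetically first protein chain), drops all HETATM records (ligands,
#' metals, waters) and any residue that is not one of the 20 standard amino
#' acids.  When a reference sequence is supplied, an offset map from
#' reference position to model residue number is built by ungapped
#' sliding-window alignment; otherwise model numbering is taken as the
#' reference numbering (identity map).
#'
#' @param pdb path to a PDB file, or PDB-format text.
#' @param chain chain identifier to keep; `NULL` selects the alphabetically
#'   first protein chain.
#' @param reference_sequence optional one-letter reference sequence used to
#'   build the offset map.
#' @param model_id identifier stored on the model.
#' @return object of class `clean_model`: list with `model_id`, `chain`,
#'   `residues` (data.frame `resno`, `aa`), `atoms` (the retained ATOM
#'   records) and `offset_map` (named integer vector, reference position ->
#'   model residue number).
#' @export
standardize_structure <- function(pdb, chain = NULL, reference_sequence = NULL,
                                  model_id = "model") {
  path <- if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    pdb
  } else {
    tf <- tempfile(fileext = ".pdb")
    writeLines(as_lines(pdb), tf)
    tf
  }
  p <- bio3d::read.pdb(path, verbose = FALSE)
  at <- p$atom
  at <- at[at$type == "ATOM" & at$resid %in% names(AA3TO1), , drop = FALSE]
  if (!nrow(at))
    stop("empty model: no standard protein residues remain", call. = FALSE)
  chains <- sort(unique(at$chain))
  if (is.null(chain)) {
    chain <- chains[1]
  } else if (!chain %in% chains) {
    stop("requested chain '", chain, "' not present (available: ",
         paste(chains, collapse = ", "), ")", call. = FALSE)
  }
  at <- at[at$chain == chain, , drop = FALSE]
  # unique residues in order of appearance
  key <- !duplicated(at$resno)
  residues <- data.frame(resno = at$resno[key],
                         aa = unname(AA3TO1[at$resid[key]]),
                         stringsAsFactors = FALSE)
  model_seq <- paste(residues$aa, collapse = "")
  if (is.null(reference_sequence)) {
    offset_map <- stats::setNames(residues$resno, residues$resno)
  } else {
    offset_map <- align_ungapped(reference_sequence, residues)
  }
  structure(list(model_id = model_id, chain = chain, residues = residues,
                 atoms = at, sequence = model_seq, offset_map = offset_map),
            class = "clean_model")
}

# Slide the model residue string along the reference sequence and keep the
# placement with the most identities; ties go to the smallest start.
align_ungapped <- function(reference_sequence, residues) {
  ref <- strsplit(reference_sequence, "")[[1]]
  mod <- residues$aa
  nr <- length(ref); nm <- length(mod)
  if (nm > nr)
    stop("model sequence is longer than the reference sequence", call. = FALSE)
  starts <- seq_len(nr - nm + 1L)
  hits <- vapply(starts, function(s) sum(ref[s:(s + nm - 1L)] == mod), integer(1))
  best <- starts[which.max(hits)]
  if (max(hits) < ceiling(nm / 2))
    warning("best ungapped placement matches fewer than half the model residues",
            call. = FALSE)
  stats::setNames(residues$resno, best:(best + nm - 1L))
}

#' Map a variant onto a standardized model
#'
#' Returns the model residue number when the offset map covers the variant's
#' reference position and the model residue matches the native amino acid.
#' Positions outside model coverage return `NA` (unmapped; downstream code
#' routes such variants to the sequence-only classifier).  A residue-type
#' mismatch at a covered position raises an error: it signals the wrong
#' model or the wrong isoform, not mere missing coverage.
#'
#' @param variant one-row data.frame (or list) with `position` and
#'   `native` (one-letter amino acid).
#' @param model a `clean_model`.
#' @return integer model residue number, or `NA_integer_` when unmapped.
#' @export
map_variant_to_model <- function(variant, model) {
  stopifnot(inherits(model, "clean_model"))
  pos <- as.integer(variant$position)
  key <- as.character(pos)
  if (!key %in% names(model$offset_map)) return(NA_integer_)
  resno <- model$offset_map[[key]]
  aa <- model$residues$aa[match(resno, model$residues$resno)]
  if (!identical(aa, as.character(variant$native)))
    stop(sprintf(
      "residue mismatch at reference position %d: model %s has %s, variant expects %s (wrong model or isoform?)",
      pos, model$model_id, aa, variant$native), call. = FALSE)
  resno
}

#' @export
print.clean_model <- function(x, ...) {
  cat(sprintf("clean model '%s': chain %s, %d residues (%d..%d)\n",
              x$model_id, x$chain, nrow(x$residues),
              min(x$residues$resno), max(x$residues$resno)))
  invisible(x)
}
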