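# Readers and writers for the external formats the pipeline touches:
# tab-separated variant tables, PSIBLAST ASCII PSSMs, Rosetta whitespace
# score files, PROBE per-residue accessibility tables and the predictions
# TSV.  All parsers are strict: malformed rows fail with the offending
# line identified rather than being silently dropped.

# ---- variant tables ---------------------------------------------------------

validate_variant <- function(protein, position, native, variant, label) {
  if (is.na(position) || position < 1 || position != as.integer(position))
    return("position must be a positive integer")
  if (!is_standard_aa(native))
    return(sprintf("native amino acid '%s' is not one of the 20 standard residues", native))
  if (!is_standard_aa(variant))
    return(sprintf("variant amino acid '%s' is not one of the 20 standard residues", variant))
  if (native == variant)
    return("native equals variant (identity substitutions are disallowed)")
  if (!label %in% c("deleterious", "neutral", "unknown"))
    return(sprintf("label '%s' is not deleterious/neutral/unknown", label))
  NULL
}

#' Read a tab-separated variant table
#'
#' Expects a header with columns `protein`, `position`, `native`, `variant`
#' and optionally `label` (`deleterious`/`neutral`; anything absent defaults
#' to `unknown`).  Rows that violate the variant contract (identity
#' substitution, non-standard residue, non-positive position) are rejected
#' and reported by row number in a warning; valid rows are returned.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns `protein`, `position`, `native`,
#'   `variant`, `label`; attribute `"rejected"` holds the rejected row
#'   numbers (of the data portion, 1-based) with reasons.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "",
                          quote = "", check.names = TRUE, fill = TRUE)
  need <- c("protein", "position", "native", "variant")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"label" %in% names(df)) df$label <- rep("unknown", nrow(df))
  df$label[is.na(df$label) | df$label == ""] <- "unknown"
  df$position <- suppressWarnings(as.numeric(df$position))

  reasons <- character(0)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    msg <- validate_variant(df$protein[i], df$position[i],
                            df$native[i], df$variant[i], df$label[i])
    keep[i] <- is.null(msg)
    if (!is.null(msg)) reasons <- c(reasons, sprintf("row %d: %s", i, msg))
  }
  if (length(reasons))
    warning("rejected ", length(reasons), " variant row(s):\n  ",
            paste(reasons, collapse = "\n  "), call. = FALSE)
  out <- df[keep, c("protein", "position", "native", "variant", "label"),
            drop = FALSE]
  out$position <- as.integer(out$position)
  rownames(out) <- NULL
  attr(out, "rejected") <- reasons
  out
}

#' Write a variant table
#' @param variants data.frame with columns `protein`, `position`, `native`,
#'   `variant` and optionally `label`.
#' @param path output path.
#' @export
write_variant_table <- function(variants, path) {
  cols <- intersect(c("protein", "position", "native", "variant", "label"),
                    names(variants))
  utils::write.table(variants[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- PSIBLAST ASCII PSSM ----------------------------------------------------

#' Parse a PSIBLAST ASCII PSSM
#'
#' Consumes the `-out_ascii_pssm` layout: header lines, then one row per
#' position carrying the residue index, the native residue, 20 integer
#' log-odds columns, 20 percentage columns, the per-position information
#' content (bits) and the relative weight.  Rows must carry exactly 42
#' numeric fields after the index and residue tokens.
#'
#' @param text PSSM file content as a single string or character vector of
#'   lines; a path to an existing file is also accepted.
#' @param protein_id identifier stored on the profile (default `""`).
#' @return object of class `seq_profile`: list with `protein_id`,
#'   `sequence`, `log_odds` (positions x 20 matrix, PSIBLAST column order)
#'   and `info_content` (bits, one value per position).
#' @export
parse_pssm <- function(text, protein_id = "") {
  lines <- as_lines(text)
  rows <- list(); aa <- character(0); info <- numeric(0); idx <- integer(0)
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 2 || is.na(suppressWarnings(as.integer(tok[1]))))
      next
    if (!tok[2] %in% AA1) next
    num <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (length(num) != 42 || anyNA(num))
      stop("PSSM dialect error: position row '", substr(trimws(ln), 1, 40),
           "...' does not carry 42 numeric fields", call. = FALSE)
    idx <- c(idx, as.integer(tok[1]))
    aa <- c(aa, tok[2])
    rows[[length(rows) + 1L]] <- num[1:20]
    info <- c(info, num[41])
  }
  if (!length(rows))
    stop("PSSM format error: no position rows found", call. = FALSE)
  if (!identical(idx, seq_along(idx)))
    stop("PSSM format error: position indices are not consecutive from 1",
         call. = FALSE)
  log_odds <- do.call(rbind, rows)
  colnames(log_odds) <- PSSM_AA_ORDER
  rownames(log_odds) <- NULL
  structure(list(protein_id = protein_id,
                 sequence = paste(aa, collapse = ""),
                 log_odds = log_odds,
                 info_content = info),
            class = "seq_profile")
}

#' Serialize a sequence profile to the PSIBLAST ASCII dialect
#'
#' The percentage block is reconstructed from the log-odds (it is not used
#' by any downstream feature), the log-odds and information-content values
#' are written verbatim so that `parse_pssm()` round-trips exactly.
#'
#' @param profile a `seq_profile`.
#' @param path output path; if `NULL`, the text is returned invisibly.
#' @export
write_pssm <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "seq_profile"))
  n <- nchar(profile$sequence)
  aa <- strsplit(profile$sequence, "")[[1]]
  hdr <- c("",
           "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
           paste0("           ", paste(sprintf("%3s", PSSM_AA_ORDER), collapse = " "),
                  "  ", paste(sprintf("%3s", PSSM_AA_ORDER), collapse = " ")))
  body <- vapply(seq_len(n), function(i) {
    lo <- profile$log_odds[i, ]
    pct <- pmax(0L, as.integer(round(lo)) * 2L + 10L)  # placeholder percentages
    paste0(sprintf("%5d %s ", i, aa[i]),
           paste(sprintf("%3s", num_str(lo)), collapse = " "), "  ",
           paste(sprintf("%3d", pct), collapse = " "), "  ",
           num_str(profile$info_content[i]), " ", "0.00")
  }, character(1))
  txt <- c(hdr, body, "")
  if (is.null(path)) return(invisible(paste(txt, collapse = "\n")))
  writeLines(txt, path)
  invisible(path)
}

# full-precision numeric rendering so parse(write(x)) == x bit for bit
num_str <- function(x) {
  out <- sprintf("%.17g", x)
  whole <- x == round(x) & abs(x) < 1e15
  out[whole] <- sprintf("%d", as.integer(x[whole]))
  out
}

as_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  if (length(text) == 1) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  text
}

# ---- Rosetta score files ----------------------------------------------------

#' Parse a Rosetta whitespace score file
#'
#' Accepts both the `SCORE:`-prefixed dialect and bare whitespace tables.
#' The first (non-`SEQUENCE:`) line is the header naming the score terms;
#' every following line is one decoy.  A trailing `description` column, if
#' present, is stored as the per-decoy tag.
#'
#' @param text file content (string, lines, or a path).
#' @param protocol `"ddg_monomer"` or `"fast_relax"`.
#' @return object of class `score_table`: list with `protocol`, `scores`
#'   (data.frame, one row per decoy, one column per score term) and
#'   `description` (character, per decoy).
#' @export
parse_rosetta_scorefile <- function(text, protocol = c("ddg_monomer", "fast_relax")) {
  protocol <- match.arg(protocol)
  lines <- as_lines(text)
  lines <- lines[!grepl("^SEQUENCE:", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty score file", call. = FALSE)
  toks <- lapply(lines, function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) && tok[1] == "SCORE:") tok <- tok[-1]
    tok
  })
  header <- toks[[1]]
  has_desc <- tolower(header[length(header)]) == "description"
  terms <- if (has_desc) header[-length(header)] else header
  if (!length(terms)) stop("score file header names no score terms", call. = FALSE)
  body <- toks[-1]
  if (!length(body))
    stop("empty score table: header present but no decoy lines", call. = FALSE)
  nfield <- length(terms) + has_desc
  desc <- character(length(body))
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(terms))
  for (i in seq_along(body)) {
    tok <- body[[i]]
    if (length(tok) != nfield)
      stop(sprintf("score file format error: decoy line %d has %d fields, expected %d",
                   i, length(tok), nfield), call. = FALSE)
    num <- suppressWarnings(as.numeric(tok[seq_along(terms)]))
    if (anyNA(num))
      stop(sprintf("score file format error: non-numeric cell in decoy line %d", i),
           call. = FALSE)
    vals[i, ] <- num
    desc[i] <- if (has_desc) tok[nfield] else sprintf("decoy_%04d", i)
  }
  scores <- as.data.frame(vals)
  names(scores) <- terms
  structure(list(protocol = protocol, scores = scores, description = desc),
            class = "score_table")
}

#' Write a score table in the `SCORE:` dialect
#' @param table a `score_table`.
#' @param path output path; if `NULL`, text is returned invisibly.
#' @export
write_scorefile <- function(table, path = NULL) {
  stopifnot(inherits(table, "score_table"))
  hdr <- paste("SCORE:", paste(names(table$scores), collapse = " "), "description")
  body <- vapply(seq_len(nrow(table$scores)), function(i) {
    paste("SCORE:", paste(num_str(as.numeric(table$scores[i, ])), collapse = " "),
          table$description[i])
  }, character(1))
  txt <- c(hdr, body)
  if (is.null(path)) return(invisible(paste(txt, collapse = "\n")))
  writeLines(txt, path)
  invisible(path)
}

# ---- PROBE per-residue accessibility ----------------------------------------

#' Parse a PROBE per-residue accessibility table
#'
#' Accepts a whitespace table with one record per residue: the residue
#' number and its accessible area, with an optional residue-name column in
#' between (`"42 SER 55.2"` or `"42 55.2"`).  Header lines and `#` comments
#' are skipped.
#'
#' @param text file content (string, lines, or a path).
#' @return data.frame with columns `resno` (integer) and `area` (numeric).
#' @export
parse_probe <- function(text) {
  lines <- as_lines(text)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  recs <- list()
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    resno <- suppressWarnings(as.integer(tok[1]))
    if (is.na(resno)) next   # header line
    area <- suppressWarnings(as.numeric(tok[length(tok)]))
    if (is.na(area))
      stop("PROBE format error: no numeric area on line '", ln, "'", call. = FALSE)
    recs[[length(recs) + 1L]] <- c(resno, area)
  }
  if (!length(recs)) stop("PROBE output contains no residue records", call. = FALSE)
  m <- do.call(rbind, recs)
  data.frame(resno = as.integer(m[, 1]), area = m[, 2])
}

# ---- predictions ------------------------------------------------------------

#' Write predictions to a TSV
#'
#' Columns: `protein`, `position`, `native`, `variant`, `score` (3
#' decimals), `label`, `top_structural_terms`, `interpretation`.
#'
#' @param predictions data.frame carrying at least those columns (missing
#'   annotation columns are filled with `""`).
#' @param path output path.
#' @export
write_predictions <- function(predictions, path) {
  cols <- c("protein", "position", "native", "variant", "score", "label",
            "top_structural_terms", "interpretation")
  df <- as.data.frame(predictions)
  for (cc in setdiff(cols, names(df))) df[[cc]] <- rep("", nrow(df))
  df <- df[, cols, drop = FALSE]
  df$score <- sprintf("%.3f", as.numeric(df$score))
  if (!nrow(df)) df$score <- character(0)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a predictions TSV written by [write_predictions()]
#' @param path path to the predictions file.
#' @return data.frame with the eight prediction columns; `score` numeric.
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "", comment.char = "")
  df$position <- as.integer(df$position)
  df$score <- as.numeric(df$score)
  df
}

#' @export
print.seq_profile <- function(x, ...) {
  cat(sprintf("sequence profile '%s': %d positions, mean information %.2f bits\n",
              x$protein_id, nchar(x$sequence), mean(x$info_content)))
  invisible(x)
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("%s score table: %d decoys x %d terms\n",
              x$protocol, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}
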