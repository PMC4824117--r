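# Shared fixtures, all generated in code.

random_sequence <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

# a tiny hand-written 3-position PSSM in the PSIBLAST ASCII dialect
HAND_PSSM <- paste(c(
  "",
  "Last position-specific scoring matrix computed",
  paste("          ", paste(c("A","R","N","D","C","Q","E","G","H","I","L","K",
                              "M","F","P","S","T","W","Y","V"), collapse = "  "),
        paste(c("A","R","N","D","C","Q","E","G","H","I","L","K",
                "M","F","P","S","T","W","Y","V"), collapse = "  ")),
  paste("    1 M ", paste(c(-1, -2, -3, -4, -1, 0, -2, -3, -2, 1,
                            2, -1, 6, 0, -3, -1, -1, -2, -1, 1), collapse = " "),
        paste(rep(5, 20), collapse = " "), "2.1 0.30"),
  paste("    2 S ", paste(c(1, -1, 1, 0, -1, 0, 0, 0, -1, -2,
                            -2, 0, -1, -2, -1, 4, 1, -3, -2, -2), collapse = " "),
        paste(rep(5, 20), collapse = " "), "0.55 0.20"),
  paste("    3 K ", paste(c(-1, 2, 0, -1, -3, 1, 1, -2, -1, -3,
                            -2, 5, -1, -3, -1, 0, -1, -3, -2, -2), collapse = " "),
        paste(rep(5, 20), collapse = " "), "0.80 0.25")),
  collapse = "\n")

# matched score tables built by hand
make_score_table <- function(df, protocol = "fast_relax",
                             desc = sprintf("decoy_%04d", seq_len(nrow(df)))) {
  structure(list(protocol = protocol, scores = df, description = desc),
            class = "score_table")
}

write_variant_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("protein\tposition\tnative\tvariant\tlabel", rows), path)
  path
}
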