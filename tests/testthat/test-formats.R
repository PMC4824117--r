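# Parsers and writers for the external formats.

test_that("variant tables parse, default labels, and reject bad rows by number", {
  path <- write_variant_file(c("IL6\t204\tS\tP", "GCK\t168\tT\tP\tdeleterious"))
  v <- read_variant_table(path)
  expect_equal(nrow(v), 2)
  expect_equal(v$protein[1], "IL6")
  expect_equal(v$position[1], 204L)
  expect_equal(v$label[1], "unknown")
  expect_equal(v$label[2], "deleterious")

  # identity substitution and a non-standard residue are rejected with row numbers
  path2 <- write_variant_file(c("A\t1\tS\tP", "GCK\t168\tT\tT",
                                "B\t2\tL\tI", "C\t3\tX\tA"))
  expect_warning(v2 <- read_variant_table(path2), "row 2.*identity")
  expect_equal(nrow(v2), 2)
  expect_length(attr(v2, "rejected"), 2)
  expect_match(attr(v2, "rejected")[2], "row 4")
})

test_that("a missing required column is a format error", {
  path <- tempfile()
  writeLines(c("protein\tposition\tnative", "A\t1\tS"), path)
  expect_error(read_variant_table(path), "missing required column")
})

test_that("hand-written PSSM parses with verbatim values", {
  prof <- parse_pssm(HAND_PSSM, protein_id = "toy")
  expect_equal(prof$sequence, "MSK")
  expect_equal(prof$info_content[1], 2.1)
  expect_equal(unname(prof$log_odds[1, "M"]), 6)
  expect_equal(unname(prof$log_odds[3, "K"]), 5)
  expect_equal(unname(prof$log_odds[2, "S"]), 4)
})

test_that("PSSM with no position rows or malformed rows errors", {
  expect_error(parse_pssm("header only\nno rows here"), "no position rows")
  bad <- sub("2.1 0.30", "2.1", HAND_PSSM, fixed = TRUE)
  expect_error(parse_pssm(bad), "42 numeric fields")
})

test_that("PSSM round-trips through the ASCII dialect bit-for-bit", {
  prof <- generate_profile(random_sequence(40, seed = 3),
                           conserved_positions = c(5, 17), seed = 11,
                           protein_id = "rt")
  txt <- write_pssm(prof)
  back <- parse_pssm(txt, protein_id = "rt")
  expect_identical(back$sequence, prof$sequence)
  expect_identical(back$info_content, prof$info_content)
  expect_equal(back$log_odds, prof$log_odds, ignore_attr = FALSE)
})

test_that("score files parse in both dialects and preserve term order", {
  bare <- "total_score fa_rep hbond_sc\n-100 5 -2\n-101.5 4.5 -2.5"
  st <- parse_rosetta_scorefile(bare, "fast_relax")
  expect_equal(nrow(st$scores), 2)
  expect_equal(names(st$scores), c("total_score", "fa_rep", "hbond_sc"))

  prefixed <- paste("SCORE: total_score fa_rep description",
                    "SCORE: -100 5 d1", "SCORE: -99 6 d2", sep = "\n")
  st2 <- parse_rosetta_scorefile(prefixed, "fast_relax")
  expect_equal(st2$description, c("d1", "d2"))
  expect_equal(st2$scores$fa_rep, c(5, 6))

  zeros <- parse_rosetta_scorefile("a b c\n0 0 0", "ddg_monomer")
  expect_equal(as.numeric(zeros$scores[1, ]), c(0, 0, 0))
})

test_that("score file contract errors: wrong field count, zero decoys, non-numeric", {
  expect_error(parse_rosetta_scorefile("a b\n1 2 3", "fast_relax"), "fields")
  expect_error(parse_rosetta_scorefile("a b c", "fast_relax"), "no decoy lines")
  expect_error(parse_rosetta_scorefile("a b\n1 x", "fast_relax"), "non-numeric")
})

test_that("a generated 50-decoy ensemble round-trips through the scorefile dialect", {
  pair <- generate_score_ensembles(n_decoys = 50, seed = 5)
  expect_equal(nrow(pair$native$scores), 50)
  txt <- write_scorefile(pair$native)
  back <- parse_rosetta_scorefile(txt, "fast_relax")
  expect_identical(back$scores, pair$native$scores)
  expect_identical(back$description, pair$native$description)
})

test_that("PROBE tables parse and error without records", {
  tab <- parse_probe("# comment\nresidue area\n42 SER 55.2\n43 0.0")
  expect_equal(tab$area[tab$resno == 42], 55.2)
  expect_equal(tab$area[tab$resno == 43], 0)
  expect_error(parse_probe("# nothing\n"), "no residue records")
})

test_that("predictions print scores with 3 decimals and round-trip", {
  df <- data.frame(protein = "IL6", position = 204L, native = "S",
                   variant = "P", score = 0.835, label = "deleterious",
                   top_structural_terms = "relax_dslf_fa13_mean",
                   interpretation = "predicted deleterious (0.835); evidence: disulfide")
  path <- tempfile(fileext = ".tsv")
  write_predictions(df, path)
  expect_match(paste(readLines(path), collapse = "\n"), "0.835")

  set.seed(9)
  many <- data.frame(protein = sprintf("P%02d", 1:10), position = 1:10,
                     native = "A", variant = "V",
                     score = round(runif(10), 3),
                     label = sample(c("deleterious", "neutral"), 10, TRUE),
                     top_structural_terms = "t", interpretation = "i")
  write_predictions(many, path)
  back <- read_predictions(path)
  expect_equal(back$score, many$score)
  expect_equal(back$protein, many$protein)
  expect_equal(back$label, many$label)

  # empty prediction set -> header-only file
  write_predictions(many[0, ], path)
  expect_equal(length(readLines(path)), 1)
})

test_that("structure standardization strips duplicate chains and heteroatoms", {
  seq <- "MSTKLLAVGH"
  pdb <- generate_stub_pdb(seq, chain = "A", duplicate_chain = "B",
                           n_waters = 3, add_zn = TRUE)
  model <- standardize_structure(pdb)
  expect_equal(model$chain, "A")
  expect_equal(nrow(model$residues), nchar(seq))
  expect_equal(model$sequence, seq)
  expect_false(any(model$atoms$resid %in% c("ZN", "HOH")))

  # idempotence: a second pass changes nothing
  pdb_clean <- generate_stub_pdb(seq, chain = "A")
  m1 <- standardize_structure(pdb_clean)
  expect_equal(m1$residues, model$residues)
})

test_that("chain selection and error contracts", {
  pdb <- generate_stub_pdb("MSTKL", chain = "A", duplicate_chain = "C")
  expect_equal(standardize_structure(pdb, chain = "C")$chain, "C")
  expect_error(standardize_structure(pdb, chain = "Z"), "chain 'Z' not present")
  # MSE residues are dropped, not translated
  pdb_mse <- generate_stub_pdb("MSTKL", mse_positions = 2)
  m <- standardize_structure(pdb_mse)
  expect_equal(m$sequence, "MTKL")
})

test_that("offset map from sliding-window alignment reconciles numbering", {
  ref <- random_sequence(100, seed = 21)
  modeled <- substr(ref, 1, 100)
  pdb <- generate_stub_pdb(modeled, start_resno = 5)
  model <- standardize_structure(pdb, reference_sequence = ref)
  expect_equal(unname(model$offset_map[["1"]]), 5)
  expect_equal(unname(model$offset_map[["100"]]), 104)

  # model covering an internal window
  window <- substr(ref, 41, 80)
  pdb2 <- generate_stub_pdb(window, start_resno = 1)
  model2 <- standardize_structure(pdb2, reference_sequence = ref)
  expect_equal(unname(model2$offset_map[[as.character(41)]]), 1)
})

test_that("variant mapping: offset arithmetic, unmapped, and mismatch", {
  ref <- random_sequence(60, seed = 33)
  pdb <- generate_stub_pdb(ref, start_resno = 5)
  model <- standardize_structure(pdb, reference_sequence = ref)
  nat10 <- substr(ref, 10, 10)
  v <- data.frame(protein = "X", position = 10L, native = nat10,
                  variant = setdiff(c("A", "V"), nat10)[1])
  expect_equal(map_variant_to_model(v, model), 14)

  v_out <- data.frame(position = 300L, native = "A", variant = "V")
  expect_true(is.na(map_variant_to_model(v_out, model)))

  wrong <- setdiff(c("A", "S"), nat10)[1]
  v_bad <- data.frame(position = 10L, native = wrong, variant = "W")
  expect_error(map_variant_to_model(v_bad, model), "mismatch")

  # the mapped residue always matches the declared native amino acid
  for (p in c(1, 17, 42, 60)) {
    vv <- data.frame(position = p, native = substr(ref, p, p), variant = "G")
    if (vv$native == "G") vv$variant <- "A"
    r <- map_variant_to_model(vv, model)
    expect_equal(model$residues$aa[match(r, model$residues$resno)], vv$native)
  }
})
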