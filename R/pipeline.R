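# End-to-end orchestration: feature generation -> classification ->
# interpretation -> report, plus the training protocol.  Configuration is
# a plain named list, optionally read from a flat key=value file so runs
# are reproducible from a single text artifact.

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines are
#' skipped; numeric-looking values are converted.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2)
      stop("config line is not key=value: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

provenance_lines <- function(config, seed) {
  keys <- sort(names(config))
  c("# provenance",
    sprintf("#   delvar %s", as.character(utils::packageVersion("delvar"))),
    sprintf("#   seed=%s", seed),
    sprintf("#   %s=%s", keys,
            vapply(config[keys], function(v) paste(format(v), collapse = ","),
                   character(1))))
}

#' Score, route and report a variant table end to end
#'
#' For every input variant: sequence features come from its PSSM
#' (`<pssm_dir>/<protein>.pssm`).  When a model PDB
#' (`<pdb_dir>/<protein>.pdb`), the four score files
#' (`<score_dir>/<protein>_<native><position><variant>_{ddg,relax}_{nat,var}.sc`)
#' and a PROBE table (`<probe_dir>/<protein>.probe`) are all present and
#' the variant maps onto the model, the 101 structure features are
#' computed and the combined model scores the variant; otherwise the
#' variant is routed to the sequence-only model and flagged.  Every input
#' variant appears exactly once in the output.
#'
#' @param config named list (or path to a key=value file) with entries:
#'   `variants` (TSV path), `pssm_dir`, `model` (combined model file from
#'   [write_delvar()]), `seq_model` (sequence-only model file), optional
#'   `pdb_dir`, `score_dir`, `probe_dir`, `out` (predictions TSV path),
#'   optional `seed` (recorded in provenance), `verbose`.
#' @return invisibly, a list with `predictions` (data.frame including a
#'   `route` column) and `reports` (per-variant interpretation reports).
#' @export
run_predict <- function(config) {
  if (is.character(config)) config <- read_config(config)
  for (k in c("variants", "pssm_dir", "model", "seq_model"))
    if (is.null(config[[k]]))
      stop("config is missing required entry '", k, "'", call. = FALSE)
  verbose <- isTRUE(config$verbose) || identical(config$verbose, 1)
  variants <- read_variant_table(config$variants)
  combined <- read_delvar(config$model)
  seqmod <- read_delvar(config$seq_model)

  rows <- vector("list", nrow(variants))
  reports <- vector("list", nrow(variants))
  failures <- character(0)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    tag <- sprintf("%s %s%d%s", v$protein, v$native, v$position, v$variant)
    pssm_path <- file.path(config$pssm_dir, paste0(v$protein, ".pssm"))
    if (!file.exists(pssm_path)) {
      failures <- c(failures, sprintf("%s: no PSSM at %s", tag, pssm_path))
      next
    }
    profile <- parse_pssm(pssm_path, protein_id = v$protein)
    seqf <- compute_sequence_features(profile, v)

    fv <- NULL
    route <- "sequence_only"
    structure_paths <- variant_structure_paths(config, v)
    if (!is.null(structure_paths)) {
      mapped <- tryCatch({
        model <- standardize_structure(structure_paths$pdb,
                                       reference_sequence = profile$sequence,
                                       model_id = v$protein)
        map_variant_to_model(v, model)
      }, error = function(e) {
        failures <<- c(failures, sprintf("%s: %s", tag, conditionMessage(e)))
        NULL
      })
      if (is.null(mapped)) next   # mismatch error: fatal per variant
      if (!is.na(mapped)) {
        ddg <- compute_ddg_features(ensemble_pair(
          parse_rosetta_scorefile(structure_paths$ddg_nat, "ddg_monomer"),
          parse_rosetta_scorefile(structure_paths$ddg_var, "ddg_monomer"),
          "ddg_monomer"))
        relax <- compute_relax_features(ensemble_pair(
          parse_rosetta_scorefile(structure_paths$relax_nat, "fast_relax"),
          parse_rosetta_scorefile(structure_paths$relax_var, "fast_relax"),
          "fast_relax"))
        sasa <- surface_area_feature(parse_probe(structure_paths$probe), mapped)
        fv <- assemble_feature_vector(seqf, ddg, relax, sasa,
                                      structure_available = TRUE)
        route <- "combined"
      }
    }
    if (is.null(fv)) fv <- assemble_feature_vector(seqf, structure_available = FALSE)

    model_used <- if (route == "combined") combined else seqmod
    pred <- classify_variants(model_used, as.data.frame(t(fv)))
    contrib <- attr(pred, "contributions")[1, ]
    rep <- categorize_contributions(contrib, pred$score[1], variant = v)
    if (route == "sequence_only") rep$sequence_only <- TRUE
    rep$narrative <- render_narrative(rep)
    top_terms <- names(sort(contrib[contrib > 0 &
                                      names(contrib) %in% feature_manifest("structure")],
                            decreasing = TRUE))
    rows[[i]] <- data.frame(v, score = pred$score[1], label = pred$label[1],
                            route = route,
                            top_structural_terms = paste(utils::head(top_terms, 3),
                                                         collapse = ","),
                            interpretation = rep$narrative,
                            stringsAsFactors = FALSE)
    reports[[i]] <- rep
    if (verbose)
      message(sprintf("%s -> %s (%.3f) via %s", tag, pred$label[1],
                      pred$score[1], route))
  }
  done <- !vapply(rows, is.null, logical(1))
  if (any(!done) && length(failures))
    warning("per-variant failures (", sum(!done), "):\n  ",
            paste(failures, collapse = "\n  "), call. = FALSE)
  predictions <- do.call(rbind, rows[done])
  if (is.null(predictions))
    predictions <- data.frame(protein = character(0), position = integer(0),
                              native = character(0), variant = character(0),
                              label = character(0), score = numeric(0),
                              route = character(0),
                              top_structural_terms = character(0),
                              interpretation = character(0))
  if (!is.null(config$out)) {
    write_predictions(predictions, config$out)
    prov <- provenance_lines(config, config$seed %||% NA)
    cat(prov, sep = "\n", file = paste0(config$out, ".prov"))
  }
  invisible(list(predictions = predictions, reports = reports[done],
                 failures = failures))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

variant_structure_paths <- function(config, v) {
  if (is.null(config$pdb_dir) || is.null(config$score_dir)) return(NULL)
  stem <- sprintf("%s_%s%d%s", v$protein, v$native, v$position, v$variant)
  p <- list(
    pdb = file.path(config$pdb_dir, paste0(v$protein, ".pdb")),
    ddg_nat = file.path(config$score_dir, paste0(stem, "_ddg_nat.sc")),
    ddg_var = file.path(config$score_dir, paste0(stem, "_ddg_var.sc")),
    relax_nat = file.path(config$score_dir, paste0(stem, "_relax_nat.sc")),
    relax_var = file.path(config$score_dir, paste0(stem, "_relax_var.sc")),
    probe = file.path(config$probe_dir %||% config$score_dir,
                      paste0(v$protein, ".probe")))
  if (!all(vapply(p, file.exists, logical(1)))) return(NULL)
  p
}

#' Train, evaluate and serialize a classifier
#'
#' Runs the full training protocol on a labeled feature table: stability
#' selection (in combined/structure mode), a final fit on all data, and a
#' protein-level split evaluation (train on each split's training
#' proteins, score its held-out proteins, average the ROC/PR curves).
#'
#' @param config named list (or key=value file path) with entries: `data`
#'   (labeled feature TSV path, or a data.frame), optional `mode`
#'   (default `"combined"`), `n_splits` (default 100), `train_frac`
#'   (default 0.8), `seed` (default 1), `out_model`, `out_eval`
#'   (output paths; omit to skip writing).
#' @return invisibly, list with `model` (the full-data `delvar` fit),
#'   `curves` (averaged `eval_curves`, `NULL` when `n_splits` is 0) and
#'   `split_curves`.
#' @export
run_train <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$data)) stop("config is missing 'data'", call. = FALSE)
  data <- if (is.data.frame(config$data)) config$data else
    utils::read.table(config$data, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  if (!"label" %in% names(data))
    stop("validation error: training data has no 'label' column", call. = FALSE)
  mode <- config$mode %||% "combined"
  seed <- as.integer(config$seed %||% 1)
  n_splits <- as.integer(config$n_splits %||% 100)
  train_frac <- config$train_frac %||% 0.8

  model <- delvar(data, mode = mode, seed = seed)
  curves <- NULL; split_curves <- list()
  if (n_splits > 0) {
    splits <- protein_level_splits(data$protein, n_splits = n_splits,
                                   train_frac = train_frac, seed = seed)
    split_curves <- lapply(splits, function(sp) {
      fit <- delvar(data[sp$train, , drop = FALSE], features = model$features,
                    mode = mode)
      test <- data[sp$test, , drop = FALSE]
      test <- test[stats::complete.cases(test[, model$features, drop = FALSE]), ,
                   drop = FALSE]
      roc_pr(predict(fit, test), test$label)
    })
    curves <- if (n_splits > 1) average_curves(split_curves) else split_curves[[1]]
  }
  if (!is.null(config$out_model)) write_delvar(model, config$out_model)
  if (!is.null(config$out_eval) && !is.null(curves)) {
    prov <- provenance_lines(config[setdiff(names(config), "data")], seed)
    con <- file(config$out_eval, "w")
    writeLines(prov, con)
    writeLines(sprintf("auroc\t%s", num_str(curves$auroc)), con)
    writeLines(sprintf("aupr\t%s", num_str(curves$aupr)), con)
    close(con)
  }
  invisible(list(model = model, curves = curves, split_curves = split_curves))
}
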