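# Seeded generators for every input the pipeline consumes: sequence
# profiles (serializable to the PSIBLAST ASCII dialect), matched
# native/variant score ensembles, stub PDB models, PROBE tables and
# labeled feature datasets with planted class signal.  All generators are
# pure functions of their seed.

#' Generate a synthetic sequence profile
#'
#' Conserved positions receive a high native log-odds (integers 7..10) with
#' strongly negative alternatives and high information content (2.5..4
#' bits); all other positions get near-zero integer log-odds and low
#' information content.  The result serializes exactly through
#' [write_pssm()] / [parse_pssm()].
#'
#' @param sequence one-letter amino-acid string.
#' @param conserved_positions integer positions treated as conserved.
#' @param seed integer seed.
#' @param protein_id identifier stored on the profile.
#' @return a `seq_profile`.
#' @export
generate_profile <- function(sequence, conserved_positions = integer(0),
                             seed = 1, protein_id = "synthetic") {
  n <- nchar(sequence)
  if (n < 1) stop("sequence must be non-empty", call. = FALSE)
  aa <- strsplit(sequence, "")[[1]]
  if (!all(is_standard_aa(aa)))
    stop("sequence contains non-standard amino acids", call. = FALSE)
  if (length(conserved_positions) &&
      (min(conserved_positions) < 1 || max(conserved_positions) > n))
    stop("conserved position out of range 1..", n, call. = FALSE)
  set.seed(seed)
  log_odds <- matrix(as.numeric(sample(-2:2, n * 20, replace = TRUE)), nrow = n,
                     dimnames = list(NULL, PSSM_AA_ORDER))
  info <- round(stats::runif(n, 0.2, 0.8), 2)
  for (p in conserved_positions) {
    log_odds[p, ] <- sample(-6:-3, 20, replace = TRUE)
    log_odds[p, aa[p]] <- sample(7:10, 1)
    info[p] <- round(stats::runif(1, 2.5, 4.0), 2)
  }
  structure(list(protein_id = protein_id, sequence = sequence,
                 log_odds = log_odds, info_content = info),
            class = "seq_profile")
}

# baseline location/spread per score term; spreads are 1 REU by default so
# planted effects are expressed directly in native-sd units
term_baselines <- function(terms) {
  mu <- stats::setNames(rep(-5, length(terms)), terms)
  mu["total_score"] <- -150
  if ("fa_rep" %in% terms) mu["fa_rep"] <- 30
  sigma <- stats::setNames(rep(1, length(terms)), terms)
  sigma["total_score"] <- 3
  list(mu = mu, sigma = sigma)
}

#' Generate a matched native/variant score ensemble pair
#'
#' Native decoys are drawn per term from Normal(mu_t, sigma_t); variant
#' decoys are shifted by `effect[t] * sigma_t`.  Effects are therefore
#' expressed in native-sd units, matching the normalization in
#' [ensemble_normalize()].
#'
#' @param effect named numeric vector of per-term shifts (sd units); terms
#'   not named shift by 0.
#' @param n_decoys decoys per side (>= 2).
#' @param protocol `"fast_relax"` (default) or `"ddg_monomer"`; fixes the
#'   term manifest.
#' @param seed integer seed.
#' @param sigma optional named per-term spreads overriding the defaults
#'   (must be positive).
#' @return an `ensemble_pair`.
#' @export
generate_score_ensembles <- function(effect = numeric(0), n_decoys = 50,
                                     protocol = c("fast_relax", "ddg_monomer"),
                                     seed = 1, sigma = NULL) {
  protocol <- match.arg(protocol)
  if (n_decoys < 2)
    stop("parameter error: n_decoys must be at least 2", call. = FALSE)
  terms <- if (protocol == "fast_relax") RELAX_TERMS else DDG_TERMS
  base <- term_baselines(terms)
  if (!is.null(sigma)) base$sigma[names(sigma)] <- sigma
  if (any(base$sigma <= 0))
    stop("parameter error: sigma must be positive for every term", call. = FALSE)
  bad <- setdiff(names(effect), terms)
  if (length(bad))
    stop("effect names not in the ", protocol, " manifest: ",
         paste(bad, collapse = ", "), call. = FALSE)
  set.seed(seed)
  draw <- function(shift) {
    cols <- lapply(terms, function(t) {
      stats::rnorm(n_decoys, base$mu[[t]] + shift[[t]] * base$sigma[[t]],
                   base$sigma[[t]])
    })
    scores <- as.data.frame(cols, col.names = terms)
    structure(list(protocol = protocol, scores = scores,
                   description = sprintf("decoy_%04d", seq_len(n_decoys))),
              class = "score_table")
  }
  shift_full <- stats::setNames(rep(0, length(terms)), terms)
  shift_full[names(effect)] <- effect
  nat <- draw(stats::setNames(rep(0, length(terms)), terms))
  var <- draw(shift_full)
  new_ensemble_pair(nat, var, protocol)
}

#' Generate a labeled synthetic feature dataset
#'
#' Emulates the shape of a curated variant training set: variants grouped
#' into proteins, a deleterious label fraction matching the 5,740/9,477
#' ratio by default, Gaussian noise on all 106 features, and a planted
#' class signal (mean shift `informative[f]`) on a chosen subset of
#' features in deleterious records.
#'
#' @param n_proteins number of proteins (default 200).
#' @param variants_per_protein single count or range `c(lo, hi)` of
#'   variants per protein (default 5).
#' @param deleterious_fraction probability a variant is deleterious
#'   (default 0.606).
#' @param informative named numeric vector: feature name -> effect size
#'   (mean shift in noise-sd units for deleterious records).
#' @param noise_sd standard deviation of the feature noise (default 1).
#' @param seed integer seed.
#' @return data.frame: `protein`, `position`, `native`, `variant`,
#'   `label`, then the 106 feature columns.
#' @export
generate_labeled_dataset <- function(n_proteins = 200, variants_per_protein = 5,
                                     deleterious_fraction = 0.606,
                                     informative = numeric(0), noise_sd = 1,
                                     seed = 1) {
  if (deleterious_fraction <= 0 || deleterious_fraction >= 1)
    stop("parameter error: deleterious_fraction must be in (0, 1)", call. = FALSE)
  feats <- feature_manifest("all")
  bad <- setdiff(names(informative), feats)
  if (length(bad))
    stop("informative feature(s) not in the manifest: ",
         paste(bad, collapse = ", "), call. = FALSE)
  set.seed(seed)
  vpp <- if (length(variants_per_protein) == 2) {
    sample(variants_per_protein[1]:variants_per_protein[2], n_proteins,
           replace = TRUE)
  } else rep(variants_per_protein, n_proteins)
  n <- sum(vpp)
  protein <- rep(sprintf("P%04d", seq_len(n_proteins)), vpp)
  label <- ifelse(stats::rbinom(n, 1, deleterious_fraction) == 1,
                  "deleterious", "neutral")
  nat <- sample(AA1, n, replace = TRUE)
  var <- vapply(nat, function(a) sample(setdiff(AA1, a), 1), character(1))
  x <- matrix(stats::rnorm(n * length(feats), 0, noise_sd), nrow = n,
              dimnames = list(NULL, feats))
  del <- label == "deleterious"
  for (f in names(informative))
    x[del, f] <- x[del, f] + informative[[f]] * noise_sd
  out <- data.frame(protein = protein,
                    position = unlist(lapply(vpp, seq_len)),
                    native = nat, variant = unname(var), label = label,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(x))
}

#' Generate a minimal stub PDB model
#'
#' Emits backbone-only (N, CA, C, O) ATOM records for a sequence, with
#' options that exercise structure standardization: a duplicated chain,
#' HETATM ligand/metal/water records, and MSE (selenomethionine) residues.
#' Coordinates are placeholders on a line; only the residue bookkeeping is
#' meaningful.
#'
#' @param sequence one-letter amino-acid string.
#' @param chain chain identifier (default `"A"`).
#' @param start_resno first residue number (default 1).
#' @param duplicate_chain identifier of an identical extra chain, or `NULL`.
#' @param n_waters,add_zn extra HETATM records to include.
#' @param mse_positions positions written as MSE HETATM residues instead of
#'   standard ATOM records.
#' @return PDB-format text (single string).
#' @export
generate_stub_pdb <- function(sequence, chain = "A", start_resno = 1,
                              duplicate_chain = NULL, n_waters = 0,
                              add_zn = FALSE, mse_positions = integer(0)) {
  aa <- strsplit(sequence, "")[[1]]
  aa3 <- names(AA3TO1)[match(aa, AA3TO1)]
  serial <- 0L
  atom_line <- function(rec, name, res, ch, resno, x, y, z) {
    serial <<- serial + 1L
    sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            rec, serial, name, res, ch, resno, x, y, z,
            substr(name, 1, 1))
  }
  chain_lines <- function(ch) {
    unlist(lapply(seq_along(aa), function(i) {
      resno <- start_resno + i - 1L
      if (i %in% mse_positions) {
        return(atom_line("HETATM", "CA", "MSE", ch, resno, i * 3.8, 0, 0))
      }
      c(atom_line("ATOM", "N",  aa3[i], ch, resno, i * 3.8 - 1.2, 0.5, 0),
        atom_line("ATOM", "CA", aa3[i], ch, resno, i * 3.8, 0, 0),
        atom_line("ATOM", "C",  aa3[i], ch, resno, i * 3.8 + 1.2, -0.5, 0),
        atom_line("ATOM", "O",  aa3[i], ch, resno, i * 3.8 + 1.4, -1.6, 0))
    }))
  }
  lines <- chain_lines(chain)
  if (!is.null(duplicate_chain)) lines <- c(lines, chain_lines(duplicate_chain))
  if (add_zn)
    lines <- c(lines, atom_line("HETATM", "ZN", "ZN", chain, 901L, 0, 5, 5))
  if (n_waters > 0)
    for (w in seq_len(n_waters))
      lines <- c(lines, atom_line("HETATM", "O", "HOH", chain, 900L + w,
                                  w * 2, 9, 9))
  paste(c(lines, "END"), collapse = "\n")
}

#' Generate a PROBE-style accessibility table
#'
#' @param resnos residue numbers.
#' @param areas accessible areas; defaults to seeded uniform draws in
#'   \[0, 120\].
#' @param seed integer seed used when `areas` is `NULL`.
#' @return text of a whitespace table (`resno aa area` per line).
#' @export
generate_probe_table <- function(resnos, areas = NULL, seed = 1) {
  if (is.null(areas)) {
    set.seed(seed)
    areas <- round(stats::runif(length(resnos), 0, 120), 1)
  }
  paste(c("# residue accessibility",
          sprintf("%d RES %.1f", resnos, areas)), collapse = "\n")
}
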