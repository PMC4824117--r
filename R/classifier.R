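# Sparse logistic regression with stability-based feature selection.
#
# Model: P(deleterious | x) = logistic(b0 + sum_j w_j z_j), where z are the
# selected features standardized by training-set center/scale.  Feature
# selection runs L1-penalized logistic fits over protein-level subsamples
# across a lambda grid and keeps the features selected most consistently
# (at most 20).  The final fit minimizes the mean logistic deviance plus a
# light ridge penalty; it is written here directly (BFGS on the penalized
# loss with analytic gradient) so it is deterministic and easy to audit.

label01 <- function(label) {
  if (is.numeric(label)) return(as.integer(label != 0))
  if (is.logical(label)) return(as.integer(label))
  l <- as.character(label)
  if (!all(l %in% c("deleterious", "neutral")))
    stop("labels must be 'deleterious'/'neutral' (or 0/1)", call. = FALSE)
  as.integer(l == "deleterious")
}

mode_features <- function(mode) {
  switch(mode,
         combined = feature_manifest("all"),
         sequence_only = feature_manifest("sequence"),
         structure_only = feature_manifest("structure"))
}

#' Stability-based feature selection
#'
#' Fits L1-penalized logistic regressions on `n_resamples` protein-level
#' subsamples of the data across a logarithmic lambda grid, records which
#' features enter each sparse model, and ranks features by their maximum
#' selection frequency over the grid.  Features above `freq_threshold` are
#' returned, most stable first, truncated to `max_features`.
#'
#' @param data labeled feature data.frame: columns `protein`, `label`
#'   (deleterious/neutral) and the feature columns.
#' @param features candidate feature names (default: every manifest feature
#'   present in `data`).
#' @param n_resamples number of subsamples (default 100).
#' @param subsample_frac fraction of proteins drawn per subsample
#'   (default 0.8).
#' @param lambda_grid lambda values; `NULL` takes a 25-point grid from a
#'   full-data glmnet path.
#' @param freq_threshold minimum selection frequency (default 0.6).
#' @param max_features cap on the returned set (default 20).
#' @param seed integer seed; results are deterministic given it.
#' @return character vector of selected names (most frequent first), with
#'   attribute `"frequency"` holding the per-feature selection frequencies.
#' @export
stability_select <- function(data, features = NULL, n_resamples = 100,
                             subsample_frac = 0.8, lambda_grid = NULL,
                             freq_threshold = 0.6, max_features = 20,
                             seed = 1) {
  if (is.null(features))
    features <- intersect(feature_manifest("all"), names(data))
  df <- data[stats::complete.cases(data[, features, drop = FALSE]), , drop = FALSE]
  y <- label01(df$label)
  if (length(unique(y)) < 2)
    stop("degenerate labels: both classes must be present", call. = FALSE)
  proteins <- unique(df$protein)
  if (length(proteins) < 2)
    stop("stability selection needs variants from at least 2 proteins", call. = FALSE)
  x <- as.matrix(df[, features, drop = FALSE])

  if (is.null(lambda_grid)) {
    fit0 <- glmnet::glmnet(x, y, family = "binomial", alpha = 1, nlambda = 25)
    lambda_grid <- fit0$lambda
  }
  n_take <- max(1L, floor(subsample_frac * length(proteins)))

  counts <- matrix(0, nrow = length(features), ncol = length(lambda_grid),
                   dimnames = list(features, NULL))
  used <- 0L
  set.seed(seed)
  for (r in seq_len(n_resamples)) {
    keep_prot <- sample(proteins, n_take)
    idx <- df$protein %in% keep_prot
    if (length(unique(y[idx])) < 2) next   # single-class draw carries no vote
    fit <- glmnet::glmnet(x[idx, , drop = FALSE], y[idx], family = "binomial",
                          alpha = 1, lambda = lambda_grid)
    beta <- as.matrix(fit$beta)
    # glmnet may drop trailing lambdas; align columns we obtained
    got <- match(signif(fit$lambda, 10), signif(lambda_grid, 10))
    sel <- abs(beta) > 1e-8   # strictly active; ignores numerical dust
    counts[, got[!is.na(got)]] <- counts[, got[!is.na(got)], drop = FALSE] +
      sel[, !is.na(got), drop = FALSE]
    used <- used + 1L
  }
  if (used == 0L)
    stop("no informative subsamples: every draw was single-class", call. = FALSE)
  freq <- apply(counts / used, 1, max)
  ord <- order(-freq, match(names(freq), features))
  freq <- freq[ord]
  chosen <- names(freq)[freq >= freq_threshold]
  chosen <- utils::head(chosen, max_features)
  attr(chosen, "frequency") <- freq
  chosen
}

# Penalized logistic fit: minimize mean log(1 + exp(-s * eta)) +
# lambda/2 * ||w||^2 (intercept unpenalized), s in {-1, +1}.
fit_logistic_ridge <- function(x, y, lambda = 1e-3) {
  s <- ifelse(y == 1, 1, -1)
  n <- nrow(x); p <- ncol(x)
  obj <- function(par) {
    eta <- par[1] + drop(x %*% par[-1])
    z <- -s * eta
    # numerically stable log(1 + exp(z))
    mean(pmax(z, 0) + log1p(exp(-abs(z)))) + lambda / 2 * sum(par[-1]^2)
  }
  grad <- function(par) {
    eta <- par[1] + drop(x %*% par[-1])
    pfit <- stats::plogis(eta)
    r <- pfit - y
    c(mean(r), drop(crossprod(x, r)) / n + lambda * par[-1])
  }
  fit <- stats::optim(rep(0, p + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  list(intercept = fit$par[1],
       weights = stats::setNames(fit$par[-1], colnames(x)),
       converged = fit$convergence == 0,
       iterations = fit$counts[["function"]],
       objective = fit$value)
}

#' Fit a deleteriousness classifier
#'
#' Trains the sparse logistic regression on a labeled feature table.
#' In `combined` (and `structure_only`) mode, features are first chosen by
#' [stability_select()] unless an explicit set is given; in
#' `sequence_only` mode the five sequence features are used as-is.
#' Selected features are standardized with training-set center/scale and a
#' ridge-penalized logistic fit yields the weights; training is
#' deterministic given the data and `seed`.
#'
#' @param data labeled feature data.frame (columns `protein`, `label`, and
#'   the manifest feature columns; rows with missing values on the active
#'   feature set are dropped).
#' @param features explicit feature names to fit on, skipping selection.
#' @param mode `"combined"`, `"sequence_only"` or `"structure_only"`.
#' @param lambda ridge penalty of the final fit (default 1e-3).
#' @param select list of arguments forwarded to [stability_select()].
#' @param seed seed for the selection resamples.
#' @return object of class `delvar` with components `mode`, `features`,
#'   `center`, `scale`, `coefficients`, `intercept`, `fitted.values`, `y`,
#'   `selection` (frequencies, when selection ran) and `call`.
#' @examples
#' d <- generate_labeled_dataset(n_proteins = 40, variants_per_protein = 4,
#'                               informative = c(pssm_diff = 2), seed = 7)
#' fit <- delvar(d, features = c("pssm_diff", "info_cont"))
#' coef(fit)
#' @export
delvar <- function(data, features = NULL,
                   mode = c("combined", "sequence_only", "structure_only"),
                   lambda = 1e-3, select = list(), seed = 1) {
  mode <- match.arg(mode)
  universe <- intersect(mode_features(mode), names(data))
  if (!length(universe))
    stop("no manifest feature columns found in `data`", call. = FALSE)
  selection <- NULL
  if (is.null(features)) {
    if (mode == "sequence_only" || length(universe) <= 20) {
      features <- universe
    } else {
      features <- do.call(stability_select,
                          c(list(data = data, features = universe, seed = seed),
                            select))
      selection <- attr(features, "frequency")
      attr(features, "frequency") <- NULL
      if (!length(features))
        stop("stability selection returned no features at this threshold",
             call. = FALSE)
    }
  } else {
    bad <- setdiff(features, universe)
    if (length(bad))
      stop("feature(s) not available in ", mode, " mode: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (mode == "combined" && length(features) > 20)
    stop("combined mode is capped at 20 selected features", call. = FALSE)

  df <- data[stats::complete.cases(data[, features, drop = FALSE]), , drop = FALSE]
  y <- label01(df$label)
  if (length(unique(y)) < 2)
    stop("degenerate labels: both classes must be present", call. = FALSE)
  x <- as.matrix(df[, features, drop = FALSE])
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  fit <- fit_logistic_ridge(z, y, lambda = lambda)
  if (!fit$converged)
    warning("final fit did not converge after ", fit$iterations,
            " function evaluations", call. = FALSE)
  eta <- fit$intercept + drop(z %*% fit$weights)
  structure(list(mode = mode, features = features,
                 center = center, scale = scale,
                 coefficients = fit$weights, intercept = fit$intercept,
                 lambda = lambda, fitted.values = stats::plogis(eta),
                 y = y, n = nrow(df), n_proteins = length(unique(df$protein)),
                 selection = selection, converged = fit$converged,
                 call = match.call()),
            class = "delvar")
}

#' Predict deleterious probabilities
#'
#' @param object a fitted `delvar` model.
#' @param newdata data.frame carrying the model's feature columns.
#' @param type `"response"` (deleterious probability), `"link"` (logit),
#'   `"class"` (`deleterious` iff score > 0.5, ties to `neutral`) or
#'   `"contrib"` (matrix of per-feature weight x standardized-value terms;
#'   attribute `"intercept"`; rows sum with the intercept to the logit).
#' @param ... unused.
#' @return numeric vector, character vector, or contribution matrix.
#' @export
predict.delvar <- function(object, newdata,
                           type = c("response", "link", "class", "contrib"),
                           ...) {
  type <- match.arg(type)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop("missing feature(s): ", paste(miss, collapse = ", "), call. = FALSE)
  x <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  if (anyNA(x))
    stop("missing feature value(s) for selected features in ", object$mode,
         " mode; route such variants to a sequence_only model", call. = FALSE)
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  contrib <- sweep(z, 2, object$coefficients, "*")
  eta <- object$intercept + rowSums(contrib)
  switch(type,
         response = stats::plogis(eta),
         link = eta,
         class = ifelse(stats::plogis(eta) > 0.5, "deleterious", "neutral"),
         contrib = structure(contrib, intercept = object$intercept))
}

#' Score variants and attach labels and contributions
#'
#' Convenience wrapper around [predict.delvar()] that returns one row per
#' variant with the confidence score (deleterious probability), the label
#' at the 0.5 threshold (strictly above) and the per-feature contributions
#' as an attribute.
#'
#' @param object a fitted `delvar` model.
#' @param newdata feature data.frame; identifying columns `protein`,
#'   `position`, `native`, `variant` are carried through when present.
#' @return data.frame with `score` and `label`; attribute
#'   `"contributions"` (matrix) and `"intercept"`.
#' @export
classify_variants <- function(object, newdata) {
  contrib <- predict(object, newdata, type = "contrib")
  eta <- attr(contrib, "intercept") + rowSums(contrib)
  score <- stats::plogis(eta)
  ids <- intersect(c("protein", "position", "native", "variant"), names(newdata))
  out <- cbind(as.data.frame(newdata)[, ids, drop = FALSE],
               data.frame(score = score,
                          label = ifelse(score > 0.5, "deleterious", "neutral")))
  rownames(out) <- NULL
  attr(out, "contributions") <- contrib
  attr(out, "intercept") <- attr(contrib, "intercept")
  out
}

#' Keep one prediction per gene across isoforms
#'
#' When a gene has predictions on several isoform models, the prediction
#' with the highest score is retained (any deleterious call for the gene is
#' treated as evidence of deleteriousness); ties go to the
#' lexicographically first isoform identifier.
#'
#' @param predictions data.frame with a `score` column and an isoform
#'   identifier column (`isoform`, else `protein`).
#' @return the retained single row.
#' @export
aggregate_isoforms <- function(predictions) {
  if (!nrow(predictions))
    stop("aggregate_isoforms() needs at least one prediction", call. = FALSE)
  idcol <- if ("isoform" %in% names(predictions)) "isoform" else "protein"
  ord <- order(-predictions$score, as.character(predictions[[idcol]]))
  predictions[ord[1], , drop = FALSE]
}

# ---- methods ----------------------------------------------------------------

#' @export
print.delvar <- function(x, ...) {
  cat(sprintf("deleteriousness classifier (%s mode)\n", x$mode))
  cat(sprintf("  %d features, fitted on %d variants in %d proteins\n",
              length(x$features), x$n, x$n_proteins))
  cat(sprintf("  intercept %.4f; ridge lambda %g\n", x$intercept, x$lambda))
  invisible(x)
}

#' @export
summary.delvar <- function(object, ...) {
  w <- sort(object$coefficients, decreasing = TRUE)
  acc <- mean((object$fitted.values > 0.5) == (object$y == 1))
  structure(list(mode = object$mode, n = object$n,
                 n_proteins = object$n_proteins,
                 weights = w, intercept = object$intercept,
                 training_accuracy = acc,
                 selection = object$selection),
            class = "summary.delvar")
}

#' @export
print.summary.delvar <- function(x, ...) {
  cat(sprintf("deleteriousness classifier (%s mode): %d variants, %d proteins\n",
              x$mode, x$n, x$n_proteins))
  cat(sprintf("training accuracy at 0.5: %.3f\n", x$training_accuracy))
  cat("standardized weights:\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
coef.delvar <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
residuals.delvar <- function(object, type = c("deviance", "pearson", "response"),
                             ...) {
  type <- match.arg(type)
  p <- object$fitted.values; y <- object$y
  switch(type,
         response = y - p,
         pearson = (y - p) / sqrt(p * (1 - p)),
         deviance = sign(y - p) *
           sqrt(-2 * (y * log(p) + (1 - y) * log1p(-p))))
}

#' Simulate labels from the fitted probabilities
#' @param object fitted `delvar` model.
#' @param nsim number of simulated label vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame of `nsim` columns of 0/1 draws.
#' @export
simulate.delvar <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted.values
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted classifier
#'
#' Horizontal bar chart of the standardized weights; when stability
#' selection ran, a second panel shows the top selection frequencies.
#'
#' @param x fitted `delvar` model.
#' @param ... passed to `barplot`.
#' @export
plot.delvar <- function(x, ...) {
  op <- graphics::par(no.readonly = TRUE); on.exit(graphics::par(op))
  if (!is.null(x$selection)) graphics::par(mfrow = c(1, 2))
  w <- sort(x$coefficients)
  graphics::par(mar = c(4, 9, 2, 1))
  graphics::barplot(w, horiz = TRUE, las = 1, cex.names = 0.6,
                    main = "standardized weights",
                    xlab = "weight (logit units per sd)", ...)
  if (!is.null(x$selection)) {
    f <- utils::head(sort(x$selection, decreasing = TRUE), 20)
    graphics::barplot(rev(f), horiz = TRUE, las = 1, cex.names = 0.6,
                      main = "selection frequency", xlab = "frequency")
  }
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

#' Write a fitted model to versioned flat text
#' @param object fitted `delvar` model.
#' @param path output path.
#' @export
write_delvar <- function(object, path) {
  stopifnot(inherits(object, "delvar"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# delvar model v1",
               paste0("mode\t", object$mode),
               paste0("lambda\t", num_str(object$lambda)),
               paste0("intercept\t", num_str(object$intercept)),
               "feature\tcenter\tscale\tweight"), con)
  for (f in object$features)
    writeLines(paste(f, num_str(object$center[[f]]), num_str(object$scale[[f]]),
                     num_str(object$coefficients[[f]]), sep = "\t"), con)
  invisible(path)
}

#' Read a model written by [write_delvar()]
#' @param path model file path.
#' @return object of class `delvar` (prediction-ready; training artifacts
#'   such as fitted values are absent).
#' @export
read_delvar <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# delvar model v1", lines[1]))
    stop("unrecognized model file (expected '# delvar model v1' header)",
         call. = FALSE)
  kv <- strsplit(lines[2:4], "\t")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  tab <- utils::read.table(text = lines[-(1:4)], header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  structure(list(mode = vals[["mode"]], features = tab$feature,
                 center = stats::setNames(tab$center, tab$feature),
                 scale = stats::setNames(tab$scale, tab$feature),
                 coefficients = stats::setNames(tab$weight, tab$feature),
                 intercept = as.numeric(vals[["intercept"]]),
                 lambda = as.numeric(vals[["lambda"]])),
            class = "delvar")
}
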