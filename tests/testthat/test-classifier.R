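# Stability selection, the penalized logistic fit, prediction and
# serialization.

test_that("stability selection recovers planted features from noise", {
  d <- generate_labeled_dataset(n_proteins = 60, variants_per_protein = 5,
                                informative = c(pssm_diff = 2,
                                                ddg_total_score = 2,
                                                relax_fa_rep_mean = 2),
                                seed = 101)
  sel <- stability_select(d, n_resamples = 30, seed = 202)
  expect_true(all(c("pssm_diff", "ddg_total_score", "relax_fa_rep_mean") %in% sel))
  expect_lte(length(sel), 20)
})

test_that("duplicated informative features: at most one survives a high penalty", {
  d <- generate_labeled_dataset(n_proteins = 50, variants_per_protein = 5,
                                informative = c(pssm_diff = 2), seed = 7)
  d$pssm_nat <- d$pssm_diff   # exact duplicate of the informative column
  sel <- stability_select(d, n_resamples = 30, lambda_grid = c(0.2, 0.15),
                          seed = 7)
  expect_lte(sum(c("pssm_diff", "pssm_nat") %in% sel), 1)
})

test_that("an unattainable frequency threshold selects nothing", {
  d <- generate_labeled_dataset(n_proteins = 20, variants_per_protein = 4,
                                informative = c(pssm_diff = 2), seed = 5)
  sel <- stability_select(d, n_resamples = 10, freq_threshold = 1.01, seed = 1)
  expect_length(sel, 0)
})

test_that("single-class data is a degenerate-label error", {
  d <- generate_labeled_dataset(n_proteins = 10, variants_per_protein = 3,
                                seed = 3)
  d$label <- "deleterious"
  expect_error(stability_select(d, n_resamples = 5, seed = 1), "degenerate")
  expect_error(delvar(d, features = "pssm_diff"), "degenerate")
})

test_that("a linearly separable toy set trains to accuracy 1", {
  d <- data.frame(protein = c("A", "A", "B", "B"),
                  label = c("deleterious", "deleterious", "neutral", "neutral"),
                  pssm_diff = c(3, 2.5, -3, -2.5),
                  info_cont = c(1, 1.2, 0.9, 1.1))
  fit <- delvar(d, features = c("pssm_diff", "info_cont"))
  expect_equal(mean((fit$fitted.values > 0.5) == (fit$y == 1)), 1)
})

test_that("the penalized fit matches a brute-force grid minimizer of its loss", {
  x <- matrix(c(-1.2, -0.4, 0.1, 0.8, 1.5), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- c(0, 0, 1, 1, 1)
  lambda <- 0.05
  fit <- delvar:::fit_logistic_ridge(x, y, lambda = lambda)

  loss <- function(b0, w) {
    eta <- b0 + x[, 1] * w
    mean(log1p(exp(-ifelse(y == 1, 1, -1) * eta))) + lambda / 2 * w^2
  }
  # coarse grid, then fine grid around the coarse optimum
  grid <- expand.grid(b0 = seq(-4, 4, 0.05), w = seq(-4, 4, 0.05))
  vals <- mapply(loss, grid$b0, grid$w)
  best <- grid[which.min(vals), ]
  fine <- expand.grid(b0 = seq(best$b0 - 0.1, best$b0 + 0.1, 0.001),
                      w = seq(best$w - 0.1, best$w + 0.1, 0.001))
  fvals <- mapply(loss, fine$b0, fine$w)
  fbest <- fine[which.min(fvals), ]
  expect_equal(fit$intercept, fbest$b0, tolerance = 2e-3)
  expect_equal(unname(fit$weights), fbest$w, tolerance = 2e-3)
})

test_that("the in-package ridge fit agrees with glmnet on the same objective", {
  set.seed(11)
  n <- 200
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(0.5 + x[, 1] - 0.7 * x[, 2]))
  lambda <- 0.01
  ours <- delvar:::fit_logistic_ridge(x, y, lambda = lambda)
  g <- glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                      standardize = FALSE, thresh = 1e-12)
  expect_equal(unname(ours$weights), as.numeric(g$beta), tolerance = 1e-3)
  expect_equal(ours$intercept, as.numeric(g$a0), tolerance = 1e-3)
})

test_that("training is invariant to record order", {
  d <- generate_labeled_dataset(n_proteins = 30, variants_per_protein = 4,
                                informative = c(pssm_diff = 1.5), seed = 9)
  fit1 <- delvar(d, features = c("pssm_diff", "info_cont", "pssm_nat"))
  set.seed(1)
  fit2 <- delvar(d[sample(nrow(d)), ], features = c("pssm_diff", "info_cont",
                                                    "pssm_nat"))
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-8)
  expect_equal(fit1$intercept, fit2$intercept, tolerance = 1e-8)
})

toy_model <- function(weights, intercept = 0) {
  structure(list(mode = "combined", features = names(weights),
                 center = setNames(rep(0, length(weights)), names(weights)),
                 scale = setNames(rep(1, length(weights)), names(weights)),
                 coefficients = weights, intercept = intercept, lambda = 0),
            class = "delvar")
}

test_that("prediction closed forms: 0.5 at zero logit, logistic(1) at (2,-1)x(1,1)", {
  m0 <- toy_model(c(f1 = 0, f2 = 0))
  nd <- data.frame(f1 = 1, f2 = 1)
  expect_equal(predict(m0, nd), 0.5)
  expect_equal(predict(m0, nd, type = "class"), "neutral")  # tie goes neutral

  m <- toy_model(c(f1 = 2, f2 = -1))
  expect_equal(predict(m, nd), plogis(1))
  expect_equal(predict(m, nd, type = "link"), 1)
  contrib <- predict(m, nd, type = "contrib")
  expect_equal(rowSums(contrib) + attr(contrib, "intercept"),
               predict(m, nd, type = "link"), ignore_attr = TRUE)
})

test_that("a masked structure vector cannot be scored in combined mode", {
  m <- toy_model(c(pssm_diff = 1, ddg_total_score = 1))
  nd <- data.frame(pssm_diff = 1, ddg_total_score = NA_real_)
  expect_error(predict(m, nd), "sequence_only")
  expect_error(predict(m, data.frame(pssm_diff = 1)), "missing feature")
})

test_that("increasing a positively weighted feature strictly increases the score", {
  m <- toy_model(c(f1 = 1.3, f2 = -0.4))
  grid <- seq(-2, 2, 0.5)
  s <- predict(m, data.frame(f1 = grid, f2 = 0))
  expect_true(all(diff(s) > 0))
  s2 <- predict(m, data.frame(f1 = 0, f2 = grid))
  expect_true(all(diff(s2) < 0))
})

test_that("contributions plus intercept reconstruct the logit in classify_variants", {
  m <- toy_model(c(f1 = 0.8, f2 = -1.1), intercept = 0.3)
  nd <- data.frame(protein = c("A", "B"), f1 = c(1, -1), f2 = c(0.5, 2))
  pred <- classify_variants(m, nd)
  expect_equal(qlogis(pred$score),
               rowSums(attr(pred, "contributions")) + attr(pred, "intercept"))
  expect_equal(pred$label, ifelse(pred$score > 0.5, "deleterious", "neutral"))
})

test_that("isoform aggregation keeps the top score with a lexicographic tie-break", {
  p <- data.frame(isoform = c("iso2", "iso1", "iso3"),
                  score = c(0.3, 0.9, 0.6))
  expect_equal(aggregate_isoforms(p)$score, 0.9)
  expect_equal(aggregate_isoforms(p[1, ])$isoform, "iso2")
  tie <- data.frame(isoform = c("B", "A"), score = c(0.8, 0.8))
  expect_equal(aggregate_isoforms(tie)$isoform, "A")
  expect_error(aggregate_isoforms(tie[0, ]), "at least one")
})

test_that("model serialization round-trips and reproduces predictions", {
  d <- generate_labeled_dataset(n_proteins = 25, variants_per_protein = 4,
                                informative = c(pssm_diff = 2, info_cont = -1),
                                seed = 31)
  fit <- delvar(d, features = c("pssm_diff", "info_cont", "aminochange"))
  path <- tempfile(fileext = ".tsv")
  write_delvar(fit, path)
  back <- read_delvar(path)
  expect_identical(back$features, fit$features)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(predict(back, d), predict(fit, d))
})

test_that("sequence-only mode restricts the feature universe", {
  d <- generate_labeled_dataset(n_proteins = 25, variants_per_protein = 4,
                                informative = c(pssm_diff = 2), seed = 13)
  fit <- delvar(d, mode = "sequence_only")
  expect_setequal(fit$features, feature_manifest("sequence"))
  expect_error(delvar(d, features = "ddg_total_score", mode = "sequence_only"),
               "not available")
})
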