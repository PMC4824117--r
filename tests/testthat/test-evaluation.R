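# Splits, ROC/PR, curve averaging, precision filtering, enrichment.

test_that("protein-level splits keep proteins whole and fractions exact", {
  protein <- rep(sprintf("P%02d", 1:10), each = 7)
  splits <- protein_level_splits(protein, n_splits = 20, train_frac = 0.8,
                                 seed = 4)
  for (sp in splits) {
    tr_prot <- unique(protein[sp$train])
    te_prot <- unique(protein[sp$test])
    expect_length(tr_prot, 8)
    expect_length(te_prot, 2)
    expect_length(intersect(tr_prot, te_prot), 0)
    expect_equal(sort(c(sp$train, sp$test)), seq_along(protein))
  }
  # grouping invariant: a 50-variant protein lands wholly on one side
  protein2 <- c(rep("BIG", 50), sprintf("P%02d", 1:9))
  for (sp in protein_level_splits(protein2, n_splits = 10, seed = 2)) {
    expect_true(all(which(protein2 == "BIG") %in% sp$train) ||
                  all(which(protein2 == "BIG") %in% sp$test))
  }
  expect_identical(protein_level_splits(protein, n_splits = 5, seed = 9),
                   protein_level_splits(protein, n_splits = 5, seed = 9))
  expect_error(protein_level_splits(rep("A", 10)), "at least 5 proteins")
})

test_that("roc_pr: perfect ranking, the printed toy case, and degenerate input", {
  perfect <- roc_pr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$aupr, 1)

  toy <- roc_pr(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))
  expect_equal(toy$auroc, 0.75)

  expect_error(roc_pr(runif(5), rep(1, 5)), "degenerate")
})

test_that("AUROC equals the pairwise concordance probability (oracle)", {
  concordance <- function(scores, y) {
    pos <- scores[y == 1]; neg <- scores[y == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    tot / (length(pos) * length(neg))
  }
  set.seed(123)
  for (i in 1:25) {
    n <- sample(8:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    expect_equal(roc_pr(s, y)$auroc, concordance(s, y))
  }
})

test_that("PR precision at recall 1 equals prevalence", {
  set.seed(5)
  y <- rbinom(60, 1, 0.4); y[1:2] <- c(0, 1)
  s <- runif(60)
  cv <- roc_pr(s, y)
  expect_equal(cv$pr_points$precision[nrow(cv$pr_points)], mean(y))
  expect_equal(max(cv$pr_points$recall), 1)
})

test_that("random scores give AUROC near 0.5", {
  set.seed(77)
  y <- rep(c(0, 1), each = 5000)
  s <- runif(10000)
  expect_lt(abs(roc_pr(s, y)$auroc - 0.5), 0.02)
})

test_that("curve averaging: identical members average to themselves, areas are means", {
  set.seed(8)
  y <- rbinom(100, 1, 0.5); y[1:2] <- c(0, 1)
  cv <- roc_pr(runif(100) + y * 0.4, y)
  avg <- average_curves(list(cv, cv, cv))
  expect_equal(avg$auroc, cv$auroc)
  expect_equal(avg$aupr, cv$aupr)
  grid_tpr <- approx(cv$roc_points$fpr, cv$roc_points$tpr,
                     xout = avg$roc_points$fpr, rule = 2, ties = max)$y
  expect_equal(avg$roc_points$tpr, grid_tpr)

  cv2 <- roc_pr(runif(100) + y * 1.5, y)
  avg2 <- average_curves(list(cv, cv2))
  expect_equal(avg2$auroc, mean(c(cv$auroc, cv2$auroc)), tolerance = 1e-12)
  expect_error(average_curves(list()), "at least one")
})

test_that("two known triangular ROC curves average to the hand-computed mid-curve", {
  c1 <- structure(list(roc_points = data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1)),
                       pr_points = data.frame(recall = c(0, 1), precision = c(1, 1)),
                       auroc = 1, aupr = 1), class = "eval_curves")
  c2 <- structure(list(roc_points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                       pr_points = data.frame(recall = c(0, 1), precision = c(0.5, 0.5)),
                       auroc = 0.5, aupr = 0.5), class = "eval_curves")
  avg <- average_curves(list(c1, c2), grid_points = 5)
  # at fpr x: member1 tpr = 1, member2 tpr = x -> mean = (1 + x)/2
  expect_equal(avg$roc_points$tpr, (1 + avg$roc_points$fpr) / 2)
  expect_equal(avg$auroc, 0.75)
})

test_that("precision_at_cutoff counts strictly above the cutoff", {
  scores <- c(0.95, 0.9, 0.8, 0.7, 0.4, 0.3, 0.2, 0.15, 0.1, 0.05)
  labels <- c(1, 1, 0, 1, 0, 1, 0, 0, 0, 0)
  r <- precision_at_cutoff(scores, labels, 0.6)
  expect_equal(r$precision, 0.75)
  expect_equal(r$fraction_above, 0.4)

  all_in <- precision_at_cutoff(scores, labels, -1)
  expect_equal(all_in$precision, mean(labels))
  expect_equal(all_in$fraction_above, 1)

  none <- precision_at_cutoff(scores, labels, 1)
  expect_true(none$empty)
  expect_true(is.na(none$precision))
})

test_that("enrichment bins conserve counts and the null case hugs the background", {
  set.seed(21)
  A <- runif(3000); B <- runif(2000)
  et <- enrichment_by_bins(A, B, n_bins = 10)
  expect_equal(sum(et$counts_A), 3000)
  expect_equal(sum(et$counts_B), 2000)
  expect_equal(et$background, 1.5)
  expect_true(all(abs(et$ratio - 1.5) < 0.6))   # identical draws: near background
  expect_error(enrichment_by_bins(A, B, n_bins = 1), "config error")
  expect_error(enrichment_by_bins(c(A, 2), B), "\\[0, 1\\]")
})

test_that("planted monotone enrichment yields positive significant Spearman,
           agreeing with a Monte-Carlo permutation oracle", {
  set.seed(42)
  A <- rbeta(2000, 2, 1)   # skewed to high scores
  B <- rbeta(1500, 1, 2)   # skewed to low scores
  et <- enrichment_by_bins(A, B, n_bins = 10)
  expect_gt(et$spearman, 0)
  expect_lt(et$spearman_p, 0.05)

  # permutation oracle for the observed rank correlation
  mid <- et$midpoints[et$defined]; ratio <- et$ratio[et$defined]
  obs <- cor(mid, ratio, method = "spearman")
  set.seed(1)
  perm <- replicate(40000, cor(mid, sample(ratio), method = "spearman"))
  p_perm <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / 40001
  expect_equal(et$spearman_p, p_perm, tolerance = 0.01)

  # the correlation sign survives bin refinement
  et20 <- enrichment_by_bins(A, B, n_bins = 20)
  expect_gt(et20$spearman, 0)
})

test_that("contingency enrichment reproduces ratio arithmetic to 2 decimals", {
  expect_equal(unname(contingency_enrichment(554, 781, 348, 543)),
               c(1.59, 1.44))
  expect_equal(unname(contingency_enrichment(907, 428, 566, 325)),
               c(1.60, 1.32))
  expect_equal(unname(contingency_enrichment(10, 10, 10, 10)), c(1, 1))
  zero <- contingency_enrichment(5, 5, 0, 5)
  expect_true(is.na(zero[["pos_ratio"]]))
})
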