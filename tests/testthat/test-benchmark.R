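make_gold <- function(n_ess = 10, n_non = 10) {
  gold_standard(sprintf("E%02d", seq_len(n_ess)), sprintf("N%02d", seq_len(n_non)))
}

# guide-level data: gold essentials near `mu_ess`, non-essentials near 0
make_guide_data <- function(gold, guides_per_gene = 4, mu_ess = -2, sd = 0.2,
                            seed = 61) {
  set.seed(seed)
  genes <- c(gold$essential, gold$nonessential)
  mu <- ifelse(genes %in% gold$essential, mu_ess, 0)
  data.frame(gene = rep(genes, each = guides_per_gene),
             logfc = rnorm(length(genes) * guides_per_gene,
                           rep(mu, each = guides_per_gene), sd))
}

test_that("Bayes factors separate essential-like from non-essential-like genes", {
  gold <- make_gold()
  d <- make_guide_data(gold)
  bf <- bayes_factors(d$logfc, d$gene, gold, seed = 1)
  expect_true(all(bf[gold$essential] > 0))
  expect_true(all(bf[gold$nonessential] < 0))
  # a non-gold gene at the essential mode scores strongly positive
  d2 <- rbind(d, data.frame(gene = "X1", logfc = rnorm(4, -2, 0.1)))
  bf2 <- bayes_factors(d2$logfc, d2$gene, gold, seed = 1)
  expect_gt(bf2[["X1"]], 5)
})

test_that("a gene between symmetric references scores near zero, and BF is additive", {
  gold <- make_gold()
  set.seed(62)
  genes <- c(gold$essential, gold$nonessential)
  mu <- ifelse(genes %in% gold$essential, -2, 2)
  d <- data.frame(gene = rep(genes, each = 6),
                  logfc = rnorm(length(genes) * 6, rep(mu, each = 6), 0.3))
  mid <- data.frame(gene = "X1", logfc = rep(0, 4))
  bf <- bayes_factors(c(d$logfc, mid$logfc), c(d$gene, mid$gene), gold, seed = 2)
  expect_lt(abs(bf[["X1"]]), 1)
  # doubling identical guides doubles the (non-gold) gene's BF exactly
  d_half <- rbind(d, data.frame(gene = "X2", logfc = c(-1.2, -0.8)))
  d_full <- rbind(d, data.frame(gene = "X2", logfc = rep(c(-1.2, -0.8), 2)))
  bf_h <- bayes_factors(d_half$logfc, d_half$gene, gold, seed = 2)
  bf_f <- bayes_factors(d_full$logfc, d_full$gene, gold, seed = 2)
  expect_equal(bf_f[["X2"]], 2 * bf_h[["X2"]], tolerance = 1e-9)
})

test_that("precision and recall follow their definitions on a toy ranking", {
  gold <- gold_standard(sprintf("E%02d", 1:20), sprintf("N%02d", 1:20))
  # ranking: 19 essentials, two non-essentials, E20, then the rest
  bf <- c(setNames(100 - seq_len(19), sprintf("E%02d", 1:19)),
          N01 = 50, N02 = 45, E20 = 40,
          setNames(-seq_len(18), sprintf("N%02d", 3:20)))
  pr <- precision_recall(bf, gold)
  at20 <- pr[20, ]  # after the first false positive
  expect_equal(at20$precision, 19 / 20)  # TP=19, FP=1
  expect_equal(at20$recall, 19 / 20)
  rec <- recall_at_fdr(pr, fdr = 0.05)
  # deeper thresholds drop below 0.95 precision (19/21, 20/22), so the
  # TP=19/FP=1 point is the 5% FDR operating point
  expect_equal(rec$recall, 19 / 20)
  # perfect separation reaches precision 1 at recall 1
  bf_perf <- c(setNames(seq_len(20), gold$essential),
               setNames(-seq_len(20), gold$nonessential))
  pr_perf <- precision_recall(bf_perf, gold)
  expect_true(any(pr_perf$precision == 1 & pr_perf$recall == 1))
  expect_equal(auc_pr(pr_perf), 1)
})

test_that("recall at FDR uses the maximal-recall tie rule and 0 fallback", {
  curve <- data.frame(threshold = c(5, 4, 3, 2),
                      precision = c(1, 0.95, 0.95, 0.80),
                      recall = c(0.2, 0.5, 0.7, 1.0))
  rec <- recall_at_fdr(curve, 0.05)
  expect_equal(rec$recall, 0.7)
  expect_equal(rec$bf_threshold, 3)
  inverted <- data.frame(threshold = 1:2, precision = c(0.1, 0.2),
                         recall = c(0.5, 1))
  expect_equal(recall_at_fdr(inverted, 0.05)$recall, 0)
})

test_that("random scores give AUC near 0.5 and AUC matches a numeric oracle", {
  gold <- gold_standard(sprintf("E%02d", 1:50), sprintf("N%02d", 1:50))
  set.seed(63)
  aucs <- replicate(100, {
    bf <- setNames(runif(100), c(gold$essential, gold$nonessential))
    auc_pr(precision_recall(bf, gold))
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
  # trapezoid equals a fine rectangle (midpoint) summation
  set.seed(64)
  bf <- setNames(rnorm(100), c(gold$essential, gold$nonessential))
  pr <- precision_recall(bf, gold)
  r <- c(0, pr$recall); p <- c(pr$precision[1], pr$precision)
  grid <- seq(0, 1, length.out = 2e5 + 1)
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  rect <- sum(approx(r, p, xout = mid, ties = "ordered")$y * diff(grid))
  expect_equal(auc_pr(pr), rect, tolerance = 1e-6)
  expect_error(auc_pr(pr[1, , drop = FALSE]), "2 curve points")
})

test_that("matched-hit false positives are deterministic and comparable", {
  gold <- make_gold(10, 10)
  bf_clean <- c(setNames(20:11, gold$essential), setNames(10:1, gold$nonessential))
  bf_noisy <- bf_clean
  bf_noisy[c("N01", "N02")] <- c(25, 24)  # two false positives promoted
  fp <- false_positives_at_matched_hits(
    list(clean = bf_clean, noisy = bf_noisy, clean2 = bf_clean), gold, n_hits = 10)
  expect_equal(unname(fp), c(0L, 2L, 0L))
  expect_equal(fp[["clean"]], fp[["clean2"]])
  expect_error(false_positives_at_matched_hits(list(a = bf_clean), gold, 21),
               "exceeds")
  # ties broken by name: all-equal scores give a reproducible hit set
  bf_tie <- setNames(rep(1, 20), names(bf_clean))
  fp_tie <- false_positives_at_matched_hits(list(a = bf_tie, b = bf_tie), gold, 5)
  expect_equal(fp_tie[["a"]], fp_tie[["b"]])
})

test_that("distortion metrics behave under identity and uniform shifts", {
  gold <- make_gold(5, 5)
  genes <- rep(c(gold$essential, gold$nonessential), each = 2)
  obs <- rnorm(20)
  d0 <- distortion(obs, obs, genes, gold)
  expect_equal(unlist(d0), c(distortion_mean = 0, distortion_median = 0,
                             separation_delta = 0))
  d1 <- distortion(obs, obs + 0.7, genes, gold)
  expect_equal(d1$distortion_mean, 0.7)
  expect_equal(d1$distortion_median, 0.7)
  expect_equal(d1$separation_delta, 0, tolerance = 1e-12)
  expect_error(distortion(obs, obs[-1], genes[-1], gold), "aligned")
})

test_that("better-separated scores never lower recall at 5% FDR (mixing)", {
  gold <- gold_standard(sprintf("E%02d", 1:30), sprintf("N%02d", 1:30))
  set.seed(65)
  genes <- c(gold$essential, gold$nonessential)
  bf_rand <- setNames(rnorm(60), genes)
  bf_perf <- setNames(ifelse(genes %in% gold$essential, 1000, -1000), genes)
  recalls <- vapply(seq(0, 1, 0.25), function(lam) {
    bf <- (1 - lam) * bf_rand + lam * bf_perf
    recall_at_fdr(precision_recall(bf, gold))$recall
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
})

test_that("cross-validation keeps a gold gene's own guides out of its references", {
  gold <- make_gold(12, 12)
  d <- make_guide_data(gold, guides_per_gene = 5, seed = 66)
  # plant one gold essential whose guides sit far outside every support;
  # had its own guides trained the essential KDE, they would dominate it
  # and push its BF strongly positive
  d$logfc[d$gene == "E01"] <- 40
  bf <- bayes_factors(d$logfc, d$gene, gold, folds = 4, seed = 3)
  expect_lt(bf[["E01"]], 1)
  # the rest of the gold standard is unaffected
  expect_true(all(bf[setdiff(gold$essential, "E01")] > 0))
  expect_true(all(bf[gold$nonessential] < 0))
})
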