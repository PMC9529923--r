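test_that("the selfloop policy fixes the evaluated pair universe per category", {
  sys <- toy_system(n = 10, seed = 30, snr = 1)
  ev_p <- grn_evaluate(grn_infer(sys$Y, sys$P, method = "ls"), sys$net)
  ev_n <- grn_evaluate(grn_infer(sys$Y, method = "clr"), sys$net)
  expect_equal(ev_p$evaluated_pairs, 100)
  expect_equal(ev_n$evaluated_pairs, 90)
  expect_equal(ev_p$evaluated_pairs - ev_n$evaluated_pairs, 10)
  # a non-P prediction with an empty diagonal is charged no diagonal FNs:
  # its gold edge count excludes the selfloops entirely
  expect_equal(ev_n$n_gold, sum(unclass(sys$net)[row(sys$net) != col(sys$net)] != 0))
  # strip_all removes the diagonal from a P-based evaluation too
  ev_s <- grn_evaluate(grn_infer(sys$Y, sys$P, method = "ls"), sys$net,
                       selfloops = "strip_all")
  expect_equal(ev_s$evaluated_pairs, 90)
  expect_false(any(ev_s$max_f1_edges[, "target"] == ev_s$max_f1_edges[, "regulator"]))
})

test_that("unique-value thresholding produces the expected nested networks", {
  S <- matrix(c(0.9, 0.5, 0.5, 0.1), 2, 2)
  sweep <- threshold_sweep(S)
  expect_length(sweep, 3)
  expect_equal(sapply(sweep, sum), c(1, 3, 4))
  # monotone nesting along the whole sweep
  for (k in seq_len(length(sweep) - 1))
    expect_true(all(sweep[[k + 1]][sweep[[k]]]))
  # penalty-sweep fits pass through their networks, reordered sparsest first
  sys <- toy_system(n = 10, seed = 31)
  fit <- grn_infer(sys$X, sys$P, method = "lasso",
                   penalties = 10^seq(-6, 0, length.out = 30))
  sw <- threshold_sweep(fit)
  expect_length(sw, 30)
  expect_true(!is.unsorted(sapply(sw, sum)))
  expect_warning(threshold_sweep(matrix(0, 2, 2)), "zero")
})

test_that("confusion counts match pair enumeration and the hand-built metric values", {
  # 3 genes without diagonal: 6 ordered pairs enumerated by hand
  counts <- confusion_counts(gold_edges = c(1, 2), predicted_edges = c(1, 5),
                             n_pairs = 6)
  expect_equal(unclass(counts), c(tp = 1, fp = 1, fn = 1, tn = 3))
  expect_equal(unclass(confusion_counts(c(1, 2), c(1, 2), 6)),
               c(tp = 2, fp = 0, fn = 0, tn = 4))
  expect_equal(unclass(confusion_counts(c(1, 2), integer(0), 6)),
               c(tp = 0, fp = 0, fn = 2, tn = 4))
  # perfect classification
  perfect <- c(tp = 1, fp = 0, fn = 0, tn = 1)
  expect_equal(mcc_score(perfect), 1)
  expect_equal(f1_score(perfect), 1)
  # balanced counts: numerator 25 - 25 = 0
  expect_equal(mcc_score(c(tp = 5, fp = 5, fn = 5, tn = 5)), 0)
  # direct arithmetic of the MCC formula
  expect_equal(mcc_score(c(tp = 3, fp = 1, fn = 6, tn = 90)),
               (3 * 90 - 1 * 6) / sqrt(4 * 9 * 91 * 96))
  # zero-denominator conventions
  expect_equal(mcc_score(c(tp = 0, fp = 0, fn = 3, tn = 3)), 0)
  expect_equal(f1_score(c(tp = 0, fp = 0, fn = 0, tn = 4)), 0)
  expect_equal(precision_score(c(tp = 0, fp = 0, fn = 2, tn = 2)), 1)
})

test_that("curve areas agree with a brute-force sweep oracle on small instances", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 5
    gold <- matrix(rbinom(n * n, 1, 0.3), n, n)
    scores <- matrix(runif(n * n), n, n)
    ev <- grn_evaluate(scores, grn_network(gold + diag(1e-9, n)), selfloops = "keep")
    expect_equal(ev$aupr, brute_force_aupr(scores, gold + diag(1e-9, n)), tolerance = 1e-12)
    expect_equal(ev$auroc, brute_force_auroc(scores, gold + diag(1e-9, n)), tolerance = 1e-12)
    # cross-check AUROC against pROC on the same ranking
    if (requireNamespace("pROC", quietly = TRUE)) {
      g <- as.vector(gold + diag(1e-9, n)) != 0
      if (length(unique(g)) == 2) {
        auc <- as.numeric(pROC::auc(pROC::roc(g, as.vector(abs(scores)), quiet = TRUE,
                                              direction = "<")))
        expect_equal(ev$auroc, auc, tolerance = 1e-9)
      }
    }
  }
})

test_that("perfect rankings score 1 and random rankings sit at the baselines", {
  sys <- toy_system(n = 10, seed = 34)
  ev <- grn_evaluate(abs(unclass(sys$net)), sys$net, selfloops = "keep")
  expect_equal(ev$aupr, 1)
  expect_equal(ev$auroc, 1)
  res <- sapply(1:20, function(s) {
    set.seed(s)
    gold <- matrix(rbinom(400, 1, 0.1), 20, 20)
    scores <- matrix(runif(400), 20, 20)
    ev <- grn_evaluate(scores, grn_network(gold + diag(1e-9, 20)), selfloops = "keep")
    c(aupr = ev$aupr, auroc = ev$auroc, prev = mean(gold + diag(1e-9, 20) != 0))
  })
  expect_gt(mean(res["aupr", ]), 0.5 * mean(res["prev", ]))
  expect_lt(mean(res["aupr", ]), 2 * mean(res["prev", ]))
  expect_lt(abs(mean(res["auroc", ]) - 0.5), 0.05)
})

test_that("areas are invariant under strictly monotone score transforms", {
  set.seed(35)
  gold <- grn_network(matrix(rbinom(64, 1, 0.25), 8, 8) + diag(1e-9, 8))
  scores <- matrix(runif(64), 8, 8)
  ev1 <- grn_evaluate(scores, gold, selfloops = "keep")
  ev2 <- grn_evaluate(scores^3, gold, selfloops = "keep")
  ev3 <- grn_evaluate(log(scores + 1), gold, selfloops = "keep")
  expect_equal(ev1$aupr, ev2$aupr)
  expect_equal(ev1$auroc, ev3$auroc)
})

test_that("a 30-point penalty sweep approximates the full-threshold area", {
  sys <- toy_system(n = 30, seed = 36, snr = 1)
  fit <- grn_infer(sys$Y, sys$P, method = "lasso")
  ev_sweep <- grn_evaluate(fit, sys$net)
  # full-threshold sweep of the densest coefficient magnitudes
  ev_dense <- grn_evaluate(abs(coef(fit)), sys$net, selfloops = "keep")
  expect_lt(abs(ev_sweep$aupr - ev_dense$aupr), 0.05)
})

test_that("the max-F1 network picks the dominating point, ties to the sparser", {
  # hand-built 3-point situation via a dense score matrix:
  # gold has 2 edges; scores rank edge1 > edge2 > a false pair
  gold <- matrix(0, 2, 2); gold[1, 1] <- 1; gold[2, 2] <- 1
  scores <- matrix(c(0.9, 0.05, 0.4, 0.8), 2, 2)
  ev <- grn_evaluate(scores, grn_network(gold + diag(c(1e-9, 0))), selfloops = "keep")
  # by direct F1 of all sweep points the all-gold cutoff dominates
  f1s <- ev$points$f1
  expect_equal(nrow(ev$max_f1_edges), 2)
  expect_equal(max(f1s), 1)
  # perfect method returns exactly the gold edges
  sys <- toy_system(n = 8, seed = 37)
  evp <- grn_evaluate(abs(unclass(sys$net)), sys$net, selfloops = "keep")
  expect_setequal(attr(evp$max_f1_edges, "index"), which(unclass(sys$net) != 0))
  # all-zero prediction: empty max-F1 set
  expect_warning(ev0 <- grn_evaluate(matrix(0, 3, 3), grn_network(diag(-1, 3)),
                                     selfloops = "keep"), "zero")
  expect_equal(nrow(ev0$max_f1_edges), 0)
})

test_that("jaccard and true-fraction follow their set definitions", {
  expect_equal(jaccard_index(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(jaccard_index(c(1, 2), c(3, 4)), 0)
  expect_equal(jaccard_index(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(jaccard_index(integer(0), integer(0)), 1)
  expect_equal(true_fraction(c(1, 2), c(2, 3), c(2, 9)), 1)
  expect_equal(true_fraction(c(1, 2), c(2, 3), c(7, 9)), 0)
  expect_equal(true_fraction(c(1, 2, 5), c(2, 5, 8), c(2, 9)), 0.5)
  expect_true(is.na(true_fraction(c(1), c(2), c(1, 2))))
})

test_that("adding a correct edge never hurts precision at matched density", {
  # enumerated 3-gene instance: compare brute-force curves with and without
  # one additional correctly scored gold edge
  gold <- matrix(0, 3, 3); gold[1, 2] <- 1; gold[2, 3] <- 1; gold[3, 1] <- 1
  base <- matrix(runif(9, 0.1, 0.4), 3, 3)
  better <- base; better[1, 2] <- 0.9   # push a gold edge to the top
  cv_base <- brute_force_curve(base, gold)
  cv_bet <- brute_force_curve(better, gold)
  for (k in unique(cv_base[, "tp"] + cv_base[, "fp"])) {
    pb <- cv_base[cv_base[, "tp"] + cv_base[, "fp"] == k, "precision"]
    pt <- cv_bet[cv_bet[, "tp"] + cv_bet[, "fp"] == k, "precision"]
    if (length(pb) && length(pt)) expect_gte(max(pt), max(pb))
  }
})
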