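# Independent oracles used across the test suite. These deliberately avoid
# the code paths they check.

# Chi-square quantile via bisection on the regularized incomplete gamma
# function P(df/2, x/2) = pgamma(x, shape = df/2, scale = 2).
chisq_quantile_bisect <- function(p, df, tol = 1e-12) {
  lo <- 0; hi <- df
  while (pgamma(hi, shape = df / 2, scale = 2) < p) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (pgamma(mid, shape = df / 2, scale = 2) < p) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, hi)) break
  }
  (lo + hi) / 2
}

# Brute-force PR/ROC sweep from a score vector: enumerate every unique
# absolute cutoff, count the confusion table by direct comparison.
brute_force_curve <- function(scores, gold) {
  s <- abs(as.vector(scores)); g <- as.vector(gold) != 0
  cuts <- sort(unique(s), decreasing = TRUE)
  t(vapply(cuts, function(ct) {
    pred <- s >= ct
    tp <- sum(pred & g); fp <- sum(pred & !g)
    fn <- sum(!pred & g); tn <- sum(!pred & !g)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 1
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    fpr <- if (fp + tn > 0) fp / (fp + tn) else 0
    c(tp = tp, fp = fp, fn = fn, tn = tn, precision = prec, recall = rec, fpr = fpr)
  }, numeric(7)))
}

# Trapezoid over a brute-force curve with the package's anchoring rules.
brute_force_aupr <- function(scores, gold) {
  cv <- brute_force_curve(scores, gold)
  o <- order(cv[, "recall"])
  rec <- c(0, cv[o, "recall"]); prec <- c(cv[1, "precision"], cv[o, "precision"])
  sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
}

brute_force_auroc <- function(scores, gold) {
  cv <- brute_force_curve(scores, gold)
  o <- order(cv[, "fpr"])
  xx <- c(0, cv[o, "fpr"], 1); yy <- c(0, cv[o, "recall"], 1)
  sum(diff(xx) * (head(yy, -1) + tail(yy, -1)) / 2)
}

# Direct plug-in mutual information of two pre-binned integer vectors.
direct_mi <- function(bx, by, nb) {
  M <- length(bx)
  mi <- 0
  for (a in seq_len(nb)) for (b in seq_len(nb)) {
    pab <- sum(bx == a & by == b) / M
    if (pab > 0) mi <- mi + pab * log(pab / ((sum(bx == a) / M) * (sum(by == b) / M)))
  }
  mi
}

# Small stable test system with a known structure.
toy_system <- function(n = 12, seed = 42, replicates = 3, snr = NULL) {
  net <- random_grn(n, avg_links = 3, seed = seed)
  P <- perturbation_design(n, replicates = replicates)
  X <- steady_state_response(net, P)
  Y <- if (is.null(snr)) X else add_noise(X, snr = snr, seed = seed + 1)
  list(net = net, P = P, X = X, Y = Y)
}
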