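#' Confusion counts over a fixed set of evaluated gene pairs
#'
#' Compares two directed edge sets over `n_pairs` evaluated ordered gene
#' pairs. Direction matters, sign never does. Undirected (symmetric)
#' predictions are handled upstream by entering each undirected edge in both
#' directions.
#'
#' @param gold_edges,predicted_edges edge sets: logical matrices, integer
#'   index vectors, or two-column (target, regulator) index matrices; both
#'   must be subsets of the evaluated pairs.
#' @param n_pairs total number of evaluated ordered pairs (fixed by the
#'   selfloop policy: `N^2` with selfloops, `N^2 - N` without).
#' @return A named numeric vector of class `confusion_counts` with elements
#'   `tp`, `fp`, `fn`, `tn`.
#' @seealso [f1_score()], [mcc_score()], [grn_evaluate()]
#' @export
confusion_counts <- function(gold_edges, predicted_edges, n_pairs) {
  g <- as_edge_index(gold_edges)
  p <- as_edge_index(predicted_edges)
  tp <- length(intersect(p, g))
  fp <- length(p) - tp
  fn <- length(g) - tp
  tn <- n_pairs - tp - fp - fn
  if (tn < 0) stop_invalid("edge sets exceed the evaluated pair count")
  structure(c(tp = tp, fp = fp, fn = fn, tn = tn), class = "confusion_counts")
}

as_edge_index <- function(x) {
  if (is.matrix(x) && is.logical(x)) return(which(x))
  if (is.matrix(x) && ncol(x) == 2L) return(paste(x[, 1L], x[, 2L]))
  if (is.matrix(x)) return(which(x != 0))
  unique(x)
}

#' Classification metrics from confusion counts
#'
#' The study's accuracy measures: recall/true-positive rate
#' `TP / (TP + FN)`, false-positive rate `FP / (FP + TN)`, precision
#' `TP / (TP + FP)`, Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` and F1-score
#' `2 * precision * recall / (precision + recall)`. Zero-denominator
#' conventions: MCC is 0 whenever any marginal is 0; F1 is 0 when
#' `precision + recall = 0`; precision of an empty prediction is 1 (the
#' precision-axis anchor of the PR curve).
#'
#' @param counts a [confusion_counts()] object or named vector with `tp`,
#'   `fp`, `fn`, `tn`.
#' @return A single number.
#' @name grn_metrics
NULL

cc <- function(counts) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
  as.numeric(counts[c("tp", "fp", "fn", "tn")])
}

#' @rdname grn_metrics
#' @export
tpr_score <- function(counts) { x <- cc(counts); if (x[1] + x[3] == 0) 0 else x[1] / (x[1] + x[3]) }

#' @rdname grn_metrics
#' @export
fpr_score <- function(counts) { x <- cc(counts); if (x[2] + x[4] == 0) 0 else x[2] / (x[2] + x[4]) }

#' @rdname grn_metrics
#' @export
precision_score <- function(counts) { x <- cc(counts); if (x[1] + x[2] == 0) 1 else x[1] / (x[1] + x[2]) }

#' @rdname grn_metrics
#' @export
f1_score <- function(counts) {
  p <- precision_score(counts); r <- tpr_score(counts)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' @rdname grn_metrics
#' @export
mcc_score <- function(counts) {
  x <- cc(counts); tp <- x[1]; fp <- x[2]; fn <- x[3]; tn <- x[4]
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Sparsity sweep of a dense score matrix
#'
#' Materializes the study's unique-value cutoff sweep: every unique absolute
#' score in the prediction is used as a cutoff, an edge being kept iff
#' `|score| >= cutoff`, producing a nested family of binary networks ordered
#' sparsest to densest. Penalty-sweep fits pass through their own networks
#' (reordered sparsest to densest) unchanged. Intended for small problems and
#' tests; [grn_evaluate()] computes the same sweep implicitly without
#' materializing the networks.
#'
#' @param x a dense numeric score matrix or a `grn_fit`.
#' @return List of logical adjacency matrices, sparsest first.
#' @export
threshold_sweep <- function(x) {
  if (inherits(x, "grn_fit") && !is.null(x$sweep)) {
    nets <- x$sweep[order(vapply(x$sweep, sum, integer(1L)))]
    return(nets)
  }
  S <- abs(as.matrix(if (inherits(x, "grn_fit")) x$weights else x))
  if (all(S == 0)) {
    warning("all scores are zero; returning a single empty network")
    return(list(S != 0))
  }
  cuts <- sort(unique(as.vector(S)), decreasing = TRUE)
  lapply(cuts, function(ct) S >= ct)
}

# ---- core evaluation -------------------------------------------------------

#' Evaluate a predicted network against the true network
#'
#' Implements the full accuracy protocol: selfloop policy, sparsity sweep,
#' per-cutoff confusion counts on directed gene pairs (sign ignored), and the
#' derived precision-recall / ROC curves, AUPR, AUROC, maximum F1, maximum
#' MCC and the maximum-F1 edge set.
#'
#' **Selfloop policy** (`selfloops = "policy"`): P-based predictions are
#' scored over all `N^2` ordered pairs with the true selfloops kept in the
#' gold standard; expression-only (non-P-based) predictions, which never
#' infer selfloops, are scored over the `N^2 - N` off-diagonal pairs with
#' selfloops removed from the gold standard, so they are not charged false
#' negatives for edges they cannot predict. `"keep"`/`"drop"` force either
#' behaviour, and `"strip_all"` removes the diagonal for every method (the
#' supplementary variant in which only high-noise accuracy changes much).
#'
#' **Sweep**: dense predictions are thresholded at every unique absolute
#' score (edge kept iff `|score| >= cutoff`); penalty-sweep fits contribute
#' one point per penalty network. Tied scores enter and leave together.
#'
#' **Curve areas**: AUPR is the trapezoidal area over the achieved
#' (recall, precision) points, anchored at recall 0 with the sparsest
#' point's precision (precision 1 when the sparsest network is empty); no
#' unachieved dense-end point is fabricated. AUROC is the trapezoidal area
#' over (FPR, TPR) anchored at (0,0) and (1,1). Random predictions score
#' AUPR near the edge prevalence and AUROC near 0.5.
#'
#' @param fit a `grn_fit` from [grn_infer()], or a dense numeric score matrix
#'   (treated as a directed P-based-style prediction).
#' @param gold the true [grn_network()] (or matrix); nonzero entries are the
#'   gold edges, signs ignored.
#' @param selfloops `"policy"` (default), `"keep"`, `"drop"` or `"strip_all"`.
#' @return An object of class `grn_eval`: list with `points` (one row per
#'   sweep cutoff, sparsest first: predicted links, confusion counts,
#'   precision, recall, fpr, f1, mcc), `aupr`, `auroc`, `max_f1`, `max_mcc`,
#'   `max_f1_edges` (two-column target/regulator index matrix, with linear
#'   indices in attribute `"index"`), `evaluated_pairs`, `prevalence`, and
#'   the applied `selfloops` mode.
#' @examples
#' net <- random_grn(15, seed = 3)
#' P <- perturbation_design(15)
#' Y <- simulate(net, design = P)  # noise-free
#' ev <- grn_evaluate(grn_infer(Y, P, method = "ls"), net)
#' c(ev$aupr, ev$max_f1)  # exact recovery: both 1
#' @export
grn_evaluate <- function(fit, gold, selfloops = c("policy", "keep", "drop", "strip_all")) {
  selfloops <- match.arg(selfloops)
  G <- as.matrix(gold)
  n <- nrow(G)
  if (nrow(G) != ncol(G)) stop_invalid("'gold' must be square")
  if (inherits(fit, "grn_fit")) {
    if (length(fit$gene_ids) && length(rownames(G)) &&
        !identical(fit$gene_ids, rownames(G)))
      stop_invalid("gene sets of prediction and gold standard differ")
    category <- fit$category
  } else {
    fit <- list(weights = as.matrix(fit), sweep = NULL, method = "scores",
                category = "p_based")
    category <- "p_based"
  }
  include_diag <- switch(selfloops,
    policy = category == "p_based",
    keep = TRUE, drop = FALSE, strip_all = FALSE)
  keep <- if (include_diag) rep(TRUE, n * n) else as.vector(row(G) != col(G))
  n_pairs <- sum(keep)
  gvec <- (as.vector(G) != 0) & keep
  n_gold <- sum(gvec)

  if (is.null(fit$sweep)) {
    pts <- dense_sweep_points(abs(as.vector(fit$weights)), gvec, keep)
  } else {
    pts <- network_sweep_points(fit$sweep, gvec, keep)
  }
  finish_eval(pts, n_pairs, n_gold, n, selfloops, fit, keep)
}

# Unique-cutoff sweep on a dense score vector, cumulative and vectorized.
# Returns points ordered sparsest -> densest plus the edge order needed to
# reconstruct any cutoff's edge set.
dense_sweep_points <- function(scores, gvec, keep) {
  idx <- which(keep)
  s <- scores[idx]; g <- gvec[idx]
  if (all(s == 0)) {
    warning("all prediction scores are zero; the sweep has a single empty network")
    return(list(df = data.frame(cutoff = NA_real_, pp = 0L, tp = 0L),
                order = integer(0), full_index = idx))
  }
  o <- order(s, decreasing = TRUE)
  s <- s[o]; g <- g[o]
  brk <- c(which(diff(s) != 0), length(s))   # last position of each unique value
  list(df = data.frame(cutoff = s[brk], pp = brk, tp = cumsum(g)[brk]),
       order = o, full_index = idx)
}

network_sweep_points <- function(nets, gvec, keep) {
  pts <- vapply(nets, function(net) {
    pv <- as.vector(net) & keep
    c(pp = sum(pv), tp = sum(pv & gvec))
  }, numeric(2L))
  df <- data.frame(cutoff = NA_real_, pp = pts["pp", ], tp = pts["tp", ],
                   sweep_index = seq_along(nets))
  df <- df[order(df$pp, df$tp), , drop = FALSE]
  list(df = df, order = NULL, full_index = which(keep))
}

finish_eval <- function(pts, n_pairs, n_gold, n, selfloops, fit, keep) {
  df <- pts$df
  df$pp <- as.double(df$pp); df$tp <- as.double(df$tp)  # avoid integer overflow in MCC
  df$fp <- df$pp - df$tp
  df$fn <- n_gold - df$tp
  df$tn <- n_pairs - n_gold - df$fp
  df$precision <- ifelse(df$pp > 0, df$tp / df$pp, 1)
  df$recall <- if (n_gold > 0) df$tp / n_gold else 0
  df$fpr <- if (n_pairs > n_gold) df$fp / (n_pairs - n_gold) else 0
  df$f1 <- ifelse(df$precision + df$recall > 0,
                  2 * df$precision * df$recall / (df$precision + df$recall), 0)
  den <- (df$tp + df$fp) * (df$tp + df$fn) * (df$tn + df$fp) * (df$tn + df$fn)
  df$mcc <- ifelse(den > 0, (df$tp * df$tn - df$fp * df$fn) / sqrt(den), 0)

  # AUPR: anchor at recall 0 with the sparsest achieved precision
  o <- order(df$recall, df$pp)
  rec <- df$recall[o]; prec <- df$precision[o]
  p0 <- df$precision[which.min(df$pp)]
  rr <- c(0, rec); qq <- c(p0, prec)
  aupr <- sum(diff(rr) * (utils::head(qq, -1) + utils::tail(qq, -1)) / 2)
  # AUROC: anchors (0,0) and (1,1)
  o2 <- order(df$fpr, df$recall)
  xx <- c(0, df$fpr[o2], 1); yy <- c(0, df$recall[o2], 1)
  auroc <- sum(diff(xx) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)

  best <- which.max(df$f1)  # ties: df is sparsest-first, so the sparser wins
  if (!is.null(pts$order)) {                 # dense sweep: top-ranked pairs
    edge_idx <- sort(pts$full_index[pts$order[seq_len(df$pp[best])]])
  } else if (!is.null(df$sweep_index)) {     # penalty sweep: that network's pairs
    edge_idx <- which(as.vector(fit$sweep[[df$sweep_index[best]]]) & keep)
  } else edge_idx <- integer(0)
  edges <- cbind(target = (edge_idx - 1L) %% n + 1L,
                 regulator = (edge_idx - 1L) %/% n + 1L)
  attr(edges, "index") <- edge_idx

  structure(list(points = df, aupr = aupr, auroc = auroc,
                 max_f1 = max(df$f1), max_mcc = max(df$mcc),
                 max_f1_edges = edges, evaluated_pairs = n_pairs,
                 n_gold = n_gold,
                 prevalence = if (n_pairs > 0) n_gold / n_pairs else NA_real_,
                 selfloops = selfloops, method = fit$method,
                 category = fit$category),
            class = "grn_eval")
}

#' Maximum-F1 network of an evaluation
#'
#' @param eval a `grn_eval`.
#' @return Two-column (target, regulator) index matrix of the F1-maximizing
#'   sweep point, with linear matrix indices in attribute `"index"`.
#' @export
max_f1_network <- function(eval) {
  stopifnot(inherits(eval, "grn_eval"))
  eval$max_f1_edges
}

#' Jaccard index of two edge sets
#'
#' `|A intersect B| / |A union B|`; 1 when both sets are empty (identical
#' predictions), by convention.
#'
#' @param a,b edge sets: logical matrices, linear index vectors, or the
#'   `max_f1_edges` of a [grn_evaluate()] result.
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  ia <- edge_set_index(a); ib <- edge_set_index(b)
  u <- length(union(ia, ib))
  if (u == 0) return(1)
  length(intersect(ia, ib)) / u
}

#' Fraction of a shared prediction confirmed by the truth
#'
#' `|A intersect B intersect gold| / |A intersect B|`: how much of the overlap
#' between two methods' predictions lies in the true network. `NA` when the
#' overlap is empty (undefined).
#'
#' @param a,b edge sets as in [jaccard_index()].
#' @param gold the true network (matrix) or its edge index set.
#' @return A number in `[0, 1]`, or `NA` for an empty overlap.
#' @export
true_fraction <- function(a, b, gold) {
  ov <- intersect(edge_set_index(a), edge_set_index(b))
  if (length(ov) == 0) return(NA_real_)
  length(intersect(ov, edge_set_index(gold))) / length(ov)
}

edge_set_index <- function(x) {
  if (is.matrix(x) && !is.null(attr(x, "index"))) return(attr(x, "index"))
  if (is.matrix(x) && is.logical(x)) return(which(x))
  if (is.matrix(x) && ncol(x) != 2L) return(which(as.matrix(x) != 0))
  if (is.matrix(x) && ncol(x) == 2L)
    stop_invalid("two-column edge matrices need the matrix size; pass linear indices instead")
  as.vector(x)
}

#' @export
print.grn_eval <- function(x, ...) {
  cat(sprintf("GRN evaluation ('%s', selfloops: %s): %d pairs, %d gold edges (prevalence %.4f)\n",
              x$method %||% "scores", x$selfloops, x$evaluated_pairs, x$n_gold, x$prevalence))
  cat(sprintf("  AUPR %.4f | AUROC %.4f | max F1 %.4f | max MCC %.4f | max-F1 links %d\n",
              x$aupr, x$auroc, x$max_f1, x$max_mcc, nrow(x$max_f1_edges)))
  invisible(x)
}

#' @export
plot.grn_eval <- function(x, which = c("pr", "roc"), ...) {
  which <- match.arg(which)
  df <- x$points
  if (which == "pr") {
    o <- order(df$recall)
    plot(df$recall[o], df$precision[o], type = "l", xlim = c(0, 1), ylim = c(0, 1),
         xlab = "recall", ylab = "precision",
         main = sprintf("PR curve (AUPR %.3f)", x$aupr), ...)
    abline(h = x$prevalence, lty = 3)
  } else {
    o <- order(df$fpr)
    plot(c(0, df$fpr[o], 1), c(0, df$recall[o], 1), type = "l",
         xlab = "FPR", ylab = "TPR",
         main = sprintf("ROC curve (AUROC %.3f)", x$auroc), ...)
    abline(0, 1, lty = 3)
  }
  invisible(x)
}
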