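#' Infer a gene regulatory network from perturbation expression data
#'
#' Central fitting function of the package. Given observed fold-change
#' expression `Y` (genes x experiments) and, for the design-based methods, the
#' perturbation design `P`, it returns a scored GRN estimate as a `grn_fit`
#' object. Two families are implemented:
#'
#' **Design-based (P-based) methods**, which exploit the steady-state model
#' `A %*% Y + P = 0`:
#' \describe{
#'   \item{`"ls"`}{Least squares, `A = -P %*% ginv(Y)` with the Moore-Penrose
#'     pseudo-inverse. Dense signed weights; exact in the noise-free
#'     full-rank case.}
#'   \item{`"lasso"`, `"elnet"`}{Per-target-gene elastic-net regressions
#'     (glmnet) of row `i` of `A` on the predictors `t(Y)` with response
#'     `-P[i, ]`, no intercept, standardized predictors, L1 mixing
#'     `mixing_alpha` = 1 (lasso) or 0.7 (elastic net). The fit is a sparsity
#'     sweep: one binary network (the nonzero support) per penalty in
#'     `penalties`, by default 30 values log-spaced from 1e-6 to 1, spanning
#'     densities from full to empty.}
#'   \item{`"ridge"`}{L2-penalized regression (`mixing_alpha = 0`) computed in
#'     closed form over the same penalty grid; since ridge solutions carry no
#'     exact zeros, the reported network is the dense signed estimate at the
#'     GCV-minimizing grid penalty, to be sparsified downstream by the
#'     unique-value cutoff sweep (the ridge-with-cutoff convention).}
#'   \item{`"zscore"`}{For every gene `i` and perturbation target `j`, the
#'     absolute z-score of gene `i`'s mean expression under the experiments
#'     knocking down `j`, relative to the mean and standard deviation of gene
#'     `i` over all *other* targets (replicates averaged first;
#'     leave-target-out reference). Scores selfloops like any other edge.}
#' }
#'
#' **Expression-only (non-P-based) methods**, which never read `P`:
#' \describe{
#'   \item{`"genie3"`}{Tree-ensemble importance scores in the GENIE3 style:
#'     each gene is regressed on all others with a random forest
#'     (`n_trees` trees, `floor(sqrt(N-1))` candidate predictors per split,
#'     impurity importance = total variance reduction). On single-knockdown
#'     steady-state data the reversed orientation of the importance matrix is
#'     markedly more accurate, so `orientation = "reversed"` is the default;
#'     `"natural"` emits the textbook predictor-to-target direction.
#'     Diagonal forced to 0 (a gene never predicts itself).}
#'   \item{`"clr"`}{CLR-style mutual information: pairwise MI on equal-width
#'     binned profiles (`n_bins` bins), background-corrected per gene
#'     (`z_i = max(0, (MI_ij - mean_i) / sd_i)` over gene `i`'s MI row) and
#'     combined as `sqrt(z_i^2 + z_j^2)`. Symmetric with zero diagonal; when
#'     evaluated as a directed prediction each undirected edge counts in both
#'     directions.}
#' }
#'
#' `method` may also be a user function `function(Y, P, ...)` returning a
#' score matrix, which is wrapped as a directed dense `grn_fit` (category
#' `"p_based"` if the function has a `P` argument in its formals and `P` was
#' supplied).
#'
#' @param Y genes x experiments expression matrix (fold changes).
#' @param P a [perturbation_design()]; required by the P-based methods and
#'   ignored by the others.
#' @param method one of `"ls"`, `"lasso"`, `"elnet"`, `"ridge"`, `"zscore"`,
#'   `"genie3"`, `"clr"`, or a function.
#' @param penalties penalty grid for the penalized methods (default
#'   `10^seq(-6, 0, length.out = 30)`).
#' @param mixing_alpha elastic-net mixing in `[0, 1]`; overrides the
#'   method-implied value (1 for lasso, 0.7 for elnet, 0 for ridge).
#' @param standardize standardize predictors in the glmnet fits (default TRUE).
#' @param n_trees trees per forest for `"genie3"` (study default 1000; tests
#'   and the shipped benchmark profile use 100).
#' @param n_bins equal-width bins for `"clr"` mutual information (default 10).
#' @param orientation `"reversed"` (default) or `"natural"` output orientation
#'   for `"genie3"`.
#' @param seed integer seed for the stochastic methods (`"genie3"`).
#' @param ... passed on to a user-supplied `method` function.
#' @return An object of class `grn_fit` with components `method`, `category`
#'   (`"p_based"`/`"non_p_based"`), `directedness`, and either dense `weights`
#'   or a sparsity `sweep` (list of logical adjacency matrices ordered densest
#'   to sparsest, with the matching `penalties`); penalized fits also carry
#'   the signed `coefficients` array (genes x genes x penalty).
#' @seealso [grn_evaluate()], [grn_benchmark()]
#' @examples
#' net <- random_grn(10, seed = 1)
#' P <- perturbation_design(10, replicates = 2)
#' Y <- simulate(net, design = P, snr = 1, seed = 2)
#' fit <- grn_infer(Y, P, method = "ls")
#' round(coef(fit)[1:3, 1:3], 2)
#' @export
grn_infer <- function(Y, P = NULL,
                      method = c("ls", "lasso", "elnet", "ridge", "zscore", "genie3", "clr"),
                      penalties = 10^seq(-6, 0, length.out = 30),
                      mixing_alpha = NULL, standardize = TRUE,
                      n_trees = 1000L, n_bins = 10L,
                      orientation = c("reversed", "natural"),
                      seed = NULL, ...) {
  Y <- as.matrix(Y)
  if (anyNA(Y) || any(!is.finite(Y))) stop_invalid("'Y' must be finite")
  gene_ids <- rownames(Y) %||% default_gene_ids(nrow(Y))
  cl <- match.call()

  if (is.function(method)) {
    W <- method(Y, P, ...)
    if (inherits(W, "grn_fit")) return(W)
    fit <- new_grn_fit(method = "custom",
                       category = if (!is.null(P) && "P" %in% names(formals(method)))
                         "p_based" else "non_p_based",
                       directedness = if (isTRUE(all.equal(as.matrix(W), t(as.matrix(W)))))
                         "symmetric" else "directed",
                       weights = as.matrix(W), gene_ids = gene_ids, call = cl)
    return(fit)
  }

  method <- match.arg(method)
  need_P <- method %in% c("ls", "lasso", "elnet", "ridge", "zscore")
  if (need_P) {
    if (is.null(P)) stop_invalid("method '", method, "' requires the perturbation design 'P'")
    P <- as.matrix(P)
    if (!all(dim(P) == dim(Y)))
      stop_invalid("'Y' and 'P' must have the same dimensions (genes x experiments)")
  }

  fit <- switch(method,
    ls     = infer_least_squares(Y, P),
    lasso  = infer_penalized(Y, P, mixing_alpha %||% 1, penalties, standardize),
    elnet  = infer_penalized(Y, P, mixing_alpha %||% 0.7, penalties, standardize),
    ridge  = infer_ridge(Y, P, penalties),
    zscore = infer_zscore(Y, P),
    genie3 = infer_tree_ensemble(Y, n_trees = n_trees, seed = seed,
                                 orientation = match.arg(orientation)),
    clr    = infer_clr(Y, n_bins = n_bins))
  fit$gene_ids <- gene_ids
  fit$call <- cl
  if (!is.null(fit$weights)) dimnames(fit$weights) <- list(gene_ids, gene_ids)
  fit
}

new_grn_fit <- function(method, category, directedness, weights = NULL,
                        sweep = NULL, coefficients = NULL, penalties = NULL,
                        mixing_alpha = NULL, penalty_selected = NULL,
                        gene_ids = NULL, call = NULL) {
  structure(list(method = method, category = category,
                 directedness = directedness, weights = weights, sweep = sweep,
                 coefficients = coefficients, penalties = penalties,
                 mixing_alpha = mixing_alpha, penalty_selected = penalty_selected,
                 gene_ids = gene_ids, call = call),
            class = "grn_fit")
}

# ---- P-based workers -------------------------------------------------------

infer_least_squares <- function(Y, P) {
  if (all(Y == 0)) stop_invalid("'Y' is identically zero; least squares is degenerate")
  A <- -P %*% MASS::ginv(Y)
  new_grn_fit("ls", "p_based", "directed", weights = A)
}

infer_penalized <- function(Y, P, mixing_alpha, penalties, standardize = TRUE) {
  if (!is.numeric(mixing_alpha) || mixing_alpha < 0 || mixing_alpha > 1)
    stop_invalid("'mixing_alpha' must lie in [0, 1]")
  if (mixing_alpha == 0) return(infer_ridge(Y, P, penalties))
  if (length(penalties) < 1L || any(penalties <= 0))
    stop_invalid("'penalties' must be positive")
  lam <- sort(penalties)            # ascending: densest fit first
  lam_desc <- rev(lam)              # glmnet wants a decreasing path
  n <- nrow(Y); K <- length(lam)
  co <- array(0, c(n, n, K))
  X <- t(Y)
  for (i in seq_len(n)) {
    y <- -P[i, ]
    if (all(y == 0)) next           # gene never perturbed: row stays empty
    f <- glmnet::glmnet(X, y, alpha = mixing_alpha, lambda = lam_desc,
                        intercept = FALSE, standardize = standardize,
                        thresh = 1e-11)
    b <- as.matrix(f$beta)
    if (ncol(b) < K)                # path terminated early: carry the last fit
      b <- cbind(b, matrix(b[, ncol(b)], n, K - ncol(b)))
    co[i, , ] <- b[, K:1L]
  }
  # coordinate descent leaves numerical dust well below any statistical
  # coefficient (true interactions are generated at |w| >= 0.1); entries
  # under `coef_zero_tol` are treated as zeros when forming the support
  sweep_nets <- lapply(seq_len(K), function(k) abs(co[, , k]) > coef_zero_tol)
  new_grn_fit(if (mixing_alpha == 1) "lasso" else "elnet", "p_based", "directed",
              sweep = sweep_nets, coefficients = co, penalties = lam,
              mixing_alpha = mixing_alpha)
}

# Numerical-zero tolerance for penalized-sweep supports (see above).
coef_zero_tol <- 1e-4

# Closed-form ridge path sharing one eigendecomposition of Y %*% t(Y).
# Penalty scaling mirrors glmnet's for intercept-free unstandardized fits:
# beta_i = (Y Y^T + (M * lambda / s_i) * I)^{-1} Y (-P_i)^T with
# s_i = sqrt(mean(P_i^2)), glmnet's internal response scaling.
infer_ridge <- function(Y, P, penalties) {
  if (length(penalties) < 1L || any(penalties <= 0))
    stop_invalid("'penalties' must be positive")
  lam <- sort(penalties)
  n <- nrow(Y); M <- ncol(Y); K <- length(lam)
  e <- eigen(tcrossprod(Y), symmetric = TRUE)
  U <- e$vectors
  d <- pmax(e$values, 0)
  s <- sqrt(rowMeans(P^2))
  s[s == 0] <- 1
  B0 <- crossprod(U, tcrossprod(Y, -P))   # n x n, column i belongs to response i
  co <- array(0, c(n, n, K))
  gcv <- numeric(K)
  for (k in seq_len(K)) {
    shrink <- 1 / outer(d, M * lam[k] / s, `+`)       # n x n: 1/(d_r + M lam / s_i)
    Bt <- U %*% (B0 * shrink)                          # columns = beta_i
    co[, , k] <- t(Bt)
    RSS <- colSums((-t(P) - crossprod(Y, Bt))^2)
    df <- colSums(d * shrink)
    gcv[k] <- sum(RSS / (M * (1 - df / M)^2))
  }
  k_best <- which.min(gcv)
  new_grn_fit("ridge", "p_based", "directed",
              weights = co[, , k_best], coefficients = co, penalties = lam,
              mixing_alpha = 0, penalty_selected = lam[k_best])
}

infer_zscore <- function(Y, P) {
  n <- nrow(Y)
  targets <- apply(P != 0, 2L, function(col) if (any(col)) which(col)[1L] else NA_integer_)
  if (anyNA(targets)) stop_invalid("z-score requires every experiment to perturb one gene")
  if (!setequal(unique(targets), seq_len(n)))
    stop_invalid("z-score requires every gene to be perturbed in at least one experiment")
  # replicate-mean response matrix: column j = mean profile under knockdown of j
  Ym <- vapply(seq_len(n), function(j) rowMeans(Y[, targets == j, drop = FALSE]),
               numeric(n))
  Z <- matrix(0, n, n)
  zero_sd <- logical(n)
  for (i in seq_len(n)) {
    x <- Ym[i, ]
    for (j in seq_len(n)) {
      ref <- x[-j]
      s <- stats::sd(ref)
      if (!is.finite(s) || s == 0) { zero_sd[i] <- TRUE; Z[i, j] <- 0 }
      else Z[i, j] <- abs((x[j] - mean(ref)) / s)
    }
  }
  if (any(zero_sd))
    warning("zero reference standard deviation for gene(s) ",
            paste(which(zero_sd), collapse = ", "), "; their scores were set to 0")
  new_grn_fit("zscore", "p_based", "directed", weights = Z)
}

# ---- expression-only workers ----------------------------------------------

infer_tree_ensemble <- function(Y, n_trees = 1000L, seed = NULL,
                                orientation = "reversed") {
  n <- nrow(Y)
  if (n < 2L) stop_invalid("need at least 2 genes")
  if (ncol(Y) < 3L) stop_invalid("need at least 3 experiments")
  if (!is_count(n_trees) || n_trees < 1L) stop_invalid("'n_trees' must be >= 1")
  Xt <- t(Y)
  colnames(Xt) <- default_gene_ids(n)
  W <- matrix(0, n, n)  # natural orientation: row target, column regulator
  for (t in seq_len(n)) {
    rf <- ranger::ranger(x = Xt[, -t, drop = FALSE], y = Y[t, ],
                         num.trees = as.integer(n_trees),
                         mtry = max(1L, floor(sqrt(n - 1))),
                         importance = "impurity", num.threads = 1L,
                         seed = if (is.null(seed)) NULL else derive_seed(seed, "genie3", t))
    W[t, -t] <- rf$variable.importance
  }
  if (orientation == "reversed") W <- t(W)
  diag(W) <- 0
  fit <- new_grn_fit("genie3", "non_p_based", "directed", weights = W)
  fit$orientation <- orientation
  fit
}

infer_clr <- function(Y, n_bins = 10L) {
  n <- nrow(Y); M <- ncol(Y)
  if (n < 2L) stop_invalid("need at least 2 genes")
  if (!is_count(n_bins) || n_bins < 2L) stop_invalid("'n_bins' must be >= 2")
  if (M < n_bins) stop_invalid("need at least as many experiments as bins")
  nb <- as.integer(n_bins)
  # equal-width bin index per gene; constant genes collapse into one bin
  B <- t(apply(Y, 1L, function(x) {
    rng <- range(x)
    if (rng[1L] == rng[2L]) return(rep(1L, length(x)))
    pmin(pmax(findInterval(x, seq(rng[1L], rng[2L], length.out = nb + 1L),
                           all.inside = TRUE), 1L), nb)
  }))
  marg <- lapply(seq_len(n), function(i) tabulate(B[i, ], nb) / M)
  MI <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    bi <- B[i, ]
    for (j in (i + 1L):n) {
      # column-major joint histogram so its layout matches outer(marg_i, marg_j)
      joint <- tabulate(bi + (B[j, ] - 1L) * nb, nb * nb) / M
      pe <- outer(marg[[i]], marg[[j]])
      nz <- joint > 0
      MI[i, j] <- MI[j, i] <- sum(joint[nz] * log(joint[nz] / pe[nz]))
    }
  }
  mu <- rowMeans(MI)
  sg <- apply(MI, 1L, stats::sd)
  Zi <- (MI - mu) / ifelse(sg > 0, sg, 1)
  Zi[Zi < 0] <- 0
  S <- sqrt(Zi^2 + t(Zi)^2)
  diag(S) <- 0
  new_grn_fit("clr", "non_p_based", "symmetric", weights = S)
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.grn_fit <- function(x, ...) {
  cat(sprintf("GRN fit: method '%s' (%s, %s)\n", x$method,
              sub("_", "-", x$category), x$directedness))
  if (!is.null(x$sweep))
    cat(sprintf("  sparsity sweep of %d networks (penalties %.1e..%.1e), densities %d..%d links\n",
                length(x$sweep), min(x$penalties), max(x$penalties),
                sum(x$sweep[[length(x$sweep)]]), sum(x$sweep[[1L]])))
  else
    cat(sprintf("  dense %d x %d score matrix, %d nonzero scores\n",
                nrow(x$weights), ncol(x$weights), sum(x$weights != 0)))
  if (!is.null(x$penalty_selected))
    cat(sprintf("  GCV-selected ridge penalty: %.3g\n", x$penalty_selected))
  invisible(x)
}

#' Extract the estimated network from a fit
#'
#' For dense fits, the signed score matrix; for penalty-sweep fits, the signed
#' coefficient matrix at `penalty` (default: the smallest, densest penalty).
#'
#' @param object a `grn_fit`.
#' @param penalty penalty value at which to extract sweep coefficients.
#' @param ... unused.
#' @return Numeric genes x genes matrix (column regulator, row target).
#' @export
coef.grn_fit <- function(object, penalty = NULL, ...) {
  if (!is.null(object$weights)) return(object$weights)
  k <- if (is.null(penalty)) 1L else which.min(abs(object$penalties - penalty))
  out <- object$coefficients[, , k]
  dimnames(out) <- list(object$gene_ids, object$gene_ids)
  out
}

#' @export
summary.grn_fit <- function(object, ...) {
  A <- coef(object)
  cat(sprintf("GRN fit ('%s', %s)\n", object$method, sub("_", "-", object$category)))
  cat(sprintf("  genes: %d; nonzero off-diagonal scores: %d; selfloop scores: %d\n",
              nrow(A), sum(A[row(A) != col(A)] != 0), sum(diag(A) != 0)))
  if (!is.null(object$sweep)) {
    sizes <- vapply(object$sweep, sum, integer(1L))
    cat(sprintf("  sweep densities (links): min %d, median %.0f, max %d over %d penalties\n",
                min(sizes), stats::median(sizes), max(sizes), length(sizes)))
  }
  invisible(object)
}

#' Predicted steady-state expression from a fitted network
#'
#' Only meaningful for P-based fits with a signed dense estimate: solves
#' `A_hat %*% Y + P = 0` for `Y` given a new design, using the pseudo-inverse
#' of the estimate.
#'
#' @param object a `grn_fit` with dense weights.
#' @param design a [perturbation_design()].
#' @param ... unused.
#' @return Predicted genes x experiments fold-change matrix.
#' @export
predict.grn_fit <- function(object, design, ...) {
  if (is.null(object$weights))
    stop_invalid("predict() needs a dense signed estimate; extract coef() at a penalty instead")
  -MASS::ginv(unclass(object$weights)) %*% as.matrix(design)
}

#' Steady-state residuals of a fitted network
#'
#' @param object a `grn_fit` with dense weights.
#' @param Y observed expression.
#' @param P the perturbation design used for fitting.
#' @param ... unused.
#' @return The residual matrix `A_hat %*% Y + P`.
#' @export
residuals.grn_fit <- function(object, Y, P, ...) {
  if (is.null(object$weights))
    stop_invalid("residuals() needs a dense signed estimate")
  unclass(object$weights) %*% as.matrix(Y) + as.matrix(P)
}

#' @export
plot.grn_fit <- function(x, ...) {
  A <- abs(coef(x))
  n <- nrow(A)
  image(seq_len(n), seq_len(n), t(A)[, n:1],
        col = grDevices::hcl.colors(33, "YlOrRd", rev = TRUE),
        xlab = "regulator", ylab = "target",
        main = sprintf("|scores|, method '%s'", x$method), ...)
  invisible(x)
}
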