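#' Single-target knockdown perturbation designs
#'
#' A perturbation design is a genes x experiments matrix `P` with entries in
#' `{-1, 0, +1}`: -1 marks a knockdown of the row gene in that experiment,
#' +1 an overexpression, 0 no perturbation. Every column perturbs at most one
#' gene (single-target design). `perturbation_design()` builds the standard
#' full design in which each gene is knocked down in `replicates` consecutive
#' experiments, so `P` is `n_genes x (n_genes * replicates)` with columns
#' ordered gene-major, replicate-minor and labelled `"G<g>_r<r>"`.
#'
#' @param n_genes number of genes (>= 1).
#' @param replicates replicates per knockdown (>= 1, default 3).
#' @param gene_ids optional gene labels.
#' @return An object of class `perturbation_design`: the design matrix with a
#'   `targets` attribute giving the perturbed gene index of each column and a
#'   `replicates` attribute.
#' @examples
#' P <- perturbation_design(4, replicates = 2)
#' colSums(P)  # every experiment knocks down exactly one gene
#' @export
perturbation_design <- function(n_genes, replicates = 3L, gene_ids = NULL) {
  if (!is_count(n_genes) || n_genes < 1L) stop_invalid("'n_genes' must be an integer >= 1")
  if (!is_count(replicates) || replicates < 1L) stop_invalid("'replicates' must be an integer >= 1")
  n <- as.integer(n_genes); r <- as.integer(replicates)
  if (is.null(gene_ids)) gene_ids <- default_gene_ids(n)
  P <- matrix(0, n, n * r)
  targets <- rep(seq_len(n), each = r)
  P[cbind(targets, seq_len(n * r))] <- -1
  dimnames(P) <- list(gene_ids,
                      paste0(gene_ids[targets], "_r", rep(seq_len(r), times = n)))
  new_design(P, targets = targets, replicates = r)
}

new_design <- function(P, targets, replicates) {
  structure(P, targets = as.integer(targets), replicates = as.integer(replicates),
            class = c("perturbation_design", "matrix", "array"))
}

#' Coerce a matrix to a perturbation design
#'
#' Validates the single-target property and recovers the per-column targets.
#'
#' @param P genes x experiments matrix with entries in `{-1, 0, 1}`.
#' @param replicates replicate count bookkeeping (default 1).
#' @return A `perturbation_design`.
#' @export
as_perturbation_design <- function(P, replicates = 1L) {
  P <- as.matrix(P)
  if (!all(P %in% c(-1, 0, 1))) stop_invalid("design entries must be in {-1, 0, 1}")
  nz <- colSums(P != 0)
  if (any(nz > 1L)) stop_invalid("each experiment may perturb at most one gene")
  targets <- apply(P != 0, 2L, function(col) if (any(col)) which(col)[1L] else NA_integer_)
  if (is.null(rownames(P))) rownames(P) <- default_gene_ids(nrow(P))
  new_design(P, targets = targets, replicates = replicates)
}

#' Scramble a perturbation design with a random derangement
#'
#' Relabels the perturbed gene of every experiment by a uniformly random
#' derangement of the gene indices (a permutation without fixed points), so no
#' perturbation stays on its true target and the link between the design and
#' the expression it generated is fully broken. Column order, replicate
#' grouping and the entry multiset are preserved. This is the negative control
#' for design-based inference: estimators fed a scrambled design should fall
#' to the random baseline.
#'
#' @param design a `perturbation_design` (single-target).
#' @param seed optional integer seed.
#' @return The scrambled `perturbation_design`.
#' @export
scramble_design <- function(design, seed = NULL) {
  P <- as.matrix(design)
  n <- nrow(P)
  if (n < 2L) stop_invalid("no derangement exists for fewer than 2 genes")
  with_seed(seed, {
    repeat {  # rejection sampling gives the uniform distribution on derangements
      perm <- sample.int(n)
      if (all(perm != seq_len(n))) break
    }
    Ps <- P[order(perm), , drop = FALSE]
    dimnames(Ps) <- dimnames(P)
    old_t <- attr(design, "targets")
    new_t <- if (is.null(old_t)) NULL else perm[old_t]
    new_design(Ps, targets = new_t, replicates = attr(design, "replicates") %||% 1L)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.perturbation_design <- function(x, ...) {
  cat(sprintf("Perturbation design: %d genes x %d experiments, %d replicate(s)/target\n",
              nrow(x), ncol(x), attr(x, "replicates") %||% 1L))
  cat(sprintf("  knockdowns: %d, overexpressions: %d, unperturbed cells: %d\n",
              sum(x == -1), sum(x == 1), sum(x == 0)))
  invisible(x)
}
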