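#' Construct a gene regulatory network object
#'
#' A `grn_network` is a square, signed, weighted adjacency matrix describing a
#' linear gene regulatory system. The direction convention is fixed throughout
#' the package: **columns are regulators, rows are targets**, so entry
#' `(i, j)` is the signed strength of the regulation j -> i and the matrix is
#' conformable with expression in the steady-state model `A %*% Y + P = 0`
#' (`Y` genes x experiments). Diagonal entries are selfloops and model
#' first-order transcript degradation; a stable system has every eigenvalue of
#' `A` in the open left half plane.
#'
#' @param weights square numeric matrix of signed regulatory strengths.
#' @param gene_ids optional character vector of gene labels; defaults to the
#'   dimnames of `weights` or `G1..Gn`.
#' @return An object of class `grn_network`: the weight matrix with gene ids
#'   as dimnames and a `has_selfloops` attribute derived from the diagonal.
#' @seealso [random_grn()], [stabilize_grn()], [steady_state_response()]
#' @export
grn_network <- function(weights, gene_ids = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights) || nrow(weights) < 1L)
    stop_invalid("'weights' must be a square matrix with at least one gene")
  if (!is.numeric(weights) || anyNA(weights) || any(!is.finite(weights)))
    stop_invalid("'weights' must be finite and numeric")
  n <- nrow(weights)
  if (is.null(gene_ids)) gene_ids <- rownames(weights)
  if (is.null(gene_ids)) gene_ids <- default_gene_ids(n)
  if (length(gene_ids) != n) stop_invalid("'gene_ids' must have one label per gene")
  dimnames(weights) <- list(gene_ids, gene_ids)
  structure(weights,
            has_selfloops = any(diag(weights) != 0),
            class = c("grn_network", "matrix", "array"))
}

#' Generate a random stable scale-free gene regulatory network
#'
#' Draws a signed, directed network with a heavy-tailed (scale-free-like)
#' degree distribution, adds a degradation selfloop to every gene, and
#' stabilizes the system. The off-diagonal topology is sampled with igraph's
#' static fitness scale-free model (power-law expected degrees, exponent 2.5
#' for both in- and out-degrees), which realises preferential attachment with
#' an exact total link count. `avg_links` is the total link budget per gene
#' *including* the selfloop, so `round(n_genes * (avg_links - 1))` off-diagonal
#' links are drawn; with the default 3 links per node a 100-gene network
#' carries about 200 regulatory edges plus 100 selfloops.
#'
#' Off-diagonal weights have magnitudes uniform on `[0.1, 1]` (so no generated
#' interaction is undetectably weak) and independent random signs. Selfloops
#' are set to -1 (unit degradation, the standard linearised-kinetics
#' convention), then [stabilize_grn()] deepens them uniformly if any eigenvalue
#' real part exceeds `-margin`.
#'
#' @param n_genes number of genes (>= 2).
#' @param avg_links average links per gene including the selfloop; must be at
#'   least 1 and strictly less than `n_genes`.
#' @param seed optional integer seed; the same seed reproduces the network
#'   bit for bit.
#' @param margin stability margin passed to [stabilize_grn()].
#' @param gene_ids optional gene labels.
#' @return A stable [grn_network()].
#' @examples
#' net <- random_grn(50, avg_links = 3, seed = 1)
#' sum(net[row(net) != col(net)] != 0)  # ~ 100 regulatory links
#' @export
random_grn <- function(n_genes, avg_links = 3, seed = NULL, margin = 0.1,
                       gene_ids = NULL) {
  if (!is_count(n_genes) || n_genes < 2L)
    stop_invalid("'n_genes' must be an integer >= 2")
  if (!is.numeric(avg_links) || length(avg_links) != 1L || avg_links < 1)
    stop_invalid("'avg_links' must be a number >= 1")
  if (avg_links >= n_genes)
    stop_invalid("'avg_links' must be smaller than 'n_genes' (cannot exceed full density)")
  with_seed(seed, {
    n <- as.integer(n_genes)
    n_links <- max(0L, as.integer(round(n * (avg_links - 1))))
    A <- matrix(0, n, n)
    if (n_links > 0L) {
      g <- igraph::sample_fitness_pl(n, n_links, exponent.out = 2.5, exponent.in = 2.5)
      el <- igraph::as_edgelist(g, names = FALSE)
      w <- stats::runif(nrow(el), 0.1, 1) * sample(c(-1, 1), nrow(el), replace = TRUE)
      A[cbind(el[, 2L], el[, 1L])] <- w  # column regulator -> row target
    }
    diag(A) <- -1
    stabilize_grn(grn_network(A, gene_ids = gene_ids), margin = margin)
  })
}

#' Stabilize a network by deepening its selfloops
#'
#' Shifts the whole diagonal by `-(max Re(eig) + margin)` whenever the largest
#' eigenvalue real part exceeds `-margin`. The sparsity pattern and all
#' off-diagonal signs are untouched, every diagonal entry becomes strictly
#' negative, and the returned system satisfies `max Re(eig(A)) <= -margin`, so
#' it is invertible and its steady state is well defined.
#'
#' @param network a [grn_network()] (or square matrix).
#' @param margin required spectral margin, a positive real (default 0.1).
#' @return A stable `grn_network` with the same topology.
#' @export
stabilize_grn <- function(network, margin = 0.1) {
  A <- unclass(as.matrix(network))
  if (nrow(A) != ncol(A)) stop_invalid("'network' must be square")
  if (!is.numeric(margin) || margin <= 0) stop_invalid("'margin' must be positive")
  ev <- max(Re(eigen(A, only.values = TRUE)$values))
  if (ev > -margin) diag(A) <- diag(A) - (ev + margin)
  grn_network(A, gene_ids = rownames(A))
}

#' Is a network stable?
#'
#' @param network a [grn_network()] or square matrix.
#' @param margin spectral margin; stability means `max Re(eig) < -margin`
#'   (use `margin = 0` for plain Hurwitz stability).
#' @return `TRUE` if all eigenvalues have real part below `-margin`.
#' @export
grn_is_stable <- function(network, margin = 0) {
  A <- unclass(as.matrix(network))
  max(Re(eigen(A, only.values = TRUE)$values)) < -margin
}

#' @export
print.grn_network <- function(x, ...) {
  n <- nrow(x)
  off <- sum(x[row(x) != col(x)] != 0)
  cat(sprintf("Gene regulatory network: %d genes, %d regulatory links (%.2f links/gene), %d selfloops\n",
              n, off, off / n, sum(diag(x) != 0)))
  cat(sprintf("  stable: %s; convention: entry (i, j) = regulation %s\n",
              grn_is_stable(x), "j -> i (column regulator, row target)"))
  invisible(x)
}

#' @export
plot.grn_network <- function(x, ...) {
  n <- nrow(x)
  image(seq_len(n), seq_len(n), t(unclass(x))[, n:1],
        col = grDevices::hcl.colors(33, "Blue-Red 3"),
        xlab = "regulator", ylab = "target", main = "GRN weights", ...)
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

#' Read and write networks and matrices as TSV
#'
#' Dense matrices (networks, designs, expression) are written as TSV with row
#' ids in the first column and column ids in the header; networks can also be
#' exchanged as edge lists with columns `source` (regulator), `target`
#' and `weight`.
#'
#' @param x matrix-like object to write.
#' @param file path of the TSV file.
#' @return Readers return a numeric matrix (with dimnames) or a
#'   `grn_network`; writers return `file` invisibly.
#' @name grn_io
NULL

#' @rdname grn_io
#' @export
write_matrix_tsv <- function(x, file) {
  m <- as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- default_gene_ids(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- paste0("C", seq_len(ncol(m)))
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname grn_io
#' @export
read_matrix_tsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname grn_io
#' @export
write_grn_tsv <- function(x, file) write_matrix_tsv(as.matrix(x), file)

#' @rdname grn_io
#' @export
read_grn_tsv <- function(file) grn_network(read_matrix_tsv(file))

#' @rdname grn_io
#' @export
write_edge_list <- function(x, file) {
  m <- as.matrix(x)
  if (is.null(rownames(m))) dimnames(m) <- list(default_gene_ids(nrow(m)),
                                                default_gene_ids(ncol(m)))
  idx <- which(m != 0, arr.ind = TRUE)
  df <- data.frame(source = colnames(m)[idx[, 2L]],
                   target = rownames(m)[idx[, 1L]],
                   weight = m[idx])
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname grn_io
#' @param gene_ids gene universe for [read_edge_list()]; defaults to the union
#'   of sources and targets, sorted.
#' @export
read_edge_list <- function(file, gene_ids = NULL) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "weight") %in% names(df)))
    stop_invalid("edge list must have columns source, target, weight")
  if (is.null(gene_ids)) gene_ids <- sort(unique(c(df$source, df$target)))
  m <- matrix(0, length(gene_ids), length(gene_ids),
              dimnames = list(gene_ids, gene_ids))
  m[cbind(match(df$target, gene_ids), match(df$source, gene_ids))] <- df$weight
  grn_network(m)
}
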