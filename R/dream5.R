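#' Read DREAM5-style expression and chip-feature tables
#'
#' The supported dialect mirrors the DREAM5 distribution: a tab-separated
#' expression table with chip ids in the first column and gene ids in the
#' header (one row per chip), and a tab-separated "chip features" table whose
#' first column is the chip id and whose remaining columns include an
#' experiment-group number plus perturbation annotations (`DeletedGenes`,
#' `OverexpressedGenes`, and optionally a knockdown column). Column name
#' matching is case-insensitive and tolerant of decorations like a leading
#' `#`.
#'
#' @param file path to the TSV file.
#' @return `read_dream5_expression()`: a genes x chips numeric matrix.
#'   `read_chip_features()`: a data.frame with normalized column names
#'   `chip`, `experiment`, `deleted`, `overexpressed`, `knockdown` (missing
#'   annotation columns come back as empty strings).
#' @name dream5_io
#' @export
read_dream5_expression <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1L, drop = FALSE]))
  colnames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname dream5_io
#' @export
read_chip_features <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(gsub("[^a-z]", "", tolower(names(df))))
  pick <- function(pattern) {
    hit <- grep(pattern, nm)
    if (length(hit)) as.character(df[[hit[1L]]]) else rep("", nrow(df))
  }
  out <- data.frame(chip = as.character(df[[1L]]),
                    experiment = pick("experiment"),
                    deleted = pick("deleted"),
                    overexpressed = pick("overexpress"),
                    knockdown = pick("knockdown"),
                    stringsAsFactors = FALSE)
  for (col in c("deleted", "overexpressed", "knockdown"))
    out[[col]][is.na(out[[col]])] <- ""
  out
}

#' Extract the known-target perturbation subset from DREAM5-style tables
#'
#' Keeps only the chips whose `DeletedGenes` (knockout) or
#' `OverexpressedGenes` annotation names a single gene present in the
#' expression matrix. Chips of the same experiment group carrying no
#' perturbation annotation are the group's controls; their per-gene average
#' is the reference from which fold changes are computed by subtraction (the
#' expression scale is already log-normalized). Knockdown-annotated chips are
#' discarded (their targets are unspecified in DREAM5), as are chips naming
#' several genes or both a deletion and an overexpression. Perturbed chips
#' whose group has no control, or whose target is not measured, are dropped
#' with a warning.
#'
#' @param expression genes x chips numeric matrix
#'   (see [read_dream5_expression()]).
#' @param features chip-feature table (see [read_chip_features()]).
#' @param genes `"all"` (default) keeps every measured gene in the output;
#'   `"perturbed"` restricts rows to the perturbed targets.
#' @return List with `expression` (genes x kept-chips fold changes), `design`
#'   (a [perturbation_design()] with -1 for deletions, +1 for
#'   overexpressions), and `gene_ids`.
#' @export
extract_known_targets <- function(expression, features, genes = c("all", "perturbed")) {
  genes <- match.arg(genes)
  expression <- as.matrix(expression)
  if (is.null(rownames(expression))) stop_invalid("expression needs gene ids as rownames")
  feat <- features[match(colnames(expression), features$chip), , drop = FALSE]
  if (anyNA(feat$chip)) stop_invalid("every expression column must appear in the chip features")

  multi <- function(x) grepl(",", x)
  is_kd <- feat$knockdown != ""
  is_del <- feat$deleted != "" & !is_kd
  is_oe <- feat$overexpressed != "" & !is_kd
  conflicted <- is_del & is_oe
  usable_del <- is_del & !conflicted & !multi(feat$deleted)
  usable_oe <- is_oe & !conflicted & !multi(feat$overexpressed)
  dropped_multi <- (is_del & multi(feat$deleted)) | (is_oe & multi(feat$overexpressed))
  if (any(dropped_multi | conflicted))
    warning(sum(dropped_multi | conflicted),
            " chip(s) with multi-gene or conflicting annotations dropped")
  is_control <- !is_kd & feat$deleted == "" & feat$overexpressed == ""

  target <- ifelse(usable_del, feat$deleted, ifelse(usable_oe, feat$overexpressed, ""))
  sign_ <- ifelse(usable_del, -1, ifelse(usable_oe, 1, 0))
  keep <- which(target != "")

  measured <- target[keep] %in% rownames(expression)
  if (any(!measured))
    warning(sum(!measured), " perturbed chip(s) dropped: target gene not measured")
  keep <- keep[measured]

  ctrl_mean <- function(group) {
    ctrl <- which(is_control & feat$experiment == group)
    if (!length(ctrl)) return(NULL)
    rowMeans(expression[, ctrl, drop = FALSE])
  }
  group_means <- lapply(stats::setNames(nm = unique(feat$experiment[keep])), ctrl_mean)
  has_ctrl <- !vapply(group_means[feat$experiment[keep]], is.null, logical(1L))
  if (any(!has_ctrl))
    warning(sum(!has_ctrl), " perturbed chip(s) dropped: no control in their experiment group")
  keep <- keep[has_ctrl]

  gene_ids <- if (genes == "all") rownames(expression)
              else unique(target[keep])
  fc <- matrix(0, length(gene_ids), length(keep),
               dimnames = list(gene_ids, feat$chip[keep]))
  P <- matrix(0, length(gene_ids), length(keep),
              dimnames = dimnames(fc))
  for (k in seq_along(keep)) {
    chip <- keep[k]
    ref <- group_means[[feat$experiment[chip]]]
    fc[, k] <- expression[gene_ids, chip] - ref[gene_ids]
    P[match(target[chip], gene_ids), k] <- sign_[chip]
  }
  list(expression = fc, design = as_perturbation_design(P), gene_ids = gene_ids)
}

#' Generate a synthetic DREAM5-style fixture
#'
#' Writes a small synthetic expression + chip-features pair in the supported
#' DREAM5 dialect, together with the analytically known expected extraction
#' (fold changes, design, kept chips), for offline testing of
#' [extract_known_targets()]. Each experiment group receives one or two
#' control chips, a knockout chip, and optionally an overexpression chip, a
#' knockdown chip (which extraction must discard) and a multi-gene deletion
#' chip (ditto).
#'
#' @param n_genes number of genes.
#' @param n_groups number of experiment groups.
#' @param seed integer seed.
#' @param dir directory in which `expression.tsv` and `chip_features.tsv`
#'   are written; defaults to a temporary directory.
#' @return List with file paths (`expression_file`, `features_file`) and the
#'   expected outputs (`expression`, `design` as a plain matrix, `chips`).
#' @export
make_dream5_fixture <- function(n_genes = 8L, n_groups = 3L, seed = 1L,
                                dir = tempfile("dream5_fixture_")) {
  stopifnot(n_genes >= 2L, n_groups >= 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    gene_ids <- default_gene_ids(n_genes)
    chips <- list()  # each: chip, experiment, deleted, over, kd
    expr_cols <- list()
    expected_fc <- list(); expected_sign <- c(); expected_target <- c()
    chip_no <- 0L
    for (g in seq_len(n_groups)) {
      base <- stats::rnorm(n_genes, mean = 5)
      n_ctrl <- sample(1:2, 1L)
      ctrl_vals <- replicate(n_ctrl, base + stats::rnorm(n_genes, sd = 0.05))
      ctrl_mean <- rowMeans(ctrl_vals)
      for (cix in seq_len(n_ctrl)) {
        chip_no <- chip_no + 1L
        id <- sprintf("chip%02d", chip_no)
        chips[[id]] <- c(id, g, "", "", "")
        expr_cols[[id]] <- ctrl_vals[, cix]
      }
      # knockout of a random gene
      chip_no <- chip_no + 1L
      id <- sprintf("chip%02d", chip_no)
      ko <- sample(gene_ids, 1L)
      v <- base + stats::rnorm(n_genes, sd = 0.05); v[match(ko, gene_ids)] <- 0
      chips[[id]] <- c(id, g, ko, "", "")
      expr_cols[[id]] <- v
      expected_fc[[id]] <- v - ctrl_mean
      expected_sign <- c(expected_sign, -1); expected_target <- c(expected_target, ko)
      # overexpression in every second group
      if (g %% 2L == 0L) {
        chip_no <- chip_no + 1L
        id <- sprintf("chip%02d", chip_no)
        oe <- sample(gene_ids, 1L)
        v <- base + stats::rnorm(n_genes, sd = 0.05); v[match(oe, gene_ids)] <- 10
        chips[[id]] <- c(id, g, "", oe, "")
        expr_cols[[id]] <- v
        expected_fc[[id]] <- v - ctrl_mean
        expected_sign <- c(expected_sign, 1); expected_target <- c(expected_target, oe)
      }
      # a knockdown chip (target unspecified -> must be discarded)
      chip_no <- chip_no + 1L
      id <- sprintf("chip%02d", chip_no)
      chips[[id]] <- c(id, g, "", "", "yes")
      expr_cols[[id]] <- base + stats::rnorm(n_genes, sd = 0.05)
      # a multi-gene deletion (must be discarded)
      if (g == 1L && n_genes >= 3L) {
        chip_no <- chip_no + 1L
        id <- sprintf("chip%02d", chip_no)
        chips[[id]] <- c(id, g, paste(gene_ids[1:2], collapse = ","), "", "")
        expr_cols[[id]] <- base + stats::rnorm(n_genes, sd = 0.05)
      }
    }
    expr <- do.call(cbind, expr_cols)
    rownames(expr) <- gene_ids
    feat <- as.data.frame(do.call(rbind, chips), stringsAsFactors = FALSE)
    names(feat) <- c("#Chip", "Experiment", "DeletedGenes", "OverexpressedGenes",
                     "KnockdownGenes")

    expression_file <- file.path(dir, "expression.tsv")
    edf <- data.frame(chip = colnames(expr), t(expr), check.names = FALSE)
    utils::write.table(edf, expression_file, sep = "\t", quote = FALSE, row.names = FALSE)
    features_file <- file.path(dir, "chip_features.tsv")
    utils::write.table(feat, features_file, sep = "\t", quote = FALSE, row.names = FALSE)

    kept <- names(expected_fc)
    fc <- if (length(kept)) do.call(cbind, expected_fc) else
      matrix(0, n_genes, 0)
    if (length(kept)) dimnames(fc) <- list(gene_ids, kept)
    design <- matrix(0, n_genes, length(kept), dimnames = list(gene_ids, kept))
    if (length(kept))
      design[cbind(match(expected_target, gene_ids), seq_along(kept))] <- expected_sign
    list(expression_file = expression_file, features_file = features_file,
         expression = fc, design = design, chips = kept)
  })
}
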