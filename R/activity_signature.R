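# Expression normalization, a documented simple differential-expression
# substitute, direction-weighted signature construction, and the weighted,
# rank-based and gene-set activity scores.

#' Normalize a counts matrix to per-gene z-scores
#'
#' Computes, per gene, z-scores of median-centered log2-transformed counts:
#' `z[g, s] = (x[g, s] - median_s x[g, .]) / sd_s x[g, .]` with
#' `x = log2(count + pseudocount)` and the sample (n-1) standard deviation.
#' Genes constant across samples get an all-zero row and are flagged in
#' `attr(, "constant_genes")`.
#'
#' @param counts Non-negative genes-by-samples matrix ([read_counts()]).
#' @param pseudocount Added before the log2 transform (default 1).
#' @return A numeric matrix of the same shape, with
#'   `attr(, "constant_genes")` naming flagged genes.
#' @export
normalize_counts <- function(counts, pseudocount = 1) {
  if (ncol(counts) < 2L) {
    stop("normalization needs >= 2 samples (sd undefined)", call. = FALSE)
  }
  x <- log2(counts + pseudocount)
  med <- apply(x, 1L, stats::median)
  sds <- apply(x, 1L, stats::sd)
  constant <- sds == 0 | is.na(sds)
  sds[constant] <- 1
  z <- (x - med) / sds
  z[constant, ] <- 0
  attr(z, "constant_genes") <- rownames(counts)[constant]
  z
}

#' Log2 counts-per-million
#'
#' @param counts Non-negative genes-by-samples matrix.
#' @param pseudocount Added to CPM before the log2 transform (default 1).
#' @return Numeric matrix of `log2(cpm + pseudocount)`.
#' @export
log2_cpm <- function(counts, pseudocount = 1) {
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero library size", call. = FALSE)
  log2(t(t(counts) / lib) * 1e6 + pseudocount)
}

#' Simple nonparametric differential expression
#'
#' A deliberately simple, documented substitute for a full count-model DE
#' stage: per gene, a two-sided Mann-Whitney U test with continuity
#' correction on log2 CPM between the two groups, with
#' `log2fc = mean(log2 CPM group2) - mean(log2 CPM group1)` and BH-adjusted
#' p-values. It performs no covariate adjustment; externally produced DE
#' tables (e.g. from a negative-binomial GLM with covariates) can be supplied
#' to [build_signature()] instead.
#'
#' @param counts Genes-by-samples matrix.
#' @param group_labels Character/factor vector over samples with exactly two
#'   levels; `log2fc` is `levels[2]` (e.g. mutant) minus `levels[1]`
#'   (e.g. unaltered). Each group needs >= 2 samples.
#' @param levels Optional explicit 2-vector fixing (reference, test) order;
#'   defaults to `c("unaltered", "mutant")` when those labels are used,
#'   otherwise sorted unique labels.
#' @return A `data.frame` with columns `gene`, `log2fc`, `p`, `padj`.
#' @export
simple_de <- function(counts, group_labels, levels = NULL) {
  stopifnot(length(group_labels) == ncol(counts))
  labs <- as.character(group_labels)
  if (is.null(levels)) {
    levels <- if (setequal(unique(labs), c("mutant", "unaltered")))
      c("unaltered", "mutant") else sort(unique(labs))
  }
  if (length(levels) != 2L || !setequal(unique(labs), levels)) {
    stop("group_labels must take exactly the two values in 'levels'",
         call. = FALSE)
  }
  g1 <- which(labs == levels[1L]); g2 <- which(labs == levels[2L])
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  lc <- log2_cpm(counts)
  p <- vapply(seq_len(nrow(lc)), function(i) {
    mann_whitney_cc(lc[i, g2], lc[i, g1])$p
  }, numeric(1))
  data.frame(
    gene = rownames(counts),
    log2fc = rowMeans(lc[, g2, drop = FALSE]) -
      rowMeans(lc[, g1, drop = FALSE]),
    p = p,
    padj = p_adjust(p, "bh"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a direction-weighted signature from DE results
#'
#' Selects genes with `padj < padj_max` and `|log2fc| >= min_abs_lfc`
#' (genes with `log2fc == 0` are excluded) and assigns directions and
#' weights: genes up in the test (mutant) group get weight -1, genes down
#' get weight +1, so that low weighted scores reflect low activity of the
#' disrupted gene.
#'
#' @param de A DE table with columns `gene`, `log2fc`, `padj` (see
#'   [simple_de()]; external DE tables are accepted).
#' @param padj_max Adjusted-p threshold (default 0.05, strict `<`).
#' @param min_abs_lfc Minimum absolute log2 fold change (default 0).
#' @return A `data.frame` with columns `gene`, `direction` (`"up"`/`"down"`
#'   in mutant), `weight` (-1/+1).
#' @export
build_signature <- function(de, padj_max = 0.05, min_abs_lfc = 0) {
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(de)))
  keep <- !is.na(de$padj) & de$padj < padj_max &
    abs(de$log2fc) >= min_abs_lfc & de$log2fc != 0
  if (!any(keep)) {
    stop("signature is empty; relax padj_max or min_abs_lfc", call. = FALSE)
  }
  sig <- data.frame(
    gene = de$gene[keep],
    direction = ifelse(de$log2fc[keep] > 0, "up", "down"),
    stringsAsFactors = FALSE)
  sig$weight <- ifelse(sig$direction == "up", -1, 1)
  rownames(sig) <- NULL
  sig
}

#' Read / write a signature file (gene, direction, weight)
#' @param path Tab-delimited file with columns `gene`, `direction`, `weight`.
#' @return `read_signature`: the signature `data.frame`.
#' @export
read_signature <- function(path) {
  df <- .read_table(path, sprintf("signature '%s'", path))
  cols <- .resolve_columns(names(df), list(gene = "gene",
                                           direction = "direction",
                                           weight = "weight"),
                           context = sprintf("signature '%s'", path))
  out <- data.frame(gene = df[[cols$gene]], direction = df[[cols$direction]],
                    weight = as.numeric(df[[cols$weight]]),
                    stringsAsFactors = FALSE)
  bad <- which(!(out$direction %in% c("up", "down")) |
                 out$weight != ifelse(out$direction == "up", -1, 1))
  if (length(bad)) {
    stop(sprintf("signature '%s': inconsistent direction/weight at row(s) %s",
                 path, paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' @rdname read_signature
#' @param sig A signature `data.frame` ([build_signature()]).
#' @export
write_signature <- function(sig, path) {
  data.table::fwrite(sig[, c("gene", "direction", "weight")], path,
                     sep = "\t", quote = FALSE)
  invisible(path)
}

.match_signature <- function(sig, genes, caller) {
  present <- sig$gene %in% genes
  if (!any(present)) {
    stop(sprintf("%s: no signature gene present in the matrix (missing: %s%s)",
                 caller, paste(utils::head(sig$gene, 5L), collapse = ", "),
                 if (nrow(sig) > 5L) ", ..." else ""), call. = FALSE)
  }
  sig[present, , drop = FALSE]
}

#' Direction-weighted activity score
#'
#' The per-sample activity score is the weighted sum (or mean) of normalized
#' expression over the signature genes:
#' `score(s) = sum_g weight(g) * z[g, s]`, with up-in-mutant genes weighted
#' -1 and down-in-mutant genes +1, so that mutant-like samples score low.
#'
#' @param norm Normalized matrix from [normalize_counts()] (any numeric
#'   genes-by-samples matrix is accepted).
#' @param sig Signature `data.frame` with `gene`, `weight`.
#' @param aggregate `"sum"` (default) or `"mean"` over signature genes.
#' @return A `data.frame` with columns `sample_id`, `score`, `method`
#'   (`"weighted"`); signature genes absent from the matrix are listed in
#'   `attr(, "missing_genes")`.
#' @export
weighted_score <- function(norm, sig, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  use <- .match_signature(sig, rownames(norm), "weighted_score")
  z <- norm[use$gene, , drop = FALSE]
  scores <- as.numeric(crossprod(z, use$weight))
  if (aggregate == "mean") scores <- scores / nrow(use)
  out <- data.frame(sample_id = colnames(norm), score = scores,
                    method = "weighted", stringsAsFactors = FALSE)
  attr(out, "missing_genes") <- setdiff(sig$gene, use$gene)
  out
}

#' Rank-based activity score
#'
#' A simplified directed mean-rank statistic (singscore-flavoured): per
#' sample, all genes in the matrix are ranked ascending by expression
#' (average ranks for ties) and ranks are normalized to (0, 1) as
#' `(rank - 0.5) / n_genes`. The score is the mean normalized rank of the
#' down-in-mutant genes minus the mean normalized rank of the up-in-mutant
#' genes, matching the weighted score's sign convention (mutant-like is
#' low). Scores lie in (-1, 1).
#'
#' @param mat A genes-by-samples expression matrix (normalized or raw log2
#'   scale; ranks make the score monotone-transform invariant per sample).
#' @param sig Signature `data.frame` with `gene`, `direction`.
#' @return A `data.frame` with columns `sample_id`, `score`, `method`
#'   (`"rank"`).
#' @export
rank_score <- function(mat, sig) {
  use <- .match_signature(sig, rownames(mat), "rank_score")
  up <- use$gene[use$direction == "up"]
  down <- use$gene[use$direction == "down"]
  n <- nrow(mat)
  scores <- vapply(seq_len(ncol(mat)), function(j) {
    r <- (rank(mat[, j]) - 0.5) / n
    names(r) <- rownames(mat)
    m_up <- if (length(up)) mean(r[up]) else 0.5
    m_down <- if (length(down)) mean(r[down]) else 0.5
    m_down - m_up
  }, numeric(1))
  out <- data.frame(sample_id = colnames(mat), score = scores,
                    method = "rank", stringsAsFactors = FALSE)
  attr(out, "missing_genes") <- setdiff(sig$gene, use$gene)
  out
}

#' Gene-set (bile-duct-style) score
#'
#' Per-sample mean of per-gene z-scores of median-centered log2 counts over
#' the genes of a set, as used for combined cell-type marker signatures
#' (e.g. pooled bile-duct cell gene sets).
#'
#' @param counts Genes-by-samples counts matrix.
#' @param geneset Character vector of gene symbols (one gene set).
#' @param pseudocount Passed to [normalize_counts()].
#' @return A `data.frame` with columns `sample_id`, `score`, `method`
#'   (`"geneset"`).
#' @export
geneset_score <- function(counts, geneset, pseudocount = 1) {
  stopifnot(length(geneset) >= 1L)
  present <- intersect(geneset, rownames(counts))
  if (length(present) == 0L) {
    stop("no gene-set gene present in the matrix", call. = FALSE)
  }
  z <- normalize_counts(counts, pseudocount = pseudocount)
  scores <- colMeans(z[present, , drop = FALSE])
  data.frame(sample_id = colnames(counts), score = as.numeric(scores),
             method = "geneset", stringsAsFactors = FALSE)
}
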