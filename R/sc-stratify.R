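#' Gene-by-cell expression matrix container
#'
#' A light wrapper around a (sparse or dense) gene-by-cell matrix tagging
#' which layer it holds: raw `counts` (non-negative integers) or `lognorm`
#' (log-normalized non-negative reals), with optional per-cell metadata.
#'
#' @param values Gene-by-cell matrix (base matrix or `Matrix` sparse matrix)
#'   with unique rownames (genes) and colnames (cell barcodes).
#' @param layer `"counts"` or `"lognorm"`.
#' @param cell_meta Optional tibble of per-cell labels, one row per cell.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, layer = c("counts", "lognorm"),
                        cell_meta = NULL) {
  layer <- match.arg(layer)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_format("expression matrix needs gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(values))) stop_format("duplicate gene names")
  if (anyDuplicated(colnames(values))) stop_format("duplicate cell barcodes")
  if (min(values) < 0) stop_domain("expression values must be non-negative")
  if (layer == "counts" && max(abs(values - round(values))) > 0) {
    stop_domain("counts layer must hold integers")
  }
  if (!is.null(cell_meta)) {
    stopifnot(nrow(cell_meta) == ncol(values))
    cell_meta <- as_tibble(cell_meta)
  }
  structure(list(values = values, layer = layer, cell_meta = cell_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> [", x$layer, "] ", nrow(x$values), " genes x ",
      ncol(x$values), " cells\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

genes <- function(x) rownames(x$values)
barcodes <- function(x) colnames(x$values)

#' Quality-control filter on cells
#'
#' Keeps cells whose detected-gene count (genes with count > 0) lies in
#' `[min_genes, max_genes]` and whose mitochondrial fraction of total counts
#' is at most `max_mito_frac`. Exclusion is strict: "fewer than `min_genes`",
#' "more than `max_genes`" and "more than `max_mito_frac`" are removed, so
#' cells exactly at a boundary are kept.
#'
#' @param counts An `expr_matrix` in the counts layer.
#' @param mito_genes Character vector of mitochondrial gene names.
#' @param min_genes,max_genes Detected-gene bounds (defaults 500, 4000).
#' @param max_mito_frac Maximum mitochondrial fraction (default 0.10).
#' @return Character vector of kept barcodes (empty, with a warning, when no
#'   cell passes).
#' @export
qc_filter <- function(counts, mito_genes, min_genes = 500, max_genes = 4000,
                      max_mito_frac = 0.10) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$layer != "counts") stop_domain("qc_filter needs the counts layer")
  v <- counts$values
  detected <- Matrix::colSums(v > 0)
  total <- Matrix::colSums(v)
  mito <- intersect(mito_genes, rownames(v))
  mito_frac <- if (length(mito)) {
    Matrix::colSums(v[mito, , drop = FALSE]) / pmax(total, 1)
  } else rep(0, ncol(v))
  keep <- detected >= min_genes & detected <= max_genes &
    mito_frac <= max_mito_frac
  if (!any(keep)) warn("no cell passes QC")
  colnames(v)[keep]
}

#' Library-size log-normalization
#'
#' `value' = log(1 + count / cell_total * scale)`, the standard per-cell
#' depth normalization with natural-log transform.
#'
#' @param counts An `expr_matrix` in the counts layer; every cell must have
#'   a positive total.
#' @param scale Scale factor (default 10000).
#' @return An `expr_matrix` in the lognorm layer.
#' @export
lognormalize <- function(counts, scale = 10000) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$layer != "counts") stop_domain("lognormalize needs the counts layer")
  totals <- Matrix::colSums(counts$values)
  if (any(totals == 0)) {
    stop_domain(paste0("zero-total cell(s): ",
                       paste(colnames(counts$values)[totals == 0], collapse = ", ")))
  }
  v <- sweep_cols(counts$values, scale / totals)
  v <- log1p_mat(v)
  expr_matrix(v, layer = "lognorm", cell_meta = counts$cell_meta)
}

sweep_cols <- function(m, f) {
  if (inherits(m, "sparseMatrix")) {
    out <- m %*% Matrix::Diagonal(x = f)
    dimnames(out) <- dimnames(m)
    out
  } else {
    sweep(m, 2, f, `*`)
  }
}

log1p_mat <- function(m) {
  if (inherits(m, "sparseMatrix")) {
    m@x <- log1p(m@x)
    dimnames(m) <- dimnames(m)
    m
  } else log1p(m)
}

#' Bin-matched gene-set module score
#'
#' For every cell, the mean log-normalized expression of the gene-set genes
#' minus the mean expression of a pool of control genes matched on overall
#' expression level: all genes are ranked by their mean expression across
#' cells and cut into `n_bins` equal-frequency bins; each gene-set gene
#' contributes `n_ctrl` control genes drawn (seeded, without replacement)
#' from its own bin. Scores are therefore centered near zero for a set with
#' no coordinated activity.
#'
#' @param expr An `expr_matrix` in the lognorm layer.
#' @param gene_set Character vector of gene names; members absent from the
#'   matrix are ignored (an error if none is present).
#' @param n_bins Number of expression bins (default 25).
#' @param n_ctrl Control genes per gene-set gene (default 100). Bins smaller
#'   than `n_ctrl` are sampled with replacement, with a warning.
#' @param seed Integer seed for the control draws.
#' @return A `module_score_result` tibble: `barcode`, `score`; attributes
#'   `gene_set_used`, `n_ctrl`, `n_bins`, `seed`.
#' @export
module_score <- function(expr, gene_set, n_bins = 25, n_ctrl = 100, seed) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$layer != "lognorm") stop_domain("module_score needs the lognorm layer")
  v <- expr$values
  used <- intersect(gene_set, rownames(v))
  if (length(used) == 0) stop_domain("no gene-set member present in the matrix")
  gene_means <- Matrix::rowMeans(v)
  # equal-frequency bins over the mean-expression ranking
  rk <- rank(gene_means, ties.method = "first")
  bin <- ceiling(rk / length(rk) * n_bins)
  ctrl <- withr::with_seed(seed, {
    unlist(lapply(used, function(g) {
      members <- rownames(v)[bin == bin[match(g, rownames(v))]]
      members <- setdiff(members, g)
      if (length(members) < n_ctrl) {
        warn("expression bin smaller than n_ctrl; sampling with replacement")
        sample(members, n_ctrl, replace = TRUE)
      } else {
        sample(members, n_ctrl)
      }
    }))
  })
  set_mean <- Matrix::colMeans(v[used, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(v[ctrl, , drop = FALSE])
  out <- tibble(barcode = colnames(v), score = as.numeric(set_mean - ctrl_mean))
  structure(out, class = c("module_score_result", class(tibble())),
            gene_set_used = used, n_ctrl = n_ctrl, n_bins = n_bins,
            seed = seed)
}

#' Stratify cells at the median score
#'
#' Cells scoring strictly above the median are labelled `"high"`, the rest
#' (including cells exactly at the median) `"low"`.
#'
#' @param scores Numeric vector of per-cell scores (length >= 2), or a
#'   `module_score_result`.
#' @return Factor of `"high"`/`"low"` labels, same order as the input.
#' @export
stratify_by_median <- function(scores) {
  if (inherits(scores, "module_score_result")) scores <- scores$score
  if (length(scores) < 2) stop_domain("need at least 2 cells to stratify")
  med <- stats::median(scores)
  lab <- ifelse(scores > med, "high", "low")
  if (all(lab == "low")) warn("all scores at or below the median; no 'high' cells")
  factor(lab, levels = c("high", "low"))
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Tests every gene expressed in at least `min_pct` of either group by the
#' two-sided rank-sum test (normal approximation with tie correction).
#' Fold changes are computed on the count scale:
#' `log2FC = log2((mean(expm1(x_high)) + eps) / (mean(expm1(x_low)) + eps))`
#' with `eps = 1e-9`. P-values are BH-adjusted across tested genes; genes
#' with `fdr < fdr_thresh` and `|log2fc| > lfc_thresh` are flagged as
#' passing.
#'
#' @param expr An `expr_matrix` in the lognorm layer.
#' @param groups Factor/character of `"high"`/`"low"` labels per cell (order
#'   of `colnames(expr$values)`).
#' @param fdr_thresh FDR threshold (default 0.05).
#' @param lfc_thresh Absolute log2 fold-change threshold (default 0.585,
#'   i.e. 1.5-fold).
#' @param min_pct Minimum detection fraction in either group (default 0.1).
#' @return A `deg_table` tibble: `gene`, `log2fc`, `pval`, `fdr`,
#'   `pct_high`, `pct_low`, `pass`.
#' @export
wilcoxon_deg <- function(expr, groups, fdr_thresh = 0.05, lfc_thresh = 0.585,
                         min_pct = 0.1) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$layer != "lognorm") stop_domain("wilcoxon_deg needs the lognorm layer")
  groups <- as.character(groups)
  hi <- groups == "high"
  lo <- groups == "low"
  if (!any(hi) || !any(lo)) stop_domain("both groups must be non-empty")
  v <- as.matrix(expr$values)
  pct_high <- rowMeans(v[, hi, drop = FALSE] > 0)
  pct_low <- rowMeans(v[, lo, drop = FALSE] > 0)
  test <- pct_high >= min_pct | pct_low >= min_pct
  n1 <- sum(hi); n2 <- sum(lo); nn <- n1 + n2

  pv <- rep(NA_real_, nrow(v))
  for (g in which(test)) {
    x <- v[g, ]
    r <- rank(x)
    W <- sum(r[hi]) - n1 * (n1 + 1) / 2
    ties <- table(x)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
    pv[g] <- if (sigma2 <= 0) 1 else {
      z <- (W - n1 * n2 / 2) / sqrt(sigma2)
      2 * pnorm(-abs(z))
    }
  }
  eps <- 1e-9
  mean_hi <- rowMeans(expm1(v[, hi, drop = FALSE]))
  mean_lo <- rowMeans(expm1(v[, lo, drop = FALSE]))
  log2fc <- log2((mean_hi + eps) / (mean_lo + eps))

  fdr <- rep(NA_real_, nrow(v))
  fdr[test] <- bh_fdr(pv[test])
  out <- tibble(gene = rownames(v), log2fc = log2fc, pval = pv, fdr = fdr,
                pct_high = pct_high, pct_low = pct_low,
                tested = test,
                pass = !is.na(fdr) & fdr < fdr_thresh & abs(log2fc) > lfc_thresh)
  structure(out, class = c("deg_table", class(tibble())),
            fdr_thresh = fdr_thresh, lfc_thresh = lfc_thresh,
            min_pct = min_pct)
}
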