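#' Simulate single-cell counts with a known gene-set activity signal
#'
#' Generates a gene-by-cell count matrix under a log-normal/Poisson model:
#' gene base means are log-normal, library-size factors log-normal, and
#' counts Poisson at the product. A known `active_fraction` of cells has the
#' `gene_set` genes' means multiplied by `activity_effect` (the coordinated
#' module activity the scoring stage should recover), and `n_deg` additional
#' non-set genes differ between the active and inactive cells by `deg_fold`
#' (spiked differentially expressed genes for the rank-sum stage).
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param gene_set Character vector of gene names (must be a subset of the
#'   generated names `gene0001`, `gene0002`, ...).
#' @param activity_effect Multiplicative elevation of gene-set genes in
#'   active cells (1 = no signal).
#' @param active_fraction Fraction of cells that are active (default 0.5).
#' @param n_deg Number of spiked non-set DE genes (default 0).
#' @param deg_fold Fold difference of the spiked genes between groups.
#' @param base_meanlog,base_sdlog Log-normal parameters of gene base means.
#' @param libsize_sdlog Log-normal SD of per-cell library factors.
#' @param seed Integer seed.
#' @return A list: `counts` (an [expr_matrix()] in the counts layer, sparse,
#'   with `cell_meta` holding the latent `active` label) and `truth` (list
#'   with `active_cells`, `deg_genes`, `gene_set`).
#' @export
simulate_expression <- function(n_genes, n_cells, gene_set,
                                activity_effect = 1, active_fraction = 0.5,
                                n_deg = 0, deg_fold = 2,
                                base_meanlog = 0, base_sdlog = 1,
                                libsize_sdlog = 0.3, seed = 1L) {
  gene_names <- sprintf("gene%04d", seq_len(n_genes))
  if (!all(gene_set %in% gene_names)) {
    stop_config("gene_set must be a subset of the generated gene names")
  }
  if (n_deg > n_genes - length(gene_set)) {
    stop_config("n_deg exceeds the number of non-set genes")
  }
  stopifnot(activity_effect > 0, active_fraction >= 0, active_fraction <= 1,
            deg_fold > 0)
  barcodes <- sprintf("cell%05d", seq_len(n_cells))

  withr::with_seed(seed, {
    base <- rlnorm(n_genes, base_meanlog, base_sdlog)
    lib <- rlnorm(n_cells, 0, libsize_sdlog)
    active <- rep(FALSE, n_cells)
    active[sample.int(n_cells, round(active_fraction * n_cells))] <- TRUE

    deg_genes <- setdiff(gene_names, gene_set)[seq_len(n_deg)]
    mu <- outer(base, lib)
    set_idx <- match(gene_set, gene_names)
    if (length(set_idx)) {
      mu[set_idx, active] <- mu[set_idx, active] * activity_effect
    }
    if (n_deg > 0) {
      deg_idx <- match(deg_genes, gene_names)
      mu[deg_idx, active] <- mu[deg_idx, active] * deg_fold
    }
    counts <- matrix(rpois(n_genes * n_cells, mu), n_genes, n_cells,
                     dimnames = list(gene_names, barcodes))
  })
  em <- expr_matrix(Matrix::Matrix(counts, sparse = TRUE), layer = "counts",
                    cell_meta = tibble(barcode = barcodes, active = active))
  list(counts = em,
       truth = list(active_cells = barcodes[active], deg_genes = deg_genes,
                    gene_set = gene_set))
}

#' Read/write gene-by-cell counts as MatrixMarket triplets
#'
#' The standard sparse exchange layout: `matrix.mtx` plus one-column sidecar
#' files `genes.tsv` and `barcodes.tsv`.
#'
#' @param dir Directory holding (or receiving) `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`.
#' @return [read_expression_mtx()]: an [expr_matrix()] in the counts layer;
#'   [write_expression_mtx()]: `dir`, invisibly.
#' @export
read_expression_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  g <- readr::read_tsv(file.path(dir, "genes.tsv"), col_names = "gene",
                       show_col_types = FALSE, progress = FALSE)
  b <- readr::read_tsv(file.path(dir, "barcodes.tsv"), col_names = "barcode",
                       show_col_types = FALSE, progress = FALSE)
  dimnames(m) <- list(g$gene, b$barcode)
  expr_matrix(methods::as(m, "CsparseMatrix"), layer = "counts")
}

#' @rdname read_expression_mtx
#' @param x An [expr_matrix()] in the counts layer.
#' @export
write_expression_mtx <- function(x, dir) {
  stopifnot(inherits(x, "expr_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(x$values, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(gene = rownames(x$values)),
                   file.path(dir, "genes.tsv"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(tibble(barcode = colnames(x$values)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE,
                   progress = FALSE)
  invisible(dir)
}
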