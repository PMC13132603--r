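#' LD correlation matrices
#'
#' An `ld_matrix` wraps a symmetric matrix of pairwise correlations (r, not
#' r-squared) with unit diagonal, indexed by variant id.
#'
#' @param r Square numeric matrix with dimnames giving variant ids, or `NULL`
#'   together with `variant_ids` for an identity (no-LD) panel.
#' @param variant_ids Variant ids (used when `r` lacks dimnames or is `NULL`).
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(r = NULL, variant_ids = NULL) {
  if (is.null(r)) {
    stopifnot(!is.null(variant_ids))
    r <- diag(length(variant_ids))
    dimnames(r) <- list(variant_ids, variant_ids)
  }
  r <- as.matrix(r)
  if (!is.null(variant_ids)) dimnames(r) <- list(variant_ids, variant_ids)
  if (is.null(rownames(r))) stop_format("LD matrix needs variant ids")
  if (nrow(r) != ncol(r)) stop_format("LD matrix must be square")
  if (max(abs(r - t(r))) > 1e-8) stop_format("LD matrix asymmetric beyond 1e-8")
  r <- (r + t(r)) / 2
  if (any(abs(r) > 1 + 1e-12)) stop_format("LD correlations must satisfy |r| <= 1")
  diag(r) <- 1
  structure(list(variant_ids = rownames(r), r = r), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("<ld_matrix> ", length(x$variant_ids), " variants\n", sep = "")
  invisible(x)
}

#' Read an LD matrix from disk
#'
#' Accepts either a square tab-separated table whose header row and first
#' column hold variant ids, or a 3-column triplet table `(id_i, id_j, r)`.
#' Triplets are symmetrized; pairs absent from a triplet file are treated as
#' r = 0 (with a warning, so sparse panels do not silently pass as complete).
#'
#' @param path Path to the file.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop_config(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  # square layout when the first column's ids reappear as the remaining
  # column names; otherwise a 3-column table is read as (id, id, r) triplets
  is_square <- !is.numeric(tab[[1]]) &&
    all(as.character(tab[[1]]) %in% names(tab)[-1])
  if (ncol(tab) == 3 && !is.numeric(tab[[1]]) && !is_square) {
    ids <- sort(unique(c(as.character(tab[[1]]), as.character(tab[[2]]))))
    r <- diag(length(ids))
    dimnames(r) <- list(ids, ids)
    rr <- as.numeric(tab[[3]])
    if (any(abs(rr) > 1)) stop_format("triplet with |r| > 1")
    i <- match(as.character(tab[[1]]), ids)
    j <- match(as.character(tab[[2]]), ids)
    r[cbind(i, j)] <- rr
    r[cbind(j, i)] <- rr
    n_pairs <- length(ids) * (length(ids) - 1) / 2
    if (nrow(tab) < n_pairs) {
      warn(paste0(n_pairs - nrow(tab),
                  " variant pair(s) missing from triplet LD file; treated as r = 0"))
    }
    ld_matrix(r)
  } else {
    ids <- names(tab)[-1]
    r <- as.matrix(tab[, -1, drop = FALSE])
    rownames(r) <- as.character(tab[[1]])
    if (!identical(rownames(r), ids)) {
      stop_format("square LD table row ids must match column header")
    }
    if (any(abs(r) > 1 + 1e-12)) stop_format("LD entry with |r| > 1")
    ld_matrix(r)
  }
}

#' Write an LD matrix as a square TSV
#' @param x An `ld_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(x, path) {
  out <- as_tibble(x$r)
  out <- dplyr::bind_cols(tibble(variant_id = x$variant_ids), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# squared correlation for a pair, 0 when either id is absent from the panel
ld_r2 <- function(ld, id1, id2) {
  i <- match(id1, ld$variant_ids)
  j <- match(id2, ld$variant_ids)
  if (is.na(i) || is.na(j)) {
    warn("variant pair absent from LD panel; treating r = 0")
    return(0)
  }
  ld$r[i, j]^2
}
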