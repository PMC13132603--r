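#' Per-variant instrument-strength F statistic
#'
#' The conventional single-SNP approximation `F = (beta/se)^2`.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return Numeric vector of F statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop_domain("se must be strictly positive")
  (beta / se)^2
}

#' Greedy LD clumping
#'
#' Thins a candidate set so that every retained pair within `window_kb` on the
#' same chromosome has squared correlation below `r2_threshold`. Candidates
#' are visited in ascending p-value order (ties broken lexicographically by
#' variant id, so the result does not depend on input row order); each is
#' kept iff it is below the r-squared threshold against every already-kept
#' variant within the window. Variants on different chromosomes, or farther
#' apart than the window, never conflict. Pairs absent from the LD panel are
#' treated as uncorrelated.
#'
#' @param candidates A `summary_stats` (or tibble with `variant_id`, `chrom`,
#'   `pos`, `pval`).
#' @param ld An [ld_matrix()].
#' @param r2_threshold Maximum allowed squared correlation (default 0.001).
#' @param window_kb Window half-width in kilobases (default 10000).
#' @return Character vector of retained variant ids.
#' @export
clump <- function(candidates, ld, r2_threshold = 0.001, window_kb = 10000) {
  if (nrow(candidates) == 0) return(character(0))
  ord <- order(candidates$pval, candidates$variant_id)
  cand <- candidates[ord, , drop = FALSE]
  idx <- match(cand$variant_id, ld$variant_ids)
  missing_any <- FALSE
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in kept) {
      if (!identical(cand$chrom[i], cand$chrom[j])) next
      if (is.na(cand$pos[i]) || is.na(cand$pos[j])) next
      if (abs(cand$pos[i] - cand$pos[j]) > window_kb * 1000) next
      if (is.na(idx[i]) || is.na(idx[j])) { missing_any <- TRUE; next }
      if (ld$r[idx[i], idx[j]]^2 >= r2_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  if (missing_any) warn("some variant pairs absent from LD panel; treated as r = 0")
  cand$variant_id[kept]
}

#' Select instrumental variables for an exposure
#'
#' Applies, in order: the genome-wide significance filter (`pval <
#' p_threshold`), greedy LD clumping ([clump()]), the weak-instrument screen
#' (F below `f_min` discarded; F equal to the minimum is kept), and a
#' confounder blacklist. The counts removed at each step are recorded in the
#' `filter_log` attribute.
#'
#' @param stats A `summary_stats` object.
#' @param ld An [ld_matrix()] covering (at least) the candidate variants.
#' @param p_threshold Instrument p-value cutoff (default 5e-6).
#' @param r2_threshold,window_kb Clumping parameters (defaults 0.001, 10000).
#' @param f_min Minimum instrument F statistic (default 10).
#' @param blacklist Character vector of variant ids to exclude (e.g. variants
#'   known to associate with confounders).
#' @return An `instrument_set` tibble (`variant_id`, `chrom`, `pos`, `bx`,
#'   `se_x`, `pval`, `f_stat`) with attributes `exposure_id` and `filter_log`.
#'   An empty selection is returned (not an error) with `empty = TRUE` in the
#'   filter log.
#' @export
select_instruments <- function(stats, ld, p_threshold = 5e-6,
                               r2_threshold = 0.001, window_kb = 10000,
                               f_min = 10, blacklist = character(0)) {
  if (nrow(stats) == 0) stop_config("empty summary statistics")
  n0 <- nrow(stats)
  sig <- stats[stats$pval < p_threshold, , drop = FALSE]
  n_p <- n0 - nrow(sig)

  kept_ids <- clump(sig, ld, r2_threshold = r2_threshold, window_kb = window_kb)
  n_clump <- nrow(sig) - length(kept_ids)
  sel <- sig[match(kept_ids, sig$variant_id), , drop = FALSE]

  f <- if (nrow(sel)) f_statistic(sel$beta, sel$se) else numeric(0)
  weak <- f < f_min
  n_f <- sum(weak)
  sel <- sel[!weak, , drop = FALSE]
  f <- f[!weak]

  bl <- sel$variant_id %in% blacklist
  n_bl <- sum(bl)
  sel <- sel[!bl, , drop = FALSE]
  f <- f[!bl]

  filter_log <- list(n_input = n0, removed_pval = n_p, removed_clump = n_clump,
                     removed_f = n_f, removed_blacklist = n_bl,
                     n_selected = nrow(sel), empty = nrow(sel) == 0)
  out <- tibble(variant_id = sel$variant_id, chrom = sel$chrom, pos = sel$pos,
                bx = sel$beta, se_x = sel$se, pval = sel$pval, f_stat = f)
  structure(out,
            class = c("instrument_set", class(tibble())),
            exposure_id = trait_id(stats),
            filter_log = filter_log)
}

#' @export
print.instrument_set <- function(x, ...) {
  fl <- attr(x, "filter_log")
  cat("<instrument_set> ", attr(x, "exposure_id"), ": ", nrow(x),
      " instruments (of ", fl$n_input, " candidates; removed ",
      fl$removed_pval, " by p, ", fl$removed_clump, " by LD, ",
      fl$removed_f, " by F, ", fl$removed_blacklist, " blacklisted)\n",
      sep = "")
  NextMethod()
}

#' Filter-log accessor
#' @param x An `instrument_set`.
#' @return Named list of per-step removal counts.
#' @export
filter_log <- function(x) attr(x, "filter_log")

#' Serialize an instrument set
#'
#' Writes the instruments as TSV (id, bx, se_x, pval, f_stat) and, when
#' `log_path` is given, the filter log as JSON.
#'
#' @param x An `instrument_set`.
#' @param path Output TSV path.
#' @param log_path Optional JSON path for the filter log.
#' @return `path`, invisibly.
#' @export
write_instrument_set <- function(x, path, log_path = NULL) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  if (!is.null(log_path)) {
    jsonlite::write_json(filter_log(x), log_path, auto_unbox = TRUE)
  }
  invisible(path)
}
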