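#' Harmonize exposure and outcome effects to a common effect allele
#'
#' Aligns one or more exposure summary-statistic tables and an outcome table
#' on their shared variants so that every retained effect is expressed
#' relative to the first exposure's effect allele. For each shared variant:
#'
#' * identical allele pair: effects kept as-is;
#' * swapped alleles (or strand-flipped equivalents): beta negated, effect
#'   allele frequency replaced by `1 - eaf`;
#' * palindromic variants (A/T or C/G): dropped when any trait's `eaf` is
#'   missing or within `palindrome_eaf_window` of 0.5, because allele
#'   orientation cannot be resolved;
#' * any other allele pair: dropped as incompatible.
#'
#' @param exposures A `summary_stats` object or a list of them (multivariable
#'   case). The first exposure defines the reference allele orientation.
#' @param outcome A `summary_stats` object.
#' @param palindrome_eaf_window Half-width of the ambiguity band around
#'   eaf = 0.5 inside which palindromic variants are dropped (default 0.08,
#'   i.e. the band \[0.42, 0.58\]).
#' @return A `harmonized_set` tibble with columns `variant_id`, `chrom`,
#'   `pos`, `bx`, `se_x` (matrices with one column per exposure when there are
#'   several), `by`, `se_y`, and attributes `exposure_ids`, `outcome_id`,
#'   `outcome_type`, `n_dropped_palindromic`, `n_dropped_incompatible`.
#' @export
harmonize <- function(exposures, outcome, palindrome_eaf_window = 0.08) {
  if (inherits(exposures, "summary_stats")) exposures <- list(exposures)
  stopifnot(length(exposures) >= 1, inherits(outcome, "summary_stats"))
  ref <- exposures[[1]]

  shared <- Reduce(intersect, c(lapply(exposures, function(s) s$variant_id),
                                list(outcome$variant_id)))
  if (length(shared) == 0) {
    stop_empty("no shared variants between exposures and outcome")
  }

  ref_rows <- ref[match(shared, ref$variant_id), , drop = FALSE]
  m <- length(exposures)
  k <- length(shared)
  bx <- matrix(NA_real_, k, m)
  se_x <- matrix(NA_real_, k, m)
  eafs <- matrix(NA_real_, k, m + 1L)
  keep <- rep(TRUE, k)
  palin_drop <- rep(FALSE, k)

  palin <- is_palindromic(ref_rows$effect_allele, ref_rows$other_allele)

  align_one <- function(tab) {
    rows <- tab[match(shared, tab$variant_id), , drop = FALSE]
    ea <- rows$effect_allele; oa <- rows$other_allele
    rea <- ref_rows$effect_allele; roa <- ref_rows$other_allele
    same  <- ea == rea & oa == roa
    swap  <- ea == roa & oa == rea
    # strand-flipped equivalents; for palindromic pairs these coincide with
    # same/swap so they only matter for non-palindromic variants
    csame <- !palin & dna_complement(ea) == rea & dna_complement(oa) == roa
    cswap <- !palin & dna_complement(ea) == roa & dna_complement(oa) == rea
    status <- ifelse(same | csame, 1L, ifelse(swap | cswap, -1L, 0L))
    beta <- ifelse(status == -1L, -rows$beta, rows$beta)
    eaf <- ifelse(status == -1L, 1 - rows$eaf, rows$eaf)
    list(status = status, beta = beta, se = rows$se, eaf = eaf)
  }

  for (j in seq_len(m)) {
    al <- align_one(exposures[[j]])
    keep <- keep & al$status != 0L
    bx[, j] <- al$beta
    se_x[, j] <- al$se
    eafs[, j] <- al$eaf
  }
  al_y <- align_one(outcome)
  keep <- keep & al_y$status != 0L
  eafs[, m + 1L] <- al_y$eaf

  # ambiguity rule for palindromic variants: checked before compatibility so
  # each dropped variant is counted exactly once
  ambig <- rowSums(is.na(eafs) |
                     abs(eafs - 0.5) <= palindrome_eaf_window) > 0
  palin_drop <- palin & ambig
  incompat <- !keep & !palin_drop
  retained <- !palin_drop & keep

  if (!any(retained)) {
    stop_empty("no compatible variants remain after harmonization")
  }

  out <- tibble(
    variant_id = shared[retained],
    chrom = ref_rows$chrom[retained],
    pos = ref_rows$pos[retained]
  )
  if (m == 1L) {
    out$bx <- bx[retained, 1L]
    out$se_x <- se_x[retained, 1L]
  } else {
    ids <- vapply(exposures, trait_id, character(1))
    bxm <- bx[retained, , drop = FALSE]; colnames(bxm) <- ids
    sxm <- se_x[retained, , drop = FALSE]; colnames(sxm) <- ids
    out$bx <- bxm
    out$se_x <- sxm
  }
  out$by <- al_y$beta[retained]
  out$se_y <- al_y$se[retained]
  out$eaf_exposure <- eafs[retained, 1L]

  structure(out,
            class = c("harmonized_set", class(tibble())),
            exposure_ids = vapply(exposures, trait_id, character(1)),
            outcome_id = trait_id(outcome),
            outcome_type = trait_type(outcome),
            n_dropped_palindromic = sum(palin_drop),
            n_dropped_incompatible = sum(incompat))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("<harmonized_set> ", paste(attr(x, "exposure_ids"), collapse = " + "),
      " -> ", attr(x, "outcome_id"), ": ", nrow(x), " variants (",
      attr(x, "n_dropped_palindromic"), " palindromic, ",
      attr(x, "n_dropped_incompatible"), " incompatible dropped)\n", sep = "")
  NextMethod()
}

n_snp <- function(h) nrow(h)

# row-subset a harmonized_set, preserving its metadata attributes
h_subset <- function(h, idx) {
  out <- as_tibble(h)[idx, , drop = FALSE]
  for (a in c("exposure_ids", "outcome_id", "outcome_type",
              "n_dropped_palindromic", "n_dropped_incompatible")) {
    attr(out, a) <- attr(h, a)
  }
  class(out) <- class(h)
  out
}

# exposure-effect matrix view (k x m), regardless of single/multi storage
bx_matrix <- function(h) {
  if (is.matrix(h$bx)) h$bx else matrix(h$bx, ncol = 1L,
                                        dimnames = list(NULL,
                                                        attr(h, "exposure_ids")[1]))
}

sx_matrix <- function(h) {
  if (is.matrix(h$se_x)) h$se_x else matrix(h$se_x, ncol = 1L)
}

# per-variant Wald ratios and IVW weights shared by IVW/median/mode/Q
ratio_components <- function(h) {
  bx <- bx_matrix(h)[, 1L]
  list(ratio = h$by / bx, w = bx^2 / h$se_y^2)
}

#' Construct a harmonized set directly from aligned vectors
#'
#' Convenience constructor for simulation studies and tests where effects are
#' already expressed on a common effect allele.
#'
#' @param variant_id Character vector of variant ids.
#' @param bx,se_x Exposure effects and SEs (vectors, or matrices with one
#'   column per exposure).
#' @param by,se_y Outcome effects and SEs.
#' @param exposure_ids,outcome_id Trait labels.
#' @param chrom,pos Optional coordinates.
#' @param outcome_type Outcome trait type label.
#' @return A `harmonized_set` tibble.
#' @export
harmonized_set <- function(variant_id, bx, se_x, by, se_y,
                           exposure_ids = "exposure", outcome_id = "outcome",
                           chrom = NA_character_, pos = NA_integer_,
                           outcome_type = "quantitative") {
  k <- length(variant_id)
  by <- rep_len(by, k); se_y <- rep_len(se_y, k)
  stopifnot(all(se_y > 0))
  out <- tibble(variant_id = as.character(variant_id),
                chrom = rep_len(chrom, k), pos = rep_len(pos, k))
  if (is.matrix(bx)) {
    stopifnot(nrow(bx) == k, all(dim(bx) == dim(se_x)))
    if (is.null(colnames(bx))) {
      colnames(bx) <- if (length(exposure_ids) == ncol(bx)) exposure_ids else
        paste0("exposure", seq_len(ncol(bx)))
    }
    colnames(se_x) <- colnames(bx)
    exposure_ids <- colnames(bx)
  } else {
    bx <- rep_len(bx, k)
    se_x <- rep_len(se_x, k)
  }
  out$bx <- bx; out$se_x <- se_x; out$by <- by; out$se_y <- se_y
  structure(out,
            class = c("harmonized_set", class(tibble())),
            exposure_ids = exposure_ids,
            outcome_id = outcome_id,
            outcome_type = outcome_type,
            n_dropped_palindromic = 0L,
            n_dropped_incompatible = 0L)
}
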