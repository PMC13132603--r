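#' GWAS summary statistics as a tibble
#'
#' A `summary_stats` object is a tibble with one row per variant and the
#' canonical columns `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `pval`, `eaf`, `n`, carrying the trait
#' identity as attributes. Effects are per effect-allele copy: log-odds for
#' case-control traits, SD units for quantitative traits.
#'
#' @param x A data frame with the canonical columns (`eaf` and `n` may be
#'   missing or `NA`).
#' @param trait_id Character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param reject_invalid If `TRUE`, rows violating the per-variant invariants
#'   (`se > 0`, `pval` in \[0,1\], `eaf` in \[0,1\] when present, distinct
#'   alleles, non-missing core fields) are dropped and counted in the
#'   `n_rejected` attribute; if `FALSE` such rows raise an error.
#' @return A `summary_stats` tibble; attributes `trait_id`, `trait_type`,
#'   `n_rejected`.
#' @export
as_summary_stats <- function(x, trait_id, trait_type = c("quantitative", "case_control"),
                             reject_invalid = FALSE) {
  trait_type <- match.arg(trait_type)
  req <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "beta", "se", "pval")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop_config(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)
  if (!"eaf" %in% names(x)) x$eaf <- NA_real_
  if (!"n" %in% names(x)) x$n <- NA_real_
  x <- x |>
    mutate(
      variant_id = as.character(.data$variant_id),
      chrom = normalize_chrom(.data$chrom),
      pos = as.integer(.data$pos),
      effect_allele = toupper(as.character(.data$effect_allele)),
      other_allele = toupper(as.character(.data$other_allele)),
      beta = as.numeric(.data$beta),
      se = as.numeric(.data$se),
      pval = as.numeric(.data$pval),
      eaf = as.numeric(.data$eaf),
      n = as.numeric(.data$n)
    ) |>
    select(all_of(c(req, "eaf", "n")))

  ok <- !is.na(x$variant_id) & !is.na(x$beta) & !is.na(x$se) & !is.na(x$pval) &
    x$se > 0 & x$pval >= 0 & x$pval <= 1 &
    (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1)) &
    !is.na(x$effect_allele) & !is.na(x$other_allele) &
    x$effect_allele != x$other_allele
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    if (!reject_invalid) {
      stop_domain(paste0(n_rejected, " row(s) violate summary-statistic invariants"))
    }
    x <- x[ok, , drop = FALSE]
  }
  if (anyDuplicated(x$variant_id)) {
    stop_domain("duplicate variant_id within a summary_stats table")
  }
  structure(x,
            class = c("summary_stats", class(tibble())),
            trait_id = as.character(trait_id),
            trait_type = trait_type,
            n_rejected = n_rejected)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("<summary_stats> trait '", attr(x, "trait_id"), "' (",
      attr(x, "trait_type"), "), ", nrow(x), " variants\n", sep = "")
  NextMethod()
}

#' Trait accessors
#' @param x A `summary_stats` object.
#' @return Character scalar.
#' @export
trait_id <- function(x) attr(x, "trait_id")

#' @rdname trait_id
#' @export
trait_type <- function(x) attr(x, "trait_type")

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-separated table with a header row and maps its columns onto the
#' canonical summary-statistic fields. Rows violating the per-variant
#' invariants (non-positive SE, p outside \[0,1\], identical alleles, ...) are
#' dropped; the count is available as `attr(x, "n_rejected")` and reported in
#' a message.
#'
#' @param path Path to a delimited text file.
#' @param column_map Named character vector mapping canonical field names to
#'   file column names. Defaults to the conventional `SNP`, `CHR`, `POS`,
#'   `EA`, `OA`, `BETA`, `SE`, `P`, `EAF`, `N` header. `eaf` and `n` entries
#'   are optional.
#' @param trait_id,trait_type Trait identity, as in [as_summary_stats()].
#' @param delim Field delimiter, default tab.
#' @return A `summary_stats` tibble.
#' @export
read_summary_stats <- function(path,
                               column_map = default_column_map(),
                               trait_id = basename(path),
                               trait_type = c("quantitative", "case_control"),
                               delim = "\t") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop_config(paste0("file not found: ", path))
  req <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "beta", "se", "pval")
  missing_map <- setdiff(req, names(column_map))
  if (length(missing_map) > 0) {
    stop_config(paste0("column_map is missing mapping(s) for: ",
                       paste(missing_map, collapse = ", ")))
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(unname(column_map[req]), names(raw))
  if (length(missing_cols) > 0) {
    stop_config(paste0("file lacks mapped column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  keep <- intersect(names(column_map), c(req, "eaf", "n"))
  keep <- keep[column_map[keep] %in% names(raw)]
  out <- raw[, unname(column_map[keep]), drop = FALSE]
  names(out) <- keep
  ss <- as_summary_stats(out, trait_id = trait_id, trait_type = trait_type,
                         reject_invalid = TRUE)
  if (attr(ss, "n_rejected") > 0) {
    message(attr(ss, "n_rejected"), " row(s) rejected while reading ", path)
  }
  ss
}

#' @rdname read_summary_stats
#' @export
default_column_map <- function() {
  c(variant_id = "SNP", chrom = "CHR", pos = "POS", effect_allele = "EA",
    other_allele = "OA", beta = "BETA", se = "SE", pval = "P",
    eaf = "EAF", n = "N")
}

#' Write summary statistics in the default tabular layout
#'
#' @param x A `summary_stats` object.
#' @param path Output path (tab-separated, default column names).
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  map <- default_column_map()
  out <- as_tibble(x)
  names(out) <- unname(map[names(out)])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
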