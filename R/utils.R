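#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange left_join inner_join bind_rows
#'   group_by summarise ungroup across all_of row_number n
#' @importFrom stats pnorm pchisq qnorm median sd quantile rnorm runif rpois
#'   rlnorm p.adjust setNames density complete.cases
#' @importFrom utils head
#' @importFrom methods as
NULL

`%||%` <- rlang::`%||%`

# two-sided normal p-value from an estimate and its SE
z_pval <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

CI_Z <- 1.959964

# strip leading "chr" and normalize case so "chr1", "Chr1" and "1" compare equal
normalize_chrom <- function(x) sub("^chr", "", tolower(as.character(x)))

dna_complement <- function(a) {
  chartr("ACGT", "TGCA", toupper(a))
}

# palindromic = single-base allele pair that is its own reverse complement (A/T, C/G)
is_palindromic <- function(a1, a2) {
  nchar(a1) == 1L & nchar(a2) == 1L & dna_complement(a1) == a2
}

stop_domain <- function(msg) abort(msg, class = "mrmediate_domain_error")
stop_config <- function(msg) abort(msg, class = "mrmediate_config_error")
stop_format <- function(msg) abort(msg, class = "mrmediate_format_error")
stop_empty  <- function(msg) abort(msg, class = "mrmediate_empty_error")
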