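#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MR result into one row per method
#'
#' @param x An `mr_result` from [run_all_methods()].
#' @param ... Unused.
#' @return A plain tibble of estimates.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  out <- as_tibble(x)
  out$exposure <- attr(x, "exposure_id")
  out$outcome <- attr(x, "outcome_id")
  dplyr::relocate(out, "exposure", "outcome")
}

#' @rdname tidy.mr_result
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  head_est <- x[x$method %in% c("ivw", "wald"), ][1, ]
  tibble(exposure = attr(x, "exposure_id"), outcome = attr(x, "outcome_id"),
         n_methods = nrow(x), n_snp = head_est$n_snp,
         headline_beta = head_est$beta, headline_pval = head_est$pval,
         direction_consistent = attr(x, "direction_consistent"))
}

#' Tidiers for the remaining result types
#'
#' @param x The fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name mrmediate-tidiers
NULL

#' @rdname mrmediate-tidiers
#' @method tidy mvmr_result
#' @export
tidy.mvmr_result <- function(x, ...) {
  out <- as_tibble(x)
  out$model <- attr(x, "model_label")
  dplyr::relocate(out, "model")
}

#' @rdname mrmediate-tidiers
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), dplyr::everything(),
                      names_to = "term", values_to = "estimate")
}

#' @rdname mrmediate-tidiers
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble(mediation_effect = x$mediation_effect,
         direct_effect = x$direct_effect,
         mediated_proportion_pct = x$mediated_proportion_pct,
         proportion_defined = attr(x, "proportion_defined"))
}

#' @rdname mrmediate-tidiers
#' @method tidy coloc_result
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(hypothesis = paste0("H", 0:4), posterior = unname(x$pp))
}

#' @rdname mrmediate-tidiers
#' @method glance coloc_result
#' @export
glance.coloc_result <- function(x, ...) {
  tibble(pp4 = x$pp[["pp4"]], n_snps = x$n_snps,
         classification = x$classification)
}

#' @rdname mrmediate-tidiers
#' @method tidy presso_result
#' @export
tidy.presso_result <- function(x, ...) x$outlier_table

#' @rdname mrmediate-tidiers
#' @method glance presso_result
#' @export
glance.presso_result <- function(x, ...) {
  tibble(global_rss = x$global_rss, global_pval = x$global_pval,
         n_outliers = length(x$outlier_ids), n_sim = x$n_sim)
}
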