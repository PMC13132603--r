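#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbarh geom_col
#'   geom_vline geom_hline labs theme_minimal geom_density
#' @export
ggplot2::autoplot

#' Forest plot of MR estimates across methods
#'
#' @param object An `mr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_result
#' @export
autoplot.mr_result <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$beta, y = .data$method)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_point(size = 2) +
    labs(x = "causal estimate (log scale for binary outcomes)", y = NULL,
         title = paste0(attr(object, "exposure_id"), " → ",
                        attr(object, "outcome_id"))) +
    theme_minimal()
}

#' Leave-one-out influence plot
#'
#' @param loo A tibble from [leave_one_out()].
#' @param full_beta Optional full-set IVW estimate drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo, full_beta = NULL) {
  p <- ggplot(loo, aes(x = .data$beta, y = .data$excluded_id)) +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_point() +
    labs(x = "IVW estimate excluding variant", y = NULL) +
    theme_minimal()
  if (!is.null(full_beta)) {
    p <- p + geom_vline(xintercept = full_beta, linetype = "dashed")
  }
  p
}

#' Posterior-probability bar chart for a colocalization result
#'
#' @param object A `coloc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coloc_result
#' @export
autoplot.coloc_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$hypothesis, y = .data$posterior)) +
    geom_col() +
    geom_hline(yintercept = c(0.5, 0.8), linetype = "dotted") +
    labs(y = "posterior probability",
         title = paste0("PPH4 = ", signif(object$pp[["pp4"]], 3), " (",
                        object$classification, ")")) +
    theme_minimal()
}

#' Module-score distribution by stratum
#'
#' @param object A `module_score_result`.
#' @param groups Optional `"high"`/`"low"` labels (defaults to
#'   [stratify_by_median()] of the scores).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot module_score_result
#' @export
autoplot.module_score_result <- function(object, groups = NULL, ...) {
  d <- as_tibble(object)
  d$group <- groups %||% stratify_by_median(object$score)
  ggplot(d, aes(x = .data$score, fill = .data$group)) +
    geom_density(alpha = 0.5) +
    labs(x = "module score", fill = NULL) +
    theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param deg A `deg_table` from [wilcoxon_deg()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(deg) {
  d <- dplyr::filter(as_tibble(deg), .data$tested)
  ggplot(d, aes(x = .data$log2fc, y = -log10(pmax(.data$fdr, 1e-300)),
                colour = .data$pass)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = -log10(attr(deg, "fdr_thresh")),
               linetype = "dotted") +
    geom_vline(xintercept = c(-1, 1) * attr(deg, "lfc_thresh"),
               linetype = "dotted") +
    labs(x = "log2 fold change (high vs low)", y = "-log10 FDR",
         colour = "passes") +
    theme_minimal()
}
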