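#' Multivariable MR by inverse-variance weighted regression
#'
#' Weighted least squares of the outcome effects on all exposure-effect
#' columns jointly, with no intercept and weights `1/se_y^2`. Each
#' coefficient is the direct effect of that exposure on the outcome holding
#' the other exposures fixed; in a mediation model the mediator's coefficient
#' is the `beta4` of the product-of-coefficients decomposition. The
#' coefficient covariance is the inverse weighted normal matrix scaled by
#' `max(1, RSS/(k - m))` (multiplicative over-dispersion, never deflating).
#'
#' @param h A `harmonized_set` with `m >= 1` exposure columns and more
#'   variants than exposures.
#' @param model_label Optional label stored with the result.
#' @return An `mvmr_result` tibble: one row per exposure with `exposure`,
#'   `beta`, `se`, `pval`, `ci_low`, `ci_high`, `n_snp`; attribute
#'   `model_label`.
#' @export
mvmr_ivw <- function(h, model_label = NULL) {
  X <- bx_matrix(h)
  m <- ncol(X)
  k <- n_snp(h)
  if (k <= m) stop_domain("underdetermined: need more variants than exposures")
  w <- 1 / h$se_y^2
  XtWX <- crossprod(X, w * X)
  if (rcond(XtWX) < 1e-12) {
    abort("collinear exposure-effect columns", class = "mrmediate_collinearity_error")
  }
  coef <- solve(XtWX, crossprod(X, w * h$by))
  rss <- sum(w * (h$by - X %*% coef)^2)
  scale <- max(1, rss / (k - m))
  vcov <- solve(XtWX) * scale
  se <- unname(sqrt(diag(vcov)))
  beta <- unname(drop(coef))
  out <- tibble(exposure = colnames(X) %||% attr(h, "exposure_ids"),
                beta = beta, se = se, pval = z_pval(beta, se),
                ci_low = beta - CI_Z * se, ci_high = beta + CI_Z * se,
                n_snp = k)
  structure(out, class = c("mvmr_result", class(tibble())),
            model_label = model_label %||% paste(out$exposure, collapse = " + "),
            outcome_id = attr(h, "outcome_id"))
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat("<mvmr_result> model '", attr(x, "model_label"), "' -> ",
      attr(x, "outcome_id") %||% "outcome", ", ", x$n_snp[1], " SNPs\n",
      sep = "")
  NextMethod()
}

#' Product-of-coefficients mediation decomposition
#'
#' Given the total effect of the exposure on the outcome (`beta1`, from
#' univariable MR), the exposure's effect on the mediator (`beta2`, from
#' univariable MR), and the mediator's direct effect on the outcome
#' (`beta4`, from multivariable MR adjusting for the exposure), computes
#'
#' * mediation (indirect) effect `= beta2 * beta4`,
#' * direct effect `= beta1 - beta2 * beta4`,
#' * mediated proportion `= 100 * beta2 * beta4 / beta1` (percent; undefined
#'   when `beta1 = 0`),
#' * optional Sobel SE `sqrt(beta2^2 * se4^2 + beta4^2 * se2^2)`.
#'
#' @param beta_total Total exposure-to-outcome effect (beta1).
#' @param beta_exp_to_med Exposure-to-mediator effect (beta2).
#' @param beta_med_to_out_mvmr Mediator-to-outcome direct effect from MVMR
#'   (beta4).
#' @param se2,se4 Optional SEs of beta2 and beta4 for the Sobel SE.
#' @param beta_med_to_out_tsmr Optional univariable mediator-to-outcome
#'   effect (beta3); recorded for reference, never used in the product.
#' @return A `mediation_result` one-row tibble: `beta1`, `beta2`, `beta3`,
#'   `beta4`, `mediation_effect`, `direct_effect`,
#'   `mediated_proportion_pct` (`NA` with attribute
#'   `proportion_defined = FALSE` when `beta1 = 0`), `sobel_se`.
#' @export
mediation_effects <- function(beta_total, beta_exp_to_med,
                              beta_med_to_out_mvmr,
                              se2 = NA_real_, se4 = NA_real_,
                              beta_med_to_out_tsmr = NA_real_) {
  med <- beta_exp_to_med * beta_med_to_out_mvmr
  direct <- beta_total - med
  defined <- beta_total != 0
  prop <- if (defined) 100 * med / beta_total else NA_real_
  sobel <- if (!is.na(se2) && !is.na(se4)) {
    sqrt(beta_exp_to_med^2 * se4^2 + beta_med_to_out_mvmr^2 * se2^2)
  } else NA_real_
  out <- tibble(beta1 = beta_total, beta2 = beta_exp_to_med,
                beta3 = beta_med_to_out_tsmr, beta4 = beta_med_to_out_mvmr,
                mediation_effect = med, direct_effect = direct,
                mediated_proportion_pct = prop, sobel_se = sobel)
  structure(out, class = c("mediation_result", class(tibble())),
            proportion_defined = defined)
}

#' Bidirectional two-sample MR between a pair of traits
#'
#' Runs the full TSMR workflow in both directions: trait A's instruments on
#' trait B (forward) and trait B's instruments on trait A (reverse). A
#' direction with no selectable instruments is reported as not estimable
#' rather than aborting.
#'
#' @param trait_a,trait_b `summary_stats` objects.
#' @param ld An [ld_matrix()].
#' @param seed Integer seed for the bootstrap SEs.
#' @param p_threshold,r2_threshold,window_kb,f_min Instrument-selection
#'   parameters, as in [select_instruments()].
#' @param n_boot Bootstrap resamples.
#' @return A list with elements `forward` and `reverse`, each either an
#'   `mr_result` or `NULL` (not estimable), plus `forward_estimable`,
#'   `reverse_estimable` flags.
#' @export
bidirectional_tsmr <- function(trait_a, trait_b, ld, seed,
                               p_threshold = 5e-6, r2_threshold = 0.001,
                               window_kb = 10000, f_min = 10, n_boot = 1000) {
  one_direction <- function(expo, outc, seed) {
    iv <- select_instruments(expo, ld, p_threshold = p_threshold,
                             r2_threshold = r2_threshold,
                             window_kb = window_kb, f_min = f_min)
    if (nrow(iv) == 0) return(NULL)
    expo_sub <- expo[expo$variant_id %in% iv$variant_id, , drop = FALSE]
    expo_sub <- as_summary_stats(expo_sub, trait_id(expo), trait_type(expo))
    h <- tryCatch(harmonize(expo_sub, outc),
                  mrmediate_empty_error = function(e) NULL)
    if (is.null(h)) return(NULL)
    run_all_methods(h, seed = seed, n_boot = n_boot)
  }
  fwd <- one_direction(trait_a, trait_b, seed)
  rev <- one_direction(trait_b, trait_a, seed + 1L)
  list(forward = fwd, reverse = rev,
       forward_estimable = !is.null(fwd), reverse_estimable = !is.null(rev))
}

#' Write a mediation report as JSON
#'
#' Serializes the coefficient set, derived effects and (when present) the
#' provenance of each coefficient.
#'
#' @param x A `mediation_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_mediation_json <- function(x, path) {
  out <- as.list(as_tibble(x))
  out$proportion_defined <- attr(x, "proportion_defined")
  prov <- attr(x, "provenance")
  if (!is.null(prov)) out$provenance <- prov
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
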