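#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_i * (ratio_i - beta)^2)` over per-variant Wald ratios with IVW
#' weights `w_i = bx_i^2/se_y_i^2`, referred to a chi-square with `k - 1`
#' degrees of freedom. Large Q flags heterogeneity across instruments
#' (possible pleiotropy or invalid instruments).
#'
#' @param h A `harmonized_set` with at least two variants.
#' @param beta Pooled causal estimate the ratios are compared against
#'   (defaults to the fixed-effect IVW estimate).
#' @return A one-row tibble: `Q`, `df`, `pval`.
#' @export
cochran_q <- function(h, beta = NULL) {
  k <- n_snp(h)
  if (k < 2) stop_domain("Cochran's Q requires at least 2 variants")
  if (is.null(beta)) beta <- ivw(h, model = "fixed")$beta
  rc <- ratio_components(h)
  q <- sum(rc$w * (rc$ratio - beta)^2)
  df <- k - 1L
  tibble(Q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Reports the intercept of the MR-Egger regression with its SE and two-sided
#' p-value; `p > 0.05` is conventionally read as no evidence of directional
#' pleiotropy.
#'
#' @param h A `harmonized_set` with at least three variants.
#' @return A one-row tibble: `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(h) {
  e <- mr_egger(h)
  tibble(intercept = e$intercept, se = e$intercept_se, pval = e$intercept_pval)
}

#' MR-PRESSO-style global outlier test
#'
#' The observed residual sum of squares is
#' `RSS = sum((by_i - bx_i * beta_{-i})^2 / se_y_i^2)` where `beta_{-i}` is
#' the IVW estimate excluding variant i. A null RSS distribution is built
#' from `n_sim` seeded parametric resamples (`bx* ~ N(bx, se_x^2)`,
#' `by* ~ N(bx * beta_{-i}, se_y^2)`), recomputing the leave-one-out fits on
#' each resample. The global empirical p-value is
#' `(1 + #\{RSS* >= RSS\}) / (1 + n_sim)`; per-variant outlier p-values come
#' from each variant's simulated residual distribution and are
#' Bonferroni-corrected across variants.
#'
#' @param h A `harmonized_set` with at least four variants.
#' @param n_sim Number of parametric resamples (default 1000).
#' @param seed Integer seed (required; results are bit-reproducible given it).
#' @param outlier_alpha Significance level applied to the corrected
#'   per-variant p-values (default 0.05).
#' @return A `presso_result` list: `global_rss`, `global_pval`,
#'   `outlier_table` (tibble of `variant_id`, `residual`, `pval`,
#'   `pval_bonferroni`, `outlier`), `outlier_ids`, `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, seed, outlier_alpha = 0.05) {
  k <- n_snp(h)
  if (k < 4) stop_domain("MR-PRESSO requires at least 4 variants")
  bx <- bx_matrix(h)[, 1L]
  sx <- sx_matrix(h)[, 1L]
  by <- h$by
  sy <- h$se_y
  w <- 1 / sy^2

  loo_beta <- function(bxm, bym) {
    # rows = replicates, cols = variants; returns matrix of beta_{-i}
    sxy <- rowSums(w2 <- sweep(bxm * bym, 2, w, `*`))
    sxx <- rowSums(w3 <- sweep(bxm^2, 2, w, `*`))
    (sxy - w2) / (sxx - w3)
  }

  obs <- loo_beta(matrix(bx, 1), matrix(by, 1))
  resid_obs <- (by - bx * obs[1, ])^2 * w
  rss_obs <- sum(resid_obs)

  sim <- withr::with_seed(seed, {
    bxs <- matrix(rnorm(n_sim * k, rep(bx, each = n_sim),
                        rep(sx, each = n_sim)), n_sim, k)
    mu <- rep(bx * obs[1, ], each = n_sim)
    bys <- matrix(rnorm(n_sim * k, mu, rep(sy, each = n_sim)), n_sim, k)
    bsim <- loo_beta(bxs, bys)
    rsim <- sweep((bys - bxs * bsim)^2, 2, w, `*`)
    list(rss = rowSums(rsim), resid = rsim)
  })

  global_pval <- (1 + sum(sim$rss >= rss_obs)) / (1 + n_sim)
  pv <- (1 + colSums(sweep(sim$resid, 2, resid_obs, `>=`))) / (1 + n_sim)
  pv_bonf <- pmin(1, pv * k)
  out_tab <- tibble(variant_id = h$variant_id, residual = resid_obs,
                    pval = pv, pval_bonferroni = pv_bonf,
                    outlier = pv_bonf < outlier_alpha)
  structure(list(global_rss = rss_obs, global_pval = global_pval,
                 outlier_table = out_tab,
                 outlier_ids = out_tab$variant_id[out_tab$outlier],
                 n_sim = n_sim, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat("<presso_result> global RSS ", signif(x$global_rss, 4), ", p = ",
      signif(x$global_pval, 4), "; ", length(x$outlier_ids),
      " outlier(s)\n", sep = "")
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate excluding each variant in turn, to flag
#' estimates driven by a single influential instrument.
#'
#' @param h A `harmonized_set` with at least three variants.
#' @param model IVW variance model, as in [ivw()].
#' @return A tibble with one row per excluded variant: `excluded_id`,
#'   `n_snp`, `beta`, `se`, `pval`, `ci_low`, `ci_high`.
#' @export
leave_one_out <- function(h, model = "auto") {
  k <- n_snp(h)
  if (k < 3) stop_domain("leave-one-out requires at least 3 variants")
  purrr::map_dfr(seq_len(k), function(i) {
    est <- ivw(h_subset(h, -i), model = model)
    tibble(excluded_id = h$variant_id[i], n_snp = est$n_snp, beta = est$beta,
           se = est$se, pval = est$pval, ci_low = est$ci_low,
           ci_high = est$ci_high)
  })
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, capped at one and returned in input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) stop_domain("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop_domain("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}
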