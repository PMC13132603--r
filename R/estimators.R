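#' @keywords internal
#' Assemble the standard one-row estimate table (CI and odds-ratio scale)
mr_estimate <- function(method, beta, se, pval, n_snp, ...) {
  extra <- list(...)
  out <- tibble(method = method, n_snp = as.integer(n_snp),
                beta = beta, se = se, pval = pval,
                ci_low = beta - CI_Z * se, ci_high = beta + CI_Z * se)
  out$odds_ratio <- exp(out$beta)
  out$or_ci_low <- exp(out$ci_low)
  out$or_ci_high <- exp(out$ci_high)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("mr_estimate", class(tibble()))
  out
}

#' Wald ratio estimate for a single variant
#'
#' Single-instrument causal estimate `by/bx` with first-order delta-method
#' standard error `se_y/|bx|` (the exposure SE does not enter at first
#' order).
#'
#' @param bx,se_x Exposure effect and SE.
#' @param by,se_y Outcome effect and SE.
#' @return A one-row `mr_estimate` tibble.
#' @export
wald_ratio <- function(bx, se_x, by, se_y) {
  if (bx == 0) stop_domain("Wald ratio undefined for bx = 0")
  if (se_y <= 0) stop_domain("se_y must be positive")
  beta <- by / bx
  se <- se_y / abs(bx)
  mr_estimate("wald", beta, se, z_pval(beta, se), 1L)
}

#' Inverse-variance weighted (IVW) estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_y^2`:
#' `beta = sum(bx*by/se_y^2) / sum(bx^2/se_y^2)`. The fixed-effect SE is
#' `sum(bx^2/se_y^2)^(-1/2)`; under the multiplicative random-effects model
#' the SE is inflated by `sqrt(Q/(k-1))`. `model = "auto"` applies the
#' inflation only when `Q/(k-1) > 1` (never deflating).
#'
#' @param h A `harmonized_set` with at least two variants. Use [wald_ratio()]
#'   when only one instrument is available.
#' @param model `"fixed"`, `"random"` or `"auto"`.
#' @return A one-row `mr_estimate` tibble (method `"ivw"`).
#' @export
ivw <- function(h, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  k <- n_snp(h)
  if (k < 2) {
    stop_domain("IVW requires at least 2 variants; use wald_ratio() for a single instrument")
  }
  bx <- bx_matrix(h)[, 1L]
  w <- 1 / h$se_y^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * h$by) / sxx
  se <- sqrt(1 / sxx)
  rc <- ratio_components(h)
  q <- sum(rc$w * (rc$ratio - beta)^2)
  phi <- q / (k - 1)
  inflate <- switch(model,
                    fixed = 1,
                    random = sqrt(max(phi, .Machine$double.eps)),
                    auto = sqrt(max(1, phi)))
  se <- se * inflate
  mr_estimate("ivw", beta, se, z_pval(beta, se), k)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with an intercept,
#' weights `1/se_y^2`. The slope is the causal estimate; a non-zero intercept
#' indexes directional pleiotropy. Standard errors are inflated by
#' `max(1, sqrt(RSS/(k-2)))`.
#'
#' @param h A `harmonized_set` with at least three variants.
#' @return A one-row `mr_estimate` tibble (method `"egger"`) carrying
#'   `intercept`, `intercept_se`, `intercept_pval` columns.
#' @export
mr_egger <- function(h) {
  k <- n_snp(h)
  if (k < 3) stop_domain("MR-Egger requires at least 3 variants")
  bx <- bx_matrix(h)[, 1L]
  w <- 1 / h$se_y^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * h$by)
  coef <- solve(XtWX, XtWy)
  resid <- h$by - X %*% coef
  rss <- sum(w * resid^2)
  sigma <- max(1, sqrt(rss / (k - 2)))
  vcov <- solve(XtWX) * sigma^2
  slope <- coef[2]; slope_se <- sqrt(vcov[2, 2])
  icpt <- coef[1]; icpt_se <- sqrt(vcov[1, 1])
  mr_estimate("egger", slope, slope_se, z_pval(slope, slope_se), k,
              intercept = icpt, intercept_se = icpt_se,
              intercept_pval = z_pval(icpt, icpt_se))
}

# cumulative-weight interpolation of ordered ratio estimates at probability p
weighted_quantile_ratio <- function(ratio, w, p = 0.5) {
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  stats::approx(s, ratio, xout = p, rule = 2)$y
}

# parametric bootstrap SE shared by the median and mode estimators
bootstrap_se <- function(h, estimator, n_boot, seed) {
  bx <- bx_matrix(h)[, 1L]
  sx <- sx_matrix(h)[, 1L]
  k <- n_snp(h)
  est <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bxs <- rnorm(k, bx, sx)
      bys <- rnorm(k, h$by, h$se_y)
      estimator(bys / bxs, bxs^2 / h$se_y^2)
    }, numeric(1))
  })
  stats::sd(est)
}

#' Weighted median estimate
#'
#' The weighted median of per-variant Wald ratios: ratios are ordered, IVW
#' weights `bx^2/se_y^2` normalized to sum one, and the estimate is the
#' linear interpolation of the ordered ratios at cumulative weight 0.5.
#' Consistent when at least half the weight comes from valid instruments.
#' The SE is the standard deviation of the estimate over `n_boot` seeded
#' parametric resamples of `(bx, by)`.
#'
#' @param h A `harmonized_set` with at least three variants.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap (required for reproducibility).
#' @return A one-row `mr_estimate` tibble (method `"weighted_median"`).
#' @export
weighted_median <- function(h, n_boot = 1000, seed) {
  k <- n_snp(h)
  if (k < 3) stop_domain("weighted median requires at least 3 variants")
  rc <- ratio_components(h)
  beta <- weighted_quantile_ratio(rc$ratio, rc$w)
  se <- bootstrap_se(h, function(r, w) weighted_quantile_ratio(r, w),
                     n_boot, seed)
  mr_estimate("weighted_median", beta, se, z_pval(beta, se), k)
}

# kernel-density mode of ratio estimates; bandwidth modified Silverman rule
mode_point <- function(ratio, w, phi) {
  w <- w / sum(w)
  s <- stats::sd(ratio)
  iqr <- stats::IQR(ratio) / 1.349
  scale <- min(s, iqr)
  if (!is.finite(scale) || scale == 0) scale <- s  # guard zero-IQR clusters
  bw <- phi * 0.9 * scale * length(ratio)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) return(ratio[1])
  grid <- seq(min(ratio) - bw, max(ratio) + bw, length.out = 512)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm((x - ratio) / bw)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' Smooths the per-variant ratio estimates with a normal kernel (bandwidth
#' `phi * 0.9 * min(sd, IQR/1.349) * k^(-1/5)`) and returns the grid argmax of
#' the (weighted) density over 512 points spanning the ratio range padded by
#' one bandwidth. The simple mode uses equal weights, the weighted mode IVW
#' weights. Consistent when the largest group of instruments with the same
#' ratio is valid. SE by seeded parametric bootstrap. When all ratios are
#' identical (zero bandwidth) the common ratio is returned.
#'
#' @inheritParams weighted_median
#' @param weighted Use IVW weights (`TRUE`) or equal weights (`FALSE`).
#' @param phi Bandwidth multiplier (default 1).
#' @return A one-row `mr_estimate` tibble (method `"weighted_mode"` or
#'   `"simple_mode"`).
#' @export
mode_estimate <- function(h, weighted = TRUE, phi = 1.0, n_boot = 1000, seed) {
  k <- n_snp(h)
  if (k < 3) stop_domain("mode estimate requires at least 3 variants")
  rc <- ratio_components(h)
  use_w <- function(w) if (weighted) w else rep(1, length(w))
  beta <- mode_point(rc$ratio, use_w(rc$w), phi)
  se <- bootstrap_se(h, function(r, w) mode_point(r, use_w(w), phi),
                     n_boot, seed)
  if (!is.finite(se) || se == 0) se <- .Machine$double.eps
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
              beta, se, z_pval(beta, se), k)
}

#' Run the full MR estimator battery
#'
#' With a single instrument only the Wald ratio is computed; with two, only
#' IVW; with three or more, all five methods (IVW, MR-Egger, weighted median,
#' weighted mode, simple mode). `direction_consistent` is `TRUE` when at
#' least three of the computed estimates share the sign of the IVW (headline)
#' estimate — the "majority of methods agree" robustness rule.
#'
#' @param h A `harmonized_set`.
#' @param seed Integer seed used for all bootstrap SEs.
#' @param n_boot Bootstrap resamples for median/mode SEs.
#' @return An `mr_result`: a tibble of estimates (one row per method) with
#'   attributes `direction_consistent`, `exposure_id`, `outcome_id`.
#' @export
run_all_methods <- function(h, seed, n_boot = 1000) {
  k <- n_snp(h)
  if (k < 1) stop_domain("no variants")
  ests <- if (k == 1) {
    wald_ratio(bx_matrix(h)[1, 1], sx_matrix(h)[1, 1], h$by[1], h$se_y[1])
  } else if (k == 2) {
    ivw(h)
  } else {
    bind_rows(
      ivw(h),
      mr_egger(h),
      weighted_median(h, n_boot = n_boot, seed = seed),
      mode_estimate(h, weighted = TRUE, n_boot = n_boot, seed = seed + 1L),
      mode_estimate(h, weighted = FALSE, n_boot = n_boot, seed = seed + 2L)
    )
  }
  head_beta <- ests$beta[ests$method %in% c("ivw", "wald")][1]
  consistent <- sum(sign(ests$beta) == sign(head_beta)) >= min(3L, nrow(ests))
  structure(ests,
            class = c("mr_result", class(tibble())),
            direction_consistent = consistent,
            exposure_id = attr(h, "exposure_ids")[1],
            outcome_id = attr(h, "outcome_id"))
}

#' @export
print.mr_result <- function(x, ...) {
  cat("<mr_result> ", attr(x, "exposure_id"), " -> ", attr(x, "outcome_id"),
      " (direction consistent: ", attr(x, "direction_consistent"), ")\n",
      sep = "")
  NextMethod()
}
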