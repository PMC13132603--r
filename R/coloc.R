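#' Wakefield approximate Bayes factor
#'
#' Closed-form log Bayes factor for association at a single variant from its
#' effect estimate, SE, and a normal prior on the true effect with standard
#' deviation `prior_sd`:
#' `log ABF = 0.5 * log(1 - r) + 0.5 * z^2 * r` with `z = beta/se`,
#' `V = se^2`, `W = prior_sd^2`, `r = W/(V + W)`.
#'
#' @param beta,se Effect estimate and standard error (`se > 0`).
#' @param prior_sd Prior standard deviation of the true effect (`>= 0`).
#' @return A tibble with `z`, `V`, `W`, `r`, `log_abf` (vectorized).
#' @export
wakefield_log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop_domain("se must be strictly positive")
  if (any(prior_sd < 0)) stop_domain("prior_sd must be non-negative")
  z <- beta / se
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  tibble(z = z, V = V, W = W, r = r,
         log_abf = 0.5 * log1p(-r) + 0.5 * z^2 * r)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Bayesian colocalization over a region
#'
#' Enumerates the five single-causal-variant hypotheses for two traits over a
#' shared set of Q variants — H0 (no association), H1/H2 (association with
#' one trait only), H3 (two distinct causal variants), H4 (one shared causal
#' variant) — using per-variant Wakefield log approximate Bayes factors and
#' per-configuration priors `p1`, `p2`, `p12`. All sums are carried in log
#' space:
#' `L1 = logsumexp(l1)`, `L2 = logsumexp(l2)`, `L12 = logsumexp(l1 + l2)`,
#' with H3's sum over distinct pairs computed as `exp(L1)*exp(L2) -
#' exp(L12)` in log space. Posteriors are the prior-weighted terms
#' normalized to one.
#'
#' @param stats1,stats2 Regional summary statistics: `summary_stats` objects
#'   or tibbles with `variant_id`, `beta`, `se`. Effects must already refer
#'   to a common allele orientation (ABFs depend on `z^2`, so orientation
#'   does not alter the result).
#' @param p1,p2 Prior probability that a variant is causal for trait 1
#'   (resp. 2) only (defaults 1e-4).
#' @param p12 Prior probability that a variant is causal for both (default
#'   1e-5).
#' @param prior_sd1,prior_sd2 Prior effect SDs; defaults 0.15 for
#'   quantitative traits and 0.2 for case-control traits (resolved from the
#'   `trait_type` attribute when present).
#' @return A `coloc_result` list: `pp` (named vector `pp0`..`pp4`),
#'   `n_snps`, `priors`, `classification` (from [classify_coloc()]).
#' @export
coloc_abf <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = NULL, prior_sd2 = NULL) {
  default_sd <- function(s, given) {
    if (!is.null(given)) return(given)
    tt <- attr(s, "trait_type")
    if (identical(tt, "case_control")) 0.2 else 0.15
  }
  prior_sd1 <- default_sd(stats1, prior_sd1)
  prior_sd2 <- default_sd(stats2, prior_sd2)
  shared <- intersect(stats1$variant_id, stats2$variant_id)
  q <- length(shared)
  if (q == 0) stop_empty("no shared variants in the region")
  s1 <- stats1[match(shared, stats1$variant_id), , drop = FALSE]
  s2 <- stats2[match(shared, stats2$variant_id), , drop = FALSE]
  l1 <- wakefield_log_abf(s1$beta, s1$se, prior_sd1)$log_abf
  l2 <- wakefield_log_abf(s2$beta, s2$se, prior_sd2)$log_abf

  L1 <- logsumexp(l1)
  L2 <- logsumexp(l2)
  L12 <- logsumexp(l1 + l2)
  # sum over ordered pairs i != j of BF1_i * BF2_j
  L3 <- logdiffexp(L1 + L2, L12)

  logterm <- c(h0 = 0,
               h1 = log(p1) + L1,
               h2 = log(p2) + L2,
               h3 = log(p1) + log(p2) + L3,
               h4 = log(p12) + L12)
  denom <- logsumexp(logterm)
  pp <- exp(logterm - denom)
  names(pp) <- paste0("pp", 0:4)
  structure(list(pp = pp, n_snps = q,
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 prior_sd = c(prior_sd1, prior_sd2),
                 classification = classify_coloc(pp[["pp4"]])),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("<coloc_result> ", x$n_snps, " variants; PPH4 = ",
      signif(x$pp[["pp4"]], 4), " (", x$classification, ")\n", sep = "")
  print(round(x$pp, 4))
  invisible(x)
}

#' Classify colocalization evidence from PPH4
#'
#' `PPH4 >= 0.8` is strong evidence of a shared causal variant, `0.5 <= PPH4
#' < 0.8` moderate, and below 0.5 none.
#'
#' @param pp4 Posterior probability of hypothesis H4, in \[0, 1\].
#' @return `"strong"`, `"moderate"` or `"none"`.
#' @export
classify_coloc <- function(pp4) {
  if (any(pp4 < 0 | pp4 > 1)) stop_domain("pp4 must lie in [0, 1]")
  ifelse(pp4 >= 0.8, "strong", ifelse(pp4 >= 0.5, "moderate", "none"))
}
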