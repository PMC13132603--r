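#' Configuration for the GWAS summary-statistic triplet simulator
#'
#' Defines an exposure -> mediator -> outcome system measured in three
#' non-overlapping cohorts. Traits have unit variance; structural effects are
#' on the standardized scale (interpretable as log-odds for a case-control
#' outcome on the liability/log-odds scale). The defaults emulate a
#' well-powered metabolite -> protein -> disease screen: 150 exposure
#' instruments explaining 30% of exposure variance (molecular-QTL-class
#' instruments, per-SNP F around 200, so estimates are not distorted by
#' winner's curse or weak-instrument dilution), 50 mediator-specific
#' instruments (QTLs of the mediator itself, required for multivariable MR to
#' be identified) explaining 15% of mediator variance, 100 000 samples per
#' cohort, and structural effects beta2 = 0.3, beta4 = 0.2, direct = 0.14
#' (total effect 0.2, mediated proportion 30%).
#'
#' @param n_instruments Exposure instruments (gamma effects).
#' @param n_mediator_instruments Mediator-specific instruments (alpha
#'   effects with no exposure effect).
#' @param n_null_snps Variants with no effect on any trait.
#' @param maf_range Minor-allele-frequency range, within (0, 0.5].
#' @param nX,nM,nY GWAS sample sizes for exposure, mediator, outcome.
#' @param instrument_h2 Exposure variance explained by its instruments.
#' @param mediator_h2 Mediator variance explained by its own instruments
#'   (over and above the exposure path).
#' @param beta2,beta4,direct Structural effects: exposure->mediator,
#'   mediator->outcome, exposure->outcome direct.
#' @param pleiotropy_fraction Fraction of exposure instruments with
#'   horizontal pleiotropic effects on mediator and outcome.
#' @param pleiotropy_sd SD of those pleiotropic effects.
#' @param ld_blocks Optional list of `c(size, r)` pairs; each places `size`
#'   consecutive exposure instruments in one LD block with pairwise
#'   correlation `r`.
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_instruments = 150, n_mediator_instruments = 50,
                       n_null_snps = 200, maf_range = c(0.05, 0.5),
                       nX = 1e5, nM = 1e5, nY = 1e5,
                       instrument_h2 = 0.30, mediator_h2 = 0.15,
                       beta2 = 0.3, beta4 = 0.2, direct = 0.14,
                       pleiotropy_fraction = 0, pleiotropy_sd = 0.05,
                       ld_blocks = NULL, seed = 1L) {
  stopifnot(n_instruments > 0, n_mediator_instruments >= 0, n_null_snps >= 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            nX > 0, nM > 0, nY > 0,
            instrument_h2 > 0, instrument_h2 < 1,
            mediator_h2 >= 0, mediator_h2 < 1,
            pleiotropy_fraction >= 0, pleiotropy_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a GWAS summary-statistic triplet under a known causal structure
#'
#' Draws per-variant allele frequencies and instrument effects, propagates
#' them through the structural equations
#' `X = sum(gamma G) + eX`, `M = beta2 X + sum(alpha G) + eM`,
#' `Y = direct X + beta4 M + sum(delta G) + eY`
#' (residual variances completing unit trait variances), folds joint effects
#' through LD (`marginal_j = sum_k r_jk * joint_k`), and reports noisy
#' marginal estimates with `se = (2 maf (1-maf) N)^(-1/2)` per trait, drawn
#' independently for the three cohorts. True per-SNP marginal effects are
#' `gamma` on the exposure, `gamma beta2 + alpha` on the mediator and
#' `gamma (direct + beta2 beta4) + alpha beta4 + delta` on the outcome.
#'
#' @param config A [sim_config()].
#' @return A list: `exposure`, `mediator`, `outcome` (`summary_stats`), `ld`
#'   (an [ld_matrix()]), `truth` (a `triplet_truth` list with the structural
#'   parameters, per-variant effects, and the implied total effect).
#' @export
simulate_gwas_triplet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  nI <- cf$n_instruments; nA <- cf$n_mediator_instruments; n0 <- cf$n_null_snps
  p <- nI + nA + n0

  withr::with_seed(cf$seed, {
    maf <- runif(p, cf$maf_range[1], cf$maf_range[2])
    v <- 2 * maf * (1 - maf)

    # LD: identity outside the configured blocks of exposure instruments
    R <- diag(p)
    if (!is.null(cf$ld_blocks)) {
      at <- 1L
      for (blk in cf$ld_blocks) {
        size <- blk[1]; r <- blk[2]
        if (at + size - 1L > nI) stop_config("ld_blocks exceed instrument count")
        idx <- at:(at + size - 1L)
        R[idx, idx] <- r
        diag(R)[idx] <- 1
        at <- at + size
      }
    }

    gamma <- rep(0, p)
    g_raw <- rnorm(nI)
    idxI <- seq_len(nI)
    # scale so the instruments explain instrument_h2 of unit-variance X,
    # accounting for LD cross-terms
    scale_to <- function(raw, idx, target) {
      eff <- rep(0, p); eff[idx] <- raw
      gv <- eff * sqrt(v)
      var_raw <- drop(crossprod(gv, R %*% gv))
      eff * sqrt(target / var_raw)
    }
    gamma <- scale_to(g_raw, idxI, cf$instrument_h2)

    alpha <- rep(0, p)
    if (nA > 0) {
      idxA <- nI + seq_len(nA)
      alpha <- scale_to(rnorm(nA), idxA, max(cf$mediator_h2, 1e-12))
      if (cf$mediator_h2 == 0) alpha[] <- 0
    }
    delta <- rep(0, p)
    if (cf$pleiotropy_fraction > 0) {
      n_pleio <- round(cf$pleiotropy_fraction * nI)
      pleio <- sample(idxI, n_pleio)
      alpha[pleio] <- alpha[pleio] + rnorm(n_pleio, 0, cf$pleiotropy_sd)
      delta[pleio] <- rnorm(n_pleio, 0, cf$pleiotropy_sd)
    }

    # residual variances completing unit trait variances
    gv <- gamma * sqrt(v); av <- alpha * sqrt(v); dv <- delta * sqrt(v)
    qf <- function(a, b) drop(crossprod(a, R %*% b))
    var_gx <- qf(gv, gv)
    cov_xa <- qf(gv, av)
    var_a <- qf(av, av)
    var_eX <- 1 - var_gx
    var_eM <- 1 - (cf$beta2^2 + var_a + 2 * cf$beta2 * cov_xa)
    cov_xm <- cf$beta2 + cov_xa
    cov_xd <- qf(gv, dv); cov_ad <- qf(av, dv); var_d <- qf(dv, dv)
    cov_md <- cf$beta2 * cov_xd + cov_ad
    var_eY <- 1 - (cf$direct^2 + cf$beta4^2 +
                     2 * cf$direct * cf$beta4 * cov_xm + var_d +
                     2 * cf$direct * cov_xd + 2 * cf$beta4 * cov_md)
    if (var_eX <= 0 || var_eM <= 0 || var_eY <= 0) {
      stop_config("infeasible variance budget: structural + genetic variance exceeds 1")
    }

    # joint (conditional) per-allele effects and their LD-folded marginals
    total <- cf$direct + cf$beta2 * cf$beta4
    joint_x <- gamma
    joint_m <- gamma * cf$beta2 + alpha
    joint_y <- gamma * total + alpha * cf$beta4 + delta
    marg <- function(j) drop(R %*% j)

    ids <- sprintf("rs%05d", seq_len(p))
    chrom <- as.character(rep_len(1:22, p))
    pos <- as.integer(20e6 * (seq_len(p) %/% 22 + 1) + seq_len(p))
    # LD-block members must sit within the clumping window of each other
    if (!is.null(cf$ld_blocks)) {
      at <- 1L
      for (blk in cf$ld_blocks) {
        idx <- at:(at + blk[1] - 1L)
        chrom[idx] <- chrom[idx[1]]
        pos[idx] <- pos[idx[1]] + seq_along(idx) * 1000L
        at <- at + blk[1]
      }
    }

    make_stats <- function(joint, n, id, type) {
      se <- 1 / sqrt(v * n)
      b_true <- marg(joint)
      b_hat <- rnorm(p, b_true, se)
      as_summary_stats(
        tibble(variant_id = ids, chrom = chrom, pos = pos,
               effect_allele = "A", other_allele = "G",
               beta = b_hat, se = se, pval = z_pval(b_hat, se),
               eaf = maf, n = n),
        trait_id = id, trait_type = type)
    }

    res <- list(
      exposure = make_stats(joint_x, cf$nX, "exposure", "quantitative"),
      mediator = make_stats(joint_m, cf$nM, "mediator", "quantitative"),
      outcome  = make_stats(joint_y, cf$nY, "outcome", "case_control"),
      ld = ld_matrix(R, variant_ids = ids),
      truth = structure(list(
        beta2_true = cf$beta2, beta4_true = cf$beta4,
        direct_true = cf$direct, total_true = total,
        mediated_proportion_true = if (total != 0) 100 * cf$beta2 * cf$beta4 / total else NA_real_,
        gamma = gamma, alpha = alpha, delta = delta,
        maf = maf, variant_ids = ids,
        pleiotropy_fraction = cf$pleiotropy_fraction, seed = cf$seed
      ), class = "triplet_truth")
    )
  })
  res
}

#' @export
print.triplet_truth <- function(x, ...) {
  cat("<triplet_truth> beta2 = ", x$beta2_true, ", beta4 = ", x$beta4_true,
      ", direct = ", x$direct_true, " (total ", x$total_true, ", mediated ",
      signif(x$mediated_proportion_true, 4), "%)\n", sep = "")
  invisible(x)
}
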