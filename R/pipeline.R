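#' Pipeline configuration
#'
#' Thresholds and switches for the five-stage MR workflow: discovery TSMR
#' over an exposure panel, replication against an independent outcome GWAS,
#' bidirectional TSMR between the surviving exposure and candidate
#' mediators, multivariable MR models, and product-of-coefficients
#' mediation.
#'
#' @param iv_p Instrument p-value cutoff (default 5e-6).
#' @param r2 Clumping r-squared threshold (default 0.001).
#' @param window_kb Clumping window (default 10000).
#' @param f_min Minimum instrument F statistic (default 10).
#' @param fdr FDR significance threshold (default 0.05).
#' @param fdr_family `"per_panel"` (adjust within each exposure panel, e.g.
#'   metabolites and proteins separately) or `"pooled"`.
#' @param seed Integer seed for all stochastic components.
#' @param n_boot Bootstrap resamples for median/mode SEs.
#' @param presso_n_sim MR-PRESSO resamples.
#' @param blacklist Variant ids excluded from instrument sets (confounder
#'   screen).
#' @param stages Character subset of
#'   `c("discovery", "replication", "bidirectional", "mvmr", "mediation")`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(iv_p = 5e-6, r2 = 0.001, window_kb = 10000,
                            f_min = 10, fdr = 0.05,
                            fdr_family = c("per_panel", "pooled"),
                            seed = 1L, n_boot = 1000, presso_n_sim = 1000,
                            blacklist = character(0),
                            stages = c("discovery", "replication",
                                       "bidirectional", "mvmr", "mediation")) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(iv_p > 0, r2 > 0, window_kb > 0, f_min >= 0, fdr > 0, fdr < 1)
  structure(list(iv_p = iv_p, r2 = r2, window_kb = window_kb, f_min = f_min,
                 fdr = fdr, fdr_family = fdr_family, seed = as.integer(seed),
                 n_boot = n_boot, presso_n_sim = presso_n_sim,
                 blacklist = blacklist, stages = stages),
            class = "pipeline_config")
}

# instrument selection + harmonization + estimator battery + sensitivity
# diagnostics for one exposure/outcome pair; NULL rows when not estimable
analyze_pair <- function(exposure, outcome, ld, config, seed) {
  iv <- select_instruments(exposure, ld, p_threshold = config$iv_p,
                           r2_threshold = config$r2,
                           window_kb = config$window_kb, f_min = config$f_min,
                           blacklist = config$blacklist)
  if (nrow(iv) == 0) return(NULL)
  expo_sub <- as_summary_stats(
    as_tibble(exposure)[exposure$variant_id %in% iv$variant_id, , drop = FALSE],
    trait_id(exposure), trait_type(exposure))
  h <- tryCatch(harmonize(expo_sub, outcome),
                mrmediate_empty_error = function(e) NULL)
  if (is.null(h)) return(NULL)
  res <- run_all_methods(h, seed = seed, n_boot = config$n_boot)
  k <- n_snp(h)
  head_est <- res[res$method %in% c("ivw", "wald"), ][1, ]
  q_p <- if (k >= 2) cochran_q(h)$pval else NA_real_
  egger_p <- if (k >= 3) egger_intercept_test(h)$pval else NA_real_
  presso_p <- if (k >= 4) {
    mr_presso(h, n_sim = config$presso_n_sim, seed = seed)$global_pval
  } else NA_real_
  list(h = h, estimates = res,
       row = tibble(exposure = trait_id(exposure),
                    outcome = trait_id(outcome),
                    n_snp = k, beta = head_est$beta, se = head_est$se,
                    pval = head_est$pval,
                    odds_ratio = head_est$odds_ratio,
                    direction_consistent = attr(res, "direction_consistent"),
                    q_pval = q_p, egger_intercept_pval = egger_p,
                    presso_global_pval = presso_p))
}

sensitivity_clean <- function(row) {
  (is.na(row$egger_intercept_pval) | row$egger_intercept_pval > 0.05) &
    (is.na(row$presso_global_pval) | row$presso_global_pval > 0.05)
}

#' Stage 1: discovery TSMR screen over an exposure panel
#'
#' Runs the full TSMR workflow for every exposure against the discovery
#' outcome, BH-adjusts the headline (IVW/Wald) p-values — within each
#' exposure panel when `fdr_family = "per_panel"`, jointly when `"pooled"` —
#' and flags exposures passing the FDR threshold.
#'
#' @param exposures List of `summary_stats` (the exposure panel).
#' @param outcome Discovery outcome `summary_stats`.
#' @param ld An [ld_matrix()].
#' @param config A [pipeline_config()].
#' @param panels Optional character vector (same length as `exposures`)
#'   assigning each exposure to an adjustment family.
#' @return A `stage_report` tibble (one row per exposure, not-estimable
#'   exposures flagged by `estimable = FALSE`) with columns including
#'   `fdr_adjusted_p` and `pass`; attribute `estimates` holds the per-exposure
#'   `mr_result` objects.
#' @export
stage1_discovery <- function(exposures, outcome, ld, config,
                             panels = NULL) {
  if (length(exposures) == 0) stop_config("empty exposure panel")
  panels <- panels %||% rep("panel", length(exposures))
  fits <- purrr::map2(exposures, seq_along(exposures), function(e, i) {
    analyze_pair(e, outcome, ld, config, seed = config$seed + i)
  })
  rows <- purrr::map2_dfr(fits, seq_along(fits), function(f, i) {
    if (is.null(f)) {
      tibble(exposure = trait_id(exposures[[i]]), outcome = trait_id(outcome),
             n_snp = 0L, beta = NA_real_, se = NA_real_, pval = NA_real_,
             odds_ratio = NA_real_, direction_consistent = NA,
             q_pval = NA_real_, egger_intercept_pval = NA_real_,
             presso_global_pval = NA_real_)
    } else f$row
  })
  rows$panel <- panels
  rows$estimable <- !is.na(rows$pval)
  rows$fdr_adjusted_p <- NA_real_
  fam <- if (config$fdr_family == "per_panel") rows$panel else "all"
  for (g in unique(fam)) {
    idx <- fam == g & rows$estimable
    if (any(idx)) rows$fdr_adjusted_p[idx] <- bh_fdr(rows$pval[idx])
  }
  rows$pass <- rows$estimable & !is.na(rows$fdr_adjusted_p) &
    rows$fdr_adjusted_p < config$fdr
  structure(rows, class = c("stage_report", class(tibble())),
            stage = "discovery",
            estimates = purrr::map(fits, ~ if (is.null(.x)) NULL else .x$estimates))
}

#' Stage 2: replication of discovery hits
#'
#' Re-estimates every stage-1 passing exposure against an independent
#' replication outcome. An exposure passes when its replication FDR is below
#' the threshold, the replication IVW sign agrees with discovery, and the
#' sensitivity block is clean (Egger intercept p > 0.05 and PRESSO global
#' p > 0.05 where computable).
#'
#' @param stage1 The stage-1 `stage_report`.
#' @param exposures The same exposure panel given to stage 1.
#' @param replication_outcome Replication outcome `summary_stats`.
#' @inheritParams stage1_discovery
#' @return A `stage_report` tibble over the stage-1 passers.
#' @export
stage2_replication <- function(stage1, exposures, replication_outcome, ld,
                               config) {
  passers <- stage1$exposure[stage1$pass]
  if (length(passers) == 0) stop_config("no stage-1 passing exposures to replicate")
  ids <- vapply(exposures, trait_id, character(1))
  rows <- purrr::map_dfr(passers, function(ex) {
    f <- analyze_pair(exposures[[match(ex, ids)]], replication_outcome, ld,
                      config, seed = config$seed + 1000L + match(ex, ids))
    if (is.null(f)) {
      tibble(exposure = ex, outcome = trait_id(replication_outcome),
             n_snp = 0L, beta = NA_real_, se = NA_real_, pval = NA_real_,
             odds_ratio = NA_real_, direction_consistent = NA,
             q_pval = NA_real_, egger_intercept_pval = NA_real_,
             presso_global_pval = NA_real_)
    } else f$row
  })
  rows$estimable <- !is.na(rows$pval)
  rows$fdr_adjusted_p <- NA_real_
  if (any(rows$estimable)) {
    rows$fdr_adjusted_p[rows$estimable] <- bh_fdr(rows$pval[rows$estimable])
  }
  disc_beta <- stage1$beta[match(rows$exposure, stage1$exposure)]
  rows$sign_consistent <- sign(rows$beta) == sign(disc_beta)
  rows$sensitivity_clean <- sensitivity_clean(rows)
  rows$pass <- rows$estimable & !is.na(rows$fdr_adjusted_p) &
    rows$fdr_adjusted_p < config$fdr &
    rows$sign_consistent & rows$sensitivity_clean
  structure(rows, class = c("stage_report", class(tibble())),
            stage = "replication")
}

#' Stage 3: bidirectional TSMR between an exposure and candidate mediators
#'
#' @param exposure The replicated exposure `summary_stats`.
#' @param mediators Named list of mediator `summary_stats`.
#' @inheritParams stage1_discovery
#' @return A tibble with one row per (direction, mediator): `mediator`,
#'   `direction` (`"forward"` = exposure to mediator), `estimable`, headline
#'   `beta`, `se`, `pval`, `n_snp`, `significant`; attribute `results` holds
#'   the full `bidirectional_tsmr()` outputs.
#' @export
stage3_bidirectional <- function(exposure, mediators, ld, config) {
  if (length(mediators) == 0) stop_config("no mediators supplied")
  names(mediators) <- vapply(mediators, trait_id, character(1))
  results <- purrr::imap(mediators, function(m, nm) {
    bidirectional_tsmr(exposure, m, ld, seed = config$seed + 2000L,
                       p_threshold = config$iv_p, r2_threshold = config$r2,
                       window_kb = config$window_kb, f_min = config$f_min,
                       n_boot = config$n_boot)
  })
  rows <- purrr::imap_dfr(results, function(res, nm) {
    one <- function(r, dir) {
      if (is.null(r)) {
        tibble(mediator = nm, direction = dir, estimable = FALSE,
               n_snp = 0L, beta = NA_real_, se = NA_real_, pval = NA_real_,
               significant = NA)
      } else {
        head_est <- r[r$method %in% c("ivw", "wald"), ][1, ]
        tibble(mediator = nm, direction = dir, estimable = TRUE,
               n_snp = head_est$n_snp, beta = head_est$beta,
               se = head_est$se, pval = head_est$pval,
               significant = head_est$pval < 0.05)
      }
    }
    bind_rows(one(res$forward, "forward"), one(res$reverse, "reverse"))
  })
  structure(rows, class = c("stage_report", class(tibble())),
            stage = "bidirectional", results = results)
}

# joint instrument set for MVMR: union of per-trait instruments, re-clumped
# at the same thresholds, then harmonized across all traits
mvmr_harmonize <- function(traits, outcome, ld, config) {
  ivs <- purrr::map(traits, function(tr) {
    select_instruments(tr, ld, p_threshold = config$iv_p,
                       r2_threshold = config$r2, window_kb = config$window_kb,
                       f_min = config$f_min, blacklist = config$blacklist)
  })
  cand <- bind_rows(purrr::map(ivs, ~ as_tibble(.x)[, c("variant_id", "chrom",
                                                        "pos", "pval")])) |>
    group_by(.data$variant_id) |>
    summarise(chrom = .data$chrom[1], pos = .data$pos[1],
              pval = min(.data$pval), .groups = "drop")
  if (nrow(cand) == 0) stop_config("no instruments for any MVMR exposure")
  kept <- clump(cand, ld, r2_threshold = config$r2,
                window_kb = config$window_kb)
  h <- harmonize(traits, outcome)
  h <- h_subset(h, h$variant_id %in% kept)
  if (n_snp(h) == 0) stop_empty("no harmonized MVMR instruments")
  h
}

#' Stage 4: multivariable MR models
#'
#' Fits one MVMR model per requested exposure combination. With one exposure
#' and two mediators the default mirrors the three-model design: exposure +
#' mediator A, exposure + mediator B, exposure + both.
#'
#' @param exposure Exposure `summary_stats`.
#' @param mediators Named list of mediator `summary_stats`.
#' @param outcome Outcome `summary_stats`.
#' @inheritParams stage1_discovery
#' @return Named list of `mvmr_result` objects (a failed model carries the
#'   condition object instead, so the remaining models still run).
#' @export
stage4_mvmr <- function(exposure, mediators, outcome, ld, config) {
  if (length(mediators) == 0) stop_config("MVMR requires at least one mediator")
  names(mediators) <- vapply(mediators, trait_id, character(1))
  combos <- c(purrr::imap(mediators, ~ list(traits = list(exposure, .x),
                                            label = paste0(trait_id(exposure),
                                                           " + ", .y))),
              if (length(mediators) > 1) {
                list(all = list(traits = c(list(exposure), unname(mediators)),
                                label = paste(c(trait_id(exposure),
                                                names(mediators)),
                                              collapse = " + ")))
              })
  purrr::map(combos, function(cb) {
    tryCatch({
      h <- mvmr_harmonize(cb$traits, outcome, ld, config)
      mvmr_ivw(h, model_label = cb$label)
    }, error = function(e) e)
  })
}

#' Stage 5: mediation decomposition
#'
#' Combines the total effect (discovery/replication TSMR), the
#' exposure-to-mediator effect (stage-3 forward TSMR) and the mediator's
#' direct effect on the outcome (the stage-4 MVMR model containing that
#' mediator) into the product-of-coefficients decomposition, recording the
#' provenance of each coefficient.
#'
#' @param beta_total Total exposure-to-outcome effect (beta1).
#' @param beta_exp_to_med Exposure-to-mediator effect (beta2).
#' @param mvmr_model An `mvmr_result` containing the mediator's coefficient.
#' @param mediator_id Which exposure row of `mvmr_model` is the mediator.
#' @param se2 Optional SE of beta2 for the Sobel SE.
#' @param beta_med_to_out_tsmr Optional univariable beta3, recorded only.
#' @return A `mediation_result` with a `provenance` attribute.
#' @export
stage5_mediation <- function(beta_total, beta_exp_to_med, mvmr_model,
                             mediator_id, se2 = NA_real_,
                             beta_med_to_out_tsmr = NA_real_) {
  if (missing(beta_total) || missing(beta_exp_to_med) || missing(mvmr_model)) {
    stop_config("mediation needs beta_total, beta_exp_to_med and an MVMR model")
  }
  if (!inherits(mvmr_model, "mvmr_result")) {
    stop_config("mvmr_model must be an mvmr_result")
  }
  i <- match(mediator_id, mvmr_model$exposure)
  if (is.na(i)) stop_config("mediator not found in the MVMR model")
  out <- mediation_effects(beta_total, beta_exp_to_med,
                           mvmr_model$beta[i], se2 = se2,
                           se4 = mvmr_model$se[i],
                           beta_med_to_out_tsmr = beta_med_to_out_tsmr)
  attr(out, "provenance") <- list(
    beta1 = "univariable TSMR, exposure -> outcome",
    beta2 = "univariable TSMR, exposure -> mediator",
    beta4 = paste0("MVMR model '", attr(mvmr_model, "model_label"), "'"))
  out
}

#' Run the five-stage workflow end to end
#'
#' Executes the enabled stages in order, short-circuiting when a stage
#' yields no passing exposures, and returns every stage report together with
#' a reproducibility manifest (configuration hash, seed, package version).
#'
#' @param exposures Named list of exposure `summary_stats`.
#' @param outcome_discovery,outcome_replication Outcome `summary_stats`.
#' @param mediators Named list of mediator `summary_stats`.
#' @param ld An [ld_matrix()].
#' @param config A [pipeline_config()].
#' @param panels Optional panel labels for the FDR family.
#' @return A `pipeline_result` list: `stage1`, `stage2`, `stage3`, `stage4`,
#'   `stage5`, `manifest`.
#' @export
run_pipeline <- function(exposures, outcome_discovery,
                         outcome_replication = NULL, mediators = list(),
                         ld, config = pipeline_config(), panels = NULL) {
  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("mrmediate")),
    stages = config$stages)
  out <- list(manifest = manifest)
  on <- function(s) s %in% config$stages

  if (!on("discovery")) return(structure(out, class = "pipeline_result"))
  out$stage1 <- stage1_discovery(exposures, outcome_discovery, ld, config,
                                 panels = panels)
  if (!any(out$stage1$pass)) return(structure(out, class = "pipeline_result"))

  if (on("replication") && !is.null(outcome_replication)) {
    out$stage2 <- stage2_replication(out$stage1, exposures,
                                     outcome_replication, ld, config)
    if (!any(out$stage2$pass)) return(structure(out, class = "pipeline_result"))
    lead <- out$stage2$exposure[out$stage2$pass][1]
  } else {
    lead <- out$stage1$exposure[out$stage1$pass][1]
  }
  lead_stats <- exposures[[match(lead, vapply(exposures, trait_id,
                                              character(1)))]]

  if (on("bidirectional") && length(mediators) > 0) {
    out$stage3 <- stage3_bidirectional(lead_stats, mediators, ld, config)
  }
  if (on("mvmr") && length(mediators) > 0) {
    out$stage4 <- stage4_mvmr(lead_stats, mediators, outcome_discovery, ld,
                              config)
  }
  if (on("mediation") && length(mediators) > 0 && !is.null(out$stage4)) {
    med_id <- trait_id(mediators[[1]])
    model <- purrr::detect(out$stage4, function(m) {
      inherits(m, "mvmr_result") && med_id %in% m$exposure
    })
    fwd <- out$stage3$beta[out$stage3$mediator == med_id &
                             out$stage3$direction == "forward"][1] %||% NA_real_
    beta1 <- out$stage1$beta[out$stage1$exposure == lead][1]
    if (!is.null(model) && !is.na(fwd)) {
      out$stage5 <- stage5_mediation(beta1, fwd, model, mediator_id = med_id)
    }
  }
  structure(out, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages run:",
      paste(intersect(c("stage1", "stage2", "stage3", "stage4", "stage5"),
                      names(x)), collapse = ", "), "\n")
  if (!is.null(x$stage5)) {
    cat("mediated proportion:",
        signif(x$stage5$mediated_proportion_pct, 4), "%\n")
  }
  invisible(x)
}
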