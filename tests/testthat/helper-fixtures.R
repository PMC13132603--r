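# Fixture builders shared across test files. All fixtures are built in code;
# nothing is read from disk unless the test is exercising the readers.

make_stats <- function(variant_id, beta, se, pval = NULL,
                       chrom = "1", pos = NULL,
                       ea = "A", oa = "G", eaf = 0.3, n = 1e5,
                       trait = "trait", type = "quantitative") {
  k <- length(variant_id)
  pos <- pos %||% (seq_len(k) * 2e7)
  pval <- pval %||% (2 * pnorm(-abs(beta / se)))
  as_summary_stats(
    tibble::tibble(variant_id = variant_id, chrom = rep_len(chrom, k),
                   pos = pos, effect_allele = rep_len(ea, k),
                   other_allele = rep_len(oa, k), beta = beta, se = se,
                   pval = pval, eaf = rep_len(eaf, k), n = rep_len(n, k)),
    trait_id = trait, trait_type = type)
}

make_h <- function(bx, se_x, by, se_y, ids = NULL) {
  ids <- ids %||% paste0("rs", seq_along(by))
  harmonized_set(ids, bx = bx, se_x = se_x, by = by, se_y = se_y)
}

# weighted-least-squares oracle via lm(); independent of the package's own
# normal-equations code paths
wls_oracle <- function(y, X, w, intercept = FALSE) {
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  fm <- paste("y ~", paste(names(df), collapse = " + "),
              if (!intercept) "- 1" else "")
  df$y <- y
  lm(as.formula(fm), data = df, weights = w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force enumeration oracle: loop explicitly over every single-variant
# configuration for H1/H2/H4 and every ordered pair for H3, in linear space.
coloc_oracle <- function(b1, s1, b2, s2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         sd1 = 0.15, sd2 = 0.2) {
  abf <- function(b, s, w) {
    r <- w^2 / (s^2 + w^2)
    exp(0.5 * log(1 - r) + 0.5 * (b / s)^2 * r)
  }
  bf1 <- abf(b1, s1, sd1)
  bf2 <- abf(b2, s2, sd2)
  q <- length(bf1)
  t0 <- 1
  t1 <- 0; t2 <- 0; t3 <- 0; t4 <- 0
  for (i in seq_len(q)) {
    t1 <- t1 + p1 * bf1[i]
    t2 <- t2 + p2 * bf2[i]
    t4 <- t4 + p12 * bf1[i] * bf2[i]
    for (j in seq_len(q)) {
      if (i != j) t3 <- t3 + p1 * p2 * bf1[i] * bf2[j]
    }
  }
  terms <- c(t0, t1, t2, t3, t4)
  terms / sum(terms)
}

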