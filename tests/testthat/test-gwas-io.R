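test_that("read_summary_stats parses well-formed tables and rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    SNP = c("rs1", "rs2", "rs3"), CHR = c("1", "1", "chr2"),
    POS = c(100L, 200L, 300L), EA = c("A", "C", "T"), OA = c("G", "T", "A"),
    BETA = c(0.1, -0.2, 0.05), SE = c(0.02, 0.03, 0.01),
    P = c(1e-6, 1e-8, 0.5), EAF = c(0.2, 0.4, 0.5), N = c(1e5, 1e5, 1e5)
  ), path)
  ss <- read_summary_stats(path, trait_id = "t", trait_type = "quantitative")
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss), 3L)
  expect_equal(attr(ss, "n_rejected"), 0L)
  expect_equal(ss$chrom, c("1", "1", "2"))  # "chr" prefix normalized

  # a zero-SE row violates the invariant and is dropped with a count
  readr::write_tsv(tibble::tibble(
    SNP = c("rs1", "rs2"), CHR = "1", POS = c(1L, 2L), EA = "A", OA = "G",
    BETA = c(0.1, 0.2), SE = c(0, 0.02), P = c(0.1, 0.2), EAF = 0.3, N = 10
  ), path)
  expect_message(ss2 <- read_summary_stats(path, trait_id = "t"),
                 "1 row")
  expect_equal(nrow(ss2), 1L)
  expect_equal(attr(ss2, "n_rejected"), 1L)
})

test_that("read_summary_stats flags configuration problems", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(SNP = "rs1", CHR = "1", POS = 1L,
                                  EA = "A", OA = "G", BETA = 0.1,
                                  SE = 0.01, P = 0.5), path)
  bad_map <- default_column_map()[setdiff(names(default_column_map()), "beta")]
  expect_error(read_summary_stats(path, column_map = bad_map),
               class = "mrmediate_config_error")
  expect_error(read_summary_stats(file.path(tempdir(), "nope.tsv")),
               class = "mrmediate_config_error")
})

test_that("summary stats round-trip through the default tabular layout", {
  ss <- make_stats(c("rs1", "rs2"), beta = c(0.1, -0.3), se = c(0.01, 0.02))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  back <- read_summary_stats(path, trait_id = trait_id(ss))
  expect_equal(as.data.frame(back), as.data.frame(ss))
})

test_that("harmonize keeps matched alleles, flips swapped ones, drops ambiguous palindromes", {
  expo <- make_stats("rs1", beta = 0.10, se = 0.01, ea = "A", oa = "G")
  out_same <- make_stats("rs1", beta = -0.05, se = 0.01, ea = "A", oa = "G",
                         trait = "out")
  h <- harmonize(expo, out_same)
  expect_equal(h$by, -0.05)

  out_swap <- make_stats("rs1", beta = -0.05, se = 0.01, ea = "G", oa = "A",
                         trait = "out")
  h2 <- harmonize(expo, out_swap)
  expect_equal(h2$by, +0.05)

  # palindromic with eaf at 0.5: orientation unresolvable
  expo_pal <- make_stats("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "T",
                         eaf = 0.5)
  out_pal <- make_stats(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.2, 0.3),
                        se = 0.01, ea = c("A", "C", "A"),
                        oa = c("T", "G", "G"), eaf = c(0.5, 0.5, 0.2),
                        trait = "out")
  expo_two <- make_stats(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.01,
                         ea = c("A", "C", "A"), oa = c("T", "G", "G"),
                         eaf = c(0.5, 0.2, 0.2))
  h3 <- harmonize(expo_two, out_pal)
  # rs1 ambiguous via exposure eaf, rs2 via outcome eaf; rs3 retained
  expect_equal(attr(h3, "n_dropped_palindromic"), 2L)
  expect_equal(h3$variant_id, "rs3")
  expect_error(harmonize(expo_pal, make_stats("rs1", 0.1, 0.01, ea = "A",
                                              oa = "T", eaf = 0.5,
                                              trait = "out")),
               class = "mrmediate_empty_error")
})

test_that("harmonize drops incompatible allele sets and accounts for every shared variant", {
  expo <- make_stats(c("rs1", "rs2", "rs3", "rs4"),
                     beta = c(0.1, 0.2, 0.3, 0.4), se = 0.01,
                     ea = c("A", "A", "A", "A"), oa = c("G", "G", "G", "T"),
                     eaf = c(0.2, 0.2, 0.2, 0.5))
  outc <- make_stats(c("rs1", "rs2", "rs3", "rs4"),
                     beta = c(0.5, 0.6, 0.7, 0.8), se = 0.01,
                     ea = c("A", "G", "A", "A"), oa = c("G", "A", "C", "T"),
                     eaf = c(0.2, 0.8, 0.2, 0.5), trait = "out")
  h <- harmonize(expo, outc)
  # rs3 has A/C vs A/G: incompatible; rs4 palindromic at eaf 0.5: ambiguous
  expect_equal(sort(h$variant_id), c("rs1", "rs2"))
  expect_equal(attr(h, "n_dropped_incompatible"), 1L)
  expect_equal(attr(h, "n_dropped_palindromic"), 1L)
  shared <- length(intersect(expo$variant_id, outc$variant_id))
  expect_equal(shared, nrow(h) + attr(h, "n_dropped_palindromic") +
                 attr(h, "n_dropped_incompatible"))
})

test_that("harmonize is idempotent and round-trips under allele-label swap", {
  set.seed(41)
  k <- 8
  expo <- make_stats(paste0("rs", 1:k), beta = rnorm(k, 0, 0.1),
                     se = runif(k, 0.01, 0.03), eaf = runif(k, 0.1, 0.35))
  outc <- make_stats(paste0("rs", 1:k), beta = rnorm(k, 0, 0.05),
                     se = runif(k, 0.01, 0.03), eaf = runif(k, 0.1, 0.35),
                     trait = "out")
  h <- harmonize(expo, outc)

  # idempotence: re-harmonizing the aligned tables changes nothing
  outc2 <- make_stats(h$variant_id, beta = h$by, se = h$se_y,
                      eaf = 0.2, trait = "out")
  expo2 <- make_stats(h$variant_id, beta = h$bx, se = h$se_x, eaf = 0.2)
  h2 <- harmonize(expo2, outc2)
  expect_equal(h2$by, h$by)
  expect_equal(h2$bx, h$bx)

  # swapping outcome allele labels and negating betas is a no-op after harmonization
  outc_swapped <- make_stats(paste0("rs", 1:k), beta = -outc$beta,
                             se = outc$se, ea = "G", oa = "A",
                             eaf = 1 - outc$eaf, trait = "out")
  h3 <- harmonize(expo, outc_swapped)
  expect_equal(h3$by, h$by)
})

test_that("LD matrices read from square and triplet layouts with validation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\ts1\ts2", "s1\t1\t0", "s2\t0\t1"), path)
  ld <- read_ld_matrix(path)
  expect_equal(ld$r["s1", "s2"], 0)
  expect_equal(diag(ld$r), c(s1 = 1, s2 = 1))

  trip <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id1\tid2\tr", "s1\ts2\t0.7"), trip)
  ld2 <- read_ld_matrix(trip)
  expect_equal(ld2$r["s2", "s1"], 0.7)  # symmetrized

  writeLines(c("id1\tid2\tr", "s1\ts2\t1.2"), trip)
  expect_error(read_ld_matrix(trip), class = "mrmediate_format_error")

  m <- matrix(c(1, 0.5, 0.2, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(ld_matrix(m), class = "mrmediate_format_error")  # asymmetric
})

test_that("LD matrices round-trip through the square TSV writer", {
  r <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(c("s1", "s2"),
                                                       c("s1", "s2")))
  ld <- ld_matrix(r)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, path)
  expect_equal(read_ld_matrix(path)$r, ld$r)
})
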