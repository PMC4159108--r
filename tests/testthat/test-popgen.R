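test_that("allele frequencies count chromosomes, excluding missing calls", {
  panel <- tiny_panel(c(A = 5L, B = 5L))
  geno <- rbind(rep(0L, 10),
                c(1L, rep(0L, 9)),
                c(1L, NA, rep(0L, 8)))
  vt <- vt_from_geno(geno, panel)
  af <- allele_frequencies(vt, "population")
  expect_equal(unname(af$freq["A", ]), c(0, 0.1, 0.125))
  expect_equal(unname(af$n_chrom["A", ]), c(10L, 10L, 8L))
  expect_equal(unname(af$freq["B", ]), c(0, 0, 0))
})

test_that("pooled grouping excludes admixed samples from both pools", {
  panel <- tiny_panel(c(A = 3L, B = 3L, C = 2L),
                      regions = c(A = "Africa", B = "Europe", C = "Admixed"),
                      admixed = "C")
  vt <- vt_from_geno(matrix(1L, 1, 8), panel)
  af <- allele_frequencies(vt, "pooled")
  expect_setequal(rownames(af$freq), c("Africa", "non-Africa"))
  expect_equal(unname(af$n_chrom[, 1]), c(6L, 6L))  # C's 2 samples in neither
})

test_that("watterson_theta matches hand arithmetic and scales with L", {
  expect_equal(watterson_theta(0, 10, 1000)$theta_per_site, 0)
  expect_equal(watterson_theta(11, 4, 1000)$theta_per_site, 0.006)
  expect_equal(watterson_theta(5, 2, 100)$theta_per_site, 5 / 100)  # a_1 = 1
  th1 <- watterson_theta(7, 20, 500)$theta_per_site
  th2 <- watterson_theta(7, 20, 1000)$theta_per_site
  expect_equal(th1, 2 * th2)
  expect_error(watterson_theta(5, 1, 100), "n >= 2")
})

test_that("PSMA detection finds exclusive alleles and high-frequency flags", {
  panel <- tiny_panel(c(A = 5L, B = 5L, C = 5L),
                      regions = c(A = "Africa", B = "Europe", C = "Asia"))
  geno <- rbind(c(1L, rep(0L, 14)),                       # only in A
                c(1L, 0L, 0L, 0L, 0L, 1L, rep(0L, 9)),    # A and B
                c(rep(0L, 5), rep(0L, 5), 2L, 2L, 2L, 0L, 0L))  # only C, f=0.6
  vt <- vt_from_geno(geno, panel)
  ps <- detect_psma(vt)
  expect_equal(nrow(ps$records), 2)
  expect_setequal(ps$records$population, c("A", "C"))
  expect_equal(ps$records$high_frequency[ps$records$population == "A"], FALSE)
  expect_equal(ps$records$high_frequency[ps$records$population == "C"], TRUE)
  expect_equal(ps$density$density[ps$density$population == "A"], 1 / 5)
  expect_equal(ps$density$density[ps$density$population == "B"], 0)
})

test_that("wc_fst reproduces worked examples and is symmetric", {
  expect_equal(wc_fst(1, 20, 0, 20)$theta_raw, 1)
  f <- wc_fst(0.5, 10, 0.5, 10)
  expect_equal(f$theta_raw, -1 / 9)
  expect_equal(f$theta_reported, 0)
  expect_equal(wc_fst(0.8, 10, 0.2, 10)$theta_raw, 0.477124183, tolerance = 1e-8)
  set.seed(31)
  for (i in 1:50) {
    n1 <- 2 * sample(2:40, 1); n2 <- 2 * sample(2:40, 1)
    p1 <- sample(0:n1, 1) / n1; p2 <- sample(0:n2, 1) / n2
    a <- wc_fst(p1, n1, p2, n2); b <- wc_fst(p2, n2, p1, n1)
    expect_equal(a$theta_raw, b$theta_raw)
    expect_equal(a$a, b$a); expect_equal(a$w, b$w)
  }
  # both groups monomorphic for the same allele: undefined, not an exception
  u <- wc_fst(0, 10, 0, 10)
  expect_false(u$defined)
  expect_true(is.na(u$theta_raw))
})

test_that("welch_test matches stats::t.test and handles degenerate groups", {
  a <- c(0, 1, 1, 2) / 2
  b <- c(2, 2, 1, 2) / 2
  got <- welch_test(a, b)
  expect_equal(got$t, -1.5667, tolerance = 1e-4)
  expect_equal(got$df, 4.97, tolerance = 1e-2)
  ref <- t.test(a, b)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$df, unname(ref$parameter))
  expect_equal(got$p, ref$p.value)
  set.seed(41)
  for (i in 1:50) {
    x <- rbinom(8, 2, 0.5) / 2; y <- rbinom(12, 2, 0.3) / 2
    if (var(x) == 0 && var(y) == 0) next
    ref <- t.test(x, y)
    got <- welch_test(x, y)
    expect_equal(got$t, unname(ref$statistic))
    expect_equal(got$p, ref$p.value)
  }
  ident <- welch_test(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(ident$t, 0); expect_equal(ident$p, 1)
  expect_false(ident$degenerate)
  deg <- welch_test(c(0, 0, 0), c(1, 1, 1))
  expect_equal(deg$p, 0); expect_true(deg$degenerate)
  expect_error(welch_test(0.5, c(0, 1)), ">= 2")
})

test_that("welch_test vectorises over loci identically to the scalar path", {
  set.seed(43)
  A <- matrix(rbinom(50 * 6, 2, 0.4) / 2, 50)
  B <- matrix(rbinom(50 * 8, 2, 0.6) / 2, 50)
  vec <- welch_test(A, B)
  for (i in c(1, 17, 50)) {
    one <- welch_test(A[i, ], B[i, ])
    expect_equal(vec$t[i], one$t)
    expect_equal(vec$p[i], one$p)
  }
})

test_that("percentile_threshold interpolates between order statistics", {
  expect_equal(percentile_threshold(rep(0.3, 10), 0.95), 0.3)
  vals <- seq(0, 0.99, by = 0.01)
  expect_equal(percentile_threshold(vals, 0.95), 0.9405)
  expect_error(percentile_threshold(vals, 1.2), "q must be")
  expect_error(percentile_threshold(numeric(0), 0.95), "no defined values")
  # NA / undefined values are ignored
  expect_equal(percentile_threshold(c(vals, NA, NaN), 0.95), 0.9405)
})

test_that("fst_scan enumerates hierarchical contrasts", {
  panel <- default_panel()
  cts <- make_contrasts(panel)
  lv <- vapply(cts, `[[`, character(1), "level")
  expect_equal(sum(lv == "population"), choose(14, 2))  # 91
  expect_equal(sum(lv == "region"), choose(4, 2))
  expect_equal(sum(lv == "pooled"), 1)
  pooled <- cts[[which(lv == "pooled")]]
  expect_equal(length(pooled$samplesA), 32)
  expect_equal(length(pooled$samplesB), 25)

  vt <- vt_from_geno(matrix(rep(0:1, length.out = 69), 1, 69), panel)
  one_pair <- fst_scan(vt, cts[1])
  expect_equal(nrow(one_pair), 1)
  full <- fst_scan(vt)
  expect_equal(nrow(full), length(cts))
  expect_true(all(is.na(full$p_welch[full$level != "pooled"])))
  expect_true(all(!is.na(full$p_welch[full$level == "pooled"])))
})

test_that("PD/HPD classification is an inclusive conjunction of both criteria", {
  # 100 pooled records with theta 0.00..0.99; p small for a chosen few
  th <- seq(0, 0.99, by = 0.01)
  fp <- data.frame(variant_key = sprintf("chr1:%d:A>G", seq_along(th)),
                   contrast = "Africa_vs_non-Africa", level = "pooled",
                   theta_reported = th, defined = TRUE,
                   p_welch = 0.5, stringsAsFactors = FALSE)
  fp$p_welch[c(96, 98, 100)] <- 0.01   # theta 0.95, 0.97, 0.99
  # exactly at the q95 threshold with p < 0.05: PD (inclusive >=)
  q95 <- percentile_threshold(th, 0.95)  # 0.9405
  fp <- rbind(fp, data.frame(variant_key = "chr1:999:A>G",
                             contrast = "Africa_vs_non-Africa",
                             level = "pooled", theta_reported = q95,
                             defined = TRUE, p_welch = 0.01))
  pd <- classify_pd(fp)
  lab <- setNames(pd$variants$label, pd$variants$variant_key)
  expect_equal(unname(lab["chr1:999:A>G"]), "PD")
  # theta above q99 but p = 0.5 -> none
  expect_equal(unname(lab["chr1:99:A>G"]), "none")   # theta 0.98, p 0.5
  expect_equal(unname(lab["chr1:100:A>G"]), "HPD")   # theta 0.99, p 0.01
  expect_equal(unname(lab["chr1:96:A>G"]), "PD")     # theta 0.95, p 0.01
  expect_equal(unname(lab["chr1:1:A>G"]), "none")    # below q95
})

test_that("miRNA-level PD label is the max over its variants", {
  cat <- tiny_catalog()
  panel <- tiny_panel(c(A = 2L))
  vt <- vt_from_geno(matrix(c(0L, 1L), 3, 2, byrow = TRUE), panel,
                     pos = c(1004L, 1040L, 2030L))
  ann <- classify_variants(vt, cat)
  keys <- variant_key(vt)
  fp <- data.frame(variant_key = keys, contrast = "c", level = "pooled",
                   theta_reported = c(0.9, 0.2, 0.1), defined = TRUE,
                   p_welch = c(0.01, 0.01, 0.5), stringsAsFactors = FALSE)
  pd <- classify_pd(fp, ann, q95 = 0.5, q99 = 0.9)
  ml <- setNames(pd$mirnas$label, pd$mirnas$mirna_id)
  expect_equal(unname(ml["mir-A"]), "HPD")  # its best variant is HPD
  expect_equal(unname(ml["mir-B"]), "none")
})
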