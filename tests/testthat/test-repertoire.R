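ref_panel <- function(n = 30, seed = 121) {
  gen <- generate_panel(panel_spec(n, high_fraction = 0.4, seed = seed))
  data.frame(cdr3b = gen$panel$cdr3b, label = gen$panel$label)
}

test_that("repertoire labelling matches by normalized CDR3beta identity", {
  ref <- ref_panel()
  samp <- data.frame(cdr3b = tolower(paste0(" ", ref$cdr3b, " ")),
                     count = rep(5L, nrow(ref)))
  lab <- label_repertoire(ref, samp)
  expect_equal(lab$label, ref$label)
  expect_equal(attr(lab, "match_stats")$fraction_matched, 1)
  # row order does not matter
  perm <- sample(nrow(samp))
  lab2 <- label_repertoire(ref, samp[perm, ])
  expect_equal(lab2$label, ref$label[perm])
})

test_that("disjoint repertoires match nothing and report it", {
  ref <- ref_panel(10)
  samp <- data.frame(cdr3b = replicate(5, random_cdr3(15)), count = rep(5L, 5))
  lab <- label_repertoire(ref, samp)
  expect_equal(attr(lab, "match_stats")$n_matched, 0)
  expect_true(all(is.na(lab$label)))
  expect_error(ha_enrichment_test(lab, lab, b = 10), "at least 2")
})

test_that("the observed statistic is zero and p near 1 when both sides are all high", {
  tu <- data.frame(cdr3b = replicate(20, random_cdr3(14)), count = 5L,
                   label = 1L)
  bl <- data.frame(cdr3b = replicate(20, random_cdr3(14)), count = 5L,
                   label = 1L)
  res <- ha_enrichment_test(tu, bl, b = 99, seed = 1)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)  # every replicate statistic >= 0 is impossible;
                                # all-high pool relabels everyone high, tie = 0
})

test_that("a fully polarized contrast is highly significant", {
  set.seed(122)
  tu <- data.frame(cdr3b = replicate(20, random_cdr3(14)), count = 5L,
                   label = 1L)
  bl <- data.frame(cdr3b = replicate(20, random_cdr3(14)), count = 5L,
                   label = 0L)
  res <- ha_enrichment_test(tu, bl, b = 1000, seed = 2)
  expect_equal(res$observed, 100)
  expect_lte(res$p_value, 0.01)
})

test_that("replicate relabelling preserves the expected high count", {
  set.seed(123)
  tu <- data.frame(cdr3b = replicate(25, random_cdr3(14)), count = 5L,
                   label = rbinom(25, 1, 0.6))
  bl <- data.frame(cdr3b = replicate(15, random_cdr3(14)), count = 5L,
                   label = rbinom(15, 1, 0.2))
  res <- ha_enrichment_test(tu, bl, b = 4000, seed = 3)
  null <- attr(res, "null_distribution")
  # mean replicate statistic centers on 0 under exchangeable relabelling
  expect_lt(abs(mean(null)), 2 * stats::sd(null) / sqrt(length(null)) + 1.5)
  expect_equal(res$pooled_high, sum(tu$label) + sum(bl$label))
})

test_that("singleton clonotypes are excluded by default", {
  tu <- data.frame(cdr3b = replicate(10, random_cdr3(14)),
                   count = c(1L, rep(5L, 9)), label = c(1L, rep(0L, 9)))
  bl <- data.frame(cdr3b = replicate(10, random_cdr3(14)), count = 5L,
                   label = rep(0L, 10))
  res <- ha_enrichment_test(tu, bl, b = 9, seed = 4)
  expect_equal(res$n, 9)        # the singleton high clone dropped
  expect_equal(res$pct_ha_tumor, 0)
  res_all <- ha_enrichment_test(tu, bl, b = 9, seed = 4, min_count = 1)
  expect_equal(res_all$n, 10)
})

test_that("clonotype-level and read-weighted percentages agree at equal counts", {
  tu <- data.frame(cdr3b = replicate(12, random_cdr3(14)), count = 7L,
                   label = rbinom(12, 1, 0.5))
  bl <- data.frame(cdr3b = replicate(12, random_cdr3(14)), count = 7L,
                   label = rbinom(12, 1, 0.5))
  a <- ha_enrichment_test(tu, bl, b = 19, seed = 5)
  b <- ha_enrichment_test(tu, bl, b = 19, seed = 5, weight_by_reads = TRUE)
  expect_equal(a$observed, b$observed)
  expect_equal(a$p_value, b$p_value)
})
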