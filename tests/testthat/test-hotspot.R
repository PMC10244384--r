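make_tree_panel <- function(n, seed, motif = NULL, high_fraction = 0.25) {
  gen <- generate_panel(panel_spec(n_tcrs = n, high_fraction = high_fraction,
                                   motif = motif, seed = seed))
  d <- suppressWarnings(distance_matrix(gen$panel))
  list(panel = gen$panel, tree = upgma(d),
       hl = setNames(gen$panel$halflife_s, gen$panel$tcr_id))
}

test_that("an all-high tree returns the whole tree as hotspot", {
  x <- make_tree_panel(12, seed = 41, high_fraction = 1)
  hot <- find_hotspot(x$tree, x$hl, threshold = 10, min_size = 3)
  expect_setequal(hot$members, x$panel$tcr_id)
  expect_equal(hot$clade_high_fraction, 1)
  expect_equal(hot$inside_fraction, 1)
})

test_that("a unique all-high clade among all-low leaves is recovered", {
  # three high TCRs share a planted 4-mer (pairwise distance 0); the rest are
  # low and unrelated
  x <- make_tree_panel(16, seed = 42, motif = "WHWH", high_fraction = 3 / 16)
  hot <- find_hotspot(x$tree, x$hl, threshold = 60, min_size = 3)
  planted <- x$panel$tcr_id[x$panel$label == 1]
  expect_true(all(planted %in% hot$members))
  expect_equal(hot$clade_high_fraction, 1)
})

test_that("hotspot search agrees with exhaustive clade enumeration", {
  set.seed(43)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    m <- random_dist_matrix(n)
    tr <- upgma(m)
    hl <- setNames(runif(n, 0, 100), rownames(m))
    hot <- find_hotspot(tr, hl, threshold = 40, min_size = 2)
    # enumerate every clade directly from the merge tree
    best <- -Inf
    for (k in seq_along(tr$members)) {
      mem <- tr$members[[k]]
      if (length(mem) < 2) next
      best <- max(best, mean(hl[tr$labels[mem]] > 40))
    }
    expect_equal(hot$clade_high_fraction, best)
  }
})

test_that("planted high-avidity clades are recovered across seeds", {
  hits <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    x <- make_tree_panel(28, seed = 1000 + s, motif = "WHWH")
    hot <- find_hotspot(x$tree, x$hl, threshold = 60, min_size = 5)
    planted <- x$panel$tcr_id[x$panel$label == 1]
    if (setequal(hot$members, planted)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("permutation p-values follow the add-one convention and bounds", {
  x <- make_tree_panel(28, seed = 44, motif = "WHWH")
  n_high <- sum(x$panel$label == 1)
  hot <- cluster_enrichment_null(x$tree, x$hl, threshold = 60,
                                 min_size = n_high, b = 199, seed = 7)
  expect_gte(hot$p_value, 1 / 200)
  expect_lte(hot$p_value, 1)
  # a planted pure clade is essentially never beaten by label permutation
  expect_lte(hot$p_value, 0.01)

  # observed enrichment at the permutation minimum: p = 1
  hl_const <- setNames(rep(5, length(x$hl)), names(x$hl))  # nobody above threshold
  hot0 <- find_hotspot(x$tree, hl_const, threshold = 10, min_size = 5)
  p0 <- cluster_enrichment_null(x$tree, hl_const, hotspot = hot0,
                                b = 99, seed = 8)$p_value
  expect_equal(p0, 1)
})

test_that("missing half-lives are excluded from scoring, all-missing errors", {
  x <- make_tree_panel(12, seed = 45)
  hl <- x$hl
  hl[1:3] <- NA
  hot <- find_hotspot(x$tree, hl, threshold = 10, min_size = 3)
  expect_s3_class(hot, "hotspot_report")
  expect_error(find_hotspot(x$tree, setNames(rep(NA_real_, 12), names(x$hl))),
               "no leaf")
})
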