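test_that("4-mer extraction trims the first 4 and last 3 residues", {
  expect_identical(extract_kmers("CASSLAPGATNEKLFF"),
                   c("LAPG", "APGA", "PGAT", "GATN", "ATNE", "TNEK"))
  # L = 10 leaves no window; L = 11 leaves exactly positions 5-8
  s10 <- "CASSLAPGFF"
  expect_identical(extract_kmers(s10), character(0))
  s11 <- "CASSLAPGTFF"
  expect_identical(extract_kmers(s11), substr(s11, 5, 8))
})

test_that("4-mer count law holds for lengths 0 to 40", {
  set.seed(11)
  for (L in 0:40) {
    s <- if (L == 0) "" else random_cdr3(L)
    expect_length(extract_kmers(s), max(0, L - 10))
  }
})

test_that("invalid residues are rejected with their position", {
  expect_error(extract_kmers("CASS1APGATNEKLFF"), "position 5")
  expect_error(extract_kmers("CASSXAPGATNEKLFF"), "'X'")
})

test_that("Atchley encoding is position-major and matches the published table", {
  tab <- atchley_table()
  expect_equal(dim(tab), c(20, 5))
  # spot checks against the published five-factor solution
  expect_equal(unname(tab["A", ]), c(-0.591, -1.302, -0.733, 1.570, -0.146))
  expect_equal(unname(tab["R", "f5"]), 2.897)   # arginine: largest charge
  expect_equal(unname(tab["S", "f3"]), -4.760)  # serine: smallest size factor
  v <- encode_kmer("AAAA")
  expect_equal(unname(v), rep(unname(tab["A", ]), 4))
  # every entry is the table value for that position's letter
  w <- encode_kmer("ACDE")
  expect_equal(unname(w), c(tab["A", ], tab["C", ], tab["D", ], tab["E", ]),
               ignore_attr = TRUE)
  # position sensitivity: reversed 4-mer has the same blocks, different vector
  expect_false(isTRUE(all.equal(encode_kmer("ACDE"), encode_kmer("EDCA"),
                                check.attributes = FALSE)))
  expect_setequal(unname(round(encode_kmer("ACDE"), 3)),
                  unname(round(encode_kmer("EDCA"), 3)))
  expect_error(encode_kmer("ACDEF"))
  expect_error(encode_kmer("ACDX"), "unknown")
})

test_that("kmer distance is a symmetric normalized Manhattan distance", {
  u <- encode_kmer("NEIK"); v <- encode_kmer("ARDL")
  expect_equal(kmer_distance(u, u), 0)
  expect_equal(kmer_distance(u, v), kmer_distance(v, u))
  expect_gte(kmer_distance(u, v), 0)
  expect_lte(kmer_distance(u, v), 1)
  expect_error(kmer_distance(u, v[-1]), "mismatched")
})

test_that("the most dissimilar letter pair attains distance 1 under the default d_max", {
  tab <- atchley_table()
  # brute force over all 20 x 20 letter pairs
  best <- -Inf; best_pair <- NULL
  for (a in rownames(tab)) for (b in rownames(tab)) {
    d <- sum(abs(tab[a, ] - tab[b, ]))
    if (d > best) { best <- d; best_pair <- c(a, b) }
  }
  expect_equal(kmer_dmax(), 4 * best)
  u <- encode_kmer(strrep(best_pair[1], 4))
  v <- encode_kmer(strrep(best_pair[2], 4))
  expect_equal(kmer_distance(u, v), 1)
  # the per-dimension-range normalizer is strictly larger, so the same pair
  # cannot reach 1 under it
  expect_lt(kmer_distance(u, v, kmer_dmax("dimension_range")), 1)
})
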