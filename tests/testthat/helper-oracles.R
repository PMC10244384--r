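# Independent oracles and small fixture builders used across the suite.

AA <- rownames(atchley_table())

random_cdr3 <- function(len) paste(sample(AA, len, replace = TRUE), collapse = "")

random_panel_df <- function(n, len_range = c(11, 16)) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  data.frame(tcr_id = sprintf("T%02d", seq_len(n)),
             cdr3b = vapply(lens, random_cdr3, character(1)),
             stringsAsFactors = FALSE)
}

# brute-force minimum 4-mer distance: explicit double loop over all 4-mer
# pairs using only extract/encode primitives
oracle_tcr_distance <- function(s1, s2, d_max = kmer_dmax()) {
  k1 <- extract_kmers(s1); k2 <- extract_kmers(s2)
  if (!length(k1) || !length(k2)) return(1)
  best <- Inf
  for (a in k1) for (b in k2) {
    d <- sum(abs(encode_kmer(a) - encode_kmer(b))) / d_max
    if (d < best) best <- d
  }
  min(best, 1)
}

# direct UPGMA recurrence, written independently of upgma(): returns the
# sorted merge heights and the cophenetic matrix
oracle_upgma <- function(d) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  D <- d
  heights <- numeric(0)
  coph <- matrix(0, n, n)
  while (length(members) > 1) {
    m <- length(members)
    best <- c(NA, NA); bd <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (D[i, j] < bd) { bd <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bd / 2)
    for (a in members[[i]]) for (b in members[[j]]) {
      coph[a, b] <- coph[b, a] <- bd
    }
    ni <- length(members[[i]]); nj <- length(members[[j]])
    newd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- matrix(0, m - 1, m - 1)
    if (length(keep)) {
      D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
      D2[m - 1, seq_along(keep)] <- D2[seq_along(keep), m - 1] <- newd[keep]
    }
    D <- D2
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
  }
  list(heights = sort(heights), cophenetic = coph)
}

# random symmetric distance matrix with distinct off-diagonal entries
random_dist_matrix <- function(n, labels = sprintf("L%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  vals <- runif(n * (n - 1) / 2)
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# AUC as the exhaustive fraction of concordant (high, low) pairs, ties = 1/2
oracle_auc <- function(scores, labels) {
  hi <- scores[labels == 1]; lo <- scores[labels == 0]
  tot <- 0
  for (h in hi) for (l in lo) tot <- tot + (h > l) + 0.5 * (h == l)
  tot / (length(hi) * length(lo))
}

# closed-form OLS via normal equations, independent of lm()
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
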