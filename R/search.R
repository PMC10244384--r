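#' Number of residue subsets explored per encoding
#'
#' Binomial counts of subsets of the 20 canonical amino acids for the given
#' sizes; the default 5..8 gives 15,504 + 38,760 + 77,520 + 125,970 = 257,754
#' candidate feature sets per encoding.
#'
#' @param sizes Integer subset sizes; default `5:8`.
#' @return Named integer vector of counts plus a `"total"` element.
#' @export
subset_count <- function(sizes = 5:8) {
  counts <- choose(20, sizes)
  c(setNames(counts, sizes), total = sum(counts))
}

# unrank a lexicographic k-combination of 1..n (1-based index)
unrank_combination <- function(rank, n, k) {
  out <- integer(k)
  r <- rank - 1
  x <- 1L
  for (i in seq_len(k)) {
    repeat {
      c_rest <- choose(n - x, k - i)
      if (r < c_rest) break
      r <- r - c_rest
      x <- x + 1L
    }
    out[i] <- x
    x <- x + 1L
  }
  out
}

#' Exhaustive residue-subset search for avidity features
#'
#' For every subset of `sizes` amino acids (out of the 20) and every requested
#' encoding, fits a multiple linear regression of the high/low label on the
#' features and records R-squared. The top candidates by R-squared are then
#' refit as logistic classifiers and ranked by AUC, then by accuracy at the
#' decision threshold, then by R-squared.
#'
#' @param panel Data frame with `tcr_id`, `cdr3b` and either a `label` column
#'   (1/0) or `halflife_s` (labelled by [avidity_labels()]).
#' @param exposures Long exposure table; needed for `exposed_presence`.
#' @param sizes Subset sizes to explore; default `5:8`.
#' @param encodings Encodings to explore; default all three.
#' @param exposure_threshold Exposed-fraction gate; default 0.30.
#' @param top_k Number of top-R-squared candidates per encoding refit as
#'   logistic models; default 20.
#' @param label_threshold Half-life class boundary when labels are derived;
#'   default 60 s.
#' @param verbose Emit progress messages; default FALSE.
#' @return Data frame ranked best-first: `residues` (collapsed string),
#'   `encoding`, `size`, `r_squared`, `auc`, `accuracy`.
#' @export
exhaustive_feature_search <- function(panel, exposures = NULL, sizes = 5:8,
                                      encodings = c("exposed_presence",
                                                    "presence", "frequency"),
                                      exposure_threshold = 0.30, top_k = 20,
                                      label_threshold = 60, verbose = FALSE) {
  stopifnot(is.data.frame(panel), all(sizes >= 1), all(sizes <= 20))
  y <- if ("label" %in% names(panel)) as.integer(panel$label)
       else avidity_labels(panel$halflife_s, label_threshold)
  if (anyNA(y)) stop("panel has unlabelled rows")
  if (length(unique(y)) < 2) stop("both avidity classes must be present")
  yc <- y - mean(y)
  ss_y <- sum(yc^2)

  results <- list()
  for (enc in encodings) {
    fdef_all <- feature_definition(AA_ALPHABET, encoding = enc,
                                   exposure_threshold = exposure_threshold)
    X <- feature_matrix(panel, exposures, fdef_all)
    Xc <- sweep(X, 2, colMeans(X))
    G <- crossprod(Xc)
    v <- drop(crossprod(Xc, yc))
    if (verbose)
      message(sprintf("scanning %d subsets (%s encoding)",
                      sum(choose(20, sizes)), enc))
    scan <- subset_r2_scan(G, v, ss_y, as.integer(sizes))
    for (si in seq_along(sizes)) {
      r2 <- scan[[si]]
      k <- sizes[si]
      ord <- order(r2, decreasing = TRUE, na.last = NA)
      take <- utils::head(ord, top_k)
      for (rank_idx in take) {
        subset <- unrank_combination(rank_idx, 20L, k)
        results[[length(results) + 1]] <- data.frame(
          residues = paste(AA_ALPHABET[subset], collapse = ""),
          encoding = enc, size = k, r_squared = r2[rank_idx],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, results)
  res <- res[order(res$r_squared, decreasing = TRUE), , drop = FALSE]
  res <- utils::head(res, top_k)

  # refit the shortlisted candidates as logistic classifiers
  res$auc <- NA_real_
  res$accuracy <- NA_real_
  for (i in seq_len(nrow(res))) {
    fdef <- feature_definition(strsplit(res$residues[i], "")[[1]],
                               encoding = res$encoding[i],
                               exposure_threshold = exposure_threshold)
    X <- feature_matrix(panel, exposures, fdef)
    fit <- try(fit_logistic(X, y, fdef = fdef), silent = TRUE)
    if (inherits(fit, "try-error")) next
    pred <- predict_avidity(fit, X)
    ev <- evaluate_classifier(pred$p, y, threshold = fit$threshold)
    res$auc[i] <- ev$auc
    res$accuracy[i] <- ev$accuracy
  }
  res <- res[order(-res$auc, -res$accuracy, -res$r_squared), , drop = FALSE]
  rownames(res) <- NULL
  res
}
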