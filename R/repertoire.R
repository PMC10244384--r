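#' Label a bulk repertoire with predicted avidity classes
#'
#' Matches repertoire rows to a reference library of classifier-labelled
#' clonotypes by exact CDR3beta amino-acid identity (case-normalized,
#' whitespace-stripped). Unmatched clonotypes are labelled `NA` and excluded
#' from percentage computations.
#'
#' @param reference Data frame with `cdr3b` and `label` (1 = predicted high,
#'   0 = predicted low).
#' @param sample Data frame with `cdr3b` (or AIRR-style `cdr3_aa`) and
#'   `count`.
#' @return The sample with a `label` column attached; match statistics in
#'   `attr(, "match_stats")` (`n_rows`, `n_matched`, `fraction_matched`).
#' @export
label_repertoire <- function(reference, sample) {
  stopifnot(is.data.frame(reference), nrow(reference) > 0,
            all(c("cdr3b", "label") %in% names(reference)))
  if (!"cdr3b" %in% names(sample) && "cdr3_aa" %in% names(sample))
    sample$cdr3b <- sample$cdr3_aa
  stopifnot(is.data.frame(sample), "cdr3b" %in% names(sample))
  norm <- function(x) toupper(trimws(x))
  key <- norm(reference$cdr3b)
  if (anyDuplicated(key)) {
    dup <- duplicated(key)
    conflict <- vapply(split(reference$label, key), function(l)
      length(unique(l)) > 1, TRUE)
    if (any(conflict))
      stop("reference assigns conflicting labels to the same CDR3beta")
    reference <- reference[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  m <- match(norm(sample$cdr3b), key)
  sample$label <- reference$label[m]
  attr(sample, "match_stats") <- list(
    n_rows = nrow(sample), n_matched = sum(!is.na(m)),
    fraction_matched = if (nrow(sample)) mean(!is.na(m)) else NA_real_)
  sample
}

# percentage of high-avidity clonotypes in a labelled repertoire
pct_ha <- function(labels, counts = NULL, weight_by_reads = FALSE) {
  keep <- !is.na(labels)
  if (!any(keep)) return(NA_real_)
  if (weight_by_reads) {
    stopifnot(!is.null(counts))
    100 * sum(counts[keep] * (labels[keep] == 1)) / sum(counts[keep])
  } else {
    100 * mean(labels[keep] == 1)
  }
}

#' Randomization test for tumor-vs-blood enrichment in high-avidity clonotypes
#'
#' Observed statistic: percentage of predicted high-avidity (HA) clonotypes
#' among tumor-matched clonotypes minus the same percentage in blood. Null:
#' pool the n tumor and m blood clonotypes, count the HA clonotypes F among
#' them, then independently relabel every clonotype high with probability
#' F / (n + m) and recompute the statistic, `b` times. The add-one p-value is
#' the probability of a randomized statistic at least as large as observed.
#' Clonotypes supported by a single read are excluded by default.
#'
#' @param tumor,blood Labelled repertoires from [label_repertoire()] (columns
#'   `cdr3b`, `count`, `label`).
#' @param b Randomization replicates; default 1000.
#' @param seed Optional integer seed.
#' @param min_count Minimum read support per clonotype; default 2 (drops
#'   singletons). Set to 1 to keep everything.
#' @param weight_by_reads Compute percentages over reads instead of unique
#'   clonotypes; default FALSE (clonotype-level).
#' @return Object of class `ha_enrichment`: `n` (tumor clonotypes), `m`
#'   (blood), `pct_ha_tumor`, `pct_ha_blood`, `observed` (difference in
#'   percentage points), `b`, `p_value`, with the replicate statistics in
#'   `attr(, "null_distribution")`.
#' @export
ha_enrichment_test <- function(tumor, blood, b = 1000, seed = NULL,
                               min_count = 2, weight_by_reads = FALSE) {
  stopifnot(b >= 1)
  prep <- function(x) {
    stopifnot(is.data.frame(x), all(c("cdr3b", "label") %in% names(x)))
    if (!"count" %in% names(x)) x$count <- 1L
    x <- x[!is.na(x$label) & x$count >= min_count, , drop = FALSE]
    x
  }
  tu <- prep(tumor); bl <- prep(blood)
  n <- nrow(tu); m <- nrow(bl)
  if (n + m < 2) stop("need at least 2 labelled clonotypes across compartments")

  obs_tu <- pct_ha(tu$label, tu$count, weight_by_reads)
  obs_bl <- pct_ha(bl$label, bl$count, weight_by_reads)
  observed <- obs_tu - obs_bl

  f_count <- sum(tu$label == 1) + sum(bl$label == 1)
  p_high <- f_count / (n + m)

  run <- function() {
    vapply(seq_len(b), function(i) {
      lt <- rbinom(n, 1, p_high)
      lb <- rbinom(m, 1, p_high)
      pct_ha(lt, tu$count, weight_by_reads) -
        pct_ha(lb, bl$count, weight_by_reads)
    }, numeric(1))
  }
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  p <- (1 + sum(null >= observed)) / (b + 1)

  structure(list(n = n, m = m,
                 pct_ha_tumor = obs_tu, pct_ha_blood = obs_bl,
                 observed = observed, b = b, p_value = p,
                 pooled_high = f_count),
            class = "ha_enrichment",
            null_distribution = null)
}

#' @export
print.ha_enrichment <- function(x, ...) {
  cat(sprintf(
    "HA enrichment: %%HA tumor = %.1f (n = %d), %%HA blood = %.1f (m = %d)\n  difference = %.1f points, randomization p = %.4g (b = %d)\n",
    x$pct_ha_tumor, x$n, x$pct_ha_blood, x$m, x$observed, x$p_value, x$b))
  invisible(x)
}
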