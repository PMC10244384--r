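#' Find the high-avidity hotspot clade of a UPGMA tree
#'
#' Scans every clade (internal node) with at least `min_size` members and
#' returns the one maximizing the fraction of scored members whose half-life
#' exceeds `threshold` (members with missing half-life belong to the clade but
#' do not enter the fraction). Ties are broken toward the larger clade, then
#' toward the clade of lower merge height.
#'
#' @param tree `tcr_dendro` from [upgma()].
#' @param halflives Named numeric vector of measured half-lives (seconds),
#'   names matching the tree's leaf labels; leaves absent from it are unscored.
#' @param threshold Half-life (s) separating low from intermediate/high
#'   avidity; default 10.
#' @param min_size Smallest admissible clade size; default 5.
#' @return Object of class `hotspot_report`: list with `members` (tcr ids),
#'   `clade_high_fraction` (the maximized statistic), `inside_fraction`
#'   (share of all above-threshold TCRs captured by the clade),
#'   `outside_low_fraction` (share of below-threshold TCRs among scored TCRs
#'   outside the clade), `height`, `threshold`, `p_value` (NA until
#'   [cluster_enrichment_null()] fills it).
#' @export
find_hotspot <- function(tree, halflives, threshold = 10, min_size = 5) {
  stopifnot(inherits(tree, "tcr_dendro"), is.numeric(threshold), min_size >= 1)
  labels <- tree$labels
  hl <- halflives[match(labels, names(halflives))]
  if (all(is.na(hl))) stop("no leaf has a half-life; nothing to score")
  high <- hl > threshold

  best <- NULL
  for (k in seq_along(tree$members)) {
    mem <- tree$members[[k]]
    if (length(mem) < min_size) next
    scored <- mem[!is.na(high[mem])]
    if (!length(scored)) next
    frac <- mean(high[scored])
    cand <- list(k = k, frac = frac, size = length(mem),
                 height = tree$height[k])
    if (is.null(best) ||
        cand$frac > best$frac ||
        (cand$frac == best$frac && cand$size > best$size) ||
        (cand$frac == best$frac && cand$size == best$size &&
           cand$height < best$height)) {
      best <- cand
    }
  }
  if (is.null(best)) stop("no clade of size >= min_size")

  mem <- tree$members[[best$k]]
  inside <- rep(FALSE, length(labels)); inside[mem] <- TRUE
  n_high_total <- sum(high, na.rm = TRUE)
  inside_fraction <- if (n_high_total > 0) {
    sum(high[mem], na.rm = TRUE) / n_high_total
  } else NA_real_
  out_scored <- which(!inside & !is.na(high))
  outside_low_fraction <- if (length(out_scored)) {
    mean(!high[out_scored])
  } else NA_real_

  structure(list(members = labels[mem],
                 clade_high_fraction = best$frac,
                 inside_fraction = inside_fraction,
                 outside_low_fraction = outside_low_fraction,
                 height = best$height, threshold = threshold,
                 min_size = min_size, p_value = NA_real_),
            class = "hotspot_report")
}

#' @export
print.hotspot_report <- function(x, ...) {
  cat(sprintf(
    "Hotspot clade: %d TCRs at height %.4g\n  clade fraction T1/2 > %g s: %.3f\n  captures %.1f%% of all above-threshold TCRs; %.1f%% of outside TCRs are below threshold\n",
    length(x$members), x$height, x$threshold, x$clade_high_fraction,
    100 * x$inside_fraction, 100 * x$outside_low_fraction))
  if (!is.na(x$p_value)) cat(sprintf("  permutation p = %.4g\n", x$p_value))
  invisible(x)
}

# maximal clade high-fraction for a given high/low labelling (internal;
# shared by find_hotspot's permutation null)
max_clade_fraction <- function(tree, high, min_size) {
  best <- -Inf
  for (k in seq_along(tree$members)) {
    mem <- tree$members[[k]]
    if (length(mem) < min_size) next
    scored <- mem[!is.na(high[mem])]
    if (!length(scored)) next
    f <- mean(high[scored])
    if (f > best) best <- f
  }
  best
}

#' Permutation control for the hotspot enrichment
#'
#' Reassigns the observed half-lives at random across the leaves `b` times and
#' re-runs the maximal-clade enrichment search each time, mirroring the
#' selection step of [find_hotspot()]. The add-one permutation p-value is the
#' probability of a permuted maximal enrichment at least as large as observed.
#'
#' @param tree `tcr_dendro`.
#' @param halflives Named half-life vector, as in [find_hotspot()].
#' @param hotspot Optional `hotspot_report`; recomputed when missing.
#' @param threshold,min_size As in [find_hotspot()].
#' @param b Number of permutation replicates; default 1000.
#' @param seed Optional integer seed.
#' @return The `hotspot_report` with `p_value` filled in and the permutation
#'   maxima attached as `attr(, "null_distribution")`.
#' @export
cluster_enrichment_null <- function(tree, halflives, hotspot = NULL,
                                    threshold = 10, min_size = 5,
                                    b = 1000, seed = NULL) {
  stopifnot(b >= 1)
  if (is.null(hotspot)) {
    hotspot <- find_hotspot(tree, halflives, threshold = threshold,
                            min_size = min_size)
  } else {
    threshold <- hotspot$threshold
    min_size <- hotspot$min_size
  }
  labels <- tree$labels
  hl <- halflives[match(labels, names(halflives))]
  high <- hl > threshold
  observed <- hotspot$clade_high_fraction

  run <- function() {
    vapply(seq_len(b), function(i) {
      max_clade_fraction(tree, sample(high), min_size)
    }, numeric(1))
  }
  maxima <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  p <- (1 + sum(maxima >= observed)) / (b + 1)
  hotspot$p_value <- p
  attr(hotspot, "null_distribution") <- maxima
  hotspot
}
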