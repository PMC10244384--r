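#' Amino-acid composition enrichment between high- and low-avidity CDR3betas
#'
#' Pools residue counts across each panel's CDR3beta sequences and tests each
#' of the 20 amino acids with a two-sided Fisher exact test on the 2x2 table
#' (this letter vs all others, high vs low panel). Effect direction is the
#' difference of pooled per-letter frequencies (high minus low).
#'
#' @param high_panel,low_panel Data frames with a `cdr3b` column (or character
#'   vectors of CDR3beta sequences).
#' @return Data frame, one row per amino acid: `residue`, `freq_high`,
#'   `freq_low`, `delta` (high - low), `odds_ratio`, `p_value`,
#'   `p_bonferroni`, `enriched_in`, ordered by `p_value`.
#' @export
composition_enrichment <- function(high_panel, low_panel) {
  seq_of <- function(x) {
    s <- if (is.data.frame(x)) x$cdr3b else x
    if (!length(s)) stop("empty panel")
    toupper(s)
  }
  count_letters <- function(seqs) {
    letters <- unlist(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE))
    tab <- table(factor(letters, levels = AA_ALPHABET))
    as.integer(tab)
  }
  hi <- count_letters(seq_of(high_panel))
  lo <- count_letters(seq_of(low_panel))
  n_hi <- sum(hi); n_lo <- sum(lo)

  res <- data.frame(residue = AA_ALPHABET,
                    freq_high = hi / n_hi, freq_low = lo / n_lo,
                    delta = hi / n_hi - lo / n_lo,
                    odds_ratio = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(AA_ALPHABET)) {
    tab <- matrix(c(hi[i], n_hi - hi[i], lo[i], n_lo - lo[i]), nrow = 2)
    ft <- fisher.test(tab, alternative = "two.sided")
    res$p_value[i] <- ft$p.value
    res$odds_ratio[i] <- unname(ft$estimate)
  }
  res$p_bonferroni <- p.adjust(res$p_value, method = "bonferroni")
  res$enriched_in <- ifelse(res$delta > 0, "high",
                            ifelse(res$delta < 0, "low", "none"))
  res[order(res$p_value), ]
}
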