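#' Extract CDR3beta 4-mer subunits
#'
#' Slides a 4-residue window over the CDR3beta after trimming the first 4 and
#' last 3 residues, which rarely contact the presented peptide. A sequence of
#' length L therefore yields `max(0, L - 10)` 4-mers; sequences shorter than 11
#' residues yield none.
#'
#' @param cdr3b Amino-acid string over the 20 canonical upper-case letters.
#' @return Character vector of 4-mer strings, in sequence order.
#' @export
#' @examples
#' extract_kmers("CASSLAPGATNEKLFF")
extract_kmers <- function(cdr3b) {
  stopifnot(is.character(cdr3b), length(cdr3b) == 1L, !is.na(cdr3b))
  check_aa(cdr3b)
  L <- nchar(cdr3b)
  n <- max(0L, L - 10L)
  if (n == 0L) return(character(0))
  # windows start at positions 5 .. L-6, staying within positions 5..(L-3)
  starts <- 5L + seq_len(n) - 1L
  substring(cdr3b, starts, starts + 3L)
}

check_aa <- function(seq) {
  letters <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(letters %in% AA_ALPHABET))
  if (length(bad)) {
    stop(sprintf("invalid amino-acid character '%s' at position %d of '%s'",
                 letters[bad[1]], bad[1], seq), call. = FALSE)
  }
  invisible(TRUE)
}

#' Encode a 4-mer with the Atchley factors
#'
#' Each position contributes its residue's five Atchley factors; the encoding
#' concatenates positions in order (position-major), giving a 20-value vector.
#'
#' @param kmer 4-letter amino-acid string.
#' @param table Factor table, by default [atchley_table()].
#' @return Named numeric vector of length 20 (`p1.f1` .. `p4.f5`).
#' @export
encode_kmer <- function(kmer, table = atchley_table()) {
  stopifnot(is.character(kmer), length(kmer) == 1L, nchar(kmer) == 4L)
  letters <- strsplit(kmer, "", fixed = TRUE)[[1]]
  unknown <- setdiff(letters, rownames(table))
  if (length(unknown)) {
    stop(sprintf("unknown amino acid '%s' in 4-mer '%s'", unknown[1], kmer),
         call. = FALSE)
  }
  v <- as.vector(t(table[letters, , drop = FALSE]))
  names(v) <- paste0("p", rep(1:4, each = 5), ".", rep(colnames(table), 4))
  v
}

#' Normalized Manhattan distance between two encoded 4-mers
#'
#' Manhattan distance between the 20-value encodings, divided by the maximum
#' possible distance `d_max`, so that identical 4-mers score 0 and the most
#' biophysicochemically dissimilar pair scores 1.
#'
#' @param u,v Numeric vectors of equal length (4-mer encodings).
#' @param d_max Positive normalizing constant; default [kmer_dmax()].
#' @return Distance in `[0, 1]`.
#' @export
kmer_distance <- function(u, v, d_max = kmer_dmax()) {
  if (length(u) != length(v)) stop("encoded 4-mers have mismatched lengths")
  stopifnot(is.numeric(d_max), d_max > 0)
  min(sum(abs(u - v)) / d_max, 1)
}

#' Build the 4-mer biophysicochemical profile of one TCR
#'
#' @param tcr_id Identifier.
#' @param cdr3b CDR3beta amino-acid string.
#' @param table Atchley factor table.
#' @return Object of class `fourmer_profile`: list with `tcr_id`, `kmers`
#'   (character) and `encoding` (n_kmers x 20 matrix; 0 rows when the CDR3beta
#'   is shorter than 11 residues).
#' @export
fourmer_profile <- function(tcr_id, cdr3b, table = atchley_table()) {
  kmers <- extract_kmers(cdr3b)
  enc <- if (length(kmers)) {
    t(vapply(kmers, encode_kmer, numeric(20), table = table))
  } else {
    matrix(numeric(0), nrow = 0, ncol = 20)
  }
  structure(list(tcr_id = tcr_id, cdr3b = cdr3b, kmers = kmers,
                 encoding = enc),
            class = "fourmer_profile")
}

#' Minimum 4-mer distance between two TCRs
#'
#' Compares every 4-mer of one profile with every 4-mer of the other and keeps
#' the smallest normalized Manhattan distance: two TCRs are as close as their
#' most similar subunits. If either TCR has no eligible 4-mer (CDR3beta shorter
#' than 11), the pair is maximally distant (1) and flagged with a warning.
#'
#' @param a,b `fourmer_profile` objects built from the same factor table.
#' @param d_max Normalizing constant shared by both profiles.
#' @return Distance in `[0, 1]`.
#' @export
tcr_distance <- function(a, b, d_max = kmer_dmax()) {
  stopifnot(inherits(a, "fourmer_profile"), inherits(b, "fourmer_profile"))
  if (nrow(a$encoding) == 0L || nrow(b$encoding) == 0L) {
    warning(sprintf("no eligible 4-mer for pair (%s, %s); distance set to 1",
                    a$tcr_id, b$tcr_id), call. = FALSE)
    return(1)
  }
  # row-wise cross Manhattan distance, minimized
  best <- Inf
  for (i in seq_len(nrow(a$encoding))) {
    d <- rowSums(abs(sweep(b$encoding, 2, a$encoding[i, ])))
    m <- min(d)
    if (m < best) best <- m
  }
  min(best / d_max, 1)
}

#' Pairwise minimum 4-mer distance matrix for a TCR panel
#'
#' @param panel Data frame with columns `tcr_id` and `cdr3b` (one row per
#'   clonotype), or a list of `fourmer_profile` objects.
#' @param d_max Normalizing constant, or the string `"observed"` to normalize
#'   by the largest raw Manhattan minimum observed in this panel.
#' @return Object of class `tcr_dist`: symmetric numeric matrix with zero
#'   diagonal, entries in `[0, 1]`, and `tcr_id` dimnames. TCRs without an
#'   eligible 4-mer are listed in `attr(, "no_kmer_ids")`.
#' @export
distance_matrix <- function(panel, d_max = kmer_dmax()) {
  profiles <- if (is.data.frame(panel)) {
    stopifnot(all(c("tcr_id", "cdr3b") %in% names(panel)), nrow(panel) > 0)
    Map(fourmer_profile, panel$tcr_id, panel$cdr3b)
  } else {
    stopifnot(length(panel) > 0, all(vapply(panel, inherits, TRUE, "fourmer_profile")))
    panel
  }
  ids <- unname(vapply(profiles, `[[`, character(1), "tcr_id"))
  if (anyDuplicated(ids)) {
    stop("duplicate tcr_ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  n <- length(profiles)
  empty <- vapply(profiles, function(p) nrow(p$encoding) == 0L, TRUE)
  if (any(empty)) {
    warning("TCRs without an eligible 4-mer (CDR3beta < 11 residues) are at ",
            "distance 1 from all others: ", paste(ids[empty], collapse = ", "),
            call. = FALSE)
  }
  raw <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (empty[i] || empty[j]) {
          raw[i, j] <- raw[j, i] <- NA_real_
          next
        }
        best <- Inf
        ei <- profiles[[i]]$encoding
        ej <- profiles[[j]]$encoding
        for (r in seq_len(nrow(ei))) {
          m <- min(rowSums(abs(sweep(ej, 2, ei[r, ]))))
          if (m < best) best <- m
        }
        raw[i, j] <- raw[j, i] <- best
      }
    }
  }
  if (identical(d_max, "observed")) {
    d_max <- max(raw[is.finite(raw)], na.rm = TRUE)
    if (!is.finite(d_max) || d_max <= 0) d_max <- 1
  }
  out <- pmin(raw / d_max, 1)
  out[is.na(out)] <- 1
  diag(out) <- 0
  structure(out, class = c("tcr_dist", "matrix"),
            d_max = d_max, no_kmer_ids = ids[empty])
}
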