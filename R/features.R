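#' Define a residue feature set for the avidity classifier
#'
#' A feature definition is a set of amino-acid letters plus an encoding rule:
#' * `exposed_presence` — 1 iff the residue occurs in the CDR3beta with
#'   relative solvent exposure strictly above `exposure_threshold` (the rule
#'   behind the final model's R/N/D/G/I/L/F indicators);
#' * `presence` — 1 iff the residue occurs at all;
#' * `frequency` — occurrence count divided by CDR3beta length.
#'
#' @param residues Character vector of distinct upper-case amino-acid letters.
#' @param encoding One of `"exposed_presence"`, `"presence"`, `"frequency"`.
#' @param exposure_threshold Exposed-fraction gate in (0, 1); default 0.30,
#'   applied strictly (`> 0.30`).
#' @return Object of class `feature_definition`.
#' @export
feature_definition <- function(residues,
                               encoding = c("exposed_presence", "presence",
                                            "frequency"),
                               exposure_threshold = 0.30) {
  encoding <- match.arg(encoding)
  residues <- toupper(residues)
  stopifnot(all(residues %in% AA_ALPHABET), length(residues) >= 1,
            exposure_threshold > 0, exposure_threshold < 1)
  if (anyDuplicated(residues)) stop("duplicated residues in feature set")
  structure(list(residues = residues, encoding = encoding,
                 exposure_threshold = exposure_threshold),
            class = "feature_definition")
}

#' Build the feature vector of one TCR
#'
#' @param cdr3b CDR3beta amino-acid string.
#' @param exposure Numeric vector of per-position exposed fractions in
#'   `[0, 1]`, same length as `cdr3b`; required for the `exposed_presence`
#'   encoding, ignored otherwise.
#' @param fdef `feature_definition`.
#' @return Named numeric vector, one entry per residue in `fdef$residues`.
#' @export
build_features <- function(cdr3b, exposure = NULL, fdef) {
  stopifnot(inherits(fdef, "feature_definition"))
  check_aa(cdr3b)
  letters <- strsplit(cdr3b, "", fixed = TRUE)[[1]]
  if (fdef$encoding == "exposed_presence") {
    if (is.null(exposure))
      stop("exposed_presence encoding requires an exposure profile for ", cdr3b)
    if (length(exposure) != length(letters))
      stop(sprintf("exposure profile length %d does not match CDR3beta length %d",
                   length(exposure), length(letters)))
    if (any(exposure < 0 | exposure > 1, na.rm = TRUE))
      stop("exposed fractions must lie in [0, 1]")
    keep <- !is.na(exposure) & exposure > fdef$exposure_threshold
    x <- as.numeric(vapply(fdef$residues,
                           function(r) any(letters[keep] == r), TRUE))
  } else if (fdef$encoding == "presence") {
    x <- as.numeric(vapply(fdef$residues, function(r) any(letters == r), TRUE))
  } else {
    x <- vapply(fdef$residues, function(r) sum(letters == r), numeric(1)) /
      length(letters)
  }
  setNames(x, fdef$residues)
}

# exposure long table -> named list of per-TCR exposed-fraction vectors
exposure_list <- function(exposures) {
  stopifnot(is.data.frame(exposures),
            all(c("tcr_id", "position", "exposed_fraction") %in% names(exposures)))
  split_idx <- split(seq_len(nrow(exposures)), exposures$tcr_id)
  lapply(split_idx, function(ix) {
    e <- exposures[ix, ]
    e <- e[order(e$position), ]
    if (!identical(as.integer(e$position), seq_len(nrow(e))))
      stop("exposure positions must be 1..L without gaps for tcr ",
           e$tcr_id[1])
    e$exposed_fraction
  })
}

#' Feature matrix for a TCR panel
#'
#' @param panel Data frame with `tcr_id`, `cdr3b`.
#' @param exposures Long-format exposure table (`tcr_id`, `position`,
#'   `exposed_fraction`); required for the `exposed_presence` encoding.
#' @param fdef `feature_definition`.
#' @return Numeric matrix, rows = TCRs (rownames `tcr_id`), columns =
#'   `fdef$residues`.
#' @export
feature_matrix <- function(panel, exposures = NULL, fdef) {
  stopifnot(is.data.frame(panel), all(c("tcr_id", "cdr3b") %in% names(panel)))
  expo <- if (!is.null(exposures)) exposure_list(exposures) else NULL
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    e <- if (!is.null(expo)) expo[[as.character(panel$tcr_id[i])]] else NULL
    if (fdef$encoding == "exposed_presence" && is.null(e))
      stop("missing exposure profile for tcr ", panel$tcr_id[i])
    build_features(panel$cdr3b[i], e, fdef)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- panel$tcr_id
  X
}

#' High/low avidity labels from measured half-lives
#'
#' High avidity is a half-life strictly above the threshold (default 60 s);
#' a half-life exactly at the threshold is classified low.
#'
#' @param halflife_s Numeric vector of half-lives (s).
#' @param threshold Class boundary (s); default 60.
#' @return Integer vector (1 = high, 0 = low, NA where unmeasured).
#' @export
avidity_labels <- function(halflife_s, threshold = 60) {
  ifelse(is.na(halflife_s), NA_integer_, as.integer(halflife_s > threshold))
}
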