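#' Read a clonotype table
#'
#' Tab-separated, UTF-8, header row; required columns `tcr_id` and `cdr3b`
#' (CDR3beta amino-acid sequence, upper-cased on read), optional columns such
#' as `pmhc`, `halflife_s`, `label`, `compartment`, `count` are kept as-is.
#'
#' @param path File path.
#' @param strict When TRUE (default) any malformed CDR3beta aborts the read,
#'   reporting the offending line numbers; when FALSE malformed rows are
#'   dropped with a warning.
#' @return Data frame of validated clonotypes.
#' @export
read_clonotype_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0) stop("empty clonotype table: ", path)
  missing <- setdiff(c("tcr_id", "cdr3b"), names(tab))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  tab$cdr3b <- toupper(trimws(tab$cdr3b))
  ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), tab$cdr3b)
  if (any(!ok)) {
    lines <- which(!ok) + 1L  # +1 for the header row
    msg <- sprintf("malformed CDR3beta on line(s) %s of %s",
                   paste(lines, collapse = ", "), path)
    if (strict) stop(msg) else {
      warning(msg, "; rows dropped", call. = FALSE)
      tab <- tab[ok, , drop = FALSE]
    }
  }
  if (anyDuplicated(tab$tcr_id))
    stop("duplicate tcr_id values in ", path)
  tab
}

#' Write a clonotype table
#'
#' @param panel Data frame with at least `tcr_id` and `cdr3b`.
#' @param path Output path.
#' @export
write_clonotype_table <- function(panel, path) {
  stopifnot(all(c("tcr_id", "cdr3b") %in% names(panel)))
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an exposure profile table
#'
#' Long format: one row per CDR3beta position with columns `tcr_id`,
#' `position` (1-based), `exposed_fraction` in `[0, 1]`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_exposure_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("tcr_id", "position", "exposed_fraction")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (any(tab$exposed_fraction < 0 | tab$exposed_fraction > 1, na.rm = TRUE))
    stop("exposed_fraction outside [0, 1] in ", path)
  tab
}

#' @rdname read_exposure_table
#' @param exposures Long-format exposure data frame.
#' @export
write_exposure_table <- function(exposures, path) {
  write.table(exposures, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a contact-count table
#'
#' Columns: `complex_id`, `n_apolar`, `n_polar`, `halflife_s` (may be NA for
#' prediction-only rows).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_contact_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("complex_id", "n_apolar", "n_polar", "halflife_s")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (any(tab$n_apolar < 0, na.rm = TRUE) || any(tab$n_polar < 0, na.rm = TRUE))
    stop("negative contact counts in ", path)
  tab
}

#' @rdname read_contact_table
#' @param table Contact-count data frame.
#' @export
write_contact_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bulk repertoire table
#'
#' AIRR-style tab-separated columns: `cdr3_aa` (or `cdr3b`), optional
#' `v_gene`, `j_gene`, and `count` (defaults to 1 when absent).
#'
#' @param path File path.
#' @return Data frame with normalized `cdr3b` and integer `count`.
#' @export
read_repertoire_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!"cdr3b" %in% names(tab)) {
    if (!"cdr3_aa" %in% names(tab))
      stop("repertoire table needs a cdr3_aa (or cdr3b) column: ", path)
    tab$cdr3b <- tab$cdr3_aa
  }
  tab$cdr3b <- toupper(trimws(tab$cdr3b))
  if (!"count" %in% names(tab)) tab$count <- 1L
  if (any(tab$count < 1)) stop("repertoire counts must be >= 1 in ", path)
  tab
}

#' Write a distance matrix
#'
#' @param d `tcr_dist` matrix.
#' @param path Output path (square TSV with a header row of tcr ids).
#' @param long Also write a long-format companion (`<path>.long.tsv` with
#'   columns id_a, id_b, distance)? Default FALSE.
#' @export
write_distance_matrix <- function(d, path, long = FALSE) {
  m <- as.matrix(unclass(d))
  df <- data.frame(tcr_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (long) {
    ut <- which(upper.tri(m), arr.ind = TRUE)
    lf <- data.frame(id_a = rownames(m)[ut[, 1]], id_b = colnames(m)[ut[, 2]],
                     distance = m[ut])
    write.table(lf, paste0(path, ".long.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a square distance matrix written by [write_distance_matrix()]
#'
#' @param path File path.
#' @return `tcr_dist` matrix.
#' @export
read_distance_matrix <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  structure(m, class = c("tcr_dist", "matrix"))
}

#' Serialize / restore an avidity model as key-value text
#'
#' Plain-text `key\tvalue` format holding the bias, per-residue weights,
#' decision threshold and the feature definition.
#'
#' @param model `avidity_logistic`.
#' @param path Output path.
#' @export
write_avidity_model <- function(model, path) {
  stopifnot(inherits(model, "avidity_logistic"))
  lines <- c(
    paste0("model\tavidity_logistic"),
    paste0("b0\t", format(model$b0, digits = 17)),
    paste0("threshold\t", format(model$threshold, digits = 17)),
    paste0("separable\t", as.integer(model$separable)),
    paste0("ridge\t", format(model$ridge, digits = 17)),
    paste0("encoding\t", model$fdef$encoding),
    paste0("exposure_threshold\t",
           format(model$fdef$exposure_threshold, digits = 17)),
    paste0("residues\t", paste(model$fdef$residues, collapse = "")),
    vapply(seq_along(model$weights), function(i)
      paste0("w.", names(model$weights)[i], "\t",
             format(model$weights[i], digits = 17)), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_avidity_model
#' @return `read_avidity_model()` returns the restored `avidity_logistic`.
#' @export
read_avidity_model <- function(path) {
  kv <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("key", "value"))
  get <- function(k) kv$value[kv$key == k]
  residues <- strsplit(get("residues"), "")[[1]]
  fdef <- feature_definition(residues, encoding = get("encoding"),
                             exposure_threshold = as.numeric(get("exposure_threshold")))
  w <- vapply(residues, function(r) as.numeric(get(paste0("w.", r))),
              numeric(1))
  structure(list(b0 = as.numeric(get("b0")), weights = w, fdef = fdef,
                 threshold = as.numeric(get("threshold")),
                 separable = get("separable") == "1",
                 converged = TRUE, ridge = as.numeric(get("ridge")),
                 n = NA_integer_),
            class = "avidity_logistic")
}
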