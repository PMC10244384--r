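#' Specification of a synthetic TCR panel
#'
#' Describes the planted structure of a simulated clone panel: a fraction of
#' high-avidity clonotypes whose CDR3beta composition is biased toward an
#' enrichment residue set (low-avidity clonotypes are biased toward a
#' depletion set), class-specific half-life intervals on either side of the
#' 60 s avidity boundary, and i.i.d. per-position solvent-exposure masks.
#'
#' @param n_tcrs Number of clonotypes.
#' @param cdr3_length_range Min/max CDR3beta length; default `c(11, 20)` so
#'   every clonotype has at least one 4-mer.
#' @param high_fraction Fraction of high-avidity clonotypes in `[0, 1]`.
#' @param enrichment_residues Letters favored in high-avidity CDR3betas;
#'   default N, E, I, K, T, Y, V.
#' @param depletion_residues Letters favored in low-avidity CDR3betas;
#'   default A, R, D, L, M, P.
#' @param mixing_weight Probability that a position is drawn from the class's
#'   favored set rather than uniformly from all 20 letters; default 0.35
#'   (detectable but imperfect signal).
#' @param halflife_low,halflife_high Class half-life intervals (s); must lie
#'   strictly below / above 60 s. Defaults `c(0.5, 55)` and `c(65, 250)`.
#' @param exposure_rate Probability a residue is exposed above 30%; default
#'   0.5.
#' @param couple_exposure When TRUE, enrichment residues are exposed with
#'   probability `min(1, 1.6 * exposure_rate)` (composition-exposure
#'   coupling); default FALSE (masks independent of sequence).
#' @param motif Optional amino-acid string (>= 4 letters) written into every
#'   high-avidity CDR3beta at a random 4-mer-eligible offset, planting a
#'   zero-distance high-avidity clade.
#' @param seed Integer seed.
#' @return Object of class `panel_spec`.
#' @export
panel_spec <- function(n_tcrs, cdr3_length_range = c(11L, 20L),
                       high_fraction = 0.25,
                       enrichment_residues = c("N", "E", "I", "K", "T", "Y", "V"),
                       depletion_residues = c("A", "R", "D", "L", "M", "P"),
                       mixing_weight = 0.35,
                       halflife_low = c(0.5, 55), halflife_high = c(65, 250),
                       exposure_rate = 0.5, couple_exposure = FALSE,
                       motif = NULL, seed = 1L) {
  stopifnot(n_tcrs >= 0,
            length(cdr3_length_range) == 2,
            cdr3_length_range[1] <= cdr3_length_range[2],
            high_fraction >= 0, high_fraction <= 1,
            all(enrichment_residues %in% AA_ALPHABET),
            all(depletion_residues %in% AA_ALPHABET),
            mixing_weight >= 0, mixing_weight <= 1,
            length(halflife_low) == 2, length(halflife_high) == 2,
            halflife_low[1] <= halflife_low[2],
            halflife_high[1] <= halflife_high[2],
            exposure_rate >= 0, exposure_rate <= 1)
  if (cdr3_length_range[1] < 11)
    stop("cdr3_length_range minimum must be >= 11 (no 4-mer otherwise)")
  if (halflife_low[2] >= 60 || halflife_high[1] <= 60)
    stop("half-life intervals must not straddle the 60 s class boundary")
  if (!is.null(motif)) {
    stopifnot(is.character(motif), nchar(motif) >= 4,
              nchar(motif) <= cdr3_length_range[1] - 7)
    check_aa(toupper(motif))
  }
  structure(list(n_tcrs = as.integer(n_tcrs),
                 cdr3_length_range = as.integer(cdr3_length_range),
                 high_fraction = high_fraction,
                 enrichment_residues = enrichment_residues,
                 depletion_residues = depletion_residues,
                 mixing_weight = mixing_weight,
                 halflife_low = halflife_low, halflife_high = halflife_high,
                 exposure_rate = exposure_rate,
                 couple_exposure = couple_exposure,
                 motif = if (is.null(motif)) NULL else toupper(motif),
                 seed = as.integer(seed)),
            class = "panel_spec")
}

# sample() that never interprets a length-1 vector as 1:n
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# draw one CDR3beta of length L from the class mixture
draw_cdr3 <- function(L, favored, w) {
  from_set <- runif(L) < w & length(favored) > 0
  out <- character(L)
  out[from_set] <- sample(favored, sum(from_set), replace = TRUE)
  out[!from_set] <- sample(AA_ALPHABET, sum(!from_set), replace = TRUE)
  paste(out, collapse = "")
}

#' Generate a synthetic TCR panel with planted avidity structure
#'
#' Draws `n_tcrs` clonotypes, assigns exactly `round(n * high_fraction)` of
#' them (at random positions) to the high-avidity class, samples half-lives
#' uniformly within the class interval, biases CDR3beta composition toward
#' the class's favored residue set, and attaches one exposure profile per
#' clonotype. Identical spec (including seed) reproduces identical output.
#'
#' @param spec `panel_spec`.
#' @return List with `panel` (data frame: `tcr_id`, `cdr3b`, `pmhc`,
#'   `halflife_s`, `label`) and `exposures` (long data frame: `tcr_id`,
#'   `position`, `exposed_fraction`).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  n <- spec$n_tcrs
  empty <- list(panel = data.frame(tcr_id = character(0), cdr3b = character(0),
                                   pmhc = character(0), halflife_s = numeric(0),
                                   label = integer(0)),
                exposures = data.frame(tcr_id = character(0),
                                       position = integer(0),
                                       exposed_fraction = numeric(0)))
  if (n == 0) return(empty)
  withr::with_seed(spec$seed, {
    n_high <- round(n * spec$high_fraction)
    label <- integer(n)
    label[sample(n, n_high)] <- 1L
    L <- resample(seq(spec$cdr3_length_range[1], spec$cdr3_length_range[2]),
                  n, replace = TRUE)
    cdr3 <- vapply(seq_len(n), function(i) {
      fav <- if (label[i] == 1) spec$enrichment_residues
             else spec$depletion_residues
      s <- draw_cdr3(L[i], fav, spec$mixing_weight)
      if (label[i] == 1 && !is.null(spec$motif)) {
        # overwrite at an offset keeping the motif within positions 5..(L-3)
        lm <- nchar(spec$motif)
        start <- resample(5:(L[i] - 3 - lm + 1), 1)
        substr(s, start, start + lm - 1) <- spec$motif
      }
      s
    }, character(1))
    halflife <- ifelse(label == 1,
                       runif(n, spec$halflife_high[1], spec$halflife_high[2]),
                       runif(n, spec$halflife_low[1], spec$halflife_low[2]))
    # a nominal epitope annotation: high/low clones spread over 4 pMHCs
    pmhc <- paste0("pMHC", sample(1:4, n, replace = TRUE))
    panel <- data.frame(tcr_id = sprintf("TCR%04d", seq_len(n)),
                        cdr3b = cdr3, pmhc = pmhc,
                        halflife_s = halflife, label = label,
                        stringsAsFactors = FALSE)
    exposures <- do.call(rbind, lapply(seq_len(n), function(i) {
      letters <- strsplit(cdr3[i], "", fixed = TRUE)[[1]]
      rate <- rep(spec$exposure_rate, L[i])
      if (spec$couple_exposure) {
        rate[letters %in% spec$enrichment_residues] <-
          pmin(1, 1.6 * spec$exposure_rate)
      }
      exposed <- runif(L[i]) < rate
      frac <- ifelse(exposed, runif(L[i], 0.301, 1), runif(L[i], 0, 0.30))
      data.frame(tcr_id = panel$tcr_id[i], position = seq_len(L[i]),
                 exposed_fraction = frac, stringsAsFactors = FALSE)
    }))
    list(panel = panel, exposures = exposures)
  })
}

#' Specification of a synthetic contact-count table
#'
#' @param n_complexes Number of TCR-pMHC complexes.
#' @param k,gamma,delta Linear-model coefficients: intercept (s), seconds per
#'   apolar contact, seconds per polar contact.
#' @param noise_sd Gaussian noise SD on the half-life (s); >= 0.
#' @param apolar_range,polar_range Integer ranges for the contact counts.
#' @param clip_at_zero Truncate negative half-lives at 0; default FALSE
#'   (fitting is unconstrained).
#' @param seed Integer seed.
#' @return Object of class `contact_spec`.
#' @export
contact_spec <- function(n_complexes, k = -62.89, gamma = 2.647,
                         delta = 8.747, noise_sd = 0,
                         apolar_range = c(15L, 45L), polar_range = c(2L, 12L),
                         clip_at_zero = FALSE, seed = 1L) {
  stopifnot(n_complexes >= 0, noise_sd >= 0,
            length(apolar_range) == 2, length(polar_range) == 2,
            apolar_range[1] >= 0, polar_range[1] >= 0,
            apolar_range[1] <= apolar_range[2],
            polar_range[1] <= polar_range[2])
  structure(list(n_complexes = as.integer(n_complexes), k = k, gamma = gamma,
                 delta = delta, noise_sd = noise_sd,
                 apolar_range = as.integer(apolar_range),
                 polar_range = as.integer(polar_range),
                 clip_at_zero = clip_at_zero, seed = as.integer(seed)),
            class = "contact_spec")
}

#' Generate a synthetic contact-count table
#'
#' Draws integer contact counts uniformly within the spec ranges and sets
#' `halflife_s = k + gamma * n_apolar + delta * n_polar + N(0, noise_sd)`.
#'
#' @param spec `contact_spec`.
#' @param n_apolar,n_polar Optional fixed contact-count vectors overriding the
#'   random draw (lengths must equal `n_complexes`).
#' @return Data frame: `complex_id`, `n_apolar`, `n_polar`, `halflife_s`.
#' @export
generate_contacts <- function(spec, n_apolar = NULL, n_polar = NULL) {
  stopifnot(inherits(spec, "contact_spec"))
  n <- spec$n_complexes
  withr::with_seed(spec$seed, {
    na <- if (is.null(n_apolar)) {
      resample(seq(spec$apolar_range[1], spec$apolar_range[2]), n, replace = TRUE)
    } else {
      stopifnot(length(n_apolar) == n); as.integer(n_apolar)
    }
    np <- if (is.null(n_polar)) {
      resample(seq(spec$polar_range[1], spec$polar_range[2]), n, replace = TRUE)
    } else {
      stopifnot(length(n_polar) == n); as.integer(n_polar)
    }
    halflife <- spec$k + spec$gamma * na + spec$delta * np +
      if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0
    if (spec$clip_at_zero) halflife <- pmax(halflife, 0)
    data.frame(complex_id = sprintf("CPLX%03d", seq_len(n)),
               n_apolar = na, n_polar = np, halflife_s = halflife,
               stringsAsFactors = FALSE)
  })
}

#' Generate paired blood/tumor bulk repertoires from a labelled panel
#'
#' Read counts are multinomial over the panel's clonotypes at the given
#' sequencing depth. In the tumor sample only, the sampling weight of
#' high-avidity clonotypes is multiplied by `tumor_high_bias`; `bias = 1`
#' makes the two compartments exchangeable, `bias = Inf` restricts the tumor
#' to high-avidity clonotypes.
#'
#' @param panel Labelled panel data frame (`tcr_id`, `cdr3b`, `label`).
#' @param tumor_high_bias Odds multiplier >= 0 (or Inf).
#' @param depth Total reads per compartment; > 0.
#' @param seed Integer seed.
#' @return List of two data frames (`blood`, `tumor`) with columns
#'   `compartment`, `tcr_id`, `cdr3b`, `label`, `count` (zero-count
#'   clonotypes dropped).
#' @export
generate_repertoires <- function(panel, tumor_high_bias = 1, depth = 10000L,
                                 seed = 1L) {
  stopifnot(is.data.frame(panel), nrow(panel) > 0,
            all(c("cdr3b", "label") %in% names(panel)),
            tumor_high_bias >= 0)
  if (depth <= 0) stop("depth must be positive")
  base_w <- rep(1, nrow(panel))
  tumor_w <- base_w
  if (is.infinite(tumor_high_bias)) {
    tumor_w[panel$label != 1] <- 0
  } else {
    tumor_w[panel$label == 1] <- tumor_high_bias
  }
  if (sum(tumor_w) == 0) stop("tumor weights all zero; no high-avidity clones")
  withr::with_seed(seed, {
    draw <- function(w, compartment) {
      counts <- drop(rmultinom(1, size = depth, prob = w / sum(w)))
      keep <- counts > 0
      data.frame(compartment = compartment,
                 tcr_id = panel$tcr_id[keep], cdr3b = panel$cdr3b[keep],
                 label = panel$label[keep], count = counts[keep],
                 stringsAsFactors = FALSE)
    }
    list(blood = draw(base_w, "blood"), tumor = draw(tumor_w, "tumor"))
  })
}

#' Generate a synthetic panel with labels planted by a logistic model
#'
#' Sequences and exposure masks are drawn as in [generate_panel()] (uniform
#' composition), features are built under `fdef`, and the high/low label is
#' Bernoulli with probability `plogis(b0 + X w)`; half-lives are then drawn
#' from the class interval. Used for logistic parameter-recovery validation.
#'
#' @param n Number of TCRs.
#' @param fdef `feature_definition` whose residues carry the planted weights.
#' @param b0 Planted bias.
#' @param weights Planted weights, one per residue of `fdef`.
#' @param exposure_rate Per-position exposure probability; default 0.5.
#' @param cdr3_length_range Length range; default `c(11, 20)`.
#' @param seed Integer seed.
#' @return List with `panel`, `exposures`, `features` (matrix) and
#'   `prob` (planted probabilities).
#' @export
generate_logistic_panel <- function(n, fdef, b0, weights, exposure_rate = 0.5,
                                    cdr3_length_range = c(11L, 20L),
                                    seed = 1L) {
  stopifnot(inherits(fdef, "feature_definition"),
            length(weights) == length(fdef$residues), n >= 1)
  withr::with_seed(seed, {
    L <- resample(seq(cdr3_length_range[1], cdr3_length_range[2]), n,
                  replace = TRUE)
    cdr3 <- vapply(L, function(l)
      paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = ""),
      character(1))
    ids <- sprintf("TCR%04d", seq_len(n))
    exposures <- do.call(rbind, lapply(seq_len(n), function(i) {
      exposed <- runif(L[i]) < exposure_rate
      frac <- ifelse(exposed, runif(L[i], 0.301, 1), runif(L[i], 0, 0.30))
      data.frame(tcr_id = ids[i], position = seq_len(L[i]),
                 exposed_fraction = frac, stringsAsFactors = FALSE)
    }))
    panel <- data.frame(tcr_id = ids, cdr3b = cdr3,
                        pmhc = paste0("pMHC", sample(1:4, n, replace = TRUE)),
                        stringsAsFactors = FALSE)
    X <- feature_matrix(panel, exposures, fdef)
    prob <- plogis(b0 + drop(X %*% weights))
    panel$label <- rbinom(n, 1, prob)
    panel$halflife_s <- ifelse(panel$label == 1, runif(n, 65, 250),
                               runif(n, 0.5, 55))
    list(panel = panel, exposures = exposures, features = X, prob = prob)
  })
}
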