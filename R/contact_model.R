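#' Construct a contact-count half-life model
#'
#' The linear model `T1/2 (s) = K + gamma * n_apolar + delta * n_polar`, a
#' simplification of binding free-energy estimation in which gamma and delta
#' weight the numbers of apolar and polar TCR-pMHC contacts and the intercept
#' K absorbs contributions independent of contact counts.
#'
#' @param k Intercept (s).
#' @param gamma Seconds per apolar contact.
#' @param delta Seconds per polar contact.
#' @param diagnostics Optional list (r_squared, residual_sd, n).
#' @return Object of class `contact_model`.
#' @export
contact_model <- function(k, gamma, delta, diagnostics = NULL) {
  stopifnot(is.finite(k), is.finite(gamma), is.finite(delta))
  structure(list(k = k, gamma = gamma, delta = delta,
                 diagnostics = diagnostics),
            class = "contact_model")
}

#' Fit the contact-count model by ordinary least squares
#'
#' Multiple linear regression of measured half-life on the apolar and polar
#' contact counts, with intercept; no weighting and no regularization.
#'
#' @param table Data frame with columns `n_apolar`, `n_polar`, `halflife_s`
#'   (rows with missing half-life are dropped).
#' @return `contact_model` with diagnostics `r_squared`, `residual_sd`, `n`,
#'   and the underlying `lm` fit as `attr(, "fit")`.
#' @export
fit_contact_model <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("n_apolar", "n_polar", "halflife_s") %in% names(table)))
  tab <- table[!is.na(table$halflife_s), , drop = FALSE]
  if (nrow(tab) < 3) stop("need at least 3 complexes with measured half-life")
  if (any(tab$n_apolar < 0) || any(tab$n_polar < 0))
    stop("contact counts must be nonnegative")
  for (col in c("n_apolar", "n_polar")) {
    if (length(unique(tab[[col]])) < 2)
      stop(sprintf("column '%s' is constant; design is rank deficient", col))
  }
  X <- cbind(1, tab$n_apolar, tab$n_polar)
  if (qr(X)$rank < 3)
    stop("design matrix is rank deficient (collinear n_apolar / n_polar)")
  fit <- lm(halflife_s ~ n_apolar + n_polar, data = tab)
  # noiseless tables trigger the "essentially perfect fit" note; R^2 = 1 is a
  # legitimate outcome here
  s <- suppressWarnings(summary(fit))
  m <- contact_model(
    k = unname(coef(fit)[1]),
    gamma = unname(coef(fit)[2]),
    delta = unname(coef(fit)[3]),
    diagnostics = list(r_squared = s$r.squared,
                       residual_sd = s$sigma,
                       n = nrow(tab)))
  attr(m, "fit") <- fit
  m
}

#' Predict half-life from contact counts
#'
#' Linear evaluation of the fitted model; predictions are reported as-is and
#' may be negative (an extrapolation flag, returned in the `below_zero`
#' attribute, marks them).
#'
#' @param model `contact_model`.
#' @param n_apolar,n_polar Contact counts (vectorized).
#' @return Numeric vector of predicted half-lives (s) with a logical
#'   `below_zero` attribute.
#' @export
#' @examples
#' predict_halflife(contact_model(-62.89, 2.647, 8.747), 30, 5)  # 60.255
predict_halflife <- function(model, n_apolar, n_polar) {
  stopifnot(inherits(model, "contact_model"),
            length(n_apolar) == length(n_polar))
  pred <- model$k + model$gamma * n_apolar + model$delta * n_polar
  attr(pred, "below_zero") <- pred < 0
  pred
}

#' @export
print.contact_model <- function(x, ...) {
  cat(sprintf("Contact-count half-life model: T1/2 = %.4g %+.4g * n_apolar %+.4g * n_polar\n",
              x$k, x$gamma, x$delta))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  fitted on n = %d complexes, R^2 = %.3f, residual SD = %.3g s\n",
                x$diagnostics$n, x$diagnostics$r_squared,
                x$diagnostics$residual_sd))
  }
  invisible(x)
}
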