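#' Fit the logistic high/low-avidity classifier
#'
#' Maximum-likelihood logistic regression of the high/low label on the feature
#' vector, `p = 1 / (1 + exp(-(b0 + sum_i W_i x_i)))`. When the classes are
#' linearly separated (the MLE diverges), the weights are re-estimated with a
#' fixed tiny L2 penalty (`ridge` on the weights, never on the bias) and the
#' fit is flagged `separable`.
#'
#' @param X Feature matrix (rows = TCRs, columns = residues).
#' @param y Labels (1 = high, 0 = low).
#' @param fdef `feature_definition` behind `X` (stored in the model).
#' @param threshold Decision threshold on p; default 0.5, applied strictly
#'   (`p > threshold` calls high).
#' @param ridge Penalty used only under separation; default 1e-6.
#' @return Object of class `avidity_logistic`: `b0`, `weights` (named),
#'   `fdef`, `threshold`, `separable`, `converged`, `n`.
#' @export
fit_logistic <- function(X, y, fdef = NULL, threshold = 0.5, ridge = 1e-6) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2) stop("both avidity classes must be present")
  if (nrow(X) < ncol(X) + 1)
    stop("fewer TCRs than parameters; reduce the feature set")

  dat <- data.frame(y = y, X)
  fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial()))
  p_hat <- fitted(fit)
  separable <- !fit$converged || any(p_hat < 1e-8 | p_hat > 1 - 1e-8)

  if (separable) {
    co <- ridge_logistic(cbind(1, X), y, ridge)
  } else {
    co <- coef(fit)
    co[is.na(co)] <- 0  # aliased (constant) features carry no information
  }
  structure(list(b0 = unname(co[1]),
                 weights = setNames(unname(co[-1]), colnames(X)),
                 fdef = fdef, threshold = threshold,
                 separable = separable, converged = TRUE,
                 ridge = if (separable) ridge else 0,
                 n = nrow(X)),
            class = "avidity_logistic")
}

# penalized logistic log-likelihood maximized by BFGS; penalty on weights only
ridge_logistic <- function(Xb, y, lambda) {
  p <- ncol(Xb)
  nll <- function(beta) {
    eta <- drop(Xb %*% beta)
    -sum(y * eta - log1p(exp(eta))) + 0.5 * lambda * sum(beta[-1]^2)
  }
  grad <- function(beta) {
    mu <- plogis(drop(Xb %*% beta))
    g <- -drop(crossprod(Xb, y - mu))
    g[-1] <- g[-1] + lambda * beta[-1]
    g
  }
  opt <- stats::optim(rep(0, p), nll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  opt$par
}

#' Predict avidity class probabilities
#'
#' @param model `avidity_logistic`.
#' @param X Feature matrix or single named feature vector matching the model's
#'   residues.
#' @return Data frame with `p` (probability of high avidity) and `label`
#'   (1 iff `p` strictly exceeds the model threshold).
#' @export
predict_avidity <- function(model, X) {
  stopifnot(inherits(model, "avidity_logistic"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  X <- as.matrix(X)
  if (ncol(X) != length(model$weights))
    stop(sprintf("feature dimension %d does not match model dimension %d",
                 ncol(X), length(model$weights)))
  if (!is.null(colnames(X)) && !identical(colnames(X), names(model$weights)))
    stop("feature columns do not match the model's residue set")
  eta <- model$b0 + drop(X %*% model$weights)
  p <- plogis(eta)
  data.frame(p = p, label = as.integer(p > model$threshold))
}

#' @export
print.avidity_logistic <- function(x, ...) {
  cat(sprintf("Logistic avidity classifier (n = %d, threshold %.2f%s)\n",
              x$n, x$threshold,
              if (x$separable) ", separable: tiny-ridge fit" else ""))
  cat(sprintf("  b0 = %.4g\n", x$b0))
  w <- x$weights
  cat("  weights:", paste(sprintf("%s = %.4g", names(w), w), collapse = ", "),
      "\n")
  invisible(x)
}

#' Classifier performance: AUC, sensitivity, specificity, confusion counts
#'
#' The AUC is the rank (Mann-Whitney) statistic with mid-rank tie correction:
#' the probability that a random high-avidity TCR scores above a random
#' low-avidity TCR, counting ties as one half. Sensitivity and specificity are
#' evaluated at the model's decision threshold.
#'
#' @param scores Numeric predicted probabilities (or any monotone scores).
#' @param labels True labels (1 = high, 0 = low).
#' @param threshold Decision threshold; default 0.5 (strict).
#' @return List: `auc`, `sensitivity`, `specificity`, `accuracy`, and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`. With a single-class label
#'   vector, `auc` is `NA` and a note says why.
#' @export
evaluate_classifier <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(scores)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  call_high <- scores > threshold
  tp <- sum(call_high & pos); fn <- sum(!call_high & pos)
  tn <- sum(!call_high & !pos); fp <- sum(call_high & !pos)
  list(auc = auc,
       sensitivity = if (n1 > 0) tp / n1 else NA_real_,
       specificity = if (n0 > 0) tn / n0 else NA_real_,
       accuracy = (tp + tn) / length(labels),
       tp = tp, fp = fp, tn = tn, fn = fn,
       note = if (is.na(auc)) "single-class evaluation set: AUC undefined"
              else NULL)
}

#' Cross-validate the avidity classifier
#'
#' Three schemes: `leave20out_random` holds out a random 20% per fold
#' (5 folds per repetition); `leave20out_stratified` does the same with folds
#' stratified by class; `leave_one_epitope_out` holds out all TCRs of one
#' cognate pMHC at a time (the hardest test: the held-out specificity is never
#' seen in training). Success is the fraction of correct class calls at the
#' decision threshold, aggregated over all held-out predictions.
#'
#' @param X Feature matrix.
#' @param y Labels (1/0).
#' @param scheme One of the three scheme names.
#' @param epitopes Character vector of cognate pMHC per TCR (scheme 3 only).
#' @param reps Repetitions of the random/stratified 5-fold split; default 1.
#' @param seed Optional integer seed.
#' @param fdef,threshold,ridge Passed to [fit_logistic()].
#' @return List: `success` (aggregate accuracy), `fold_success`, `folds`
#'   (held-out index sets), `scheme`.
#' @export
cross_validate <- function(X, y, scheme = c("leave20out_random",
                                            "leave20out_stratified",
                                            "leave_one_epitope_out"),
                           epitopes = NULL, reps = 1, seed = NULL,
                           fdef = NULL, threshold = 0.5, ridge = 1e-6) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); y <- as.integer(y)
  n <- nrow(X)
  stopifnot(length(y) == n)

  make_folds <- function() {
    if (scheme == "leave_one_epitope_out") {
      if (is.null(epitopes) || length(unique(epitopes)) < 2)
        stop("leave_one_epitope_out needs >= 2 distinct epitopes")
      return(split(seq_len(n), epitopes))
    }
    folds_once <- function() {
      if (scheme == "leave20out_random") {
        split(sample(n), rep_len(1:5, n))
      } else {
        idx1 <- sample(which(y == 1)); idx0 <- sample(which(y == 0))
        f <- vector("list", 5)
        a1 <- split(idx1, rep_len(1:5, length(idx1)))
        a0 <- split(idx0, rep_len(1:5, length(idx0)))
        for (k in 1:5) f[[k]] <- c(a1[[as.character(k)]], a0[[as.character(k)]])
        f
      }
    }
    do.call(c, replicate(reps, folds_once(), simplify = FALSE))
  }
  folds <- if (is.null(seed)) make_folds() else withr::with_seed(seed, make_folds())
  folds <- lapply(folds, function(f) sort(as.integer(f)))
  folds <- Filter(length, folds)

  correct <- integer(0); total <- integer(0)
  fold_success <- numeric(length(folds))
  for (k in seq_along(folds)) {
    test <- folds[[k]]
    train <- setdiff(seq_len(n), test)
    model <- fit_logistic(X[train, , drop = FALSE], y[train], fdef = fdef,
                          threshold = threshold, ridge = ridge)
    pred <- predict_avidity(model, X[test, , drop = FALSE])
    ok <- pred$label == y[test]
    fold_success[k] <- mean(ok)
    correct <- c(correct, sum(ok)); total <- c(total, length(ok))
  }
  list(success = sum(correct) / sum(total),
       fold_success = fold_success, folds = folds, scheme = scheme)
}
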