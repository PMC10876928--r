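#' Area under the ROC curve (Mann-Whitney form)
#'
#' P(score of a random case > score of a random control) + 0.5 P(tie),
#' computed from midranks, which equals the average over all case-control
#' pairs.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcome (1/TRUE = case).
#' @return AUC in [0, 1].
#' @export
#' @examples
#' auc(c(1, 2, 3, 4), c(0, 1, 0, 1))  # 0.75
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop_protscan("both outcome classes are required")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Smallest penalty that zeroes every protein coefficient
#'
#' The entry value of the L1 path when baseline covariates are unpenalized:
#' `max_j |(1/n) sum_i x_ij (y_i - p0_i)|`, with `p0` the fitted
#' probabilities of the baseline-only logistic model.
#'
#' @param features standardized protein matrix.
#' @param unpenalized baseline covariate matrix/data.frame (or `NULL`).
#' @param outcome binary outcome.
#' @return lambda_max (scalar).
#' @export
lasso_lambda_max <- function(features, unpenalized, outcome) {
  y <- as.numeric(outcome)
  p0 <- if (is.null(unpenalized) || ncol(as.matrix(unpenalized)) == 0)
    rep(mean(y), length(y))
  else stats::fitted(stats::glm(y ~ ., family = stats::binomial(),
                                data = as.data.frame(unpenalized)))
  max(abs(crossprod(as.matrix(features), y - p0))) / length(y)
}

#' L1-penalized logistic regression with unpenalized baseline covariates
#'
#' Minimizes `(1/n) * negative log-likelihood + lambda * sum(|beta_protein|)`
#' with the intercept and every baseline covariate exempt from the penalty,
#' so established risk factors are always retained at their maximum
#' likelihood scale while protein coefficients are shrunk and selected.
#' Protein features should be standardized to unit SD so the penalty acts
#' on comparable scales.
#'
#' @param features numeric protein matrix (samples x proteins), no missing
#'   values.
#' @param unpenalized baseline covariate matrix/data.frame (or `NULL`).
#' @param outcome binary case indicator.
#' @param lambda penalty value (>= 0).
#' @param kkt_tol tolerance for the reported KKT check.
#' @return list with `beta_proteins`, `beta_baseline`, `intercept`,
#'   `lambda`, `n_nonzero` (protein coefficients), and `kkt_violation`
#'   (largest score-condition excess over `lambda` among zero-coefficient
#'   proteins; ~0 at a converged solution).
#' @export
fit_l1_logistic <- function(features, unpenalized, outcome, lambda,
                            kkt_tol = 1e-6) {
  features <- as.matrix(features)
  if (anyNA(features)) stop_protscan("protein features contain missing values")
  if (!is.finite(lambda) || lambda < 0)
    stop_protscan("lambda must be finite and >= 0")
  y <- as.numeric(outcome)
  base <- if (is.null(unpenalized)) NULL else
    stats::model.matrix(~ . - 1, data = as.data.frame(unpenalized))
  x <- cbind(base, features)
  pf <- c(rep(0, ncol(x) - ncol(features)), rep(1, ncol(features)))
  ## glmnet rescales penalty.factor to sum to nvars; pre-scale lambda so
  ## the effective per-protein penalty is exactly the requested one
  lam_scale <- sum(pf) / length(pf)
  lmax <- max(lasso_lambda_max(features, unpenalized, outcome), lambda,
              1e-4)
  ## decreasing warm-start sequence ending exactly at the requested lambda
  lams <- unique(sort(c(exp(seq(log(lmax * 1.05), log(max(lambda, 1e-8)),
                                length.out = 30)), lambda),
                      decreasing = TRUE))
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        lambda = lams * lam_scale, penalty.factor = pf,
                        standardize = FALSE, thresh = 1e-12,
                        maxit = 1e6)
  j <- which.min(abs(fit$lambda - lambda * lam_scale))
  cf <- as.numeric(fit$beta[, j])
  a0 <- fit$a0[j]
  nb <- ncol(x) - ncol(features)
  beta_base <- if (nb) stats::setNames(cf[seq_len(nb)], colnames(x)[seq_len(nb)])
    else numeric(0)
  beta_prot <- stats::setNames(cf[(nb + 1):ncol(x)], colnames(features))
  eta <- drop(x %*% cf) + a0
  p_hat <- 1 / (1 + exp(-eta))
  score <- abs(crossprod(features, y - p_hat)) / length(y)
  zero <- abs(beta_prot) == 0
  kkt <- if (any(zero)) max(0, max(score[zero]) - lambda) else 0
  if (kkt > 100 * kkt_tol)
    warning(sprintf("KKT violation %.2g above tolerance at lambda = %.3g",
                    kkt, lambda))
  list(beta_proteins = beta_prot, beta_baseline = beta_base,
       intercept = unname(a0), lambda = lambda,
       n_nonzero = sum(!zero), kkt_violation = kkt)
}

#' Cross-validated AUC along the L1 penalty path
#'
#' For each penalty on a 50-point log-spaced grid from `lambda_max` down to
#' `0.001 * lambda_max`, fits the penalized model (baseline covariates
#' unpenalized) on four folds and scores the held-out fold; reports the
#' mean and standard error of the five held-out AUCs, together with the
#' identically cross-validated AUC of the protein-free baseline model.
#' Folds are stratified by case status (and centre when given); missing
#' protein values are median-imputed with medians learned on the training
#' folds only; features are standardized with training-fold SDs.
#'
#' @param features protein matrix (samples x proteins; `NA` allowed).
#' @param unpenalized baseline covariate data.frame.
#' @param outcome binary case indicator.
#' @param lambda_grid decreasing penalty grid; `NULL` for the default.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed controlling fold assignment.
#' @param centre optional per-sample centre labels for stratification.
#' @return object of class `lasso_auc_path`: data.frame with `lambda`,
#'   `mean_auc`, `se_auc`, `n_nonzero` (from a full-data path fit), plus
#'   attributes `baseline_auc`, `baseline_se`, `folds`, `seed`.
#' @export
cv_auc_path <- function(features, unpenalized, outcome, lambda_grid = NULL,
                        n_folds = 5, seed = 1, centre = NULL) {
  features <- as.matrix(features)
  y <- as.numeric(outcome)
  n <- length(y)
  if (length(unique(y)) != 2) stop_protscan("outcome must have two classes")
  folds <- stratified_folds(y, centre, n_folds, seed)
  base_df <- as.data.frame(unpenalized)

  ## grid from the full-data (imputed/standardized) problem
  full <- impute_standardize(features, features)
  if (is.null(lambda_grid)) {
    lmax <- lasso_lambda_max(full, base_df, y)
    lambda_grid <- exp(seq(log(lmax), log(0.001 * lmax), length.out = 50))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  base_mm <- stats::model.matrix(~ . - 1, data = base_df)
  pf <- c(rep(0, ncol(base_mm)), rep(1, ncol(features)))
  ## see fit_l1_logistic: undo glmnet's internal penalty.factor rescaling
  lam_scale <- sum(pf) / length(pf)
  full_fit <- glmnet::glmnet(cbind(base_mm, full), y, family = "binomial",
                             lambda = lambda_grid * lam_scale,
                             penalty.factor = pf,
                             standardize = FALSE, thresh = 1e-10,
                             maxit = 1e6)
  nz <- colSums(abs(as.matrix(
    full_fit$beta[(ncol(base_mm) + 1):nrow(full_fit$beta), , drop = FALSE])) > 0)

  auc_fold <- matrix(NA_real_, n_folds, length(lambda_grid))
  auc_base <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    feat_tr <- impute_standardize(features[tr, , drop = FALSE],
                                  features[tr, , drop = FALSE])
    feat_te <- impute_standardize(features[!tr, , drop = FALSE],
                                  features[tr, , drop = FALSE])
    x_tr <- cbind(base_mm[tr, , drop = FALSE], feat_tr)
    x_te <- cbind(base_mm[!tr, , drop = FALSE], feat_te)
    fit <- glmnet::glmnet(x_tr, y[tr], family = "binomial",
                          lambda = lambda_grid * lam_scale,
                          penalty.factor = pf,
                          standardize = FALSE, thresh = 1e-10, maxit = 1e6)
    pred <- stats::predict(fit, newx = x_te)
    auc_fold[f, ] <- apply(pred, 2, auc, labels = y[!tr])
    bfit <- stats::glm(y[tr] ~ ., family = stats::binomial(),
                       data = base_df[tr, , drop = FALSE])
    auc_base[f] <- auc(stats::predict(bfit,
                                      newdata = base_df[!tr, , drop = FALSE]),
                       y[!tr])
  }
  out <- data.frame(lambda = lambda_grid,
                    mean_auc = colMeans(auc_fold),
                    se_auc = apply(auc_fold, 2, stats::sd) / sqrt(n_folds),
                    n_nonzero = as.integer(nz))
  structure(out, class = c("lasso_auc_path", "data.frame"),
            baseline_auc = mean(auc_base),
            baseline_se = stats::sd(auc_base) / sqrt(n_folds),
            folds = folds, seed = seed)
}

#' @export
print.lasso_auc_path <- function(x, ...) {
  best <- which.max(x$mean_auc)
  cat(sprintf("Cross-validated AUC path: %d penalties, %d folds\n",
              nrow(x), max(attr(x, "folds"))))
  cat(sprintf("  baseline (no proteins): AUC %.3f (SE %.3f)\n",
              attr(x, "baseline_auc"), attr(x, "baseline_se")))
  cat(sprintf("  best on path: AUC %.3f (SE %.3f) at lambda %.4g with %d protein(s)\n",
              x$mean_auc[best], x$se_auc[best], x$lambda[best],
              x$n_nonzero[best]))
  invisible(x)
}

#' @export
plot.lasso_auc_path <- function(x, ...) {
  graphics::plot(log(x$lambda), x$mean_auc, type = "l",
                 xlab = expression(log(lambda)), ylab = "mean CV AUC", ...)
  graphics::arrows(log(x$lambda), x$mean_auc - x$se_auc,
                   log(x$lambda), x$mean_auc + x$se_auc,
                   length = 0.02, angle = 90, code = 3, col = "grey60")
  graphics::abline(h = attr(x, "baseline_auc"), lty = 2, col = "red")
  invisible(x)
}

#' Write a lasso path result as TSV
#' @param path_result a `lasso_auc_path`
#' @param path output file
#' @export
write_lasso_path <- function(path_result, path) {
  utils::write.table(as.data.frame(path_result), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

## median-impute `x` with medians learned on `train`, then scale columns to
## unit SD (training SD); constant columns are left unscaled
impute_standardize <- function(x, train) {
  med <- apply(train, 2, stats::median, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- med[idx[, 2]]
  sds <- apply(train, 2, stats::sd, na.rm = TRUE)
  sds[!is.finite(sds) | sds == 0] <- 1
  sweep(x, 2, sds, "/")
}

## stratified fold assignment: shuffle within outcome x centre cells, then
## deal round-robin so every fold keeps both classes
stratified_folds <- function(y, centre, n_folds, seed) {
  set.seed(seed)
  cells <- if (is.null(centre)) as.character(y) else paste(y, centre)
  folds <- integer(length(y))
  for (cell in unique(cells)) {
    idx <- sample(which(cells == cell))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}
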