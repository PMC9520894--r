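#' Area under the ROC curve (Mann-Whitney form)
#'
#' `(concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg)`, computed from
#' midranks so ties are handled exactly.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (logical, 0/1, or two-level factor; the
#'   higher/TRUE level is the positive class).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  n1 <- as.numeric(sum(pos)); n0 <- as.numeric(sum(!pos))
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)   # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) abort("labels must have exactly two levels")
    return(labels == levels(labels)[2])
  }
  u <- sort(unique(labels))
  if (length(u) != 2) abort("labels must have exactly two distinct values")
  labels == u[2]
}

# DeLong structural components: V10[i] = mean_j psi(x_i, y_j) over negatives,
# V01[j] = mean_i psi(x_i, y_j) over positives, psi = 1/0.5/0 for x>y/x==y/x<y.
delong_components <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(theta = mean(psi), V10 = rowMeans(psi), V01 = colMeans(psi),
       m = m, n = n)
}

#' DeLong's test for two correlated AUROCs
#'
#' Nonparametric comparison of two models scored on the same samples via the
#' structural-components estimate of the AUROC covariance; returns the
#' two-sided normal p-value for the AUROC difference plus each model's AUROC
#' with a 95% confidence interval from the same components.
#'
#' @param scores_A,scores_B Paired score vectors for models A and B.
#' @param labels Binary labels shared by both models.
#' @param conf_level Confidence level for the single-model CIs (default 0.95).
#' @return Tibble: auroc_A, auroc_B, ci_A_low/high, ci_B_low/high, z,
#'   p_value.
#' @export
delong_test <- function(scores_A, scores_B, labels, conf_level = 0.95) {
  pos <- as_binary_labels(labels)
  if (length(scores_A) != length(labels) ||
      length(scores_B) != length(labels)) {
    abort("scores and labels must be paired on identical samples")
  }
  cA <- delong_components(scores_A, pos)
  cB <- delong_components(scores_B, pos)
  m <- cA$m; n <- cA$n
  # covariance matrices of the component vectors across models
  S10 <- stats::cov(cbind(cA$V10, cB$V10))
  S01 <- stats::cov(cbind(cA$V01, cB$V01))
  S <- S10 / m + S01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  theta_diff <- cA$theta - cB$theta
  if (var_diff <= .Machine$double.eps) {
    if (abs(theta_diff) < 1e-12) {
      z <- 0; p <- 1
    } else {
      abort("degenerate zero variance of the AUROC difference with unequal AUROCs")
    }
  } else {
    z <- theta_diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  q <- qnorm(1 - (1 - conf_level) / 2)
  ci <- function(comp, vv) {
    se <- sqrt(max(vv, 0))
    c(max(0, comp$theta - q * se), min(1, comp$theta + q * se))
  }
  ciA <- ci(cA, S[1, 1]); ciB <- ci(cB, S[2, 2])
  tibble(auroc_A = cA$theta, auroc_B = cB$theta,
         ci_A_low = ciA[1], ci_A_high = ciA[2],
         ci_B_low = ciB[1], ci_B_high = ciB[2],
         z = z, p_value = p)
}

#' Variance and confidence interval of a single AUROC (DeLong)
#'
#' @param scores Prediction scores.
#' @param labels Binary labels.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble: auroc, var, ci_low, ci_high.
#' @export
auroc_ci <- function(scores, labels, conf_level = 0.95) {
  pos <- as_binary_labels(labels)
  cc <- delong_components(scores, pos)
  v <- var(cc$V10) / cc$m + var(cc$V01) / cc$n
  q <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(max(v, 0))
  tibble(auroc = cc$theta, var = v,
         ci_low = max(0, cc$theta - q * se),
         ci_high = min(1, cc$theta + q * se))
}

# Ridge-penalized logistic regression by IRLS on standardized features.
# The tiny default penalty only tames complete separation; the intercept is
# unpenalized. Returns a scoring closure plus coefficients.
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100, tol = 1e-9) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  Z <- cbind(1, Xs)
  p <- ncol(Z)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Z * w)
    beta_new <- solve(XtW %*% Z + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  names(beta) <- c("(intercept)", colnames(X) %||% paste0("x", seq_len(p - 1)))
  list(coef = beta, center = ctr, scale = scl,
       predict = function(Xnew) {
         Xn <- sweep(sweep(as.matrix(Xnew), 2, ctr), 2, scl, `/`)
         drop(1 / (1 + exp(-(cbind(1, Xn) %*% beta))))
       })
}

#' Repeated 70/30 split evaluation of a response classifier
#'
#' The internal-validation scheme for binary drug response: `n_repeats`
#' times, samples are split 70/30 into train/test (stratified by class so
#' every training set contains both classes), a logistic model is fitted on
#' the training split and scored on the test split. Each sample's sensitivity
#' probability is the average of its test-set predictions; the pooled AUROC
#' combines the predictions of all repeats, with a DeLong 95% CI, and the
#' averaged probabilities are compared between response groups by Wilcoxon
#' rank-sum.
#'
#' @param features Sample x feature matrix (e.g. transposed signature
#'   activities) with sample rownames.
#' @param labels Binary response per sample (TRUE/positive = sensitive).
#' @param n_repeats Number of repeats (default 10).
#' @param train_frac Training fraction (default 0.7).
#' @param seed Integer seed governing every split.
#' @param lambda Ridge penalty of the logistic fit (default 1e-4).
#' @return A `bfsig_classifier_eval`: `probabilities` tibble (sample_id,
#'   probability, label, n_test_appearances), `pooled` tibble with pooled
#'   AUROC + CI and the Wilcoxon p, `pooled_scores`/`pooled_labels` for
#'   DeLong comparisons, per-repeat `coefficients` and `splits`.
#' @export
repeated_split_evaluate <- function(features, labels, n_repeats = 10,
                                    train_frac = 0.7, seed = 1,
                                    lambda = 1e-4) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(n))
  pos <- as_binary_labels(labels)
  if (sum(pos) < 2 || sum(!pos) < 2) abort("need >= 2 samples per class")
  y <- as.numeric(pos)

  idx_pos <- which(pos); idx_neg <- which(!pos)
  pooled_scores <- numeric(0); pooled_labels <- logical(0)
  pooled_sample <- character(0)
  prob_sum <- setNames(numeric(n), rownames(X))
  prob_cnt <- setNames(integer(n), rownames(X))
  coefs <- list(); splits <- list()

  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      tr_pos <- sample(idx_pos, max(1, round(train_frac * length(idx_pos))))
      tr_neg <- sample(idx_neg, max(1, round(train_frac * length(idx_neg))))
      train <- sort(c(tr_pos, tr_neg))
      test <- setdiff(seq_len(n), train)
      if (length(test) == 0) abort("empty test split; reduce train_frac")
      fit <- ridge_logistic(X[train, , drop = FALSE], y[train],
                            lambda = lambda)
      pr <- fit$predict(X[test, , drop = FALSE])
      pooled_scores <- c(pooled_scores, pr)
      pooled_labels <- c(pooled_labels, pos[test])
      pooled_sample <- c(pooled_sample, rownames(X)[test])
      prob_sum[test] <- prob_sum[test] + pr
      prob_cnt[test] <- prob_cnt[test] + 1L
      coefs[[r]] <- fit$coef
      splits[[r]] <- list(train = train, test = test)
    }
  })

  never_tested <- prob_cnt == 0
  if (any(never_tested)) {
    warn(sprintf("%d sample(s) never appeared in a test split; excluded from averaged probabilities",
                 sum(never_tested)))
  }
  avg <- prob_sum / pmax(prob_cnt, 1)
  probabilities <- tibble(sample_id = rownames(X),
                          probability = ifelse(never_tested, NA_real_, avg),
                          label = ifelse(pos, "sensitive", "resistant"),
                          n_test_appearances = unname(prob_cnt))

  pooled_auc <- auroc_ci(pooled_scores, pooled_labels)
  ok <- !never_tested
  wil <- suppressWarnings(
    wilcox.test(avg[ok & pos], avg[ok & !pos], alternative = "two.sided"))
  pooled <- tibble(auroc = pooled_auc$auroc, ci_low = pooled_auc$ci_low,
                   ci_high = pooled_auc$ci_high,
                   wilcoxon_p = wil$p.value,
                   n_pooled = length(pooled_scores))

  structure(list(probabilities = probabilities, pooled = pooled,
                 pooled_scores = pooled_scores,
                 pooled_labels = pooled_labels,
                 pooled_sample = pooled_sample,
                 coefficients = coefs, splits = splits,
                 n_repeats = n_repeats, train_frac = train_frac,
                 seed = seed, lambda = lambda),
            class = "bfsig_classifier_eval")
}

#' @export
print.bfsig_classifier_eval <- function(x, ...) {
  cat(sprintf(
    "<bfsig_classifier_eval> %d repeats, pooled AUROC %.3f (95%% CI %.3f-%.3f)\n",
    x$n_repeats, x$pooled$auroc, x$pooled$ci_low, x$pooled$ci_high))
  invisible(x)
}

#' @rdname repeated_split_evaluate
#' @param x A `bfsig_classifier_eval`.
#' @param ... Unused.
#' @method tidy bfsig_classifier_eval
#' @export
tidy.bfsig_classifier_eval <- function(x, ...) x$probabilities

#' @rdname repeated_split_evaluate
#' @method glance bfsig_classifier_eval
#' @export
glance.bfsig_classifier_eval <- function(x, ...) x$pooled

#' Compare two classifier evaluations with DeLong's test
#'
#' Aligns the two evaluations' pooled predictions on identical
#' (repeat, test sample) pairs — they must have been run with the same seed
#' and splits — and applies [delong_test()].
#'
#' @param eval_A,eval_B Two `bfsig_classifier_eval` objects sharing splits.
#' @return The [delong_test()] tibble.
#' @export
compare_classifiers <- function(eval_A, eval_B) {
  if (!identical(eval_A$splits, eval_B$splits)) {
    abort("evaluations must share identical splits (same seed and repeats)")
  }
  delong_test(eval_A$pooled_scores, eval_B$pooled_scores,
              eval_A$pooled_labels)
}

#' Comparator feature matrices from raw expression
#'
#' Baseline features the signature classifier is compared against: the raw
#' expression of the three (BCL2, MCL1, BFL1) or five (plus BCLXL, BCLW)
#' anti-apoptotic genes, or the top-N differential genes ranked by absolute
#' group-mean difference on the (log-scale) matrix.
#'
#' @param expr Expression matrix (genes x samples).
#' @param labels Binary response per sample (needed for `topN_deg`).
#' @param mode `"anchors3"`, `"anchors5"` or `"topN_deg"`.
#' @param N Number of genes for `topN_deg`.
#' @param anchors The five anchor gene ids, in order.
#' @return Sample x feature matrix.
#' @export
build_comparator_features <- function(expr, labels = NULL,
                                      mode = c("anchors3", "anchors5",
                                               "topN_deg"),
                                      N = 10, anchors = BFSIG_ANCHORS) {
  mode <- match.arg(mode)
  expr <- as.matrix(expr)
  if (mode %in% c("anchors3", "anchors5")) {
    want <- if (mode == "anchors3") anchors[1:3] else anchors[1:5]
    missing <- setdiff(want, rownames(expr))
    if (length(missing) > 0) {
      abort(sprintf("anchor feature(s) absent from the matrix: %s",
                    paste(missing, collapse = ", ")))
    }
    return(t(expr[want, , drop = FALSE]))
  }
  if (is.null(labels)) abort("topN_deg needs labels")
  pos <- as_binary_labels(labels)
  if (sum(pos) == 0 || sum(!pos) == 0) abort("both classes must be present")
  diffs <- abs(rowMeans(expr[, pos, drop = FALSE]) -
                 rowMeans(expr[, !pos, drop = FALSE]))
  if (N > nrow(expr)) {
    warn(sprintf("N = %d exceeds the gene count %d; using all genes",
                 N, nrow(expr)))
    N <- nrow(expr)
  }
  top <- names(sort(diffs, decreasing = TRUE))[seq_len(N)]
  t(expr[top, , drop = FALSE])
}

#' Normalized root-mean-square error
#'
#' `RMSE(predicted, observed)` divided by the range (default) or mean of the
#' observed values; the small-cohort regression performance measure.
#'
#' @param observed Observed response values.
#' @param predicted Predictions of the same length.
#' @param normalizer `"range"` (default) or `"mean"`.
#' @return Non-negative scalar.
#' @examples
#' nrmse(c(0, 1, 2), c(1, 1, 1))  # sqrt(2/3) / 2 = 0.408
#' @export
nrmse <- function(observed, predicted, normalizer = c("range", "mean")) {
  normalizer <- match.arg(normalizer)
  stopifnot(length(observed) == length(predicted))
  denom <- switch(normalizer, range = diff(range(observed)),
                  mean = mean(observed))
  if (denom == 0) abort("response normalizer is zero; NRMSE undefined")
  sqrt(mean((predicted - observed)^2)) / denom
}

#' Leave-one-out linear regression with range-normalized RMSE
#'
#' The small-cohort continuous-response evaluation: an ordinary least-squares
#' model is fitted leaving each sample out in turn and predicting its drug
#' AUC; performance is `NRMSE = RMSE / range(observed)` (set
#' `normalizer = "mean"` to divide by the observed mean instead).
#'
#' @param features Sample x feature matrix.
#' @param response Continuous response (e.g. dose-response AUC), length
#'   `nrow(features)`.
#' @param normalizer `"range"` (default) or `"mean"`.
#' @return A `bfsig_loocv`: `predictions` tibble, `nrmse`, `rmse`.
#' @export
loocv_nrmse <- function(features, response, normalizer = c("range", "mean")) {
  normalizer <- match.arg(normalizer)
  X <- as.matrix(features)
  n <- nrow(X)
  if (length(response) != n) abort("response length must match feature rows")
  if (n < ncol(X) + 2) abort("need n >= p + 2 samples for LOOCV regression")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- stats::lsfit(X[-i, , drop = FALSE], response[-i])
    preds[i] <- sum(c(1, X[i, ]) * fit$coefficients)
  }
  rmse <- sqrt(mean((preds - response)^2))
  structure(list(predictions = tibble(
    sample_id = rownames(X) %||% paste0("s", seq_len(n)),
    observed = response, predicted = preds),
    rmse = rmse, nrmse = nrmse(response, preds, normalizer),
    normalizer = normalizer),
    class = "bfsig_loocv")
}

#' @export
print.bfsig_loocv <- function(x, ...) {
  cat(sprintf("<bfsig_loocv> n = %d, NRMSE = %.4f (%s-normalized)\n",
              nrow(x$predictions), x$nrmse, x$normalizer))
  invisible(x)
}

#' @rdname loocv_nrmse
#' @param x A `bfsig_loocv`.
#' @param ... Unused.
#' @method tidy bfsig_loocv
#' @export
tidy.bfsig_loocv <- function(x, ...) x$predictions

#' @rdname loocv_nrmse
#' @method glance bfsig_loocv
#' @export
glance.bfsig_loocv <- function(x, ...) {
  tibble(n = nrow(x$predictions), rmse = x$rmse, nrmse = x$nrmse)
}
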