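test_that("auroc equals the Mann-Whitney pair probability", {
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.3), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(c(0.9, 0.35, 0.4, 0.3), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  expect_equal(auroc(c(0.5, 0.5), c(TRUE, FALSE)), 0.5)  # tie convention
  expect_error(auroc(c(1, 2), c(TRUE, TRUE)), "both classes")

  # oracle equivalence: brute-force pair enumeration, with ties
  set.seed(99)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    pos <- scores[labels]; neg <- scores[!labels]
    brute <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(auroc(scores, labels), brute, tolerance = 1e-12)
  }
})

test_that("DeLong test matches pROC and is symmetric", {
  set.seed(1)
  n <- 40; lab <- rep(c(TRUE, FALSE), each = 20)
  sA <- rnorm(n) + lab * 1.2
  sB <- rnorm(n) + lab * 0.5
  mine <- delong_test(sA, sB, lab)
  ref <- pROC::roc.test(pROC::roc(lab, sA, quiet = TRUE),
                        pROC::roc(lab, sB, quiet = TRUE), method = "delong")
  expect_equal(mine$z, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)

  swapped <- delong_test(sB, sA, lab)
  expect_equal(swapped$z, -mine$z)
  expect_equal(swapped$p_value, mine$p_value)

  # identical models: z = 0, p = 1 by convention
  same <- delong_test(sA, sA, lab)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  ci <- auroc_ci(sA, lab)
  ref_ci <- pROC::ci.auc(pROC::roc(lab, sA, quiet = TRUE), method = "delong")
  expect_equal(c(ci$ci_low, ci$ci_high), c(ref_ci[1], ref_ci[3]),
               tolerance = 1e-9)
})

test_that("DeLong variance matches Hanley-McNeil on bi-exponential scores", {
  set.seed(1)
  s0 <- rexp(60, 1); s1 <- rexp(60, 1 / 3)
  sc <- c(s1, s0); lb <- rep(c(TRUE, FALSE), each = 60)
  A <- auroc(sc, lb)
  pxxy <- A / (2 - A); pxyy <- 2 * A^2 / (1 + A)
  v_hm <- (A * (1 - A) + 59 * (pxxy - A^2) + 59 * (pxyy - A^2)) / 3600
  v_dl <- auroc_ci(sc, lb)$var
  expect_lt(abs(v_dl / v_hm - 1), 0.1)
})

test_that("repeated-split evaluation is reproducible and calibrated", {
  set.seed(7)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(paste0("s", 1:n), NULL))
  y <- X[, 1] > 0
  X[, 1] <- X[, 1] + ifelse(y, 1, -1)  # separable with a wide margin
  ev <- repeated_split_evaluate(X, y, seed = 5)
  expect_equal(ev$pooled$auroc, 1)

  ev2 <- repeated_split_evaluate(X, y, seed = 5)
  expect_identical(ev$pooled_scores, ev2$pooled_scores)
  expect_identical(ev$coefficients, ev2$coefficients)
  expect_identical(ev$splits, ev2$splits)

  # averaged probabilities only use test-set appearances
  expect_true(all(ev$probabilities$probability[
    ev$probabilities$n_test_appearances > 0] >= 0))
  expect_true(all(tidy(ev)$probability <= 1, na.rm = TRUE))
  expect_s3_class(glance(ev), "tbl_df")

  # permuted labels give near-null pooled AUROC
  aucs <- vapply(1:5, function(s) {
    yp <- sample(y)
    repeated_split_evaluate(X, yp, seed = s)$pooled$auroc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("fitted logistic coefficients recover the generating signs", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 300
    X <- matrix(rnorm(n * 3), n, 3)
    beta <- c(1.5, -1.5, 0.8)
    y <- rbinom(n, 1, plogis(X %*% beta)) == 1
    ev <- repeated_split_evaluate(X, y, seed = s)
    co <- colMeans(do.call(rbind, ev$coefficients))[-1]
    hits <- hits + all(sign(co) == sign(beta))
  }
  expect_gte(hits, 9)
})

test_that("comparator features follow the anchor and DEG contracts", {
  set.seed(3)
  g <- 20; n <- 30
  expr <- matrix(runif(g * n, 1, 10), g, n,
                 dimnames = list(c("BCL2", "MCL1", "BFL1", "BCLXL", "BCLW",
                                   paste0("g", 1:15)),
                                 paste0("s", 1:n)))
  f3 <- build_comparator_features(expr, mode = "anchors3")
  expect_equal(colnames(f3), c("BCL2", "MCL1", "BFL1"))
  f5 <- build_comparator_features(expr, mode = "anchors5")
  expect_equal(ncol(f5), 5)

  labels <- rep(c(TRUE, FALSE), each = 15)
  # a gene with identical group means never precedes one with signal
  expr["g1", ] <- 5
  expr["g2", labels] <- 9; expr["g2", !labels] <- 1
  top <- build_comparator_features(expr, labels, mode = "topN_deg", N = 19)
  expect_true("g2" %in% colnames(top))
  expect_false("g1" %in% colnames(top))  # the zero-difference gene drops out

  expect_warning(
    all_genes <- build_comparator_features(expr, labels, mode = "topN_deg",
                                           N = 100),
    "all genes")
  expect_equal(ncol(all_genes), g)

  expr2 <- expr[-1, ]
  expect_error(build_comparator_features(expr2, mode = "anchors3"),
               "BCL2")
})

test_that("LOOCV regression yields exact fits and normalized errors", {
  set.seed(11)
  X <- matrix(rnorm(40), 20, 2)
  y <- drop(2 + X %*% c(1, -0.5))
  ev <- loocv_nrmse(X, y)
  expect_lt(ev$nrmse, 1e-8)
  expect_equal(nrow(ev$predictions), 20)

  # the NRMSE formula itself: RMSE sqrt(2/3) over range 2
  expect_equal(nrmse(c(0, 1, 2), c(1, 1, 1)), sqrt(2 / 3) / 2,
               tolerance = 1e-9)
  expect_equal(round(nrmse(c(0, 1, 2), c(1, 1, 1)), 3), 0.408)

  # pure-noise features cannot beat the intercept-only LOOCV bound by much
  yn <- rnorm(20)
  Xn <- matrix(rnorm(40), 20, 2)
  ev_n <- loocv_nrmse(Xn, yn)
  loo_mean_preds <- vapply(1:20, function(i) mean(yn[-i]), numeric(1))
  bound <- nrmse(yn, loo_mean_preds)
  expect_gt(ev_n$nrmse, 0.5 * bound)

  expect_error(loocv_nrmse(X[1:3, ], y[1:3]), "p \\+ 2")
  expect_error(loocv_nrmse(X, rep(1, 20)), "normalizer")
})
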