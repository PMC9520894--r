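test_that("mean KL divergence evaluates the elementwise formula", {
  expect_equal(mean_kl_divergence(matrix(2), matrix(2)), 0)
  expect_equal(mean_kl_divergence(matrix(2), matrix(1)), 2 * log(2) - 1,
               tolerance = 1e-12)
  expect_equal(mean_kl_divergence(matrix(0), matrix(1)), 1)  # 0*log(0) = 0
  A <- matrix(c(2, 5), 1, 2)
  expect_equal(mean_kl_divergence(A, matrix(c(1, 5), 1, 2),
                                  mask = matrix(c(TRUE, FALSE), 1, 2)),
               2 * log(2) - 1, tolerance = 1e-12)
  expect_error(mean_kl_divergence(A, A, mask = matrix(FALSE, 1, 2)),
               "no observed")
})

test_that("rank-1 constant matrices are reconstructed exactly", {
  A <- matrix(5, 10, 8, dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  fit <- fit_masked_nmf(A, 1, seed = 1)
  expect_lt(max(abs(fit$W %*% fit$H - 5)), 1e-6)
})

test_that("noiseless low-rank products are recovered to mean KL < 1e-6", {
  fx <- make_rank_k(20, 15, 2, seed = 7)
  fit <- fit_masked_nmf(fx$A, 2, seed = 3)
  final <- fit$loss_trace[length(fit$loss_trace)]
  expect_lt(final, 1e-6)
  # loss trace non-increasing within relative slack
  d <- diff(fit$loss_trace)
  expect_true(all(d <= 1e-10 * pmax(head(fit$loss_trace, -1), 1e-12)))
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
})

test_that("masked fits ignore hidden entries yet reconstruct them", {
  fx <- make_rank_k(20, 15, 2, seed = 8)
  set.seed(9)
  mask <- matrix(runif(300) > 0.2, 20, 15)
  fit <- fit_masked_nmf(fx$A, 2, mask = mask, seed = 3)
  expect_lt(fit$loss_trace[length(fit$loss_trace)], 1e-6)
  expect_lt(max(abs((fit$W %*% fit$H - fx$A)[!mask])), 1e-3)
})

test_that("masked entries have zero influence on the fit", {
  fx <- make_rank_k(12, 10, 2, seed = 11)
  mask <- matrix(TRUE, 12, 10); mask[3, 4] <- FALSE
  f1 <- fit_masked_nmf(fx$A, 2, mask = mask, seed = 5, n_restarts = 1)
  A2 <- fx$A; A2[3, 4] <- 999
  f2 <- fit_masked_nmf(A2, 2, mask = mask, seed = 5, n_restarts = 1)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
})

test_that("factorization is scale-indeterminate and seeded-deterministic", {
  fx <- make_rank_k(10, 8, 2, seed = 2)
  f1 <- fit_masked_nmf(fx$A, 2, seed = 4)
  f2 <- fit_masked_nmf(fx$A, 2, seed = 4)
  expect_identical(f1$W, f2$W)
  D <- diag(c(2, 0.5))
  expect_equal((f1$W %*% D) %*% (solve(D) %*% f1$H), f1$W %*% f1$H,
               tolerance = 1e-12)
  expect_error(fit_masked_nmf(fx$A, 0), "rank")
  expect_error(fit_masked_nmf(fx$A, 99), "rank")
})

test_that("rank-1 completion recovers the proportional missing entry", {
  A <- matrix(c(1, 2, 2, NA), 2, 2, byrow = TRUE)
  out <- impute_missing_entries(A, 1, seed = 1)
  expect_equal(out[2, 2], 4, tolerance = 1e-3)
  expect_equal(out[1, ], A[1, ])  # observed untouched

  # no missing entries: identity
  B <- matrix(1:4, 2, 2)
  expect_identical(impute_missing_entries(B, 1), B)

  # fully missing row is undefined
  C <- matrix(c(1, 2, NA, NA), 2, 2, byrow = TRUE)
  expect_error(impute_missing_entries(C, 1), "fully missing")
})

test_that("imputed values track the generating factors on rank-3 data", {
  fx <- make_rank_k(50, 30, 3, seed = 13)
  A <- fx$A
  miss <- sample(30, 3)  # 10% of one row
  A[7, miss] <- NA
  out <- impute_missing_entries(A, 3, seed = 2)
  expect_gt(cor(out[7, miss], fx$A[7, miss]), 0.95)
})

test_that("projection onto a fixed basis recovers activities", {
  set.seed(21)
  W <- matrix(runif(30, 0.2, 1), 15, 2)
  H0 <- matrix(runif(16, 0.2, 1), 2, 8)
  A_new <- W %*% H0
  H <- project_onto_fixed_basis(A_new, W)
  expect_lt(max(abs(H - H0)), 1e-3)

  # all-zero input gives all-zero activities
  Z <- matrix(0, 15, 4)
  expect_true(all(project_onto_fixed_basis(Z, W) == 0))

  # unit basis: KL minimizer is the column mean
  ones <- matrix(1, 15, 1)
  Hm <- project_onto_fixed_basis(A_new, ones)
  expect_equal(drop(Hm), colMeans(A_new), tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(project_onto_fixed_basis(A_new[1:10, ], W), "incompatible|cover")
})

test_that("factorizations serialize to TSV plus JSON sidecar", {
  fx <- make_rank_k(6, 5, 2, seed = 3)
  fit <- fit_masked_nmf(fx$A, 2, seed = 1, n_restarts = 2)
  d <- tempfile()
  write_factorization(fit, d)
  expect_true(all(file.exists(file.path(d, c("W.tsv", "H.tsv", "fit.json")))))
  meta <- jsonlite::read_json(file.path(d, "fit.json"))
  expect_equal(meta$rank, 2)
  W_back <- load_expression_matrix(file.path(d, "W.tsv"))
  expect_equal(unname(W_back), unname(fit$W), tolerance = 1e-12)
})
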