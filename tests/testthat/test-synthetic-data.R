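test_that("the generator is seed-deterministic and respects its config", {
  s1 <- simulate_bfsig_dataset(n_samples = 40, n_signal = 6, n_noise = 6,
                               seed = 5)
  s2 <- simulate_bfsig_dataset(n_samples = 40, n_signal = 6, n_noise = 6,
                               seed = 5)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$truth$H_true, s2$truth$H_true)
  s3 <- simulate_bfsig_dataset(n_samples = 40, n_signal = 6, n_noise = 6,
                               seed = 6)
  expect_false(identical(s1$expression, s3$expression))

  expect_equal(dim(s1$expression), c(5 + 6 + 6, 40))
  expect_equal(as.vector(table(s1$truth$gene_roles)[c("anchor", "signal",
                                                      "noise")]),
               c(5, 6, 6))
  expect_true(all(s1$expression >= 0))
  expect_equal(unname(colSums(s1$truth$H_true)), rep(1, 40),
               tolerance = 1e-12)
  expect_error(simulate_bfsig_dataset(n_samples = 5, k = 3), "3k")
})

test_that("the noiseless limit is exactly the scaled factor product", {
  s <- simulate_bfsig_dataset(n_samples = 30, n_signal = 5, n_noise = 5,
                              noise_sd = 0, seed = 9)
  expect_equal(s$expression,
               10 * (s$truth$W_true %*% s$truth$H_true),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("anchor expression tracks its mapped latent factor", {
  s <- simulate_bfsig_dataset(seed = 3)
  cors <- vapply(names(s$truth$anchor_factor_map), function(a) {
    f <- s$truth$anchor_factor_map[[a]]
    cor(s$expression[a, ], s$truth$H_true[f, ])
  }, numeric(1))
  expect_true(all(cors > 0.8))
})

test_that("binary response respects the IC50 emission thresholds", {
  s <- simulate_bfsig_dataset(n_samples = 60, n_signal = 6, n_noise = 6,
                              seed = 4)
  r <- simulate_drug_response(s$truth, mode = "binary", seed = 4)
  rt <- binarize_response(r$response, "venetoclax")
  expect_true(all(rt$ic50_uM[rt$binary_class == "sensitive"] <= 1))
  expect_true(all(rt$ic50_uM[rt$binary_class == "resistant"] >= 10))
  expect_false(any(rt$binary_class == "excluded"))

  # patient repeats exist so deduplication is exercised
  expect_gt(sum(duplicated(rt$patient_id)), 0)
  expect_lt(nrow(suppressWarnings(deduplicate_by_latest_timepoint(rt))),
            nrow(rt) + 1)

  expect_error(simulate_drug_response(s$truth, beta = c(1, 2)), "length k")
})

test_that("a null response model yields balanced classes", {
  rates <- vapply(1:10, function(sd) {
    s <- simulate_bfsig_dataset(n_samples = 50, n_signal = 5, n_noise = 5,
                                seed = sd)
    r <- simulate_drug_response(s$truth, beta = c(0, 0, 0), seed = sd)
    mean(r$response$ic50_uM <= 1)
  }, numeric(1))
  # pooled over 500 Bernoulli(0.5) draws: 3 sigma ~ 0.067
  expect_lt(abs(mean(rates) - 0.5), 0.07)
})

test_that("a strong factor effect drives group-wise activity differences", {
  s <- simulate_bfsig_dataset(n_samples = 100, n_signal = 10, n_noise = 0,
                              seed = 8)
  r <- simulate_drug_response(s$truth, beta = c(6, -6, 0), seed = 8)
  sens <- r$response$ic50_uM <= 1
  h1 <- s$truth$H_true[1, ]
  expect_gt(mean(h1[sens]), mean(h1[!sens]))
})

test_that("continuous response is linear in the activities plus noise", {
  s <- simulate_bfsig_dataset(n_samples = 40, n_signal = 5, n_noise = 0,
                              seed = 2)
  r <- simulate_drug_response(s$truth, mode = "continuous",
                              beta = c(2, -1, 0), noise_sd = 0.01, seed = 2)
  pred <- r$beta0 + drop(crossprod(s$truth$H_true, r$beta))
  expect_gt(cor(r$response$auc, pred), 0.99)
})

test_that("batch shifts are recorded and confined to non-reference batches", {
  s <- simulate_bfsig_dataset(n_samples = 60, n_signal = 6, n_noise = 6,
                              n_batches = 2, seed = 12)
  expect_setequal(unique(s$truth$batch), c("b1", "b2"))
  s0 <- simulate_bfsig_dataset(n_samples = 60, n_signal = 6, n_noise = 6,
                               n_batches = 1, seed = 12)
  expect_true(all(s0$truth$batch == "b1"))
})
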