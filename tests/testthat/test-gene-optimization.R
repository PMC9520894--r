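test_that("anchor mask folds partition every anchor entry exactly once", {
  genes <- c(paste0("ANC", 1:5), paste0("G", 1:10))
  folds <- build_anchor_mask_folds(10, paste0("ANC", 1:5), genes,
                                   v_folds = 5, seed = 1)
  expect_length(folds, 5)
  hidden_counts <- Reduce(`+`, lapply(folds, function(m) !m))
  # every anchor x sample entry hidden exactly once, non-anchors never
  expect_true(all(hidden_counts[1:5, ] == 1))
  expect_true(all(hidden_counts[6:15, ] == 0))
  expect_equal(sum(!folds[[1]]), 5 * 2)

  # v = n edge: one sample per fold
  f2 <- build_anchor_mask_folds(2, "ANC1", c("ANC1", "G1"), v_folds = 2)
  expect_equal(sum(!f2[[1]]), 1)

  # determinism contract
  fa <- build_anchor_mask_folds(10, "ANC1", genes, seed = 3)
  fb <- build_anchor_mask_folds(10, "ANC1", genes, seed = 3)
  fc <- build_anchor_mask_folds(10, "ANC1", genes, seed = 4)
  expect_identical(fa, fb)
  expect_false(identical(fa, fc))

  expect_error(build_anchor_mask_folds(3, "ANC1", genes, v_folds = 5),
               "exceed")
})

test_that("imputation error separates informative from uninformative anchors", {
  # noiseless rank-k data where anchors are exact factor combinations
  fx <- make_rank_k(20, 40, 3, seed = 17)
  anchors <- paste0("g", 1:5)
  folds <- build_anchor_mask_folds(40, anchors, rownames(fx$A), seed = 1)
  err_clean <- imputation_error(fx$A, anchors, folds, k = 3, seed = 1)
  expect_lt(err_clean, 0.05)

  # anchors replaced by independent noise: no better than the mean baseline
  A_noise <- fx$A
  set.seed(31)
  A_noise[1:5, ] <- matrix(runif(200, 0.5, 4), 5, 40)
  err_noise <- imputation_error(A_noise, anchors, folds, k = 3, seed = 1)
  # oracle: range-normalized error of predicting each anchor by its mean
  baseline <- mean(vapply(anchors, function(a) {
    x <- A_noise[a, ]
    sqrt(mean((x - mean(x))^2)) / diff(range(x))
  }, numeric(1)))
  expect_gt(err_noise, 0.7 * baseline)
  expect_gt(err_noise, 3 * err_clean)
})

test_that("duplicating an anchor never materially increases the error", {
  fx <- make_rank_k(15, 30, 2, seed = 23)
  anchors <- paste0("g", 1:3)
  folds <- build_anchor_mask_folds(30, anchors, rownames(fx$A), seed = 2)
  base <- imputation_error(fx$A, anchors, folds, k = 2, seed = 5)
  A_dup <- rbind(fx$A, g1_copy = fx$A["g1", ])
  folds_dup <- lapply(folds, function(m) {
    m2 <- rbind(m, g1_copy = TRUE); m2
  })
  dup <- imputation_error(A_dup, anchors, folds_dup, k = 2, seed = 5)
  expect_lt(dup, base + 0.05)
})

test_that("optimization keeps anchors, is deterministic, and traces decrease", {
  sim <- simulate_bfsig_dataset(n_samples = 60, n_signal = 8, n_noise = 8,
                                seed = 41)
  opt <- optimize_gene_set(sim$expression, sim$gene_set, seed = 41)
  expect_true(all(sim$gene_set$anchors %in% opt$selected_genes))
  expect_true(all(diff(opt$error_trace) <= 1e-12))
  expect_setequal(union(opt$selected_genes, opt$removed_genes),
                  sim$gene_set$members)

  opt2 <- optimize_gene_set(sim$expression, sim$gene_set, seed = 41)
  expect_identical(opt$selected_genes, opt2$selected_genes)
  expect_identical(opt$error_trace, opt2$error_trace)
})

test_that("anchor-only pools are returned unchanged", {
  sim <- simulate_bfsig_dataset(n_samples = 30, n_signal = 4, n_noise = 0,
                                seed = 2)
  pool <- gene_set(sim$gene_set$anchors, anchors = sim$gene_set$anchors)
  opt <- optimize_gene_set(sim$expression, pool, seed = 1)
  expect_setequal(opt$selected_genes, pool$anchors)
  expect_length(opt$removed_genes, 0)
})

test_that("optimization results tidy into the removal history", {
  sim <- simulate_bfsig_dataset(n_samples = 40, n_signal = 5, n_noise = 5,
                                seed = 3)
  opt <- optimize_gene_set(sim$expression, sim$gene_set, seed = 3)
  td <- tidy(opt)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), length(opt$error_trace))
  expect_true(is.na(td$removed_gene[1]))
  gl <- glance(opt)
  expect_equal(gl$n_selected, length(opt$selected_genes))
})
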