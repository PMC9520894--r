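test_that("connectivity groups samples by dominant signature", {
  H <- matrix(c(.9, .1, .8, .2, .1, .9), 2, 3)
  C <- connectivity_matrix(H)
  expect_equal(unname(C), rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))

  # all samples dominated by signature 1
  H2 <- matrix(c(.9, .1, .7, .3), 2, 2)
  expect_true(all(connectivity_matrix(H2) == 1))

  # ties resolve to the lowest signature index
  H3 <- matrix(c(.5, .5, .9, .1), 2, 2)
  expect_equal(unname(connectivity_matrix(H3)), matrix(1, 2, 2))

  expect_error(connectivity_matrix(matrix(c(0, 0, 1, 2), 2, 2)),
               "all-zero")
})

test_that("consensus matrices are stochastic averages of connectivities", {
  fx <- make_rank_k(12, 10, 2, seed = 3)
  cc <- consensus_and_cophenetic(fx$A, 2, n_runs = 4, seed = 1)
  C <- cc$consensus
  expect_true(all(C >= 0 & C <= 1))
  expect_equal(unname(diag(C)), rep(1, 10))
  expect_equal(C, t(C))

  # duplicate runs (identical seeds) give a binary consensus
  c1 <- connectivity_matrix(fit_masked_nmf(fx$A, 2, seed = 9,
                                           n_restarts = 1,
                                           connectivity_stop = TRUE)$H)
  expect_true(all(c1 %in% c(0, 1)))
})

test_that("block-perfect consensus has cophenetic coefficient 1", {
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- 1; C[4:6, 4:6] <- 1
  expect_equal(cophenetic_coefficient(C), 1)
  expect_equal(cophenetic_coefficient(matrix(1, 4, 4)), 1)
})

test_that("rank selection applies the first-fall rule and its guards", {
  expect_error(select_rank(matrix(1, 4, 4), ranks = 3), "two ranks")
  expect_error(select_rank(matrix(1, 4, 4), ranks = c(2, 4, 6)),
               "contiguous")

  # data with no rank structure beyond noise: huge drop_tol forces the
  # no-fall branch -> max rank with warning
  fx <- make_rank_k(10, 12, 2, seed = 5)
  expect_warning(
    rr <- select_rank(fx$A, ranks = 2:3, n_runs = 3, seed = 1,
                      drop_tol = 0.9),
    "maximal rank")
  expect_equal(rr$chosen_rank, 3)
  expect_s3_class(tidy(rr), "tbl_df")
})

test_that("extracted signatures are sum-one normalized without changing the fit", {
  fx <- make_rank_k(15, 12, 3, seed = 6)
  sigs <- extract_signatures(fx$A, 3, seed = 2, n_restarts = 3)
  expect_equal(unname(colSums(sigs$W_norm)), rep(1, 3), tolerance = 1e-9)
  expect_equal(sigs$W_norm %*% sigs$H, sigs$fit$W %*% sigs$fit$H,
               tolerance = 1e-9)
})

test_that("signature weights recover generator loadings up to permutation", {
  sim <- simulate_bfsig_dataset(n_samples = 120, n_signal = 20, n_noise = 0,
                                seed = 8)
  sigs <- extract_signatures(sim$expression, 3, seed = 8)
  cors <- best_perm_cor(sigs$W_norm, sim$truth$W_true)
  expect_true(all(cors > 0.9))
})

test_that("anchor labeling is unique, permutation-invariant, and falls back", {
  W <- matrix(0.01, 8, 3,
              dimnames = list(c("BCL2", "MCL1", "BFL1", paste0("g", 1:5)),
                              NULL))
  W["BCL2", 1] <- 0.5; W["MCL1", 2] <- 0.5; W["BFL1", 3] <- 0.5
  W <- sweep(W, 2, colSums(W), `/`)
  H <- matrix(1, 3, 4)
  sigs <- structure(list(W_norm = W, H = H, labels = paste0("sig_", 1:3),
                         rank = 3, fit = NULL), class = "bfsig_signatures")
  lab <- label_signatures(sigs, anchors = c("BCL2", "MCL1", "BFL1"))
  expect_equal(lab$labels, c("BCL2", "MCL1", "BFL1"))

  # permuting signature columns permutes labels consistently
  p <- c(3, 1, 2)
  sigs_p <- sigs
  sigs_p$W_norm <- W[, p]
  sigs_p$H <- H[p, ]
  lab_p <- label_signatures(sigs_p, anchors = c("BCL2", "MCL1", "BFL1"))
  expect_equal(lab_p$labels, lab$labels[p])

  # two signatures competing for one anchor stay uniquely labeled
  W2 <- W
  W2["BCL2", ] <- c(0.5, 0.5, 0.01)
  sigs2 <- sigs; sigs2$W_norm <- sweep(W2, 2, colSums(W2), `/`)
  lab2 <- label_signatures(sigs2, anchors = c("BCL2", "MCL1", "BFL1"))
  expect_equal(anyDuplicated(lab2$labels), 0)

  # no anchors present: generic labels with warning
  sigs3 <- sigs
  rownames(sigs3$W_norm) <- paste0("x", 1:8)
  expect_warning(lab3 <- label_signatures(sigs3), "generic")
  expect_equal(lab3$labels, paste0("sig_", 1:3))
})

test_that("composite labels appear when a second anchor is near-dominant", {
  W <- matrix(0.01, 5, 2,
              dimnames = list(c("BCL2", "MCL1", "BFL1", "g1", "g2"), NULL))
  W["MCL1", 1] <- 0.5; W["BCL2", 1] <- 0.3   # secondary >= 0.5 * primary
  W["BFL1", 2] <- 0.5
  sigs <- structure(list(W_norm = sweep(W, 2, colSums(W), `/`),
                         H = matrix(1, 2, 3), labels = c("sig_1", "sig_2"),
                         rank = 2, fit = NULL), class = "bfsig_signatures")
  lab <- label_signatures(sigs, anchors = c("BCL2", "MCL1", "BFL1"))
  expect_equal(lab$labels[1], "MCL1/BCL2")
  expect_equal(lab$labels[2], "BFL1")
})

test_that("signature concordance is Spearman over shared genes", {
  set.seed(4)
  W1 <- matrix(runif(30), 10, 3,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  expect_equal(unname(diag(signature_concordance(W1, W1))), rep(1, 3))

  # the closed-form 3-gene example: ranks (1,2,3) vs (3,1,2) -> rho = -0.5
  W_a <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  W_b <- matrix(c(3, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(signature_concordance(W_a, W_b, min_overlap = 3)[1, 1], -0.5)

  # full reversal gives rho = -1
  W_c <- matrix(10:1, 10, 1, dimnames = list(paste0("g", 1:10), "s1"))
  W_d <- matrix(1:10, 10, 1, dimnames = list(paste0("g", 1:10), "s1"))
  expect_equal(signature_concordance(W_c, W_d)[1, 1], -1)

  expect_error(signature_concordance(W_a, W_b), "shared gene")
})
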