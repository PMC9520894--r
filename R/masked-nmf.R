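#' Mean Kullback-Leibler divergence over observed entries
#'
#' Elementwise generalized KL, `d(a, ahat) = a*log(a/ahat) - a + ahat` with
#' the convention `0*log(0) = 0`, averaged over entries where `mask` is TRUE.
#' This is the factorization loss throughout the package.
#'
#' @param A Non-negative data matrix.
#' @param Ahat Reconstruction; floored at 1e-12 inside logs/divisions.
#' @param mask Logical matrix, TRUE = observed. Default: all observed.
#' @return A non-negative scalar; 0 iff `A == Ahat` on observed entries.
#' @export
mean_kl_divergence <- function(A, Ahat, mask = NULL) {
  A <- as.matrix(A); Ahat <- as.matrix(Ahat)
  stopifnot(all(dim(A) == dim(Ahat)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(A), ncol(A))
  mask <- as.matrix(mask)
  stopifnot(all(dim(mask) == dim(A)))
  if (!any(mask)) abort("mask has no observed entries")
  Az <- A; Az[!mask] <- 0
  Ahz <- Ahat; Ahz[!mask] <- 1   # arbitrary positive filler, zero weight
  .cpp_mean_kl(Az, Ahz, mask * 1)
}

new_masked_nmf <- function(W, H, mask, loss_trace, seed, n_iter, gene_ids,
                           sample_ids) {
  rownames(W) <- gene_ids
  colnames(W) <- paste0("sig_", seq_len(ncol(W)))
  rownames(H) <- colnames(W)
  colnames(H) <- sample_ids
  structure(list(W = W, H = H, mask = mask, rank = ncol(W),
                 loss_trace = loss_trace, seed = seed, n_iter = n_iter),
            class = "bfsig_nmf")
}

#' @export
print.bfsig_nmf <- function(x, ...) {
  cat(sprintf(
    "<bfsig_nmf> rank %d, %d genes x %d samples, %d iterations, final mean KL %.3e\n",
    x$rank, nrow(x$W), ncol(x$H), x$n_iter,
    x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

# Single seeded run of the C++ updater. `A` must already be zeroed at masked
# entries. Initialization: uniform(0,1) entries scaled by sqrt(mean(A_obs)/k)
# in both factors, so the initial reconstruction matches the data scale.
run_nmf_once <- function(A, mask, k, seed, max_iter, tol, abs_tol = 1e-12,
                         window = 10, update_W = TRUE, W0 = NULL,
                         conn_every = 0, conn_stall = 4) {
  g <- nrow(A); n <- ncol(A)
  m_obs <- sum(A[mask]) / max(sum(mask), 1)
  s <- sqrt(max(m_obs, 1e-6) / k)
  with_seed(seed, {
    if (is.null(W0)) W0 <- matrix(runif(g * k), g, k) * s
    H0 <- matrix(runif(k * n), k, n) * s
    .cpp_nmf_kl(A, mask * 1, W0, H0, as.integer(max_iter), tol, abs_tol,
                as.integer(window), update_W, as.integer(conn_every),
                as.integer(conn_stall))
  })
}

#' Fit masked NMF with multiplicative mean-KL updates
#'
#' Factorizes a non-negative gene x sample matrix `A ~ W %*% H` at rank `k`,
#' minimizing the mean KL divergence over observed entries only: masked
#' entries contribute neither to the loss nor to the updates, which is what
#' makes the fit usable for imputation of deliberately hidden anchor-gene
#' profiles. Runs `n_restarts` seeded initializations and keeps the fit with
#' the lowest final observed-entry loss.
#'
#' @param A Non-negative matrix (genes x samples) with dimnames; `NA` entries
#'   are treated as masked.
#' @param k Rank, `1 <= k <= min(g, n)`.
#' @param mask Logical matrix, TRUE = observed; default marks `NA` entries of
#'   `A` as missing and everything else observed.
#' @param seed Integer seed; restart r uses `seed + r - 1`.
#' @param n_restarts Number of random restarts (default 5).
#' @param max_iter Maximum multiplicative updates (default 2000).
#' @param tol Relative mean-KL change over 10-iteration windows below which
#'   the fit stops (default 1e-6).
#' @param connectivity_stop If TRUE, additionally stop once the argmax
#'   sample assignment of `H` is unchanged for 40 consecutive iterations
#'   (the classical stopping rule for consensus runs, where the clustering
#'   pattern rather than the loss is the quantity of interest). Default
#'   FALSE.
#' @return A `bfsig_nmf` object: `W`, `H`, `mask`, `loss_trace`, `seed`,
#'   `n_iter`.
#' @export
fit_masked_nmf <- function(A, k, mask = NULL, seed = 1, n_restarts = 5,
                           max_iter = 2000, tol = 1e-6,
                           connectivity_stop = FALSE) {
  A <- as.matrix(A)
  g <- nrow(A); n <- ncol(A)
  if (is.null(rownames(A))) rownames(A) <- paste0("g", seq_len(g))
  if (is.null(colnames(A))) colnames(A) <- paste0("s", seq_len(n))
  if (!is_scalar_number(k) || k < 1 || k > min(g, n)) {
    abort(sprintf("rank k must lie in [1, %d]", min(g, n)))
  }
  if (is.null(mask)) mask <- !is.na(A)
  mask <- as.matrix(mask)
  stopifnot(all(dim(mask) == dim(A)))
  if (!any(mask)) abort("mask has no observed entries")
  Az <- A; Az[!mask] <- 0
  if (any(!is.finite(Az)) || any(Az < 0)) {
    abort("A must be finite and non-negative on observed entries")
  }
  if (any(rowSums(mask) < k) || any(colSums(mask) < k)) {
    warn("some rows/columns have fewer than k observed entries; fit may be underdetermined")
  }
  zero_rows <- rowSums(Az) == 0 & rowSums(mask) > 0
  best <- NULL
  conn_every <- if (connectivity_stop) 10 else 0
  for (r in seq_len(n_restarts)) {
    fit <- run_nmf_once(Az, mask, k, seed + r - 1, max_iter, tol,
                        conn_every = conn_every)
    final <- fit$loss_trace[length(fit$loss_trace)]
    if (is.null(best) || final < best$final) {
      best <- list(fit = fit, final = final, seed = seed + r - 1)
    }
  }
  if (any(zero_rows)) {
    warn(sprintf("%d gene(s) observed as all-zero; their W rows are zero",
                 sum(zero_rows)))
    best$fit$W[zero_rows, ] <- 0
  }
  new_masked_nmf(best$fit$W, best$fit$H, mask, best$fit$loss_trace,
                 best$seed, best$fit$n_iter, rownames(A), colnames(A))
}

#' Impute missing entries by low-rank reconstruction
#'
#' Entries marked `NA` are filled with the masked-NMF reconstruction
#' `(W %*% H)` at those positions, keeping the restart with the lowest final
#' observed-entry loss. This is the primitive behind anchor-profile
#' imputation in gene-set optimization.
#'
#' @param A Matrix with `NA` at missing positions.
#' @param k Rank used for completion.
#' @param n_restarts Random restarts (default 5).
#' @param seed Integer seed.
#' @param max_iter,tol Passed to [fit_masked_nmf()].
#' @return `A` with missing entries replaced; observed entries untouched.
#' @export
impute_missing_entries <- function(A, k, n_restarts = 5, seed = 1,
                                   max_iter = 2000, tol = 1e-6) {
  A <- as.matrix(A)
  miss <- is.na(A)
  if (!any(miss)) return(A)
  full_rows <- rowSums(!miss) == 0
  if (any(full_rows)) {
    abort(sprintf("imputation undefined for fully missing row(s): %s",
                  paste(which(full_rows), collapse = ", ")))
  }
  fit <- fit_masked_nmf(A, k, mask = !miss, seed = seed,
                        n_restarts = n_restarts, max_iter = max_iter,
                        tol = tol)
  out <- A
  rec <- fit$W %*% fit$H
  out[miss] <- rec[miss]
  out
}

#' Project new samples onto a fixed gene-weight basis
#'
#' Runs H-only multiplicative KL updates with `W` frozen, yielding signature
#' activities for new samples without re-extracting signatures. Deterministic:
#' H is initialized at a constant matching the data scale.
#'
#' @param A_new Non-negative matrix whose rownames align with `W_fixed`.
#' @param W_fixed Gene x signature weight matrix.
#' @param max_iter,tol Convergence controls as in [fit_masked_nmf()].
#' @return Activity matrix `H_new` (signatures x samples).
#' @export
project_onto_fixed_basis <- function(A_new, W_fixed, max_iter = 2000,
                                     tol = 1e-8) {
  A_new <- as.matrix(A_new); W_fixed <- as.matrix(W_fixed)
  if (!is.null(rownames(A_new)) && !is.null(rownames(W_fixed))) {
    if (!identical(rownames(A_new), rownames(W_fixed))) {
      if (!all(rownames(W_fixed) %in% rownames(A_new))) {
        abort("genes of `A_new` do not cover the rows of `W_fixed`")
      }
      A_new <- A_new[rownames(W_fixed), , drop = FALSE]
    }
  } else if (nrow(A_new) != nrow(W_fixed)) {
    abort("`A_new` and `W_fixed` have incompatible gene dimensions")
  }
  k <- ncol(W_fixed); n <- ncol(A_new)
  if (all(A_new == 0)) {
    H <- matrix(0, k, n, dimnames = list(colnames(W_fixed), colnames(A_new)))
    return(H)
  }
  mask <- matrix(1, nrow(A_new), n)
  h0 <- mean(A_new) / max(mean(W_fixed) * k, 1e-12)
  H0 <- matrix(h0, k, n)
  fit <- .cpp_nmf_kl(A_new, mask, W_fixed, H0, as.integer(max_iter), tol,
                     1e-14, 10L, FALSE, 0L, 4L)
  H <- fit$H
  dimnames(H) <- list(colnames(W_fixed), colnames(A_new))
  H
}

#' Serialize a factorization to TSV + JSON sidecar
#'
#' Writes `W.tsv` (genes x signatures), `H.tsv` (signatures x samples) and
#' `fit.json` (rank, seed, iterations, final loss) under `dir`.
#'
#' @param fit A `bfsig_nmf`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_factorization <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(fit$W, file.path(dir, "W.tsv"))
  Ht <- fit$H
  write.table(data.frame(signature = rownames(Ht), Ht, check.names = FALSE),
              file.path(dir, "H.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(rank = fit$rank, seed = fit$seed, n_iter = fit$n_iter,
         final_loss = fit$loss_trace[length(fit$loss_trace)]),
    file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
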