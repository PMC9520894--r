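#' Build v-fold anchor masks
#'
#' Partitions samples into `v_folds` groups and, for each fold, marks every
#' anchor-gene entry of that fold's samples as missing. Across folds each
#' anchor x sample entry is hidden exactly once; non-anchor entries are never
#' hidden. Full-row masking would make anchor profiles non-imputable, so this
#' fold-wise scheme is the minimal way to hold out every anchor value while
#' leaving it learnable from the remaining samples.
#'
#' @param n_samples Number of samples (columns).
#' @param anchors Character vector of anchor gene ids.
#' @param gene_ids Gene ids (rownames of the matrix the masks apply to).
#' @param v_folds Number of folds, >= 2 (default 5).
#' @param seed Integer seed for the sample partition.
#' @return List of `v_folds` logical matrices (TRUE = observed).
#' @export
build_anchor_mask_folds <- function(n_samples, anchors, gene_ids,
                                    v_folds = 5, seed = 1) {
  if (v_folds < 2) abort("v_folds must be >= 2")
  if (v_folds > n_samples) abort("v_folds cannot exceed n_samples")
  if (!all(anchors %in% gene_ids)) {
    abort(sprintf("anchors absent from gene_ids: %s",
                  paste(setdiff(anchors, gene_ids), collapse = ", ")))
  }
  g <- length(gene_ids)
  anchor_rows <- match(anchors, gene_ids)
  fold_of <- with_seed(seed, sample(rep(seq_len(v_folds),
                                        length.out = n_samples)))
  lapply(seq_len(v_folds), function(v) {
    m <- matrix(TRUE, g, n_samples)
    m[anchor_rows, fold_of == v] <- FALSE
    rownames(m) <- gene_ids
    m
  })
}

# per-anchor RMSE normalized by that anchor's observed range, averaged over
# anchors; the uninformative-imputation baseline of this metric is ~1 when
# predictions are no better than scattering across the range.
anchor_nrmse <- function(observed, imputed, anchors) {
  errs <- vapply(anchors, function(a) {
    obs <- observed[a, ]
    imp <- imputed[a, ]
    rng <- diff(range(obs))
    if (rng == 0) return(NA_real_)
    sqrt(mean((imp - obs)^2)) / rng
  }, numeric(1))
  if (all(is.na(errs))) abort("all anchors have zero variance; error undefined")
  if (any(is.na(errs))) {
    warn(sprintf("anchor(s) with zero variance excluded from the error: %s",
                 paste(anchors[is.na(errs)], collapse = ", ")))
  }
  mean(errs, na.rm = TRUE)
}

anchor_one_minus_pearson <- function(observed, imputed, anchors) {
  errs <- vapply(anchors, function(a) {
    obs <- observed[a, ]; imp <- imputed[a, ]
    if (sd(obs) == 0 || sd(imp) == 0) return(NA_real_)
    1 - cor(obs, imp)
  }, numeric(1))
  if (all(is.na(errs))) abort("all anchors have zero variance; error undefined")
  mean(errs, na.rm = TRUE)
}

#' Cross-validated anchor-imputation error of a candidate gene set
#'
#' For each fold mask, hides the anchor entries, completes them with
#' [impute_missing_entries()] on the candidate-gene submatrix, and scores the
#' imputed against the observed anchor values. The default metric is
#' per-anchor RMSE normalized by the anchor's observed range, averaged over
#' anchors (`metric = "nrmse"`); `"one_minus_pearson"` is available as an
#' alternative.
#'
#' @param A Expression matrix restricted to the candidate gene set
#'   (must contain all anchors).
#' @param anchors Anchor gene ids.
#' @param folds Masks from [build_anchor_mask_folds()].
#' @param k NMF rank used for completion (default 5).
#' @param n_restarts Restarts per completion (default 1; candidate ranking
#'   needs relative, not absolute, precision).
#' @param seed Integer seed.
#' @param max_iter,tol Inner NMF controls; defaults are coarser than the
#'   extraction defaults because only the error ordering matters here.
#' @param metric `"nrmse"` or `"one_minus_pearson"`.
#' @return Scalar imputation error (lower is better).
#' @export
imputation_error <- function(A, anchors, folds, k = 3, n_restarts = 1,
                             seed = 1, max_iter = 300, tol = 1e-4,
                             metric = c("nrmse", "one_minus_pearson"),
                             per_fold = FALSE) {
  metric <- match.arg(metric)
  A <- as.matrix(A)
  if (!all(anchors %in% rownames(A))) {
    abort("candidate matrix must contain every anchor gene")
  }
  if (nrow(A) <= k) abort("candidate set must exceed the NMF rank")
  imputed <- A
  fold_masks <- vector("list", length(folds))
  for (v in seq_along(folds)) {
    mask <- folds[[v]][rownames(A), , drop = FALSE]
    fold_masks[[v]] <- mask
    Amiss <- A
    Amiss[!mask] <- NA
    comp <- impute_missing_entries(Amiss, k = k, n_restarts = n_restarts,
                                   seed = seed + 1000L * v,
                                   max_iter = max_iter, tol = tol)
    imputed[!mask] <- comp[!mask]
  }
  score_fun <- switch(metric, nrmse = anchor_nrmse,
                      one_minus_pearson = anchor_one_minus_pearson)
  if (!per_fold) return(score_fun(A, imputed, anchors))
  vapply(seq_along(folds), function(v) {
    miss <- !fold_masks[[v]]
    Av <- A
    # score only this fold's held-out entries: copy imputations there and
    # restrict the per-anchor error to those columns
    cols <- which(colSums(miss) > 0)
    per_anchor <- vapply(anchors, function(a) {
      obs <- A[a, cols]; imp <- imputed[a, cols]
      rng <- diff(range(A[a, ]))
      if (rng == 0) return(NA_real_)
      if (metric == "nrmse") sqrt(mean((imp - obs)^2)) / rng
      else if (sd(obs) == 0 || sd(imp) == 0) NA_real_ else 1 - cor(obs, imp)
    }, numeric(1))
    mean(per_anchor, na.rm = TRUE)
  }, numeric(1))
}

#' Backward-select the gene set that best imputes the anchor profiles
#'
#' Greedy steepest-descent backward selection over the pre-collected pool:
#' at each step every removable (non-anchor) gene is left out in turn, the
#' candidate whose removal most decreases the cross-validated anchor
#' imputation error is dropped, and the loop stops when no removal improves
#' the error by more than `patience` or when `min_genes` genes remain.
#' Anchors are never removable, so they survive every run.
#'
#' @param A Expression matrix (genes x samples).
#' @param pool A `bfsig_geneset`; members absent from `A` are dropped with a
#'   warning.
#' @param k NMF rank inside the error evaluation (default 5).
#' @param v_folds Fold count for anchor masking (default 5).
#' @param n_restarts Restarts per completion (default 2; best of two
#'   initializations stabilizes the candidate error estimates).
#' @param seed Integer seed (folds and all inner fits derive from it).
#' @param min_genes Lower bound on the selected-set size (default
#'   `length(anchors) + k`).
#' @param patience Minimum relative error decrease (fraction of the current
#'   error) a removal must achieve on the pooled confirmation evaluation to
#'   be accepted (default 0.003). Genuine removals improve the error by a
#'   few percent; the minimum over many null candidates drifts below zero by
#'   a few tenths of a percent once the confirmation mean is pooled over two
#'   partitions, so 0.3 percent separates the regimes.
#' @param metric Error metric, see [imputation_error()].
#' @param max_iter,tol Inner NMF controls of the screening evaluations.
#' @param confirm Greedy backward selection over noisy cross-validated
#'   errors suffers a winner's-curse tail: the minimum over many near-null
#'   candidate estimates drifts slightly below the current error even when
#'   no removal truly helps. With `confirm = TRUE` (default) each proposed
#'   removal is therefore re-scored with a deeper paired evaluation on an
#'   independent fold partition (double cross-validation, with
#'   `confirm_restarts` restarts and tighter convergence) and accepted only
#'   if the improvement holds in the mean (and, when `min_fold_wins > 0`,
#'   in at least that many confirmation folds); a rejected gene is banned
#'   from later proposals and the loop continues with the remaining
#'   candidates until `reject_budget` rejections have accumulated.
#' @param confirm_restarts,confirm_max_iter,confirm_tol Controls of the
#'   confirmation evaluation (defaults 2, 1000, 1e-5).
#' @param min_fold_wins Confirmation folds (out of `v_folds`) in which a
#'   removal must additionally improve the error to be accepted (default 0:
#'   mean test only; per-fold errors are noisy enough that fold-wise
#'   majorities reject too many genuine removals).
#' @param reject_budget Consecutive rejected proposals (the counter resets
#'   on every accepted removal; bans persist) after which single-gene
#'   proposals stop (default 5). With a roughly fifty-fifty chance that a
#'   null removal passes the mean confirmation, accumulated bans plus the
#'   consecutive budget bound the winner's-curse tail, while scattered
#'   false rejections do not end the run early.
#' @param batch_rescue_size When single-gene proposals are exhausted, the
#'   joint removal of the top-screened candidates is tried as a group
#'   (starting at this size, default 5, doubling while rejected), subject to
#'   the same confirmation; this handles correlated noise genes whose harm
#'   is shared - removing one member changes little, removing the group
#'   helps clearly. Candidates are ranked by how poorly the current
#'   factorization explains them (per-gene R2), restricted to clearly
#'   under-explained genes; previously banned genes stay banned for
#'   single-gene steps. The loop stops when every group size is rejected.
#'   0 disables.
#' @param batch If TRUE, all candidates whose single-removal screening error
#'   beats the current error are dropped together each step without
#'   confirmation (faster, coarser); default FALSE (confirmed single-gene
#'   steps).
#' @return A `bfsig_optimization`: `selected_genes`, `removed_genes`,
#'   `error_trace`, `config`.
#' @export
optimize_gene_set <- function(A, pool, k = 3, v_folds = 5, n_restarts = 2,
                              seed = 1, min_genes = NULL, patience = 0.003,
                              metric = "nrmse", max_iter = 300, tol = 1e-4,
                              confirm = TRUE, confirm_restarts = 2,
                              confirm_max_iter = 1000, confirm_tol = 1e-5,
                              min_fold_wins = 0, reject_budget = 5,
                              batch_rescue_size = 5, batch = FALSE) {
  A <- as.matrix(A)
  validate_expression_matrix(A, "A")
  anchors <- pool$anchors
  members <- pool$members
  absent <- setdiff(members, rownames(A))
  if (length(absent) > 0) {
    warn(sprintf("%d pool gene(s) absent from the matrix dropped: %s",
                 length(absent), paste(head(absent, 10), collapse = ", ")))
    members <- setdiff(members, absent)
  }
  if (!all(anchors %in% rownames(A))) {
    abort(sprintf("anchor(s) absent from the matrix: %s",
                  paste(setdiff(anchors, rownames(A)), collapse = ", ")))
  }
  if (is.null(min_genes)) min_genes <- length(anchors) + k
  config <- list(k = k, v_folds = v_folds, n_restarts = n_restarts,
                 seed = seed, min_genes = min_genes, patience = patience,
                 metric = metric, max_iter = max_iter, tol = tol,
                 confirm = confirm, confirm_restarts = confirm_restarts,
                 confirm_max_iter = confirm_max_iter,
                 confirm_tol = confirm_tol, min_fold_wins = min_fold_wins,
                 reject_budget = reject_budget,
                 batch_rescue_size = batch_rescue_size, batch = batch)

  folds <- build_anchor_mask_folds(ncol(A), anchors, rownames(A),
                                   v_folds = v_folds, seed = seed)
  err_of <- function(genes) {
    imputation_error(A[genes, , drop = FALSE], anchors, folds, k = k,
                     n_restarts = n_restarts, seed = seed,
                     max_iter = max_iter, tol = tol, metric = metric)
  }
  # confirmation runs on two independent fold partitions (double
  # cross-validation): a removal that only exploits the screening folds'
  # particular sample split does not replicate here, and pooling two
  # partitions halves the variance of the confirmation mean
  folds_confirm <- c(
    build_anchor_mask_folds(ncol(A), anchors, rownames(A),
                            v_folds = v_folds, seed = seed + 7L),
    build_anchor_mask_folds(ncol(A), anchors, rownames(A),
                            v_folds = v_folds, seed = seed + 13L))
  deep_err_of <- function(genes) {
    imputation_error(A[genes, , drop = FALSE], anchors, folds_confirm, k = k,
                     n_restarts = confirm_restarts, seed = seed + 7L,
                     max_iter = confirm_max_iter, tol = confirm_tol,
                     metric = metric, per_fold = TRUE)
  }

  selected <- members
  removable <- sort(setdiff(selected, anchors))
  if (length(removable) == 0) {
    return(structure(list(selected_genes = selected,
                          removed_genes = character(0),
                          error_trace = numeric(0), config = config),
                     class = "bfsig_optimization"))
  }
  current_err <- err_of(selected)
  deep_current <- if (confirm && !batch) deep_err_of(selected) else NA_real_
  removed <- character(0)
  banned <- character(0)
  n_rejected <- 0
  trace <- if (confirm && !batch) mean(deep_current) else current_err

  stalled <- FALSE
  repeat {
    removable <- sort(setdiff(selected, c(anchors, banned)))
    if (length(selected) <= min_genes) break
    if (length(removable) == 0) stalled <- TRUE
    cand_err <- if (stalled) numeric(0) else
      vapply(removable, function(gene) err_of(setdiff(selected, gene)),
             numeric(1))
    if (!stalled && max(current_err - cand_err) <= 0) stalled <- TRUE
    if (stalled) {
      # batch rescue: correlated noise genes can be individually
      # irremovable but jointly harmful; try the top-screened group once
      if (!confirm || batch || batch_rescue_size < 1) break
      pool_left <- sort(setdiff(selected, anchors))
      if (length(pool_left) == 0) break
      m_cap <- min(length(pool_left), length(selected) - min_genes)
      if (m_cap < 1) break
      # rank rescue candidates by how poorly the current factorization
      # explains them: genes with low per-gene R2 are the high-noise ones
      gfit <- fit_masked_nmf(A[selected, , drop = FALSE], k,
                             seed = seed + 31L,
                             n_restarts = confirm_restarts,
                             max_iter = confirm_max_iter, tol = confirm_tol)
      rec <- gfit$W %*% gfit$H
      gene_r2 <- function(gene) {
        obs <- A[gene, ]
        tot <- sum((obs - mean(obs))^2)
        if (tot == 0) return(1)
        1 - sum((obs - rec[gene, ])^2) / tot
      }
      r2 <- vapply(pool_left, gene_r2, numeric(1))
      r2_all <- vapply(selected, gene_r2, numeric(1))
      # only clearly under-explained genes are rescue candidates; the R2
      # distribution is bimodal (structured vs noise), so half the median
      # sits in the gap
      low <- r2 < 0.5 * stats::median(r2_all)
      if (!any(low)) break
      pool_left <- pool_left[low]
      r2 <- r2[low]
      m_cap <- min(length(pool_left), length(selected) - min_genes)
      ranked <- pool_left[order(r2, pool_left)]
      rescued <- FALSE
      m_try <- min(batch_rescue_size, m_cap)
      repeat {
        grp <- ranked[seq_len(m_try)]
        deep_grp <- deep_err_of(setdiff(selected, grp))
        if (mean(deep_current) - mean(deep_grp) >
              patience * mean(deep_current) &&
            sum(deep_current - deep_grp > 0) >= min_fold_wins) {
          selected <- setdiff(selected, grp)
          current_err <- err_of(selected)
          deep_current <- deep_grp
          removed <- c(removed, grp)
          trace <- c(trace, rep(mean(deep_grp), length(grp)))
          # bans persist: the rescue addresses grouped noise, it does not
          # re-open the single-gene tail
          n_rejected <- 0
          stalled <- FALSE
          rescued <- TRUE
          break
        }
        if (m_try >= m_cap) break
        m_try <- min(2 * m_try, m_cap)   # escalate the group size
      }
      if (rescued) next
      break
    }
    improvement <- current_err - cand_err
    if (batch) {
      if (max(improvement) <= 0) break
      drop_genes <- removable[improvement > 0]
      # keep at least min_genes; drop best-improving first (ties: gene id)
      ord <- order(-improvement[removable %in% drop_genes], drop_genes)
      n_droppable <- length(selected) - min_genes
      drop_genes <- drop_genes[ord][seq_len(min(length(drop_genes),
                                                n_droppable))]
      selected <- setdiff(selected, drop_genes)
      current_err <- err_of(selected)
      removed <- c(removed, drop_genes)
      trace <- c(trace, rep(current_err, length(drop_genes)))
      next
    }
    if (!confirm) {
      # steepest descent on the screening error alone; ties break
      # lexicographically by gene id for determinism
      if (max(improvement) <= 0) break
      best <- removable[which(cand_err == min(cand_err))][1]
      if (current_err - cand_err[[best]] <= patience * current_err) break
      selected <- setdiff(selected, best)
      current_err <- cand_err[[best]]
      removed <- c(removed, best)
      trace <- c(trace, current_err)
      next
    }
    # confirmed steepest descent: propose the screening-best candidate and
    # accept only if the paired per-fold confirmation agrees; otherwise ban
    # the gene from later proposals and keep going
    gene <- removable[order(cand_err, removable)][1]
    deep_cand <- deep_err_of(setdiff(selected, gene))
    d <- deep_current - deep_cand
    if (mean(d) > patience * mean(deep_current) &&
        sum(d > 0) >= min_fold_wins) {
      selected <- setdiff(selected, gene)
      current_err <- cand_err[[gene]]
      deep_current <- deep_cand
      removed <- c(removed, gene)
      trace <- c(trace, mean(deep_cand))
      n_rejected <- 0
    } else {
      banned <- c(banned, gene)
      n_rejected <- n_rejected + 1
      if (n_rejected >= reject_budget) stalled <- TRUE
    }
  }

  structure(list(selected_genes = selected, removed_genes = removed,
                 error_trace = trace, config = config),
            class = "bfsig_optimization")
}

#' @export
print.bfsig_optimization <- function(x, ...) {
  cat(sprintf(
    "<bfsig_optimization> %d genes selected, %d removed; error %.4f -> %.4f\n",
    length(x$selected_genes), length(x$removed_genes),
    if (length(x$error_trace)) x$error_trace[1] else NA_real_,
    if (length(x$error_trace)) x$error_trace[length(x$error_trace)] else NA_real_))
  invisible(x)
}

#' @rdname optimize_gene_set
#' @param x A `bfsig_optimization`.
#' @param ... Unused.
#' @method tidy bfsig_optimization
#' @export
tidy.bfsig_optimization <- function(x, ...) {
  tibble(step = seq_along(x$error_trace),
         removed_gene = c(NA_character_, x$removed_genes),
         error = x$error_trace)
}

#' @rdname optimize_gene_set
#' @method glance bfsig_optimization
#' @export
glance.bfsig_optimization <- function(x, ...) {
  tibble(n_selected = length(x$selected_genes),
         n_removed = length(x$removed_genes),
         initial_error = if (length(x$error_trace)) x$error_trace[1] else NA_real_,
         final_error = if (length(x$error_trace)) x$error_trace[length(x$error_trace)] else NA_real_)
}
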