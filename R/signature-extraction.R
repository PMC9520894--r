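#' Connectivity matrix of one factorization
#'
#' Binary sample x sample matrix marking pairs assigned to the same dominant
#' signature, where a sample's assignment is the argmax of its activity
#' column (ties resolved to the lowest signature index).
#'
#' @param H Non-negative activity matrix (signatures x samples), rank >= 2.
#' @return Symmetric 0/1 matrix with unit diagonal.
#' @export
connectivity_matrix <- function(H) {
  H <- as.matrix(H)
  if (nrow(H) < 2) abort("connectivity needs rank >= 2")
  if (any(colSums(H) == 0)) {
    abort(sprintf("sample(s) with all-zero activities have no dominant signature: %s",
                  paste(which(colSums(H) == 0), collapse = ", ")))
  }
  assign <- apply(H, 2, which.max)   # which.max takes the first maximum
  C <- outer(assign, assign, `==`) * 1
  dimnames(C) <- list(colnames(H), colnames(H))
  C
}

#' Consensus matrix and cophenetic correlation at one rank
#'
#' Averages the connectivity matrices of `n_runs` seeded NMF fits into a
#' consensus matrix, then measures clustering stability as the Pearson
#' correlation between the consensus distances `1 - consensus` and the
#' cophenetic distances of their average-linkage dendrogram. A perfectly
#' stable rank yields a block 0/1 consensus and coefficient 1.
#'
#' @param A Non-negative expression matrix.
#' @param k Rank (>= 2).
#' @param n_runs Number of seeded fits (default 20).
#' @param seed Base seed; run r uses `seed + r - 1`.
#' @param max_iter,tol Passed to each fit (single restart per run: run-to-run
#'   variability is the point of consensus).
#' @return List with `consensus` (n x n) and `cophenetic` (scalar).
#' @export
consensus_and_cophenetic <- function(A, k, n_runs = 20, seed = 1,
                                     max_iter = 500, tol = 1e-5) {
  if (n_runs < 2) abort("n_runs must be >= 2")
  A <- as.matrix(A)
  n <- ncol(A)
  consensus <- matrix(0, n, n)
  for (r in seq_len(n_runs)) {
    fit <- fit_masked_nmf(A, k, seed = seed + r - 1, n_restarts = 1,
                          max_iter = max_iter, tol = tol,
                          connectivity_stop = TRUE)
    consensus <- consensus + connectivity_matrix(fit$H)
  }
  consensus <- consensus / n_runs
  dimnames(consensus) <- list(colnames(A), colnames(A))
  list(consensus = consensus,
       cophenetic = cophenetic_coefficient(consensus))
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' @param consensus Symmetric matrix with entries in `[0, 1]`, unit diagonal.
#' @return Pearson correlation between `1 - consensus` distances and the
#'   cophenetic distances of their average-linkage clustering; exactly 1 for
#'   a block-perfect 0/1 consensus.
#' @export
cophenetic_coefficient <- function(consensus) {
  d <- as.dist(1 - consensus)
  if (length(d) < 2 || sd(d) == 0) {
    # zero-variance distances: all pairs identical. A block-perfect 0/1
    # consensus (incl. the one-block case) is perfectly stable.
    if (all(consensus %in% c(0, 1))) return(1)
    abort("degenerate consensus: all pairwise distances equal but not 0/1")
  }
  hc <- hclust(d, method = "average")
  dc <- cophenetic(hc)
  if (sd(dc) == 0) {
    if (all(consensus %in% c(0, 1))) return(1)
    abort("degenerate dendrogram: cophenetic distances have zero variance")
  }
  cor(d, dc)
}

#' Select the NMF rank where clustering stability begins to fall
#'
#' Evaluates the cophenetic coefficient over a contiguous range of ranks and
#' chooses the smallest rank `k` whose coefficient drops by more than
#' `drop_tol` going to `k + 1`. If no drop exceeds `drop_tol`, the maximal
#' rank is returned with a warning.
#'
#' @param A Non-negative expression matrix.
#' @param ranks Contiguous integer range, min >= 2 (default `2:6`).
#' @param n_runs Seeded fits per rank (default 20).
#' @param seed Base seed.
#' @param drop_tol Coefficient drop that counts as "falling" (default
#'   0.002, calibrated against the paired run-to-run jitter of the consensus
#'   estimates; every rank reuses the same seed batch so the differences are
#'   paired).
#' @param max_iter,tol Per-fit controls.
#' @return A `bfsig_rank_report`: `ranks`, `cophenetic`, `consensus` (list),
#'   `chosen_rank`, `n_runs`, `seed`.
#' @export
select_rank <- function(A, ranks = 2:6, n_runs = 20, seed = 1,
                        drop_tol = 0.002, max_iter = 500, tol = 1e-5) {
  ranks <- sort(unique(as.integer(ranks)))
  if (length(ranks) < 2) abort("need at least two ranks to locate a fall")
  if (min(ranks) < 2) abort("ranks must start at 2 or above")
  if (!identical(ranks, seq(min(ranks), max(ranks)))) {
    abort("ranks must be contiguous")
  }
  coph <- numeric(length(ranks))
  cons <- vector("list", length(ranks))
  for (i in seq_along(ranks)) {
    # common random numbers: the same seed batch at every rank pairs the
    # cophenetic estimates, stabilizing their rank-to-rank differences
    cc <- consensus_and_cophenetic(A, ranks[i], n_runs = n_runs,
                                   seed = seed,
                                   max_iter = max_iter, tol = tol)
    coph[i] <- cc$cophenetic
    cons[[i]] <- cc$consensus
  }
  names(cons) <- paste0("k", ranks)
  chosen <- NA_integer_
  for (i in seq_len(length(ranks) - 1)) {
    if (coph[i] - coph[i + 1] > drop_tol) { chosen <- ranks[i]; break }
  }
  if (is.na(chosen)) {
    warn("cophenetic coefficient never falls by more than drop_tol; taking the maximal rank")
    chosen <- max(ranks)
  }
  structure(list(ranks = ranks, cophenetic = setNames(coph, paste0("k", ranks)),
                 consensus = cons, chosen_rank = chosen, n_runs = n_runs,
                 seed = seed, drop_tol = drop_tol),
            class = "bfsig_rank_report")
}

#' @export
print.bfsig_rank_report <- function(x, ...) {
  cat(sprintf("<bfsig_rank_report> chosen rank %d (n_runs %d)\n",
              x$chosen_rank, x$n_runs))
  print(round(x$cophenetic, 4))
  invisible(x)
}

#' @rdname select_rank
#' @param x A `bfsig_rank_report`.
#' @param ... Unused.
#' @method tidy bfsig_rank_report
#' @export
tidy.bfsig_rank_report <- function(x, ...) {
  tibble(rank = x$ranks, cophenetic = unname(x$cophenetic),
         chosen = x$ranks == x$chosen_rank)
}

#' Extract weight-normalized signatures
#'
#' Best-of-restarts NMF at the chosen rank, with each signature's gene
#' weights normalized to sum 1 and the activities rescaled inversely so the
#' reconstruction is unchanged. Labels are generic (`sig_i`) until
#' [label_signatures()] assigns anchor-based names.
#'
#' @param A Expression matrix restricted to the optimized gene set.
#' @param k Rank (from [select_rank()] or supplied).
#' @param n_restarts Restarts (default 10).
#' @param seed Integer seed.
#' @param max_iter,tol Fit controls (see [fit_masked_nmf()]).
#' @return A `bfsig_signatures`: `W_norm` (gene x signature, columns sum to
#'   1), `H` (signature x sample), `labels`, `rank`, `fit`.
#' @export
extract_signatures <- function(A, k, n_restarts = 10, seed = 1,
                               max_iter = 2000, tol = 1e-6) {
  fit <- fit_masked_nmf(A, k, seed = seed, n_restarts = n_restarts,
                        max_iter = max_iter, tol = tol)
  csums <- colSums(fit$W)
  if (any(csums == 0)) abort("degenerate all-zero signature column extracted")
  W_norm <- sweep(fit$W, 2, csums, `/`)
  H <- sweep(fit$H, 1, csums, `*`)
  labels <- colnames(W_norm)
  structure(list(W_norm = W_norm, H = H, labels = labels, rank = k,
                 seed = seed, fit = fit),
            class = "bfsig_signatures")
}

#' @export
print.bfsig_signatures <- function(x, ...) {
  cat(sprintf("<bfsig_signatures> rank %d over %d genes x %d samples: %s\n",
              x$rank, nrow(x$W_norm), ncol(x$H),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

# exhaustive maximal-total-weight assignment of anchors to signatures;
# sizes here are tiny (k <= ~6), so brute force over permutations is exact
best_assignment <- function(score) {
  # score: anchors x signatures; returns integer vector over signatures
  # giving the assigned anchor row index (NA if unassigned)
  na <- nrow(score); ns <- ncol(score)
  stopifnot(na >= 1, ns >= 1)
  if (na >= ns) {
    perms <- permutations_of(seq_len(na), ns)
    best <- NULL; best_total <- -Inf
    for (p in perms) {
      total <- sum(score[cbind(p, seq_len(ns))])
      if (total > best_total) { best_total <- total; best <- p }
    }
    best
  } else {
    # fewer anchors than signatures: assign each anchor to a distinct
    # signature, leave the rest generic
    perms <- permutations_of(seq_len(ns), na)
    best <- NULL; best_total <- -Inf
    for (p in perms) {
      total <- sum(score[cbind(seq_len(na), p)])
      if (total > best_total) { best_total <- total; best <- p }
    }
    out <- rep(NA_integer_, ns)
    out[best] <- seq_len(na)
    out
  }
}

# all ordered selections of `m` elements from `v`
permutations_of <- function(v, m) {
  if (m == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i], m - 1)
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}

#' Label signatures by anchor dominance
#'
#' Each anchor's weight row of `W_norm` is normalized across signatures to a
#' profile; signatures are assigned anchors by maximal-total-weight bipartite
#' assignment so labels stay unique. A signature's label becomes composite
#' (e.g. `MCL1/BCL2`) when a second anchor's profile weight on it reaches
#' `composite_ratio` times the assigned anchor's. With no anchors present the
#' generic `sig_i` labels are kept with a warning.
#'
#' @param sigs A `bfsig_signatures`.
#' @param anchors Ordered anchor gene ids (default the five-gene set).
#' @param composite_ratio Secondary-anchor inclusion threshold (default 0.5).
#' @return The `bfsig_signatures` with `labels` set; also renames the rows
#'   of `H` and columns of `W_norm`.
#' @export
label_signatures <- function(sigs, anchors = BFSIG_ANCHORS,
                             composite_ratio = 0.5) {
  present <- intersect(anchors, rownames(sigs$W_norm))
  k <- ncol(sigs$W_norm)
  if (length(present) == 0) {
    warn("no anchor genes among the signature rows; keeping generic labels")
    sigs$labels <- paste0("sig_", seq_len(k))
    return(sigs)
  }
  # anchor profiles: each anchor's weight distribution over signatures
  P <- sigs$W_norm[present, , drop = FALSE]
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- sweep(P, 1, rs, `/`)
  assigned <- best_assignment(P)   # per signature: anchor row index or NA
  labels <- character(k)
  for (s in seq_len(k)) {
    if (is.na(assigned[s])) { labels[s] <- paste0("sig_", s); next }
    primary <- present[assigned[s]]
    others <- setdiff(seq_along(present), assigned[s])
    lab <- primary
    if (length(others) > 0) {
      sec <- others[which.max(P[others, s])]
      if (P[sec, s] >= composite_ratio * P[assigned[s], s]) {
        lab <- paste(primary, present[sec], sep = "/")
      }
    }
    labels[s] <- lab
  }
  # uniqueness guard (composite parts could collide in pathological cases)
  labels <- make.unique(labels, sep = ".")
  sigs$labels <- labels
  colnames(sigs$W_norm) <- labels
  rownames(sigs$H) <- labels
  sigs
}

#' Spearman concordance between two signature weight matrices
#'
#' Rank-correlates every signature pair across the genes shared by the two
#' matrices (ties mid-ranked), the cross-dataset comparison used to show
#' signature weights agree between cohorts.
#'
#' @param W1,W2 Gene x signature weight matrices (normalized or not; rank
#'   correlation is scale-free).
#' @param min_overlap Minimum shared genes (default 5).
#' @return Matrix of Spearman's rho, signatures of `W1` x signatures of `W2`.
#' @export
signature_concordance <- function(W1, W2, min_overlap = 5) {
  shared <- intersect(rownames(W1), rownames(W2))
  if (length(shared) < min_overlap) {
    abort(sprintf("only %d shared gene(s); need >= %d", length(shared),
                  min_overlap))
  }
  cor(W1[shared, , drop = FALSE], W2[shared, , drop = FALSE],
      method = "spearman")
}

#' @rdname extract_signatures
#' @param x A `bfsig_signatures`.
#' @param ... Unused.
#' @method tidy bfsig_signatures
#' @export
tidy.bfsig_signatures <- function(x, ...) {
  W <- x$W_norm
  tibble(gene_id = rep(rownames(W), times = ncol(W)),
         signature = rep(colnames(W), each = nrow(W)),
         weight = as.vector(W))
}

#' @rdname extract_signatures
#' @method glance bfsig_signatures
#' @export
glance.bfsig_signatures <- function(x, ...) {
  tibble(rank = x$rank, n_genes = nrow(x$W_norm), n_samples = ncol(x$H),
         final_loss = x$fit$loss_trace[length(x$fit$loss_trace)],
         labels = paste(x$labels, collapse = ";"))
}

#' Per-sample signature activities as a tibble
#'
#' @param sigs A `bfsig_signatures`.
#' @return Tibble with `sample_id` plus one column per signature.
#' @export
signature_activities <- function(sigs) {
  H <- t(sigs$H)
  out <- as_tibble(as.data.frame(H, check.names = FALSE))
  dplyr::bind_cols(tibble(sample_id = rownames(H)), out)
}
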