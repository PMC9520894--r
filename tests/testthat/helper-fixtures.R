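# deterministic low-rank fixture: A = W0 %*% H0 with dimnames
make_rank_k <- function(g, n, k, seed = 1) {
  set.seed(seed)
  W0 <- matrix(runif(g * k, 0.2, 1), g, k)
  H0 <- matrix(runif(k * n, 0.2, 1), k, n)
  A <- W0 %*% H0
  dimnames(A) <- list(paste0("g", seq_len(g)), paste0("s", seq_len(n)))
  list(A = A, W0 = W0, H0 = H0)
}

make_response <- function(...) {
  response_table(tibble::tribble(...))
}

# best permutation match of estimated factor columns to true columns
best_perm_cor <- function(W_est, W_true) {
  k <- ncol(W_true)
  perms <- if (k == 1) list(1) else combinat_perms(seq_len(k))
  best <- -Inf; best_cors <- NULL
  for (p in perms) {
    cors <- vapply(seq_len(k), function(j) cor(W_est[, p[j]], W_true[, j]),
                   numeric(1))
    if (sum(cors) > best) { best <- sum(cors); best_cors <- cors }
  }
  best_cors
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}
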