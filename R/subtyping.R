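#' Cluster samples on signature activities into subtypes
#'
#' Hierarchical clustering of samples with average linkage on Pearson
#' correlation distance (`1 - r` between per-sample activity vectors across
#' the k signatures), cut at `n_clusters`. Each cluster is labeled by the
#' signature with the highest mean activity among its samples, giving the
#' signature-named subtypes (e.g. BCL2, MCL1/BCL2, BFL1/MCL1).
#'
#' @param H Signature x sample activity matrix (rownames = signature labels).
#' @param n_clusters Number of subtypes (default 3, conventionally the
#'   selected rank).
#' @return A `bfsig_subtypes`: tibble `assignment` (sample_id, cluster,
#'   subtype), `hclust` record, `n_clusters`.
#' @export
cluster_samples <- function(H, n_clusters = 3) {
  H <- as.matrix(H)
  n <- ncol(H)
  if (n < n_clusters) abort("more clusters than samples")
  if (is.null(colnames(H))) colnames(H) <- paste0("s", seq_len(n))
  if (is.null(rownames(H))) rownames(H) <- paste0("sig_", seq_len(nrow(H)))
  sds <- apply(H, 2, sd)
  degenerate <- sds == 0
  R <- suppressWarnings(cor(H))
  D <- 1 - R
  if (any(degenerate)) {
    warn(sprintf("zero-variance activity vector(s) assigned by nearest defined neighbour: %s",
                 paste(colnames(H)[degenerate], collapse = ", ")))
    # place degenerate samples maximally far from everything, then overwrite
    # their assignment with their nearest (euclidean) defined neighbour's
    D[degenerate, ] <- 2; D[, degenerate] <- 2; diag(D) <- 0
  }
  hc <- hclust(as.dist(D), method = "average")
  cluster <- cutree(hc, k = n_clusters)
  if (any(degenerate)) {
    ok <- which(!degenerate)
    for (j in which(degenerate)) {
      dmat <- colSums((H[, ok, drop = FALSE] - H[, j])^2)
      cluster[j] <- cluster[ok[which.min(dmat)]]
    }
  }
  subtype <- character(n)
  for (cl in unique(cluster)) {
    idx <- cluster == cl
    subtype[idx] <- rownames(H)[which.max(rowMeans(H[, idx, drop = FALSE]))]
  }
  structure(list(assignment = tibble(sample_id = colnames(H),
                                     cluster = unname(cluster),
                                     subtype = subtype),
                 hclust = hc, n_clusters = n_clusters),
            class = "bfsig_subtypes")
}

#' @export
print.bfsig_subtypes <- function(x, ...) {
  cat(sprintf("<bfsig_subtypes> %d samples in %d clusters\n",
              nrow(x$assignment), x$n_clusters))
  print(table(x$assignment$subtype))
  invisible(x)
}

#' @rdname cluster_samples
#' @param x A `bfsig_subtypes`.
#' @param ... Unused.
#' @method tidy bfsig_subtypes
#' @export
tidy.bfsig_subtypes <- function(x, ...) x$assignment

#' Welch's t-test of each signature between two groups
#'
#' The validity check comparing signature activities between drug-response
#' groups: per signature, an unequal-variance t-test with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param H Signature x sample activity matrix.
#' @param groups Vector of two group labels (or logicals), length
#'   `ncol(H)`; both groups need >= 2 samples.
#' @return Tibble: signature, t, df, p_value, mean per group.
#' @export
compare_signatures_between_groups <- function(H, groups) {
  H <- as.matrix(H)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) abort("`groups` must have exactly two levels")
  if (any(table(groups) < 2)) abort("both groups need >= 2 samples")
  lev <- levels(groups)
  purrr::map_dfr(seq_len(nrow(H)), function(i) {
    x <- H[i, groups == lev[1]]
    y <- H[i, groups == lev[2]]
    tt <- t.test(x, y, var.equal = FALSE)
    tibble(signature = rownames(H)[i] %||% paste0("sig_", i),
           t = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value,
           mean_1 = mean(x), mean_2 = mean(y))
  })
}

#' Chi-square test of subtype proportions across datasets
#'
#' Pearson chi-square of independence (no continuity correction) on a
#' subtype x dataset contingency table, used to ask whether subtype
#' proportions differ between cohorts.
#'
#' @param counts Contingency matrix of sample counts.
#' @return Tibble: statistic, df, p_value.
#' @export
subtype_proportion_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("contingency table has an empty row or column margin")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' Screen drugs for differential response across subtypes
#'
#' For every drug: an omnibus Kruskal-Wallis test of the response AUC across
#' subtypes, then all pairwise two-sided Wilcoxon rank-sum tests. P-values
#' are reported raw (set `adjust = "BH"` for Benjamini-Hochberg within the
#' pairwise family).
#'
#' @param responses Response tibble with `auc` present.
#' @param assignment A `bfsig_subtypes` or its `assignment` tibble.
#' @param min_per_group Minimum samples per subtype for inclusion (default 2).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List of tibbles: `omnibus` (drug, statistic, df, p_value) and
#'   `pairwise` (drug, group1, group2, w, p_value).
#' @export
drug_screen_by_subtype <- function(responses, assignment, min_per_group = 2,
                                   adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (inherits(assignment, "bfsig_subtypes")) assignment <- assignment$assignment
  responses <- as_tibble(responses)
  if (!"auc" %in% names(responses)) abort("responses need an `auc` column")
  dat <- dplyr::inner_join(responses, assignment, by = "sample_id")
  dat <- dat[!is.na(dat$auc), ]
  omnibus <- list(); pairwise <- list()
  for (dg in unique(dat$drug)) {
    d <- dat[dat$drug == dg, ]
    tab <- table(d$subtype)
    keep <- names(tab)[tab >= min_per_group]
    if (length(keep) < 2) next
    d <- d[d$subtype %in% keep, ]
    kw <- kruskal.test(d$auc, factor(d$subtype))
    omnibus[[dg]] <- tibble(drug = dg, statistic = unname(kw$statistic),
                            df = unname(kw$parameter), p_value = kw$p.value)
    cmb <- utils::combn(sort(keep), 2)
    pw <- purrr::map_dfr(seq_len(ncol(cmb)), function(j) {
      g1 <- cmb[1, j]; g2 <- cmb[2, j]
      wt <- suppressWarnings(
        wilcox.test(d$auc[d$subtype == g1], d$auc[d$subtype == g2],
                    alternative = "two.sided"))
      tibble(drug = dg, group1 = g1, group2 = g2,
             w = unname(wt$statistic), p_value = wt$p.value)
    })
    if (adjust == "BH") pw$p_value <- stats::p.adjust(pw$p_value, "BH")
    pairwise[[dg]] <- pw
  }
  list(omnibus = dplyr::bind_rows(omnibus),
       pairwise = dplyr::bind_rows(pairwise))
}
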