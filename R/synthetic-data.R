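#' Simulate an expression dataset with BCL2-family-like latent structure
#'
#' Generates a non-negative gene x sample matrix from `k` latent factors with
#' full ground truth, emulating the structure the signature pipeline assumes:
#' anchor genes (analogues of BCL2/MCL1/BFL1/BCLXL/BCLW) whose rows are
#' dominated by one factor each, co-regulated signal genes loading on the
#' same factors, independent noise genes whose expected expression is
#' factor-free, multiplicative lognormal (or gamma-Poisson) measurement
#' noise, and optional per-batch multiplicative shifts.
#'
#' Sample activities are drawn from a k-component mixture of Dirichlet
#' distributions: each component concentrates mass on one factor, and the
#' `separation` knob is the concentration of the dominant coordinate (off
#' coordinates have concentration `off_concentration`), so larger values give
#' cleaner sample clusters.
#'
#' @param n_samples Samples (default 200).
#' @param n_signal Factor-coupled signal genes (default 30).
#' @param n_noise Factor-independent noise genes (default 30).
#' @param k Latent factors (default 3).
#' @param n_anchors Anchor genes, named after the anti-apoptotic five
#'   (default 5); anchor i maps to factor `(i - 1) %% k + 1`.
#' @param separation Dominant Dirichlet concentration (default 4).
#' @param off_concentration Off-factor concentration (default 0.6).
#' @param noise_sd Lognormal sigma of multiplicative measurement noise on
#'   anchor and signal genes (default 0.3); 0 gives the noiseless limit
#'   `scale * W_true %*% H_true`.
#' @param noise_gene_sd Lognormal sigma of the per-gene independent
#'   variation of noise genes (default 1). Noise genes emulate the
#'   "high-noise" genes backward selection is meant to discard: their
#'   expected expression is flat in the latent factors and their variance is
#'   dominated by technical components, so under a Kullback-Leibler fit they
#'   actively distort the factors while carrying no usable signal. Disabled
#'   when `noise_sd = 0` so the noiseless limit stays exact.
#' @param nuisance_sd Log-scale amplitude of `n_nuisance` extrinsic nuisance
#'   programs shared among the noise genes (default 0.45), emulating the
#'   correlated technical variation (batch, cellular contamination) noisy
#'   genes carry in real cohorts. The shared component keeps residual noise
#'   genes harmful to the factorization even after most have been removed.
#' @param n_nuisance Number of shared nuisance programs (default 3).
#' @param noise_model `"lognormal"` (default) or `"gamma_poisson"`
#'   (count-like; `noise_sd` then acts as the overdispersion).
#' @param scale Global expression scale (default 10).
#' @param n_batches Number of batches; 1 (default) disables batch effects.
#' @param batch_sd Lognormal sigma of per-gene batch shifts (default 0.2).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return List: `expression` (matrix), `gene_set` (`bfsig_geneset` of all
#'   anchor+signal+noise genes), `truth` (a `bfsig_truth`: `W_true`,
#'   `H_true`, `gene_roles`, `anchor_factor_map`, `batch`, `config`, `seed`).
#' @export
simulate_bfsig_dataset <- function(n_samples = 200, n_signal = 30,
                                   n_noise = 30, k = 3, n_anchors = 5,
                                   separation = 4, off_concentration = 0.6,
                                   noise_sd = 0.3, noise_gene_sd = 1,
                                   nuisance_sd = 0.45, n_nuisance = 3,
                                   noise_model = c("lognormal",
                                                   "gamma_poisson"),
                                   scale = 10, n_batches = 1,
                                   batch_sd = 0.2, seed = 1) {
  noise_model <- match.arg(noise_model)
  if (k < 2) abort("k must be >= 2")
  if (n_samples < 3 * k) abort("need n_samples >= 3k")
  anchor_names <- if (n_anchors <= length(BFSIG_ANCHORS)) {
    BFSIG_ANCHORS[seq_len(n_anchors)]
  } else {
    c(BFSIG_ANCHORS, sprintf("ANC%02d", seq_len(n_anchors - length(BFSIG_ANCHORS))))
  }
  signal_names <- sprintf("SIG%03d", seq_len(n_signal))
  noise_names <- sprintf("NSE%03d", seq_len(n_noise))
  gene_ids <- c(anchor_names, signal_names, noise_names)
  g <- length(gene_ids)

  out <- with_seed(seed, {
    # --- H_true: Dirichlet mixture, one dominant factor per component
    comp <- sample(rep_len(seq_len(k), n_samples))
    H <- vapply(comp, function(z) {
      alpha <- rep(off_concentration, k)
      alpha[z] <- separation
      draw <- rgamma(k, shape = alpha, rate = 1)
      draw / sum(draw)
    }, numeric(k))
    # --- W_true
    W <- matrix(0, g, k)
    anchor_factor <- ((seq_len(n_anchors) - 1) %% k) + 1
    for (i in seq_len(n_anchors)) {
      W[i, ] <- 0.05
      W[i, anchor_factor[i]] <- 1
    }
    # signal genes model a curated regulatory-network pool: tightly
    # co-regulated with their factor, near-zero off-factor leakage
    signal_factor <- ((seq_len(n_signal) - 1) %% k) + 1
    for (j in seq_len(n_signal)) {
      row <- runif(k, 0, 0.05)
      row[signal_factor[j]] <- runif(1, 0.7, 1)
      W[n_anchors + j, ] <- row
    }
    # noise genes: flat rows -> expected expression constant in the factors
    # (H columns sum to 1), so all their variance comes from the noise model
    if (n_noise > 0) {
      W[(n_anchors + n_signal + 1):g, ] <-
        matrix(rep(runif(n_noise, 0.2, 1), k), n_noise, k)
    }
    mu <- scale * (W %*% H)
    # --- nuisance programs shared among noise genes (correlated extrinsic
    # variation); applied on the log scale, mean-corrected
    nuis_score <- matrix(0, max(n_nuisance, 1), n_samples)
    if (n_noise > 0 && noise_sd > 0 && n_nuisance > 0 && nuisance_sd > 0) {
      nuis_score <- matrix(rnorm(n_nuisance * n_samples), n_nuisance,
                           n_samples)
      idx <- (n_anchors + n_signal + 1):g
      prog_of <- rep_len(seq_len(n_nuisance), n_noise)
      mu[idx, ] <- mu[idx, , drop = FALSE] *
        exp(nuisance_sd * nuis_score[prog_of, , drop = FALSE] -
              nuisance_sd^2 / 2)
    }
    # --- measurement noise; noise genes carry a much larger independent
    # component
    sd_gene <- rep(noise_sd, g)
    if (n_noise > 0 && noise_sd > 0) {
      sd_gene[(n_anchors + n_signal + 1):g] <- noise_gene_sd
    }
    A <- if (noise_sd == 0) {
      mu
    } else if (noise_model == "lognormal") {
      sig <- matrix(rep(sd_gene, n_samples), g, n_samples)
      mu * exp(matrix(rnorm(g * n_samples), g, n_samples) * sig - sig^2 / 2)
    } else {
      matrix(rpois(g * n_samples,
                   lambda = mu * rgamma(g * n_samples,
                                        shape = 1 / noise_sd^2,
                                        rate = 1 / noise_sd^2)),
             g, n_samples)
    }
    # --- batch shifts (multiplicative per gene x batch, preserve >= 0)
    batch <- rep("b1", n_samples)
    if (n_batches > 1) {
      batch <- paste0("b", sample(rep_len(seq_len(n_batches), n_samples)))
      for (bt in unique(batch)) {
        if (bt == "b1") next  # first batch is the untouched reference
        shift <- exp(rnorm(g, 0, batch_sd))
        A[, batch == bt] <- A[, batch == bt, drop = FALSE] * shift
      }
    }
    list(A = A, W = W, H = H, comp = comp, batch = batch,
         anchor_factor = anchor_factor, signal_factor = signal_factor,
         nuis_score = nuis_score)
  })

  A <- out$A
  dimnames(A) <- list(gene_ids, sprintf("S%03d", seq_len(n_samples)))
  rownames(out$W) <- gene_ids
  colnames(out$W) <- paste0("factor_", seq_len(k))
  dimnames(out$H) <- list(colnames(out$W), colnames(A))
  roles <- c(rep("anchor", n_anchors), rep("signal", n_signal),
             rep("noise", n_noise))
  truth <- structure(list(
    W_true = out$W, H_true = out$H,
    gene_roles = setNames(roles, gene_ids),
    anchor_factor_map = setNames(out$anchor_factor, anchor_names),
    signal_factor_map = setNames(out$signal_factor, signal_names),
    component = setNames(out$comp, colnames(A)),
    batch = setNames(out$batch, colnames(A)),
    nuisance_scores = out$nuis_score,
    seed = seed,
    config = list(n_samples = n_samples, n_signal = n_signal,
                  n_noise = n_noise, k = k, n_anchors = n_anchors,
                  separation = separation,
                  off_concentration = off_concentration,
                  noise_sd = noise_sd, noise_gene_sd = noise_gene_sd,
                  nuisance_sd = nuisance_sd, n_nuisance = n_nuisance,
                  noise_model = noise_model,
                  scale = scale, n_batches = n_batches,
                  batch_sd = batch_sd)),
    class = "bfsig_truth")
  list(expression = A,
       gene_set = gene_set(gene_ids, anchors = anchor_names),
       truth = truth)
}

#' @export
print.bfsig_truth <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<bfsig_truth> k = %d, %d samples, genes: %d anchor / %d signal / %d noise\n",
              cfg$k, cfg$n_samples, cfg$n_anchors, cfg$n_signal, cfg$n_noise))
  invisible(x)
}

#' Simulate drug response driven by the latent factor activities
#'
#' Binary mode draws response labels from a logistic model on the true
#' activities, `P(sensitive) = plogis(beta0 + beta . H_true[, i] + eps)`,
#' then emits IC50 values on the correct side of the 1/10 uM thresholds
#' (sensitive <= 1, resistant >= 10). Continuous mode emits a dose-response
#' AUC linear in the activities plus Gaussian noise. Patient ids and time
#' points are synthesized, with a configurable fraction of patients
#' contributing two samples so latest-time-point deduplication is exercised.
#'
#' @param truth A `bfsig_truth`.
#' @param mode `"binary"` or `"continuous"`.
#' @param beta Length-k coefficient vector on the activities. Default for
#'   k = 3: `c(4, -4, 0)` (factor 1, the BCL2-like factor, drives
#'   sensitivity; factor 2 resistance), else zeros.
#' @param beta0 Intercept; default centers the score at its mean.
#' @param noise_sd SD of the latent score noise `eps` (binary) or of the AUC
#'   noise (continuous); default 0 and 0.1.
#' @param drug Drug name (default `"venetoclax"`).
#' @param repeat_frac Fraction of samples duplicated-by-patient via a second
#'   time point (default 0.1).
#' @param seed Integer seed.
#' @return List: `response` (a response tibble), `score` (latent scores),
#'   `beta`, `beta0`.
#' @export
simulate_drug_response <- function(truth, mode = c("binary", "continuous"),
                                   beta = NULL, beta0 = NULL, noise_sd = NULL,
                                   drug = "venetoclax", repeat_frac = 0.1,
                                   seed = 1) {
  mode <- match.arg(mode)
  H <- truth$H_true
  k <- nrow(H); n <- ncol(H)
  if (is.null(beta)) {
    beta <- if (k == 3) c(4, -4, 0) else rep(0, k)
  }
  if (length(beta) != k) abort("beta must have length k")
  if (is.null(noise_sd)) noise_sd <- if (mode == "binary") 0 else 0.1
  raw <- drop(crossprod(H, beta))
  if (is.null(beta0)) beta0 <- -mean(raw)

  out <- with_seed(seed, {
    score <- beta0 + raw + rnorm(n, 0, if (mode == "binary") noise_sd else 0)
    # patient lineage: most samples are one patient at t = 1; a fraction get
    # a sibling sample at t = 2 from the same patient
    patient <- paste0("P", seq_len(n))
    tp <- rep(1, n)
    n_rep <- floor(repeat_frac * n)
    if (n_rep > 0) {
      kids <- sample(seq_len(n), n_rep)
      donors <- sample(setdiff(seq_len(n), kids), n_rep)
      patient[kids] <- patient[donors]
      tp[kids] <- 2
    }
    if (mode == "binary") {
      p <- 1 / (1 + exp(-score))
      sens <- rbinom(n, 1, p) == 1
      ic50 <- ifelse(sens,
                     exp(runif(n, log(0.01), log(1))),
                     exp(runif(n, log(10), log(100))))
      list(score = score,
           tbl = tibble(sample_id = colnames(H), patient_id = patient,
                        time_point = tp, drug = drug, ic50_uM = ic50,
                        auc = NA_real_))
    } else {
      auc <- score + rnorm(n, 0, noise_sd)
      list(score = score,
           tbl = tibble(sample_id = colnames(H), patient_id = patient,
                        time_point = tp, drug = drug, ic50_uM = NA_real_,
                        auc = auc))
    }
  })
  list(response = response_table(out$tbl), score = out$score,
       beta = beta, beta0 = beta0)
}

#' Bayes-optimal AUROC of the generator's binary response model
#'
#' The best achievable AUROC for labels drawn from
#' `P(sensitive) = plogis(beta0 + beta . h)` is the AUROC of the true score
#' itself; it is computed here by a large Monte Carlo draw from the
#' generator's activity distribution (the normal-theory closed form does not
#' apply to Dirichlet-mixture activities, so simulation at large n is the
#' reference).
#'
#' @param truth A `bfsig_truth` (supplies the activity distribution config).
#' @param beta,beta0 Response model coefficients (as simulated).
#' @param n_mc Monte Carlo draws (default 200000).
#' @param seed Integer seed.
#' @return Scalar AUROC.
#' @export
bayes_auroc <- function(truth, beta, beta0, n_mc = 200000, seed = 1) {
  cfg <- truth$config
  k <- cfg$k
  with_seed(seed, {
    comp <- sample(seq_len(k), n_mc, replace = TRUE)
    H <- vapply(comp, function(z) {
      alpha <- rep(cfg$off_concentration, k)
      alpha[z] <- cfg$separation
      draw <- rgamma(k, shape = alpha, rate = 1)
      draw / sum(draw)
    }, numeric(k))
    score <- beta0 + drop(crossprod(H, beta))
    y <- rbinom(n_mc, 1, 1 / (1 + exp(-score)))
    auroc(score, y == 1)
  })
}
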