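PIPELINE_STAGES <- c("simulate", "optimize", "extract", "subtype", "classify")

#' Run the signature pipeline end to end
#'
#' Orchestrates the stages `simulate` (optional) -> `optimize` -> `extract`
#' -> `subtype` -> `classify` from a single structured configuration (a list
#' or a YAML file path), writing every stage's outputs plus a run manifest
#' (config hash, seeds, per-file MD5 digests, package version, timestamps)
#' under `out_dir`. Stages whose outputs already exist are skipped unless
#' `overwrite = TRUE`, so interrupted runs resume from the last completed
#' stage. All randomness derives from the config's `seed`.
#'
#' Configuration keys: `out_dir`, `seed`, `stages` (subset of the five, in
#' order), optional per-stage parameter blocks (`simulate`, `optimize`,
#' `extract`, `subtype`, `classify`), and an `inputs` block
#' (`expression`, `gene_set`, `gene_set_format`, `response`) when the
#' simulate stage is not used.
#'
#' @param config List or YAML file path.
#' @param overwrite Recompute stages whose outputs exist (default FALSE).
#' @return The manifest list, invisibly; artifacts under `out_dir`.
#' @export
run_pipeline <- function(config, overwrite = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  out_dir <- config$out_dir %||% abort("config needs `out_dir`")
  seed <- as.integer(config$seed %||% 1)
  stages <- config$stages %||%
    (if (is.null(config$inputs)) PIPELINE_STAGES
     else setdiff(PIPELINE_STAGES, "simulate"))
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown) > 0) {
    abort(sprintf("unknown stage name(s): %s", paste(unknown, collapse = ", ")))
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  path <- function(...) file.path(out_dir, ...)
  done <- function(files) all(file.exists(path(files)))
  outputs <- character(0)
  timestamps <- list()
  mark <- function(stage, files) {
    outputs <<- c(outputs, path(files))
    timestamps[[stage]] <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  }

  # ---- simulate ------------------------------------------------------------
  if ("simulate" %in% stages) {
    files <- c("expression.tsv", "gene_set.txt", "response.tsv", "truth.json")
    if (overwrite || !done(files)) {
      sim_cfg <- config$simulate %||% list()
      sim <- do.call(simulate_bfsig_dataset,
                     c(sim_cfg[setdiff(names(sim_cfg), c("response"))],
                       list(seed = seed)))
      resp_cfg <- sim_cfg$response %||% list()
      resp <- do.call(simulate_drug_response,
                      c(list(truth = sim$truth, seed = seed + 1), resp_cfg))
      write_expression_matrix(sim$expression, path("expression.tsv"))
      write_gene_set(sim$gene_set, path("gene_set.txt"))
      write_response_table(resp$response, path("response.tsv"))
      jsonlite::write_json(
        list(seed = seed, config = sim$truth$config,
             anchor_factor_map = as.list(sim$truth$anchor_factor_map),
             gene_roles = as.list(sim$truth$gene_roles),
             component = as.list(sim$truth$component),
             beta = resp$beta, beta0 = resp$beta0),
        path("truth.json"), auto_unbox = TRUE, digits = NA)
    }
    mark("simulate", files)
    expr_path <- path("expression.tsv")
    genes_path <- path("gene_set.txt"); genes_fmt <- "list"
    resp_path <- path("response.tsv")
  } else {
    inp <- config$inputs %||% abort("config needs `inputs` when simulate is not run")
    expr_path <- inp$expression %||% abort("inputs$expression is required")
    genes_path <- inp$gene_set %||% abort("inputs$gene_set is required")
    genes_fmt <- inp$gene_set_format %||% "list"
    resp_path <- inp$response
  }

  expr <- load_expression_matrix(expr_path)
  anchors <- config$anchors %||% BFSIG_ANCHORS
  pool <- load_gene_set(genes_path, format = genes_fmt, anchors = anchors,
                        expression = expr)

  # ---- optimize ------------------------------------------------------------
  if ("optimize" %in% stages) {
    files <- c("optimized_genes.txt", "optimization.json")
    if (overwrite || !done(files)) {
      opt <- do.call(optimize_gene_set,
                     c(list(A = expr, pool = pool, seed = seed),
                       config$optimize %||% list()))
      writeLines(opt$selected_genes, path("optimized_genes.txt"))
      jsonlite::write_json(
        list(selected_genes = opt$selected_genes,
             removed_genes = opt$removed_genes,
             error_trace = opt$error_trace, config = opt$config),
        path("optimization.json"), auto_unbox = TRUE, digits = NA)
    }
    mark("optimize", files)
    sel_genes <- readLines(path("optimized_genes.txt"))
  } else {
    sel_genes <- pool$members[pool$members %in% rownames(expr)]
  }
  A_opt <- expr[sel_genes, , drop = FALSE]

  # ---- extract -------------------------------------------------------------
  if ("extract" %in% stages) {
    files <- c("W_norm.tsv", "H.tsv", "labels.json", "rank_report.json")
    if (overwrite || !done(files)) {
      ex_cfg <- config$extract %||% list()
      ranks <- ex_cfg$ranks %||% 2:6
      if (length(ranks) == 2 && diff(ranks) > 1) ranks <- ranks[1]:ranks[2]
      report <- select_rank(A_opt, ranks = ranks,
                            n_runs = ex_cfg$n_runs %||% 20,
                            seed = seed,
                            drop_tol = ex_cfg$drop_tol %||% 0.02)
      sigs <- extract_signatures(A_opt, k = report$chosen_rank,
                                 n_restarts = ex_cfg$n_restarts %||% 10,
                                 seed = seed)
      sigs <- label_signatures(sigs, anchors = anchors,
                               composite_ratio = ex_cfg$composite_ratio %||% 0.5)
      write_expression_matrix(sigs$W_norm, path("W_norm.tsv"))
      write.table(data.frame(signature = rownames(sigs$H), sigs$H,
                             check.names = FALSE),
                  path("H.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(labels = sigs$labels, rank = sigs$rank),
                           path("labels.json"), auto_unbox = TRUE, digits = NA)
      jsonlite::write_json(
        list(ranks = report$ranks, cophenetic = as.list(report$cophenetic),
             chosen_rank = report$chosen_rank, n_runs = report$n_runs),
        path("rank_report.json"), auto_unbox = TRUE, digits = NA)
    }
    mark("extract", files)
  }
  H <- NULL
  if (any(c("subtype", "classify") %in% stages)) {
    if (!file.exists(path("H.tsv"))) {
      abort("missing upstream artifact for stage 'subtype'/'classify': H.tsv (run the extract stage)")
    }
    H_tab <- read.delim(path("H.tsv"), check.names = FALSE)
    H <- as.matrix(H_tab[, -1, drop = FALSE])
    rownames(H) <- H_tab[[1]]
  }

  # ---- subtype -------------------------------------------------------------
  if ("subtype" %in% stages) {
    files <- "subtypes.tsv"
    if (overwrite || !done(files)) {
      st_cfg <- config$subtype %||% list()
      st <- cluster_samples(H, n_clusters = st_cfg$n_clusters %||% nrow(H))
      write.table(as.data.frame(st$assignment), path("subtypes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    mark("subtype", files)
  }

  # ---- classify ------------------------------------------------------------
  if ("classify" %in% stages) {
    files <- c("predictions.tsv", "evaluation.json")
    if (overwrite || !done(files)) {
      if (is.null(resp_path) || !file.exists(resp_path)) {
        abort("classify stage needs a response table (missing upstream artifact: response)")
      }
      cl_cfg <- config$classify %||% list()
      drug <- cl_cfg$drug %||% "venetoclax"
      resp <- load_response_table(resp_path)
      resp <- binarize_response(resp, drug)
      resp <- deduplicate_by_latest_timepoint(resp)
      resp <- resp[resp$drug == drug & resp$binary_class %in%
                     c("sensitive", "resistant"), ]
      common <- intersect(resp$sample_id, colnames(H))
      resp <- resp[resp$sample_id %in% common, ]
      feats <- t(H[, resp$sample_id, drop = FALSE])
      ev <- repeated_split_evaluate(
        feats, resp$binary_class == "sensitive",
        n_repeats = cl_cfg$n_repeats %||% 10,
        train_frac = cl_cfg$train_frac %||% 0.7,
        seed = seed)
      write.table(as.data.frame(ev$probabilities), path("predictions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(auroc = ev$pooled$auroc, ci = c(ev$pooled$ci_low,
                                             ev$pooled$ci_high),
             wilcoxon_p = ev$pooled$wilcoxon_p, n_pooled = ev$pooled$n_pooled,
             n_repeats = ev$n_repeats, train_frac = ev$train_frac,
             drug = drug),
        path("evaluation.json"), auto_unbox = TRUE, digits = NA)
    }
    mark("classify", files)
  }

  # ---- manifest ------------------------------------------------------------
  cfg_file <- tempfile()
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), cfg_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = seed, stages = stages,
    files = as.list(tools::md5sum(unique(outputs))),
    package_version = as.character(packageVersion("bfsig")),
    timestamps = timestamps)
  unlink(cfg_file)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
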