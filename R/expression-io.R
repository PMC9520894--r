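#' Read a gene-by-sample expression matrix
#'
#' Expression inputs are plain delimited text: the first row holds sample
#' identifiers, the first column gene identifiers, and the body non-negative
#' numeric values (e.g. log-scale normalized counts). Values must be finite
#' and >= 0 because downstream factorization uses a Kullback-Leibler loss.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter; default tab.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_expression_matrix(matrix(1:4, 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), tf)
#' load_expression_matrix(tf)
#' @export
load_expression_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read.delim(path, sep = delimiter, header = TRUE,
                   row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort("expression table needs a gene-id column plus at least one sample column")
  gene_ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  num <- vapply(body, function(col) is.numeric(col), logical(1))
  if (!all(num)) {
    abort(sprintf("non-numeric expression column(s): %s",
                  paste(names(body)[!num], collapse = ", ")))
  }
  m <- as.matrix(body)
  rownames(m) <- gene_ids
  validate_expression_matrix(m, arg = basename(path))
  m
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [load_expression_matrix()]; round-trips values at full
#' double precision.
#'
#' @param x Validated gene x sample matrix.
#' @param path Output path.
#' @param delimiter Field delimiter; default tab.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, delimiter = "\t") {
  validate_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Optional log2(x + 1) transform
#'
#' The pipeline accepts any non-negative matrix; this convenience transform
#' floors at zero first so count-like inputs land on the log scale most
#' published AML signatures use. Default preprocessing is pass-through.
#'
#' @param x Gene x sample matrix.
#' @return Transformed matrix.
#' @export
log2p1_transform <- function(x) {
  validate_expression_matrix(x)
  log2(pmax(x, 0) + 1)
}

#' Construct a gene set with designated anchor genes
#'
#' A gene set is the pool fed to backward optimization; the anchors are the
#' five anti-apoptotic BCL2-family genes (BCL2, MCL1, BFL1, BCLXL, BCLW by
#' default) whose profiles the optimization must be able to impute. Anchors
#' are always a subset of the members and are never removable.
#'
#' @param members Character vector of gene identifiers (deduplicated).
#' @param anchors Ordered character vector of anchor genes; default the
#'   five-gene anti-apoptotic set.
#' @return A `bfsig_geneset` list with elements `members` and `anchors`.
#' @export
gene_set <- function(members, anchors = BFSIG_ANCHORS) {
  members <- unique(as.character(members))
  anchors <- as.character(anchors)
  if (length(members) == 0) abort("gene set is empty")
  if (length(anchors) == 0) abort("anchors must be non-empty")
  members <- union(anchors, members)
  structure(list(members = members, anchors = anchors),
            class = "bfsig_geneset")
}

#' @export
print.bfsig_geneset <- function(x, ...) {
  cat(sprintf("<bfsig_geneset> %d genes, %d anchors (%s)\n",
              length(x$members), length(x$anchors),
              paste(x$anchors, collapse = ", ")))
  invisible(x)
}

#' Read a gene set from GMT or plain-list text
#'
#' @param path File path. `list` format is one symbol per line; `gmt` is the
#'   standard tab-separated dialect (set name, description, then members) and
#'   takes the first line's members.
#' @param format `"list"` or `"gmt"`.
#' @param anchors Anchor genes (see [gene_set()]).
#' @param expression Optional expression matrix; members absent from its
#'   rownames trigger a warning.
#' @return A `bfsig_geneset`.
#' @export
load_gene_set <- function(path, format = c("list", "gmt"),
                          anchors = BFSIG_ANCHORS, expression = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("gene set file is empty")
  members <- if (format == "gmt") {
    fields <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) abort("malformed GMT line: need name, description, members")
    fields[-(1:2)]
  } else {
    trimws(lines)
  }
  gs <- gene_set(members, anchors = anchors)
  if (!is.null(expression)) {
    missing <- setdiff(gs$members, rownames(expression))
    if (length(missing) > 0) {
      warn(sprintf("%d gene-set member(s) absent from the expression matrix: %s",
                   length(missing), paste(head(missing, 10), collapse = ", ")))
    }
  }
  gs
}

#' Write a gene set
#'
#' @param x A `bfsig_geneset`.
#' @param path Output path.
#' @param format `"list"` (one symbol per line) or `"gmt"`.
#' @param name,description GMT set name and description.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(x, path, format = c("list", "gmt"),
                           name = "BCL2REG", description = "") {
  format <- match.arg(format)
  if (format == "gmt") {
    writeLines(paste(c(name, description, x$members), collapse = "\t"), path)
  } else {
    writeLines(x$members, path)
  }
  invisible(path)
}
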