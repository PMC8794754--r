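#' Expression dataset container
#'
#' The pipeline's universal input: a genes x samples matrix of log-scale
#' expression together with a condition label ("A" = normal, "B" = tumor)
#' for every sample, and optional survival columns carried along from the
#' phenotype table.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are taken as gene/sample ids unless `gene_ids` /
#'   `sample_ids` are given.
#' @param condition character/factor vector, one of `"A"`/`"B"` per sample,
#'   named by sample id or in column order.
#' @param gene_ids,sample_ids optional id vectors overriding dimnames.
#' @param survival optional data.frame with columns `sample_id`, `time`,
#'   `event` for (a subset of) the samples.
#' @return an object of class `expression_dataset` with elements `values`,
#'   `gene_ids`, `sample_ids`, `condition` (named character), `survival`.
#' @export
expression_dataset <- function(values, condition, gene_ids = NULL,
                               sample_ids = NULL, survival = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_field("values", "must be a numeric matrix (genes x samples)")
  gene_ids <- as.character(gene_ids %||% rownames(values) %||%
                             paste0("gene", seq_len(nrow(values))))
  sample_ids <- as.character(sample_ids %||% colnames(values) %||%
                               paste0("sample", seq_len(ncol(values))))
  if (length(gene_ids) != nrow(values))
    stop_field("gene_ids", "length must equal nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop_field("sample_ids", "length must equal ncol(values)")
  if (anyDuplicated(gene_ids))
    stop_field("gene_ids", paste("duplicate gene id:",
                                 gene_ids[duplicated(gene_ids)][1]))
  if (anyDuplicated(sample_ids))
    stop_field("sample_ids", paste("duplicate sample id:",
                                   sample_ids[duplicated(sample_ids)][1]))
  condition <- as.character(condition)
  if (!is.null(names(condition))) {
    missing <- setdiff(sample_ids, names(condition))
    if (length(missing))
      stop_field("condition", paste("no condition for sample:", missing[1]))
    condition <- condition[sample_ids]
  } else if (length(condition) != length(sample_ids)) {
    stop_field("condition", "length must equal the number of samples")
  }
  if (!all(condition %in% c("A", "B")))
    stop_field("condition",
               paste("unknown condition label:",
                     setdiff(condition, c("A", "B"))[1], "(expected A or B)"))
  names(condition) <- sample_ids
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         condition = condition, survival = survival),
    class = "expression_dataset"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples (A: %d, B: %d)\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == "A"), sum(x$condition == "B")))
  if (!is.null(x$survival))
    cat(sprintf("  survival: %d samples, %d events\n",
                nrow(x$survival), sum(x$survival$event)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Subset the samples of a dataset to one condition
#' @param ds an `expression_dataset`.
#' @param condition `"A"` or `"B"`.
#' @return numeric matrix of the samples in that condition.
#' @export
condition_matrix <- function(ds, condition) {
  stopifnot(inherits(ds, "expression_dataset"), condition %in% c("A", "B"))
  ds$values[, ds$condition == condition, drop = FALSE]
}

#' Read an expression matrix and phenotype table
#'
#' Expression TSV: first column gene id, header row of sample ids,
#' tab-separated, `NA` for missing values. Phenotype TSV: columns
#' `sample_id`, `condition` (`A` = normal / `B` = tumor), optional `time`
#' and `event` for survival.
#'
#' @param path expression TSV path.
#' @param phenotype_path phenotype TSV path; must cover every sample.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(path, phenotype_path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (!file.exists(phenotype_path))
    stop("phenotype file not found: ", phenotype_path)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression table needs >= 1 sample column")
  gene_ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat))
    stop("non-numeric expression values in ", path)
  rownames(mat) <- gene_ids
  pheno <- utils::read.delim(phenotype_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  if (!all(need %in% names(pheno)))
    stop("phenotype table must have columns sample_id, condition")
  missing <- setdiff(colnames(mat), pheno$sample_id)
  if (length(missing))
    stop("phenotype table missing sample: ", missing[1])
  cond <- stats::setNames(pheno$condition, pheno$sample_id)
  surv <- NULL
  if (all(c("time", "event") %in% names(pheno))) {
    surv <- pheno[!is.na(pheno$time) & !is.na(pheno$event),
                  c("sample_id", "time", "event")]
    if (nrow(surv) == 0) surv <- NULL
  }
  expression_dataset(mat, cond[colnames(mat)], survival = surv)
}

#' Write an expression dataset to the standard TSV pair
#'
#' @param ds an `expression_dataset`.
#' @param path expression TSV path.
#' @param phenotype_path phenotype TSV path.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(ds, path, phenotype_path) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- data.frame(gene_id = ds$gene_ids, ds$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  pheno <- data.frame(sample_id = ds$sample_ids,
                      condition = unname(ds$condition))
  if (!is.null(ds$survival)) {
    idx <- match(pheno$sample_id, ds$survival$sample_id)
    pheno$time <- ds$survival$time[idx]
    pheno$event <- ds$survival$event[idx]
  }
  utils::write.table(pheno, phenotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, phenotype_path))
}
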