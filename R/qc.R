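#' Remove bad genes and samples before network construction
#'
#' Mirrors the usual pre-WGCNA quality filter: drops genes with excess
#' missingness or zero variance and samples with excess missingness.
#' Surviving genes and samples keep their original order.
#'
#' @param ds an [expression_dataset()].
#' @param max_missing_frac maximum tolerated fraction of missing entries per
#'   gene and per sample (default 0.5).
#' @return list with elements `dataset` (filtered) and `report`, a
#'   data.frame with columns `id`, `kind` (gene/sample) and `reason`
#'   (`"excess missingness"` or `"zero variance"`).
#' @export
good_samples_genes <- function(ds, max_missing_frac = 0.5) {
  stopifnot(inherits(ds, "expression_dataset"))
  x <- ds$values
  report <- data.frame(id = character(), kind = character(),
                       reason = character(), stringsAsFactors = FALSE)

  gene_miss <- rowMeans(is.na(x))
  gene_var <- apply(x, 1, stats::var, na.rm = TRUE)
  bad_miss <- gene_miss > max_missing_frac
  bad_var <- !bad_miss & (is.na(gene_var) | gene_var == 0)
  if (any(bad_miss))
    report <- rbind(report, data.frame(id = ds$gene_ids[bad_miss],
                                       kind = "gene",
                                       reason = "excess missingness"))
  if (any(bad_var))
    report <- rbind(report, data.frame(id = ds$gene_ids[bad_var],
                                       kind = "gene",
                                       reason = "zero variance"))
  keep_genes <- !(bad_miss | bad_var)
  if (!any(keep_genes))
    stop("all genes removed by QC: degenerate dataset")
  x <- x[keep_genes, , drop = FALSE]

  samp_miss <- colMeans(is.na(x))
  bad_samp <- samp_miss > max_missing_frac
  if (any(bad_samp))
    report <- rbind(report, data.frame(id = ds$sample_ids[bad_samp],
                                       kind = "sample",
                                       reason = "excess missingness"))
  keep_samp <- !bad_samp
  out <- expression_dataset(x[, keep_samp, drop = FALSE],
                            ds$condition[keep_samp],
                            survival = ds$survival)
  attr(report, "max_missing_frac") <- max_missing_frac
  list(dataset = out, report = report)
}

#' Flag outlier samples by standardized network connectivity
#'
#' Computes the inter-sample Pearson correlation matrix (over genes,
#' pairwise-complete), sums each sample's correlations to the others
#' (whole-network connectivity), standardizes, and flags samples below
#' `z_cut`. By default connectivity is standardized within each condition
#' group, so the tumor/normal separation itself — which lowers the smaller
#' group's average inter-sample correlation — is not mistaken for
#' abnormality. Exclusion itself is a separate explicit call
#' ([exclude_samples()]), matching the practice of inspecting a sample
#' dendrogram before dropping anything.
#'
#' @param ds an [expression_dataset()].
#' @param z_cut standardized-connectivity threshold (default -2.5).
#' @param by_condition standardize within condition groups (default TRUE).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(ds, z_cut = -2.5, by_condition = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"))
  n <- ncol(ds$values)
  if (n < 3) stop("need >= 3 samples to assess outliers")
  groups <- if (by_condition) split(seq_len(n), ds$condition)
    else list(seq_len(n))
  out <- character(0)
  for (idx in groups) {
    if (length(idx) < 3) next
    cc <- stats::cor(ds$values[, idx, drop = FALSE],
                     use = "pairwise.complete.obs")
    k <- rowSums(cc, na.rm = TRUE) - 1   # drop self-correlation
    z <- (k - mean(k)) / stats::sd(k)
    out <- c(out, ds$sample_ids[idx][!is.na(z) & z < z_cut])
  }
  out[order(match(out, ds$sample_ids))]
}

#' Remove named samples from a dataset
#'
#' @param ds an [expression_dataset()].
#' @param ids sample ids to drop; every id must be present. `character(0)`
#'   returns the dataset unchanged.
#' @return the reduced `expression_dataset`.
#' @export
exclude_samples <- function(ds, ids) {
  stopifnot(inherits(ds, "expression_dataset"))
  ids <- as.character(ids)
  unknown <- setdiff(ids, ds$sample_ids)
  if (length(unknown)) stop("unknown sample id: ", unknown[1])
  keep <- !(ds$sample_ids %in% ids)
  expression_dataset(ds$values[, keep, drop = FALSE], ds$condition[keep],
                     survival = ds$survival)
}
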