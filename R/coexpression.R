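#' Gene-gene correlation matrix
#'
#' Pairwise similarity between gene expression profiles across all samples,
#' by Pearson correlation or biweight midcorrelation (bicor). Missing
#' entries are handled with pairwise-complete observations. Bicor uses the
#' standard median/MAD biweight with tuning constant 9; a gene with MAD = 0
#' falls back to its Pearson column (with a warning), the usual degenerate
#' case handling.
#'
#' @param ds an [expression_dataset()].
#' @param method `"pearson"` (default) or `"bicor"`.
#' @return symmetric genes x genes matrix with unit diagonal, class
#'   `dcnet_cor`, attribute `method`.
#' @export
correlation_matrix <- function(ds, method = c("pearson", "bicor")) {
  stopifnot(inherits(ds, "expression_dataset"))
  method <- match.arg(method)
  if (ncol(ds$values) < 3) stop("need >= 3 samples for correlations")
  v <- apply(ds$values, 1, stats::var, na.rm = TRUE)
  if (any(v == 0, na.rm = TRUE))
    stop("zero-variance gene: ", ds$gene_ids[which(v == 0)[1]])
  cm <- if (method == "pearson") {
    stats::cor(t(ds$values), use = "pairwise.complete.obs")
  } else {
    bicor_matrix(ds$values)
  }
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  structure(cm, method = method, class = c("dcnet_cor", class(cm)))
}

# Biweight midcorrelation across rows of x (genes x samples).
# Weights w = (1 - u^2)^2 on u = (x - med) / (9 * mad), zero outside |u| < 1.
bicor_matrix <- function(x) {
  n_gene <- nrow(x)
  med <- apply(x, 1, stats::median, na.rm = TRUE)
  madv <- apply(x, 1, stats::mad, na.rm = TRUE)   # scaled MAD, constant 1.4826
  degenerate <- madv == 0 | is.na(madv)
  u <- (x - med) / (9 * madv)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xc <- (x - med) * w
  denom <- sqrt(rowSums(xc^2, na.rm = TRUE))
  xs <- xc / denom
  xs[is.na(xs)] <- 0
  cm <- xs %*% t(xs)
  if (any(degenerate)) {
    warning("MAD = 0 for ", sum(degenerate),
            " gene(s); falling back to Pearson for those rows")
    pear <- stats::cor(t(x), use = "pairwise.complete.obs")
    cm[degenerate, ] <- pear[degenerate, ]
    cm[, degenerate] <- pear[, degenerate]
  }
  dimnames(cm) <- list(rownames(x), rownames(x))
  pmin(pmax(cm, -1), 1)
}

#' Power adjacency from a correlation matrix
#'
#' Unsigned network: `a_ij = |r_ij|^beta`; signed network:
#' `a_ij = ((1 + r_ij) / 2)^beta`. The diagonal is set to 0 (the
#' connectivity convention); [tom_similarity()] works directly from this.
#'
#' @param cm correlation matrix (from [correlation_matrix()]).
#' @param beta soft-threshold power, >= 1.
#' @param signed use the signed transform (default FALSE).
#' @return adjacency matrix with entries in \[0, 1\] and zero diagonal.
#' @export
adjacency_matrix <- function(cm, beta, signed = FALSE) {
  if (beta < 1) stop("beta must be >= 1")
  a <- if (signed) ((1 + cm) / 2)^beta else abs(cm)^beta
  diag(a) <- 0
  a
}

#' Signed scale-free topology fit index
#'
#' Bins the connectivity values into `n_bins` equal-width bins over the
#' connectivity range, regresses log10(frequency) on log10(mean
#' connectivity) over non-empty bins, and returns R-squared multiplied by
#' minus the sign of the slope — positive only when frequency decreases
#' with connectivity, as a scale-free degree distribution requires.
#'
#' @param connectivity non-negative numeric vector (per-gene sums of
#'   adjacency).
#' @param n_bins number of bins (default 10; reduced when fewer distinct
#'   positive values exist).
#' @return signed R-squared in \[-1, 1\]; 0 with a warning when the
#'   connectivities are all equal.
#' @export
scale_free_fit_index <- function(connectivity, n_bins = 10) {
  k <- connectivity[connectivity > 0 & !is.na(connectivity)]
  if (length(unique(k)) < 2) {
    warning("connectivity is constant; scale-free fit undefined")
    return(0)
  }
  n_bins <- min(n_bins, length(unique(k)))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  keep <- counts > 0
  mean_k <- tapply(k, bin, mean)[keep]
  freq <- counts[keep] / length(k)
  if (sum(keep) < 3) return(0)
  fit <- stats::lm(log10(freq) ~ log10(as.numeric(mean_k)))
  # suppressed: "essentially perfect fit" on exactly log-linear fixtures
  r2 <- suppressWarnings(summary(fit)$r.squared)
  slope <- stats::coef(fit)[2]
  unname(r2 * -sign(slope))
}

#' Choose the soft-threshold power by the scale-free criterion
#'
#' For each candidate power computes the adjacency, per-gene connectivity
#' `k_i = sum_j a_ij`, the signed scale-free fit R-squared, and the mean
#' connectivity; picks the smallest power whose fit reaches `target_R2`.
#' When no candidate reaches the target the argmax is returned with
#' `reached_target = FALSE`.
#'
#' @param cm correlation matrix.
#' @param powers candidate integer powers (default 1:20).
#' @param target_R2 scale-free fit target (default 0.9).
#' @param signed signed network (default FALSE).
#' @return list with `table` (data.frame power, fit_R2, mean_k), `power`
#'   (chosen), `reached_target` (logical).
#' @export
pick_soft_threshold <- function(cm, powers = 1:20, target_R2 = 0.9,
                                signed = FALSE) {
  tab <- data.frame(power = powers, fit_R2 = NA_real_, mean_k = NA_real_)
  for (i in seq_along(powers)) {
    a <- adjacency_matrix(cm, powers[i], signed = signed)
    k <- rowSums(a)
    tab$fit_R2[i] <- scale_free_fit_index(k)
    tab$mean_k[i] <- mean(k)
  }
  hit <- which(tab$fit_R2 >= target_R2)
  if (length(hit)) {
    chosen <- powers[hit[1]]
    reached <- TRUE
  } else {
    chosen <- powers[which.max(tab$fit_R2)]
    reached <- FALSE
    warning(sprintf(
      "no candidate power reached scale-free R2 >= %.2f; using argmax %d",
      target_R2, chosen))
  }
  list(table = tab, power = chosen, reached_target = reached)
}

#' Topological overlap similarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`; the diagonal is 1. Two
#' genes score high when they are connected and share neighbors.
#'
#' @param a symmetric adjacency with zero diagonal and entries in \[0, 1\].
#' @return symmetric TOM matrix, entries in \[0, 1\], unit diagonal.
#' @export
tom_similarity <- function(a) {
  if (!isTRUE(all.equal(a, t(a), tolerance = 1e-10)))
    stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency must have zero diagonal")
  k <- rowSums(a)
  l <- a %*% a               # shared-neighbor term (diagonal unused)
  kmin <- outer(k, k, pmin)
  denom <- pmax(kmin + 1 - a, 1e-12)
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Average-linkage gene dendrogram on topological-overlap dissimilarity
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @return an [stats::hclust] tree built on `1 - TOM` with average linkage.
#' @export
cluster_genes <- function(tom) {
  if (nrow(tom) == 1)
    return(structure(list(merge = matrix(numeric(0), 0, 2), height = numeric(0),
                          order = 1L, labels = rownames(tom),
                          method = "average"),
                     class = "hclust"))
  stats::hclust(stats::as.dist(1 - tom), method = "average")
}

# Static cut height as a fraction of the maximum merge height, indexed by
# the deep-split level (0..3): deeper splits cut higher, producing more,
# smaller branches.
deep_split_fraction <- c(`0` = 0.95, `1` = 0.97, `2` = 0.99, `3` = 0.995)

#' Cut a gene dendrogram into modules
#'
#' Tree-variant dynamic cut: the dendrogram is cut at
#' `deep_split_fraction[deepSplit] * max(height)`; branches with at least
#' `minModuleSize` leaves become modules (labelled `"M1"`, `"M2"`, ... by
#' decreasing size), all remaining genes are assigned to `"grey"`.
#'
#' @param dend an `hclust` tree from [cluster_genes()].
#' @param minModuleSize minimum module size (default 30).
#' @param deepSplit split sensitivity 0..3 (default 2).
#' @return named character vector gene -> module label.
#' @export
cut_modules <- function(dend, minModuleSize = 30, deepSplit = 2) {
  if (is.null(dend) || length(dend$order) == 0) stop("empty dendrogram")
  labels <- dend$labels %||% as.character(seq_along(dend$order))
  if (length(dend$height) == 0)
    return(stats::setNames(rep("grey", length(labels)), labels))
  if (!deepSplit %in% 0:3) stop("deepSplit must be one of 0, 1, 2, 3")
  h <- deep_split_fraction[[as.character(deepSplit)]] * max(dend$height)
  raw <- stats::cutree(dend, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= minModuleSize]
  # label modules by decreasing size, ties by first occurrence
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  lab <- stats::setNames(rep("grey", length(raw)), labels)
  for (i in seq_along(keep)) lab[raw == as.integer(keep[i])] <- paste0("M", i)
  lab
}

#' Module eigengenes (first principal component per module)
#'
#' Each module's genes are z-scored across samples; the eigengene is the
#' first principal-component score across samples, scaled to unit variance
#' and sign-aligned so it correlates non-negatively with the module's mean
#' expression. The grey (unassigned) label is skipped.
#'
#' @param ds an [expression_dataset()].
#' @param modules named gene -> module vector from [cut_modules()].
#' @return list with `eigengenes` (samples x modules matrix) and
#'   `var_explained` (named fraction per module).
#' @export
module_eigengenes <- function(ds, modules) {
  stopifnot(inherits(ds, "expression_dataset"))
  mods <- setdiff(unique(modules), "grey")
  mods <- mods[order(match(mods, modules))]
  if (!length(mods)) stop("no non-grey module")
  me <- matrix(NA_real_, ncol(ds$values), length(mods),
               dimnames = list(ds$sample_ids, mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- names(modules)[modules == m]
    if (length(genes) < 2) stop("module ", m, " has < 2 genes")
    x <- ds$values[genes, , drop = FALSE]
    xs <- t(scale(t(x)))                      # z-score each gene
    xs[is.na(xs)] <- 0
    sv <- svd(t(xs), nu = 1, nv = 0)
    score <- sv$u[, 1] * sv$d[1]
    if (stats::sd(score) > 0) score <- score / stats::sd(score)
    mean_prof <- colMeans(xs)
    if (sum(score * mean_prof) < 0) score <- -score
    me[, m] <- score
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, var_explained = ve)
}

#' Merge modules with highly correlated eigengenes
#'
#' Average-linkage clustering of eigengenes on `1 - cor`; clusters joined
#' below `cut_height` (i.e. eigengene correlation above `1 - cut_height`)
#' are merged into the largest member module, eigengenes are recomputed,
#' and the procedure iterates until stable.
#'
#' @param ds an [expression_dataset()].
#' @param modules gene -> module vector.
#' @param mes eigengene list from [module_eigengenes()] (recomputed if NULL).
#' @param cut_height eigengene dissimilarity threshold (default 0.25).
#' @return list `modules`, `eigengenes` (as [module_eigengenes()] output).
#' @export
merge_close_modules <- function(ds, modules, mes = NULL, cut_height = 0.25) {
  repeat {
    if (is.null(mes)) mes <- module_eigengenes(ds, modules)
    me <- mes$eigengenes
    if (ncol(me) < 2) return(list(modules = modules, eigengenes = mes))
    d <- 1 - stats::cor(me)
    tree <- stats::hclust(stats::as.dist(d), method = "average")
    grp <- stats::cutree(tree, h = cut_height)
    if (max(grp) == ncol(me)) return(list(modules = modules, eigengenes = mes))
    for (g in unique(grp)) {
      members <- colnames(me)[grp == g]
      if (length(members) < 2) next
      sizes <- vapply(members, function(m) sum(modules == m), integer(1))
      target <- members[which.max(sizes)]
      modules[modules %in% members] <- target
    }
    mes <- NULL   # recompute and re-test for further merges
  }
}

#' Correlation of module eigengenes with a binary trait
#'
#' @param mes eigengene list from [module_eigengenes()].
#' @param trait per-sample 0/1 vector (e.g. tumor indicator); must contain
#'   both classes.
#' @return data.frame `module`, `r`, `p` (two-sided t-transform p-value).
#' @export
module_trait_correlation <- function(mes, trait) {
  if (length(unique(trait)) < 2) stop("trait is constant")
  me <- mes$eigengenes
  n <- nrow(me)
  r <- as.numeric(stats::cor(me, trait))
  p <- cor_t_pvalue(r, n)
  data.frame(module = colnames(me), r = r, p = p, stringsAsFactors = FALSE)
}

# exact two-sided p for a Pearson correlation via t = r sqrt((n-2)/(1-r^2))
cor_t_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Per-gene module membership and gene significance
#'
#' MM = correlation of the gene with its own module's eigengene; GS =
#' correlation of the gene with the trait. Both carry exact t-transform
#' p-values. Grey genes get NA MM.
#'
#' @param ds an [expression_dataset()].
#' @param modules gene -> module vector.
#' @param mes eigengene list.
#' @param trait per-sample 0/1 vector.
#' @return data.frame `gene`, `module`, `MM`, `MM_p`, `GS`, `GS_p`.
#' @export
gene_module_stats <- function(ds, modules, mes, trait) {
  n <- ncol(ds$values)
  gs <- as.numeric(stats::cor(t(ds$values), trait,
                              use = "pairwise.complete.obs"))
  mm <- rep(NA_real_, nrow(ds$values))
  for (m in colnames(mes$eigengenes)) {
    idx <- which(modules[ds$gene_ids] == m)
    if (length(idx))
      mm[idx] <- as.numeric(stats::cor(t(ds$values[idx, , drop = FALSE]),
                                       mes$eigengenes[, m],
                                       use = "pairwise.complete.obs"))
  }
  data.frame(gene = ds$gene_ids,
             module = unname(modules[ds$gene_ids]),
             MM = mm, MM_p = cor_t_pvalue(mm, n),
             GS = gs, GS_p = cor_t_pvalue(gs, n),
             stringsAsFactors = FALSE)
}

#' Per-module correlation between module membership and |gene significance|
#'
#' Summarizes how strongly a module's genes tie their centrality (MM) to
#' their trait association (|GS|); high values mark modules whose core
#' genes drive the trait signal.
#'
#' @param stats data.frame from [gene_module_stats()].
#' @return named numeric vector, one `cor(MM, |GS|)` per non-grey module
#'   (NA for modules with fewer than 3 genes).
#' @export
mm_gs_correlation <- function(stats) {
  mods <- setdiff(unique(stats$module), "grey")
  vapply(stats::setNames(mods, mods), function(m) {
    sub <- stats[stats$module == m & !is.na(stats$MM), ]
    if (nrow(sub) < 3) return(NA_real_)
    stats::cor(sub$MM, abs(sub$GS))
  }, numeric(1))
}

#' Select disease-relevant modules
#'
#' Keeps modules whose eigengene-trait correlation exceeds `trait_cut` in
#' absolute value AND whose within-module correlation between module
#' membership and absolute gene significance exceeds `mmgs_cut` — the
#' two-stage rule used to focus differential-correlation analysis on
#' modules dominated by trait-associated genes. Both inequalities are
#' strict, so a module sitting exactly at a threshold is excluded.
#'
#' @param trait_cors data.frame from [module_trait_correlation()].
#' @param mmgs_cors named vector from [mm_gs_correlation()] (names are
#'   module labels).
#' @param trait_cut,mmgs_cut strict thresholds (default 0.5 each).
#' @return data.frame `module`, `trait_r`, `mmgs_r`, `selected`.
#' @export
select_significant_modules <- function(trait_cors, mmgs_cors,
                                       trait_cut = 0.5, mmgs_cut = 0.5) {
  mmgs <- unname(mmgs_cors[trait_cors$module])
  data.frame(module = trait_cors$module,
             trait_r = trait_cors$r,
             mmgs_r = mmgs,
             selected = abs(trait_cors$r) > trait_cut &
               !is.na(mmgs) & mmgs > mmgs_cut,
             stringsAsFactors = FALSE)
}
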