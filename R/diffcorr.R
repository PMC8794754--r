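#' Fisher z-transform of a correlation coefficient
#'
#' `z = (1/2) log((1 + r) / (1 - r)) = atanh(r)`. Correlations at exactly
#' +/-1 are clamped to +/-(1 - 1e-12) with a warning so degenerate
#' noiseless fixtures still run.
#'
#' @param r numeric vector of correlations, |r| <= 1 (up to 1e-9 rounding).
#' @return the transformed values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-9, na.rm = TRUE))
    stop("correlation outside [-1, 1]")
  clamp <- 1 - 1e-12
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("correlation at +/-1 clamped before Fisher transform")
    r <- pmin(pmax(r, -clamp), clamp)
  }
  atanh(r)
}

#' Two-condition differential-correlation test statistic
#'
#' Tests whether a gene pair's correlation differs between conditions:
#' `Z = (z_A - z_B) / sqrt(1/(n_A - 3) + 1/(n_B - 3))` with `z` the Fisher
#' transforms, referred to the standard normal (two-sided).
#'
#' @param rA,rB the pair's Pearson correlation in each condition.
#' @param nA,nB per-condition sample sizes; must exceed 3.
#' @return list with `Z`, `p`, and the transforms `zA`, `zB`.
#' @export
diff_corr_statistic <- function(rA, rB, nA, nB) {
  if (any(c(nA, nB) <= 3)) stop("need > 3 samples per condition")
  zA <- fisher_z(rA)
  zB <- fisher_z(rB)
  Z <- (zA - zB) / sqrt(1 / (nA - 3) + 1 / (nB - 3))
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)), zA = zA, zB = zB)
}

#' All pairwise differential correlations within a gene set
#'
#' Computes each unordered pair's Pearson correlation separately in the
#' condition-A and condition-B samples and the Fisher z difference test.
#' Genes with zero variance in either condition are skipped with a warning.
#'
#' @param ds an [expression_dataset()].
#' @param genes gene ids to analyze (default: all).
#' @param module optional module label stored on every record.
#' @return data.frame of records: `molecule_X`, `molecule_Y`, `r1`
#'   (condition A), `r2` (condition B), `zA`, `zB`, `Z`, `p`, `lfdr` (NA
#'   until [local_fdr()]), `module`.
#' @export
pairwise_differential_correlations <- function(ds, genes = NULL,
                                               module = NA_character_) {
  stopifnot(inherits(ds, "expression_dataset"))
  genes <- genes %||% ds$gene_ids
  missing <- setdiff(genes, ds$gene_ids)
  if (length(missing)) stop("unknown gene: ", missing[1])
  xA <- condition_matrix(ds, "A")[genes, , drop = FALSE]
  xB <- condition_matrix(ds, "B")[genes, , drop = FALSE]
  nA <- ncol(xA); nB <- ncol(xB)
  if (nA < 4 || nB < 4) stop("need >= 4 samples in each condition")
  vA <- apply(xA, 1, stats::var, na.rm = TRUE)
  vB <- apply(xB, 1, stats::var, na.rm = TRUE)
  bad <- vA == 0 | vB == 0 | is.na(vA) | is.na(vB)
  if (any(bad)) {
    warning("skipping degenerate gene(s): ",
            paste(genes[bad], collapse = ", "))
    genes <- genes[!bad]
    xA <- xA[!bad, , drop = FALSE]; xB <- xB[!bad, , drop = FALSE]
  }
  if (length(genes) < 2) stop("fewer than 2 usable genes")
  cA <- stats::cor(t(xA), use = "pairwise.complete.obs")
  cB <- stats::cor(t(xB), use = "pairwise.complete.obs")
  idx <- which(upper.tri(cA), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  r1 <- cA[idx]; r2 <- cB[idx]
  st <- diff_corr_statistic(r1, r2, nA, nB)
  data.frame(molecule_X = genes[idx[, "row"]],
             molecule_Y = genes[idx[, "col"]],
             r1 = r1, r2 = r2, zA = st$zA, zB = st$zB,
             Z = st$Z, p = st$p, lfdr = NA_real_,
             module = module, stringsAsFactors = FALSE)
}

#' Local false discovery rate for differential-correlation records
#'
#' Efron-style empirical-null estimation on the Z statistics: the marginal
#' density f(z) is fit by Poisson regression of histogram counts on a
#' natural-spline basis; the null component (mean, sd and proportion pi0)
#' is obtained by central matching — a quadratic fit to log f on the
#' central interquartile z-range — and `lfdr(z) = pi0 * phi0(z) / f(z)`,
#' clipped to \[0, 1\]. With fewer than 100 records (too few for density
#' estimation) the method falls back to Benjamini-Hochberg adjusted
#' p-values stored in the same column, flagged in the `lfdr_method`
#' attribute.
#'
#' @param records data.frame from [pairwise_differential_correlations()].
#' @param method `"empirical-null"` (default) or `"BH"`.
#' @param bins,spline_df tuning of the density fit.
#' @return `records` with `lfdr` filled; attribute `lfdr_method` records
#'   which estimator was used.
#' @export
local_fdr <- function(records, method = c("empirical-null", "BH"),
                      bins = 120, spline_df = 7) {
  method <- match.arg(method)
  z <- records$Z
  if (length(unique(z)) < 2) stop("all Z statistics identical")
  if (method == "empirical-null" && nrow(records) < 100) {
    warning("fewer than 100 records; falling back to BH adjusted p-values")
    method <- "BH"
  }
  if (method == "BH") {
    records$lfdr <- stats::p.adjust(records$p, method = "BH")
    attr(records, "lfdr_method") <- "BH"
    return(records)
  }
  est <- empirical_null_lfdr(z, bins = bins, spline_df = spline_df)
  records$lfdr <- est$lfdr
  attr(records, "lfdr_method") <- "empirical-null"
  attr(records, "null_params") <- est$null
  records
}

empirical_null_lfdr <- function(z, bins = 120, spline_df = 7) {
  n <- length(z)
  rng <- range(z)
  rng <- rng + c(-1, 1) * 1e-8 * max(1, diff(rng))
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  counts <- tabulate(cut(z, breaks, include.lowest = TRUE), nbins = bins)
  dfree <- min(spline_df, max(3, sum(counts > 0) - 2))
  fit <- suppressWarnings(
    stats::glm(counts ~ splines::ns(mids, df = dfree),
               family = stats::poisson()))   # zero bins warn benignly
  width <- diff(breaks)[1]
  f_mid <- pmax(stats::fitted(fit), 1e-10) / (n * width)  # marginal density
  log_f <- log(f_mid)
  # central matching: quadratic in z on the interquartile range
  qs <- stats::quantile(z, c(0.25, 0.75))
  central <- mids >= qs[1] & mids <= qs[2] & counts > 0
  null <- list(mean = 0, sd = 1, pi0 = 1)
  ok <- FALSE
  if (sum(central) >= 5) {
    quad <- stats::lm(log_f[central] ~ mids[central] + I(mids[central]^2))
    b <- stats::coef(quad)
    if (!any(is.na(b)) && b[3] < 0) {
      sd0 <- sqrt(-1 / (2 * b[3]))
      mu0 <- b[2] * sd0^2
      pi0 <- exp(b[1] + mu0^2 / (2 * sd0^2)) * sqrt(2 * pi) * sd0
      null <- list(mean = unname(mu0), sd = unname(sd0),
                   pi0 = min(1, unname(pi0)))
      ok <- TRUE
    }
  }
  if (!ok) {
    # degenerate central fit: assume the theoretical N(0,1) null
    null$pi0 <- min(1, stats::median(
      stats::dnorm(z) / pmax(approx_density(mids, f_mid, z), 1e-10)))
  }
  f_z <- approx_density(mids, f_mid, z)
  lfdr <- null$pi0 * stats::dnorm(z, null$mean, null$sd) / pmax(f_z, 1e-300)
  list(lfdr = pmin(1, pmax(0, lfdr)), null = null)
}

approx_density <- function(x, fx, at) {
  stats::approx(x, fx, xout = at, rule = 2)$y
}

#' Cluster genes into eigen-molecule groups
#'
#' Average-linkage hierarchical clustering of genes on distance
#' `1 - r` (pooled-condition Pearson correlation), cut at height `cutoff`;
#' each cluster is summarized by its first principal component,
#' sign-aligned as in [module_eigengenes()].
#'
#' @param ds an [expression_dataset()].
#' @param genes gene ids to cluster (>= 2).
#' @param cutoff tree cut height on the 1 - r scale (default 0.6).
#' @return list with `cluster` (named gene -> integer id) and `profiles`
#'   (samples x clusters matrix of first-PC scores).
#' @export
eigen_molecule_clusters <- function(ds, genes = NULL, cutoff = 0.6) {
  stopifnot(inherits(ds, "expression_dataset"))
  genes <- genes %||% ds$gene_ids
  if (length(genes) < 2) stop("need >= 2 genes to cluster")
  x <- ds$values[genes, , drop = FALSE]
  d <- 1 - stats::cor(t(x), use = "pairwise.complete.obs")
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(tree, h = cutoff)
  profiles <- vapply(sort(unique(cl)), function(g) {
    xs <- t(scale(t(x[cl == g, , drop = FALSE])))
    xs[is.na(xs)] <- 0
    if (nrow(xs) == 1) return(as.numeric(xs))
    sv <- svd(t(xs), nu = 1, nv = 0)
    score <- sv$u[, 1] * sv$d[1]
    if (stats::sd(score) > 0) score <- score / stats::sd(score)
    if (sum(score * colMeans(xs)) < 0) score <- -score
    score
  }, numeric(ncol(x)))
  colnames(profiles) <- paste0("C", sort(unique(cl)))
  rownames(profiles) <- ds$sample_ids
  list(cluster = cl, profiles = profiles)
}

#' Top significantly differential pairs
#'
#' Filters records to `lfdr < fdr_cut`, sorts by (lfdr ascending, |Z|
#' descending, then gene ids), and returns the first `k` in the Table-1
#' column order.
#'
#' @param records records with `lfdr` filled by [local_fdr()].
#' @param k number of pairs to keep (default 10).
#' @param fdr_cut lfdr threshold (default 0.05).
#' @return data.frame `molecule_X`, `molecule_Y`, `r1`, `r2`, `lfdr`,
#'   `module` (plus `Z`, `p` as trailing columns).
#' @export
top_differential_pairs <- function(records, k = 10, fdr_cut = 0.05) {
  if (all(is.na(records$lfdr))) stop("run local_fdr() first")
  keep <- records[!is.na(records$lfdr) & records$lfdr < fdr_cut, ]
  ord <- order(keep$lfdr, -abs(keep$Z), keep$molecule_X, keep$molecule_Y)
  keep <- keep[ord, , drop = FALSE]
  keep <- utils::head(keep, k)
  rownames(keep) <- NULL
  keep[, c("molecule_X", "molecule_Y", "r1", "r2", "lfdr", "module",
           "Z", "p")]
}
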