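test_that("correlation matrix matches the textbook formula", {
  ds <- toy_dataset(5, 4, 5)
  cm <- correlation_matrix(ds)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(cm[i, j],
                 naive_pearson(ds$values[i, ], ds$values[j, ]),
                 tolerance = 1e-12)
  expect_equal(unname(diag(cm)), rep(1, 5))
  # perfectly anti-correlated pair
  anti <- expression_dataset(rbind(g1 = 1:6, g2 = -(1:6) + 0.5),
                             rep(c("A", "B"), 3))
  expect_equal(correlation_matrix(anti)["g1", "g2"], -1, tolerance = 1e-12)
  bad <- toy_dataset(3, 3, 3)
  bad$values[2, ] <- 7
  expect_error(correlation_matrix(bad), "g2")
})

test_that("bicor agrees with Pearson on clean data and falls back on MAD 0", {
  ds <- toy_dataset(6, 20, 20, seed = 1)
  cb <- correlation_matrix(ds, "bicor")
  cp <- correlation_matrix(ds, "pearson")
  expect_lt(max(abs(cb - cp)), 0.15)
  expect_equal(unname(diag(cb)), rep(1, 6), tolerance = 1e-9)
  ds$values[3, ] <- rep(c(0, 0, 0, 100), 10)   # MAD 0 but nonzero variance
  expect_warning(correlation_matrix(ds, "bicor"), "MAD")
})

test_that("adjacency follows the power function and is monotone in beta", {
  cm <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(adjacency_matrix(cm, 3)[1, 2], 0.125)
  cm[1, 2] <- cm[2, 1] <- -0.5
  expect_equal(adjacency_matrix(cm, 3)[1, 2], 0.125)   # unsigned: |r|^beta
  expect_equal(adjacency_matrix(cm, 3, signed = TRUE)[1, 2], 0.25^3)
  set.seed(10)
  r <- matrix(runif(100, -1, 1), 10); r <- (r + t(r)) / 2; diag(r) <- 1
  expect_equal(adjacency_matrix(r, 1), abs(r) - diag(1, 10),
               tolerance = 1e-12)
  for (beta in 2:6)
    expect_true(all(adjacency_matrix(r, beta) <=
                      adjacency_matrix(r, beta - 1) + 1e-15))
})

test_that("TOM matches hand computation and the brute-force oracle", {
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  expect_equal(tom_similarity(a)[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5))
  # two genes connected only to each other: TOM = x
  b <- matrix(0, 4, 4); b[1, 2] <- b[2, 1] <- 0.37
  expect_equal(tom_similarity(b)[1, 2], 0.37)
  for (seed in 1:50) {
    n <- sample(3:20, 1)
    a <- random_adjacency(n, seed)
    expect_equal(tom_similarity(a), naive_tom(a), tolerance = 1e-12)
  }
})

test_that("scale-free fit index honors its sign convention", {
  # connectivity concentrated at equally spaced bin centers with counts
  # proportional to 1/k: log10(freq) exactly linear in log10(k), slope < 0
  k_centers <- c(10, 20, 30, 40)
  k <- rep(k_centers, 1200 / k_centers)        # counts 120, 60, 40, 30
  expect_equal(scale_free_fit_index(k, n_bins = 4), 1, tolerance = 1e-10)
  # counts proportional to k: exactly linear with positive slope
  k_inc <- rep(k_centers, k_centers)
  expect_equal(scale_free_fit_index(k_inc, n_bins = 4), -1, tolerance = 1e-10)
  expect_warning(res <- scale_free_fit_index(rep(2, 10)), "constant")
  expect_equal(res, 0)
})

test_that("scale-free fit equals an independent least-squares oracle", {
  set.seed(3)
  k <- runif(1000, 0.1, 50)
  got <- scale_free_fit_index(k, n_bins = 10)
  # independent re-derivation: equal-width bins, lm on log10 means
  bin <- cut(k, seq(min(k), max(k), length.out = 11), include.lowest = TRUE)
  freq <- as.numeric(table(bin)) / length(k)
  mk <- tapply(k, bin, mean)
  keep <- freq > 0
  fit <- summary(lm(log10(freq[keep]) ~ log10(mk[keep])))
  expect_equal(abs(got), fit$r.squared, tolerance = 1e-10)
})

test_that("soft-threshold choice follows the scale-free criterion", {
  # strict hub fixture following p(k) ~ k^-1: target reached already there
  k <- rep(c(5, 10, 20, 40), round(400 / c(5, 10, 20, 40)))
  expect_gte(scale_free_fit_index(k), 0.9)
  # on generator data mean connectivity strictly decreases with beta
  sim <- simulate_two_condition(sim_config(seed = 4))
  cm <- correlation_matrix(sim$dataset)
  sft <- suppressWarnings(pick_soft_threshold(cm, powers = 1:12))
  expect_true(all(diff(sft$table$mean_k) < 0))
  expect_true(sft$power %in% 1:12)
  expect_identical(sft$power,
                   if (sft$reached_target)
                     sft$table$power[which(sft$table$fit_R2 >= 0.9)[1]]
                   else sft$table$power[which.max(sft$table$fit_R2)])
})

test_that("average-linkage dendrogram matches the naive oracle", {
  # two perfect blocks with no cross overlap: top split separates them
  tom <- diag(6)
  tom[1:3, 1:3] <- 0.9; tom[4:6, 4:6] <- 0.9; diag(tom) <- 1
  rownames(tom) <- colnames(tom) <- paste0("g", 1:6)
  dend <- cluster_genes(tom)
  top2 <- cutree(dend, k = 2)
  expect_equal(length(unique(top2[1:3])), 1)
  expect_equal(length(unique(top2[4:6])), 1)
  expect_false(top2[1] == top2[4])
  # merge heights equal the O(n^3) oracle
  set.seed(5)
  a <- random_adjacency(6, 77)
  tom <- tom_similarity(a)
  d <- 1 - tom
  dend <- cluster_genes(tom)
  expect_equal(sort(dend$height), naive_average_linkage_heights(d),
               tolerance = 1e-10)
  single <- cluster_genes(matrix(1, 1, 1, dimnames = list("g1", "g1")))
  expect_equal(length(single$order), 1)
})

test_that("module cut recovers planted modules and handles edge cases", {
  sim <- simulate_two_condition(sim_config(seed = 1))
  cm <- correlation_matrix(sim$dataset)
  sft <- suppressWarnings(pick_soft_threshold(cm))
  tom <- tom_similarity(adjacency_matrix(cm, sft$power))
  dend <- cluster_genes(tom)
  mods <- cut_modules(dend, minModuleSize = 30, deepSplit = 2)
  truth <- sim$truth$module_of_gene
  expect_gte(adjusted_rand_index(mods, truth), 0.9)
  expect_setequal(setdiff(unique(mods), "grey"), c("M1", "M2"))
  # minModuleSize beyond n: everything grey
  all_grey <- cut_modules(dend, minModuleSize = 1000)
  expect_true(all(all_grey == "grey"))
  # pure noise: >= 90% grey
  noise <- simulate_null_dataset(120, 30, 30, seed = 2)
  cmn <- correlation_matrix(noise)
  tomn <- tom_similarity(adjacency_matrix(cmn, 6))
  modsn <- cut_modules(cluster_genes(tomn), minModuleSize = 30)
  expect_gte(mean(modsn == "grey"), 0.9)
  expect_error(cut_modules(NULL), "empty dendrogram")
})

test_that("module eigengene is the first PC, sign-aligned and permutation-invariant", {
  set.seed(6)
  v <- rnorm(20)
  x <- matrix(rep(v, each = 5), 5, byrow = FALSE)
  x <- t(replicate(5, v))
  rownames(x) <- paste0("g", 1:5)
  colnames(x) <- paste0("s", 1:20)
  ds <- expression_dataset(x + 0, rep(c("A", "B"), 10))
  mods <- setNames(rep("M1", 5), rownames(x))
  me <- module_eigengenes(ds, mods)
  expect_equal(me$var_explained[["M1"]], 1, tolerance = 1e-12)
  expect_equal(cor(me$eigengenes[, "M1"], v), 1, tolerance = 1e-12)
  # two genes v and -v: variance explained still 1
  ds2 <- expression_dataset(rbind(g1 = v, g2 = -v), rep(c("A", "B"), 10))
  me2 <- module_eigengenes(ds2, setNames(c("M1", "M1"), c("g1", "g2")))
  expect_equal(me2$var_explained[["M1"]], 1, tolerance = 1e-12)
  # permuting genes within the module leaves the eigengene unchanged
  sim <- simulate_two_condition(sim_config(seed = 2))
  truth <- sim$truth$module_of_gene
  mods <- setNames(ifelse(truth > 0, paste0("M", truth), "grey"),
                   names(truth))
  me_a <- module_eigengenes(sim$dataset, mods)
  perm <- sample(names(mods))
  me_b <- module_eigengenes(sim$dataset, mods[perm])
  expect_equal(me_a$eigengenes, me_b$eigengenes, tolerance = 1e-10)
  # factor-model module: eigengene tracks the latent factor
  expect_gte(abs(cor(me_a$eigengenes[, "M1"],
                     sim$truth$factor_scores[, 1])), 0.95)
})

test_that("modules from one latent factor merge; orthogonal ones do not", {
  shared <- simulate_two_condition(
    sim_config(n_genes = 120, module_sizes = c(40, 40),
               module_trait_cor = c(0.6, 0.6), module_factors = c(1, 1),
               n_switched_pairs = 0, seed = 9))
  truth <- shared$truth$module_of_gene
  mods <- setNames(ifelse(truth > 0, paste0("M", truth), "grey"),
                   names(truth))
  merged <- merge_close_modules(shared$dataset, mods)
  expect_equal(ncol(merged$eigengenes$eigengenes), 1)
  distinct <- simulate_two_condition(
    sim_config(n_genes = 120, module_sizes = c(40, 40),
               module_trait_cor = c(0, 0), n_switched_pairs = 0, seed = 9))
  truth2 <- distinct$truth$module_of_gene
  mods2 <- setNames(ifelse(truth2 > 0, paste0("M", truth2), "grey"),
                    names(truth2))
  merged2 <- merge_close_modules(distinct$dataset, mods2)
  expect_equal(ncol(merged2$eigengenes$eigengenes), 2)
  expect_identical(sort(unique(merged2$modules)), sort(unique(mods2)))
  # single module: identity
  one <- merge_close_modules(shared$dataset, merged$modules,
                             merged$eigengenes)
  expect_identical(one$modules, merged$modules)
})

test_that("module-trait correlation uses the exact t transform", {
  trait <- c(0, 0, 0, 1, 1, 1)
  mes <- list(eigengenes = cbind(M1 = c(0.1, -0.2, 0.05, 0.9, 1.1, 0.7)))
  got <- module_trait_correlation(mes, trait)
  r <- cor(mes$eigengenes[, 1], trait)
  t_or <- r * sqrt(4 / (1 - r^2))
  expect_equal(got$p, 2 * pt(-abs(t_or), 4), tolerance = 1e-10)
  mes$eigengenes <- cbind(M1 = trait)
  expect_equal(module_trait_correlation(mes, trait)$r, 1, tolerance = 1e-12)
  expect_error(module_trait_correlation(mes, rep(1, 6)), "constant")
})

test_that("MM and GS behave at their fixed points and correlate on planted data", {
  sim <- simulate_two_condition(sim_config(seed = 3))
  ds <- sim$dataset
  trait <- as.integer(ds$condition == "B")
  truth <- sim$truth$module_of_gene
  mods <- setNames(ifelse(truth > 0, paste0("M", truth), "grey"),
                   names(truth))
  mes <- module_eigengenes(ds, mods)
  # plant a gene equal to its eigengene and one equal to the trait
  ds$values["g0001", ] <- mes$eigengenes[, "M1"]
  ds$values["g0002", ] <- trait
  stats <- gene_module_stats(ds, mods, mes, trait)
  expect_equal(stats$MM[stats$gene == "g0001"], 1, tolerance = 1e-6)
  expect_equal(abs(stats$GS[stats$gene == "g0002"]), 1, tolerance = 1e-12)
  mmgs <- mm_gs_correlation(gene_module_stats(sim$dataset, mods, mes, trait))
  expect_gt(mmgs[["M1"]], 0.5)
  expect_gt(mmgs[["M2"]], 0.5)
})

test_that("module selection applies both strict thresholds", {
  trait_cors <- data.frame(module = c("turquoise", "purple", "edge"),
                           r = c(0.77, 0.52, 0.50))
  mmgs <- c(turquoise = 0.87, purple = 0.38, edge = 0.9)
  sel <- select_significant_modules(trait_cors, mmgs)
  expect_identical(sel$selected, c(TRUE, FALSE, FALSE))
})
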