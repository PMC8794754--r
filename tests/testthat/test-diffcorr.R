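test_that("fisher_z is atanh with clamping at the boundary", {
  grid <- seq(-0.999, 0.999, by = 0.003)
  expect_equal(fisher_z(grid), atanh(grid), tolerance = 1e-12)
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(-grid), -fisher_z(grid), tolerance = 1e-14)
  expect_equal(fisher_z(0.7333939), 0.936033, tolerance = 1e-5)
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_true(is.finite(z1))
  expect_error(fisher_z(1.01), "outside")
})

test_that("difference statistic matches the independent formula", {
  # published example pair: r1 = -0.6314071 (normal), r2 = 0.7333939 (tumor)
  got <- diff_corr_statistic(-0.6314071, 0.7333939, 100, 300)
  oracle_z <- (0.5 * log((1 - 0.6314071) / (1 + 0.6314071)) -
                 0.5 * log((1 + 0.7333939) / (1 - 0.7333939))) /
    sqrt(1 / 97 + 1 / 297)
  expect_equal(got$Z, oracle_z, tolerance = 1e-6)
  expect_equal(abs(got$Z), 14.36, tolerance = 0.01)
  expect_lt(got$p, 1e-15)
  # equal correlations: Z = 0, p = 1
  same <- diff_corr_statistic(0.4, 0.4, 10, 20)
  expect_equal(same$Z, 0)
  expect_equal(same$p, 1)
  # antisymmetry under swapping conditions
  set.seed(1)
  for (i in 1:20) {
    rA <- runif(1, -0.95, 0.95); rB <- runif(1, -0.95, 0.95)
    nA <- sample(5:200, 1); nB <- sample(5:200, 1)
    fwd <- diff_corr_statistic(rA, rB, nA, nB)
    rev <- diff_corr_statistic(rB, rA, nB, nA)
    expect_equal(fwd$Z, -rev$Z, tolerance = 1e-12)
    expect_equal(fwd$p, rev$p, tolerance = 1e-12)
  }
  expect_error(diff_corr_statistic(0.1, 0.2, 3, 10), "> 3 samples")
})

test_that("type-I error is calibrated and power is monotone", {
  # 10^4 independent null pairs at n = 100 / 300
  ds <- simulate_null_dataset(200, 100, 300, seed = 17)
  rec <- pairwise_differential_correlations(ds)
  expect_gte(nrow(rec), 1e4)
  rate <- mean(rec$p < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
  # power non-decreasing in |rho_A - rho_B| at fixed n (tolerance 0.03)
  power_at <- function(delta, reps = 2000, n = 60) {
    set.seed(1000 + round(100 * delta))
    hits <- 0
    rho <- delta / 2
    for (i in seq_len(reps)) {
      a1 <- rnorm(n); a2 <- -rho * a1 + sqrt(1 - rho^2) * rnorm(n)
      b1 <- rnorm(n); b2 <- rho * b1 + sqrt(1 - rho^2) * rnorm(n)
      p <- diff_corr_statistic(cor(a1, a2), cor(b1, b2), n, n)$p
      hits <- hits + (p < 0.05)
    }
    hits / reps
  }
  pw <- vapply(c(0, 0.2, 0.4, 0.6), power_at, numeric(1))
  expect_true(all(diff(pw) > -0.03))
  expect_gt(pw[4], pw[1])
})

test_that("pairwise records cover all pairs and carry the module label", {
  ds <- toy_dataset(5, 8, 8)
  rec <- pairwise_differential_correlations(ds, module = "pink")
  expect_equal(nrow(rec), 10)
  expect_true(all(rec$module == "pink"))
  expect_true(all(rec$molecule_X < rec$molecule_Y))
  # r1/r2 really are per-condition correlations
  xA <- condition_matrix(ds, "A")
  expect_equal(rec$r1[rec$molecule_X == "g1" & rec$molecule_Y == "g2"],
               cor(xA["g1", ], xA["g2", ]), tolerance = 1e-12)
  # degenerate gene skipped with warning
  ds$values[3, ds$condition == "A"] <- 5
  expect_warning(rec2 <- pairwise_differential_correlations(ds), "g3")
  expect_equal(nrow(rec2), 6)
  expect_error(pairwise_differential_correlations(toy_dataset(5, 3, 8)),
               ">= 4 samples")
})

test_that("planted switched pairs reach tiny p-values", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_two_condition(
      sim_config(n_genes = 30, module_sizes = integer(0),
                 module_trait_cor = numeric(0),
                 module_factors = integer(0),
                 n_switched_pairs = 1, switch_strength = 0.7, seed = s))
    sp <- sim$truth$switched_pairs[1, ]
    rec <- pairwise_differential_correlations(
      sim$dataset, c(sp$geneX, sp$geneY))
    rec$p < 1e-6
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("lfdr separates null from planted signal", {
  ds <- simulate_null_dataset(150, 100, 300, seed = 23)
  rec <- local_fdr(pairwise_differential_correlations(ds))
  expect_identical(attr(rec, "lfdr_method"), "empirical-null")
  expect_gte(mean(rec$lfdr > 0.2), 0.95)
  # planted strong switches among module-style nulls
  sim <- simulate_two_condition(sim_config(seed = 31))
  genes <- c(names(sim$truth$module_of_gene)[sim$truth$module_of_gene == 1],
             sim$truth$switched_pairs$geneX[1:5],
             sim$truth$switched_pairs$geneY[1:5])
  rec2 <- local_fdr(pairwise_differential_correlations(sim$dataset,
                                                       unique(genes)))
  planted <- pair_key(sim$truth$switched_pairs$geneX[1:5],
                      sim$truth$switched_pairs$geneY[1:5])
  keys <- pair_key(rec2$molecule_X, rec2$molecule_Y)
  expect_true(all(rec2$lfdr[keys %in% planted] < 0.05))
  expect_error(local_fdr(data.frame(Z = rep(1, 200), p = rep(1, 200))),
               "identical")
})

test_that("BH fallback reproduces the step-up adjustment", {
  rec <- data.frame(molecule_X = letters[1:4], molecule_Y = LETTERS[1:4],
                    Z = c(2.5, 2.3, 2.1, 2.0),
                    p = c(0.01, 0.02, 0.03, 0.04), lfdr = NA_real_)
  expect_warning(out <- local_fdr(rec), "fewer than 100")
  expect_identical(attr(out, "lfdr_method"), "BH")
  expect_equal(out$lfdr, rep(0.04, 4), tolerance = 1e-12)
})

test_that("eigen-molecule clustering respects the 1 - r cutoff", {
  set.seed(12)
  base <- rnorm(60)
  x <- rbind(g1 = base + 0.2 * rnorm(60),      # r ~ 0.98 with g2
             g2 = base + 0.2 * rnorm(60),
             g3 = rnorm(60))                   # near-zero r
  ds <- expression_dataset(x, rep(c("A", "B"), 30))
  cl <- eigen_molecule_clusters(ds, cutoff = 0.6)
  expect_identical(cl$cluster[["g1"]], cl$cluster[["g2"]])
  expect_false(cl$cluster[["g3"]] == cl$cluster[["g1"]])
  expect_equal(ncol(cl$profiles), length(unique(cl$cluster)))
  # planted factor groups recovered
  sim <- simulate_two_condition(
    sim_config(n_genes = 60, module_sizes = c(25, 25),
               module_trait_cor = c(0, 0), n_switched_pairs = 0, seed = 13))
  truth <- sim$truth$module_of_gene
  genes <- names(truth)[truth > 0]
  cl2 <- eigen_molecule_clusters(sim$dataset, genes, cutoff = 0.6)
  expect_gte(adjusted_rand_index(cl2$cluster, truth[genes]), 0.8)
  expect_error(eigen_molecule_clusters(ds, "g1"), ">= 2 genes")
})

test_that("top pairs are filtered, ranked and column-ordered", {
  sim <- simulate_two_condition(sim_config(seed = 37))
  truth <- sim$truth
  genes <- unique(c(names(truth$module_of_gene)[truth$module_of_gene == 1][1:15],
                    truth$switched_pairs$geneX[1:3],
                    truth$switched_pairs$geneY[1:3]))
  rec <- local_fdr(pairwise_differential_correlations(sim$dataset, genes))
  top <- top_differential_pairs(rec, k = 10)
  expect_identical(names(top)[1:6],
                   c("molecule_X", "molecule_Y", "r1", "r2", "lfdr",
                     "module"))
  expect_true(all(top$lfdr < 0.05))
  expect_true(!is.unsorted(top$lfdr))
  planted <- pair_key(truth$switched_pairs$geneX[1:3],
                      truth$switched_pairs$geneY[1:3])
  expect_true(all(planted %in% pair_key(top$molecule_X, top$molecule_Y)[1:3]))
  expect_equal(nrow(top_differential_pairs(rec, k = 0)), 0)
  few <- top_differential_pairs(rec, k = 1e6)
  expect_equal(nrow(few), sum(rec$lfdr < 0.05))
})
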