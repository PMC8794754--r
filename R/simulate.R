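#' Configuration for the two-condition expression simulator
#'
#' The generator plants the structures the downstream analysis assumes:
#' latent-factor co-expression modules whose factor is shifted between
#' conditions (so the module correlates with the tumor/normal trait),
#' "switching" gene pairs whose correlation sign flips between conditions,
#' background noise genes, and (separately, via [simulate_survival()])
#' survival times driven by one gene's expression.
#'
#' Switched pairs are organized into hubs: each hub gene is paired with
#' `switch_hub_size` partner genes that load on the hub's private factor
#' with a condition-dependent sign (negative in condition A, positive in
#' condition B), so each (hub, partner) pair flips sign while the hub
#' accumulates network degree — the pattern seen around dominant genes in
#' real differential-correlation networks.
#'
#' @param n_genes total number of genes.
#' @param n_samples_A,n_samples_B samples per condition (A = normal,
#'   B = tumor); both must be >= 4 because the Fisher z variance needs
#'   n - 3 > 0.
#' @param module_sizes integer vector of planted module sizes.
#' @param module_trait_cor per-module target correlation of the module's
#'   latent factor with the condition indicator, each in \[-1, 1\].
#' @param module_factors integer vector mapping modules to latent factors
#'   (default: one private factor per module). Two modules sharing a factor
#'   produce eigengenes correlated enough to be merged downstream.
#' @param n_switched_pairs number of planted sign-flip gene pairs.
#' @param switch_hub_size partners per hub gene (default 5).
#' @param switch_strength target |population correlation| of each switched
#'   pair in each condition, in (0, 1).
#' @param noise_sd standard deviation of per-gene additive noise on module
#'   genes (latent factors have unit variance, so 0.3 gives strong modules).
#' @param background_fraction optional; if given, `n_genes` is enlarged so
#'   this fraction of genes is unassigned background noise.
#' @param seed integer seed; all randomness flows from it through named
#'   substreams, so e.g. adding background genes does not perturb module
#'   draws.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 200, n_samples_A = 100, n_samples_B = 300,
                       module_sizes = c(50, 50),
                       module_trait_cor = c(0.7, -0.7),
                       module_factors = seq_along(module_sizes),
                       n_switched_pairs = 10, switch_hub_size = 5,
                       switch_strength = 0.7, noise_sd = 0.3,
                       background_fraction = NULL, seed = 1) {
  n_genes <- check_count(n_genes, "n_genes", 1L)
  n_samples_A <- check_count(n_samples_A, "n_samples_A", 4L)
  n_samples_B <- check_count(n_samples_B, "n_samples_B", 4L)
  n_switched_pairs <- check_count(n_switched_pairs, "n_switched_pairs", 0L)
  switch_hub_size <- check_count(switch_hub_size, "switch_hub_size", 1L)
  if (length(module_sizes) && any(module_sizes < 2))
    stop_field("module_sizes", "each module needs >= 2 genes")
  if (length(module_trait_cor) != length(module_sizes))
    stop_field("module_trait_cor", "must have one entry per module")
  if (any(abs(module_trait_cor) > 1))
    stop_field("module_trait_cor", "entries must lie in [-1, 1]")
  if (length(module_factors) != length(module_sizes))
    stop_field("module_factors", "must have one entry per module")
  if (switch_strength <= 0 || switch_strength >= 1)
    stop_field("switch_strength", "must lie strictly in (0, 1)")
  if (noise_sd < 0) stop_field("noise_sd", "must be non-negative")
  n_hubs <- if (n_switched_pairs > 0)
    ceiling(n_switched_pairs / switch_hub_size) else 0L
  n_switch_genes <- n_hubs + n_switched_pairs
  n_structured <- sum(module_sizes) + n_switch_genes
  if (!is.null(background_fraction)) {
    if (background_fraction < 0 || background_fraction >= 1)
      stop_field("background_fraction", "must lie in [0, 1)")
    n_genes <- max(n_genes,
                   as.integer(ceiling(n_structured / (1 - background_fraction))))
  }
  if (n_structured > n_genes)
    stop_field("n_genes",
               sprintf("need >= %d genes for %d module genes + %d switch genes",
                       n_structured, sum(module_sizes), n_switch_genes))
  structure(
    list(n_genes = n_genes, n_samples_A = n_samples_A,
         n_samples_B = n_samples_B, module_sizes = as.integer(module_sizes),
         module_trait_cor = module_trait_cor,
         module_factors = as.integer(module_factors),
         n_switched_pairs = n_switched_pairs,
         switch_hub_size = switch_hub_size,
         switch_strength = switch_strength, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a two-condition expression dataset with planted structure
#'
#' Module genes follow `x_ij = a_i * f_m(j) + noise`, with the module's
#' latent factor `f_m` a unit-variance mixture of a shared Gaussian and the
#' standardized condition indicator, weighted to hit `module_trait_cor`.
#' Each switched (hub, partner) pair shares the hub's private factor; the
#' partner's loading is negative in condition A and positive in condition B,
#' with noise sized so the pair's population correlation is
#' `-switch_strength` in A and `+switch_strength` in B. Background genes are
#' i.i.d. standard normal. Output is a pure function of `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (an [expression_dataset()]) and `truth`, a
#'   list with `module_of_gene` (named integer, 0 = background),
#'   `switched_pairs` (data.frame geneX, geneY, sign_A, sign_B),
#'   `hub_genes`, `factor_scores` (sample x module matrix of the latent
#'   factors) and `survival_driver_gene` (NA here; see
#'   [simulate_survival()]).
#' @export
simulate_two_condition <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nA <- config$n_samples_A; nB <- config$n_samples_B
  n <- nA + nB
  trait <- c(rep(0, nA), rep(1, nB))
  t_std <- (trait - mean(trait)) / stats::sd(trait)
  sample_ids <- c(sprintf("N%03d", seq_len(nA)), sprintf("T%03d", seq_len(nB)))
  gene_pool <- sprintf("g%04d", seq_len(config$n_genes))
  x <- matrix(NA_real_, config$n_genes, n,
              dimnames = list(gene_pool, sample_ids))
  module_of_gene <- stats::setNames(rep(0L, config$n_genes), gene_pool)

  # shared latent factors (one RNG substream per factor id)
  n_modules <- length(config$module_sizes)
  factor_g <- lapply(sort(unique(config$module_factors)), function(fid)
    with_seed(substream_seed(config$seed, paste0("factor", fid)),
              stats::rnorm(n)))
  names(factor_g) <- as.character(sort(unique(config$module_factors)))

  gi <- 0L
  factor_scores <- matrix(NA_real_, n, n_modules,
                          dimnames = list(sample_ids,
                                          sprintf("module%d",
                                                  seq_len(n_modules))))
  for (m in seq_len(n_modules)) {
    rho <- config$module_trait_cor[m]
    g <- factor_g[[as.character(config$module_factors[m])]]
    f <- sqrt(1 - rho^2) * g + rho * t_std
    factor_scores[, m] <- f
    sz <- config$module_sizes[m]
    idx <- gi + seq_len(sz)
    draws <- with_seed(substream_seed(config$seed, paste0("module", m)), {
      list(load = stats::runif(sz, 0.8, 1.2),
           eps = matrix(stats::rnorm(sz * n), sz, n))
    })
    x[idx, ] <- draws$load %o% f + config$noise_sd * draws$eps
    module_of_gene[idx] <- m
    gi <- gi + sz
  }

  # switched hub/partner pairs
  switched <- data.frame(geneX = character(), geneY = character(),
                         sign_A = integer(), sign_B = integer(),
                         stringsAsFactors = FALSE)
  hub_ids <- character(0)
  if (config$n_switched_pairs > 0) {
    s <- config$switch_strength
    sd_e <- sqrt(1 / s - 1)   # so cor = 1 / (1 + sd_e^2) = s
    n_hubs <- ceiling(config$n_switched_pairs / config$switch_hub_size)
    cond_sign <- ifelse(trait == 1, 1, -1)  # partner loading: -u in A, +u in B
    pair <- 0L
    for (h in seq_len(n_hubs)) {
      hub_gene <- gene_pool[gi + 1L]; gi <- gi + 1L
      hub_ids <- c(hub_ids, hub_gene)
      n_part <- min(config$switch_hub_size,
                    config$n_switched_pairs - pair)
      draws <- with_seed(substream_seed(config$seed, paste0("hub", h)), {
        list(u = stats::rnorm(n),
             eps = matrix(stats::rnorm((n_part + 1L) * n), n_part + 1L, n))
      })
      x[hub_gene, ] <- draws$u + sd_e * draws$eps[1L, ]
      for (k in seq_len(n_part)) {
        partner <- gene_pool[gi + 1L]; gi <- gi + 1L
        x[partner, ] <- cond_sign * draws$u + sd_e * draws$eps[k + 1L, ]
        switched <- rbind(switched,
                          data.frame(geneX = hub_gene, geneY = partner,
                                     sign_A = -1L, sign_B = 1L))
        pair <- pair + 1L
      }
    }
  }

  # i.i.d. background
  n_bg <- config$n_genes - gi
  if (n_bg > 0) {
    bg <- with_seed(substream_seed(config$seed, "background"),
                    matrix(stats::rnorm(n_bg * n), n_bg, n))
    x[gi + seq_len(n_bg), ] <- bg
  }

  # per-gene baseline log-intensity, as on a log2 microarray scale; makes
  # inter-sample correlations realistically high without touching any
  # gene-gene correlation
  baseline <- with_seed(substream_seed(config$seed, "baseline"),
                        stats::rnorm(config$n_genes, mean = 6, sd = 2))
  x <- x + baseline

  ds <- expression_dataset(x, rep(c("A", "B"), c(nA, nB)))
  list(dataset = ds,
       truth = list(module_of_gene = module_of_gene,
                    switched_pairs = switched,
                    hub_genes = hub_ids,
                    factor_scores = factor_scores,
                    survival_driver_gene = NA_character_))
}

#' Simulate a structure-free null dataset
#'
#' Every gene is i.i.d. standard normal in both conditions, so no pair has
#' differential correlation by construction; used to calibrate the type-I
#' error of the Fisher z difference test.
#'
#' @param n_genes,n_A,n_B dimensions; `n_A`, `n_B` >= 4.
#' @param seed integer seed.
#' @return an [expression_dataset()] of shape `n_genes x (n_A + n_B)`.
#' @export
simulate_null_dataset <- function(n_genes, n_A, n_B, seed = 1) {
  n_genes <- check_count(n_genes, "n_genes", 1L)
  n_A <- check_count(n_A, "n_A", 4L)
  n_B <- check_count(n_B, "n_B", 4L)
  x <- with_seed(substream_seed(seed, "null"),
                 matrix(stats::rnorm(n_genes * (n_A + n_B)), n_genes))
  dimnames(x) <- list(sprintf("g%04d", seq_len(n_genes)),
                      c(sprintf("N%03d", seq_len(n_A)),
                        sprintf("T%03d", seq_len(n_B))))
  expression_dataset(x, rep(c("A", "B"), c(n_A, n_B)))
}

#' Simulate survival times driven by one gene's expression
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(beta * z)` where `z` is the z-scored expression
#' (proportional hazards by construction); censoring times are independent
#' exponential with rate `censor_rate` (0 = no censoring). The recorded
#' time is the minimum, the event flag is 1 when death precedes censoring.
#'
#' @param expression numeric vector, one value per sample; must be finite.
#' @param beta log hazard ratio per SD of expression (positive = higher
#'   expression, worse survival).
#' @param baseline_rate positive baseline hazard.
#' @param censor_rate non-negative censoring hazard.
#' @param seed integer seed.
#' @return data.frame `sample_id`, `time`, `event`, `expression` (a
#'   SurvivalTable).
#' @export
simulate_survival <- function(expression, beta, baseline_rate = 0.1,
                              censor_rate = 0.05, seed = 1) {
  if (!all(is.finite(expression)))
    stop_field("expression", "must be finite")
  if (baseline_rate <= 0) stop_field("baseline_rate", "must be positive")
  if (censor_rate < 0) stop_field("censor_rate", "must be non-negative")
  n <- length(expression)
  z <- if (stats::sd(expression) > 0)
    (expression - mean(expression)) / stats::sd(expression)
  else rep(0, n)
  with_seed(substream_seed(seed, "survival"), {
    t_event <- stats::rexp(n, rate = baseline_rate * exp(beta * z))
    t_cens <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate)
      else rep(Inf, n)
    data.frame(
      sample_id = names(expression) %||% paste0("s", seq_len(n)),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      expression = as.numeric(expression))
  })
}

#' Write a simulated dataset to the pipeline's input files
#'
#' @param sim result of [simulate_two_condition()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written: `expression.tsv`, `phenotype.tsv`,
#'   `ground_truth.json`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             phenotype = file.path(dir, "phenotype.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_expression(sim$dataset, paths[["expression"]], paths[["phenotype"]])
  truth <- sim$truth
  truth$factor_scores <- NULL   # bulky and reconstructible from the seed
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
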