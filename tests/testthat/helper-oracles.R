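# Independent oracles and fixture builders shared across the test files.
# Each oracle is a deliberately naive implementation of the textbook
# definition, kept structurally unlike the package's code path.

# Topological overlap by triple loop, straight from the definition.
naive_tom <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  k <- rowSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# O(n^3) agglomerative average linkage; returns the sorted merge heights.
naive_average_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1))
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# Pearson correlation from the textbook covariance/sd formula.
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Random symmetric adjacency in [0, 1) with zero diagonal.
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n, 0, 0.95), n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# Canonical unordered-pair keys for recall/precision bookkeeping.
pair_key <- function(x, y) paste(pmin(x, y), pmax(x, y))

# Small deterministic expression fixture: `n_genes` rows of N(0, 1).
toy_dataset <- function(n_genes = 6, n_A = 10, n_B = 12, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * (n_A + n_B)), n_genes)
  rownames(x) <- paste0("g", seq_len(n_genes))
  colnames(x) <- paste0("s", seq_len(n_A + n_B))
  expression_dataset(x, rep(c("A", "B"), c(n_A, n_B)))
}

# The six published clinicopathological 2x2 tables (counts as printed),
# shipped as a plain-text fixture with the package.
clinico_tables <- function() {
  read.delim(system.file("extdata", "clinico_tables.tsv", package = "dcnet"),
             stringsAsFactors = FALSE)
}
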