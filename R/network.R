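#' Detect switching-mechanism gene pairs
#'
#' A pair "switches" when its correlation is at least moderately strong in
#' both conditions but with opposite signs: `r1 * r2 < 0` and
#' `min(|r1|, |r2|) > threshold` (strict). Input order is preserved.
#'
#' @param records data.frame carrying `molecule_X`, `molecule_Y`, `r1`,
#'   `r2` (and optionally `module`).
#' @param threshold strict |r| threshold applied in both conditions
#'   (default 0.5).
#' @return data.frame of switched edges: `geneX`, `geneY`, `r_normal`,
#'   `r_tumor`, `sign_normal`, `sign_tumor`, `module`.
#' @export
detect_switched_pairs <- function(records, threshold = 0.5) {
  keep <- records$r1 * records$r2 < 0 &
    pmin(abs(records$r1), abs(records$r2)) > threshold
  out <- records[keep, , drop = FALSE]
  data.frame(geneX = out$molecule_X, geneY = out$molecule_Y,
             r_normal = out$r1, r_tumor = out$r2,
             sign_normal = ifelse(out$r1 > 0, "+", "-"),
             sign_tumor = ifelse(out$r2 > 0, "+", "-"),
             module = if ("module" %in% names(out)) out$module
               else rep(NA_character_, nrow(out)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene differential-expression direction
#'
#' Welch two-sample t-test per gene (tumor vs normal) with
#' Benjamini-Hochberg adjustment across all tested genes; a gene is
#' `"increased"`/`"decreased"` (in condition B) when its adjusted p falls
#' below `alpha`, otherwise `"unchanged"`. Degenerate genes (zero variance
#' in both conditions) are reported `"unchanged"` with a warning.
#'
#' @param ds an [expression_dataset()].
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.frame `gene`, `t`, `p`, `adj_p`, `direction`.
#' @export
de_direction <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "expression_dataset"))
  xA <- condition_matrix(ds, "A"); xB <- condition_matrix(ds, "B")
  if (ncol(xA) < 2 || ncol(xB) < 2)
    stop("need >= 2 samples per condition")
  mA <- rowMeans(xA, na.rm = TRUE); mB <- rowMeans(xB, na.rm = TRUE)
  vA <- apply(xA, 1, stats::var, na.rm = TRUE)
  vB <- apply(xB, 1, stats::var, na.rm = TRUE)
  nA <- rowSums(!is.na(xA)); nB <- rowSums(!is.na(xB))
  se2 <- vA / nA + vB / nB
  t_stat <- (mB - mA) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  degenerate <- !is.finite(t_stat) | !is.finite(p)
  if (any(degenerate)) {
    warning("degenerate gene(s) set to 'unchanged': ",
            paste(ds$gene_ids[degenerate], collapse = ", "))
    p[degenerate] <- 1
  }
  adj <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(adj < alpha & !degenerate,
                      ifelse(mB > mA, "increased", "decreased"), "unchanged")
  data.frame(gene = ds$gene_ids, t = unname(t_stat), p = unname(p),
             adj_p = unname(adj), direction = direction,
             stringsAsFactors = FALSE)
}

#' Assemble node and edge tables for the switch network
#'
#' Nodes are the union of edge endpoints, annotated with their
#' differential-expression direction and degree; the displayed edge sign
#' is the tumor-condition correlation sign.
#'
#' @param edges switched edges from [detect_switched_pairs()].
#' @param directions data.frame from [de_direction()] (optional; direction
#'   defaults to `"unchanged"` for genes absent from it).
#' @return list of class `dcnet_network` with `nodes` (gene, direction,
#'   degree) and `edges` (geneX, geneY, sign, r_normal, r_tumor).
#' @export
build_network <- function(edges, directions = NULL) {
  if (nrow(edges) == 0) {
    return(structure(list(
      nodes = data.frame(gene = character(), direction = character(),
                         degree = integer(), stringsAsFactors = FALSE),
      edges = data.frame(geneX = character(), geneY = character(),
                         sign = character(), r_normal = numeric(),
                         r_tumor = numeric(), stringsAsFactors = FALSE)),
      class = "dcnet_network"))
  }
  genes <- sort(unique(c(edges$geneX, edges$geneY)))
  degree <- vapply(genes, function(g)
    sum(edges$geneX == g) + sum(edges$geneY == g), integer(1))
  dir <- stats::setNames(rep("unchanged", length(genes)), genes)
  if (!is.null(directions)) {
    hit <- intersect(genes, directions$gene)
    dir[hit] <- directions$direction[match(hit, directions$gene)]
  }
  structure(list(
    nodes = data.frame(gene = genes, direction = unname(dir),
                       degree = unname(degree), stringsAsFactors = FALSE),
    edges = data.frame(geneX = edges$geneX, geneY = edges$geneY,
                       sign = edges$sign_tumor, r_normal = edges$r_normal,
                       r_tumor = edges$r_tumor, stringsAsFactors = FALSE)),
    class = "dcnet_network")
}

#' @export
print.dcnet_network <- function(x, ...) {
  cat(sprintf("<dcnet_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export a network to SIF, GraphML or TSV
#'
#' SIF lines read `geneX pos|neg geneY`; GraphML carries the node
#' `direction` attribute and edge `sign`/`r_normal`/`r_tumor` attributes;
#' TSV writes the node and edge tables verbatim (`<path>.nodes.tsv`,
#' `<path>.edges.tsv`). All formats round-trip through [import_network()].
#'
#' @param network a `dcnet_network`.
#' @param path output path (base path for TSV).
#' @param format `"SIF"`, `"GraphML"` or `"TSV"`.
#' @return invisibly, the file path(s) written.
#' @export
export_network <- function(network, path, format = c("SIF", "GraphML", "TSV")) {
  format <- match.arg(format)
  if (format == "SIF") {
    rel <- ifelse(network$edges$sign == "+", "pos", "neg")
    writeLines(paste(network$edges$geneX, rel, network$edges$geneY,
                     sep = "\t"), path)
    return(invisible(path))
  }
  if (format == "GraphML") {
    g <- network_to_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  paths <- paste0(path, c(".nodes.tsv", ".edges.tsv"))
  utils::write.table(network$nodes, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network$edges, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

network_to_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = network$nodes[, c("gene", "direction", "degree")])
}

#' Read a network written by [export_network()]
#'
#' @param path file path (base path for TSV).
#' @param format `"SIF"`, `"GraphML"` or `"TSV"`.
#' @return a `dcnet_network`. SIF carries no node annotation or
#'   correlation values, so those fields come back as defaults/NA.
#' @export
import_network <- function(path, format = c("SIF", "GraphML", "TSV")) {
  format <- match.arg(format)
  if (format == "SIF") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    edges <- data.frame(
      geneX = vapply(parts, `[`, "", 1),
      geneY = vapply(parts, `[`, "", 3),
      sign_tumor = ifelse(vapply(parts, `[`, "", 2) == "pos", "+", "-"),
      r_normal = NA_real_, r_tumor = NA_real_,
      sign_normal = NA_character_, stringsAsFactors = FALSE)
    return(build_network(edges))
  }
  if (format == "GraphML") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    vs <- igraph::as_data_frame(g, what = "vertices")
    net <- structure(list(
      nodes = data.frame(gene = vs$name, direction = vs$direction,
                         degree = as.integer(vs$degree),
                         stringsAsFactors = FALSE),
      edges = data.frame(geneX = el$from, geneY = el$to, sign = el$sign,
                         r_normal = el$r_normal, r_tumor = el$r_tumor,
                         stringsAsFactors = FALSE)), class = "dcnet_network")
    ord <- order(net$nodes$gene)
    net$nodes <- net$nodes[ord, , drop = FALSE]
    rownames(net$nodes) <- NULL
    return(net)
  }
  nodes <- utils::read.delim(paste0(path, ".nodes.tsv"),
                             stringsAsFactors = FALSE)
  edges <- utils::read.delim(paste0(path, ".edges.tsv"),
                             stringsAsFactors = FALSE,
                             colClasses = c(sign = "character"))
  structure(list(nodes = nodes, edges = edges), class = "dcnet_network")
}

#' Rank network genes by degree
#'
#' @param network a `dcnet_network`.
#' @param k number of genes to return (all nodes if larger).
#' @return data.frame `gene`, `direction`, `degree`, descending degree with
#'   lexicographic tie-break.
#' @export
hub_genes <- function(network, k = 10) {
  nodes <- network$nodes
  ord <- order(-nodes$degree, nodes$gene)
  out <- utils::head(nodes[ord, , drop = FALSE], k)
  rownames(out) <- NULL
  out
}
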