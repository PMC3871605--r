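#' Pairwise Pearson correlation of genes within one condition
#'
#' Correlates gene expression profiles across the samples of a single
#' condition. Genes with zero variance across those samples have no
#' defined correlation and are dropped with a warning. At least three
#' samples are required: on two points every correlation is +/-1 and the
#' resulting network is meaningless.
#'
#' @param matrix numeric genes x samples matrix restricted to one
#'   condition's samples (and typically to the selected genes).
#' @return symmetric correlation matrix with unit diagonal over the
#'   retained genes.
#' @export
pearson_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("'matrix' must be a numeric matrix", call. = FALSE)
  }
  if (ncol(matrix) < 3L) {
    stop("need >= 3 samples per condition for correlation networks",
         call. = FALSE)
  }
  sds <- apply(matrix, 1L, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    warning("dropping ", sum(flat), " zero-variance gene(s): ",
            paste(utils::head(rownames(matrix)[flat], 5L), collapse = ", "),
            call. = FALSE)
    matrix <- matrix[!flat, , drop = FALSE]
  }
  if (nrow(matrix) == 0L) {
    stop("no genes with nonzero variance remain", call. = FALSE)
  }
  r <- stats::cor(t(matrix))
  diag(r) <- 1
  r
}

#' Build a signed co-expression network from a correlation matrix
#'
#' Keeps an undirected edge between genes i and j iff `|r_ij|` is strictly
#' greater than `threshold` (default 0.999; ties at the threshold are
#' excluded). Edge sign records whether the correlation is positive or
#' negative.
#'
#' @param corr symmetric correlation matrix with gene IDs as dimnames.
#' @param threshold absolute-correlation cutoff in [0, 1).
#' @param condition label stored on the network (e.g. `"HC"`).
#' @return object of class `coexpression_network`: a list with `condition`,
#'   `nodes`, `edges` (data.frame `gene1`, `gene2`, `r`, `sign`) and
#'   `threshold`.
#' @export
build_network <- function(corr, threshold = 0.999, condition = "") {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stop("'corr' must be a square matrix", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1) {
    stop("'threshold' must lie in [0, 1)", call. = FALSE)
  }
  nodes <- rownames(corr)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(corr)))
  keep <- which(upper.tri(corr) & abs(corr) > threshold, arr.ind = TRUE)
  edges <- data.frame(
    gene1 = nodes[keep[, 1L]],
    gene2 = nodes[keep[, 2L]],
    r = corr[keep],
    sign = ifelse(corr[keep] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  structure(list(condition = condition, nodes = nodes, edges = edges,
                 threshold = threshold),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("coexpression_network", if (nzchar(x$condition))
    paste0("[", x$condition, "]"), "\n")
  cat("  nodes:", length(x$nodes), " edges:", nrow(x$edges),
      " |r| >", x$threshold, "\n")
  invisible(x)
}

#' Degree centrality: raw link counts per node
#'
#' @param net a [build_network()] result.
#' @return named integer vector over all nodes (isolated nodes get 0);
#'   the degrees sum to twice the number of edges.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  deg <- table(factor(c(net$edges$gene1, net$edges$gene2),
                      levels = net$nodes))
  stats::setNames(as.integer(deg), net$nodes)
}

#' k-core decomposition of a co-expression network
#'
#' The k-core of a graph is the maximal subgraph in which every node has
#' at least k neighbours within the subgraph; a node's core index is the
#' largest k for which it survives. Computed by iterative peeling: nodes
#' of minimum remaining degree are removed and assigned the current core
#' level.
#'
#' @param net a [build_network()] result.
#' @return list with `core` (named integer vector of core indices),
#'   `max_k`, and `max_core_members` (nodes of the maximum k-core).
#' @export
kcore_decompose <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  nodes <- net$nodes
  nv <- length(nodes)
  core <- stats::setNames(integer(nv), nodes)
  if (nv == 0L) {
    return(list(core = core, max_k = 0L, max_core_members = character(0)))
  }
  adj <- lapply(stats::setNames(vector("list", nv), nodes), function(x) character(0))
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$gene1[i]; b <- net$edges$gene2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  deg <- vapply(adj, length, integer(1))
  alive <- stats::setNames(rep(TRUE, nv), nodes)
  k <- 0L
  while (any(alive)) {
    k <- max(k, min(deg[alive]))
    while (any(alive & deg <= k)) {
      v <- names(which(alive & deg <= k))
      core[v] <- k
      alive[v] <- FALSE
      for (u in v) {
        nb <- adj[[u]]
        nb <- nb[alive[nb]]
        deg[nb] <- deg[nb] - vapply(nb, function(w) sum(adj[[u]] == w),
                                    integer(1))
      }
    }
  }
  max_k <- max(core)
  list(core = core, max_k = max_k,
       max_core_members = names(core)[core == max_k])
}

#' Rank core regulatory factors by between-condition degree difference
#'
#' Compares the degree of every gene in two condition networks (genes
#' missing from one network count as degree 0 there) and ranks by the
#' absolute degree difference, descending; ties broken by the degree in
#' the second network (descending) and then by gene ID.
#'
#' @param net_a,net_b [build_network()] results for the two conditions.
#' @return data.frame with columns `gene`, `degree_A`, `degree_B`,
#'   `degree_diff` (`degree_B - degree_A`) and `rank`.
#' @export
core_regulators <- function(net_a, net_b) {
  da <- degree_centrality(net_a)
  db <- degree_centrality(net_b)
  genes <- sort(union(names(da), names(db)))
  degA <- ifelse(genes %in% names(da), da[genes], 0L)
  degB <- ifelse(genes %in% names(db), db[genes], 0L)
  degA[is.na(degA)] <- 0L
  degB[is.na(degB)] <- 0L
  out <- data.frame(gene = genes,
                    degree_A = as.integer(degA),
                    degree_B = as.integer(degB),
                    degree_diff = as.integer(degB - degA),
                    stringsAsFactors = FALSE)
  ord <- order(-abs(out$degree_diff), -out$degree_B, out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Convert a co-expression network to an igraph object
#'
#' Edge attributes `r` (signed Pearson correlation), `weight` (|r|) and
#' `sign` are carried over; useful for export and for visualisation in
#' Cytoscape-style viewers.
#'
#' @param net a [build_network()] result.
#' @return an [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  g <- igraph::graph_from_data_frame(net$edges[, c("gene1", "gene2")],
                                     directed = FALSE,
                                     vertices = net$nodes)
  igraph::E(g)$r <- net$edges$r
  igraph::E(g)$weight <- abs(net$edges$r)
  igraph::E(g)$sign <- net$edges$sign
  g
}

#' Write network artifacts: edge list, node table, GraphML
#'
#' @param net a [build_network()] result.
#' @param prefix file path prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>_nodes.tsv` and `<prefix>.graphml`.
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "coexpression_network"))
  kc <- kcore_decompose(net)
  deg <- degree_centrality(net)
  paths <- c(edges = paste0(prefix, "_edges.tsv"),
             nodes = paste0(prefix, "_nodes.tsv"),
             graphml = paste0(prefix, ".graphml"))
  utils::write.table(net$edges, paths["edges"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nodes <- data.frame(gene = net$nodes, degree = deg[net$nodes],
                      core_index = kc$core[net$nodes],
                      stringsAsFactors = FALSE)
  utils::write.table(nodes, paths["nodes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  g <- as_igraph(net)
  igraph::V(g)$core_index <- kc$core[igraph::V(g)$name]
  igraph::write_graph(g, paths["graphml"], format = "graphml")
  invisible(paths)
}
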