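#' Distance closure of a pathway graph
#'
#' Returns a graph on the same gene nodes where two genes are joined iff
#' their shortest-path distance in `graph` is at most `k` hops (and
#' finite; genes in different connected components are never joined).
#' Subpathway mining reduces to maximal-clique enumeration on this graph.
#'
#' @param graph A `pathway_graph` (see [build_enzyme_graph()]).
#' @param k Positive integer distance bound.
#' @return A `pathway_graph` holding the closure edges.
#' @export
distance_closure <- function(graph, k) {
  stopifnot(inherits(graph, "pathway_graph"))
  assert_scalar_number(k, "k", lower = 1)
  ig <- as_igraph(graph)
  d <- igraph::distances(ig)
  nodes <- rownames(d)
  within <- is.finite(d) & d <= k & d > 0
  idx <- which(within & upper.tri(d), arr.ind = TRUE)
  edges <- if (nrow(idx) > 0L) {
    a <- nodes[idx[, 1L]]
    b <- nodes[idx[, 2L]]
    cbind(gene_a = pmin(a, b), gene_b = pmax(a, b))
  } else {
    matrix(character(), ncol = 2L,
           dimnames = list(NULL, c("gene_a", "gene_b")))
  }
  out <- graph
  out$edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  out
}

#' Mine k-clique subpathways from a pathway graph
#'
#' A subpathway is a maximal set of genes whose pairwise shortest-path
#' distance in the pathway's enzyme graph does not exceed `k` (the
#' "k-clique" of social network analysis, distinct from clique
#' percolation). Maximal sets are enumerated as maximal cliques of the
#' [distance_closure()] graph. Results are deterministic: cliques are
#' ordered by decreasing size, ties by the lexicographic gene list, and
#' labelled `<pathway_id>_<index>` with 1-based indices.
#'
#' @param graph A `pathway_graph`.
#' @param k Distance bound in hops (default 4, the stable mining default
#'   for KEGG metabolic pathways).
#' @param min_size Minimum number of genes per subpathway (default 3;
#'   smaller sets carry little enrichment signal, set to 1 to keep all
#'   maximal sets).
#' @return A named list of character gene vectors — one element per
#'   subpathway, names like `"00100_6"` — with the parent pathway name in
#'   the `"descriptions"` attribute, ready for [write_gmt()] and
#'   [score_matrix()]. An empty graph yields an empty list.
#' @examples
#' r <- lapply(1:4, function(i) {
#'   reaction_record(paste0("R", i), paste0("g", i),
#'                   substrates = paste0("c", i),
#'                   products = paste0("c", i + 1))
#' })
#' g <- build_enzyme_graph("00001", r)  # chain g1 - g2 - g3 - g4
#' mine_subpathways(g, k = 4, min_size = 3)
#' @export
mine_subpathways <- function(graph, k = 4, min_size = 3) {
  stopifnot(inherits(graph, "pathway_graph"))
  assert_scalar_number(min_size, "min_size", lower = 1)
  if (length(graph$nodes) == 0L) {
    out <- stats::setNames(list(), character())
    attr(out, "descriptions") <- character()
    return(out)
  }
  closure <- distance_closure(graph, k)
  ig <- as_igraph(closure)
  cliques <- igraph::max_cliques(ig, min = min_size)
  genes <- lapply(cliques, function(cl) sort(igraph::V(ig)$name[cl]))
  if (length(genes) > 0L) {
    key <- vapply(genes, paste, character(1), collapse = "\r")
    ord <- order(-lengths(genes), key)
    genes <- genes[ord]
  }
  ids <- if (length(genes) > 0L) {
    sprintf("%s_%d", graph$pathway_id, seq_along(genes))
  } else character()
  out <- stats::setNames(genes, ids)
  attr(out, "descriptions") <- stats::setNames(
    rep(if (nzchar(graph$pathway_name)) graph$pathway_name else
      graph$pathway_id, length(ids)), ids)
  out
}

#' Mine subpathways from a directory of KGML files
#'
#' Applies [read_pathway_graph()] and [mine_subpathways()] to every
#' `*.xml` file in `kgml_dir` and concatenates the collections.
#'
#' @param kgml_dir Directory of KGML files.
#' @inheritParams mine_subpathways
#' @inheritParams read_pathway_graph
#' @param verbose Emit one message per pathway (id, node count,
#'   subpathway count).
#' @return A named list of gene vectors across all pathways (GMT-ready).
#' @export
mine_subpathways_dir <- function(kgml_dir, k = 4, min_size = 3,
                                 exclude_compounds = NULL, id_map = NULL,
                                 verbose = TRUE) {
  files <- sort(list.files(kgml_dir, pattern = "\\.xml$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop("no .xml files found in ", kgml_dir, call. = FALSE)
  }
  all_sets <- list()
  all_desc <- character()
  for (f in files) {
    g <- read_pathway_graph(f, exclude_compounds = exclude_compounds,
                            id_map = id_map)
    sp <- mine_subpathways(g, k = k, min_size = min_size)
    if (verbose) {
      message(sprintf("pathway %s: %d genes, %d subpathways",
                      g$pathway_id, length(g$nodes), length(sp)))
    }
    all_desc <- c(all_desc, attr(sp, "descriptions"))
    all_sets <- c(all_sets, sp)
  }
  if (anyDuplicated(names(all_sets))) {
    stop("duplicate subpathway ids across pathway files", call. = FALSE)
  }
  attr(all_sets, "descriptions") <- all_desc
  all_sets
}
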