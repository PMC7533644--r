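#' Parse a KGML metabolic pathway file
#'
#' Reads one KGML (KEGG Markup Language) XML file and extracts the pathway
#' identifier, its title, and one reaction record per `<reaction>` element.
#' Gene identifiers are taken from `<entry type="gene">` elements: an entry
#' whose space-separated `name` attribute lists several identifiers is
#' expanded so that every identifier becomes its own gene. An entry is
#' linked to a reaction either through its `reaction` attribute (which may
#' itself list several reaction names) or, for older KGML revisions, through
#' a matching numeric `id`.
#'
#' @param path Path to a KGML XML file.
#' @return A list with components `pathway_id` (the numeric pathway id as a
#'   zero-padded string, e.g. `"00100"`), `pathway_name` (the pathway
#'   title), and `reactions`, a list of reaction records. Each record is a
#'   list with `reaction_id`, `gene_ids`, `substrates` and `products`
#'   (character vectors; identifiers passed through verbatim).
#'   A file with entries but no reactions yields an empty `reactions` list.
#'   A reaction that cannot be linked to any gene entry is skipped with a
#'   warning.
#' @seealso [build_enzyme_graph()] to turn the records into an enzyme graph.
#' @export
parse_kgml <- function(path) {
  if (!file.exists(path)) stop("KGML file not found: ", path, call. = FALSE)
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop(sprintf("malformed XML in KGML file '%s': %s",
                   path, conditionMessage(e)), call. = FALSE)
    }
  )
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) {
    stop(sprintf("KGML file '%s' has no <pathway> root element", path),
         call. = FALSE)
  }

  raw_name <- xml2::xml_attr(root, "name") %||% ""
  num <- xml2::xml_attr(root, "number")
  pathway_id <- if (!is.na(num) && nzchar(num)) {
    num
  } else {
    # fall back to the digits in e.g. "path:hsa00100"
    sub(".*?(\\d+)$", "\\1", raw_name)
  }
  pathway_name <- xml2::xml_attr(root, "title")
  if (is.na(pathway_name)) pathway_name <- ""

  entries <- xml2::xml_find_all(doc, "/pathway/entry[@type='gene']")
  entry_ids <- xml2::xml_attr(entries, "id")
  entry_genes <- lapply(xml2::xml_attr(entries, "name"),
                        function(s) strsplit(trimws(s %||% ""), "\\s+")[[1]])
  entry_rxns <- lapply(xml2::xml_attr(entries, "reaction"), function(s) {
    if (is.na(s)) character() else strsplit(trimws(s), "\\s+")[[1]]
  })

  rxn_nodes <- xml2::xml_find_all(doc, "/pathway/reaction")
  reactions <- vector("list", length(rxn_nodes))
  keep <- logical(length(rxn_nodes))
  for (i in seq_along(rxn_nodes)) {
    rx <- rxn_nodes[[i]]
    rname <- xml2::xml_attr(rx, "name") %||% ""
    rid <- xml2::xml_attr(rx, "id")

    by_name <- vapply(entry_rxns, function(v) any(v %in% rname), logical(1))
    by_id <- !is.na(rid) & entry_ids == rid
    genes <- unique(unlist(entry_genes[by_name | by_id]))

    if (length(genes) == 0L) {
      warning(sprintf(
        "reaction '%s' in '%s' references no known gene entry; skipped",
        if (nzchar(rname)) rname else rid %||% "?", basename(path)))
      next
    }
    subs <- xml2::xml_attr(xml2::xml_find_all(rx, "./substrate"), "name")
    prods <- xml2::xml_attr(xml2::xml_find_all(rx, "./product"), "name")
    reactions[[i]] <- reaction_record(
      reaction_id = if (nzchar(rname)) rname else rid %||% sprintf("rn%d", i),
      gene_ids = genes,
      substrates = subs[!is.na(subs)],
      products = prods[!is.na(prods)]
    )
    keep[i] <- TRUE
  }

  list(pathway_id = pathway_id,
       pathway_name = pathway_name,
       reactions = reactions[keep])
}

#' Construct a reaction record
#'
#' @param reaction_id Reaction identifier (e.g. `"rn:R01234"`).
#' @param gene_ids Character vector of genes catalyzing the reaction.
#' @param substrates,products Character vectors of compound identifiers.
#' @return A list of class `reaction_record`.
#' @export
reaction_record <- function(reaction_id, gene_ids, substrates = character(),
                            products = character()) {
  structure(
    list(reaction_id = as.character(reaction_id),
         gene_ids = unique(as.character(gene_ids)),
         substrates = unique(as.character(substrates)),
         products = unique(as.character(products))),
    class = "reaction_record")
}

#' Build an undirected enzyme graph from reaction records
#'
#' Two genes are joined by an edge when some reaction of one and some
#' reaction of the other share at least one compound, counting substrates
#' and products on either side (reaction direction is ignored — the graph
#' is undirected). Genes catalyzing the same reaction are therefore
#' connected through that reaction's own compounds.
#'
#' @param pathway_id Pathway identifier (e.g. `"00100"`).
#' @param reactions List of [reaction_record()] objects, as returned in
#'   `parse_kgml(...)$reactions`.
#' @param pathway_name Optional pathway title carried into the graph.
#' @param exclude_compounds Optional character vector of compound ids
#'   (e.g. ubiquitous currency metabolites) removed before testing for
#'   shared compounds. None are excluded by default.
#' @param source_file Optional provenance string.
#' @return An object of class `pathway_graph`: a list with `pathway_id`,
#'   `pathway_name`, `nodes` (character vector of gene ids), `edges`
#'   (two-column character matrix, each row one undirected edge stored with
#'   endpoints in lexicographic order, no self-loops) and `source_file`.
#' @examples
#' r1 <- reaction_record("R1", "A", substrates = "c1", products = "c2")
#' r2 <- reaction_record("R2", "B", substrates = "c2", products = "c3")
#' g <- build_enzyme_graph("00001", list(r1, r2))
#' g$edges  # A - B via shared compound c2
#' @export
build_enzyme_graph <- function(pathway_id, reactions, pathway_name = "",
                               exclude_compounds = NULL, source_file = "") {
  nodes <- sort(unique(as.character(
    unlist(lapply(reactions, `[[`, "gene_ids")))))

  # compounds touched by each gene across all of its reactions
  cmp <- stats::setNames(vector("list", length(nodes)), nodes)
  for (r in reactions) {
    compounds <- setdiff(union(r$substrates, r$products), exclude_compounds)
    if (length(compounds) == 0L) next
    for (g in r$gene_ids) cmp[[g]] <- union(cmp[[g]], compounds)
  }

  edges <- matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("gene_a", "gene_b")))
  if (length(nodes) >= 2L) {
    pairs <- utils::combn(nodes, 2L)
    share <- vapply(seq_len(ncol(pairs)), function(j) {
      length(intersect(cmp[[pairs[1L, j]]], cmp[[pairs[2L, j]]])) > 0L
    }, logical(1))
    if (any(share)) {
      edges <- t(pairs[, share, drop = FALSE])
      colnames(edges) <- c("gene_a", "gene_b")
    }
  }

  structure(
    list(pathway_id = as.character(pathway_id),
         pathway_name = as.character(pathway_name),
         nodes = nodes,
         edges = edges,
         source_file = as.character(source_file)),
    class = "pathway_graph")
}

#' Construct a pathway graph from nodes and an edge list
#'
#' Low-level constructor used when a graph comes from somewhere other
#' than a KGML file (simulations, tests, custom curation). Edges are
#' canonicalized (endpoints in lexicographic order), de-duplicated, and
#' self-loops rejected.
#'
#' @param pathway_id Pathway identifier.
#' @param nodes Character vector of gene ids (may include isolated genes).
#' @param edges Two-column character matrix or data frame of undirected
#'   edges; every endpoint must appear in `nodes`.
#' @param pathway_name,source_file Optional metadata.
#' @return An object of class `pathway_graph`.
#' @export
pathway_graph <- function(pathway_id, nodes, edges = NULL,
                          pathway_name = "", source_file = "") {
  nodes <- sort(unique(as.character(nodes)))
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L,
                    dimnames = list(NULL, c("gene_a", "gene_b")))
  } else {
    if (is.data.frame(edges)) edges <- as.matrix(edges)
    a <- as.character(edges[, 1L]); b <- as.character(edges[, 2L])
    if (any(a == b)) stop("self-loop edges are not allowed", call. = FALSE)
    if (!all(c(a, b) %in% nodes)) {
      stop("every edge endpoint must be in `nodes`", call. = FALSE)
    }
    edges <- unique(cbind(gene_a = pmin(a, b), gene_b = pmax(a, b)))
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  structure(
    list(pathway_id = as.character(pathway_id),
         pathway_name = as.character(pathway_name),
         nodes = nodes, edges = edges,
         source_file = as.character(source_file)),
    class = "pathway_graph")
}

#' Read a KGML file directly into a pathway graph
#'
#' Convenience composition of [parse_kgml()] and [build_enzyme_graph()].
#'
#' @inheritParams parse_kgml
#' @inheritParams build_enzyme_graph
#' @param id_map Optional id-mapping data frame; see [map_gene_ids()].
#' @return A `pathway_graph`.
#' @export
read_pathway_graph <- function(path, exclude_compounds = NULL,
                               id_map = NULL) {
  parsed <- parse_kgml(path)
  g <- build_enzyme_graph(parsed$pathway_id, parsed$reactions,
                          pathway_name = parsed$pathway_name,
                          exclude_compounds = exclude_compounds,
                          source_file = path)
  if (!is.null(id_map)) g <- map_gene_ids(g, id_map)
  g
}

#' Relabel pathway-graph genes through an id-mapping table
#'
#' Converts verbatim KGML identifiers (e.g. `"hsa:4047"`) to the namespace
#' used by expression matrices (e.g. gene symbols). Identifiers absent from
#' the table are kept unchanged. If several source ids map to the same
#' symbol the nodes are merged; self-loops created by merging are dropped.
#'
#' @param graph A `pathway_graph`.
#' @param id_map Data frame whose first two columns are the source id and
#'   the target id (e.g. columns `kgml_id`, `gene_symbol`), or a path to a
#'   two-column TSV with a header.
#' @return The relabelled `pathway_graph`.
#' @export
map_gene_ids <- function(graph, id_map) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (is.character(id_map) && length(id_map) == 1L) {
    id_map <- utils::read.delim(id_map, header = TRUE,
                                colClasses = "character")
  }
  if (ncol(id_map) < 2L) stop("`id_map` needs two columns", call. = FALSE)
  lut <- stats::setNames(as.character(id_map[[2L]]),
                         as.character(id_map[[1L]]))
  relab <- function(x) ifelse(x %in% names(lut), unname(lut[x]), x)

  nodes <- sort(unique(relab(graph$nodes)))
  edges <- graph$edges
  if (nrow(edges) > 0L) {
    a <- relab(edges[, 1L]); b <- relab(edges[, 2L])
    keep <- a != b
    edges <- unique(cbind(gene_a = pmin(a[keep], b[keep]),
                          gene_b = pmax(a[keep], b[keep])))
  }
  graph$nodes <- nodes
  graph$edges <- edges
  graph
}

#' Serialize pathway-graph edges as a TSV edge list
#'
#' Writes one row per edge: `pathway_id`, `gene_a`, `gene_b`. Intended for
#' inspection and downstream tooling; isolated nodes do not appear.
#'
#' @param graph A `pathway_graph`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  df <- data.frame(pathway_id = rep(graph$pathway_id, nrow(graph$edges)),
                   gene_a = graph$edges[, 1L],
                   gene_b = graph$edges[, 2L])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph %s (%s): %d genes, %d edges\n",
              x$pathway_id,
              if (nzchar(x$pathway_name)) x$pathway_name else "unnamed",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# igraph view of a pathway_graph; keeps isolated nodes.
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  igraph::graph_from_data_frame(
    as.data.frame(graph$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE))
}
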