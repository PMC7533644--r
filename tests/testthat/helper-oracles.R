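# Shared fixtures and independent oracles, kept deliberately naive: they
# re-derive each quantity by direct enumeration so the implementation and
# its check never share code.

# A connected undirected random graph as a pathway_graph: Erdos-Renyi,
# then consecutive components are stitched with single edges.
random_connected_pgraph <- function(n, p_edge = 0.2, id = "99999") {
  stopifnot(n >= 2)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- pairs[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    matrix(nodes[edges], ncol = 2L), directed = FALSE)
  g <- g + igraph::vertices(setdiff(nodes, igraph::V(g)$name))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    reps <- vapply(seq_len(comp$no), function(cc) {
      igraph::V(g)$name[which(comp$membership == cc)[1L]]
    }, character(1))
    extra <- cbind(reps[-length(reps)], reps[-1L])
    edges <- rbind(matrix(nodes[edges], ncol = 2L), extra)
  } else {
    edges <- matrix(nodes[edges], ncol = 2L)
  }
  pathway_graph(id, nodes, if (nrow(edges) > 0) edges else NULL)
}

pgraph_distances <- function(graph) {
  igraph::distances(igraph::graph_from_data_frame(
    as.data.frame(graph$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = graph$nodes)))
}

# Brute-force subpathway oracle: every vertex subset with pairwise
# distance <= k, maximality by single-vertex extension (the qualifying
# property is hereditary, so this equals global maximality), then the
# size filter. Returns a list of sorted gene vectors.
brute_force_subpathways <- function(graph, k = 4, min_size = 3) {
  nodes <- graph$nodes
  n <- length(nodes)
  stopifnot(n <= 14)
  D <- pgraph_distances(graph)[nodes, nodes, drop = FALSE]
  within <- is.finite(D) & D <= k
  out <- list()
  for (code in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(code, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(idx) < min_size) next
    if (!all(within[idx, idx])) next
    extendable <- any(vapply(setdiff(seq_len(n), idx), function(v) {
      all(within[v, idx])
    }, logical(1)))
    if (!extendable) out[[length(out) + 1L]] <- sort(nodes[idx])
  }
  unique(out)
}

# Naive prefix re-computation of the KS-like walk.
naive_walk_score <- function(r_walk, member_walk, tau = 1) {
  p <- length(r_walk)
  n_set <- sum(member_walk)
  denom_hit <- sum(r_walk[member_walk]^tau)
  nu <- numeric(p)
  for (l in seq_len(p)) {
    hit <- sum(r_walk[seq_len(l)][member_walk[seq_len(l)]]^tau) / denom_hit
    miss <- sum(!member_walk[seq_len(l)]) / (p - n_set)
    nu[l] <- hit - miss
  }
  c(es_plus = max(0, max(nu)), es_minus = min(0, min(nu)),
    es = max(0, max(nu)) + min(0, min(nu)))
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

# Chain pathway v1 - v2 - ... - vn built through reaction records.
chain_pgraph <- function(n, id = "00001") {
  r <- lapply(seq_len(n), function(i) {
    reaction_record(paste0("R", i), sprintf("v%02d", i),
                    substrates = paste0("c", i),
                    products = paste0("c", i + 1))
  })
  build_enzyme_graph(id, r)
}

# One full synthetic cohort under the default study design.
simulate_cohort <- function(seed, sets, implant = list(
                              list(selector = 1L, delta = 1,
                                   direction = "up"))) {
  spec <- simulation_spec(seed = seed, implant = implant)
  simulate_expression(spec, sets)
}

# Mined subpathways of the default synthetic pathway collection.
default_synthetic_sets <- function(seed = 1) {
  spec <- simulation_spec(seed = seed)
  dir <- tempfile("kgml")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  generate_pathways(spec, dir)
  suppressMessages(mine_subpathways_dir(dir, verbose = FALSE))
}
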