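#' Specify a synthetic study design
#'
#' Bundles and validates the parameters of the synthetic-data generator:
#' pathway topologies, cohort sizes, the noise model, and the subpathways
#' to implant with a coordinated expression shift. Defaults describe a
#' two-group study of 20 cases vs 20 controls with ten 10-gene hub
#' pathways over standard-normal background noise — the regime in which a
#' coordinated one-standard-deviation shift of one subpathway is the
#' implanted signal.
#'
#' @param n_pathways Number of pathways to generate.
#' @param genes_per_pathway Genes per pathway.
#' @param topology `"chain"` (a path graph), `"hub"` (a star; every
#'   pathway then mines to a single subpathway covering its genes), or
#'   `"random"` (Erdos-Renyi with `edge_prob`).
#' @param edge_prob Edge probability for `topology = "random"`.
#' @param n_case,n_control Samples per group (each >= 2).
#' @param implant List of implants, each a list with `selector` (a
#'   subpathway id, or an integer index into the mined collection),
#'   `delta` (shift size >= 0, in background-SD units for continuous
#'   noise; log-fold scale for counts) and `direction` (`"up"` or
#'   `"down"`).
#' @param noise `"continuous"` (N(0, 1) background) or `"counts"`
#'   (negative binomial).
#' @param nb_mean,nb_dispersion Negative-binomial background mean and
#'   dispersion (`size = 1/dispersion`) for count noise.
#' @param n_background Extra unannotated background genes appended to the
#'   matrix (they shape the per-sample ranking the way genes outside
#'   metabolic pathways do in real data).
#' @param implant_fraction Fraction of each implanted subpathway's genes
#'   that receive the shift (default 1 = all genes).
#' @param seed Mandatory integer seed; all generation is deterministic.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_pathways = 10, genes_per_pathway = 10,
                            topology = c("hub", "chain", "random"),
                            edge_prob = 0.3,
                            n_case = 20, n_control = 20,
                            implant = list(list(selector = 1L, delta = 1,
                                                direction = "up")),
                            noise = c("continuous", "counts"),
                            nb_mean = 100, nb_dispersion = 0.1,
                            n_background = 100,
                            implant_fraction = 1,
                            seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  topology <- match.arg(topology)
  noise <- match.arg(noise)
  assert_scalar_number(n_case, "n_case", lower = 2)
  assert_scalar_number(n_control, "n_control", lower = 2)
  assert_scalar_number(n_pathways, "n_pathways", lower = 1)
  assert_scalar_number(genes_per_pathway, "genes_per_pathway", lower = 1)
  if (edge_prob < 0 || edge_prob > 1) {
    stop("`edge_prob` must lie in [0, 1]", call. = FALSE)
  }
  if (implant_fraction <= 0 || implant_fraction > 1) {
    stop("`implant_fraction` must lie in (0, 1]", call. = FALSE)
  }
  for (im in implant) {
    if (is.null(im$selector)) stop("implant needs a `selector`", call. = FALSE)
    assert_scalar_number(im$delta %||% 1, "delta", lower = 0)
    if (!(im$direction %||% "up") %in% c("up", "down")) {
      stop("implant direction must be 'up' or 'down'", call. = FALSE)
    }
  }
  structure(
    list(n_pathways = as.integer(n_pathways),
         genes_per_pathway = as.integer(genes_per_pathway),
         topology = topology, edge_prob = edge_prob,
         n_case = as.integer(n_case), n_control = as.integer(n_control),
         implant = implant, noise = noise,
         nb_mean = nb_mean, nb_dispersion = nb_dispersion,
         n_background = as.integer(n_background),
         implant_fraction = implant_fraction,
         seed = as.integer(seed)),
    class = "simulation_spec")
}

# Deterministic gene label for pathway i, gene j.
synth_gene <- function(i, j) sprintf("g%02d_%02d", i, j)

# Designed edge set (2-column index matrix) for one pathway's topology.
synth_topology_edges <- function(spec, pathway_index) {
  m <- spec$genes_per_pathway
  switch(spec$topology,
    chain = if (m >= 2L) cbind(1:(m - 1L), 2:m) else
      matrix(integer(), ncol = 2L),
    hub = if (m >= 2L) cbind(1L, 2:m) else matrix(integer(), ncol = 2L),
    random = {
      pairs <- if (m >= 2L) t(utils::combn(m, 2L)) else
        matrix(integer(), ncol = 2L)
      with_seed(spec$seed + 7919L * pathway_index, {
        pairs[stats::runif(nrow(pairs)) < spec$edge_prob, , drop = FALSE]
      })
    })
}

#' Generate one synthetic KGML pathway file
#'
#' Writes a minimal well-formed KGML file whose reactions induce exactly
#' the designed topology under the enzyme-graph construction rules: each
#' gene gets one reaction whose substrates are one unique compound per
#' incident edge (plus a private filler compound), so two genes share a
#' compound iff they are joined by a designed edge. The returned graph is
#' the ground truth for round-trip assertions.
#'
#' @param spec A [simulation_spec()].
#' @param pathway_index 1-based pathway number; the pathway id is the
#'   zero-padded index.
#' @param dir Output directory (created if missing).
#' @return A list with `file` (the KGML path) and `graph` (the designed
#'   `pathway_graph`). Regenerating with the same spec gives
#'   byte-identical files.
#' @export
generate_pathway_kgml <- function(spec, pathway_index, dir) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- spec$genes_per_pathway
  pid <- sprintf("%05d", pathway_index)
  genes <- vapply(seq_len(m), function(j) synth_gene(pathway_index, j),
                  character(1))
  edges <- synth_topology_edges(spec, pathway_index)

  # compounds: one per designed edge, shared by its two endpoint genes;
  # plus one private filler per gene so every reaction has a compound
  gene_cmps <- lapply(seq_len(m), function(j) sprintf("cpd:X%05d_%03d", pathway_index, j))
  if (nrow(edges) > 0L) {
    for (e in seq_len(nrow(edges))) {
      ce <- sprintf("cpd:C%05d_%03d", pathway_index, e)
      gene_cmps[[edges[e, 1L]]] <- c(gene_cmps[[edges[e, 1L]]], ce)
      gene_cmps[[edges[e, 2L]]] <- c(gene_cmps[[edges[e, 2L]]], ce)
    }
  }

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<pathway name="path:syn%s" org="syn" number="%s" title="synthetic pathway %d">',
            pid, pid, pathway_index))
  for (j in seq_len(m)) {
    lines <- c(lines, sprintf(
      '  <entry id="%d" name="%s" type="gene" reaction="rn:R%s_%d"/>',
      j, genes[[j]], pid, j))
  }
  for (j in seq_len(m)) {
    cl <- gene_cmps[[j]]
    half <- ceiling(length(cl) / 2)
    subs <- cl[seq_len(half)]
    prods <- cl[setdiff(seq_along(cl), seq_len(half))]
    lines <- c(lines,
      sprintf('  <reaction id="%d" name="rn:R%s_%d" type="reversible">', j, pid, j),
      sprintf('    <substrate id="%d" name="%s"/>', seq_along(subs) + 1000L, subs),
      if (length(prods) > 0L)
        sprintf('    <product id="%d" name="%s"/>', seq_along(prods) + 2000L, prods),
      '  </reaction>')
  }
  lines <- c(lines, '</pathway>')
  file <- file.path(dir, sprintf("syn%s.xml", pid))
  writeLines(lines, file)

  truth_edges <- if (nrow(edges) > 0L) {
    cbind(genes[edges[, 1L]], genes[edges[, 2L]])
  } else NULL
  graph <- pathway_graph(
    pid, genes, truth_edges,
    pathway_name = sprintf("synthetic pathway %d", pathway_index),
    source_file = file)
  list(file = file, graph = graph)
}

#' Generate all pathways of a simulation spec
#'
#' @inheritParams generate_pathway_kgml
#' @return List of [generate_pathway_kgml()] results, one per pathway.
#' @export
generate_pathways <- function(spec, dir) {
  lapply(seq_len(spec$n_pathways), function(i) {
    generate_pathway_kgml(spec, i, dir)
  })
}

#' Simulate a case/control expression matrix with implanted subpathways
#'
#' Background expression is i.i.d. noise (standard normal for
#' `noise = "continuous"`, negative binomial for `"counts"`). For every
#' implant in the spec, the genes of the selected subpathway receive a
#' coordinated shift in case samples only: `+/- delta` (in background-SD
#' units, the background SD being 1) for continuous data, or a
#' multiplicative `exp(+/- delta)` factor on the mean for counts.
#'
#' @param spec A [simulation_spec()].
#' @param genesets Named list of gene sets (mined subpathways) against
#'   which implant selectors are resolved.
#' @return A list with `expr` (genes x samples matrix, background genes
#'   appended), `groups` (data frame `sample_id`, `group` with levels
#'   `"case"`/`"control"`), and `truth` (data frame `subpathway_id`,
#'   `delta`, `direction` of the implants).
#' @export
simulate_expression <- function(spec, genesets) {
  stopifnot(inherits(spec, "simulation_spec"))
  resolve <- function(sel) {
    if (is.character(sel)) {
      if (!sel %in% names(genesets)) {
        stop("implant selector matches no subpathway: ", sel, call. = FALSE)
      }
      sel
    } else {
      if (sel < 1L || sel > length(genesets)) {
        stop("implant selector index out of range: ", sel, call. = FALSE)
      }
      names(genesets)[[sel]]
    }
  }
  implant_ids <- vapply(spec$implant, function(im) resolve(im$selector),
                        character(1))

  genes <- unique(unlist(genesets))
  if (spec$n_background > 0L) {
    genes <- c(genes, sprintf("bg%04d", seq_len(spec$n_background)))
  }
  p <- length(genes)
  n <- spec$n_case + spec$n_control
  samples <- c(sprintf("case_%02d", seq_len(spec$n_case)),
               sprintf("ctrl_%02d", seq_len(spec$n_control)))
  case_cols <- seq_len(spec$n_case)

  expr <- with_seed(spec$seed, {
    base <- if (spec$noise == "continuous") {
      matrix(stats::rnorm(p * n), p, n)
    } else {
      matrix(stats::rnbinom(p * n, mu = spec$nb_mean,
                            size = 1 / spec$nb_dispersion), p, n)
    }
    dimnames(base) <- list(genes, samples)
    for (idx in seq_along(spec$implant)) {
      im <- spec$implant[[idx]]
      target <- genesets[[implant_ids[[idx]]]]
      if (spec$implant_fraction < 1) {
        n_hit <- max(1L, floor(length(target) * spec$implant_fraction))
        target <- sort(target)[seq_len(n_hit)]
      }
      target <- intersect(target, genes)
      sgn <- if ((im$direction %||% "up") == "up") 1 else -1
      delta <- im$delta %||% 1
      if (spec$noise == "continuous") {
        base[target, case_cols] <- base[target, case_cols] + sgn * delta
      } else {
        mu <- spec$nb_mean * exp(sgn * delta)
        base[target, case_cols] <- matrix(
          stats::rnbinom(length(target) * spec$n_case, mu = mu,
                         size = 1 / spec$nb_dispersion),
          length(target), spec$n_case)
      }
    }
    base
  })

  groups <- data.frame(
    sample_id = samples,
    group = rep(c("case", "control"), c(spec$n_case, spec$n_control)))
  truth <- data.frame(
    subpathway_id = implant_ids,
    delta = vapply(spec$implant, function(im) im$delta %||% 1, numeric(1)),
    direction = vapply(spec$implant,
                       function(im) im$direction %||% "up", character(1)))
  list(expr = expr, groups = groups, truth = truth)
}

#' Recovery metrics for an implanted-signal run
#'
#' @param truth Character vector of implanted subpathway ids (or the
#'   `truth` data frame from [simulate_expression()]).
#' @param significant Character vector of ids called significant (or a
#'   [significant_set()] data frame).
#' @return Named list: `sensitivity` (implanted ids recovered / number
#'   implanted) and `fdr` (non-implanted significant / total significant;
#'   0 when nothing is significant).
#' @export
recovery_report <- function(truth, significant) {
  t_ids <- if (is.data.frame(truth)) truth$subpathway_id else truth
  s_ids <- if (is.data.frame(significant)) significant$subpathway_id else
    significant
  sens <- if (length(t_ids) == 0L) NA_real_ else
    length(intersect(t_ids, s_ids)) / length(t_ids)
  fdr <- if (length(s_ids) == 0L) 0 else
    length(setdiff(s_ids, t_ids)) / length(s_ids)
  list(sensitivity = sens, fdr = fdr)
}
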