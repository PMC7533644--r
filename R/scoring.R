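#' Collapse probe-level expression to gene level
#'
#' Probes containing a zero value in any sample are removed first; the
#' remaining probes mapping to the same gene are averaged per sample.
#' Unmapped probes are dropped (a message reports how many).
#'
#' @param probe_matrix Numeric matrix, probes in rows (rownames = probe
#'   ids), samples in columns.
#' @param probe_to_gene Data frame whose first two columns are probe id
#'   and gene id, or a named character vector (names = probes).
#' @param drop_zero_probes Remove probes with any zero value before
#'   averaging (default `TRUE`, appropriate for array intensities; disable
#'   for count data, where zeros are informative).
#' @return Numeric matrix, genes in rows.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene,
                            drop_zero_probes = TRUE) {
  stopifnot(is.matrix(probe_matrix), !is.null(rownames(probe_matrix)))
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene[[2L]]),
                           as.character(probe_to_gene[[1L]]))
  } else {
    map <- probe_to_gene
  }
  if (drop_zero_probes) {
    has_zero <- apply(probe_matrix == 0, 1L, any)
    probe_matrix <- probe_matrix[!has_zero, , drop = FALSE]
  }
  mapped <- rownames(probe_matrix) %in% names(map)
  n_drop <- sum(!mapped)
  if (n_drop > 0L) message(n_drop, " unmapped probe(s) dropped")
  probe_matrix <- probe_matrix[mapped, , drop = FALSE]
  if (nrow(probe_matrix) == 0L) {
    stop(paste("no probes left after filtering/mapping;",
               "for count data set drop_zero_probes = FALSE"),
         call. = FALSE)
  }
  gene <- unname(map[rownames(probe_matrix)])
  counts <- as.vector(table(gene)[sort(unique(gene))])
  out <- rowsum(probe_matrix, gene) / counts
  out[sort(unique(gene)), , drop = FALSE]
}

#' Gaussian-kernel CDF scores for continuous expression
#'
#' For gene i with values x_i1..x_in, each value is scored by the kernel
#' estimate of its cumulative density across samples:
#' z_ij = (1/n) * sum_m Phi((x_ij - x_im) / h_i), with Phi the standard
#' normal CDF and bandwidth h_i = s_i / 4 (s_i the sample standard
#' deviation, n - 1 denominator). Scores lie strictly in (0, 1) and are
#' increasing in x_ij within a gene. Genes with zero variance have no
#' defined bandwidth and are removed with a warning.
#'
#' @param x Numeric matrix, genes in rows, at least 2 samples.
#' @return Matrix of z scores (rows may be fewer than `x` if
#'   constant genes were dropped), with per-gene bandwidths in the
#'   `"bandwidths"` attribute.
#' @export
kcdf_gaussian <- function(x) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2L) {
    stop("kernel CDF estimation needs at least 2 samples", call. = FALSE)
  }
  s <- apply(x, 1L, stats::sd)
  if (any(s == 0)) {
    warning(sum(s == 0), " constant gene(s) removed (zero variance)")
    x <- x[s > 0, , drop = FALSE]
    s <- s[s > 0]
  }
  h <- s / 4
  z <- t(vapply(seq_len(nrow(x)), function(i) {
    xi <- x[i, ]
    rowMeans(stats::pnorm(outer(xi, xi, "-") / h[i]))
  }, numeric(ncol(x))))
  dimnames(z) <- dimnames(x)
  attr(z, "bandwidths") <- stats::setNames(h, rownames(x))
  z
}

#' Poisson-kernel CDF scores for count expression
#'
#' For integer counts, z_ij = (1/n) * sum_m F_Pois(x_ij; lambda = x_im + r)
#' with F_Pois the Poisson CDF and continuity offset r (default 0.5, which
#' keeps the rate positive for zero counts).
#'
#' @param x Non-negative integer matrix, genes in rows.
#' @param offset Continuity offset r added to each rate.
#' @return Matrix of z scores in (0, 1).
#' @export
kcdf_poisson <- function(x, offset = 0.5) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2L) {
    stop("kernel CDF estimation needs at least 2 samples", call. = FALSE)
  }
  bad <- which(is.na(x) | x < 0 | x != round(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    g <- rownames(x)[bad[1L, 1L]] %||% bad[1L, 1L]
    s <- colnames(x)[bad[1L, 2L]] %||% bad[1L, 2L]
    stop(sprintf(
      "counts must be non-negative integers (offending gene %s, sample %s)",
      g, s), call. = FALSE)
  }
  z <- t(vapply(seq_len(nrow(x)), function(i) {
    xi <- x[i, ]
    lam <- xi + offset
    vapply(xi, function(v) mean(stats::ppois(v, lam)), numeric(1))
  }, numeric(ncol(x))))
  dimnames(z) <- dimnames(x)
  z
}

#' Symmetric rank statistics per sample
#'
#' For each sample, genes are ranked by decreasing kernel-CDF score: the
#' largest z gets rank p, the smallest rank 1 (ties broken stably by input
#' gene order). The symmetric rank statistic is r_ij = |p/2 - rank_ij|,
#' which up-weights genes at either extreme of the ranking. The walk order
#' of [ks_walk_score()] is the decreasing-z order.
#'
#' @param z Numeric matrix of kernel-CDF scores (genes x samples), or a
#'   single column.
#' @return A list with `ranks` (p x n integer matrix), `r` (p x n matrix of
#'   symmetric rank statistics, rows aligned with `z`) and `walk_order`
#'   (p x n integer matrix: row l of column j is the index into `z`'s rows
#'   of the l-th gene walked for sample j).
#' @export
rank_statistic <- function(z) {
  if (!is.matrix(z)) z <- matrix(z, ncol = 1L)
  p <- nrow(z)
  if (p < 2L) stop("need at least 2 genes to rank", call. = FALSE)
  n <- ncol(z)
  walk_order <- matrix(0L, p, n)
  ranks <- matrix(0L, p, n)
  for (j in seq_len(n)) {
    ord <- order(-z[, j])          # stable: ties keep input gene order
    walk_order[, j] <- ord
    ranks[ord, j] <- p - seq_len(p) + 1L
  }
  r <- abs(p / 2 - ranks)
  dimnames(r) <- dimnames(z)
  list(ranks = ranks, r = r, walk_order = walk_order)
}

#' KS-like random-walk enrichment score for one sample
#'
#' Walking the genes in decreasing-z order, the deviation after step l is
#' nu(l) = sum of r^tau over set members seen so far, normalized by the
#' set total, minus the fraction of non-members seen so far. The activity
#' score is the sum of the maximum positive and minimum negative
#' deviations (equivalently, the difference between the maximum and
#' minimum enrichment deviations), so it lies in \[-1, 1\] and is 0-capped
#' on each side; nu(p) = 0 always.
#'
#' @param r_walk Numeric vector of symmetric rank statistics in walk order.
#' @param member_walk Logical vector: is the l-th walked gene in the set?
#' @param tau Weight exponent on the rank statistic (default 1).
#' @return Named numeric vector `c(es_plus, es_minus, es)` with
#'   `es = es_plus + es_minus`, `es_plus >= 0 >= es_minus`.
#' @export
ks_walk_score <- function(r_walk, member_walk, tau = 1) {
  p <- length(r_walk)
  stopifnot(length(member_walk) == p)
  n_set <- sum(member_walk)
  if (n_set == 0L || n_set == p) {
    stop("gene set must be a non-empty proper subset of the genes",
         call. = FALSE)
  }
  w <- r_walk^tau
  hit <- cumsum(w * member_walk) / sum(w[member_walk])
  miss <- cumsum(!member_walk) / (p - n_set)
  nu <- hit - miss
  es_plus <- max(0, max(nu))
  es_minus <- min(0, min(nu))
  c(es_plus = es_plus, es_minus = es_minus, es = es_plus + es_minus)
}

#' Subpathway activity score matrix
#'
#' Transforms a gene expression matrix into a subpathway x sample activity
#' matrix: kernel-CDF scoring of each gene across samples
#' ([kcdf_gaussian()] for continuous data, [kcdf_poisson()] for counts),
#' symmetric rank statistics per sample ([rank_statistic()]), then one
#' [ks_walk_score()] per gene set per sample. Set members absent from the
#' matrix are intersected out; sets retaining fewer than `min_set` genes
#' are dropped with a warning.
#'
#' @param expr Numeric matrix, genes in rows (rownames required), samples
#'   in columns. At least 2 samples.
#' @param genesets Named list of character gene vectors (e.g. from
#'   [mine_subpathways()] or [read_gmt()]).
#' @param kcdf `"auto"` (Poisson iff every value is a non-negative
#'   integer), `"gaussian"`, or `"poisson"`.
#' @param tau Rank weight exponent passed to [ks_walk_score()].
#' @param min_set Minimum retained set size (default 2).
#' @param return_components Also return the per-cell positive and negative
#'   walk deviations.
#' @return Numeric matrix of activity scores, subpathways x samples. With
#'   `return_components = TRUE`, a list `list(es, es_plus, es_minus)`.
#' @export
score_matrix <- function(expr, genesets,
                         kcdf = c("auto", "gaussian", "poisson"),
                         tau = 1, min_set = 2, return_components = FALSE) {
  kcdf <- match.arg(kcdf)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (ncol(expr) < 2L) {
    stop("need at least 2 samples: kernel CDF estimation is undefined for n = 1",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) {
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  }
  if (kcdf == "auto") {
    kcdf <- if (is_count_matrix(expr)) "poisson" else "gaussian"
  }
  z <- switch(kcdf, gaussian = kcdf_gaussian(expr), poisson = kcdf_poisson(expr))

  genes <- rownames(z)
  kept <- lapply(genesets, intersect, genes)
  n_lost <- sum(lengths(genesets) - lengths(kept))
  if (n_lost > 0L) {
    message(n_lost, " gene-set member(s) absent from the matrix were dropped")
  }
  small <- lengths(kept) < min_set | lengths(kept) >= length(genes)
  if (any(small)) {
    warning(sum(small), " gene set(s) dropped (fewer than min_set genes ",
            "present, or covering every gene)")
    kept <- kept[!small]
  }
  if (length(kept) == 0L) {
    stop("no gene sets retained after intersection with the matrix",
         call. = FALSE)
  }

  rk <- rank_statistic(z)
  p <- nrow(z)
  n <- ncol(z)
  member <- vapply(kept, function(g) genes %in% g, logical(p))
  # member: p x n_sets
  es <- esp <- esm <- matrix(
    0, length(kept), n,
    dimnames = list(names(kept), colnames(expr)))
  for (j in seq_len(n)) {
    ord <- rk$walk_order[, j]
    w <- rk$r[ord, j]^tau
    memb_w <- member[ord, , drop = FALSE]
    for (s in seq_along(kept)) {
      m <- memb_w[, s]
      hit <- cumsum(w * m) / sum(w[m])
      miss <- cumsum(!m) / (p - sum(m))
      nu <- hit - miss
      esp[s, j] <- max(0, max(nu))
      esm[s, j] <- min(0, min(nu))
    }
  }
  es <- esp + esm
  if (return_components) list(es = es, es_plus = esp, es_minus = esm) else es
}

#' Read an expression matrix from TSV
#'
#' First column = gene id, header = sample ids.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Write a matrix as TSV with an id column
#'
#' @param m Matrix with rownames.
#' @param path Output path.
#' @param id_col Name of the first (id) column.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
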