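#' Read a sample-to-group design TSV
#'
#' Two columns with a header: sample id, group label.
#'
#' @param path TSV path.
#' @return Data frame with columns `sample_id`, `group`.
#' @export
read_groups_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) stop("groups file needs two columns", call. = FALSE)
  data.frame(sample_id = df[[1L]], group = df[[2L]])
}

#' Run the full subpathway pipeline
#'
#' Orchestrates graph construction, subpathway mining, activity scoring,
#' per-dataset differential analysis, and (for more than one dataset) the
#' cross-dataset intersection. A machine-readable manifest (JSON) with
#' parameters, package version, and input checksums is written beside the
#' outputs. Stages whose output files already exist are skipped unless
#' `force = TRUE`; any stage error is re-signalled with the stage name.
#'
#' @param config A list (or path to a YAML/JSON file readable by
#'   [jsonlite::read_json()]) with elements:
#'   \describe{
#'     \item{kgml_dir}{directory of KGML files}
#'     \item{datasets}{list of `list(expr = , groups = )` TSV path pairs}
#'     \item{out_dir}{output directory}
#'     \item{k, min_size, kcdf, tau, min_set, alpha, adjustment,
#'       direction_consistency, contrast}{stage parameters; defaults
#'       `k = 4`, `min_size = 3`, `kcdf = "auto"`, `tau = 1`,
#'       `min_set = 2`, `alpha = 0.05`, `adjustment = "BH"`,
#'       `direction_consistency = TRUE`, `contrast = c("case","control")`}
#'   }
#' @param force Recompute stages whose outputs already exist.
#' @return Invisibly, a list with the output file paths, the per-dataset
#'   [diff_table()]s, and the intersection data frame (when >= 2
#'   datasets).
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.data.frame(config$datasets)) {
    config$datasets <- lapply(seq_len(nrow(config$datasets)), function(i) {
      as.list(config$datasets[i, , drop = FALSE])
    })
  }
  cfg <- utils::modifyList(
    list(k = 4, min_size = 3, kcdf = "auto", tau = 1, min_set = 2,
         alpha = 0.05, adjustment = "BH", direction_consistency = TRUE,
         contrast = c("case", "control")),
    config)
  for (field in c("kgml_dir", "datasets", "out_dir")) {
    if (is.null(cfg[[field]])) {
      stop("pipeline config lacks `", field, "`", call. = FALSE)
    }
  }
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  gmt_path <- file.path(cfg$out_dir, "subpathways.gmt")
  stage("mine", {
    if (force || !file.exists(gmt_path)) {
      sets <- mine_subpathways_dir(cfg$kgml_dir, k = cfg$k,
                                   min_size = cfg$min_size,
                                   verbose = FALSE)
      write_gmt(sets, gmt_path)
    }
  })
  sets <- read_gmt(gmt_path)

  diff_paths <- character(length(cfg$datasets))
  diffs <- vector("list", length(cfg$datasets))
  for (i in seq_along(cfg$datasets)) {
    ds <- cfg$datasets[[i]]
    act_path <- file.path(cfg$out_dir, sprintf("activity_%d.tsv", i))
    diff_paths[i] <- file.path(cfg$out_dir, sprintf("diff_%d.tsv", i))
    stage("score", {
      if (!file.exists(ds$expr)) {
        stop("expression file not found: ", ds$expr, call. = FALSE)
      }
      if (force || !file.exists(act_path)) {
        expr <- read_expression_tsv(ds$expr)
        act <- score_matrix(expr, sets, kcdf = cfg$kcdf, tau = cfg$tau,
                            min_set = cfg$min_set)
        write_matrix_tsv(act, act_path, id_col = "subpathway_id")
      }
    })
    diffs[[i]] <- stage("diff", {
      if (is.null(ds$groups) || !file.exists(ds$groups %||% "")) {
        stop("groups file not found: ", ds$groups %||% "<missing>",
             call. = FALSE)
      }
      act <- read_expression_tsv(act_path)
      groups <- read_groups_tsv(ds$groups)
      tb <- diff_activity(act, groups, contrast = cfg$contrast,
                          adjust = cfg$adjustment)
      utils::write.table(tb, diff_paths[i], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      tb
    })
  }

  intersection <- NULL
  inter_path <- NULL
  if (length(diffs) > 1L) {
    inter_path <- file.path(cfg$out_dir, "related_subpathways.tsv")
    intersection <- stage("intersect", {
      sig <- lapply(diffs, significant_set, alpha = cfg$alpha)
      inter <- intersect_significant(
        sig, direction_consistent = isTRUE(cfg$direction_consistency))
      for (i in seq_along(diffs)) {
        adj <- stats::setNames(diffs[[i]]$adj_p, diffs[[i]]$subpathway_id)
        inter[[sprintf("adj_p_%d", i)]] <- unname(
          adj[inter$subpathway_id])
      }
      utils::write.table(inter, inter_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      inter
    })
  }

  manifest <- list(
    package = "metaspw",
    version = as.character(utils::packageVersion("metaspw")),
    parameters = cfg[c("k", "min_size", "kcdf", "tau", "min_set",
                       "alpha", "adjustment", "direction_consistency",
                       "contrast")],
    inputs = lapply(cfg$datasets, function(ds) {
      list(expr = ds$expr, groups = ds$groups,
           expr_md5 = unname(tools::md5sum(ds$expr)),
           groups_md5 = unname(tools::md5sum(ds$groups)))
    }),
    outputs = c(gmt_path, diff_paths, inter_path))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(gmt = gmt_path, diff_paths = diff_paths,
                 diff_tables = diffs, intersection = intersection,
                 manifest = file.path(cfg$out_dir, "manifest.json")))
}
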