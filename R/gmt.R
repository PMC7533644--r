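#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file (tab-separated: set id, description,
#'   then member genes).
#' @return A named list of character vectors (one per set), with the
#'   per-set descriptions stored in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      stop("malformed GMT line (need id and description): ", ln,
           call. = FALSE)
    }
    id <- parts[[1L]]
    if (id %in% names(sets)) {
      stop("duplicate gene-set id in GMT file: ", id, call. = FALSE)
    }
    sets[[id]] <- parts[-(1:2)]
    desc[[id]] <- parts[[2L]]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors, e.g. the result of
#'   [mine_subpathways()] or [read_gmt()].
#' @param path Output path.
#' @param descriptions Optional named character vector of per-set
#'   descriptions; defaults to the `"descriptions"` attribute of `sets`,
#'   then to the set id itself.
#' @return Invisibly, `path`. Writing then reading back with [read_gmt()]
#'   reproduces the collection.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  ids <- names(sets)
  if (length(sets) > 0L && (is.null(ids) || anyDuplicated(ids) ||
                            any(!nzchar(ids)))) {
    stop("gene sets must have unique non-empty ids", call. = FALSE)
  }
  descriptions <- descriptions %||% attr(sets, "descriptions")
  lines <- vapply(ids, function(id) {
    d <- if (!is.null(descriptions) && !is.na(descriptions[id]))
      descriptions[[id]] else id
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
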