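#' Empirical-Bayes moderated two-group t-statistics
#'
#' For every subpathway (row) of an activity matrix, computes the
#' case-minus-control mean difference, the pooled within-group variance
#' s_g^2 on d_g = n1 + n2 - 2 degrees of freedom, and a moderated
#' t-statistic in which s_g^2 is shrunk toward a prior variance s0^2
#' estimated from all rows: the posterior variance is
#' (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g) and the statistic is referred to
#' a t distribution on d0 + d_g degrees of freedom.
#'
#' The prior (d0, s0^2) is fitted by the method of moments for a scaled F
#' distribution of the sample variances: with z_g = log s_g^2, d0 solves
#' trigamma(d0/2) = var(z) - trigamma(d_g/2) (monotone root-finding on the
#' trigamma inverse) and log s0^2 = mean(z) - digamma(d_g/2) + log(d_g/2)
#' + digamma(d0/2) - log(d0/2). When var(z) <= trigamma(d_g/2) the
#' variances are consistent with a single common value, d0 = Inf, and the
#' posterior variance equals s0^2 for every row (p-values become normal).
#'
#' @param activity Numeric matrix, subpathways x samples (rownames and
#'   colnames required).
#' @param groups Sample-to-group assignment: a named character vector
#'   (names = sample ids), or a data frame whose first two columns are
#'   sample id and group label.
#' @param contrast Length-2 character vector `c(case, control)`.
#' @param prior_df Optional fixed prior degrees of freedom d0; `0` gives
#'   the classical pooled two-sample t, `Inf` full shrinkage. `NULL`
#'   (default) estimates d0 from the data, which needs >= 2 rows.
#' @return An object of class `moderated_fit`: a list with `table` (data
#'   frame: `subpathway_id`, `delta`, `s2`, `s2_post`, `t`, `df_total`,
#'   `p`), `d0`, `s02`, `contrast`, and the group sizes.
#' @export
fit_moderated_t <- function(activity, groups, contrast,
                            prior_df = NULL) {
  stopifnot(is.matrix(activity), !is.null(rownames(activity)),
            !is.null(colnames(activity)))
  groups <- as_group_vector(groups)
  missing_s <- setdiff(colnames(activity), names(groups))
  if (length(missing_s) > 0L) {
    stop("samples absent from the group design: ",
         paste(utils::head(missing_s, 5L), collapse = ", "), call. = FALSE)
  }
  if (length(contrast) != 2L) {
    stop("`contrast` must be c(case, control)", call. = FALSE)
  }
  g <- groups[colnames(activity)]
  case <- which(g == contrast[[1L]])
  ctrl <- which(g == contrast[[2L]])
  n1 <- length(case); n2 <- length(ctrl)
  if (n1 < 2L || n2 < 2L) {
    stop(sprintf("each contrast group needs >= 2 samples (got %d vs %d)",
                 n1, n2), call. = FALSE)
  }
  if (is.null(prior_df) && nrow(activity) < 2L) {
    stop("estimating the variance prior needs >= 2 rows; pass prior_df",
         call. = FALSE)
  }

  xc <- activity[, case, drop = FALSE]
  xk <- activity[, ctrl, drop = FALSE]
  delta <- rowMeans(xc) - rowMeans(xk)
  ss1 <- rowSums((xc - rowMeans(xc))^2)
  ss2 <- rowSums((xk - rowMeans(xk))^2)
  dg <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / dg

  if (is.null(prior_df)) {
    fit <- fit_f_prior(s2, dg)
    d0 <- fit$d0
    s02 <- fit$s02
  } else {
    assert_scalar_number(prior_df, "prior_df", lower = 0)
    d0 <- prior_df
    zp <- log(s2[s2 > 0])
    s02 <- if (length(zp) > 0L) exp(mean(zp)) else NA_real_
  }

  s2_post <- if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s02 + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- delta / se
  df_total <- d0 + dg
  p <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  if (any(!is.finite(tstat))) {
    warning("zero posterior variance for some rows; t and p set to NaN")
    p[!is.finite(tstat)] <- NaN
    tstat[!is.finite(tstat)] <- NaN
  }

  structure(
    list(table = data.frame(subpathway_id = rownames(activity),
                            delta = delta, s2 = s2, s2_post = s2_post,
                            t = tstat, df_total = df_total, p = p,
                            row.names = NULL),
         d0 = d0, s02 = s02, dg = dg,
         contrast = contrast, n1 = n1, n2 = n2),
    class = "moderated_fit")
}

# Method-of-moments fit of the scaled-F model to sample variances.
fit_f_prior <- function(s2, dg) {
  z <- log(s2)
  if (any(!is.finite(z))) {
    # zero variances carry no usable log; fit on the finite ones
    z <- z[is.finite(z)]
    if (length(z) < 2L) stop("too few positive variances to fit the prior",
                             call. = FALSE)
  }
  vz <- stats::var(z)
  target <- vz - trigamma(dg / 2)
  if (is.na(target) || target <= 0) {
    # variances consistent with one common value: pool them directly
    return(list(d0 = Inf, s02 = mean(pmax(s2, 0))))
  } else {
    d0 <- 2 * trigamma_inverse(target)
    log_s02 <- mean(z) - digamma(dg / 2) + log(dg / 2) +
      digamma(d0 / 2) - log(d0 / 2)
    list(d0 = d0, s02 = exp(log_s02))
  }
}

# Solve trigamma(y) = x by Newton iteration; trigamma is monotone
# decreasing so the root is unique.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

as_group_vector <- function(groups) {
  if (is.data.frame(groups)) {
    stats::setNames(as.character(groups[[2L]]), as.character(groups[[1L]]))
  } else if (!is.null(names(groups))) {
    stats::setNames(as.character(groups), names(groups))
  } else {
    stop("`groups` must be a named vector or a two-column data frame",
         call. = FALSE)
  }
}

#' Benjamini-Hochberg (or Bonferroni) p-value adjustment
#'
#' Thin validated wrapper over [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, elementwise >= the raw ones, capped at 1.
#' @export
bh_adjust <- function(pvals, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!all(ok)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = method)
}

#' Differential-activity table
#'
#' Adds adjusted p-values and up/down direction to a [fit_moderated_t()]
#' result and sorts rows by adjusted then raw p-value.
#'
#' @param fit A `moderated_fit`.
#' @param adjust Multiple-testing adjustment, `"BH"` or `"bonferroni"`.
#' @return Data frame of class `diff_table` with columns `subpathway_id`,
#'   `delta`, `t`, `p`, `adj_p`, `direction`.
#' @export
diff_table <- function(fit, adjust = c("BH", "bonferroni")) {
  stopifnot(inherits(fit, "moderated_fit"))
  adjust <- match.arg(adjust)
  tb <- fit$table
  out <- data.frame(
    subpathway_id = tb$subpathway_id,
    delta = tb$delta,
    t = tb$t,
    p = tb$p,
    adj_p = bh_adjust(tb$p, adjust),
    direction = ifelse(tb$delta > 0, "up", "down"),
    row.names = NULL)
  out <- out[order(out$adj_p, out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diff_table", "data.frame")
  out
}

#' One-call differential analysis of an activity matrix
#'
#' @inheritParams fit_moderated_t
#' @inheritParams diff_table
#' @return A `diff_table`.
#' @export
diff_activity <- function(activity, groups, contrast,
                          adjust = c("BH", "bonferroni"),
                          prior_df = NULL) {
  diff_table(fit_moderated_t(activity, groups, contrast,
                             prior_df = prior_df),
             adjust = match.arg(adjust))
}

#' Significantly different subpathways
#'
#' @param table A `diff_table`.
#' @param alpha Significance level on the adjusted p-value; strict
#'   (`adj_p < alpha`), default 0.05.
#' @return Data frame with `subpathway_id` and `direction` (`"up"` if the
#'   case-minus-control difference is positive, else `"down"`).
#' @export
significant_set <- function(table, alpha = 0.05) {
  stopifnot(is.data.frame(table))
  sel <- !is.na(table$adj_p) & table$adj_p < alpha
  out <- table[sel, c("subpathway_id", "direction"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect significant subpathways across datasets
#'
#' An id is retained when it is significant in every dataset; with
#' `direction_consistent = TRUE` (default) its up/down direction must also
#' agree across all datasets.
#'
#' @param sets List of [significant_set()] data frames (or plain character
#'   vectors of ids, in which case direction checking is skipped for
#'   those entries).
#' @param direction_consistent Require a common direction.
#' @return Data frame with `subpathway_id` and `direction` (`NA` when no
#'   direction information was available).
#' @export
intersect_significant <- function(sets, direction_consistent = TRUE) {
  if (length(sets) == 0L) stop("need at least one set", call. = FALSE)
  norm <- lapply(sets, function(s) {
    if (is.character(s)) {
      data.frame(subpathway_id = s, direction = NA_character_)
    } else {
      s[, c("subpathway_id", "direction"), drop = FALSE]
    }
  })
  ids <- Reduce(intersect, lapply(norm, `[[`, "subpathway_id"))
  dir_of <- function(id) {
    d <- unlist(lapply(norm, function(s) {
      s$direction[s$subpathway_id == id]
    }))
    d <- d[!is.na(d)]
    if (length(d) == 0L) return(NA_character_)
    if (length(unique(d)) == 1L) unique(d) else "conflict"
  }
  dirs <- vapply(ids, dir_of, character(1))
  if (direction_consistent) {
    keep <- dirs != "conflict" | is.na(dirs)
    ids <- ids[keep]
    dirs <- dirs[keep]
  } else {
    dirs[dirs == "conflict"] <- NA_character_
  }
  data.frame(subpathway_id = ids, direction = unname(dirs),
             row.names = NULL)
}
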