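make_activity <- function(n_row, n1, n2, sd_row = NULL, seed = 1) {
  set.seed(seed)
  sd_row <- sd_row %||% rep(1, n_row)
  act <- t(sapply(seq_len(n_row), function(g) {
    rnorm(n1 + n2, sd = sd_row[g])
  }))
  dimnames(act) <- list(sprintf("sp%03d", seq_len(n_row)),
                        sprintf("s%02d", seq_len(n1 + n2)))
  act
}
`%||%` <- function(a, b) if (is.null(a)) b else a
two_groups <- function(act, n1) {
  stats::setNames(rep(c("case", "control"),
                      c(n1, ncol(act) - n1)), colnames(act))
}

test_that("d0 = 0 reproduces the classical pooled two-sample t exactly", {
  act <- make_activity(50, 8, 7, sd_row = runif(50, 0.5, 2), seed = 2)
  g <- two_groups(act, 8)
  fit <- fit_moderated_t(act, g, c("case", "control"), prior_df = 0)
  classical <- apply(act, 1, function(r) {
    tt <- t.test(r[g == "case"], r[g == "control"], var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  })
  expect_equal(fit$table$t, unname(classical[1, ]), tolerance = 1e-10)
  expect_equal(fit$table$p, unname(classical[2, ]), tolerance = 1e-10)
  expect_equal(fit$table$df_total, rep(13, 50))
})

test_that("identical sample variances are a shrinkage fixed point", {
  act <- make_activity(30, 6, 6, seed = 3)
  g <- two_groups(act, 6)
  # rescale within-group residuals so every row has pooled variance 1
  mu <- cbind(matrix(rowMeans(act[, g == "case"]), 30, 6),
              matrix(rowMeans(act[, g == "control"]), 30, 6))
  pooled <- rowSums((act - mu)^2) / 10
  act <- mu + (act - mu) / sqrt(pooled)
  s2 <- apply(act, 1, function(r) {
    (sum((r[g == "case"] - mean(r[g == "case"]))^2) +
       sum((r[g == "control"] - mean(r[g == "control"]))^2)) / 10
  })
  expect_equal(s2, rep(1, 30), ignore_attr = TRUE)
  for (d0 in list(0, 2, 50, NULL)) {
    fit <- fit_moderated_t(act, g, c("case", "control"), prior_df = d0)
    expect_equal(fit$table$s2_post, fit$table$s2, tolerance = 1e-10)
  }
})

test_that("the variance prior is recovered from scaled-chi-square draws", {
  set.seed(4)
  d0 <- 4; s02 <- 1; dg <- 10; n1 <- 6; n2 <- 6; G <- 200
  # hierarchical draw: row variance from the scaled inverse-chi-square
  # prior, then data with that variance
  s2g_true <- d0 * s02 / rchisq(G, df = d0)
  act <- t(sapply(seq_len(G), function(g) {
    rnorm(n1 + n2, sd = sqrt(s2g_true[g]))
  }))
  dimnames(act) <- list(sprintf("sp%03d", 1:G), sprintf("s%02d", 1:(n1 + n2)))
  g <- two_groups(act, n1)
  fit <- fit_moderated_t(act, g, c("case", "control"))
  expect_lt(abs(fit$d0 - d0) / d0, 0.5)
  expect_lt(abs(fit$s02 - s02) / s02, 0.5)

  # step-by-step oracle evaluation of the moderated statistic
  delta <- rowMeans(act[, g == "case"]) - rowMeans(act[, g == "control"])
  s2 <- apply(act, 1, function(r) {
    (sum((r[g == "case"] - mean(r[g == "case"]))^2) +
       sum((r[g == "control"] - mean(r[g == "control"]))^2)) / dg
  })
  s2_post <- (fit$d0 * fit$s02 + dg * s2) / (fit$d0 + dg)
  t_oracle <- delta / sqrt(s2_post * (1 / n1 + 1 / n2))
  expect_equal(fit$table$t, unname(t_oracle), tolerance = 1e-12)
  expect_equal(fit$table$p,
               unname(2 * pt(abs(t_oracle), fit$d0 + dg, lower.tail = FALSE)),
               tolerance = 1e-12)
  # posterior variances sit between the observed and prior variances
  expect_true(all(fit$table$s2_post >= pmin(s2, fit$s02) - 1e-12))
  expect_true(all(fit$table$s2_post <= pmax(s2, fit$s02) + 1e-12))
})

test_that("the empirical-Bayes fit matches limma's moderated statistics", {
  set.seed(5)
  for (rep in 1:3) {
    G <- 40; n1 <- 8; n2 <- 6
    act <- make_activity(G, n1, n2, sd_row = sqrt(1 / rgamma(G, 2, 2)),
                         seed = 50 + rep)
    g <- two_groups(act, n1)
    fit <- fit_moderated_t(act, g, c("case", "control"))
    design <- cbind(intercept = 1, case = as.integer(g == "case"))
    lf <- limma::eBayes(limma::lmFit(act, design))
    expect_equal(fit$d0, lf$df.prior, tolerance = 1e-6)
    expect_equal(fit$s02, lf$s2.prior, tolerance = 1e-6)
    expect_equal(fit$table$t, unname(lf$t[, "case"]), tolerance = 1e-9)
    expect_equal(fit$table$p, unname(lf$p.value[, "case"]), tolerance = 1e-9)
  }
})

test_that("fit is invariant to row order and antisymmetric in the contrast", {
  act <- make_activity(25, 5, 7, sd_row = runif(25, 0.5, 2), seed = 6)
  g <- two_groups(act, 5)
  fit <- fit_moderated_t(act, g, c("case", "control"))
  perm <- sample(25)
  fit_perm <- fit_moderated_t(act[perm, ], g, c("case", "control"))
  expect_equal(fit_perm$table$t,
               fit$table$t[match(fit_perm$table$subpathway_id,
                                 fit$table$subpathway_id)])
  swapped <- fit_moderated_t(act, g, c("control", "case"))
  expect_equal(swapped$table$t, -fit$table$t)
  expect_equal(swapped$table$delta, -fit$table$delta)
  expect_equal(swapped$table$p, fit$table$p)
})

test_that("group-design validation catches undersized and unknown groups", {
  act <- make_activity(5, 3, 3, seed = 7)
  g <- two_groups(act, 3)
  expect_error(fit_moderated_t(act[, 1:4], g[c(1:3, 4)],
                               c("case", "control")), ">= 2 samples")
  expect_error(fit_moderated_t(act, g[1:5], c("case", "control")),
               "absent from the group design")
  expect_error(fit_moderated_t(act[1, , drop = FALSE], g,
                               c("case", "control")), "prior_df")
  # zero-variance rows with no shrinkage propagate NaN with a warning
  act0 <- act
  act0[1, ] <- 5
  expect_warning(fit0 <- fit_moderated_t(act0, g, c("case", "control"),
                                         prior_df = 0), "NaN")
  expect_true(is.nan(fit0$table$p[1]))
})

test_that("BH adjustment wrapper validates and reproduces step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(8)
  p <- runif(20)
  expect_true(all(bh_adjust(p) >= p))
  expect_equal(bh_adjust(p, "bonferroni"), pmin(1, p * 20))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance is strict at alpha and intersection respects direction", {
  tb <- data.frame(subpathway_id = c("A", "B", "C"),
                   delta = c(1, -1, 2), t = c(3, -3, 1),
                   p = c(0.001, 0.002, 0.1),
                   adj_p = c(0.04, 0.05, 0.2),
                   direction = c("up", "down", "up"))
  sig <- significant_set(tb, alpha = 0.05)
  expect_equal(sig$subpathway_id, "A")            # adj_p = 0.05 excluded
  expect_equal(significant_set(tb[0, ], 0.05)$subpathway_id, character())
  expect_equal(significant_set(tb, alpha = 1.01)$subpathway_id,
               c("A", "B", "C"))

  s1 <- data.frame(subpathway_id = c("A", "B", "C"),
                   direction = c("up", "up", "down"))
  s2 <- data.frame(subpathway_id = c("B", "C", "D"),
                   direction = c("up", "down", "up"))
  s3 <- data.frame(subpathway_id = c("B", "C"),
                   direction = c("down", "down"))
  # plain id intersection
  inter_ids <- intersect_significant(list(s1, s2, s3),
                                     direction_consistent = FALSE)
  expect_setequal(inter_ids$subpathway_id, c("B", "C"))
  # B flips direction between cohorts, so consistency drops it
  inter_dir <- intersect_significant(list(s1, s2, s3))
  expect_equal(inter_dir$subpathway_id, "C")
  expect_equal(inter_dir$direction, "down")
  # single input is the identity
  expect_equal(intersect_significant(list(s1))$subpathway_id, s1$subpathway_id)
  # character inputs carry no direction information
  expect_setequal(intersect_significant(list(c("A", "B"), c("B")))$subpathway_id,
                  "B")
})

test_that("diff tables sort by adjusted p and tag directions", {
  act <- make_activity(20, 6, 6, seed = 9)
  act[3, 1:6] <- act[3, 1:6] + 3
  g <- two_groups(act, 6)
  tb <- diff_activity(act, g, c("case", "control"))
  expect_s3_class(tb, "diff_table")
  expect_equal(tb$subpathway_id[1], "sp003")
  expect_equal(tb$direction[1], "up")
  expect_true(all(tb$adj_p >= tb$p))
  expect_false(is.unsorted(tb$adj_p))
})

test_that("null activity keeps the significant fraction near alpha", {
  set.seed(10)
  sizes <- replicate(50, {
    act <- matrix(rnorm(100 * 40), 100, 40,
                  dimnames = list(sprintf("sp%03d", 1:100),
                                  sprintf("s%02d", 1:40)))
    g <- stats::setNames(sample(rep(c("case", "control"), 20)),
                         colnames(act))
    nrow(significant_set(diff_activity(act, g, c("case", "control")), 0.05))
  })
  expect_lte(mean(sizes), 10)  # <= 10% of 100 rows on average
})
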