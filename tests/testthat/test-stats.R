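# brute-force correlation oracles written from the definitions
pearson_bf <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
spearman_bf <- function(x, y) pearson_bf(rank(x), rank(y))

test_that("correlations agree with brute-force oracles to 1e-12", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 0.3 * x + rnorm(n)
    if (s %% 3 == 0) y <- round(y)    # inject ties to exercise midranks
    if (var(y) == 0) next
    expect_equal(correlate(x, y, "pearson")$estimate, pearson_bf(x, y),
                 tolerance = 1e-12)
    expect_equal(correlate(x, y, "spearman")$estimate, spearman_bf(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Spearman equals Pearson on midranks, including heavy ties", {
  set.seed(13)
  for (i in 1:25) {
    x <- sample(1:6, 30, replace = TRUE)
    y <- x + sample(0:3, 30, replace = TRUE)
    expect_equal(correlate(x, y, "spearman")$estimate,
                 correlate(rank(x), rank(y), "pearson")$estimate,
                 tolerance = 1e-12)
  }
})

test_that("identity and monotone-nonlinear pairs behave as expected", {
  x <- 1:10
  expect_equal(correlate(x, x, "pearson")$estimate, 1)
  expect_equal(correlate(x, x, "spearman")$estimate, 1)
  y <- exp(x)
  expect_equal(correlate(x, y, "spearman")$estimate, 1)
  expect_lt(correlate(x, y, "pearson")$estimate, 1)
  expect_error(correlate(x, rep(2, 10)), "zero variance")
  expect_error(correlate(1:2, 2:3), "at least 3")
})

test_that("auto method routes ordinal and non-normal data to Spearman", {
  set.seed(2)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  expect_equal(correlate(x, y, "auto")$method, "pearson")
  scores <- factor(sample(0:2, 30, TRUE), ordered = TRUE)
  expect_equal(correlate(x, scores, "auto")$method, "spearman")
  expect_equal(correlate(exp(rnorm(30, 0, 2)), y, "auto")$method, "spearman")
})

mk_table <- function(values, diet, week) {
  data.frame(animal = seq_along(values), diet = diet, week = week,
             region = "commissure", metric = "m", value = values)
}

test_that("compare_groups gates on residual normality", {
  set.seed(4)
  norm_tab <- mk_table(rnorm(24, 10), rep(c("control", "pro_calcific"), each = 12),
                       rep(rep(c(4, 16), each = 6), 2))
  r1 <- compare_groups(norm_tab, "m")
  expect_equal(r1$test_used, "anova_tukey")
  expect_setequal(r1$factors$term, c("diet", "week", "diet:week"))
  expect_equal(nrow(r1$contrasts), choose(4, 2))
  expect_true(all(r1$contrasts$p_adj >= 0 & r1$contrasts$p_adj <= 1))

  skew_tab <- mk_table(exp(rnorm(24, 0, 2.5)),
                       rep(c("control", "pro_calcific"), each = 12),
                       rep(rep(c(4, 16), each = 6), 2))
  r2 <- compare_groups(skew_tab, "m")
  expect_equal(r2$test_used, "kruskal_wallis")
  expect_equal(nrow(r2$contrasts), choose(4, 2))
})

test_that("degenerate tables raise errors instead of fake p-values", {
  expect_error(compare_groups(mk_table(rep(5, 12),
                                       rep(c("control", "pro_calcific"), each = 6), 4),
                              "m"), "constant")
  expect_error(compare_groups(mk_table(c(1, 2), c("control", "pro_calcific"), 4),
                              "m"), "2 observations")
  expect_error(compare_groups(mk_table(rnorm(6), "control", 4), "m"),
               "at least 2 groups")
})

test_that("Tukey-adjusted p never undercuts the unadjusted pairwise p", {
  set.seed(8)
  for (i in 1:10) {
    tab <- mk_table(rnorm(24, 10, 1 + i / 10),
                    rep(c("control", "pro_calcific"), each = 12),
                    rep(rep(c(4, 16), each = 6), 2))
    r <- compare_groups(tab, "m")
    if (r$test_used != "anova_tukey") next
    cell <- interaction(factor(tab$diet), factor(tab$week), sep = ":")
    pt <- stats::pairwise.t.test(tab$value, cell, p.adjust.method = "none",
                                 pool.sd = TRUE)$p.value
    lookup <- function(a, b) {
      v <- NA_real_
      if (a %in% rownames(pt) && b %in% colnames(pt)) v <- pt[a, b]
      if (is.na(v) && b %in% rownames(pt) && a %in% colnames(pt)) v <- pt[b, a]
      v
    }
    for (k in seq_len(nrow(r$contrasts))) {
      parts <- strsplit(r$contrasts$contrast[k], "-", fixed = TRUE)[[1]]
      p_un <- lookup(parts[1], parts[2])
      expect_gte(r$contrasts$p_adj[k] + 1e-12, p_un)
    }
  }
})

test_that("empirical type-I error of the gated comparison sits near alpha", {
  # 300-table smoke version; the full 1000-replicate calibration runs with
  # the acceptance checks
  set.seed(99)
  hits <- 0L
  for (i in 1:300) {
    tab <- mk_table(rnorm(20), rep(c("control", "pro_calcific"), each = 10), 4)
    r <- compare_groups(tab, "m")
    p <- r$factors$p[1]
    if (p < 0.05) hits <- hits + 1L
  }
  expect_lt(abs(hits / 300 - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})
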