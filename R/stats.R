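#' Normality-gated group comparison (two-way ANOVA / Kruskal-Wallis)
#'
#' Compares a metric across diet groups and time points the way the study's
#' statistics layer does: fit `value ~ diet * week`, test residual normality
#' (Shapiro-Wilk at `alpha`); if residuals pass, report Type-II two-way
#' ANOVA F tests for diet, week and their interaction plus Tukey HSD
#' contrasts over all diet-by-week cells; if not, fall back to a
#' Kruskal-Wallis rank test over the cells with Dunn-style pairwise rank
#' contrasts (z from the shared ranking, tie-corrected, Holm-adjusted).
#' Degenerate tables (constant values) raise an error rather than returning
#' p = 0. When only one factor varies the model collapses to a one-way
#' layout automatically.
#'
#' @param table long-format study table: data.frame with columns `diet`,
#'   `week`, `region`, `metric`, `value` (plus `animal`).
#' @param metric,region which records to compare.
#' @param alpha significance level for the normality gate (default 0.05).
#' @return a `comparison_result`: list with `test_used` (`"anova_tukey"` or
#'   `"kruskal_wallis"`), `normality_p`, `factors` (term/statistic/p),
#'   `contrasts` (all pairwise cell contrasts with adjusted p), `cell_means`,
#'   `alpha`.
#' @export
compare_groups <- function(table, metric, region = NULL, alpha = 0.05) {
  d <- table[table$metric == metric, , drop = FALSE]
  if (!is.null(region)) d <- d[d$region == region, , drop = FALSE]
  d <- d[is.finite(d$value), , drop = FALSE]
  if (nrow(d) == 0L) stop("no records for metric '", metric, "'")
  d$diet <- factor(d$diet)
  d$week <- factor(d$week)
  cell <- interaction(d$diet, d$week, drop = TRUE, sep = ":")
  if (nlevels(cell) < 2L) stop("need at least 2 groups")
  if (any(tabulate(cell) < 2L)) stop("need >= 2 observations per group")
  if (stats::var(d$value) == 0) stop("constant data: comparison is degenerate")

  two_way <- nlevels(d$diet) > 1L && nlevels(d$week) > 1L
  fml <- if (two_way) value ~ diet * week
         else if (nlevels(d$diet) > 1L) value ~ diet else value ~ week
  fit <- stats::lm(fml, data = d)
  res <- stats::residuals(fit)
  norm_p <- tryCatch(stats::shapiro.test(res)$p.value, error = function(e) 0)
  cm <- stats::aggregate(value ~ cell, data = data.frame(value = d$value, cell = cell), mean)
  names(cm) <- c("cell", "mean")
  cm$n <- as.vector(table(cell)[as.character(cm$cell)])

  if (norm_p >= alpha) {
    a2 <- car::Anova(fit, type = 2)
    terms <- rownames(a2)
    keep <- terms != "Residuals"
    factors <- data.frame(term = terms[keep],
                          statistic = a2[keep, "F value"],
                          p = a2[keep, "Pr(>F)"])
    cfit <- stats::aov(value ~ cell, data = data.frame(value = d$value, cell = cell))
    tk <- stats::TukeyHSD(cfit)$cell
    contrasts <- data.frame(contrast = rownames(tk),
                            estimate = tk[, "diff"],
                            p_adj = tk[, "p adj"], row.names = NULL)
    test_used <- "anova_tukey"
  } else {
    kw <- stats::kruskal.test(d$value, cell)
    factors <- data.frame(term = "groups",
                          statistic = unname(kw$statistic), p = kw$p.value)
    contrasts <- dunn_contrasts(d$value, cell)
    test_used <- "kruskal_wallis"
  }
  structure(list(test_used = test_used, normality_p = norm_p,
                 factors = factors, contrasts = contrasts,
                 cell_means = cm, alpha = alpha),
            class = "comparison_result")
}

# Dunn's rank contrasts from the shared Kruskal-Wallis ranking, with the
# usual tie correction; Holm-adjusted two-sided p-values.
dunn_contrasts <- function(value, group) {
  rk <- rank(value)
  n <- length(value)
  ties <- table(value)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(group)
  rb <- tapply(rk, group, mean)
  ng <- tapply(rk, group, length)
  pairs <- utils::combn(lv, 2)
  z <- p <- est <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ng[[a]] + 1 / ng[[b]]))
    z[k] <- (rb[[a]] - rb[[b]]) / se
    est[k] <- rb[[a]] - rb[[b]]
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(contrast = paste(pairs[2, ], pairs[1, ], sep = "-"),
             estimate = -est, z = -z,
             p_adj = stats::p.adjust(p, "holm"), row.names = NULL)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>", x$test_used,
      sprintf("(residual normality p = %.4f)\n", x$normality_p))
  print(x$factors, row.names = FALSE)
  cat("contrasts:\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Correlation with method selection
#'
#' Pearson's correlation for normally distributed pairs, Spearman's rank
#' correlation (midranks for ties) for ordinal or non-normal data.
#' `method = "auto"` picks Spearman when either input is an ordered factor /
#' ordinal score or fails a Shapiro-Wilk normality check at 0.05, Pearson
#' otherwise.
#'
#' @param x,y paired numeric vectors (ordered factors are accepted and
#'   treated as ordinal). Pairs with missing values are dropped; at least 3
#'   complete pairs are required and both sides must vary.
#' @param method `"pearson"`, `"spearman"` or `"auto"`.
#' @return data.frame with `method`, `estimate`, `p`, `n`.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  ordinal <- is.ordered(x) || is.ordered(y)
  if (is.factor(x)) x <- as.numeric(x)
  if (is.factor(y)) y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation is undefined")
  if (method == "auto") {
    nonnormal <- function(v) {
      p <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
      p < 0.05
    }
    method <- if (ordinal || nonnormal(x) || nonnormal(y)) "spearman" else "pearson"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  data.frame(method = method, estimate = unname(ct$estimate),
             p = ct$p.value, n = n)
}
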