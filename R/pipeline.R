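#' Per-section metric extraction
#'
#' Runs every applicable quantification stage on one dataset — TPEF region
#' summary (with a background-estimated intensity floor), QPLI fiber maps,
#' local directional variance and region summary, ARS percent-area and PSR
#' hue binning — and returns the results as long-format records ready for
#' the statistics layer. Stages whose inputs are absent from the dataset are
#' skipped.
#'
#' @param ds a `phantom_dataset` (or any list with the same fields built
#'   from real images).
#' @param variance_window,variance_min_count window parameters for
#'   [directional_variance()].
#' @param collagen_threshold_deg retardation threshold for collagen-positive
#'   pixels.
#' @param ars_threshold,ars_min_particle parameters for
#'   [ars_percent_area()].
#' @return data.frame with columns `region`, `metric`, `value`.
#' @export
analyze_dataset <- function(ds, variance_window = 11L, variance_min_count = 10L,
                            collagen_threshold_deg = 5,
                            ars_threshold = 100, ars_min_particle = 4L) {
  masks <- ds$masks
  rows <- list()
  long <- function(df, cols) {
    do.call(rbind, lapply(cols, function(cl)
      data.frame(region = df$region, metric = cl, value = df[[cl]])))
  }
  if (!is.null(ds$channels)) {
    floor1 <- estimate_intensity_floor(ds$channels, masks, "755_860")
    ts <- tpef_region_summary(ds$channels, masks, floor = floor1)
    rows$tpef <- long(ts, c("mean_a755_460", "mean_a860_525", "mean_a810_460",
                            "mean_a810_525", "mean_ratio_755_860",
                            "mean_ratio_col_cal"))
  }
  if (!is.null(ds$stack)) {
    fm <- fit_retardation_orientation(ds$stack,
                                      collagen_threshold_deg = collagen_threshold_deg)
    vm <- directional_variance(fm, variance_window, variance_min_count)
    qs <- qpli_region_summary(fm, vm, masks)
    rows$qpli <- long(qs, c("mean_retardation_deg", "mean_directional_variance",
                            "collagen_density"))
  }
  if (!is.null(ds$ars)) {
    ar <- ars_percent_area(ds$ars, masks, threshold = ars_threshold,
                           min_particle = ars_min_particle)
    rows$ars <- long(ar$per_region, "percent_positive_area")
    rows$ars$metric <- "ars_percent_area"
  }
  if (!is.null(ds$psr)) {
    pb <- psr_bin(ds$psr, masks)
    rows$psr <- long(pb, grep("^pct_", names(pb), value = TRUE))
  }
  if (!is.null(ds$truth$region_calcium)) {
    rows$truth <- data.frame(region = names(ds$truth$region_calcium),
                             metric = "truth_calcium",
                             value = unname(ds$truth$region_calcium))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the long-format study table
#'
#' Applies [analyze_dataset()] to every section of a study and binds the
#' records with the animal metadata.
#'
#' @param study a `phantom_study` from [generate_study()].
#' @param ... forwarded to [analyze_dataset()].
#' @return data.frame with `animal`, `diet`, `week`, `region`, `metric`,
#'   `value`.
#' @export
study_table <- function(study, ...) {
  stopifnot(inherits(study, "phantom_study"))
  out <- lapply(names(study$datasets), function(id) {
    rec <- analyze_dataset(study$datasets[[id]], ...)
    meta <- study$info[study$info$animal == id, c("animal", "diet", "week")]
    cbind(meta[rep(1, nrow(rec)), ], rec, row.names = NULL)
  })
  do.call(rbind, out)
}

run_correlations <- function(tab) {
  wide <- function(metric, region = NULL) {
    d <- tab[tab$metric == metric & is.finite(tab$value), ]
    if (!is.null(region)) d <- d[d$region == region, ]
    if (nrow(d) == 0L) return(NULL)
    stats::aggregate(value ~ animal, data = d, mean)
  }
  pair <- function(mx, my, region, method, label) {
    a <- wide(mx, region); b <- wide(my, region)
    if (is.null(a) || is.null(b)) return(NULL)
    m <- merge(a, b, by = "animal")
    if (nrow(m) < 3L || stats::var(m$value.x) == 0 || stats::var(m$value.y) == 0)
      return(NULL)
    ct <- correlate(m$value.x, m$value.y, method)
    data.frame(x = mx, y = my, scope = label, method = ct$method,
               estimate = ct$estimate, p = ct$p, n = ct$n)
  }
  specs <- list(
    list("mean_ratio_755_860", "truth_calcium", "commissure", "spearman"),
    list("mean_ratio_755_860", "truth_calcium", NULL, "spearman"),
    list("mean_ratio_755_860", "mean_directional_variance", NULL, "pearson"),
    list("mean_retardation_deg", "mean_directional_variance", NULL, "pearson"),
    list("mean_ratio_755_860", "ars_percent_area", "commissure", "spearman"),
    list("mean_a810_460", "collagen_density", NULL, "pearson"),
    list("mean_a810_525", "collagen_density", NULL, "pearson"))
  out <- lapply(specs, function(s)
    pair(s[[1]], s[[2]], s[[3]], s[[4]],
         if (is.null(s[[3]])) "pooled" else s[[3]]))
  do.call(rbind, out)
}

#' Run the full analysis pipeline on a phantom study
#'
#' End-to-end driver: extracts per-region metrics from every section,
#' runs the normality-gated group comparisons for the headline metrics,
#' computes the correlation panel (pooled across regions and per-region,
#' labelled by scope), derives echo volumes/EF/CO and aggregates rater
#' scores. Deterministic given the study object. If `out_dir` is given, the
#' report tables are written there as CSV.
#'
#' @param study a `phantom_study`.
#' @param out_dir optional output directory for CSV tables.
#' @param compare_metrics metrics to pass through [compare_groups()]
#'   (per region).
#' @param ... forwarded to [analyze_dataset()].
#' @return a `pipeline_report`: list with `table` (long metric records),
#'   `comparisons` (named list of `comparison_result`), `correlations`,
#'   `echo`, `scores`, `seed`.
#' @export
run_pipeline <- function(study, out_dir = NULL,
                         compare_metrics = c("mean_ratio_755_860",
                                             "mean_ratio_col_cal",
                                             "ars_percent_area"),
                         ...) {
  stopifnot(inherits(study, "phantom_study"))
  tab <- study_table(study, ...)
  comparisons <- list()
  for (met in intersect(compare_metrics, unique(tab$metric))) {
    for (reg in unique(tab$region)) {
      key <- paste(met, reg, sep = ".")
      comparisons[[key]] <- tryCatch(
        compare_groups(tab, met, reg),
        error = function(e) structure(list(error = conditionMessage(e)),
                                      class = "comparison_skipped"))
    }
  }
  correlations <- run_correlations(tab)
  echo <- NULL
  if (!is.null(study$echo_table)) {
    ed <- echo_derive(study$echo_table$lvidd_mm, study$echo_table$lvids_mm,
                      study$echo_table$hr_bpm)
    echo <- cbind(study$echo_table[c("animal", "diet", "week")],
                  ed[c("edv", "esv", "ef", "co")])
  }
  scores <- NULL
  if (!is.null(study$score_table)) {
    st <- study$score_table
    scores <- do.call(rbind, lapply(
      split(st, list(st$animal, st$marker), drop = TRUE), function(d) {
        ag <- aggregate_scores(d$score, n_raters = nrow(d))
        data.frame(animal = d$animal[1], diet = d$diet[1], week = d$week[1],
                   marker = d$marker[1], mean_score = ag$mean,
                   grade = as.character(ag$grade))
      }))
    rownames(scores) <- NULL
  }
  report <- structure(list(table = tab, comparisons = comparisons,
                           correlations = correlations, echo = echo,
                           scores = scores, seed = study$config$seed),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @rdname run_pipeline
#' @param report a `pipeline_report`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$table, file.path(out_dir, "metrics_long.csv"),
                   row.names = FALSE)
  if (!is.null(report$correlations))
    utils::write.csv(report$correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
  if (!is.null(report$echo))
    utils::write.csv(report$echo, file.path(out_dir, "echo_derived.csv"),
                     row.names = FALSE)
  if (!is.null(report$scores))
    utils::write.csv(report$scores, file.path(out_dir, "ihc_grades.csv"),
                     row.names = FALSE)
  comp <- do.call(rbind, lapply(names(report$comparisons), function(k) {
    cr <- report$comparisons[[k]]
    if (!inherits(cr, "comparison_result")) return(NULL)
    data.frame(comparison = k, test = cr$test_used,
               normality_p = cr$normality_p,
               term = cr$factors$term, statistic = cr$factors$statistic,
               p = cr$factors$p)
  }))
  if (!is.null(comp))
    utils::write.csv(comp, file.path(out_dir, "group_comparisons.csv"),
                     row.names = FALSE)
  contr <- do.call(rbind, lapply(names(report$comparisons), function(k) {
    cr <- report$comparisons[[k]]
    if (!inherits(cr, "comparison_result")) return(NULL)
    cbind(comparison = k, test = cr$test_used,
          cr$contrasts[c("contrast", "estimate", "p_adj")])
  }))
  if (!is.null(contr))
    utils::write.csv(contr, file.path(out_dir, "pairwise_contrasts.csv"),
                     row.names = FALSE)
  invisible(out_dir)
}

#' Headline disease signatures of a report
#'
#' Checks the three qualitative signatures the pipeline is designed to
#' surface on a calcific study: (1) the commissure 755-860 ratio of
#' pro-calcific week-16 animals is lower than week-16 controls with a
#' significant adjusted pairwise contrast; (2) the commissure 755-860 ratio
#' correlates negatively (p < 0.05) with the ground-truth calcium burden;
#' (3) ARS percent-area in pro-calcific animals increases from the earliest
#' to the latest week.
#'
#' @param report a `pipeline_report` from a study containing weeks 4 and 16
#'   (and ideally 28) for both diets.
#' @return named logical vector
#'   `c(lower_ratio, negative_correlation, ars_increase)`.
#' @export
headline_signs <- function(report) {
  tab <- report$table
  lower_ratio <- FALSE
  cr <- report$comparisons[["mean_ratio_755_860.commissure"]]
  if (inherits(cr, "comparison_result")) {
    cm <- cr$cell_means
    mp <- cm$mean[cm$cell == "pro_calcific:16"]
    mc <- cm$mean[cm$cell == "control:16"]
    ct <- cr$contrasts
    hit <- grepl("pro_calcific:16", ct$contrast) & grepl("control:16", ct$contrast)
    if (length(mp) == 1 && length(mc) == 1 && any(hit))
      lower_ratio <- mp < mc && min(ct$p_adj[hit]) < 0.05
  }
  neg <- report$correlations
  neg <- neg[neg$x == "mean_ratio_755_860" & neg$y == "truth_calcium" &
             neg$scope == "commissure", ]
  negative_correlation <- nrow(neg) == 1 && neg$estimate < 0 && neg$p < 0.05
  ars <- tab[tab$metric == "ars_percent_area" & tab$diet == "pro_calcific", ]
  ars_increase <- FALSE
  if (nrow(ars) > 0 && length(unique(ars$week)) >= 2) {
    m <- tapply(ars$value, ars$week, mean)
    ars_increase <- unname(m[length(m)] > m[1])
  }
  c(lower_ratio = lower_ratio, negative_correlation = negative_correlation,
    ars_increase = ars_increase)
}
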