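# Aggregation and statistical comparison of per-field-of-view metrics.

#' Build a tidy metric table
#'
#' One row per (field of view, metric): columns `condition`, `timepoint_h`,
#' `well`, `fov`, `metric`, `value`.
#'
#' @param condition,timepoint_h,well,fov,metric,value equal-length vectors.
#' @return A `data.frame` of class `MetricTable`.
#' @export
metric_table <- function(condition, timepoint_h, well, fov, metric, value) {
  df <- data.frame(condition = condition, timepoint_h = timepoint_h,
                   well = well, fov = fov, metric = metric, value = value,
                   stringsAsFactors = FALSE)
  dup <- duplicated(df[, c("fov", "well", "condition", "timepoint_h",
                           "metric")])
  if (any(dup)) stop("one value per (fov, metric) is required")
  class(df) <- c("MetricTable", "data.frame")
  df
}

#' Aggregate metrics to field-of-view or well level
#'
#' Unweighted means within the requested grouping; the number of
#' contributing values is recorded as `n`. Missing values are dropped
#' (means are over the available fields of view).
#'
#' @param table a [metric_table()].
#' @param level `"fov"` (identity grouping) or `"well"` (mean over each
#'   well's fields of view).
#' @return Aggregated `data.frame` with an `n` column.
#' @export
aggregate_metrics <- function(table, level = c("fov", "well")) {
  level <- match.arg(level)
  if (nrow(table) == 0L) stop("empty metric table")
  df <- table[!is.na(table$value), , drop = FALSE]
  keys <- if (level == "fov") {
    c("condition", "timepoint_h", "well", "fov", "metric")
  } else {
    c("condition", "timepoint_h", "well", "metric")
  }
  agg <- stats::aggregate(df$value, by = df[keys], FUN = mean)
  names(agg)[names(agg) == "x"] <- "value"
  cnt <- stats::aggregate(df$value, by = df[keys], FUN = length)
  agg$n <- cnt$x
  agg[do.call(order, agg[keys]), , drop = FALSE]
}

#' One-way ANOVA with Tukey-Kramer post-hoc comparisons
#'
#' Standard one-way ANOVA across groups followed by Tukey's honest
#' significant difference test with the Kramer adjustment for unequal group
#' sizes; pairs are flagged significant at `alpha`. Degenerate input in
#' which every group has zero variance and equal means reports F = 0,
#' p = 1; zero within-group variance with differing means reports
#' F = Inf, p = 0.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @param alpha significance level (default 0.05).
#' @return A `ComparisonResult`: list with `anova` (F, df1, df2, p) and
#'   `tukey` data frame (pair, difference, adjusted p, significant).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 values")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                levels = names(groups))
  k <- length(groups)
  pairs_idx <- utils::combn(names(groups), 2L)
  pair_names <- paste(pairs_idx[2L, ], pairs_idx[1L, ], sep = "-")
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    means <- vapply(groups, mean, numeric(1))
    same <- max(means) == min(means)
    Fst <- if (same) 0 else Inf
    p <- if (same) 1 else 0
    tuk <- data.frame(pair = pair_names,
                      diff = means[pairs_idx[2L, ]] - means[pairs_idx[1L, ]],
                      p_adj = if (same) 1 else 0)
    tuk$significant <- tuk$p_adj < alpha & tuk$diff != 0
    res <- list(anova = data.frame(F = Fst, df1 = k - 1L,
                                   df2 = length(value) - k, p = p),
                tukey = tuk, alpha = alpha)
    class(res) <- "ComparisonResult"
    return(res)
  }
  fit <- stats::aov(value ~ grp)
  sfit <- summary(fit)[[1L]]
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$grp
  tuk <- data.frame(pair = rownames(hsd), diff = hsd[, "diff"],
                    p_adj = hsd[, "p adj"])
  tuk$significant <- tuk$p_adj < alpha
  rownames(tuk) <- NULL
  res <- list(anova = data.frame(F = sfit[["F value"]][1L],
                                 df1 = sfit[["Df"]][1L],
                                 df2 = sfit[["Df"]][2L],
                                 p = sfit[["Pr(>F)"]][1L]),
              tukey = tuk, alpha = alpha)
  class(res) <- "ComparisonResult"
  res
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A `ComparisonResult` list: `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  res <- list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
  class(res) <- "ComparisonResult"
  res
}

#' @export
print.ComparisonResult <- function(x, ...) {
  if (!is.null(x$anova)) {
    cat(sprintf("One-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
                x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
    sig <- x$tukey[x$tukey$significant, , drop = FALSE]
    cat(sprintf("Tukey-Kramer: %d/%d pairs significant at %.2g\n",
                nrow(sig), nrow(x$tukey), x$alpha))
  } else {
    cat(sprintf("Pearson: r = %.3f, p = %.3g, n = %d\n", x$r, x$p, x$n))
  }
  invisible(x)
}
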