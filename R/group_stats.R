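# Nonparametric comparison of image-quality metrics across post-injection
# time points: Shapiro-Wilk normality per group, Kruskal-Wallis omnibus,
# Dunn's post hoc pairwise test, and boxplot summaries.

split_groups <- function(data, value, group) {
  stopifnot(is.data.frame(data))
  v <- data[[value]]; g <- data[[group]]
  if (is.null(v)) stop("no column '", value, "' in data")
  if (is.null(g)) stop("no column '", group, "' in data")
  split(v, factor(g, levels = unique(g)))
}

#' Shapiro-Wilk normality test per group
#'
#' @param data Data frame of metric values.
#' @param value,group Column names of the metric and the grouping label.
#' @return Tibble: group label, `n`, `W`, `p_value`, `normal`
#'   (p >= 0.05). Groups must have 3 to 5000 observations; a constant
#'   group yields `NA` statistics with a warning.
#' @export
shapiro_by_group <- function(data, value = "value", group = "time_point_min") {
  gs <- split_groups(data, value, group)
  purrr::imap_dfr(gs, function(x, lab) {
    if (length(x) < 3 || length(x) > 5000) {
      stop("group ", lab, ": Shapiro-Wilk needs 3 <= n <= 5000")
    }
    if (length(unique(x)) == 1) {
      warning("group ", lab, ": constant sample, normality undefined")
      return(tibble::tibble(!!group := lab, n = length(x),
                            W = NA_real_, p_value = NA_real_, normal = NA))
    }
    sw <- shapiro.test(x)
    tibble::tibble(!!group := lab, n = length(x),
                   W = unname(sw$statistic), p_value = sw$p.value,
                   normal = sw$p.value >= 0.05)
  })
}

#' Kruskal-Wallis rank-sum omnibus test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom (delegates to [stats::kruskal.test()]).
#'
#' @inheritParams shapiro_by_group
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, `n_groups`,
#'   `n_total`.
#' @examples
#' d <- data.frame(g = rep(1:2, each = 3), value = c(1, 2, 3, 4, 5, 6))
#' kruskal_wallis(d, group = "g")$statistic  # 3.857
#' @export
kruskal_wallis <- function(data, value = "value", group = "time_point_min") {
  gs <- split_groups(data, value, group)
  if (length(gs) < 2) stop("omnibus test needs >= 2 groups")
  all_v <- unlist(gs, use.names = FALSE)
  if (length(all_v) < 5) stop("omnibus test needs total n >= 5")
  if (length(unique(all_v)) == 1) {
    stop("no rank variation: all values identical across groups")
  }
  kw <- kruskal.test(gs)
  tibble::tibble(statistic = unname(kw$statistic),
                 df = unname(kw$parameter),
                 p_value = kw$p.value,
                 n_groups = length(gs), n_total = length(all_v))
}

#' Dunn's post hoc pairwise comparisons
#'
#' For each group pair (i, j) the tie-corrected rank-mean z statistic
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - sum(t^3 - t) / (12(N - 1))) *
#' (1/ni + 1/nj))` with a two-sided standard-normal p-value. Unadjusted by
#' default; `adjust = "bonferroni"` multiplies by the number of pairs.
#'
#' @inheritParams shapiro_by_group
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return Tibble: `group1`, `group2`, `z`, `p_value`, `significance`.
#' @export
dunn_posthoc <- function(data, value = "value", group = "time_point_min",
                         adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  gs <- split_groups(data, value, group)
  if (length(gs) < 2) stop("pairwise comparison needs >= 2 groups")
  all_v <- unlist(gs, use.names = FALSE)
  if (length(unique(all_v)) == 1) {
    stop("no rank variation: all values identical across groups")
  }
  N <- length(all_v)
  rk <- rank(all_v)
  idx <- rep(seq_along(gs), lengths(gs))
  rbar <- tapply(rk, idx, mean)
  n <- lengths(gs)
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(length(gs), 2)
  labs <- names(gs)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(var_base * (1 / n[i] + 1 / n[j]))
    z <- (rbar[i] - rbar[j]) / se
    tibble::tibble(group1 = labs[i], group2 = labs[j], z = unname(z),
                   p_value = 2 * pnorm(-abs(z)))
  })
  if (adjust == "bonferroni") {
    out$p_value <- pmin(out$p_value * ncol(pairs), 1)
  }
  out$significance <- vapply(out$p_value, significance_stars, character(1))
  out
}

#' Significance label for a p-value
#'
#' `"ns"` for p >= 0.05, then `"*"`, `"**"`, `"***"`, `"****"` for
#' p < 0.05, 0.01, 0.001, 0.0001 (most extreme applicable label, strict
#' inequalities).
#'
#' @param p A p-value in `[0, 1]`.
#' @return Character label.
#' @export
significance_stars <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Boxplot summary with 1.5 IQR whiskers
#'
#' Median and quartiles by linear interpolation between closest ranks
#' (quantile type 7); whiskers extend to the most extreme observations
#' within `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`; points outside are outliers.
#'
#' @param x Numeric vector, n >= 1.
#' @return List: `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @examples
#' boxplot_summary(c(1, 2, 3, 4, 100))$outliers
#' @export
boxplot_summary <- function(x) {
  stopifnot(length(x) >= 1, all(is.finite(x)))
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
  inside <- x >= lo & x <= hi
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(x[inside]), whisker_high = max(x[inside]),
       outliers = sort(x[!inside]))
}

#' Compare metric distributions across time points
#'
#' The full comparison procedure for one image-quality metric: Shapiro-Wilk
#' normality per time point, Kruskal-Wallis omnibus test across time
#' points, Dunn's post hoc pairwise comparisons with significance labels,
#' and per-group boxplot summaries.
#'
#' @inheritParams shapiro_by_group
#' @param adjust Dunn p-value adjustment, `"none"` (default) or
#'   `"bonferroni"`.
#' @param alpha Significance threshold (0.05).
#' @return An object of class `pa_comparison` with elements `normality`,
#'   `omnibus`, `pairwise`, `box`, `metric`, `alpha`. Supports [tidy()]
#'   (pairwise table), [glance()] (omnibus row), and [ggplot2::autoplot()].
#' @examples
#' samples <- sample_metric_groups(default_group_spec("gcnr"), seed = 1)
#' cmp <- compare_groups(samples, value = "value")
#' glance(cmp)
#' @export
compare_groups <- function(data, value = "value", group = "time_point_min",
                           adjust = c("none", "bonferroni"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  gs <- split_groups(data, value, group)
  if (length(gs) < 2) stop("comparison needs >= 2 groups")
  if (any(lengths(gs) < 3)) stop("each group needs n >= 3")
  box <- purrr::imap_dfr(gs, function(x, lab) {
    b <- boxplot_summary(x)
    tibble::tibble(!!group := lab, n = length(x), median = b$median,
                   q1 = b$q1, q3 = b$q3, whisker_low = b$whisker_low,
                   whisker_high = b$whisker_high,
                   n_outliers = length(b$outliers))
  })
  structure(list(normality = shapiro_by_group(data, value, group),
                 omnibus = kruskal_wallis(data, value, group),
                 pairwise = dunn_posthoc(data, value, group, adjust),
                 box = box, metric = value, group = group, alpha = alpha),
            class = "pa_comparison")
}

#' @export
print.pa_comparison <- function(x, ...) {
  cat("<pa_comparison> metric '", x$metric, "', ", x$omnibus$n_groups,
      " groups, N = ", x$omnibus$n_total, "\n", sep = "")
  cat("  Kruskal-Wallis H = ", signif(x$omnibus$statistic, 5),
      ", df = ", x$omnibus$df, ", p = ", format.pval(x$omnibus$p_value),
      "\n", sep = "")
  sig <- x$pairwise[x$pairwise$significance != "ns", ]
  cat("  ", nrow(sig), " of ", nrow(x$pairwise),
      " pairwise comparisons significant at alpha = ", x$alpha, "\n",
      sep = "")
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `pa_comparison` object.
#' @param ... Unused.
#' @export
tidy.pa_comparison <- function(x, ...) x$pairwise

#' @rdname compare_groups
#' @export
glance.pa_comparison <- function(x, ...) x$omnibus

#' Boxplot of metric distributions by time point
#'
#' Box = median and interquartile range; whiskers = extrema excluding
#' outliers beyond 1.5 IQR, which are drawn as points.
#'
#' @param object A `pa_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pa_comparison <- function(object, ...) {
  b <- object$box
  grp <- object$group
  b$label <- factor(b[[grp]], levels = b[[grp]])
  ggplot2::ggplot(b, ggplot2::aes(x = .data$label)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$whisker_low,
                                        ymax = .data$whisker_high),
                           width = 0.25) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$q1,
                                        ymax = .data$q3),
                           fill = "grey90", width = 0.6) +
    ggplot2::labs(x = "Time after injection (min)", y = object$metric)
}
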