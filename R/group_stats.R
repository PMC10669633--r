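# Group comparison of per-eye choroid metrics across control / MS / PD
# cohorts: per-group mean +/- SD summaries, a one-way ANOVA omnibus test,
# and Welch pairwise post hoc tests with Bonferroni adjustment. Metrics
# are assumed approximately normal within groups (parametric analysis).

check_groups <- function(values, group, min_k = 2L, min_n = 2L) {
  if (length(values) != length(group))
    stop("values and group must have equal length", call. = FALSE)
  if (anyNA(values) || anyNA(group))
    stop("missing values are not supported", call. = FALSE)
  group <- factor(group)
  n <- table(group)
  if (nlevels(group) < min_k)
    stop("need >= ", min_k, " groups", call. = FALSE)
  if (any(n < min_n))
    stop("every group needs >= ", min_n, " observations", call. = FALSE)
  group
}

#' Per-group mean and standard deviation of each metric
#'
#' @param table data frame with a `group` column and one numeric column
#'   per metric (by default `CA`, `COID`, `CD`).
#' @param metrics metric column names to summarize.
#' @return data frame with columns `group`, `metric`, `n`, `mean`, `sd`
#'   (sample SD, `n - 1` denominator; `NA` for single-observation
#'   groups).
#' @export
summarize_groups <- function(table, metrics = c("CA", "COID", "CD")) {
  if (!is.data.frame(table) || nrow(table) == 0 || !"group" %in% names(table))
    stop("table must be a nonempty data frame with a `group` column",
         call. = FALSE)
  metrics <- intersect(metrics, names(table))
  if (length(metrics) == 0) stop("no metric columns found", call. = FALSE)
  g <- factor(table$group)
  out <- lapply(metrics, function(m) {
    v <- table[[m]]
    data.frame(group = levels(g),
               metric = m,
               n = as.integer(table(g)),
               mean = as.numeric(tapply(v, g, mean)),
               sd = as.numeric(tapply(v, g, sd)))
  })
  do.call(rbind, out)
}

#' One-way ANOVA across groups
#'
#' Computes `F = (SSB / (k - 1)) / (SSW / (N - k))` from between- and
#' within-group sums of squares, with the p-value from the upper tail of
#' the F distribution ([stats::pf()]). Degenerate data with zero between-
#' and within-group variance yields `F = 0`, `p = 1`.
#'
#' @param values numeric vector of a metric.
#' @param group group label per value (`k >= 2` groups, each `n >= 2`).
#' @return an `anova_result` list: `F`, `df_between`, `df_within`, `p`,
#'   `group_means`, `group_sds`.
#' @export
one_way_anova <- function(values, group) {
  group <- check_groups(values, group)
  k <- nlevels(group); N <- length(values)
  gm <- tapply(values, group, mean)
  gn <- tapply(values, group, length)
  grand <- mean(values)
  ssb <- sum(gn * (gm - grand)^2)
  ssw <- sum((values - gm[group])^2)
  df1 <- k - 1L; df2 <- N - k
  if (ssw == 0 && ssb == 0) {
    f <- 0; p <- 1
  } else if (ssw == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = f, df_between = df1, df_within = df2, p = p,
                 group_means = setNames(as.numeric(gm), levels(group)),
                 group_sds = setNames(as.numeric(tapply(values, group, sd)),
                                      levels(group))),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

welch_p <- function(x, y) {
  if (sd(x) == 0 && sd(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  stats::t.test(x, y)$p.value
}

#' Pairwise Welch post hoc tests with Bonferroni adjustment
#'
#' All `k (k - 1) / 2` pairwise Welch t-tests, with
#' `p_adj = min(1, p * m)` and significance flags at `alpha`.
#'
#' @param values numeric vector of a metric.
#' @param group group label per value.
#' @param alpha significance level (default 0.05).
#' @return data frame with columns `group1`, `group2`, `mean_diff`, `p`,
#'   `p_adj`, `significant`.
#' @export
pairwise_posthoc <- function(values, group, alpha = 0.05) {
  group <- check_groups(values, group)
  lev <- levels(group)
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(pr) {
    x <- values[group == pr[1]]; y <- values[group == pr[2]]
    data.frame(group1 = pr[1], group2 = pr[2],
               mean_diff = mean(x) - mean(y),
               p = welch_p(x, y))
  })
  res <- do.call(rbind, res)
  res$p_adj <- stats::p.adjust(res$p, method = "bonferroni")
  res$significant <- res$p_adj < alpha
  res
}
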