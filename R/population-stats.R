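# Cohort-level statistics on per-individual mean symmetry scores: one-way
# fixed-effects ANOVA by locality, post hoc Student's t-tests, and summary
# tables. The one-way F depends on group data only through (mean, sd, n), so
# an exactly equivalent summary-statistics route is provided.

#' One-way fixed-effects ANOVA from raw scores
#'
#' `SSB = sum n_i (xbar_i - xbar)^2`, `SSW = sum_i sum_j (x_ij - xbar_i)^2`,
#' `F = (SSB / (k - 1)) / (SSW / (N - k))`, with the p-value from the central
#' F distribution.
#'
#' @param groups A named list of numeric score vectors, one per population
#'   (>= 2 groups, each n >= 2).
#' @return An object of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, and `summaries` (a data.frame of per-group mean/sd/n).
#' @export
anova_raw <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs n >= 2")
  k <- length(groups)
  ns <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw <= 0) stop("degenerate within-group variance (SSW = 0)")
  dfb <- k - 1L; dfw <- N - k
  F <- (ssb / dfb) / (ssw / dfw)
  new_anova_result(F, dfb, dfw,
                   summaries = data.frame(
                     population = names(groups) %||% paste0("group", seq_len(k)),
                     mean_r = unname(means),
                     sd = vapply(groups, sd, numeric(1), USE.NAMES = FALSE),
                     n = unname(ns)))
}

#' One-way ANOVA from group summary statistics
#'
#' Algebraically identical to [anova_raw()] on any raw data with the same
#' moments: `SSB` from the means and `SSW = sum (n_i - 1) s_i^2`.
#'
#' @param summaries A data.frame with columns `mean_r` (or `mean`), `sd`,
#'   `n` (each n >= 2), optionally `population`.
#' @return An `anova_result`.
#' @export
anova_summary <- function(summaries) {
  m <- summaries[["mean_r"]] %||% summaries[["mean"]]
  s <- summaries$sd; n <- summaries$n
  stopifnot(!is.null(m), !is.null(s), !is.null(n), length(m) >= 2,
            all(n >= 2), all(s >= 0))
  N <- sum(n); k <- length(m)
  gm <- sum(n * m) / N
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * s^2)
  if (ssw <= 0) stop("degenerate within-group variance (all sd = 0)")
  dfb <- k - 1L; dfw <- as.integer(N - k)
  F <- (ssb / dfb) / (ssw / dfw)
  new_anova_result(F, dfb, dfw,
                   summaries = data.frame(
                     population = summaries[["population"]] %||%
                       paste0("group", seq_len(k)),
                     mean_r = m, sd = s, n = n))
}

new_anova_result <- function(F, dfb, dfw, summaries, pairwise = NULL) {
  structure(list(F = F, df_between = as.integer(dfb),
                 df_within = as.integer(dfw),
                 p = stats::pf(F, dfb, dfw, lower.tail = FALSE),
                 summaries = summaries, pairwise = pairwise),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df_between, x$df_within, x$F, x$p))
  print(x$summaries, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("Post hoc pairwise t-tests:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Post hoc pairwise Student's t-tests
#'
#' All unordered group pairs, two-sided. The default is the classical
#' pooled-variance Student's t with `df = n1 + n2 - 2`; Welch's unequal
#' variance form is available behind `welch`. No multiple-testing correction
#' is applied by default; Bonferroni is available. The significance flag uses
#' the corrected p-value against `alpha`.
#'
#' @param groups A named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha Significance level, default 0.05.
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @param welch Use Welch's t instead of pooled-variance Student's t?
#' @return A data.frame with columns `group1`, `group2`, `t`, `df`, `p`,
#'   `p_adj`, `significant`.
#' @export
posthoc_ttests <- function(groups, alpha = 0.05,
                           correction = c("none", "bonferroni"),
                           welch = FALSE) {
  correction <- match.arg(correction)
  stopifnot(length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs n >= 2")
  nm <- names(groups) %||% paste0("group", seq_along(groups))
  pairs <- utils::combn(length(groups), 2)
  rows <- apply(pairs, 2, function(ij) {
    a <- groups[[ij[1]]]; b <- groups[[ij[2]]]
    n1 <- length(a); n2 <- length(b)
    if (welch) {
      se <- sqrt(var(a) / n1 + var(b) / n2)
      df <- se^4 / ((var(a) / n1)^2 / (n1 - 1) + (var(b) / n2)^2 / (n2 - 1))
    } else {
      sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    }
    t <- if (se > 0) (mean(a) - mean(b)) / se else 0
    p <- if (se > 0) 2 * stats::pt(-abs(t), df) else 1
    data.frame(group1 = nm[ij[1]], group2 = nm[ij[2]],
               t = t, df = df, p = p)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- switch(correction,
                      none = res$p,
                      bonferroni = pmin(1, res$p * nrow(res)))
  res$significant <- res$p_adj < alpha
  res
}

#' Summarize cohort scores by population
#'
#' Sample mean and sample SD (n - 1 denominator) of the per-individual mean
#' symmetry scores, per population, in first-appearance order.
#'
#' @param scores Numeric vector of per-individual mean R values.
#' @param population Population label per score.
#' @return A data.frame with columns `population`, `mean_r`, `sd`, `n`.
#' @export
summarize_cohort <- function(scores, population) {
  stopifnot(length(scores) == length(population))
  if (!length(scores))
    return(data.frame(population = character(0), mean_r = numeric(0),
                      sd = numeric(0), n = integer(0)))
  pops <- unique(population)
  do.call(rbind, lapply(pops, function(p) {
    s <- scores[population == p]
    data.frame(population = p, mean_r = mean(s),
               sd = if (length(s) > 1) sd(s) else 0, n = length(s))
  }))
}

#' Render a cohort summary in a three-decimal table layout
#' @param summary A data.frame from [summarize_cohort()].
#' @return A character matrix with columns
#'   `Population | Mean Symmetry Score (R) | +/-SD | N`.
#' @export
format_summary_table <- function(summary) {
  cbind(`Population` = as.character(summary$population),
        `Mean Symmetry Score (R)` = sprintf("%.3f", summary$mean_r),
        `+/-SD` = sprintf("%.3f", summary$sd),
        `N` = as.character(summary$n))
}
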