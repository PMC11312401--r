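#' Welch's t-test for two cohorts
#'
#' Unpaired two-sided Welch test (unequal variances, Satterthwaite degrees
#' of freedom) via [stats::t.test()], with the degenerate cases given
#' defined outputs: fewer than two observations per group, or zero variance
#' in both groups with equal means, return `t = 0, p = 1`; zero variance in
#' both groups with different means returns `|t| = Inf, p = 0`.
#'
#' @param group_a,group_b numeric vectors of per-cilium values.
#' @param paired logical; paired test (groups must then have equal length).
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
welch_t_test <- function(group_a, group_b, paired = FALSE) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2)
    return(list(statistic = 0, df = NA_real_, p_value = 1))
  degenerate <- if (paired) stats::sd(a - b) == 0
                else stats::sd(a) == 0 && stats::sd(b) == 0
  if (degenerate) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(statistic = 0, df = NA_real_, p_value = 1))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf,
                df = NA_real_, p_value = 0))
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' One-way analysis of variance across conditions
#'
#' Classic fixed-effects one-way ANOVA (between / within mean-square ratio,
#' p from the F distribution) via [stats::oneway.test()] with equal
#' variances. All-identical groups (zero within- and between-variance)
#' return `F = 0, p = 1` by convention.
#'
#' @param groups a list (optionally named) of numeric vectors, one per
#'   condition; at least two groups with at least two observations each.
#' @return A list with `statistic` (F), `df` (`c(between, within)`) and
#'   `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("one_way_anova needs at least two groups", call. = FALSE)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(vapply(groups, length, 0L) < 2))
    stop("every group needs at least two observations", call. = FALSE)
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  df1 <- length(groups) - 1
  df2 <- length(values) - length(groups)
  if (stats::sd(values) == 0)
    return(list(statistic = 0, df = c(df1, df2), p_value = 1))
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic),
       df = unname(c(ft$parameter[1], ft$parameter[2])),
       p_value = ft$p.value)
}
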