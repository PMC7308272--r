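#' Summary statistics for one variable
#'
#' The descriptive block used in cohort tables: mean, sample SD (n - 1
#' denominator), median, IQR (Q3 - Q1 with linear-interpolation, type-7
#' quantiles), minimum and maximum. A single observation is a degenerate
#' sample: its SD is reported as 0 by convention and flagged.
#'
#' @param values Nonempty numeric vector (NAs dropped).
#'
#' @return One-row tibble: `n`, `mean`, `sd`, `median`, `iqr`, `min`,
#'   `max`, `degenerate`.
#' @examples
#' summarize_values(c(1, 2, 3, 4, 5))
#' @export
summarize_values <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) == 0L) stop("`values` must be nonempty", call. = FALSE)
  n <- length(x)
  tibble::tibble(
    n = n,
    mean = mean(x),
    sd = if (n < 2L) 0 else stats::sd(x),
    median = stats::median(x),
    iqr = stats::IQR(x, type = 7),
    min = min(x),
    max = max(x),
    degenerate = n < 2L
  )
}

#' Two-group rank-sum comparison
#'
#' Wilcoxon–Mann–Whitney comparison of two samples, the two-group special
#' case of the Kruskal–Wallis rank-sum test (cohort tables report the
#' standardized z for it). `z` is the tie-corrected standardized rank sum
#' of the first group. The p-value is the exact two-sided permutation
#' probability — enumerated over all `choose(n, n_a)` group assignments
#' using integer doubled-midrank arithmetic — whenever
#' `n_a + n_b <= exact_limit`, and the normal approximation
#' `2 * pnorm(-|z|)` otherwise.
#'
#' @param a,b Nonempty numeric vectors.
#' @param exact_limit Largest combined sample size for which the exact
#'   permutation p-value is enumerated (default 16).
#'
#' @return One-row tibble: `z`, `p`, `n_a`, `n_b`, `method`.
#' @examples
#' rank_sum_compare(c(1, 2, 3), c(10, 11, 12)) # complete separation: p = 0.1
#' @export
rank_sum_compare <- function(a, b, exact_limit = 16) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b)) # midranks for ties
  w <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  v <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- if (v > 0) (w - mu) / sqrt(v) else 0
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r)) # doubled midranks are integers
    mu2 <- na * (n + 1L) # = 2 * mu, integer
    d_obs <- abs(as.integer(round(2 * w)) - mu2)
    splits <- utils::combn(n, na)
    s <- colSums(matrix(r2[splits], nrow = na))
    p <- mean(abs(s - mu2) >= d_obs)
    method <- "exact permutation"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  tibble::tibble(z = z, p = p, n_a = na, n_b = nb, method = method)
}

#' Kruskal–Wallis comparison (k groups)
#'
#' Thin wrapper around [stats::kruskal.test()] returning a tidy one-row
#' tibble; for two groups the chi-squared statistic equals `z^2` from
#' [rank_sum_compare()] up to tie handling.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector of the same length.
#' @return One-row tibble: `statistic`, `df`, `p`.
#' @export
kruskal_compare <- function(values, groups) {
  kt <- stats::kruskal.test(values, factor(groups))
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p = kt$p.value)
}

#' One-way ANOVA comparison
#'
#' Classical equal-variance one-way ANOVA, provided for variables whose
#' distribution supports it (e.g. normally distributed PIR in controls);
#' the rank-based path remains the primary comparison.
#'
#' @inheritParams kruskal_compare
#' @return One-row tibble: `f`, `df1`, `df2`, `p`.
#' @export
anova_compare <- function(values, groups) {
  ot <- stats::oneway.test(values ~ factor(groups), var.equal = TRUE)
  tibble::tibble(f = unname(ot$statistic),
                 df1 = unname(ot$parameter[1]),
                 df2 = unname(ot$parameter[2]),
                 p = ot$p.value)
}

#' Spearman rank association
#'
#' Spearman's rho computed as the Pearson correlation of midranks (so ties
#' are handled by averaging), with a two-sided p-value from the standard
#' large-sample t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, neither constant.
#'
#' @return One-row tibble: `rho`, `p`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("`x` and `y` must not be constant", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(rho = rho, p = p, n = n)
}

#' Cohort summary table with group comparisons
#'
#' Builds the familiar two-group cohort table: for each requested variable,
#' one row per group with the [summarize_values()] block, plus the
#' [rank_sum_compare()] z and p for the between-group comparison (repeated
#' on both rows of a variable). Comparison direction is first group level
#' minus second. Optionally applies a Holm adjustment across variables; no
#' adjustment is the default.
#'
#' @param records Data frame with a group column (exactly two levels) and
#'   the metric columns.
#' @param variables Character vector of column names to summarise.
#' @param group_col Name of the grouping column (default `"group"`).
#' @param adjust `"none"` (default) or `"holm"`.
#'
#' @return A tibble with columns `variable`, `group`, the summary block,
#'   `z`, `p` (and `p_adj` when adjusted).
#' @examples
#' cohort <- generate_cohort(n_ds = 12, n_control = 12, seed = 1)
#' build_group_table(cohort, c("nuclear_pir", "visual_acuity_logmar"))
#' @export
build_group_table <- function(records, variables, group_col = "group",
                              adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  records <- tibble::as_tibble(records)
  if (!group_col %in% names(records)) {
    stop(sprintf("grouping column '%s' not found", group_col), call. = FALSE)
  }
  missing <- setdiff(variables, names(records))
  if (length(missing) > 0) {
    stop(sprintf("variable(s) absent from records: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  g <- records[[group_col]]
  lev <- if (is.factor(g)) levels(droplevels(g)) else unique(as.character(g))
  if (length(lev) != 2L) {
    stop("`build_group_table()` requires exactly two groups", call. = FALSE)
  }
  rows <- purrr::map_dfr(variables, function(v) {
    va <- records[[v]][g == lev[1]]
    vb <- records[[v]][g == lev[2]]
    if (all(is.na(va)) || all(is.na(vb))) {
      stop(sprintf("variable '%s' has no data in one group", v), call. = FALSE)
    }
    cmp <- rank_sum_compare(va, vb)
    dplyr::bind_rows(
      dplyr::mutate(summarize_values(va), group = lev[1], .before = 1),
      dplyr::mutate(summarize_values(vb), group = lev[2], .before = 1)
    ) |>
      dplyr::mutate(variable = v, .before = 1) |>
      dplyr::mutate(z = cmp$z, p = cmp$p)
  })
  if (adjust == "holm") {
    pv <- rows$p[!duplicated(rows$variable)]
    adj <- stats::p.adjust(pv, method = "holm")
    rows$p_adj <- adj[match(rows$variable, rows$variable[!duplicated(rows$variable)])]
  }
  rows
}
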