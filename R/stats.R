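# The statistical battery used for the courtship endpoints: Fisher's
# exact test for success rates, Kruskal-Wallis with Steel-Dwass post hoc
# for latency, one-way ANOVA with Tukey HSD for the courtship index.
# Significance threshold alpha = 0.05 throughout.

test_result <- function(method, statistic, p_value, alpha = 0.05, ...) {
  data.frame(method = method, statistic = statistic, p_value = p_value,
             significant = p_value < alpha, ...,
             stringsAsFactors = FALSE)
}

as_group_samples <- function(values, groups) {
  if (is.list(values) && missing(groups)) {
    groups <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values)
  list(values = as.numeric(values[keep]), groups = factor(groups[keep]))
}

#' Fisher's exact test on a 2x2 success table
#'
#' Two-sided p-value under the point-probability convention of the
#' standard R implementation: the sum of hypergeometric point
#' probabilities not exceeding that of the observed table. A
#' central-interval convention (doubling the smaller tail, capped at 1)
#' is available behind `convention = "central"`.
#'
#' @param table 2x2 matrix of counts (rows = groups, columns =
#'   success/failure), or the count `a` with `b`, `c`, `d` supplied.
#' @param a,b,c,d cell counts (group1 success/failure, group2
#'   success/failure) when `table` is not a matrix.
#' @param convention `"point"` (default) or `"central"`.
#' @param alpha significance level.
#' @return One-row data.frame: `method`, `statistic` (odds ratio
#'   estimate), `p_value`, `significant`.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
#' @export
fisher_exact <- function(table = NULL, a = NULL, b = NULL, c = NULL,
                         d = NULL, convention = c("point", "central"),
                         alpha = 0.05) {
  convention <- match.arg(convention)
  if (!is.matrix(table)) table <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  if (any(table < 0) || any(table != round(table)))
    stop_input("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_input("degenerate table: a margin is zero")
  ft <- stats::fisher.test(table, alternative = "two.sided")
  p <- if (convention == "point") {
    ft$p.value
  } else {
    x <- table[1, 1]; m <- sum(table[1, ]); n <- sum(table[2, ])
    k <- sum(table[, 1])
    lo <- stats::phyper(x, m, n, k)
    hi <- stats::phyper(x - 1, m, n, k, lower.tail = FALSE)
    min(1, 2 * min(lo, hi))
  }
  test_result("fisher_exact", unname(ft$estimate), p, alpha)
}

#' Kruskal-Wallis rank-sum test
#'
#' Omnibus nonparametric comparison of k groups: the H statistic with
#' tie correction, referred to a chi-square distribution with k - 1
#' degrees of freedom.
#'
#' @param values numeric observations (or a named list of group vectors,
#'   in which case `groups` is omitted).
#' @param groups group labels aligned with `values`.
#' @param alpha significance level.
#' @return One-row data.frame: `method`, `statistic` (H), `df`,
#'   `p_value`, `significant`. All observations identical yields H = 0,
#'   p = 1 with a warning.
#' @examples
#' kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))
#' @export
kruskal_wallis <- function(values, groups, alpha = 0.05) {
  g <- as_group_samples(values, groups)
  if (nlevels(g$groups) < 2) stop_input("need at least two groups")
  if (length(unique(g$values)) == 1L) {
    warning("all observations identical: H = 0, p = 1")
    return(test_result("kruskal_wallis", 0, 1, alpha,
                       df = nlevels(g$groups) - 1L))
  }
  kt <- stats::kruskal.test(g$values, g$groups)
  test_result("kruskal_wallis", unname(kt$statistic), kt$p.value, alpha,
              df = unname(kt$parameter))
}

#' Steel-Dwass all-pairs comparisons
#'
#' Nonparametric post hoc for the Kruskal-Wallis setting. For each of
#' the k(k-1)/2 group pairs, the Wilcoxon rank sum is computed on that
#' pair alone, standardized with the tie-corrected null variance, and
#' the statistic sqrt(2)*|t| is referred to the studentized-range
#' distribution with k groups and infinite degrees of freedom, which
#' controls the family-wise error over all pairs. An exact per-pair
#' permutation p-value (no family adjustment; a small-sample diagnostic)
#' is available with `method = "permutation"`.
#'
#' @inheritParams kruskal_wallis
#' @param method `"asymptotic"` (studentized range; the test proper) or
#'   `"permutation"` (exact per-pair rank-sum reference).
#' @return data.frame with one row per pair: `group1`, `group2`,
#'   `statistic` (standardized rank-sum t), `p_value`, `significant`.
#'   Pairs involving a group of fewer than 2 observations are dropped
#'   with a warning.
#' @examples
#' steel_dwass(list(a = 1:5, b = 11:15, c = 21:25))
#' @export
steel_dwass <- function(values, groups, alpha = 0.05,
                        method = c("asymptotic", "permutation")) {
  method <- match.arg(method)
  g <- as_group_samples(values, groups)
  lev <- levels(g$groups)
  k <- length(lev)
  if (k < 2) stop_input("need at least two groups")
  sizes <- table(g$groups)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    warning("groups with fewer than 2 observations excluded from pairs: ",
            paste(small, collapse = ", "))
  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    if (g1 %in% small || g2 %in% small) return(NULL)
    x <- g$values[g$groups == g1]
    y <- g$values[g$groups == g2]
    t_obs <- sd_pair_statistic(x, y)
    p <- if (method == "asymptotic") {
      stats::ptukey(sqrt(2) * abs(t_obs), nmeans = k, df = Inf,
                    lower.tail = FALSE)
    } else {
      sd_pair_permutation_p(x, y)
    }
    data.frame(group1 = g1, group2 = g2, statistic = t_obs, p_value = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# standardized pairwise rank-sum statistic with tie correction
sd_pair_statistic <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  E <- n1 * (N + 1) / 2
  V <- n1 * n2 / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) return(0)
  (R1 - E) / sqrt(V)
}

# exact two-sided permutation p of |t| for one pair (enumerates all
# choose(N, n1) splits; intended for tiny samples)
sd_pair_permutation_p <- function(x, y, max_comb = 200000) {
  n1 <- length(x); N <- n1 + length(y)
  if (choose(N, n1) > max_comb)
    stop_input("too many permutations for the exact option")
  v <- c(x, y)
  t_obs <- abs(sd_pair_statistic(x, y))
  idx <- utils::combn(N, n1)
  tt <- apply(idx, 2, function(i) abs(sd_pair_statistic(v[i], v[-i])))
  mean(tt >= t_obs - 1e-12)
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' F test from the one-way decomposition, then Tukey's honestly
#' significant difference for all group pairs (Tukey-Kramer for unequal
#' group sizes).
#'
#' @inheritParams kruskal_wallis
#' @return list with `omnibus` (one-row data.frame: F statistic, df,
#'   p_value, significant) and `pairwise` (one row per pair: difference
#'   of means, adjusted p, significant).
#' @examples
#' anova_tukey(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(8, 9, 10)))
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  g <- as_group_samples(values, groups)
  if (nlevels(g$groups) < 2) stop_input("need at least two groups")
  if (any(table(g$groups) < 2)) stop_input("each group needs n >= 2")
  within_var <- tapply(g$values, g$groups, stats::var)
  if (all(within_var == 0))
    stop_input("zero within-group variance everywhere: F undefined")
  fit <- stats::aov(v ~ grp, data = data.frame(v = g$values,
                                               grp = g$groups))
  sm <- summary(fit)[[1]]
  omnibus <- test_result("anova", sm$`F value`[1], sm$`Pr(>F)`[1], alpha,
                         df1 = sm$Df[1], df2 = sm$Df[2])
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$grp
  pw <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                   p_value = tk[, "p adj"],
                   significant = tk[, "p adj"] < alpha,
                   stringsAsFactors = FALSE)
  rownames(pw) <- NULL
  list(omnibus = omnibus, pairwise = pw)
}
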