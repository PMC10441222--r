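#' One-way analysis of variance across condition groups
#'
#' Classical between/within mean-square F test, as used to compare
#' steady-state viability between sparger/kLa conditions.
#'
#' @param groups A named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values), or a data frame with columns `group` and `value`.
#' @return A list with elements `f` (F statistic), `p` (p-value),
#'   `df_between`, `df_within`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
#' @export
one_way_anova <- function(groups) {
  groups <- .as_group_list(groups)
  if (length(groups) < 2L) stop("at least 2 groups are required")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least 2 values")
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names(groups), sizes))
  ht <- stats::oneway.test(value ~ group, var.equal = TRUE)
  list(f = unname(ht$statistic), p = unname(ht$p.value),
       df_between = unname(ht$parameter[1L]),
       df_within = unname(ht$parameter[2L]))
}

.as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  groups
}

#' Bonferroni-adjusted significance threshold
#'
#' @param family_alpha Family-wise significance level (default 0.05).
#' @param n_comparisons Number of pairwise comparisons; >= 1.
#' @return `family_alpha / n_comparisons`, rounded to 4 decimals for
#'   display/decision consistency (0.05 over 3 comparisons gives 0.0167).
#' @export
bonferroni_threshold <- function(family_alpha = 0.05, n_comparisons) {
  if (n_comparisons < 1) stop("n_comparisons must be >= 1")
  round(family_alpha / n_comparisons, 4)
}

#' Pairwise post-hoc comparison with Bonferroni adjustment
#'
#' Pooled-variance two-sample t test for every pair of groups; a pair is
#' significant when its p-value falls below the family alpha divided by the
#' number of pairs.
#'
#' @inheritParams one_way_anova
#' @param family_alpha Family-wise significance level; default 0.05.
#' @return A tibble with columns `group1`, `group2`, `t`, `p`, `threshold`,
#'   `significant`.
#' @export
pairwise_posthoc <- function(groups, family_alpha = 0.05) {
  groups <- .as_group_list(groups)
  if (length(groups) < 2L) stop("at least 2 groups are required")
  if (any(lengths(groups) < 2L)) stop("every group needs at least 2 values")
  pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
  thr <- bonferroni_threshold(family_alpha, length(pairs))
  rows <- lapply(pairs, function(pr) {
    ht <- stats::t.test(groups[[pr[1L]]], groups[[pr[2L]]], var.equal = TRUE)
    tibble::tibble(group1 = pr[1L], group2 = pr[2L],
                   t = unname(ht$statistic), p = unname(ht$p.value),
                   threshold = thr, significant = unname(ht$p.value) < thr)
  })
  do.call(rbind, rows)
}
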