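#' Comparative-CT (2^-ddCt) fold changes
#'
#' Technical replicates are averaged on the Ct scale per (gene, condition);
#' `dCt = Ct_target - Ct_reference` within each condition, `ddCt = dCt_condition -
#' dCt_control`, fold change `2^-ddCt`. The control condition's fold change is
#' exactly 1 by construction. Fold changes are invariant to adding a constant
#' to every Ct.
#'
#' @param table a [ct_table()] (long data.frame with attributes
#'   `reference_gene` and `control_condition`).
#' @return a `fold_change_table` data.frame with per (gene, condition)
#'   `delta_ct`, `delta_delta_ct`, `fold_change`, `log2_fold_change`.
#' @export
ddct_fold_change <- function(table) {
  ref <- attr(table, "reference_gene")
  ctrl <- attr(table, "control_condition")
  if (is.null(ref) || is.null(ctrl))
    stop_input("`table` must be a ct_table with reference_gene and control_condition")
  conditions <- unique(table$condition)
  # the reference gene must be measured in every (condition, replicate)
  combos <- unique(table[c("condition", "replicate")])
  refrows <- table[table$gene == ref, c("condition", "replicate")]
  gaps <- combos[!do.call(paste, combos) %in% do.call(paste, refrows), , drop = FALSE]
  if (nrow(gaps))
    stop_input("missing reference-gene measurements for: ",
               paste(sprintf("%s/rep%s", gaps$condition, gaps$replicate),
                     collapse = ", "))
  mean_ct <- aggregate(ct ~ gene + condition, data = table, FUN = mean)
  ref_ct <- mean_ct[mean_ct$gene == ref, ]
  targets <- setdiff(unique(table$gene), ref)
  out <- do.call(rbind, lapply(targets, function(g) {
    gi <- mean_ct[mean_ct$gene == g, ]
    dct <- gi$ct - ref_ct$ct[match(gi$condition, ref_ct$condition)]
    dct_ctrl <- dct[gi$condition == ctrl]
    if (length(dct_ctrl) != 1)
      stop_input("gene ", g, " lacks a control-condition measurement")
    ddct <- dct - dct_ctrl
    data.frame(gene = g, condition = gi$condition, delta_ct = dct,
               delta_delta_ct = ddct, fold_change = 2^(-ddct),
               log2_fold_change = -ddct)
  }))
  rownames(out) <- NULL
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Gene-set overlap summary
#'
#' Case-normalised intersection of two identifier sets, with the overlap
#' percentage taken over the query set (reported both at full precision and
#' integer-rounded); the reverse percentage (over the reference) is also
#' emitted.
#'
#' @param query,reference character vectors of gene identifiers (duplicates
#'   and case differences are collapsed).
#' @return an `overlap_summary` list with `query_set_size`,
#'   `reference_set_size`, `intersection_size`, `overlap_pct`,
#'   `overlap_pct_rounded`, `reverse_pct`. An empty query yields `NA`
#'   percentages.
#' @export
gene_set_overlap <- function(query, reference) {
  q <- unique(toupper(as.character(query)))
  r <- unique(toupper(as.character(reference)))
  inter <- length(intersect(q, r))
  pct <- if (length(q) > 0) 100 * inter / length(q) else NA_real_
  structure(list(query_set_size = length(q), reference_set_size = length(r),
                 intersection_size = inter, overlap_pct = pct,
                 overlap_pct_rounded = if (is.na(pct)) NA_real_ else round(pct),
                 reverse_pct = if (length(r) > 0) 100 * inter / length(r) else NA_real_),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("Gene-set overlap: %d of %d query genes in reference (%s%%)\n",
              x$intersection_size, x$query_set_size,
              if (is.na(x$overlap_pct)) "NA" else sprintf("%.2f", x$overlap_pct)))
  invisible(x)
}

#' @noRd
new_stat_report <- function(test, statistic, p_value, ...) {
  structure(c(list(test = test, statistic = statistic, p_value = p_value),
              list(...)), class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("  Tukey HSD adjusted p-values:\n")
    print(x$pairwise, row.names = FALSE)
  }
  if (!is.null(x$estimate)) cat(sprintf("  estimate: %.4g\n", x$estimate))
  if (isTRUE(x$degenerate)) cat("  (degenerate: zero variance in both groups)\n")
  invisible(x)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Omnibus one-way ANOVA across the groups followed by all-pairs Tukey honest
#' significant difference comparisons with family-wise adjusted p-values.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return a `stat_report` with the F statistic, its p-value, a `pairwise`
#'   data.frame (difference, confidence bounds, adjusted p) and per-group
#'   descriptives.
#' @export
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_input("`groups` must be a list of >= 2 numeric vectors")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns < 2))
    stop_input("every group needs n >= 2; offending: ",
               paste(names(groups)[ns < 2], collapse = ", "))
  d <- data.frame(value = unlist(groups, use.names = FALSE),
                  group = factor(rep(names(groups), ns), levels = names(groups)))
  fit <- aov(value ~ group, data = d)
  tab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"], row.names = NULL)
  desc <- data.frame(group = names(groups),
                     mean = vapply(groups, mean, numeric(1)),
                     sd = vapply(groups, sd, numeric(1)), n = as.integer(ns))
  new_stat_report("anova_tukey", tab[["F value"]][1], tab[["Pr(>F)"]][1],
                  pairwise = pairwise, group_stats = desc,
                  df = c(tab[["Df"]][1], tab[["Df"]][2]))
}

#' Unpaired two-sample t-test
#'
#' Two-tailed Student's unpaired t-test (pooled variance by default). When
#' both groups have zero variance the test is degenerate: p = 1 (flagged) if
#' the means are equal, `NA` statistics (flagged) otherwise.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param var.equal pooled-variance (classic Student) when `TRUE`.
#' @return a `stat_report` with `statistic` (t), `p_value`, `df`,
#'   `group_stats` and a `degenerate` flag.
#' @export
t_test_unpaired <- function(a, b, var.equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop_input("need n >= 2 per group")
  desc <- data.frame(group = c("a", "b"), mean = c(mean(a), mean(b)),
                     sd = c(sd(a), sd(b)), n = c(length(a), length(b)))
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(new_stat_report("t_test", 0, 1, df = length(a) + length(b) - 2,
                             group_stats = desc, degenerate = TRUE))
    return(new_stat_report("t_test", NA_real_, NA_real_,
                           df = length(a) + length(b) - 2,
                           group_stats = desc, degenerate = TRUE))
  }
  ht <- t.test(a, b, var.equal = var.equal)
  new_stat_report("t_test", unname(ht$statistic), ht$p.value,
                  df = unname(ht$parameter), group_stats = desc,
                  degenerate = FALSE)
}

#' Pearson correlation with two-tailed p-value
#'
#' @param x,y numeric vectors, n >= 3, finite, each with positive variance.
#' @return a `stat_report` with `statistic` (t), `p_value`, `estimate` (r)
#'   and `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_input("`x` and `y` lengths differ")
  if (length(x) < 3) stop_input("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_input("non-finite values")
  if (var(x) == 0 || var(y) == 0)
    stop_input("undefined correlation: zero variance in x or y")
  ht <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  new_stat_report("pearson", unname(ht$statistic), ht$p.value,
                  estimate = unname(ht$estimate), n = length(x),
                  df = unname(ht$parameter))
}
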