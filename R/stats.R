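# Group-comparison statistics: per-class medians with IQR, Kruskal-Wallis
# global tests and Dunn's post hoc pairwise comparisons, for electrolyte
# emission values and for ordinal HOES grades.

#' Per-class medians and interquartile ranges
#'
#' Summarizes one variable across margin classes with the linear-interpolation
#' (type 7) quantile convention. Undefined values (`NA`, e.g. undefined Ca/K
#' ratios) are excluded from the variable they affect only.
#'
#' @param values numeric vector.
#' @param class character/factor vector of margin classes, same length.
#' @return `data.frame` with one row per class: `n`, `median`, `q1`, `q3`.
#' @export
class_medians <- function(values, class) {
  stopifnot(length(values) == length(class))
  classes <- intersect(margin_classes(), unique(as.character(class)))
  if (length(classes) == 0L) stop("no recognized margin classes present")
  rows <- lapply(classes, function(cl) {
    v <- values[class == cl & !is.na(values)]
    if (length(v) == 0L) stop("empty class after NA exclusion: ", cl)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(margin_class = cl, n = length(v),
               median = q[2], q1 = q[1], q3 = q[3])
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Wrapper around the tie-corrected Kruskal-Wallis test returning the H
#' statistic and the chi-square p-value on g-1 degrees of freedom. The
#' fully degenerate case (every observation identical) is reported as
#' H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param group grouping vector (>= 2 non-empty groups).
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, group) {
  group <- factor(group)
  if (any(table(group) == 0L) || nlevels(group) < 2L)
    stop("kruskal_wallis needs >= 2 non-empty groups")
  if (length(values) < 3L) stop("kruskal_wallis needs total n >= 3")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(group) - 1L, p = 1))
  kt <- stats::kruskal.test(values, group)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn's post hoc test for pairwise group comparisons
#'
#' Pairwise z statistics from mean ranks with tie-corrected pooled variance:
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j)),
#' T = sum over tie groups of (t^3 - t). Two-sided p-values from the normal
#' distribution, adjusted over all g(g-1)/2 comparisons (Bonferroni by
#' default, Holm by flag), capped at 1.
#'
#' @param values numeric vector.
#' @param group grouping vector with >= 2 non-empty groups.
#' @param adjustment `"bonferroni"` (default) or `"holm"`.
#' @return `data.frame` with one row per pair: `group1`, `group2`, `z`,
#'   `p`, `p_adj`.
#' @export
dunn_posthoc <- function(values, group, adjustment = c("bonferroni", "holm")) {
  adjustment <- match.arg(adjustment)
  group <- factor(group)
  if (nlevels(group) < 2L) stop("dunn_posthoc needs >= 2 groups")
  if (any(table(group) == 0L)) stop("dunn_posthoc: empty group")
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, group, mean)
  n <- tapply(r, group, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  s2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  lev <- levels(group)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(s2 * (1 / n[[a]] + 1 / n[[b]]))
    z[j] <- if (se > 0) (mean_rank[[a]] - mean_rank[[b]]) / se else 0
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  p_adj <- stats::p.adjust(p, method = adjustment)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = z, p = p, p_adj = p_adj, stringsAsFactors = FALSE)
}

#' Group comparison of one variable across margin classes
#'
#' Bundles [class_medians()], [kruskal_wallis()] and [dunn_posthoc()] into
#' one report (the building block of the per-class electrolyte and HOES
#' summary tables).
#'
#' @param values numeric vector.
#' @param class margin-class vector.
#' @param variable label for the variable.
#' @param adjustment passed to [dunn_posthoc()].
#' @return object of class `group_comparison`: list with `variable`,
#'   `summary` (medians/IQR), `H`, `p`, `pairwise`.
#' @export
group_comparison <- function(values, class, variable = "value",
                             adjustment = "bonferroni") {
  keep <- !is.na(values)
  values <- values[keep]; class <- as.character(class)[keep]
  med <- class_medians(values, class)
  kw <- kruskal_wallis(values, class)
  pw <- if (kw$H > 0) dunn_posthoc(values, class, adjustment) else {
    pairs <- utils::combn(sort(unique(class)), 2)
    data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
               z = 0, p = 1, p_adj = 1, stringsAsFactors = FALSE)
  }
  structure(list(variable = variable, summary = med,
                 H = kw$H, df = kw$df, p = kw$p, pairwise = pw),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: Kruskal-Wallis H = %.3f (df %d), p = %.3g\n",
              x$variable, x$H, x$df, x$p))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Electrolyte summary table across margin classes
#'
#' The per-class median/IQR table for K, soluble Ca and the soluble Ca/K
#' ratio, with the Kruskal-Wallis p-value and Dunn pairwise significance per
#' variable. Undefined ratios are excluded from the ratio row only.
#'
#' @param profiles profile table from [process_cohort()].
#' @param class margin-class vector aligned with `profiles` rows.
#' @param adjustment Dunn adjustment method.
#' @return named list of `group_comparison` objects
#'   (`k_emission`, `soluble_ca`, `ca_k_ratio`).
#' @export
electrolyte_comparison <- function(profiles, class, adjustment = "bonferroni") {
  vars <- c("k_emission", "soluble_ca", "ca_k_ratio")
  out <- lapply(vars, function(v)
    group_comparison(profiles[[v]], class, variable = v, adjustment = adjustment))
  names(out) <- vars
  out
}

#' HOES grade comparison across margin classes
#'
#' Applies the same Kruskal-Wallis + Dunn machinery to the ordinal HOES
#' grades (bone neogenesis/fibrosis and lymphocyte/macrophage infiltrates)
#' of the spot records, and reports the ordering of median grades.
#'
#' @param spots spot-record `data.frame` with `margin_class`, `hoes_nf`,
#'   `hoes_lm`.
#' @param adjustment Dunn adjustment method.
#' @return named list of `group_comparison` objects (`hoes_nf`, `hoes_lm`),
#'   each with an extra `median_ordering` element (classes sorted from
#'   tumor outward with their median grades).
#' @export
hoes_comparison <- function(spots, adjustment = "bonferroni") {
  out <- lapply(c(hoes_nf = "hoes_nf", hoes_lm = "hoes_lm"), function(v) {
    gc <- group_comparison(spots[[v]], spots$margin_class,
                           variable = v, adjustment = adjustment)
    med <- gc$summary$median[match(margin_classes(), gc$summary$margin_class)]
    gc$median_ordering <- stats::setNames(med, margin_classes())
    gc
  })
  out
}

#' Flat summary table of electrolyte medians (report surface)
#'
#' One row per variable x class with median, IQR bounds, the global
#' Kruskal-Wallis p and, per class, which other classes differ at the 0.05
#' level after adjustment.
#'
#' @param comparisons result of [electrolyte_comparison()] (or
#'   [hoes_comparison()]).
#' @return `data.frame` report.
#' @export
comparison_report <- function(comparisons) {
  rows <- lapply(comparisons, function(gc) {
    sig <- vapply(gc$summary$margin_class, function(cl) {
      pw <- gc$pairwise
      hit <- pw[(pw$group1 == cl | pw$group2 == cl) & pw$p_adj < 0.05, ]
      others <- setdiff(c(hit$group1, hit$group2), cl)
      paste(others, collapse = ";")
    }, character(1))
    data.frame(variable = gc$variable, gc$summary,
               kw_p = gc$p, differs_from = sig,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
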