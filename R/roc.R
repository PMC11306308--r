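# Diagnostic stage: empirical ROC curves with DeLong confidence intervals,
# Youden-index threshold rules per margin transition, and the cascaded
# four-class margin-status classifier built from those rules.

#' Empirical ROC curve with AUC, DeLong CI and test against 0.5
#'
#' The curve is computed over all distinct thresholds of the score. The
#' orientation is chosen so AUC >= 0.5: direction `">="` means high scores
#' indicate the positive class, `"<="` the reverse. AUC equals the
#' Mann-Whitney concordance (concordant pairs + half ties over all
#' positive-negative pairs); its variance is the DeLong placement variance,
#' giving a normal 95% CI (clipped to [0, 1]) and a p-value against
#' AUC = 0.5.
#'
#' @param scores finite numeric scores.
#' @param labels binary labels (logical or 0/1), 1 = positive class.
#' @return object of class `roc_result`: list with `auc`, `ci`, `se`, `p`,
#'   `direction`, `points` (data.frame `threshold`, `fpr`, `tpr` on the
#'   oriented scale), `n_pos`, `n_neg`, and the oriented data for
#'   [youden_threshold()].
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("roc_curve needs both classes present")

  auc_of <- function(s) {
    r <- rank(s)
    (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  direction <- if (auc_of(scores) >= 0.5) ">=" else "<="
  oriented <- if (direction == ">=") scores else -scores
  auc <- auc_of(oriented)

  # DeLong placements via ranks
  x <- oriented[labels == 1L]; y <- oriented[labels == 0L]
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(n_pos)] - rank(x)) / n_neg
  v01 <- 1 - (r_all[n_pos + seq_len(n_neg)] - rank(y)) / n_pos
  var_auc <- (if (n_pos > 1) stats::var(v10) / n_pos else 0) +
    (if (n_neg > 1) stats::var(v01) / n_neg else 0)
  se <- sqrt(var_auc)
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else
    as.numeric(auc == 0.5)

  # empirical ROC points over all distinct oriented thresholds
  thr <- sort(unique(oriented), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(x >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(y >= t), numeric(1))
  points <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))

  structure(list(auc = auc, ci = ci, se = se, p = p, direction = direction,
                 points = points, n_pos = n_pos, n_neg = n_neg,
                 oriented_scores = oriented, scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), p vs 0.5 = %.3g, direction %s\n",
              x$auc, x$ci[1], x$ci[2], x$p, x$direction))
  invisible(x)
}

#' Youden-index optimal threshold rule from a ROC curve
#'
#' Scans every empirical candidate cutoff (midpoints between adjacent
#' distinct score values, plus one below the minimum and one above the
#' maximum) and maximizes J = sensitivity + specificity - 1. Ties are broken
#' toward higher sensitivity, then toward the lower reported cutoff. The
#' reported cutoff is the midpoint between adjacent observed values, on the
#' original score scale and with the ROC's direction.
#'
#' @param roc a `roc_result`.
#' @param score_name label carried into the rule.
#' @return object of class `threshold_rule`: list with `score`, `direction`,
#'   `cutoff`, `sensitivity`, `specificity`, `youden`, plus ROC provenance
#'   (`auc`, `ci`, `p`).
#' @export
youden_threshold <- function(roc, score_name = "score") {
  stopifnot(inherits(roc, "roc_result"))
  s <- roc$oriented_scores; y <- roc$labels
  u <- sort(unique(s))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  sens <- vapply(cand, function(t) mean(s[y == 1L] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(s[y == 0L] < t), numeric(1))
  j <- sens + spec - 1
  # reported cutoff on the original scale
  rep_cut <- if (roc$direction == ">=") cand else -cand
  best <- which(j > max(j) - 1e-12)
  best <- best[order(-sens[best], rep_cut[best])][1]
  structure(list(score = score_name, direction = roc$direction,
                 cutoff = rep_cut[best], sensitivity = sens[best],
                 specificity = spec[best], youden = j[best],
                 auc = roc$auc, ci = roc$ci, p = roc$p),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("<threshold_rule> %s %s %.4f: sens %.3f, spec %.3f, J %.3f (AUC %.3f)\n",
              x$score, x$direction, x$cutoff, x$sensitivity, x$specificity,
              x$youden, x$auc))
  invisible(x)
}

#' Apply a threshold rule to scores
#'
#' @param rule a `threshold_rule`.
#' @param scores numeric scores.
#' @return logical vector: does the rule call the positive class?
#' @export
apply_rule <- function(rule, scores) {
  if (rule$direction == ">=") scores >= rule$cutoff else scores <= rule$cutoff
}

#' ROC/Youden rule set over all margin transitions and scores
#'
#' For each transition (very close vs tumor, close vs very close, clear vs
#' close) and each score (K, soluble Ca, soluble Ca/K), computes the ROC
#' curve and the Youden-optimal threshold rule. Undefined ratios are
#' excluded from the ratio rules only.
#'
#' @param data `data.frame` with the score columns and `margin_class`; all
#'   four classes must be present.
#' @param scores score columns to analyze.
#' @return object of class `margin_rule_set`: nested list
#'   `rules[[transition]][[score]]` of `threshold_rule`s.
#' @export
build_rule_set <- function(data,
                           scores = c("k_emission", "soluble_ca", "ca_k_ratio")) {
  missing_cls <- setdiff(margin_classes(), unique(data$margin_class))
  if (length(missing_cls) > 0)
    stop("missing margin class: ", paste(missing_cls, collapse = ", "))
  rules <- list()
  for (tr in names(margin_transitions())) {
    cls <- margin_transitions()[[tr]]
    d <- data[data$margin_class %in% cls, , drop = FALSE]
    rules[[tr]] <- list()
    for (sc in scores) {
      keep <- !is.na(d[[sc]])
      roc <- roc_curve(d[[sc]][keep],
                       as.integer(d$margin_class[keep] == cls[["positive"]]))
      rules[[tr]][[sc]] <- youden_threshold(roc, score_name = sc)
    }
  }
  structure(list(rules = rules, scores = scores), class = "margin_rule_set")
}

#' Diagnostic report across transitions (ROC summary table)
#'
#' One row per transition x score: AUC with 95% CI, p-value against 0.5,
#' Youden-optimal cutoff with its direction, sensitivity and specificity.
#'
#' @param rule_set a `margin_rule_set`.
#' @return `data.frame` report.
#' @export
rule_set_report <- function(rule_set) {
  rows <- list()
  for (tr in names(rule_set$rules)) {
    for (sc in names(rule_set$rules[[tr]])) {
      r <- rule_set$rules[[tr]][[sc]]
      rows[[length(rows) + 1L]] <-
        data.frame(transition = tr, variable = sc,
                   auc = r$auc, ci_low = r$ci[1], ci_high = r$ci[2], p = r$p,
                   direction = r$direction, cutoff = r$cutoff,
                   sensitivity = r$sensitivity, specificity = r$specificity,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cascaded four-class margin-status prediction
#'
#' Operationalizes the three binary threshold rules as a cascade from most
#' to least severe: if the very-close-vs-tumor rule fires the spot is called
#' tumor; otherwise if the close-vs-very-close rule fires, very close;
#' otherwise if the clear-vs-close rule fires, close; otherwise clear.
#' Every profile receives exactly one status. Profiles with an undefined
#' ratio score fall back to the K-based rules.
#'
#' @param profiles `data.frame` with the score columns (and optionally
#'   `spot_id`).
#' @param rule_set a `margin_rule_set` from [build_rule_set()].
#' @param score which score's rules drive the cascade.
#' @return `data.frame`: `spot_id` (if present), `predicted`,
#'   `triggering_rule`.
#' @export
classify_margin <- function(profiles, rule_set, score = "k_emission") {
  stopifnot(inherits(rule_set, "margin_rule_set"))
  if (!score %in% rule_set$scores) stop("no rules for score ", score)
  n <- nrow(profiles)
  use_score <- rep(score, n)
  if (score == "ca_k_ratio")
    use_score[is.na(profiles[[score]])] <- "k_emission"
  cascade <- c(very_close_vs_tumor = "tumor",
               close_vs_very_close = "very_close",
               clear_vs_close = "close")
  predicted <- rep("clear", n)
  trigger <- rep("none", n)
  undecided <- rep(TRUE, n)
  for (tr in names(cascade)) {
    fired <- undecided
    for (sc in unique(use_score)) {
      sel <- undecided & use_score == sc
      fired[sel] <- apply_rule(rule_set$rules[[tr]][[sc]], profiles[[sc]][sel])
    }
    hit <- undecided & fired
    predicted[hit] <- cascade[[tr]]
    trigger[hit] <- tr
    undecided <- undecided & !hit
  }
  out <- data.frame(predicted = predicted, triggering_rule = trigger,
                    stringsAsFactors = FALSE)
  if (!is.null(profiles$spot_id)) out <- cbind(spot_id = profiles$spot_id, out)
  out
}
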