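test_that("AUC reproduces fixed concordance-count instances", {
  r1 <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r1$auc, 1.0)
  r2 <- roc_curve(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r2$auc, 0.75)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
  expect_error(roc_curve(c(1, NA, 3), c(0, 1, 1)), "finite")
})

test_that("AUC equals the Mann-Whitney pair statistic exactly, including ties", {
  set.seed(2718)
  for (rep in 1:200) {
    n <- sample(4:50, 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) %in% c(0, n)) next
    r <- roc_curve(scores, labels)
    ref <- oracle_auc(scores, labels)
    expect_equal(r$auc, max(ref, 1 - ref), tolerance = 1e-12)
  }
})

test_that("ROC points are monotone from (0,0) to (1,1) and AUC is bounded", {
  set.seed(99)
  r <- roc_curve(rnorm(60), rbinom(60, 1, 0.4))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
  expect_equal(tail(r$points$fpr, 1), 1); expect_equal(tail(r$points$tpr, 1), 1)
  expect_true(r$auc >= 0.5 && r$auc <= 1)
  expect_true(all(r$ci >= 0 & r$ci <= 1) && r$ci[1] <= r$auc & r$auc <= r$ci[2])
})

test_that("DeLong AUC confidence intervals match pROC", {
  skip_if_not_installed("pROC")
  set.seed(404)
  for (rep in 1:20) {
    n <- sample(30:80, 1)
    scores <- rnorm(n) + rbinom(n, 1, 0.5)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) %in% c(0, n)) next
    r <- roc_curve(scores, labels)
    # pin the orientation so both compute the same oriented AUC
    pr <- suppressMessages(pROC::roc(labels, r$oriented_scores, direction = "<"))
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    ci <- suppressWarnings(as.numeric(pROC::ci.auc(pr, method = "delong")))
    expect_equal(unname(r$ci), pmin(pmax(ci[c(1, 3)], 0), 1), tolerance = 1e-9)
  }
})

test_that("Youden thresholds reproduce the exhaustive-scan oracle", {
  # fixed instance: scores {1,2,3,4,10}, labels {0,0,1,1,1} separate at 2.5
  r <- roc_curve(c(1, 2, 3, 4, 10), c(0, 0, 1, 1, 1))
  rule <- youden_threshold(r, "k_emission")
  expect_equal(rule$cutoff, 2.5)
  expect_equal(rule$sensitivity, 1)
  expect_equal(rule$specificity, 1)
  expect_equal(rule$youden, 1)

  set.seed(1618)
  for (rep in 1:200) {
    n <- sample(5:50, 1)
    scores <- round(rnorm(n), 1)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) %in% c(0, n)) next
    r <- roc_curve(scores, labels)
    rule <- youden_threshold(r)
    s_or <- if (r$direction == ">=") scores else -scores
    ref <- oracle_youden(s_or, labels)
    expect_equal(rule$youden, ref$j, tolerance = 1e-12)
    expect_equal(rule$sensitivity, ref$sens, tolerance = 1e-12)
    expect_equal(rule$specificity, ref$spec, tolerance = 1e-12)
    # sensitivity/specificity at the cutoff match direct recounting
    called <- apply_rule(rule, scores)
    expect_equal(mean(called[labels == 1]), rule$sensitivity)
    expect_equal(mean(!called[labels == 0]), rule$specificity)
  }
})

test_that("label swap maps AUC to 1 - AUC and flips the rule direction", {
  set.seed(12)
  for (rep in 1:20) {
    scores <- rnorm(40) + seq(0, 1.5, length.out = 40)
    labels <- rbinom(40, 1, seq(0.2, 0.8, length.out = 40))
    if (sum(labels) %in% c(0, 40)) next
    r <- roc_curve(scores, labels)
    rsw <- roc_curve(scores, 1 - labels)
    # both are reported on the oriented scale: same magnitude of separation
    raw_auc <- oracle_auc(scores, labels)
    expect_equal(r$auc, max(raw_auc, 1 - raw_auc), tolerance = 1e-12)
    expect_equal(rsw$auc, max(1 - raw_auc, raw_auc), tolerance = 1e-12)
    if (raw_auc != 0.5) expect_false(r$direction == rsw$direction)
  }
})

test_that("rule sets require all four classes and report one row per transition x score", {
  set.seed(3)
  n <- 60
  tab <- data.frame(
    margin_class = rep(margin_classes(), each = n / 4),
    k_emission = rexp(n), soluble_ca = rexp(n), ca_k_ratio = rexp(n))
  rs <- build_rule_set(tab)
  rep_tab <- rule_set_report(rs)
  expect_equal(nrow(rep_tab), 9L)
  expect_true(all(rep_tab$direction %in% c(">=", "<=")))
  expect_error(build_rule_set(tab[tab$margin_class != "close", ]), "close")
})

test_that("the cascade is total, respects precedence, and falls back on undefined ratios", {
  set.seed(44)
  tab <- default_rule_fixture <- data.frame(
    margin_class = rep(margin_classes(), each = 50),
    k_emission = c(rlnorm(50, log(6), 0.4), rlnorm(50, log(0.6), 0.4),
                   rlnorm(50, log(0.45), 0.4), rlnorm(50, log(0.33), 0.4)))
  tab$soluble_ca <- rlnorm(200, log(20), 0.5)
  tab$ca_k_ratio <- tab$soluble_ca / tab$k_emission
  rs <- build_rule_set(tab)
  calls <- classify_margin(tab, rs)
  expect_equal(nrow(calls), nrow(tab))
  expect_true(all(calls$predicted %in% margin_classes()))

  # precedence: a score above the tumor rule's cutoff is called tumor
  rule_t <- rs$rules$very_close_vs_tumor$k_emission
  hi <- data.frame(k_emission = rule_t$cutoff + 1, soluble_ca = 1,
                   ca_k_ratio = 0.01)
  expect_identical(classify_margin(hi, rs)$predicted, "tumor")
  # below every K cutoff: clear
  lo <- data.frame(k_emission = 1e-6, soluble_ca = 1, ca_k_ratio = 1e6)
  expect_identical(classify_margin(lo, rs)$predicted, "clear")
  # undefined ratio falls back to the K rules
  und <- data.frame(k_emission = rule_t$cutoff + 1, soluble_ca = 0,
                    ca_k_ratio = NA_real_)
  expect_identical(classify_margin(und, rs, score = "ca_k_ratio")$predicted,
                   "tumor")
})

test_that("null cohorts give chance-level AUCs and more separation never hurts", {
  set.seed(246)
  n <- 200
  null_tab <- data.frame(margin_class = rep(margin_classes(), each = n / 4),
                         k_emission = rlnorm(n, 0, 0.5))
  null_tab$soluble_ca <- rlnorm(n, 1, 0.5)
  null_tab$ca_k_ratio <- null_tab$soluble_ca / null_tab$k_emission
  rs <- build_rule_set(null_tab)
  for (row in seq_len(9)) {
    r <- rule_set_report(rs)[row, ]
    se <- sqrt(0.25 / 50 + 0.25 / 50)  # conservative null AUC se
    expect_lt(r$auc, 0.5 + 3 * se)
  }

  # doubling the configured class separation never decreases K AUCs
  sep_auc <- function(gap) {
    meds <- exp(gap * c(tumor = 3, very_close = 1, close = 0.5, clear = 0))
    tab <- data.frame(margin_class = rep(margin_classes(), each = 100))
    tab$k_emission <- rlnorm(400, log(meds[tab$margin_class]), 0.5)
    tab$soluble_ca <- rlnorm(400, 1, 0.1)
    tab$ca_k_ratio <- tab$soluble_ca / tab$k_emission
    rep_tab <- rule_set_report(build_rule_set(tab))
    rep_tab$auc[rep_tab$variable == "k_emission"]
  }
  set.seed(8)
  a1 <- sep_auc(0.6)
  set.seed(8)
  a2 <- sep_auc(1.2)
  expect_true(all(a2 >= a1 - 1e-9))
})
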