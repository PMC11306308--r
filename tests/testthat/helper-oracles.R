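# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# Kruskal-Wallis H by direct rank arithmetic with the textbook tie correction
oracle_kruskal_H <- function(values, group) {
  group <- as.character(group)
  N <- length(values)
  r <- rank(values)
  H <- 0
  for (g in unique(group)) {
    rg <- r[group == g]
    H <- H + length(rg) * (mean(rg) - (N + 1) / 2)^2
  }
  H <- 12 / (N * (N + 1)) * H
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) return(0)
  H / corr
}

# Dunn z for one pair by direct mean-rank arithmetic
oracle_dunn_z <- function(values, group, a, b) {
  group <- as.character(group)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  na <- sum(group == a); nb <- sum(group == b)
  (mean(r[group == a]) - mean(r[group == b])) / sqrt(s2 * (1 / na + 1 / nb))
}

# AUC as the Mann-Whitney pair statistic: concordant + half-tied pairs over
# all positive-negative pairs, counted by explicit double loop
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Youden-optimal rule by exhaustive scan over every candidate midpoint
# cutoff, for the ">=" orientation on the supplied scores
oracle_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  best <- NULL
  for (t in cand) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (sens > best$sens + 1e-12 ||
          (abs(sens - best$sens) <= 1e-12 && t < best$t)))) {
      best <- list(t = t, sens = sens, spec = spec, j = j)
    }
  }
  best
}

# logistic log-likelihood maximized directly with optim (BFGS), independent
# of glm's IRLS path
oracle_logistic <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  gr <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    drop(t(X) %*% (p - y))
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  fit$par
}

# closed-form area of a Gaussian line with unit-peak amplitude A and FWHM w
oracle_gauss_area <- function(amplitude, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  amplitude * sigma * sqrt(2 * pi)
}
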