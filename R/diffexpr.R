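# The statistical tests applied between cell groups: a
# negative-binomial GLM likelihood-ratio test, the zero-inflated
# "bimodal" likelihood-ratio test for full-length platforms, a
# jackknife-resampled Wilcoxon rank-sum test for uneven group sizes,
# one-way ANOVA, and BH-FDR adjustment.

test_result <- function(statistic, p_value, test_name, n_a, n_b,
                        effect = NA_real_, converged = TRUE) {
  structure(list(statistic = statistic, p_value = p_value,
                 test_name = test_name, n_a = n_a, n_b = n_b,
                 effect = effect, converged = converged),
            class = "mito_test")
}

#' @export
print.mito_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d vs %d)\n",
              x$test_name, x$statistic, x$p_value, x$n_a, x$n_b))
  if (!x$converged) cat("  [model did not converge; p is NA]\n")
  invisible(x)
}

# NB log-likelihood with mean vector mu and dispersion 1/theta.
nb_loglik <- function(y, mu, theta) sum(dnbinom(y, size = theta, mu = mu,
                                                log = TRUE))

#' Negative-binomial likelihood-ratio test between two count vectors
#'
#' Compares an NB GLM (log link) with a group term against the
#' intercept-only model. The dispersion is estimated once by maximum
#' likelihood under the alternative and shared by both models, keeping
#' the test at one degree of freedom. Without covariates the NB MLE
#' group means are the sample means, so the profile likelihood in the
#' dispersion is maximized directly; with per-cell totals supplied the
#' models are refit as GLMs with a log-total offset.
#'
#' @param counts_a,counts_b non-negative integer vectors.
#' @param covariates optional per-cell total counts, `c(totals_a,
#'   totals_b)`, used as a log offset.
#' @return A `mito_test` (chi-square statistic, df 1). Non-convergence
#'   yields `p_value = NA` with `converged = FALSE`.
#' @export
negbinom_lrt <- function(counts_a, counts_b, covariates = NULL) {
  na <- length(counts_a); nb <- length(counts_b)
  if (na < 3 || nb < 3) stop_ctx("each group needs >= 3 cells")
  y <- c(counts_a, counts_b)
  if (any(y < 0) || any(y != round(y)))
    stop_ctx("counts must be non-negative integers")
  grp <- factor(rep(c("a", "b"), c(na, nb)))
  eff <- log((mean(counts_a) + 0.5) / (mean(counts_b) + 0.5))
  if (all(y == 0) ||
      (var(counts_a) == 0 && var(counts_b) == 0 &&
       mean(counts_a) == mean(counts_b)))
    return(test_result(0, 1, "negbinom_lrt", na, nb, eff))

  fit <- tryCatch({
    if (is.null(covariates)) {
      mu_alt <- rep(c(mean(counts_a), mean(counts_b)), c(na, nb))
      mu_null <- rep(mean(y), na + nb)
      opt <- optimize(function(lt) nb_loglik(y, mu_alt, exp(lt)),
                      interval = c(-7, 12), maximum = TRUE)
      theta <- exp(opt$maximum)
      list(ll_alt = opt$objective,
           ll_null = nb_loglik(y, mu_null, theta))
    } else {
      stopifnot(length(covariates) == na + nb)
      off <- log(covariates)
      alt <- suppressWarnings(MASS::glm.nb(y ~ grp + offset(off)))
      theta <- alt$theta
      null <- suppressWarnings(
        stats::glm(y ~ 1 + offset(off),
                   family = MASS::negative.binomial(theta)))
      list(ll_alt = nb_loglik(y, stats::fitted(alt), theta),
           ll_null = nb_loglik(y, stats::fitted(null), theta))
    }
  }, error = function(e) NULL)
  if (is.null(fit))
    return(test_result(NA_real_, NA_real_, "negbinom_lrt", na, nb, eff,
                       converged = FALSE))
  lr <- max(0, 2 * (fit$ll_alt - fit$ll_null))
  test_result(lr, pchisq(lr, df = 1, lower.tail = FALSE),
              "negbinom_lrt", na, nb, eff)
}

# Zero-inflated normal log-likelihood: an observation is zero with
# probability 1 - pi, otherwise Normal(mu, sd). Zeros contribute
# log(1 - pi); positives log(pi) + dnorm.
zin_loglik <- function(x, pi, mu, sdv) {
  nz <- sum(x == 0); pos <- x[x != 0]
  ll <- 0
  if (nz > 0) ll <- ll + nz * log(max(1 - pi, 1e-300))
  if (length(pos)) {
    if (sdv <= 0) sdv <- 1e-6
    ll <- ll + length(pos) * log(max(pi, 1e-300)) +
      sum(dnorm(pos, mu, sdv, log = TRUE))
  }
  ll
}

#' Bimodal (zero-inflated normal) likelihood-ratio test
#'
#' Models each log-normalized observation as zero with probability
#' `1 - pi` or, when expressed, Normal(mu, sigma^2). The alternative
#' allows group-specific (pi, mu); the null shares them; sigma is
#' pooled over expressing cells and re-estimated under each hypothesis.
#' The statistic is referred to chi-square with 2 degrees of freedom.
#'
#' @param expr_a,expr_b log-normalized expression vectors.
#' @return A `mito_test`.
#' @export
bimod_lrt <- function(expr_a, expr_b) {
  na <- length(expr_a); nb <- length(expr_b)
  if (na < 3 || nb < 3) stop_ctx("each group needs >= 3 cells")
  x <- c(expr_a, expr_b)
  eff <- mean(expr_a) - mean(expr_b)
  pos <- x[x != 0]
  if (!length(pos))   # both groups entirely zero
    return(test_result(0, 1, "bimod_lrt", na, nb, eff))
  mle <- function(v, mu) {
    p <- v[v != 0]
    if (!length(p)) return(0)
    sqrt(sum((p - mu)^2) / length(p))
  }
  # null: shared pi, mu, sigma
  pi0 <- length(pos) / length(x)
  mu0 <- mean(pos)
  sd0 <- mle(x, mu0)
  ll0 <- zin_loglik(x, pi0, mu0, sd0)
  # alternative: group-specific pi and mu, pooled sigma
  pa <- expr_a[expr_a != 0]; pb <- expr_b[expr_b != 0]
  pia <- length(pa) / na; pib <- length(pb) / nb
  mua <- if (length(pa)) mean(pa) else 0
  mub <- if (length(pb)) mean(pb) else 0
  ss <- sum((pa - mua)^2) + sum((pb - mub)^2)
  sd1 <- if (length(pos)) sqrt(ss / length(pos)) else 1e-6
  ll1 <- zin_loglik(expr_a, pia, mua, sd1) +
    zin_loglik(expr_b, pib, mub, sd1)
  lr <- max(0, 2 * (ll1 - ll0))
  test_result(lr, pchisq(lr, df = 2, lower.tail = FALSE),
              "bimod_lrt", na, nb, eff)
}

#' Wilcoxon rank-sum test with jackknife subsampling
#'
#' For uneven group sizes, the larger group is subsampled without
#' replacement to the smaller group's size `n_resamples` times; each
#' resample is tested with a two-sided rank-sum test and the resample
#' p-values are aggregated (median by default). Equal-sized groups get
#' a single test.
#'
#' @param x,y numeric vectors (each of size >= 2).
#' @param n_resamples resamples when sizes differ.
#' @param seed integer seed.
#' @param aggregate `"median"` or `"mean"` of resample p-values.
#' @return A `mito_test`; `statistic` is the aggregated W.
#' @export
wilcoxon_jackknife <- function(x, y, n_resamples = 1000, seed = 1L,
                               aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (length(x) < 2 || length(y) < 2)
    stop_ctx("each group needs >= 2 values")
  eff <- median(x) - median(y)
  if (length(x) == length(y)) {
    w <- suppressWarnings(wilcox.test(x, y))
    return(test_result(unname(w$statistic), w$p.value,
                       "wilcoxon_jackknife", length(x), length(y), eff))
  }
  small <- if (length(x) < length(y)) x else y
  big <- if (length(x) < length(y)) y else x
  flip <- length(x) >= length(y)   # TRUE: x was subsampled
  res <- with_seed(seed, vapply(seq_len(n_resamples), function(i) {
    sub <- sample(big, length(small))
    w <- suppressWarnings(
      if (flip) wilcox.test(sub, small) else wilcox.test(small, sub))
    c(w$statistic, w$p.value)
  }, numeric(2)))
  agg <- if (aggregate == "median") median else mean
  test_result(agg(res[1, ]), agg(res[2, ]), "wilcoxon_jackknife",
              length(x), length(y), eff)
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance.
#'
#' @param values numeric vector.
#' @param labels group factor (>= 2 groups, each with >= 2 values).
#' @return A `mito_test`; `statistic` is the F value.
#' @export
anova_oneway <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop_ctx("need >= 2 groups")
  if (any(table(labels) < 2)) stop_ctx("every group needs >= 2 values")
  fit <- aov(values ~ labels)
  tab <- summary(fit)[[1]]
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (is.na(f)) { f <- 0; p <- 1 }   # zero residual variance everywhere
  test_result(f, p, "anova_oneway", length(values), nlevels(labels))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()].
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop_ctx("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}
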