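#' Beta-binomial log probability mass
#'
#' `log P(X = x) = log C(n, x) + log B(x + alpha, n - x + beta) - log B(alpha, beta)`:
#' a binomial whose success probability is Beta(alpha, beta) distributed,
#' capturing overdispersion of spectral-count fractions across replicates.
#' The mean fraction is `pi = alpha / (alpha + beta)` and the overdispersion
#' is `theta = 1 / (alpha + beta + 1)`; `theta -> 0` recovers the binomial.
#'
#' @param x count(s), `0 <= x <= n`.
#' @param n trial total(s).
#' @param alpha,beta positive shape parameters.
#' @return log-probabilities (vectorized).
#' @export
betabin_logpmf <- function(x, n, alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0))
    stop("alpha and beta must be positive")
  if (any(x < 0) || any(x > n)) stop("x must satisfy 0 <= x <= n")
  lchoose(n, x) + lbeta(x + alpha, n - x + beta) - lbeta(alpha, beta)
}

#' Mean/overdispersion and shape parameterizations
#'
#' `pi_theta_to_shape()` maps the mean fraction `pi` and overdispersion
#' `theta = 1/(alpha + beta + 1)` to `(alpha, beta)`.
#'
#' @param pi mean success fraction in (0,1).
#' @param theta overdispersion in (0,1).
#' @return list with `alpha` and `beta`.
#' @export
pi_theta_to_shape <- function(pi, theta) {
  stopifnot(pi > 0, pi < 1, theta > 0, theta < 1)
  s <- (1 - theta) / theta           # alpha + beta
  list(alpha = pi * s, beta = (1 - pi) * s)
}

# log-likelihood of counts x with totals n at (pi, theta), WITHOUT the
# parameter-free lchoose(n, x) term (a constant, omitted during fitting)
bb_loglik <- function(x, n, pi, theta) {
  if (theta < 1e-10)
    return(sum(dbinom(x, n, pi, log = TRUE)) - sum(lchoose(n, x)))
  sh <- pi_theta_to_shape(pi, theta)
  sum(lbeta(x + sh$alpha, n - x + sh$beta) - lbeta(sh$alpha, sh$beta))
}

# maximize over pi for fixed theta; the MLE lies near the pooled fraction,
# so the search bracket is a generous factor around it (speed, not accuracy:
# a 200x margin on either side)
fit_pi_given_theta <- function(x, n, theta) {
  m <- sum(x) / sum(n)
  interval <-
    if (m == 0) c(1e-12, 1e-6)
    else if (m == 1) c(1 - 1e-6, 1 - 1e-12)
    else c(max(1e-12, m / 200), min(1 - 1e-12, max(200 * m, 1e-6)))
  f <- function(pi) bb_loglik(x, n, pi, theta)
  opt <- optimize(f, interval = interval, maximum = TRUE, tol = 1e-9)
  list(pi = opt$maximum, ll = opt$objective)
}

#' Fit a beta-binomial model by profile maximum likelihood
#'
#' Maximizes the likelihood of counts `x` with per-sample totals `n` over
#' the mean fraction `pi` and the shared overdispersion `theta`, profiling
#' `theta` by bounded one-dimensional optimization (tolerance 1e-8) with an
#' inner one-dimensional fit of `pi`.
#'
#' @param x,n integer count and total vectors of equal length.
#' @param theta optional fixed overdispersion; `NULL` (default) profiles it.
#' @param theta_max upper bound of the profiled search (default 0.95).
#' @return list with `pi`, `theta`, `loglik` (constants included).
#' @export
fit_betabin <- function(x, n, theta = NULL, theta_max = 0.95) {
  stopifnot(length(x) == length(n), all(n > 0), all(x >= 0), all(x <= n))
  if (!is.null(theta)) {
    fp <- fit_pi_given_theta(x, n, theta)
    return(list(pi = fp$pi, theta = theta,
                loglik = fp$ll + sum(lchoose(n, x))))
  }
  prof <- function(th) fit_pi_given_theta(x, n, th)$ll
  opt <- optimize(prof, interval = c(0, theta_max), maximum = TRUE, tol = 1e-8)
  # the binomial boundary can beat the interior optimum
  ll0 <- fit_pi_given_theta(x, n, 0)
  if (ll0$ll >= opt$objective)
    return(list(pi = ll0$pi, theta = 0, loglik = ll0$ll + sum(lchoose(n, x))))
  fp <- fit_pi_given_theta(x, n, opt$maximum)
  list(pi = fp$pi, theta = opt$maximum, loglik = fp$ll + sum(lchoose(n, x)))
}

#' Two-group beta-binomial likelihood-ratio test
#'
#' Tests a common success fraction (null: one `pi`, shared `theta`) against
#' group-specific fractions (alternative: `pi_A`, `pi_B`, shared `theta`).
#' A single overdispersion is profiled under the full two-fraction model
#' (consistent under both hypotheses, so a true group difference does not
#' masquerade as dispersion) and shared by both hypotheses; the statistic
#' is the likelihood ratio `2 * (loglik_alt - loglik_null)` and the
#' direction is the sign of `pi_A - pi_B` under the alternative fit.
#'
#' Two reference distributions for the p-value are offered.  The default,
#' `"bootstrap"`, simulates `n_boot` datasets from the fitted null
#' (beta-binomial with `pi_hat`, `theta_hat` at the observed totals),
#' recomputes the statistic on each with the same fixed `theta`, and reports
#' `(1 + #\{boot >= observed\}) / (1 + n_boot)` -- at the few-replicate,
#' low-count scale typical of AP-MS the chi-square asymptotics are
#' measurably anticonservative, and the bootstrap restores type-I control.
#' `"chisq"` is the classical upper chi-square tail with 1 degree of
#' freedom, with `theta` additionally re-profiled under the alternative
#' (the pure maximum-likelihood ratio).
#'
#' @param counts_a,counts_b integer count vectors (one entry per sample).
#' @param totals_a,totals_b per-sample trial totals (positive).
#' @param theta optional fixed overdispersion for both hypotheses
#'   (`theta = 0` with `p_method = "chisq"` gives the two-sample binomial
#'   LRT).
#' @param p_method reference distribution (see above).
#' @param n_boot bootstrap replicates (default 199; the attainable p floor
#'   is `1/(n_boot + 1)`).
#' @return list with `p_value`, `direction` (+1 when A > B, -1 when A < B,
#'   0 for no difference), `statistic`, `pi_a`, `pi_b`, `theta_null`,
#'   `theta_alt`.  The bootstrap draws from the current RNG stream; seed
#'   callers that need reproducibility.
#' @export
bb_test <- function(counts_a, totals_a, counts_b, totals_b, theta = NULL,
                    p_method = c("bootstrap", "chisq"), n_boot = 199L) {
  p_method <- match.arg(p_method)
  stopifnot(length(counts_a) == length(totals_a),
            length(counts_b) == length(totals_b))
  if (length(counts_a) + length(counts_b) < 2L)
    stop("at least 2 samples overall are required")
  if (any(totals_a <= 0) || any(totals_b <= 0))
    stop("per-sample totals must be positive")
  if (all(counts_a == 0) && all(counts_b == 0))
    return(list(p_value = 1, direction = 0, statistic = 0,
                pi_a = 0, pi_b = 0, theta_null = 0, theta_alt = 0))
  x <- c(counts_a, counts_b)
  n <- c(totals_a, totals_b)
  lrt_at <- function(xa, xb, th) {
    f0 <- fit_pi_given_theta(c(xa, xb), n, th)
    fa <- fit_pi_given_theta(xa, totals_a, th)
    fb <- fit_pi_given_theta(xb, totals_b, th)
    list(stat = max(0, 2 * (fa$ll + fb$ll - f0$ll)), pi_a = fa$pi, pi_b = fb$pi)
  }
  if (p_method == "chisq") {
    # pure maximum-likelihood ratio: theta profiled under each hypothesis
    if (is.null(theta)) {
      prof_alt <- function(th)
        fit_pi_given_theta(counts_a, totals_a, th)$ll +
        fit_pi_given_theta(counts_b, totals_b, th)$ll
      opt <- optimize(prof_alt, interval = c(0, 0.95), maximum = TRUE,
                      tol = 1e-8)
      th_alt <- if (prof_alt(0) >= opt$objective) 0 else opt$maximum
    } else th_alt <- theta
    fit0 <- fit_betabin(x, n, theta = theta)
    fa <- fit_pi_given_theta(counts_a, totals_a, th_alt)
    fb <- fit_pi_given_theta(counts_b, totals_b, th_alt)
    ll_alt <- fa$ll + fb$ll + sum(lchoose(n, x))
    stat <- max(0, 2 * (ll_alt - fit0$loglik))
    return(list(p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                direction = sign(fa$pi - fb$pi), statistic = stat,
                pi_a = fa$pi, pi_b = fb$pi,
                theta_null = fit0$theta, theta_alt = th_alt))
  }
  # bootstrap reference: the statistic fixes theta at a df-corrected
  # residual (quasi-binomial moment) estimate recomputed identically on
  # every dataset -- group means are subtracted, so a real effect does not
  # inflate it, and the N-2 correction removes the small-sample downward
  # bias of maximum likelihood
  na <- length(counts_a)
  theta_of <- function(xa, xb) {
    if (!is.null(theta)) return(theta)
    chi2 <- 0
    for (g in list(list(xa, totals_a), list(xb, totals_b))) {
      pg <- sum(g[[1]]) / sum(g[[2]])
      if (pg > 0 && pg < 1)
        chi2 <- chi2 + sum((g[[1]] - g[[2]] * pg)^2 / (g[[2]] * pg * (1 - pg)))
    }
    phi <- chi2 / (length(n) - 2)           # E[chi2] = df * (1 + (nbar-1) theta)
    min(max((phi - 1) / mean(n - 1), 0), 0.95)
  }
  th_obs <- theta_of(counts_a, counts_b)
  obs <- lrt_at(counts_a, counts_b, th_obs)
  pi0 <- fit_pi_given_theta(x, n, th_obs)$pi
  hits <- 0L
  for (b in seq_len(n_boot)) {
    xs <- rbetabinom(n, pi0, th_obs)
    xa <- xs[seq_len(na)]
    xb <- xs[-seq_len(na)]
    if (lrt_at(xa, xb, theta_of(xa, xb))$stat >= obs$stat)
      hits <- hits + 1L
  }
  list(p_value = (1 + hits) / (1 + n_boot),
       direction = sign(obs$pi_a - obs$pi_b), statistic = obs$stat,
       pi_a = obs$pi_a, pi_b = obs$pi_b,
       theta_null = th_obs, theta_alt = th_obs)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min over j >= i of min(1, m * p_(j) / j)` on the sorted p-values,
#' returned in the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in the same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0L) return(numeric())
  o <- order(p_values)
  q <- pmin(1, m * p_values[o] / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Simulate beta-binomial counts
#'
#' Draws `length(n)` counts with totals `n`, mean fraction `pi` and
#' overdispersion `theta` (binomial when `theta = 0`).
#'
#' @param n vector of trial totals.
#' @param pi mean success fraction.
#' @param theta overdispersion in `[0, 1)`.
#' @return integer vector of counts.
#' @export
rbetabinom <- function(n, pi, theta) {
  if (theta < 1e-12) return(rbinom(length(n), n, pi))
  sh <- pi_theta_to_shape(pi, theta)
  p <- stats::rbeta(length(n), sh$alpha, sh$beta)
  rbinom(length(n), n, p)
}
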