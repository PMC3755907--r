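#' Luria-Delbruck mutant-count distribution (Ma-Sandri-Sarkar recursion)
#'
#' Probability of observing `k` mutant cells in a culture when the expected
#' number of mutation events per culture is `m`, under the classic
#' Luria-Delbruck model (deterministic growth, mutants breed true, no
#' differential fitness). Computed by the stable recursion
#' `p0 = exp(-m)`, `p_k = (m/k) * sum_{j<k} p_j / (k - j + 1)`.
#'
#' @param m Expected mutations per culture (>= 0).
#' @param k_max Largest count to evaluate.
#' @return Numeric vector `p[0..k_max]` (length `k_max + 1`); the mass not
#'   covered, `1 - sum(p)`, is the tail beyond `k_max`.
#' @examples
#' ld_pmf(1, 5)   # p1 = exp(-1)/2
#' @export
ld_pmf <- function(m, k_max) {
  if (m < 0) stop("m must be non-negative", call. = FALSE)
  if (k_max < 0) stop("k_max must be >= 0", call. = FALSE)
  p <- numeric(k_max + 1L)
  p[1L] <- exp(-m)
  if (k_max >= 1L && m > 0) {
    for (k in seq_len(k_max)) {
      j <- 0:(k - 1L)
      p[k + 1L] <- (m / k) * sum(p[j + 1L] / (k - j + 1))
    }
  }
  p
}

new_fluctuation_fit <- function(method, m, m_ci, n_final, n_cultures,
                                extra = list()) {
  structure(c(list(method = method, m = m,
                   m_ci_low = m_ci[1L], m_ci_high = m_ci[2L],
                   rate = m / n_final,
                   ci_low = m_ci[1L] / n_final,
                   ci_high = m_ci[2L] / n_final,
                   n_final = n_final, n_cultures = n_cultures), extra),
            class = "fluctuation_fit")
}

#' @export
print.fluctuation_fit <- function(x, ...) {
  cat(sprintf("Fluctuation assay (%s): m = %.4g, rate = %.3g per division\n",
              x$method, x$m, x$rate))
  cat(sprintf("  95%% CI on rate: [%.3g, %.3g]  (%d cultures, Nf = %.3g)\n",
              x$ci_low, x$ci_high, x$n_cultures, x$n_final))
  invisible(x)
}

#' @export
coef.fluctuation_fit <- function(object, ...) {
  c(m = object$m, rate = object$rate)
}

#' @export
confint.fluctuation_fit <- function(object, parm = "rate", level = 0.95, ...) {
  matrix(c(object$ci_low, object$ci_high), nrow = 1,
         dimnames = list("rate", c("2.5 %", "97.5 %")))
}

#' P0 (null-class) estimator of the mutation rate
#'
#' Uses only the fraction of cultures with zero mutants: under the
#' Luria-Delbruck model `P(0 mutants) = exp(-m)`, so
#' `m = -log(fraction of zero cultures)` and the per-division rate is
#' `m / n_final`. The confidence interval is the Clopper-Pearson binomial
#' interval on the zero fraction, propagated through `-log`.
#'
#' @param mutant_counts Integer vector of mutant counts, one per culture.
#' @param n_final Cells per culture at plating.
#' @param conf Confidence level (default 0.95).
#' @return A `fluctuation_fit`.
#' @examples
#' p0_estimate(c(rep(0, 10), rep(3, 10)), n_final = 1e7)  # m = log(2)
#' @export
p0_estimate <- function(mutant_counts, n_final, conf = 0.95) {
  C <- length(mutant_counts)
  z <- sum(mutant_counts == 0L)
  if (z == 0L) {
    stop("no culture with zero mutants: the P0 estimator is undefined; ",
         "use mss_mle()", call. = FALSE)
  }
  p0 <- z / C
  m <- -log(p0)
  a <- 1 - conf
  # Clopper-Pearson bounds on the zero fraction
  p_lo <- if (z == 0L) 0 else qbeta(a / 2, z, C - z + 1)
  p_hi <- if (z == C) 1 else qbeta(1 - a / 2, z + 1, C - z)
  m_ci <- c(-log(p_hi), -log(p_lo))
  new_fluctuation_fit("P0", m, m_ci, n_final, C,
                      extra = list(zero_fraction = p0))
}

#' Ma-Sandri-Sarkar maximum-likelihood estimator of the mutation rate
#'
#' Maximises the Luria-Delbruck log-likelihood of the per-culture mutant
#' counts over the expected mutations per culture `m` (derivative-free
#' bounded search on log m). Jackpot counts above `k_cap` are lumped into a
#' single tail class with probability `1 - sum(p_k, k <= k_cap)` for
#' numerical stability. The 95% confidence interval uses the standard
#' normal approximation on `ln m` with
#' `sigma = 1.225 * m^-0.315 / sqrt(n_cultures)`.
#'
#' @inheritParams p0_estimate
#' @param k_cap Counts above this are pooled into the tail class (default
#'   1000; the tail above that holds only ~m/1000 of the mass, and pooling
#'   keeps the quadratic pmf recursion cheap even with jackpot cultures).
#' @param weights Optional per-count weights (e.g. expected frequencies);
#'   defaults to 1 per culture.
#' @return A `fluctuation_fit` with a `loglik` component. If every count is
#'   zero the P0 result is returned with a warning.
#' @export
mss_mle <- function(mutant_counts, n_final, k_cap = 1000L, weights = NULL,
                    conf = 0.95) {
  if (length(mutant_counts) < 2L) stop("need at least 2 cultures",
                                       call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(mutant_counts))
  C <- sum(weights)
  if (all(mutant_counts == 0L)) {
    warning("all cultures have zero mutants; falling back to the P0 estimator")
    return(p0_estimate(mutant_counts, n_final, conf))
  }
  in_tail <- mutant_counts > k_cap
  k_top <- if (all(in_tail)) 0L else max(mutant_counts[!in_tail])
  agg <- tapply(weights[!in_tail], mutant_counts[!in_tail], sum)
  ks <- as.integer(names(agg))
  w_tail <- sum(weights[in_tail])
  negll <- function(log_m) {
    m <- exp(log_m)
    p <- ld_pmf(m, k_top)
    ll <- sum(agg * log(pmax(p[ks + 1L], 1e-300)))
    if (w_tail > 0) ll <- ll + w_tail * log(max(1 - sum(p), 1e-300))
    -ll
  }
  opt <- optimize(negll, interval = log(c(1e-6, 1e3)), tol = 1e-7)
  m <- exp(opt$minimum)
  z <- qnorm(1 - (1 - conf) / 2)
  sigma <- 1.225 * m^(-0.315) / sqrt(C)
  m_ci <- exp(log(m) + c(-1, 1) * z * sigma)
  new_fluctuation_fit("MSS-MLE", m, m_ci, n_final, length(mutant_counts),
                      extra = list(loglik = -opt$objective, sigma_ln_m = sigma))
}
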