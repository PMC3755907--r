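#' Insertion/deletion bias test for one motif class
#'
#' Pearson chi-square goodness of fit of the insertion and deletion counts
#' against a 50:50 expectation (df = 1, no continuity correction -- the
#' statistic is `(n_ins - n_del)^2 / n`). Classes with fewer than five
#' events are computed anyway but flagged as too sparse for inference.
#'
#' @param n_ins,n_del Non-negative event counts.
#' @param motif_class Optional label carried through to the result.
#' @return A `bias_result` list: `motif_class`, `n_ins`, `n_del`, `n`,
#'   `majority`, `majority_fraction`, `chi2`, `p_value`, `low_n`.
#' @examples
#' indel_bias_test(10, 28)   # deletion-biased, p = 3.5e-3
#' @export
indel_bias_test <- function(n_ins, n_del, motif_class = NA_character_) {
  n <- n_ins + n_del
  if (n < 1) stop("need at least one event", call. = FALSE)
  chi2 <- (n_ins - n_del)^2 / n
  structure(list(
    motif_class = motif_class, n_ins = n_ins, n_del = n_del, n = n,
    majority = if (n_del >= n_ins) "deletion" else "insertion",
    majority_fraction = max(n_ins, n_del) / n,
    chi2 = chi2,
    p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
    low_n = n < 5), class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("%s: %d ins / %d del  (%s %.0f%%)  chi2 = %.3g, p = %.2g%s\n",
              ifelse(is.na(x$motif_class), "indel bias", x$motif_class),
              x$n_ins, x$n_del, x$majority, 100 * x$majority_fraction,
              x$chi2, x$p_value, if (x$low_n) "  [low n]" else ""))
  invisible(x)
}

#' Per-class insertion/deletion bias table
#'
#' Runs [indel_bias_test()] for every motif class present among the
#' assigned indels of a classified mutation table, or for a supplied
#' ins/del count table.
#'
#' @param x Classified mutation table, or a data frame with columns
#'   `motif_class`, `n_ins`, `n_del`.
#' @return Data frame with one row per class plus the test columns.
#' @export
indel_bias_table <- function(x) {
  if (all(c("n_ins", "n_del") %in% names(x))) {
    counts <- x
  } else {
    ind <- x[x$kind == "indel" & !is.na(x$motif_class), , drop = FALSE]
    counts <- aggregate(
      list(n_ins = ind$indel_sign == "insertion",
           n_del = ind$indel_sign == "deletion"),
      by = list(motif_class = ind$motif_class), FUN = sum)
  }
  res <- lapply(seq_len(nrow(counts)), function(i) {
    b <- indel_bias_test(counts$n_ins[i], counts$n_del[i],
                         counts$motif_class[i])
    data.frame(motif_class = b$motif_class, n_ins = b$n_ins,
               n_del = b$n_del, n = b$n, majority = b$majority,
               majority_fraction = b$majority_fraction, chi2 = b$chi2,
               p_value = b$p_value, low_n = b$low_n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$motif_class), , drop = FALSE]
}

#' Two-sample Kolmogorov-Smirnov comparison of repeat-distance distributions
#'
#' Compares the nearest-repeat distances of mutated loci against those of
#' all genomic loci: a left shift of the mutated ECDF means repeats with a
#' proximal repeat are more mutable. The statistic is the supremum
#' difference between the two empirical distribution functions over the
#' pooled support; the p-value is the asymptotic Smirnov tail evaluated at
#' the effective sample size `n1*n2/(n1+n2)`.
#'
#' @param mutated_distances,all_distances Numeric samples (`NA`s dropped);
#'   each needs at least 2 values.
#' @return A `proximity_result` list: `ks_D`, `p_value`, `n_mutated`,
#'   `n_all`, and `ecdf_table` (pooled support with both ECDFs, for
#'   plotting).
#' @export
proximity_ks <- function(mutated_distances, all_distances) {
  x <- sort(mutated_distances[!is.na(mutated_distances)])
  y <- sort(all_distances[!is.na(all_distances)])
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  support <- sort(unique(c(x, y)))
  Fx <- cumsum(tabulate(findInterval(x, support), length(support))) / length(x)
  Fy <- cumsum(tabulate(findInterval(y, support), length(support))) / length(y)
  D <- max(abs(Fx - Fy))
  ne <- length(x) * length(y) / (length(x) + length(y))
  structure(list(ks_D = D,
                 p_value = ks_asymptotic_p(D, ne),
                 n_mutated = length(x), n_all = length(y),
                 ecdf_table = data.frame(distance = support, ecdf_mutated = Fx,
                                         ecdf_all = Fy)),
            class = "proximity_result")
}

# Asymptotic Smirnov tail probability, with the standard small-sample
# refinement of the argument (as used by MATLAB's kstest2).
ks_asymptotic_p <- function(D, ne) {
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  if (lambda < 1e-12) return(1)
  j <- 1:101
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.4f (n = %d vs %d), p = %.3g\n",
              x$ks_D, x$n_mutated, x$n_all, x$p_value))
  invisible(x)
}

#' Fraction of distances at or below a cutoff
#'
#' @param distances Numeric distances (`NA` dropped).
#' @param cutoff_bp Cutoff in bp.
#' @return Fraction of distances `<= cutoff_bp`.
#' @export
cumulative_within <- function(distances, cutoff_bp) {
  d <- distances[!is.na(distances)]
  if (!length(d)) stop("no distances", call. = FALSE)
  mean(d <= cutoff_bp)
}

#' Monte-Carlo Fisher-type comparison of two mutation spectra
#'
#' Tests whether two category-count vectors (e.g. the spectra of two
#' strains) come from the same multinomial, by the exact-conditional
#' (Fisher) criterion on the 2 x k table: the p-value is the probability,
#' over tables with the observed margins, of a table no more likely than
#' the observed one under the multivariate hypergeometric distribution.
#' The null distribution is sampled (`stats::r2dtable`) because full
#' enumeration is combinatorial for k > 2. A Pearson chi-square p-value is
#' reported alongside.
#'
#' @param table_a,table_b Non-negative integer count vectors over the same
#'   categories (length >= 2).
#' @param n_mc Number of Monte-Carlo tables (default 1e5).
#' @param seed Mandatory RNG seed for reproducibility.
#' @return List with `p_mc`, `p_chisq`, `chi2`, `n_mc`.
#' @export
compare_spectra <- function(table_a, table_b, n_mc = 1e5, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  k <- length(table_a)
  if (k < 2L || length(table_b) != k) {
    stop("need two count vectors over the same >= 2 categories",
         call. = FALSE)
  }
  if (sum(table_a) < 1 || sum(table_b) < 1) {
    stop("both spectra need at least one event", call. = FALSE)
  }
  obs <- rbind(as.integer(table_a), as.integer(table_b))
  # log-likelihood of a margins-conditioned table, up to a constant:
  # -sum(lgamma(cell + 1)); larger penalty = less likely table.
  penalty <- function(tab) sum(lgamma(tab + 1))
  obs_pen <- penalty(obs)
  set.seed(seed)
  sims <- r2dtable(n_mc, rowSums(obs), colSums(obs))
  pens <- vapply(sims, penalty, numeric(1))
  p_mc <- (1 + sum(pens >= obs_pen - 1e-7)) / (n_mc + 1)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  chi2 <- sum((obs - expected)^2 / expected)
  df <- (nrow(obs) - 1L) * (k - 1L)
  list(p_mc = p_mc, chi2 = chi2,
       p_chisq = pchisq(chi2, df, lower.tail = FALSE), n_mc = n_mc)
}
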