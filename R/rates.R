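#' Per-base-pair mutation rate with exact Poisson confidence interval
#'
#' The rate is the event count divided by the mutational opportunity
#' (lineages x generations x callable genome size); the 95% interval is the
#' exact (Garwood) Poisson interval on the count, scaled by the opportunity.
#'
#' @param events Non-negative event count.
#' @param n_lineages,generations,callable_bp Opportunity factors; all must
#'   be positive.
#' @param conf Confidence level (default 0.95).
#' @return A `rate_estimate` list: `events`, `opportunity`, `rate`,
#'   `ci_low`, `ci_high`.
#' @examples
#' per_bp_rate(147, n_lineages = 1, generations = 170,
#'             callable_bp = 1.216e7)
#' @export
per_bp_rate <- function(events, n_lineages, generations, callable_bp,
                        conf = 0.95) {
  opportunity <- as.numeric(n_lineages) * as.numeric(generations) *
    as.numeric(callable_bp)
  rate_estimate(events, opportunity, conf)
}

#' Generic rate estimate over an arbitrary opportunity
#'
#' @param events Non-negative event count.
#' @param opportunity Positive product of target size and time
#'   (e.g. bp x generations x lineages, or repeats x generations).
#' @param conf Confidence level.
#' @return A `rate_estimate` object.
#' @export
rate_estimate <- function(events, opportunity, conf = 0.95) {
  if (!is.finite(opportunity) || opportunity <= 0) {
    stop("opportunity must be positive", call. = FALSE)
  }
  if (events < 0) stop("events must be non-negative", call. = FALSE)
  ci <- poisson_ci(events, conf)
  structure(list(events = events, opportunity = opportunity,
                 rate = events / opportunity,
                 ci_low = ci[1L] / opportunity,
                 ci_high = ci[2L] / opportunity,
                 conf = conf),
            class = "rate_estimate")
}

# Exact (Garwood) Poisson CI on a count.
poisson_ci <- function(k, conf = 0.95) {
  a <- 1 - conf
  lo <- if (k == 0) 0 else qchisq(a / 2, 2 * k) / 2
  hi <- qchisq(1 - a / 2, 2 * k + 2) / 2
  c(lo, hi)
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate %.3g  (%d events / %.4g opportunity), %g%% CI [%.3g, %.3g]\n",
              x$rate, x$events, x$opportunity, 100 * x$conf,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Fold induction over a reference mutation rate
#'
#' @param rate Estimated rate (or a `rate_estimate`).
#' @param reference_rate Positive wild-type reference rate; the default
#'   3.3e-10 per bp per generation is the published wild-type yeast value
#'   used for fold-induction columns.
#' @return List with `fold` (unrounded) and `fold_rounded` (integer).
#' @export
fold_induction <- function(rate, reference_rate = 3.3e-10) {
  if (inherits(rate, "rate_estimate")) rate <- rate$rate
  if (reference_rate <= 0) stop("reference_rate must be positive")
  f <- rate / reference_rate
  list(fold = f, fold_rounded = round(f))
}

SPECTRUM_CATEGORIES <- c("deletions_at_homopolymers",
                         "insertions_at_homopolymers",
                         "transitions", "transversions",
                         "insertions_at_microsatellites",
                         "deletions_at_microsatellites")

#' Mutational spectrum table
#'
#' Tallies classified mutations into the six-category spectrum used for
#' genome-wide MMR-deficient summaries: deletions/insertions at
#' homopolymers, transitions, transversions, and insertions/deletions at
#' larger (unit length >= 2) microsatellites. Percentages are of the grand
#' total; homopolymer-indel and microsatellite-indel subtotals are included.
#'
#' @param x Either a classified mutation table (from
#'   [classify_mutations()]) or a named numeric vector of the six category
#'   counts (names as in the returned table).
#' @return A `spectrum_table` data frame with `category`, `count`,
#'   `percent`, plus attributes `total`, `hpr_indel_percent`,
#'   `ms_indel_percent`, `n_unassigned_indels`.
#' @export
spectrum_table <- function(x) {
  n_unassigned <- 0L
  if (is.data.frame(x)) {
    needed <- c("kind", "ts_tv", "indel_sign", "unit_len")
    missing_cols <- setdiff(needed, names(x))
    if (length(missing_cols)) {
      stop("mutations must be classified first; missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    bad <- which(x$kind == "SNV" & is.na(x$ts_tv))
    if (length(bad)) {
      stop("unclassified substitution rows: ",
           paste(head(bad, 10L), collapse = ", "), call. = FALSE)
    }
    is_indel <- x$kind == "indel"
    assigned <- is_indel & !is.na(x$unit_len)
    n_unassigned <- sum(is_indel & is.na(x$unit_len))
    hp <- assigned & x$unit_len == 1L
    ms <- assigned & x$unit_len >= 2L
    counts <- c(
      deletions_at_homopolymers  = sum(hp & x$indel_sign == "deletion"),
      insertions_at_homopolymers = sum(hp & x$indel_sign == "insertion"),
      transitions   = sum(x$kind == "SNV" & x$ts_tv == "transition"),
      transversions = sum(x$kind == "SNV" & x$ts_tv == "transversion"),
      insertions_at_microsatellites = sum(ms & x$indel_sign == "insertion"),
      deletions_at_microsatellites  = sum(ms & x$indel_sign == "deletion"))
  } else {
    counts <- x
    if (is.null(names(counts))) names(counts) <- SPECTRUM_CATEGORIES
    counts <- counts[SPECTRUM_CATEGORIES]
    if (any(is.na(counts))) stop("need all six spectrum categories")
  }
  total <- sum(counts)
  if (total == 0) stop("no classified mutations to tabulate")
  tab <- data.frame(category = SPECTRUM_CATEGORIES,
                    count = as.integer(counts),
                    percent = 100 * as.numeric(counts) / total,
                    stringsAsFactors = FALSE)
  structure(tab, class = c("spectrum_table", "data.frame"),
            total = total,
            hpr_indel_percent = 100 * sum(counts[1:2]) / total,
            ms_indel_percent = 100 * sum(counts[5:6]) / total,
            n_unassigned_indels = n_unassigned)
}

#' @export
print.spectrum_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$percent <- sprintf("%.1f", df$percent)
  print(df, row.names = FALSE)
  cat(sprintf("total %d; homopolymer indels %.1f%%; microsatellite indels %.1f%%\n",
              attr(x, "total"), attr(x, "hpr_indel_percent"),
              attr(x, "ms_indel_percent")))
  invisible(x)
}

#' Mutation rate per repeat, stratified by repeat length
#'
#' For each motif class and length `L` (run length in bp for homopolymers,
#' unit count for larger microsatellites) the rate is the number of slippage
#' events divided by (number of such repeats in the genome x lineages x
#' generations). Rows with repeat span >= `dropout_bp` are flagged: indel
#' detection degrades at long repeats, so those rates are potential
#' underestimates.
#'
#' @param classified Classified mutation table (indels must carry
#'   `motif_class`, `unit_len`, `repeat_id`).
#' @param census `repeat_census` giving the per-(class, L) denominators.
#' @param n_lineages,generations Opportunity factors.
#' @param classes Motif classes to include (default: homopolymers plus the
#'   three common dinucleotide classes; tetranucleotides are censused but
#'   excluded by default because events are sparse).
#' @param dropout_bp Span (bp) above which rates are flagged (default 14).
#' @return A `length_rate_curve` data frame: `motif_class`, `unit_len`, `L`,
#'   `n_repeats`, `events`, `rate`, `flagged`.
#' @export
per_repeat_rate_by_length <- function(classified, census, n_lineages,
                                      generations,
                                      classes = c("A/T", "C/G", "AT/TA",
                                                  "GT/CA", "GA/CT"),
                                      dropout_bp = 14L) {
  hist <- census$by_class_and_length
  hist <- hist[hist$motif_class %in% classes, , drop = FALSE]
  ind <- classified[classified$kind == "indel" & !is.na(classified$repeat_id), ,
                    drop = FALSE]
  loci <- census$loci
  if (nrow(ind)) {
    ind$L <- ifelse(ind$unit_len == 1L,
                    loci$length_bp[ind$repeat_id],
                    loci$n_units[ind$repeat_id])
    ev <- aggregate(list(events = rep(1L, nrow(ind))),
                    by = list(motif_class = ind$motif_class,
                              unit_len = ind$unit_len, L = ind$L), FUN = sum)
  } else {
    ev <- data.frame(motif_class = character(), unit_len = integer(),
                     L = integer(), events = integer())
  }
  curve <- merge(hist, ev, all.x = TRUE,
                 by = c("motif_class", "unit_len", "L"))
  orphan <- merge(ev[ev$motif_class %in% classes, , drop = FALSE], hist,
                  all.x = TRUE, by = c("motif_class", "unit_len", "L"))
  if (any(is.na(orphan$n))) {
    bad <- orphan[is.na(orphan$n), ]
    stop("events observed at uncensused (class, length) combinations: ",
         paste(sprintf("%s L=%d", bad$motif_class, bad$L), collapse = "; "),
         call. = FALSE)
  }
  curve$events[is.na(curve$events)] <- 0L
  names(curve)[names(curve) == "n"] <- "n_repeats"
  curve$rate <- curve$events /
    (as.numeric(curve$n_repeats) * n_lineages * generations)
  curve$flagged <- ifelse(curve$unit_len == 1L, curve$L,
                          curve$L * curve$unit_len) >= dropout_bp
  curve <- curve[order(curve$motif_class, curve$unit_len, curve$L), ,
                 drop = FALSE]
  rownames(curve) <- NULL
  structure(curve, class = c("length_rate_curve", "data.frame"),
            n_lineages = n_lineages, generations = generations)
}

#' Fit exponential and linear regimes to a length-rate curve
#'
#' Over short repeats the per-repeat mutation rate grows exponentially with
#' length; the fit regresses log10(rate) on `L` over `exp_range` (default
#' 3-8) by ordinary least squares and reports `fold_per_unit = 10^slope`,
#' the multiplicative rate increase per added unit. For long repeats
#' (`L >= lin_min`, default 9) growth is closer to linear; rate is
#' regressed on `L` directly and the R-squared reported. Zero-rate lengths
#' are excluded from the log fit (and listed); a regime with too few points
#' is marked unavailable rather than extrapolated.
#'
#' @param curve A `length_rate_curve` (or compatible data frame).
#' @param class Motif class to fit (default `"A/T"`).
#' @param exp_range,lin_min Length windows for the two regimes.
#' @return List with components `exp_fit` (`slope`, `intercept`,
#'   `fold_per_unit`, `r_squared`, `n_points`, `zero_lengths`) and `lin_fit`
#'   (`slope`, `intercept`, `r_squared`, `n_points`); unavailable fits are
#'   `NULL`.
#' @export
fit_regimes <- function(curve, class = "A/T", exp_range = 3:8, lin_min = 9L) {
  cc <- curve[curve$motif_class == class, , drop = FALSE]
  exp_pts <- cc[cc$L %in% exp_range, , drop = FALSE]
  zero_lengths <- exp_pts$L[exp_pts$rate == 0]
  exp_pts <- exp_pts[exp_pts$rate > 0, , drop = FALSE]
  exp_fit <- NULL
  if (nrow(exp_pts) >= 3L) {
    fit <- lm(log10(rate) ~ L, data = exp_pts)
    exp_fit <- list(slope = unname(coef(fit)[2L]),
                    intercept = unname(coef(fit)[1L]),
                    fold_per_unit = 10^unname(coef(fit)[2L]),
                    r_squared = summary(fit)$r.squared,
                    n_points = nrow(exp_pts),
                    zero_lengths = zero_lengths)
  }
  lin_pts <- cc[cc$L >= lin_min, , drop = FALSE]
  lin_fit <- NULL
  if (nrow(lin_pts) >= 2L) {
    fit <- lm(rate ~ L, data = lin_pts)
    lin_fit <- list(slope = unname(coef(fit)[2L]),
                    intercept = unname(coef(fit)[1L]),
                    r_squared = summary(fit)$r.squared,
                    n_points = nrow(lin_pts))
  }
  list(exp_fit = exp_fit, lin_fit = lin_fit)
}

#' Regression of mutation count on chromosome size
#'
#' Under a uniform genome-wide mutation process the per-chromosome mutation
#' count is proportional to chromosome length; the R-squared of the OLS fit
#' (with intercept) quantifies that proportionality.
#'
#' @param positions Data frame with a `chrom` column (one row per mutation).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @return List with `table` (chrom, length_bp, count), `slope`,
#'   `intercept`, `r_squared`.
#' @export
chromosome_size_regression <- function(positions, chrom_lengths) {
  if (length(chrom_lengths) < 3L) {
    stop("need at least 3 chromosomes", call. = FALSE)
  }
  counts <- table(factor(positions$chrom, levels = names(chrom_lengths)))
  df <- data.frame(chrom = names(chrom_lengths),
                   length_bp = as.numeric(chrom_lengths),
                   count = as.integer(counts), stringsAsFactors = FALSE)
  fit <- lm(count ~ length_bp, data = df)
  list(table = df,
       slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = summary(fit)$r.squared)
}

#' Chi-square test of mutation-rate homogeneity across replication-timing bins
#'
#' Bins tile the genome (e.g. 10-minute replication-timing intervals);
#' expected mutation counts are proportional to bin size in bp. A Pearson
#' chi-square over the bins (df = bins - 1) tests whether the observed
#' counts deviate from the uniform-rate expectation. Bins whose expected
#' count falls below `min_expected` are merged into the previous bin (and
#' reported).
#'
#' @param positions Data frame with `chrom` and `pos` (0-based) columns.
#' @param bins Data frame with `chrom`, `start`, `end` (0-based half-open)
#'   and a `bin` label column.
#' @param min_expected Merge threshold for small expected counts (default 1).
#' @return List with `statistic`, `df`, `p_value`, `table` (bin, bp,
#'   observed, expected), `merged_bins`.
#' @export
replication_timing_test <- function(positions, bins, min_expected = 1) {
  gr_bins <- GenomicRanges::GRanges(
    bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))
  gr_mut <- GenomicRanges::GRanges(
    positions$chrom, IRanges::IRanges(positions$pos + 1L, positions$pos + 1L))
  hit <- GenomicRanges::findOverlaps(gr_mut, gr_bins, select = "first")
  if (anyNA(hit)) {
    stop(sum(is.na(hit)), " mutation(s) fall outside the bin tiling",
         call. = FALSE)
  }
  lab <- as.character(bins$bin)
  obs <- tapply(rep(1L, length(hit)), factor(lab[hit], levels = unique(lab)),
                sum, default = 0L)
  bp <- tapply(bins$end - bins$start, factor(lab, levels = unique(lab)), sum)
  n <- sum(obs)
  expected <- n * bp / sum(bp)
  merged <- character(0)
  while (length(expected) > 1L && any(expected < min_expected)) {
    i <- which(expected < min_expected)[1L]
    j <- if (i == 1L) 2L else i - 1L
    merged <- c(merged, names(expected)[i])
    expected[j] <- expected[j] + expected[i]
    obs[j] <- obs[j] + obs[i]
    bp[j] <- bp[j] + bp[i]
    expected <- expected[-i]; obs <- obs[-i]; bp <- bp[-i]
  }
  stat <- sum((obs - expected)^2 / expected)
  df <- length(obs) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       table = data.frame(bin = names(expected), bp = as.numeric(bp),
                          observed = as.integer(obs),
                          expected = as.numeric(expected),
                          stringsAsFactors = FALSE),
       merged_bins = merged)
}

#' Fraction of mutations falling in coding sequence
#'
#' @param classified Classified mutation table (`chrom`, `pos`, `kind`).
#' @param coding Data frame of coding intervals (`chrom`, `start`, `end`,
#'   0-based half-open); overlapping intervals are merged first.
#' @return List with overall `fraction`, and `by_kind` (fraction for SNVs
#'   and indels separately).
#' @export
coding_fraction <- function(classified, coding) {
  gr_cds <- GenomicRanges::reduce(GenomicRanges::GRanges(
    coding$chrom, IRanges::IRanges(coding$start + 1L, coding$end)))
  gr_mut <- GenomicRanges::GRanges(
    classified$chrom,
    IRanges::IRanges(classified$pos + 1L, classified$pos + 1L))
  inside <- GenomicRanges::countOverlaps(gr_mut, gr_cds) > 0L
  frac <- function(sel) if (any(sel)) mean(inside[sel]) else NA_real_
  list(fraction = mean(inside),
       by_kind = c(SNV = frac(classified$kind == "SNV"),
                   indel = frac(classified$kind == "indel")))
}
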