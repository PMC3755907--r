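test_that("per-bp rates reproduce the published per-lineage arithmetic", {
  r <- per_bp_rate(147, n_lineages = 1, generations = 170,
                   callable_bp = 1.216e7)
  expect_equal(signif(r$rate, 2), 7.1e-8)
  expect_true(r$ci_low <= r$rate && r$rate <= r$ci_high)

  pooled <- per_bp_rate(158, n_lineages = 16, generations = 170,
                        callable_bp = 1.216e7)
  expect_equal(signif(pooled$rate, 2), 4.8e-9)

  zero <- per_bp_rate(0, 1, 170, 1.216e7)
  expect_equal(zero$rate, 0)
  expect_equal(zero$ci_low, 0)
  expect_gt(zero$ci_high, 0)
  expect_error(per_bp_rate(5, 0, 170, 1e6), "positive")

  # opportunity linearity: rate(k*events, k*opportunity) = rate(events, opp)
  r1 <- rate_estimate(12, 3.4e8)
  r2 <- rate_estimate(36, 3 * 3.4e8)
  expect_equal(r1$rate, r2$rate)
})

test_that("fold induction matches the published rounding", {
  expect_equal(fold_induction(7.111e-8)$fold_rounded, 215)
  expect_equal(fold_induction(1e-9, 1e-9)$fold, 1)
  expect_equal(fold_induction(6.6e-10)$fold, 2)
})

test_that("spectrum table computes category percentages and subtotals", {
  counts <- c(deletions_at_homopolymers = 2011,
              insertions_at_homopolymers = 161,
              transitions = 112, transversions = 46,
              insertions_at_microsatellites = 86,
              deletions_at_microsatellites = 60)
  tab <- spectrum_table(counts)
  expect_equal(round(attr(tab, "hpr_indel_percent"), 1), 87.7)
  expect_equal(round(attr(tab, "ms_indel_percent"), 1), 5.9)
  expect_equal(round(tab$percent[tab$category == "transversions"], 1), 1.9)
  expect_equal(sum(tab$percent), 100)

  single <- spectrum_table(c(0, 0, 1, 0, 0, 0))
  expect_equal(single$percent[single$category == "transitions"], 100)

  expect_error(spectrum_table(data.frame(kind = "SNV")), "classified")
})

test_that("per-repeat rates by length follow the opportunity arithmetic", {
  loci <- data.frame(chrom = "c", start = (0:99) * 20L,
                     end = (0:99) * 20L + 5L, unit = "A",
                     unit_len = 1L, n_units = 5L)
  cen <- as_repeat_census(loci)
  cl <- data.frame(lineage_id = "L1", chrom = "c", pos = 0L, ref = "AA",
                   alt = "A", kind = "indel", ts_tv = NA, snv_class = NA,
                   repeat_id = 1L, indel_sign = "deletion",
                   units_changed = -1L, motif_class = "A/T", unit_len = 1L)
  curve <- per_repeat_rate_by_length(cl, cen, n_lineages = 16,
                                     generations = 170)
  row <- curve[curve$L == 5, ]
  expect_equal(row$n_repeats, 100L)
  expect_equal(row$events, 1L)
  expect_equal(row$rate, 1 / (100 * 16 * 170), tolerance = 1e-12)
  expect_false(row$flagged)
  # zero events at a censused length give rate zero, not a dropped row
  expect_equal(nrow(curve), 1L)
  cl0 <- cl[0, ]
  curve0 <- per_repeat_rate_by_length(cl0, cen, 16, 170)
  expect_equal(curve0$events, 0L)
  expect_equal(curve0$rate, 0)
  # an event whose class/length has no census entry is a data inconsistency
  cen_cg <- as_repeat_census(transform(loci, unit = "C"))
  expect_error(per_repeat_rate_by_length(cl, cen_cg, 16, 170),
               "uncensused")
  loci14 <- transform(loci, end = start + 14L, n_units = 14L)
  curve14 <- per_repeat_rate_by_length(cl, as_repeat_census(loci14), 16, 170)
  expect_true(curve14$flagged)
})

test_that("regime fits recover exact and noisy synthetic curves", {
  exact <- data.frame(motif_class = "A/T", unit_len = 1L, L = 3:8,
                      n_repeats = 100L, events = 1L,
                      rate = 1e-9 * 4^(0:5), flagged = FALSE)
  fit <- fit_regimes(exact, "A/T")
  expect_equal(fit$exp_fit$fold_per_unit, 4, tolerance = 1e-9)
  expect_equal(fit$exp_fit$r_squared, 1, tolerance = 1e-12)

  lin <- data.frame(motif_class = "A/T", unit_len = 1L, L = 9:13,
                    n_repeats = 10L, events = 1L,
                    rate = 1e-4 * (9:13 - 9) + 1e-5, flagged = FALSE)
  fit2 <- fit_regimes(rbind(exact, lin), "A/T")
  expect_equal(fit2$lin_fit$slope, 1e-4, tolerance = 1e-12)
  expect_equal(fit2$lin_fit$r_squared, 1, tolerance = 1e-12)

  set.seed(17)
  noisy <- exact
  noisy$rate <- noisy$rate * 10^rnorm(6, 0, 0.1)
  fit3 <- fit_regimes(noisy, "A/T")
  expect_lt(abs(fit3$exp_fit$fold_per_unit - 4) / 4, 0.1)

  # zero-rate lengths are excluded and reported; sparse fits unavailable
  holes <- exact
  holes$rate[1:4] <- 0
  fit4 <- fit_regimes(holes, "A/T")
  expect_null(fit4$exp_fit)
  holes$rate[3] <- 1e-8
  fit5 <- fit_regimes(holes, "A/T")
  expect_equal(fit5$exp_fit$zero_lengths, c(3L, 4L, 6L))
})

test_that("chromosome-size regression behaves at the extremes", {
  lens <- setNames(c(1, 2, 3, 4) * 1e5, paste0("chr", 1:4))
  prop <- data.frame(chrom = rep(names(lens), times = c(10, 20, 30, 40)))
  expect_equal(chromosome_size_regression(prop, lens)$r_squared, 1,
               tolerance = 1e-12)

  lens10 <- setNames(rep(1e5, 10) + (1:10), paste0("chr", 1:10))
  conc <- data.frame(chrom = rep("chr1", 100))
  expect_lt(chromosome_size_regression(conc, lens10)$r_squared, 0.5)
  expect_error(chromosome_size_regression(prop, lens[1:2]), "3 chromosomes")
})

test_that("uniform mutations correlate with chromosome size", {
  set.seed(8)
  lens <- setNames(round(runif(16, 2e5, 1.5e6)), paste0("chr", 1:16))
  pos <- sample(rep(names(lens), times = round(lens / 1000)), 2500,
                replace = TRUE)
  r2 <- chromosome_size_regression(data.frame(chrom = pos), lens)$r_squared
  expect_gt(r2, 0.7)
})

test_that("replication-timing homogeneity test matches closed forms", {
  bins <- data.frame(chrom = "c", start = c(0, 100), end = c(100, 200),
                     bin = c("b1", "b2"))
  prop <- data.frame(chrom = "c", pos = c(rep(10L, 15), rep(150L, 15)))
  t1 <- replication_timing_test(prop, bins)
  expect_equal(t1$statistic, 0)
  expect_equal(t1$p_value, 1)

  skew <- data.frame(chrom = "c", pos = c(rep(10L, 30), rep(150L, 10)))
  t2 <- replication_timing_test(skew, bins)
  expect_equal(t2$statistic, 10)
  expect_equal(t2$p_value, 0.001565402, tolerance = 1e-6)

  outside <- data.frame(chrom = "c", pos = 500L)
  expect_error(replication_timing_test(outside, bins), "outside")
})

test_that("the homogeneity p-value is calibrated under the null", {
  bins <- data.frame(chrom = "c", start = (0:4) * 200L, end = (1:5) * 200L,
                     bin = paste0("b", 1:5))
  set.seed(99)
  pvals <- replicate(200, {
    pos <- sample.int(1000L, 150L, replace = TRUE) - 1L
    replication_timing_test(data.frame(chrom = "c", pos = pos),
                            bins)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value,
            0.01)
})

test_that("coding fractions follow the interval annotation", {
  cds <- data.frame(chrom = "c", start = c(0, 50), end = c(20, 80))
  all_in <- data.frame(chrom = "c", pos = c(5L, 60L), kind = c("SNV", "indel"))
  expect_equal(coding_fraction(all_in, cds)$fraction, 1)
  none_in <- data.frame(chrom = "c", pos = c(30L, 90L), kind = "SNV")
  expect_equal(coding_fraction(none_in, cds)$fraction, 0)

  set.seed(12)
  n <- 1e5
  cds2 <- simulate_coding_intervals(c(chr = random_dna(n)), 0.74)
  pos <- sample.int(n, 5000L) - 1L
  cf <- coding_fraction(data.frame(chrom = "chr", pos = pos, kind = "SNV"),
                        cds2)
  expect_lt(abs(cf$fraction - 0.74), 0.02)
})
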