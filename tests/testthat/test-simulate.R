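test_that("generated genomes embed their truth set exactly and reproducibly", {
  cfg <- sim_config(genome_length = 5e4, n_chrom = 2L,
                    repeat_spec = rbind(
                      data.frame(unit = "A", L = c(8L, 14L), copies = 3L),
                      data.frame(unit = "AT", L = 5L, copies = 4L),
                      data.frame(unit = "AAC", L = 4L, copies = 2L)))
  gg <- generate_genome(cfg, seed = 3)
  expect_equal(nrow(gg$truth) >= 12, TRUE)   # embedded + companions
  cen <- find_repeats(gg$genome)
  truth_keys <- paste(gg$truth$chrom, gg$truth$start, gg$truth$end,
                      gg$truth$unit_len)
  cen_keys <- paste(cen$loci$chrom, cen$loci$start, cen$loci$end,
                    cen$loci$unit_len)
  expect_true(all(truth_keys %in% cen_keys))

  gg2 <- generate_genome(cfg, seed = 3)
  expect_identical(gg$genome, gg2$genome)
  expect_identical(gg$truth, gg2$truth)
  gg3 <- generate_genome(cfg, seed = 4)
  expect_false(identical(gg$genome, gg3$genome))

  # a single embedded repeat is recovered at exact coordinates
  cfg1 <- sim_config(genome_length = 1e4, n_chrom = 1L, cluster_fraction = 0,
                     repeat_spec = data.frame(unit = "A", L = 8L,
                                              copies = 1L))
  g1 <- generate_genome(cfg1, seed = 6)
  expect_equal(nrow(g1$truth), 1L)
  expect_equal(g1$truth$end - g1$truth$start, 8L)
  cen1 <- find_repeats(g1$genome)
  hit <- cen1$loci[cen1$loci$start == g1$truth$start &
                     cen1$loci$unit_len == 1L, ]
  expect_equal(hit$end, g1$truth$end)

  # infeasible packing errors out
  expect_error(generate_genome(
    sim_config(genome_length = 500, n_chrom = 1L,
               repeat_spec = data.frame(unit = "A", L = 10L, copies = 60L)),
    seed = 1), "fit|crowded")
})

test_that("lineage simulation is deterministic and rate-faithful", {
  cfg <- small_sim_config()
  gg <- generate_genome(cfg, seed = 41)
  cen <- find_repeats(gg$genome)
  s1 <- simulate_ma_lines(gg$genome, cen$loci, cfg, seed = 42)
  s2 <- simulate_ma_lines(gg$genome, cen$loci, cfg, seed = 42)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$events, s2$events)

  # all rates zero -> no mutations at all
  cfg0 <- small_sim_config(snv_rate = 0, slippage_base_rate = 0)
  s0 <- simulate_ma_lines(gg$genome, cen$loci, cfg0, seed = 42)
  expect_equal(nrow(s0$calls), 0L)

  # substitution counts follow the Poisson expectation
  cfgs <- small_sim_config(snv_rate = 2e-6, slippage_base_rate = 0,
                           n_lineages = 8L)
  ss <- simulate_ma_lines(gg$genome, cen$loci, cfgs, seed = 43)
  lam <- 2e-6 * sum(nchar(gg$genome)) * 50 * 8
  expect_lt(abs(nrow(ss$snv_truth) - lam) / lam, 0.25)
  expect_true(all(ss$snv_truth$ref != ss$snv_truth$alt))

  # deletion bias propagates to the event stream
  cfgb <- small_sim_config(bias = c("A/T" = 0.93))
  sb <- simulate_ma_lines(gg$genome, cen$loci, cfgb, seed = 44)
  at_ids <- sb$loci$locus_id[sb$loci$motif_class == "A/T"]
  ev <- sb$events[sb$events$locus_id %in% at_ids, ]
  expect_gt(nrow(ev), 100)
  frac_del <- mean(ev$delta_units < 0)
  ci <- binom.test(sum(ev$delta_units < 0), nrow(ev))$conf.int
  expect_true(ci[1] <= 0.93 && 0.93 <= ci[2])
})

test_that("detection dropout removes the configured share of long-repeat indels", {
  cfg <- small_sim_config()
  gg <- generate_genome(cfg, seed = 51)
  cen <- find_repeats(gg$genome)
  sim <- simulate_ma_lines(gg$genome, cen$loci, cfg, seed = 52)
  is_indel <- nchar(sim$calls$ref) != nchar(sim$calls$alt)

  keep_all <- apply_detection_dropout(sim$calls, sim$loci,
                                      small_sim_config(dropout_prob = 0),
                                      seed = 53)
  expect_equal(nrow(keep_all$calls), nrow(sim$calls))
  expect_true(all(keep_all$calls$span_reads_sample[
    nchar(keep_all$calls$ref) != nchar(keep_all$calls$alt)] >= 3))

  drop_all <- apply_detection_dropout(sim$calls, sim$loci,
                                      small_sim_config(dropout_prob = 1),
                                      seed = 53)
  long_ids <- sim$loci$locus_id[sim$loci$end - sim$loci$start >= 14]
  kept_ind <- drop_all$calls[nchar(drop_all$calls$ref) !=
                               nchar(drop_all$calls$alt), ]
  expect_false(any(kept_ind$locus_id %in% long_ids))
  expect_gt(nrow(drop_all$dropped), 0)

  # dropout at 0.5 behaves binomially over many replicated draws
  n_long <- sum(is_indel & sim$calls$locus_id %in% long_ids)
  n_dropped <- sum(vapply(1:10, function(s) {
    nrow(apply_detection_dropout(sim$calls, sim$loci,
                                 small_sim_config(dropout_prob = 0.5),
                                 seed = 54 + s)$dropped)
  }, numeric(1)))
  ci <- binom.test(n_dropped, 10 * n_long)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})

test_that("fluctuation cultures respect the growth-mutation model", {
  expect_equal(simulate_fluctuation(10, 1000, 0, 50, seed = 1),
               rep(0L, 50))
  expect_equal(simulate_fluctuation(10, 1000, 1, 20, seed = 1),
               rep(1000L, 20))
  # null-class law: P(0 mutants) = exp(-m)
  ni <- 100; nf <- 102400
  cnt <- simulate_fluctuation(ni, nf, 1 / (nf - ni), 5e4, seed = 2)
  expect_equal(mean(cnt == 0), exp(-1), tolerance = 0.01)
  expect_error(simulate_fluctuation(10, 5e8, 1e-7, 10, seed = 1), "scale")
  expect_error(simulate_fluctuation(10, 5, 1e-7, 10, seed = 1), "n_initial")
})

test_that("proximity-boosted loci are over-represented among mutated repeats", {
  cfg <- small_sim_config(proximity_boost = 8, cluster_fraction = 0.5)
  gg <- generate_genome(cfg, seed = 61)
  cen <- find_repeats(gg$genome)
  sim <- simulate_ma_lines(gg$genome, cen$loci, cfg, seed = 62)
  nn <- nearest_neighbor_distances(sim$loci)
  nn <- nn[order(nn$locus_id), ]
  mutated <- unique(sim$net$locus_id)
  expect_gt(cumulative_within(nn$distance[mutated], 3),
            cumulative_within(nn$distance, 3))
})
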