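test_that("substitutions classify into the six strand-collapsed classes", {
  cases <- data.frame(
    ref = c("G", "C", "A", "T", "G", "C", "G", "C", "A", "T", "A", "T"),
    alt = c("A", "T", "G", "C", "T", "A", "C", "G", "T", "A", "C", "G"),
    ts  = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 8)),
    cls = c("G:C>A:T", "G:C>A:T", "A:T>G:C", "A:T>G:C",
            "G:C>T:A", "G:C>T:A", "G:C>C:G", "G:C>C:G",
            "A:T>T:A", "A:T>T:A", "A:T>C:G", "A:T>C:G"))
  got <- classify_snv(cases$ref, cases$alt)
  expect_equal(got$ts_tv, ifelse(cases$ts, "transition", "transversion"))
  expect_equal(got$snv_class, cases$cls)
  expect_error(classify_snv("GA", "G"), "indel")
  expect_error(classify_snv("A", "A"), "differ")
  # class counts always cover every substitution
  set.seed(3)
  r <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  a <- vapply(r, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  cl <- classify_snv(r, a)
  expect_true(all(cl$snv_class %in% mapipe:::SNV_CLASSES))
})

test_that("indels are assigned to matching repeat loci", {
  gen <- c(chr = "GGTCAAAAAAAAGTCGGTAC")      # A8 at [4,12)
  cen <- find_repeats(gen)
  del <- data.frame(lineage_id = "L1", chrom = "chr", pos = 6L,
                    ref = "AA", alt = "A")
  got <- assign_indel(del, cen, gen)
  expect_equal(got$indel_sign, "deletion")
  expect_equal(got$units_changed, -1L)
  expect_equal(cen$loci$unit[got$repeat_id], "A")

  gen2 <- c(chr = "GGCATATATATATGCCGGTT")     # (AT)5 at [3,13)
  cen2 <- find_repeats(gen2)
  ins <- data.frame(lineage_id = "L1", chrom = "chr", pos = 11L,
                    ref = "A", alt = "ATA")   # one extra unit near right edge
  got2 <- assign_indel(ins, cen2, gen2)
  expect_equal(got2$units_changed, 1L)
  expect_equal(cen2$loci$unit_len[got2$repeat_id], 2L)
  # brute-force check: applying the call gives the locus with one more unit
  mut <- paste0(substr(gen2, 1, 11), "ATA", substr(gen2, 13, nchar(gen2)))
  expect_equal(find_repeats(c(chr = mut))$loci$n_units, 6L)

  # insertion in non-repeat context stays unassigned
  bare <- data.frame(lineage_id = "L1", chrom = "chr", pos = 16L,
                     ref = "G", alt = "GG")
  expect_true(is.na(assign_indel(bare, cen2, gen2)$repeat_id))
})

test_that("assignment is invariant to the reported indel position", {
  gen <- c(chr = "GGCATATATATATGCCGGTT")
  cen <- find_repeats(gen)
  # one-unit insertion reported at several equivalent positions in the run
  for (pos in c(2L, 4L, 6L, 8L)) {
    anchor <- substr(gen, pos + 1L, pos + 1L)
    nxt <- substr(gen, pos + 2L, pos + 3L)
    call <- data.frame(lineage_id = "L1", chrom = "chr", pos = pos,
                       ref = anchor, alt = paste0(anchor, nxt))
    got <- assign_indel(call, cen, gen)
    expect_equal(got$aligned_pos, 3L)
    expect_equal(got$units_changed, 1L)
    expect_equal(cen$loci$start[got$repeat_id], 3L)
  }
})

test_that("spanning-read filtering keeps SNVs and well-covered indels", {
  calls <- data.frame(
    lineage_id = "L1", chrom = "c", pos = c(1L, 5L, 9L),
    ref = c("AA", "AA", "G"), alt = c("A", "A", "T"),
    span_reads_sample = c(5L, 2L, NA),
    span_reads_ancestor = c(4L, 7L, NA))
  kept <- filter_span_coverage(calls, min_span = 3L)
  expect_equal(nrow(kept), 2L)
  expect_equal(attr(kept, "n_removed"), 1L)
  expect_true("G" %in% kept$ref)            # the SNV passes without spans
  calls$span_reads_sample[1] <- NA
  expect_error(filter_span_coverage(calls, 3L), "span-read")
})

test_that("mutations shared by many lineages are removed everywhere", {
  shared <- data.frame(lineage_id = paste0("L", 1:10), chrom = "c",
                       pos = 100L, ref = "A", alt = "G")
  private <- data.frame(lineage_id = c("L1", "L2", "L3"), chrom = "c",
                        pos = c(7L, 7L, 55L), ref = "C", alt = "T")
  out <- remove_shared_mutations(rbind(shared, private), min_lineages = 3L)
  expect_equal(attr(out, "n_removed"), 10L)
  expect_equal(nrow(out), 3L)               # pos 7 in 2 lineages is kept
  expect_true(all(out$pos %in% c(7L, 55L)))
  out2 <- remove_shared_mutations(rbind(shared, private), min_lineages = 11L)
  expect_equal(attr(out2, "n_removed"), 0L)
})

test_that("boundary-shift substitutions are detected at repeat junctions", {
  g <- c(chr = "GCGTATAAAATTTTGAATGC")       # A4 [6,10) | T4 [10,14)
  expect_true(detect_boundary_shift("chr", 10, "T", "A", g))
  expect_true(detect_boundary_shift("chr", 9, "A", "T", g))
  # junction SNV with no valid one-unit re-decomposition
  g2 <- c(chr = "GCGTAAAACTTTGAATGCAA")      # A4 [4,8) C T3 [9,12)
  expect_false(detect_boundary_shift("chr", 8, "C", "G", g2))
  # substitutions away from any junction
  expect_false(detect_boundary_shift("chr", 1, "C", "A", g))
  expect_false(detect_boundary_shift("chr", 16, "A", "C", g))
  expect_error(detect_boundary_shift("chr", 10, "G", "A", g), "match")
})

test_that("every simulated slippage event is recovered at its locus", {
  cfg <- small_sim_config(dropout_prob = 0)
  gg <- generate_genome(cfg, seed = 31)
  cen <- find_repeats(gg$genome)
  sim <- simulate_ma_lines(gg$genome, cen$loci, cfg, seed = 32)
  cl <- classify_mutations(sim$calls, cen, gg$genome, boundary_shift = FALSE)
  ind <- cl[cl$kind == "indel", ]
  expect_gt(nrow(ind), 20)
  expect_true(all(!is.na(ind$repeat_id)))
  # recovered (lineage, locus, net units) match the simulator's bookkeeping
  truth_key <- paste(sim$net$lineage_id, sim$net$locus_id)
  got_key <- paste(ind$lineage_id, sim$loci$locus_id[ind$repeat_id])
  m <- match(got_key, truth_key)
  expect_true(all(!is.na(m)))
  expect_equal(ind$units_changed, sim$net$net_units[m])
  # class conservation: snv classes sum to SNVs, signs sum to indels
  expect_equal(sum(!is.na(cl$snv_class)), sum(cl$kind == "SNV"))
  expect_equal(sum(ind$indel_sign %in% c("insertion", "deletion")), nrow(ind))
})
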