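# Independent oracles used across the suite. These deliberately avoid the
# package's own scanning machinery: repeats are found by per-start
# character-level extension, distances and KS statistics by all-pairs /
# pooled-support brute force.

# Brute-force maximal perfect tandem repeat finder: tests every
# (start, unit_len) pair, extends character by character, keeps the
# leftmost phase of each maximal stretch and primitive units only.
oracle_find_repeats <- function(seq, min_hpr = 3L, min_units = 3L,
                                max_unit_len = 4L) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  rows <- list()
  for (u in seq_len(max_unit_len)) {
    for (p in seq_len(n)) {
      if (p + 2L * u - 1L > n) break
      if (any(ch[p:(p + u - 1L)] == "N")) next
      if (!all(ch[p:(p + u - 1L)] == ch[(p + u):(p + 2L * u - 1L)])) next
      # leftmost phase: the stretch must not extend one base left
      if (p > 1L && ch[p - 1L] != "N" && ch[p - 1L] == ch[p + u - 1L]) next
      i <- p + u
      while (i <= n && ch[i] != "N" && ch[i] == ch[i - u]) i <- i + 1L
      stretch <- i - p
      n_units <- stretch %/% u
      if (u == 1L) { if (stretch < min_hpr) next } else {
        if (n_units < min_units) next
      }
      unit <- paste(ch[p:(p + u - 1L)], collapse = "")
      if (u > 1L) {
        prim <- TRUE
        for (d in seq_len(u - 1L)) {
          if (u %% d == 0L &&
              strrep(substr(unit, 1L, d), u / d) == unit) prim <- FALSE
        }
        if (!prim) next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(start = p - 1L, end = p - 1L + n_units * u,
                   unit_len = u, n_units = n_units, unit = unit,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      unit_len = integer(), n_units = integer(),
                      unit = character(), stringsAsFactors = FALSE)
  }
  out[order(out$start, out$unit_len), , drop = FALSE]
}

oracle_nn_distances <- function(loci) {
  n <- nrow(loci)
  vapply(seq_len(n), function(i) {
    same <- setdiff(which(loci$chrom == loci$chrom[i]), i)
    if (!length(same)) return(NA_integer_)
    min(vapply(same, function(j) {
      max(0L, max(loci$start[j] - loci$end[i], loci$start[i] - loci$end[j]))
    }, integer(1)))
  }, integer(1))
}

oracle_ks_D <- function(x, y) {
  support <- sort(unique(c(x, y)))
  max(vapply(support, function(t) abs(mean(x <= t) - mean(y <= t)),
             numeric(1)))
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

loci_key <- function(df) paste(df$start, df$end, df$unit_len)

# small simulation config used by several test files
small_sim_config <- function(...) {
  defaults <- list(
    genome_length = 3e4, n_chrom = 2L,
    repeat_spec = rbind(
      data.frame(unit = "A", L = 5:8, copies = 6L),
      data.frame(unit = "AT", L = c(4L, 6L), copies = 4L),
      data.frame(unit = "A", L = 14L, copies = 4L)),
    slippage_base_rate = 2e-5,
    n_lineages = 4L, generations = 50L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
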