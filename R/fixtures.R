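#' Packaged genome-wide mutation count tables
#'
#' The package ships the published genome-wide count tables for the 16
#' MMR-null-like mutation-accumulation lineages plus the wild-type control:
#' per-lineage substitution and indel counts, the six-category spectrum
#' counts, and the per-motif-class insertion/deletion counts. These small
#' plain-text fixtures let the reporting and statistics layers be exercised
#' against published totals without the (unavailable) per-read data.
#'
#' @param which One of `"lineages"`, `"spectrum"`, `"bias"`.
#' @return Data frame.
#' @export
ma_fixture <- function(which = c("lineages", "spectrum", "bias")) {
  which <- match.arg(which)
  f <- c(lineages = "lineage_counts.tsv",
         spectrum = "spectrum_counts.tsv",
         bias = "indel_bias_counts.tsv")[[which]]
  path <- system.file("extdata", f, package = "mapipe", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Recompute the published summary statistics from the packaged counts
#'
#' From the packaged count fixtures this derives, by plain arithmetic on
#' integer counts: the six-category spectrum percentages with the
#' homopolymer- and microsatellite-indel subtotals; the per-class
#' insertion/deletion bias fractions and chi-square p-values; the
#' per-lineage overall mutation rates and fold inductions over the
#' wild-type reference; and the pooled substitution rate across the 16
#' null-like lineages.
#'
#' @param callable_bp Callable genome size (default 1.216e7 bp, the value
#'   implied by the published per-lineage rates).
#' @param generations Generations per lineage (default 170).
#' @param reference_rate Wild-type reference rate for fold induction
#'   (default 3.3e-10 per bp per generation).
#' @return A `fixtures_report` list with components `spectrum`, `bias`,
#'   `lineages` (counts + rate + fold per lineage), `snv_total`,
#'   `pooled_snv_rate`, `null_rate` (the msh2-null lineage), and the
#'   parameters used.
#' @export
fixtures_report <- function(callable_bp = 1.216e7, generations = 170,
                            reference_rate = 3.3e-10) {
  spec_counts <- ma_fixture("spectrum")
  spec <- spectrum_table(setNames(spec_counts$count, spec_counts$category))

  bias_counts <- ma_fixture("bias")
  bias <- indel_bias_table(bias_counts)

  lin <- ma_fixture("lineages")
  lin$events <- lin$snv + lin$indel
  rates <- lapply(lin$events, per_bp_rate, n_lineages = 1,
                  generations = generations, callable_bp = callable_bp)
  lin$rate <- vapply(rates, `[[`, numeric(1), "rate")
  lin$fold <- vapply(lin$rate, function(r) {
    fold_induction(r, reference_rate)$fold
  }, numeric(1))

  nulls <- lin[lin$strain_class == "null_like", , drop = FALSE]
  snv_total <- sum(nulls$snv)
  pooled_snv <- per_bp_rate(snv_total, n_lineages = nrow(nulls),
                            generations = generations,
                            callable_bp = callable_bp)
  null_rate <- per_bp_rate(lin$events[lin$genotype == "msh2-null"],
                           n_lineages = 1, generations = generations,
                           callable_bp = callable_bp)
  structure(list(spectrum = spec, bias = bias, lineages = lin,
                 snv_total = snv_total,
                 n_null_lineages = nrow(nulls),
                 pooled_snv_rate = pooled_snv,
                 null_rate = null_rate,
                 callable_bp = callable_bp, generations = generations,
                 reference_rate = reference_rate),
            class = "fixtures_report")
}

#' @export
print.fixtures_report <- function(x, ...) {
  cat("Recomputed genome-wide summary (packaged count tables)\n\n")
  print(x$spectrum)
  cat("\nInsertion/deletion bias by motif class:\n")
  b <- x$bias
  b$majority_fraction <- sprintf("%.2f", b$majority_fraction)
  b$p_value <- signif(b$p_value, 2)
  print(b, row.names = FALSE)
  cat(sprintf("\n%d substitutions across %d null-like lineages\n",
              x$snv_total, x$n_null_lineages))
  cat(sprintf("pooled substitution rate: %.2g per bp per generation\n",
              x$pooled_snv_rate$rate))
  cat(sprintf("msh2-null overall rate:   %.2g per bp per generation (%.0f-fold over wild type)\n",
              x$null_rate$rate,
              fold_induction(x$null_rate, x$reference_rate)$fold))
  invisible(x)
}
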