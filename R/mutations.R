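#' Classify a single-base substitution
#'
#' Assigns each ref/alt base pair to transition vs transversion and to one of
#' the six strand-collapsed substitution classes (`G:C>A:T`, `A:T>G:C`,
#' `G:C>T:A`, `G:C>C:G`, `A:T>T:A`, `A:T>C:G`): a change and its reverse
#' complement (e.g. G>A and C>T) are the same class.
#'
#' @param ref,alt Single bases (vectorised), `ref != alt`.
#' @return Data frame with columns `ts_tv` and `snv_class`.
#' @examples
#' classify_snv(c("G", "C", "T"), c("A", "A", "A"))
#' @export
classify_snv <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(nchar(ref) != 1L | nchar(alt) != 1L)) {
    stop("classify_snv takes single bases; use assign_indel for ",
         "length-changing calls", call. = FALSE)
  }
  if (any(!(ref %in% DNA_BASES) | !(alt %in% DNA_BASES))) {
    stop("ref/alt must be A, C, G or T", call. = FALSE)
  }
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  purine <- c("A", "G")
  ts <- (ref %in% purine) == (alt %in% purine)
  # collapse onto the strand where ref is G or A
  flip <- ref %in% c("C", "T")
  r <- ifelse(flip, DNA_COMPLEMENT[ref], ref)
  a <- ifelse(flip, DNA_COMPLEMENT[alt], alt)
  lab <- ifelse(r == "G", paste0("G:C>", a, ":", DNA_COMPLEMENT[a]),
                          paste0("A:T>", a, ":", DNA_COMPLEMENT[a]))
  data.frame(ts_tv = ifelse(ts, "transition", "transversion"),
             snv_class = unname(lab), stringsAsFactors = FALSE)
}

# Left-align an indel against the reference. `start` is the 0-based start of
# the inserted/deleted segment, `seq` its sequence. Shifting is the standard
# VCF normalisation: while the base before the segment equals its last base,
# rotate the segment right and move left.
left_align_indel <- function(chrom_seq, start, seq) {
  n <- nchar(seq)
  while (start > 0L &&
         substr(chrom_seq, start, start) == substr(seq, n, n)) {
    seq <- paste0(substr(seq, n, n), substr(seq, 1L, n - 1L))
    start <- start - 1L
  }
  list(start = start, seq = seq)
}

# Decompose a VCF-style (pos0, ref, alt) record into an indel segment.
# Returns NULL for SNVs/MNVs; errors on complex substitutions.
indel_segment <- function(pos0, ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == la) return(NULL)
  common <- 0L
  while (common < min(lr, la) &&
         substr(ref, common + 1L, common + 1L) ==
         substr(alt, common + 1L, common + 1L)) common <- common + 1L
  if (common < min(lr, la)) {
    stop("complex substitution (not a pure indel): ", ref, ">", alt,
         call. = FALSE)
  }
  if (lr > la) {
    list(sign = -1L, start = pos0 + la, seq = substr(ref, la + 1L, lr))
  } else {
    list(sign = +1L, start = pos0 + lr, seq = substr(alt, lr + 1L, la))
  }
}

#' Assign insertion/deletion calls to repeat loci
#'
#' Left-aligns each indel against the genome, then assigns it to the repeat
#' locus whose interval the (normalised) breakpoint touches (gap 0) and whose
#' unit matches the inserted/deleted sequence as a whole number of unit
#' copies, up to rotation. When several loci qualify the longest wins, ties
#' broken leftmost. Indels matching no locus are left unassigned.
#'
#' @param calls Data frame of mutation calls with columns `chrom`, `pos`
#'   (0-based), `ref`, `alt` (VCF anchored representation for indels), and
#'   optionally `lineage_id`.
#' @param census A `repeat_census` for the same genome.
#' @param genome Named character vector or `DNAStringSet` (needed for
#'   left-alignment).
#' @return `calls` with added columns `repeat_id` (row index into
#'   `census$loci`, `NA` when unassigned), `indel_sign` (`"insertion"` /
#'   `"deletion"`), `units_changed` (signed integer), `aligned_pos`
#'   (0-based start of the left-aligned segment).
#' @export
assign_indel <- function(calls, census, genome) {
  genome <- as_genome_chr(genome)
  loci <- census$loci
  calls$repeat_id <- NA_integer_
  calls$indel_sign <- NA_character_
  calls$units_changed <- NA_integer_
  calls$aligned_pos <- NA_integer_
  if (!nrow(calls)) return(calls)
  # per-chromosome index over loci sorted by start, for fast point lookups
  chrom_idx <- split(seq_len(nrow(loci)), loci$chrom)
  chrom_idx <- lapply(chrom_idx, function(ix) ix[order(loci$start[ix])])
  max_w <- if (nrow(loci)) max(loci$end - loci$start) else 0L
  for (i in seq_len(nrow(calls))) {
    seg <- indel_segment(calls$pos[i], calls$ref[i], calls$alt[i])
    if (is.null(seg)) next
    chrom <- calls$chrom[i]
    al <- left_align_indel(genome[[chrom]], seg$start, seg$seq)
    calls$indel_sign[i] <- if (seg$sign > 0L) "insertion" else "deletion"
    calls$aligned_pos[i] <- al$start
    ix <- chrom_idx[[chrom]]
    if (is.null(ix)) next
    st <- loci$start[ix]
    lo <- findInterval(al$start - max_w - 1L, st) + 1L
    hi <- findInterval(al$start, st)
    cand <- if (hi >= lo) ix[lo:hi] else integer(0)
    cand <- cand[loci$start[cand] <= al$start & loci$end[cand] >= al$start]
    if (!length(cand)) next
    n <- nchar(al$seq)
    ok <- vapply(cand, function(j) {
      u <- loci$unit_len[j]
      if (n %% u != 0L) return(FALSE)
      seq_matches_unit(al$seq, loci$unit[j])
    }, logical(1))
    cand <- cand[ok]
    if (!length(cand)) next
    best <- cand[order(-(loci$end[cand] - loci$start[cand]),
                       loci$start[cand])][1L]
    calls$repeat_id[i] <- best
    calls$units_changed[i] <- seg$sign * (n %/% loci$unit_len[best])
  }
  calls
}

# Is `seq` a whole number of copies of some rotation of `unit`?
seq_matches_unit <- function(seq, unit) {
  u <- nchar(unit)
  n <- nchar(seq)
  if (n %% u != 0L) return(FALSE)
  first <- substr(seq, 1L, u)
  if (!grepl(first, strrep(unit, 2L), fixed = TRUE)) return(FALSE)
  seq == strrep(first, n %/% u)
}

#' Filter indel calls on spanning-read coverage
#'
#' Keeps indel calls only when at least `min_span` reads traversed the full
#' repeat region in both the evolved sample and its ancestor; substitutions
#' pass unchanged. This models the callability rule used when scoring
#' slippage indels from short-read data.
#'
#' @param calls Classified calls with `span_reads_sample` and
#'   `span_reads_ancestor` columns populated for indel rows.
#' @param min_span Minimum spanning reads on each side (default 3).
#' @return Filtered calls; the number removed is attached as
#'   `attr(, "n_removed")`.
#' @export
filter_span_coverage <- function(calls, min_span = 3L) {
  is_indel <- nchar(calls$ref) != nchar(calls$alt)
  if (!all(c("span_reads_sample", "span_reads_ancestor") %in% names(calls)) ||
      any(is_indel & (is.na(calls$span_reads_sample) |
                      is.na(calls$span_reads_ancestor)))) {
    stop("span-read counts must be populated for all indel calls when ",
         "spanning-coverage filtering is requested", call. = FALSE)
  }
  drop <- is_indel & (calls$span_reads_sample < min_span |
                      calls$span_reads_ancestor < min_span)
  out <- calls[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Remove mutations shared across many lineages
#'
#' An identical variant (same chrom, pos, ref, alt) observed in at least
#' `min_lineages` independent lineages almost certainly arose in the shared
#' ancestor before the lines were founded, not during passaging, and is
#' removed from every lineage.
#'
#' @param calls Data frame with `lineage_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param min_lineages Sharing threshold (default 3).
#' @return Filtered calls with `attr(, "n_removed")` and
#'   `attr(, "shared_variants")` describing what was dropped.
#' @export
remove_shared_mutations <- function(calls, min_lineages = 3L) {
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
  n_lin <- tapply(calls$lineage_id, key, function(x) length(unique(x)))
  shared <- names(n_lin)[n_lin >= min_lineages]
  drop <- key %in% shared
  out <- calls[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  attr(out, "shared_variants") <- unique(calls[drop, c("chrom", "pos", "ref",
                                                       "alt"), drop = FALSE])
  out
}

#' Detect boundary-shift (double slippage) substitutions
#'
#' A substitution at the junction of two immediately adjacent repeats
#' (gap of at most 1 bp) can be explained as two simultaneous slippage
#' events -- one repeat gaining a unit while its neighbour loses one --
#' rather than a polymerase misincorporation. The test re-decomposes the
#' mutated local sequence into maximal repeats (with relaxed minimum sizes,
#' two units / 2 bp) and reports `TRUE` iff some adjacent repeat pair shows
#' exactly the +1/-1 unit exchange with outer boundaries preserved.
#'
#' @param chrom,pos,ref,alt A single substitution call (`pos` 0-based).
#' @param genome Named character vector or `DNAStringSet`.
#' @param window Context half-width in bp (default 20).
#' @return Logical.
#' @examples
#' g <- c(chr = "GCGCATAAAATTTTGCATGC")
#' detect_boundary_shift("chr", 10, "T", "A", g)   # A4|T4 -> A5|T3
#' @export
detect_boundary_shift <- function(chrom, pos, ref, alt, genome, window = 20L) {
  genome <- as_genome_chr(genome)
  s <- genome[[chrom]]
  if (substr(s, pos + 1L, pos + 1L) != toupper(ref)) {
    stop("ref base does not match the genome at ", chrom, ":", pos,
         call. = FALSE)
  }
  lo <- max(1L, pos + 1L - window)
  hi <- min(nchar(s), pos + 1L + window)
  ref_win <- substr(s, lo, hi)
  p <- pos + 1L - lo + 1L                      # SNV position within window
  mut_win <- ref_win
  substr(mut_win, p, p) <- toupper(alt)
  ref_reps <- window_repeats(ref_win)
  mut_reps <- window_repeats(mut_win)
  if (!nrow(ref_reps)) return(FALSE)
  ord <- order(ref_reps$start)
  ref_reps <- ref_reps[ord, , drop = FALSE]
  p0 <- p - 1L                                 # 0-based within window
  for (i in seq_len(nrow(ref_reps))) {
    for (j in seq_len(nrow(ref_reps))) {
      if (i == j) next
      r1 <- ref_reps[i, ]; r2 <- ref_reps[j, ]
      if (r2$start < r1$end || r2$start - r1$end > 1L) next  # adjacency
      if (p0 < r1$end - 1L || p0 > r2$start) next            # at junction
      if (shift_pair_found(mut_reps, r1, r2, +1L, -1L) ||
          shift_pair_found(mut_reps, r1, r2, -1L, +1L)) return(TRUE)
    }
  }
  FALSE
}

# Repeats in a short window with relaxed thresholds (>=2 bp / >=2 units).
window_repeats <- function(win) {
  find_repeats(c(w = win), min_hpr = 2L, min_units = 2L)$loci
}

shift_pair_found <- function(mut_reps, r1, r2, d1, d2) {
  if (!nrow(mut_reps)) return(FALSE)
  m1 <- mut_reps$motif_class == r1$motif_class &
        mut_reps$unit_len == r1$unit_len &
        mut_reps$n_units == r1$n_units + d1 &
        mut_reps$start == r1$start
  m2 <- mut_reps$motif_class == r2$motif_class &
        mut_reps$unit_len == r2$unit_len &
        mut_reps$n_units == r2$n_units + d2 &
        mut_reps$end == r2$end
  any(m1) && any(m2)
}

#' Classify a full set of mutation calls
#'
#' Convenience wrapper running substitution classification, indel locus
#' assignment and (optionally) boundary-shift detection over a call table.
#'
#' @inheritParams assign_indel
#' @param boundary_shift Also flag substitutions at repeat junctions that
#'   re-decompose as double slippage (default `TRUE`).
#' @return The call table with `kind` (`"SNV"`/`"indel"`), `ts_tv`,
#'   `snv_class`, `repeat_id`, `indel_sign`, `units_changed`,
#'   `boundary_shift` columns, plus `motif_class`/`unit_len` of the assigned
#'   locus.
#' @export
classify_mutations <- function(calls, census, genome, boundary_shift = TRUE) {
  genome <- as_genome_chr(genome)
  calls$kind <- ifelse(nchar(calls$ref) == nchar(calls$alt), "SNV", "indel")
  if (any(calls$kind == "SNV" & nchar(calls$ref) != 1L)) {
    stop("multi-base substitutions are not supported", call. = FALSE)
  }
  calls$ts_tv <- NA_character_
  calls$snv_class <- NA_character_
  snv <- calls$kind == "SNV"
  if (any(snv)) {
    cl <- classify_snv(calls$ref[snv], calls$alt[snv])
    calls$ts_tv[snv] <- cl$ts_tv
    calls$snv_class[snv] <- cl$snv_class
  }
  calls <- assign_indel(calls, census, genome)
  calls$motif_class <- NA_character_
  calls$unit_len <- NA_integer_
  assigned <- !is.na(calls$repeat_id)
  calls$motif_class[assigned] <- census$loci$motif_class[calls$repeat_id[assigned]]
  calls$unit_len[assigned] <- census$loci$unit_len[calls$repeat_id[assigned]]
  calls$boundary_shift <- FALSE
  if (boundary_shift && any(snv)) {
    for (i in which(snv)) {
      calls$boundary_shift[i] <- detect_boundary_shift(
        calls$chrom[i], calls$pos[i], calls$ref[i], calls$alt[i], genome)
    }
  }
  calls
}
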