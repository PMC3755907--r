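#' Census all perfect tandem repeats in a genome
#'
#' Scans every sequence for maximal perfect homopolymeric runs and
#' di-/tri-/tetranucleotide microsatellites. A locus is reported when it meets
#' the minimum-size threshold for its unit length and its unit is primitive
#' (a region that is perfect under several unit lengths is reported once,
#' under the smallest unit: `"ATATAT"` is an AT microsatellite, never a
#' trinucleotide repeat; `"AAAA"` is a homopolymer, never an AA dinucleotide).
#' Partially overlapping repeats of genuinely different units are all
#' reported. Runs of `N` split a sequence into independently scanned
#' segments; any other non-ACGTN character is an error.
#'
#' Coordinates are 0-based, half-open. For every locus `end - start` equals
#' `unit_len * n_units`; a trailing partial unit is not included in the locus
#' but does prevent one-unit extension, so reported loci are always maximal.
#' When a repeat stretch admits several phases the leftmost full-unit
#' placement is reported.
#'
#' @param genome A named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param min_hpr Minimum homopolymer run length in bp (default 3).
#' @param min_units Minimum number of full units for unit lengths 2-4
#'   (default 3; recycled to length 3, or give one value per unit length).
#' @param max_unit_len Largest unit length censused (2-4, default 4).
#' @return An object of class `repeat_census`: a list with
#'   \describe{
#'     \item{loci}{data frame with columns `chrom`, `start`, `end`, `unit`,
#'       `unit_len`, `n_units`, `length_bp`, `motif_class`, ordered by
#'       (chrom, start, unit_len).}
#'     \item{by_class_and_length}{data frame of locus counts per
#'       (`motif_class`, `L`), where `L` is run length in bp for
#'       homopolymers and the unit count for larger microsatellites.}
#'   }
#' @examples
#' find_repeats(c(chr1 = "GGGTTTTTACACACAC"))
#' @export
find_repeats <- function(genome, min_hpr = 3L, min_units = 3L,
                         max_unit_len = 4L) {
  genome <- as_genome_chr(genome)
  if (!(max_unit_len %in% 2:4)) stop("max_unit_len must be 2, 3 or 4")
  min_units <- rep_len(as.integer(min_units), 3L)
  thresholds <- c(as.integer(min_hpr), min_units)  # indexed by unit_len

  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    out[[i]] <- scan_sequence(names(genome)[i], genome[[i]],
                              thresholds, max_unit_len)
  }
  loci <- do.call(rbind, out)
  if (is.null(loci) || nrow(loci) == 0L) {
    loci <- empty_loci_df()
  }
  loci <- loci[order(loci$chrom, loci$start, loci$unit_len), , drop = FALSE]
  rownames(loci) <- NULL
  new_repeat_census(loci, min_hpr = thresholds[1L], min_units = min_units)
}

empty_loci_df <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             unit = character(), unit_len = integer(), n_units = integer(),
             length_bp = integer(), motif_class = character(),
             stringsAsFactors = FALSE)
}

as_genome_chr <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome)) {
    stop("genome must be a named character vector or DNAStringSet")
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("every genome sequence must be named")
  }
  toupper(genome)
}

# Scan one sequence: split on N runs, scan each segment at each unit length.
scan_sequence <- function(chrom, seq, thresholds, max_unit_len) {
  ch <- strsplit(seq, "")[[1]]
  bad <- which(!(ch %in% c(DNA_BASES, "N")))
  if (length(bad)) {
    stop("non-IUPAC character '", ch[bad[1L]], "' in sequence '", chrom,
         "' at position ", bad[1L], " (1-based)", call. = FALSE)
  }
  if (!length(ch)) return(NULL)
  is_n <- ch == "N"
  seg <- rle(is_n)
  seg_end <- cumsum(seg$lengths)
  seg_start <- seg_end - seg$lengths + 1L
  res <- list()
  for (k in which(!seg$values)) {
    a <- seg_start[k]; b <- seg_end[k]
    for (u in seq_len(max_unit_len)) {
      res[[length(res) + 1L]] <-
        scan_segment(chrom, seq, ch, a, b, u, thresholds[u])
    }
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

# Maximal perfect tandem repeats of unit length u inside ch[a..b] (1-based),
# vectorised over the match-run structure. For u == 1 the threshold is run
# length in bp, otherwise full-unit count.
scan_segment <- function(chrom, seq, ch, a, b, u, threshold) {
  n <- b - a + 1L
  if (n < max(u + 1L, if (u == 1L) threshold else u * threshold)) return(NULL)
  eq <- ch[(a + u):b] == ch[a:(b - u)]
  r <- rle(eq)
  if (!any(r$values)) return(NULL)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  idx <- which(r$values)
  stretch_len <- r$lengths[idx] + u              # bp, incl. partial unit
  n_units <- stretch_len %/% u
  keep <- if (u == 1L) stretch_len >= threshold else n_units >= threshold
  if (!any(keep)) return(NULL)
  idx <- idx[keep]; n_units <- n_units[keep]
  s1 <- a + run_start[idx] - 1L                  # stretch start, 1-based
  unit <- substring(seq, s1, s1 + u - 1L)
  if (u > 1L) {                                  # primitive units only:
    c1 <- substring(unit, 1L, 1L); c2 <- substring(unit, 2L, 2L)
    prim <- switch(u - 1L,
      c1 != c2,
      !(c1 == c2 & c2 == substring(unit, 3L, 3L)),
      {
        c3 <- substring(unit, 3L, 3L); c4 <- substring(unit, 4L, 4L)
        !(c1 == c3 & c2 == c4)
      })
    if (!any(prim)) return(NULL)
    s1 <- s1[prim]; unit <- unit[prim]; n_units <- n_units[prim]
  }
  data.frame(chrom = chrom, start = s1 - 1L, end = s1 - 1L + n_units * u,
             unit = unit, unit_len = u, n_units = n_units,
             length_bp = n_units * u, stringsAsFactors = FALSE)
}

new_repeat_census <- function(loci, min_hpr = NA_integer_,
                              min_units = NA_integer_) {
  if (nrow(loci) && is.null(loci$motif_class)) {
    uu <- unique(loci$unit)
    loci$motif_class <- canonical_motif(uu)[match(loci$unit, uu)]
  }
  structure(
    list(loci = loci,
         by_class_and_length = census_histogram(loci),
         min_hpr = min_hpr, min_units = min_units),
    class = "repeat_census")
}

#' Rebuild a repeat census object from a locus table
#'
#' Used to treat an externally supplied locus table (e.g. the simulator's
#' truth BED) as the census frame for rate denominators.
#'
#' @param loci Data frame with at least `chrom`, `start`, `end`, `unit`,
#'   `unit_len`, `n_units` (and optionally `motif_class`).
#' @return A `repeat_census` object.
#' @export
as_repeat_census <- function(loci) {
  stopifnot(all(c("chrom", "start", "end", "unit", "unit_len", "n_units")
                %in% names(loci)))
  loci$length_bp <- loci$end - loci$start
  loci <- loci[order(loci$chrom, loci$start, loci$unit_len), , drop = FALSE]
  rownames(loci) <- NULL
  new_repeat_census(loci)
}

# Histogram of loci per (motif_class, L); L = bp for homopolymers,
# unit count for unit_len >= 2.
census_histogram <- function(loci) {
  if (!nrow(loci)) {
    return(data.frame(motif_class = character(), unit_len = integer(),
                      L = integer(), n = integer(), stringsAsFactors = FALSE))
  }
  L <- ifelse(loci$unit_len == 1L, loci$length_bp, loci$n_units)
  agg <- aggregate(list(n = rep(1L, nrow(loci))),
                   by = list(motif_class = loci$motif_class,
                             unit_len = loci$unit_len, L = L), FUN = sum)
  agg <- agg[order(agg$motif_class, agg$unit_len, agg$L), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' @export
print.repeat_census <- function(x, ...) {
  cat("Perfect tandem repeat census:", nrow(x$loci), "loci on",
      length(unique(x$loci$chrom)), "sequence(s)\n")
  tab <- table(factor(x$loci$unit_len, levels = 1:4))
  cat("  unit length 1/2/3/4:", paste(as.integer(tab), collapse = " / "), "\n")
  invisible(x)
}

#' Nearest-neighbour distances between repeat loci
#'
#' For each locus, the minimum base-pair gap (end-to-start, clamped at zero
#' for touching or overlapping loci) to any other repeat locus on the same
#' chromosome. A chromosome carrying a single locus yields `NA`, which
#' downstream empirical distribution functions drop.
#'
#' @param census A `repeat_census`, or its `loci` data frame.
#' @return The locus table with an added integer `distance` column.
#' @export
nearest_neighbor_distances <- function(census) {
  loci <- if (inherits(census, "repeat_census")) census$loci else census
  loci <- loci[order(loci$chrom, loci$start, loci$end), , drop = FALSE]
  loci$distance <- NA_integer_
  for (chr in unique(loci$chrom)) {
    i <- which(loci$chrom == chr)
    if (length(i) < 2L) next
    s <- loci$start[i]; e <- loci$end[i]
    # gap to the closest later-starting locus / to the closest earlier end
    gap_next <- c(pmax(0L, s[-1L] - e[-length(e)]), NA_integer_)
    prev_maxend <- c(NA_integer_, cummax(e[-length(e)]))
    gap_prev <- pmax(0L, s - prev_maxend)
    loci$distance[i] <- pmin(gap_next, gap_prev, na.rm = TRUE)
  }
  rownames(loci) <- NULL
  loci
}
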