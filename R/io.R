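#' Read a genome from FASTA
#'
#' @param path FASTA file (plain text).
#' @return Named character vector of upper-case sequences.
#' @export
read_genome_fasta <- function(path) {
  as_genome_chr(Biostrings::readDNAStringSet(path))
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Write a repeat census as BED6
#'
#' BED is 0-based half-open, matching the internal convention; the name
#' field is `motif_class:n_units`, the score the unit count.
#'
#' @param census A `repeat_census`.
#' @param path Output path.
#' @export
write_repeats_bed <- function(census, path) {
  loci <- census$loci
  bed <- data.frame(loci$chrom, loci$start, loci$end,
                    paste0(loci$motif_class, ":", loci$n_units),
                    loci$n_units, ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a repeats BED (as written by [write_repeats_bed()]) or any BED
#'
#' Uses `rtracklayer` for parsing; coordinates are returned 0-based
#' half-open. For a repeats BED the name field is split back into motif
#' class and unit count.
#'
#' @param path BED file.
#' @return Data frame with `chrom`, `start`, `end` (+ `motif_class`,
#'   `n_units` when the name field encodes them).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm) && all(grepl(":", nm))) {
    parts <- strsplit(nm, ":", fixed = TRUE)
    df$motif_class <- vapply(parts, `[`, character(1), 1L)
    df$n_units <- as.integer(vapply(parts, `[`, character(1), 2L))
  } else if (!is.null(nm)) {
    df$name <- nm
  }
  df
}

#' Write mutation calls as a minimal VCF
#'
#' Plain-text VCF 4.2 with anchored indel representation; positions are
#' converted from the internal 0-based convention to VCF's 1-based one.
#'
#' @param calls Call table (`chrom`, `pos` 0-based, `ref`, `alt`).
#' @param path Output path.
#' @param sample_name Sample column name (default the lineage id, else
#'   `"sample"`).
#' @export
write_mutation_vcf <- function(calls, path, sample_name = NULL) {
  if (is.null(sample_name)) {
    sample_name <- if ("lineage_id" %in% names(calls) && nrow(calls)) {
      as.character(calls$lineage_id[1L])
    } else "sample"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=mapipe",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample_name)), con)
  if (nrow(calls)) {
    ord <- order(calls$chrom, calls$pos)
    c2 <- calls[ord, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t1",
                       c2$chrom, c2$pos + 1L, c2$ref, c2$alt), con)
  }
  invisible(path)
}

#' Read mutation calls from a VCF
#'
#' Parses with `vcfR`; multi-allelic records are rejected (out of scope).
#'
#' @param path VCF file.
#' @param lineage_id Lineage label to attach (default: file name).
#' @return Call table with `lineage_id`, `chrom`, `pos` (0-based), `ref`,
#'   `alt`.
#' @export
read_mutation_vcf <- function(path, lineage_id = NULL) {
  if (is.null(lineage_id)) {
    lineage_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(cbind(empty_calls_df()))
  }
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic records are not supported: ", path, call. = FALSE)
  }
  data.frame(lineage_id = lineage_id, chrom = fix$CHROM,
             pos = as.integer(fix$POS) - 1L, ref = fix$REF, alt = fix$ALT,
             stringsAsFactors = FALSE)
}

#' Read the lineage metadata table
#'
#' @param path TSV with columns `lineage_id`, `generations`, `class`.
#' @return Data frame.
#' @export
read_lineage_metadata <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("lineage_id", "generations") %in% names(df)))
  df
}
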