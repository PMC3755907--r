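#' Canonical strand-collapsed motif class of a repeat unit
#'
#' Repeat units that describe the same genomic tandem repeat -- rotations of
#' one another, or rotations of the reverse complement (the same repeat read
#' off the opposite strand) -- are pooled into a single motif class so that
#' counts from both strands and from any phase of the repeat can be combined.
#' The class label has the conventional form `"X/complement(X)"` used in
#' microsatellite-instability tables, e.g. `"A/T"`, `"GT/CA"`, `"AAC/TTG"`.
#'
#' The representative `X` is the lexicographically smallest unit in the
#' rotation/reverse-complement closure, except for three dinucleotide and
#' trinucleotide classes where the conventional field name is kept instead
#' (`GT/CA` rather than `AC/TG`, `GA/CT` rather than `AG/TC`, `ATG/TAC`
#' rather than `ATC/TAG`).
#'
#' @param unit Character vector of repeat units (1-4 bp, `ACGT` only). Each
#'   unit must be primitive, i.e. not itself a tandem repeat of a shorter
#'   unit (`"AA"` is rejected: reduce it to unit `"A"` first).
#' @return Character vector of motif class labels.
#' @examples
#' canonical_motif(c("T", "TG", "TTG"))
#' @export
canonical_motif <- function(unit) {
  vapply(unit, canonical_motif_one, character(1), USE.NAMES = FALSE)
}

rotations_of <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  vapply(seq_len(n), function(i) {
    paste(ch[c(i:n, seq_len(i - 1L))], collapse = "")
  }, character(1))
}

is_primitive_unit <- function(s) {
  n <- nchar(s)
  if (n == 1L) return(TRUE)
  divs <- setdiff(which(n %% seq_len(n - 1L) == 0L), integer(0))
  for (d in divs) {
    rep_d <- strrep(substr(s, 1L, d), n / d)
    if (rep_d == s) return(FALSE)
  }
  TRUE
}

# Conventional representatives where they differ from the lexicographic one.
MOTIF_REPRESENTATIVE_OVERRIDES <- c(AC = "GT", AG = "GA", CG = "GC",
                                    ATC = "ATG")

canonical_motif_one <- function(unit) {
  if (is.na(unit) || !nzchar(unit) || nchar(unit) > 4L ||
      grepl("[^ACGT]", unit)) {
    stop("repeat unit must be a 1-4 bp string over ACGT, got: ",
         deparse(unit), call. = FALSE)
  }
  if (!is_primitive_unit(unit)) {
    stop("unit '", unit, "' is not primitive; reduce it to its shortest ",
         "period (e.g. 'AA' -> 'A') before classification", call. = FALSE)
  }
  closure <- unique(c(rotations_of(unit), rotations_of(revcomp_chr(unit))))
  rep_unit <- sort(closure)[1L]
  if (rep_unit %in% names(MOTIF_REPRESENTATIVE_OVERRIDES)) {
    rep_unit <- MOTIF_REPRESENTATIVE_OVERRIDES[[rep_unit]]
  }
  paste0(rep_unit, "/", complement_chr(rep_unit))
}
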