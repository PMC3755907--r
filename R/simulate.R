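#' Simulation configuration for synthetic MA experiments
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' reduced-scale mutation-accumulation experiment in a mismatch-repair
#' deficient background: 16 lineages passaged 170 generations over a 1 Mb
#' genome seeded with several hundred repeats, single-base substitutions at
#' 4.8e-9 per bp per generation, slippage rates growing fourfold per added
#' repeat unit from a base rate at three units, and the class-specific
#' deletion biases observed for MMR-deficient yeast (A/T 0.93, C/G 0.74,
#' AT/TA 0.37, GT/CA 0.65).
#'
#' @param genome_length Total genome size in bp, split across `n_chrom`
#'   chromosomes of unequal length.
#' @param n_chrom Number of chromosomes.
#' @param gc_fraction Background GC content.
#' @param repeat_spec Data frame (`unit`, `L`, `copies`) of repeats to
#'   embed; `L` is run length in bp for 1 bp units and unit count
#'   otherwise.
#' @param snv_rate Substitutions per bp per generation.
#' @param slippage_base_rate Slippage rate per repeat per generation at
#'   L = 3.
#' @param slippage_fold_per_unit Multiplicative rate increase per added
#'   unit, up to 8 units; beyond that the rate grows linearly
#'   (`slippage_linear_factor` per extra unit, relative to the 8-unit
#'   rate), emulating the exponential-to-linear regime change seen at long
#'   repeats.
#' @param slippage_linear_factor Linear-regime growth per unit beyond 8.
#' @param slippage_rate_cap Per-generation per-locus event-rate ceiling;
#'   keeps long repeats inside the low-event-rate regime the accumulation
#'   model assumes.
#' @param bias Named deletion probabilities per motif class.
#' @param default_bias Deletion probability for unlisted classes.
#' @param n_lineages,generations MA design.
#' @param dropout_len,dropout_prob Detection dropout: indels at repeats
#'   spanning at least `dropout_len` bp are lost with this probability.
#' @param cluster_fraction Fraction of embedded repeats given a companion
#'   homopolymer within 0-3 bp (emulates repeat-dense neighbourhoods).
#' @param proximity_boost Slippage-rate multiplier for loci whose nearest
#'   repeat is within `proximity_cutoff` bp.
#' @param proximity_cutoff Proximity threshold in bp.
#' @param coding_fraction Fraction of the genome marked coding when
#'   interval annotations are simulated.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 1e6,
                       n_chrom = 4L,
                       gc_fraction = 0.38,
                       repeat_spec = default_repeat_spec(),
                       snv_rate = 4.8e-9,
                       slippage_base_rate = 2e-7,
                       slippage_fold_per_unit = 4,
                       slippage_linear_factor = 0.5,
                       slippage_rate_cap = 0.05,
                       bias = c("A/T" = 0.93, "C/G" = 0.74,
                                "AT/TA" = 0.37, "GT/CA" = 0.65),
                       default_bias = 0.5,
                       n_lineages = 16L,
                       generations = 170L,
                       dropout_len = 14L,
                       dropout_prob = 0.5,
                       cluster_fraction = 0.15,
                       proximity_boost = 3,
                       proximity_cutoff = 3L,
                       coding_fraction = 0.74) {
  cfg <- list(genome_length = genome_length, n_chrom = as.integer(n_chrom),
              gc_fraction = gc_fraction, repeat_spec = repeat_spec,
              snv_rate = snv_rate,
              slippage_base_rate = slippage_base_rate,
              slippage_fold_per_unit = slippage_fold_per_unit,
              slippage_linear_factor = slippage_linear_factor,
              slippage_rate_cap = slippage_rate_cap,
              bias = bias, default_bias = default_bias,
              n_lineages = as.integer(n_lineages),
              generations = as.integer(generations),
              dropout_len = as.integer(dropout_len),
              dropout_prob = dropout_prob,
              cluster_fraction = cluster_fraction,
              proximity_boost = proximity_boost,
              proximity_cutoff = as.integer(proximity_cutoff),
              coding_fraction = coding_fraction)
  probs <- c(cfg$gc_fraction, cfg$bias, cfg$default_bias, cfg$dropout_prob,
             cfg$cluster_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(c(cfg$snv_rate, cfg$slippage_base_rate) < 0)) {
    stop("rates must be non-negative")
  }
  if (!all(c("unit", "L", "copies") %in% names(cfg$repeat_spec))) {
    stop("repeat_spec needs columns unit, L, copies")
  }
  for (u in unique(cfg$repeat_spec$unit)) {
    if (!is_primitive_unit(u)) stop("repeat_spec unit '", u,
                                    "' is not primitive")
  }
  structure(cfg, class = "sim_config")
}

default_repeat_spec <- function() {
  # The random background already supplies short repeats in genome-like
  # abundance (counts fall roughly geometrically with length); embedding
  # tops up the long tail that a 1 Mb i.i.d. background lacks.
  rbind(
    data.frame(unit = "A",  L = 7:8,  copies = 20L),
    data.frame(unit = "C",  L = 5:8,  copies = 12L),
    data.frame(unit = "AT", L = 4:8,  copies = 20L),
    data.frame(unit = "GT", L = 4:8,  copies = 20L),
    data.frame(unit = "A",  L = 14:15, copies = 8L))
}

# deletion probability for a motif class
bias_for <- function(cfg, motif_class) {
  ifelse(motif_class %in% names(cfg$bias),
         unname(cfg$bias[motif_class]), cfg$default_bias)
}

# Per-generation slippage event rate at length L (bp for unit_len 1, units
# otherwise); inert below the census floor of 3. Exponential growth up to
# 8 units, then the much flatter (linear) regime seen at long repeats:
# rate(L) = rate(8) * (1 + linear_factor * (L - 8)), capped for stability.
slippage_rate <- function(cfg, L) {
  base <- cfg$slippage_base_rate
  fold <- cfg$slippage_fold_per_unit
  r8 <- base * fold^5
  r <- ifelse(L < 3, 0,
              ifelse(L <= 8, base * fold^(L - 3),
                     r8 * (1 + cfg$slippage_linear_factor * (L - 8))))
  pmin(r, cfg$slippage_rate_cap)
}

#' Generate a synthetic genome with a known repeat landscape
#'
#' Draws an i.i.d. background at the requested GC content, embeds the
#' repeats of `repeat_spec` at random non-overlapping positions (optionally
#' pairing a fraction with a nearby companion homopolymer), and fixes the
#' flanking bases so that every embedded locus is exactly maximal: the
#' repeat census of the emitted genome always contains the truth set at
#' exact coordinates.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical (seed, config) gives byte-identical
#'   output.
#' @return List with `genome` (named character vector) and `truth` (locus
#'   data frame with `locus_id`, coordinates, `unit`, `unit_len`,
#'   `n_units`, `motif_class`, `clustered`).
#' @export
generate_genome <- function(config, seed) {
  set.seed(seed)
  cfg <- config
  # chromosome lengths: unequal, proportional to 2,3,4,...
  w <- seq_len(cfg$n_chrom) + 1
  chrom_len <- floor(cfg$genome_length * w / sum(w))
  names(chrom_len) <- paste0("chr", seq_len(cfg$n_chrom))

  gc <- cfg$gc_fraction
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chrom_chars <- lapply(chrom_len, function(n) {
    sample(DNA_BASES, n, replace = TRUE, prob = base_prob[DNA_BASES])
  })

  spec <- cfg$repeat_spec
  units <- rep(spec$unit, spec$copies)
  Ls <- rep(spec$L, spec$copies)
  ord <- sample.int(length(units))
  units <- units[ord]; Ls <- Ls[ord]
  companion <- runif(length(units)) < cfg$cluster_fraction

  occupied <- lapply(chrom_len, function(n) {
    data.frame(start = integer(), end = integer())
  })
  truth <- list()
  margin <- 8L
  total_bp <- sum(ifelse(nchar(units) == 1L, Ls, Ls * nchar(units))) +
    sum(companion) * 8L
  if (total_bp + margin * length(units) > cfg$genome_length * 0.8) {
    stop("repeat_spec does not fit in genome_length", call. = FALSE)
  }
  for (i in seq_along(units)) {
    u <- units[i]
    ulen <- nchar(u)
    n_units <- if (ulen == 1L) Ls[i] else Ls[i]
    rep_bp <- if (ulen == 1L) Ls[i] else Ls[i] * ulen
    comp_bp <- if (companion[i]) 9L else 0L   # gap (<=3) + 4 bp run + flanks
    placed <- FALSE
    for (try in 1:200) {
      chr <- sample.int(cfg$n_chrom, 1L)
      n <- chrom_len[chr]
      span <- rep_bp + comp_bp + 2L
      if (n < span + 2L * margin) next
      s <- sample.int(n - span - 2L * margin, 1L) + margin  # 0-based start
      occ <- occupied[[chr]]
      if (nrow(occ) && any(pmax(occ$start, s - margin) <
                           pmin(occ$end, s + span + margin))) next
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place all repeats; genome too crowded",
                      call. = FALSE)
    ch <- chrom_chars[[chr]]
    rep_seq <- strsplit(strrep(u, ceiling(rep_bp / ulen)), "")[[1]][1:rep_bp]
    ch[(s + 1):(s + rep_bp)] <- rep_seq
    u_first <- substr(u, 1L, 1L)
    u_last <- substr(u, ulen, ulen)
    ch[s] <- sample(setdiff(DNA_BASES, u_last), 1L)        # left flank
    truth[[length(truth) + 1L]] <- data.frame(
      chrom = names(chrom_len)[chr], start = s, end = s + rep_bp,
      unit = u, unit_len = ulen, n_units = n_units,
      clustered = companion[i], stringsAsFactors = FALSE)
    occ_new <- data.frame(start = s - 1L, end = s + span)
    if (companion[i]) {
      gap <- sample(0:3, 1L)
      cu <- sample(setdiff(DNA_BASES, c(u_first, u_last)), 1L)
      if (gap > 0L) {
        gb <- sample(setdiff(DNA_BASES, c(u_first, cu)), 1L)
        ch[(s + rep_bp + 1):(s + rep_bp + gap)] <- gb
      } else if (cu == u_first) {
        cu <- sample(setdiff(DNA_BASES, c(u_first, u_last)), 1L)
      }
      cs <- s + rep_bp + gap
      ch[(cs + 1):(cs + 4)] <- cu
      ch[cs + 5] <- sample(setdiff(DNA_BASES, cu), 1L)     # companion flank
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = names(chrom_len)[chr], start = cs, end = cs + 4L,
        unit = cu, unit_len = 1L, n_units = 4L,
        clustered = TRUE, stringsAsFactors = FALSE)
      if (gap == 0L) {
        # host's right flank is the companion itself; nothing more to fix
      }
    } else {
      ch[s + rep_bp + 1] <- sample(setdiff(DNA_BASES, u_first), 1L)
    }
    chrom_chars[[chr]] <- ch
    occupied[[chr]] <- rbind(occ, occ_new)
  }
  truth <- do.call(rbind, truth)
  truth$motif_class <- canonical_motif(truth$unit)
  truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  truth$locus_id <- seq_len(nrow(truth))
  rownames(truth) <- NULL
  genome <- vapply(chrom_chars, paste, character(1), collapse = "")
  list(genome = genome, truth = truth)
}

#' Simulate mutation-accumulation lineages
#'
#' Evolves each lineage for `generations` generations under the neutral
#' accumulation model (every mutation fixes in the single bottlenecked
#' survivor). Substitutions arise as Poisson (`snv_rate` x genome bp x
#' generations) at uniform positions; each repeat locus slips with per-
#' generation Poisson rate `slippage_rate(current length)` (times the
#' proximity boost for loci with a close neighbour), gaining or losing one
#' unit with the class-specific deletion bias. Loci whose expected total
#' event count is non-negligible are stepped generation by generation so
#' the rate tracks the drifting length; for the (vast) low-rate remainder
#' the per-lineage event count is drawn in one Poisson step at the
#' reference length, which is exact up to the vanishing probability of a
#' same-locus second hit. Lineage RNG streams are derived from the master
#' seed by fixed offsets, so any lineage can be regenerated independently.
#'
#' @param genome Named character vector from [generate_genome()].
#' @param loci Locus frame: the `loci` table of a full [find_repeats()]
#'   census (recommended: mirrors how a real analysis stratifies rates by
#'   the genome-wide census), or the generator's embedded-truth table.
#' @param config A [sim_config()].
#' @param seed Master integer seed.
#' @return List with
#'   \describe{
#'     \item{calls}{VCF-style call table across lineages (`lineage_id`,
#'       `chrom`, `pos` 0-based, `ref`, `alt`) with anchored, left-aligned
#'       indel records for every locus whose net length changed.}
#'     \item{events}{one row per slippage event (`lineage_id`, `locus_id`,
#'       `generation` where tracked, `delta_units`).}
#'     \item{net}{per (lineage, locus) net unit change, including zero-net
#'       loci that slipped.}
#'     \item{snv_truth}{the simulated substitutions.}
#'     \item{loci}{the locus frame used, with `locus_id`.}
#'   }
#' @export
simulate_ma_lines <- function(genome, loci, config, seed) {
  cfg <- config
  genome <- as_genome_chr(genome)
  truth <- loci
  if (is.null(truth$locus_id)) truth$locus_id <- seq_len(nrow(truth))
  if (is.null(truth$motif_class)) {
    uu <- unique(truth$unit)
    truth$motif_class <- canonical_motif(uu)[match(truth$unit, uu)]
  }
  nn <- nearest_neighbor_distances(truth)
  nn <- nn[order(nn$locus_id), , drop = FALSE]
  boost <- ifelse(!is.na(nn$distance) & nn$distance <= cfg$proximity_cutoff,
                  cfg$proximity_boost, 1)
  del_prob <- bias_for(cfg, truth$motif_class)
  glen <- sum(nchar(genome))
  g_tot <- cfg$generations
  lambda_ref <- slippage_rate(cfg, truth$n_units) * boost
  slow <- which(lambda_ref * g_tot > 0.1)   # length drift matters here
  fast <- which(lambda_ref * g_tot <= 0.1 & lambda_ref > 0)

  all_calls <- list(); all_events <- list(); all_net <- list()
  all_snv <- list()
  for (lin in seq_len(cfg$n_lineages)) {
    set.seed((seed + 1009L * lin) %% .Machine$integer.max)
    lineage_id <- sprintf("L%02d", lin)
    n_units <- truth$n_units
    ev_locus <- integer(0); ev_gen <- integer(0); ev_delta <- integer(0)
    # low-rate loci: one Poisson draw per locus at the reference length
    k_fast <- rpois(length(fast), lambda_ref[fast] * g_tot)
    for (h in fast[k_fast > 0L]) {
      k <- k_fast[match(h, fast)]
      gens <- sort(sample.int(g_tot, k, replace = TRUE))
      for (g in gens) {
        delta <- if (runif(1) < del_prob[h]) -1L else 1L
        n_units[h] <- max(0L, n_units[h] + delta)
        ev_locus <- c(ev_locus, h); ev_gen <- c(ev_gen, g)
        ev_delta <- c(ev_delta, delta)
      }
    }
    # high-rate loci: generation-by-generation with length feedback
    if (length(slow)) {
      for (g in seq_len(g_tot)) {
        lambda <- slippage_rate(cfg, n_units[slow]) * boost[slow]
        k <- rpois(length(slow), lambda)
        for (h in slow[k > 0L]) {
          for (e in seq_len(k[match(h, slow)])) {
            delta <- if (runif(1) < del_prob[h]) -1L else 1L
            n_units[h] <- max(0L, n_units[h] + delta)
            ev_locus <- c(ev_locus, h); ev_gen <- c(ev_gen, g)
            ev_delta <- c(ev_delta, delta)
          }
        }
      }
    }
    # substitutions, pooled over generations (uniform in time and space)
    n_snv <- rpois(1L, cfg$snv_rate * glen * g_tot)
    snv <- draw_snvs(genome, n_snv)
    if (nrow(snv)) snv$lineage_id <- lineage_id

    net_units <- n_units - truth$n_units
    slipped <- sort(unique(ev_locus))
    net_df <- if (length(slipped)) {
      data.frame(lineage_id = lineage_id,
                 locus_id = truth$locus_id[slipped],
                 net_units = net_units[slipped])
    } else NULL
    calls_ind <- indel_calls_for(genome, truth, n_units, lineage_id)
    ev_df <- if (length(ev_locus)) {
      data.frame(lineage_id = lineage_id, locus_id = truth$locus_id[ev_locus],
                 generation = ev_gen, delta_units = ev_delta)
    } else NULL
    all_calls[[lin]] <- rbind(snv_calls_df(snv), calls_ind)
    all_events[[lin]] <- ev_df
    all_net[[lin]] <- net_df
    all_snv[[lin]] <- snv
  }
  calls <- do.call(rbind, all_calls)
  if (is.null(calls)) calls <- empty_calls_df()
  rownames(calls) <- NULL
  list(calls = calls,
       events = rbind_or_empty(all_events,
                               c("lineage_id", "locus_id", "generation",
                                 "delta_units")),
       net = rbind_or_empty(all_net, c("lineage_id", "locus_id",
                                       "net_units")),
       snv_truth = rbind_or_empty(all_snv, c("chrom", "pos", "ref", "alt",
                                             "lineage_id")),
       loci = truth)
}

rbind_or_empty <- function(lst, cols) {
  out <- do.call(rbind, lst)
  if (is.null(out)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols))
  }
  rownames(out) <- NULL
  out
}

empty_calls_df <- function() {
  data.frame(lineage_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), stringsAsFactors = FALSE)
}

draw_snvs <- function(genome, n_snv) {
  if (n_snv == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  chrom_len <- nchar(genome)
  offsets <- cumsum(c(0, chrom_len[-length(chrom_len)]))
  names(offsets) <- names(genome)
  glen <- sum(chrom_len)
  p <- floor(runif(n_snv) * glen)           # 0-based global positions
  chr_i <- findInterval(p, cumsum(chrom_len) - 0.5) + 1L
  chr <- names(genome)[chr_i]
  pos <- as.integer(p - offsets[chr_i])
  ref <- substring(genome[chr_i], pos + 1L, pos + 1L)
  alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                character(1), USE.NAMES = FALSE)
  data.frame(chrom = chr, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

snv_calls_df <- function(snv) {
  if (!nrow(snv)) return(NULL)
  data.frame(lineage_id = snv$lineage_id, chrom = snv$chrom, pos = snv$pos,
             ref = snv$ref, alt = snv$alt, locus_id = NA_integer_,
             stringsAsFactors = FALSE)
}

# Anchored, left-aligned VCF records for every locus with a net change.
indel_calls_for <- function(genome, truth, n_units_final, lineage_id) {
  changed <- which(n_units_final != truth$n_units)
  if (!length(changed)) return(NULL)
  d <- n_units_final[changed] - truth$n_units[changed]
  s <- truth$start[changed]
  u <- truth$unit[changed]
  ulen <- truth$unit_len[changed]
  chrom <- truth$chrom[changed]
  anchor <- ref <- alt <- character(length(changed))
  for (chr in unique(chrom)) {
    i <- chrom == chr
    anchor[i] <- substring(genome[[chr]], s[i], s[i])   # base before locus
    del <- i & d < 0
    if (any(del)) {
      ref[del] <- paste0(anchor[del],
                         substring(genome[[chr]], s[del] + 1L,
                                   s[del] - d[del] * ulen[del]))
      alt[del] <- anchor[del]
    }
  }
  ins <- d > 0
  if (any(ins)) {
    ref[ins] <- anchor[ins]
    alt[ins] <- paste0(anchor[ins], strrep(u[ins], d[ins]))
  }
  data.frame(lineage_id = lineage_id, chrom = chrom, pos = s - 1L,
             ref = ref, alt = alt, locus_id = truth$locus_id[changed],
             stringsAsFactors = FALSE)
}

#' Apply detection dropout to simulated indel calls
#'
#' Emulates the reduced callability of indels at long repeats: indel calls
#' at loci spanning at least `dropout_len` bp in the reference are removed
#' with probability `dropout_prob`; every surviving call is given simulated
#' spanning-read counts of at least 3 for both sample and ancestor.
#'
#' @param calls Call table from [simulate_ma_lines()].
#' @param truth Truth locus table.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `calls` (filtered, with `span_reads_sample` /
#'   `span_reads_ancestor`) and `dropped` (the removed rows).
#' @export
apply_detection_dropout <- function(calls, truth, config, seed) {
  set.seed(seed)
  cfg <- config
  is_indel <- nchar(calls$ref) != nchar(calls$alt)
  locus_bp <- rep(NA_integer_, nrow(calls))
  if (any(is_indel)) {
    if (!is.null(calls$locus_id)) {
      j <- match(calls$locus_id, truth$locus_id)
      locus_bp <- truth$end[j] - truth$start[j]
    } else {
      for (i in which(is_indel)) {
        j <- which(truth$chrom == calls$chrom[i] &
                     truth$start == calls$pos[i] + 1L)
        if (length(j)) {
          j <- j[which.max(truth$end[j] - truth$start[j])]
          locus_bp[i] <- truth$end[j] - truth$start[j]
        }
      }
    }
  }
  long <- is_indel & !is.na(locus_bp) & locus_bp >= cfg$dropout_len
  drop <- long & runif(nrow(calls)) < cfg$dropout_prob
  kept <- calls[!drop, , drop = FALSE]
  kept$span_reads_sample <- ifelse(nchar(kept$ref) != nchar(kept$alt),
                                   3L + rpois(nrow(kept), 5), NA_integer_)
  kept$span_reads_ancestor <- ifelse(nchar(kept$ref) != nchar(kept$alt),
                                     3L + rpois(nrow(kept), 5), NA_integer_)
  rownames(kept) <- NULL
  list(calls = kept, dropped = calls[drop, , drop = FALSE])
}

#' Forward simulation of Luria-Delbruck fluctuation cultures
#'
#' Grows each culture from `n_initial` to `n_final` cells through the
#' `n_final - n_initial` successive cell divisions; each division mutates
#' with probability `per_division_rate`, and a mutant clone founded when
#' the population has `N` cells expands deterministically to
#' `floor(n_final / N)` cells (mutants breed true, no differential
#' fitness). Divisions are asynchronous, so clone sizes follow the classic
#' heavy-tailed Luria-Delbruck law; this is the independent growth-process
#' oracle for the distribution-based estimators.
#'
#' @param n_initial,n_final Inoculum and final population
#'   (`1 <= n_initial < n_final <= 1e8`).
#' @param per_division_rate Mutation probability per cell division.
#' @param n_cultures Number of parallel cultures.
#' @param seed Integer seed.
#' @return Integer vector of final mutant counts, one per culture (capped
#'   at `n_final`).
#' @export
simulate_fluctuation <- function(n_initial, n_final, per_division_rate,
                                 n_cultures, seed) {
  if (n_final > 1e8) {
    stop("n_final > 1e8: scale the culture size down (the distribution ",
         "depends on m = rate * n_final, not on n_final alone)",
         call. = FALSE)
  }
  if (n_initial < 1 || n_final <= n_initial) {
    stop("need 1 <= n_initial < n_final", call. = FALSE)
  }
  if (per_division_rate < 0 || per_division_rate > 1) {
    stop("per_division_rate must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  divisions <- n_final - n_initial
  n_mut <- rbinom(n_cultures, size = divisions, prob = per_division_rate)
  counts <- numeric(n_cultures)
  hit <- which(n_mut > 0L)
  if (length(hit)) {
    culture <- rep(hit, n_mut[hit])
    # population size at each mutation (division events are exchangeable)
    birth_pop <- n_initial + ceiling(runif(length(culture)) * divisions)
    clone <- floor(n_final / birth_pop)
    counts[hit] <- tapply(clone, factor(culture, levels = hit), sum)
  }
  as.integer(pmin(counts, n_final))
}

#' Simulated coding-interval annotation
#'
#' Tiles each chromosome with alternating coding/noncoding blocks so that
#' the requested fraction of the genome is coding; used to calibrate the
#' coding-fraction statistic.
#'
#' @param genome Named character vector of sequences.
#' @param coding_fraction Target coding fraction.
#' @param block_bp Coding block size (default 1500 bp, gene-sized).
#' @return Data frame of 0-based half-open coding intervals.
#' @export
simulate_coding_intervals <- function(genome, coding_fraction,
                                      block_bp = 1500L) {
  out <- list()
  for (chr in names(genome)) {
    n <- nchar(genome[[chr]])
    period <- round(block_bp / coding_fraction)
    starts <- seq(0L, n - 1L, by = period)
    ends <- pmin(starts + block_bp, n)
    out[[chr]] <- data.frame(chrom = chr, start = starts, end = ends,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
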