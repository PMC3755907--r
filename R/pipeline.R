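RUN_CONFIG_KEYS <- c("fasta", "vcf", "meta", "repeats_bed", "coding_bed",
                     "timing_bed", "fluct_counts", "n_final", "out_dir",
                     "genome_size", "generations", "min_hpr", "min_units",
                     "min_span", "shared_min", "seed")

#' Parse and validate a pipeline run configuration
#'
#' The configuration is a flat, typed key = value text file (`#` comments
#' allowed). Unknown keys are errors, guarding against silent typos.
#' Required keys: `fasta`, `vcf` (comma-separated list of per-lineage VCF
#' paths), `out_dir`. Optional: `meta` (lineage metadata TSV),
#' `repeats_bed`, `coding_bed`, `timing_bed`, `fluct_counts` + `n_final`,
#' `genome_size`, `generations` (default 170), `min_hpr` (3), `min_units`
#' (3), `min_span` (0 = no span filtering), `shared_min` (3), `seed` (1).
#' Every referenced input path must exist at validation time.
#'
#' @param x Path to a config file, or a named list.
#' @return Validated `run_config` list.
#' @export
run_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    lines <- readLines(x)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad)) stop("malformed config line: ", lines[bad][1L],
                       call. = FALSE)
    cfg <- setNames(lapply(kv, function(p) trimws(p[2L])),
                    vapply(kv, function(p) trimws(p[1L]), character(1)))
  } else {
    cfg <- x
  }
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in c("fasta", "out_dir")) {
    if (is.null(cfg[[k]])) stop("config key '", k, "' is required",
                                call. = FALSE)
  }
  if (is.null(cfg$vcf)) stop("config key 'vcf' is required", call. = FALSE)
  if (is.character(cfg$vcf) && length(cfg$vcf) == 1L) {
    cfg$vcf <- trimws(strsplit(cfg$vcf, ",")[[1]])
  }
  num_keys <- c("n_final", "genome_size", "generations", "min_hpr",
                "min_units", "min_span", "shared_min", "seed")
  for (k in num_keys) if (!is.null(cfg[[k]])) cfg[[k]] <- as.numeric(cfg[[k]])
  defaults <- list(generations = 170, min_hpr = 3, min_units = 3,
                   min_span = 0, shared_min = 3, seed = 1)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("fasta", "meta", "repeats_bed", "coding_bed", "timing_bed",
              "fluct_counts")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      stop("config path for '", k, "' does not exist: ", cfg[[k]],
           call. = FALSE)
    }
  }
  missing_vcf <- cfg$vcf[!file.exists(cfg$vcf)]
  if (length(missing_vcf)) {
    stop("VCF path(s) do not exist: ", paste(missing_vcf, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Run the full mutation-accumulation analysis pipeline
#'
#' Orchestrates repeat census, mutation classification, rate and spectrum
#' estimation, and bias/proximity statistics over a set of per-lineage VCFs
#' against one reference FASTA, writing a reproducible report bundle
#' (tables, JSON stats, a manifest with checksums, and a log). A stage
#' failure aborts with the failing stage named and leaves a `FAILED` marker
#' next to any partial outputs.
#'
#' @param config A `run_config` (or something [run_config()] accepts).
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, msg)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
  }
  unlink(file.path(cfg$out_dir, "FAILED"))
  cat("", file = log_path)
  artifacts <- character(0)
  stage <- function(name, fun) {
    logf(name, "start")
    out <- tryCatch(fun(), error = function(e) {
      logf(name, paste("FAILED:", conditionMessage(e)))
      writeLines(name, file.path(cfg$out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logf(name, "done")
    out
  }

  # config echo (verbatim serialisation of the validated config)
  cfg_path <- file.path(cfg$out_dir, "config.txt")
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, function(v) paste(v, collapse = ","),
                            character(1))), cfg_path)

  genome <- stage("read-genome", function() read_genome_fasta(cfg$fasta))

  census <- stage("repeats", function() {
    cen <- find_repeats(genome, min_hpr = cfg$min_hpr,
                        min_units = cfg$min_units)
    write_repeats_bed(cen, file.path(cfg$out_dir, "repeats.bed"))
    write.table(cen$by_class_and_length,
                file.path(cfg$out_dir, "repeat_census.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cen
  })
  artifacts <- c(artifacts, "repeats.bed", "repeat_census.tsv")

  classified <- stage("classify", function() {
    calls <- do.call(rbind, lapply(cfg$vcf, read_mutation_vcf))
    calls <- remove_shared_mutations(calls, min_lineages = cfg$shared_min)
    logf("classify", paste(attr(calls, "n_removed"),
                           "shared ancestral mutation rows removed"))
    cl <- classify_mutations(calls, census, genome)
    if (cfg$min_span > 0) cl <- filter_span_coverage(cl, cfg$min_span)
    write.table(cl, file.path(cfg$out_dir, "classified.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cl
  })
  artifacts <- c(artifacts, "classified.tsv")

  n_lineages <- length(unique(classified$lineage_id))
  genome_bp <- if (!is.null(cfg$genome_size)) cfg$genome_size
               else sum(nchar(genome))

  rates <- stage("rates", function() {
    spec <- spectrum_table(classified)
    write.table(as.data.frame(spec), file.path(cfg$out_dir, "spectrum.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    overall <- per_bp_rate(nrow(classified), n_lineages, cfg$generations,
                           genome_bp)
    curve <- per_repeat_rate_by_length(classified, census, n_lineages,
                                       cfg$generations)
    write.table(as.data.frame(curve),
                file.path(cfg$out_dir, "length_rates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(spectrum = spec, overall = overall, curve = curve)
  })
  artifacts <- c(artifacts, "spectrum.tsv", "length_rates.tsv")

  stats <- stage("stats", function() {
    bias <- indel_bias_table(classified)
    write.table(bias, file.path(cfg$out_dir, "bias.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    nn <- nearest_neighbor_distances(census)
    mutated <- unique(classified$repeat_id[!is.na(classified$repeat_id)])
    prox <- NULL
    if (length(mutated) >= 2L) {
      prox <- proximity_ks(nn$distance[mutated], nn$distance)
      write.table(prox$ecdf_table,
                  file.path(cfg$out_dir, "proximity_ecdf.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out <- list(
      overall_rate = rates$overall$rate,
      overall_rate_ci = c(rates$overall$ci_low, rates$overall$ci_high),
      n_mutations = nrow(classified),
      n_lineages = n_lineages,
      genome_bp = genome_bp,
      bias = bias,
      proximity = if (!is.null(prox)) {
        list(ks_D = prox$ks_D, p_value = prox$p_value)
      })
    jsonlite::write_json(out, file.path(cfg$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out
  })
  artifacts <- c(artifacts, "bias.tsv", "stats.json")
  if (file.exists(file.path(cfg$out_dir, "proximity_ecdf.tsv"))) {
    artifacts <- c(artifacts, "proximity_ecdf.tsv")
  }

  if (!is.null(cfg$fluct_counts)) {
    stage("fluctuation", function() {
      counts <- read.table(cfg$fluct_counts, header = TRUE, sep = "\t")
      if (is.null(cfg$n_final)) stop("n_final required with fluct_counts")
      fits <- list(
        p0 = tryCatch(unclass(p0_estimate(counts$mutants, cfg$n_final)),
                      error = function(e) list(error = conditionMessage(e))),
        mss = unclass(mss_mle(counts$mutants, cfg$n_final)))
      jsonlite::write_json(fits, file.path(cfg$out_dir, "fluctuation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      fits
    })
    artifacts <- c(artifacts, "fluctuation.json")
  }

  manifest <- stage("manifest", function() {
    paths <- file.path(cfg$out_dir, artifacts)
    m <- list(
      package = "mapipe",
      version = as.character(utils::packageVersion("mapipe")),
      seed = cfg$seed,
      inputs = as.list(tools::md5sum(c(cfg$fasta, cfg$vcf))),
      artifacts = setNames(as.list(unname(tools::md5sum(paths))), artifacts))
    jsonlite::write_json(m, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    m
  })
  invisible(manifest)
}
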