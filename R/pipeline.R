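#' Pipeline configuration
#'
#' Collects file paths and stage parameters for [run_pipeline()]. May also
#' be loaded from a YAML file with the same field names via
#' [read_pipeline_config()].
#'
#' @param genome,transcripts paths to FASTA files (required).
#' @param utrs path to a UTR FASTA (optional; enables the homology scan).
#' @param reads path to a small-RNA FASTA (optional; enables mapping).
#' @param ct_table path to a Ct TSV (optional; enables qPCR analysis).
#' @param output_dir directory for all outputs.
#' @param seed integer seed recorded in the run log (the pipeline itself
#'   is deterministic).
#' @param align named list of [align_params()] overrides.
#' @param scan_modes character vector of scan modes to run
#'   (`"deregulated"`, `"utrdb"`).
#' @param pirna named list of [pirna_params()] overrides.
#' @param target_chrom chromosome for the exclusivity flag (default:
#'   first genome record).
#' @param strict non-zero exit/error on empty results.
#' @return config list.
#' @export
pipeline_config <- function(genome, transcripts, utrs = NULL, reads = NULL,
                            ct_table = NULL, output_dir = "pirnascan_out",
                            seed = 1L, align = list(),
                            scan_modes = "deregulated", pirna = list(),
                            target_chrom = NULL, strict = FALSE) {
  cfg <- list(genome = genome, transcripts = transcripts, utrs = utrs,
              reads = reads, ct_table = ct_table, output_dir = output_dir,
              seed = as.integer(seed), align = align,
              scan_modes = scan_modes, pirna = pirna,
              target_chrom = target_chrom, strict = isTRUE(strict))
  for (f in c("genome", "transcripts")) {
    if (is.null(cfg[[f]])) stop("config error: missing required path: ", f)
  }
  if (!all(cfg$scan_modes %in% c("deregulated", "utrdb")))
    stop("config error: unknown scan mode")
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes align -> junction annotation -> homology scan (per mode) ->
#' dedupe/summary -> small-RNA mapping -> qPCR quantification, writing all
#' module outputs plus a machine-readable `summary.json` and a run log
#' under `config$output_dir`. Any stage failure aborts with a stage-named
#' error; outputs of completed stages are retained.
#'
#' @param config list from [pipeline_config()] or [read_pipeline_config()].
#' @return invisibly, the summary list written to `summary.json`.
#' @export
run_pipeline <- function(config) {
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  logf <- file.path(out, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               ..., "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("pirnascan ", as.character(utils::packageVersion("pirnascan")),
          " seed=", config$seed)
  summary <- list(seed = config$seed)
  stage <- function(name, expr) {
    logline("stage ", name, " start")
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logline("stage ", name, " done")
    r
  }

  genome <- stage("load", {
    g <- read_fasta(config$genome)
    if (!nrow(g)) stop("empty genome")
    g
  })
  transcripts <- read_fasta(config$transcripts)
  ap <- do.call(align_params, config$align)

  chains_by_tx <- stage("align", align_transcripts(transcripts, genome, ap))
  locus <- assign_locus_groups(chains_by_tx)
  write_tsv(locus, file.path(out, "locus_report.tsv"))
  all_chains <- unlist(unname(lapply(chains_by_tx, identity)),
                       recursive = FALSE)
  if (length(all_chains))
    write_chains_gff3(all_chains, file.path(out, "chains.gff3"))
  summary$locus <- list(
    n_transcripts = nrow(locus),
    n_placed = sum(locus$n_loci > 0L),
    n_single_locus = sum(locus$single_locus, na.rm = TRUE),
    n_multi_locus = sum(!locus$single_locus, na.rm = TRUE))

  best <- best_chains(chains_by_tx)
  juncs <- stage("annotate", {
    j <- do.call(rbind, c(lapply(best, annotate_junctions, genome = genome),
                          make.row.names = FALSE))
    if (is.null(j)) j <- annotate_junctions(
      exon_chain("x", genome$id[1], "+",
                 data.frame(start = 0L, end = 1L)), genome)
    j
  })
  write_tsv(juncs, file.path(out, "junctions.tsv"))
  summary$junctions <- list(
    n = nrow(juncs),
    pct_canonical = if (nrow(juncs)) round(100 * mean(juncs$canonical), 2)
    else NA)

  if (!is.null(config$utrs)) {
    utrs <- read_fasta(config$utrs)
    summary$scan <- list()
    for (mode in config$scan_modes) {
      sp <- scan_params(mode)
      res <- stage(paste0("scan_", mode), {
        h <- scan_homology(transcripts, utrs, sp)
        h <- classify_location(h, best, sp$junction_min_overhang)
        dd <- dedupe_unique_stretches(h, transcripts)
        list(hits = h, dd = dd)
      })
      write_tsv(res$hits, file.path(out, paste0("hits_", mode, ".tsv")))
      write_hits_bed(res$hits, file.path(out, paste0("hits_", mode, ".bed")))
      write_tsv(res$dd$unique, file.path(out, paste0("unique_", mode, ".tsv")))
      write_tsv(res$dd$summary,
                file.path(out, paste0("summary_", mode, ".tsv")))
      summary$scan[[mode]] <- as.list(res$dd$summary)
    }
  }

  if (!is.null(config$reads)) {
    reads <- read_fasta(config$reads)
    pp <- do.call(pirna_params, config$pirna)
    mp <- stage("map_smallrna", {
      kept <- length_filter(reads, pp)
      m <- map_exact(kept, genome, pp,
                     target_chrom = config$target_chrom %||% genome$id[1])
      tx <- match_to_transcripts(kept, transcripts)
      list(kept = kept, map = m, tx = tx)
    })
    write_tsv(mp$map$placements, file.path(out, "read_placements.tsv"))
    write_placements_bed(mp$map$placements,
                         file.path(out, "read_placements.bed"))
    write_tsv(mp$map$summary, file.path(out, "read_summary.tsv"))
    write_tsv(mp$tx$matches, file.path(out, "read_transcript_matches.tsv"))
    summary$smallrna <- list(
      n_reads = nrow(reads), n_length_pass = nrow(mp$kept),
      n_placed = sum(mp$map$summary$copy_count > 0L),
      n_target_exclusive = sum(mp$map$summary$target_exclusive &
                                 mp$map$summary$copy_count > 0L),
      n_derived_from_transcripts = sum(mp$tx$derived$derives),
      copy_count_range = if (nrow(mp$map$summary))
        range(mp$map$summary$copy_count) else c(NA, NA))
    if (config$strict && summary$smallrna$n_placed == 0L)
      stop("stage 'map_smallrna' failed: no placements in strict mode",
           call. = FALSE)
  }

  if (!is.null(config$ct_table)) {
    lv <- stage("qpcr", livak(read_ct_table(config$ct_table)))
    write_tsv(data.frame(metric = names(unclass(lv)),
                         value = unlist(unclass(lv))),
              file.path(out, "qpcr_result.tsv"))
    summary$qpcr <- list(fold_change = lv$fold_change,
                         fold_reduction = lv$fold_reduction,
                         p_value = lv$p_value)
  }

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("pipeline complete")
  invisible(summary)
}

# BED6 of homology hits on the UTR targets.
write_hits_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$target_id, start = hits$t_start,
                    end = hits$t_end,
                    name = sprintf("%s:%d-%d:%s:%d", hits$query_id,
                                   hits$q_start, hits$q_end,
                                   hits$orientation, hits$mismatches),
                    score = hits$mismatches,
                    strand = ifelse(hits$orientation == "+/+", "+", "-"))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# BED6 of read placements.
write_placements_bed <- function(p, path) {
  if (is.null(p) || !nrow(p)) { cat("", file = path); return(invisible(path)) }
  bed <- data.frame(chrom = p$chrom, start = p$start, end = p$end,
                    name = p$read_id, score = 0L, strand = p$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
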