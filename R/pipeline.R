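# End-to-end pipeline driver: pileup -> units -> CDPs -> per-population
# statistics -> classification -> MAIR -> consensus genome(s) -> summaries,
# with a machine-readable run log.

#' Run the full pipeline on a pileup
#'
#' Chains candidate extraction, unit building and filtering, per-population
#' statistics, classification, MAIR derivation, consensus construction and
#' summary reporting, writing every artifact under `outdir`:
#' `cdps.bed`, per-population `<pop>_positions.tsv` / `<pop>_indels.tsv` /
#' `<pop>_rare.tsv` / `<pop>.vcf` / `<pop>_mair.tsv` / `vcg_<pop>.fa` /
#' `<pop>_liftover.tsv` / `<pop>_summary.json`, and `run_log.json` with
#' thresholds, stage counts and the CDP reduction ratio.
#'
#' @param pileup a `pileup` object, or a path to an mpileup file.
#' @param reference named reference sequences, or a FASTA path.
#' @param populations named list of sample-name vectors; union populations
#'   are expressed by listing the union's members (e.g.
#'   `list(CHB = b, CHS = s, CHN = c(b, s))`). Default: one population
#'   `ALL` covering the manifest.
#' @param outdir output directory, created if needed; `NULL` computes
#'   everything in memory and writes nothing.
#' @param filter a [filter_config()].
#' @param classification a [classification_config()].
#' @param class_map chromosome class map for the summaries.
#' @param samples sample manifest, used when `pileup` is a path.
#' @return A `vcg_run` list: `cdps`, `units` (retained), per-population
#'   lists (`stats`, `dynamic`, `mair`, `vcg`, `summary`) and `log`.
#' @export
run_pipeline <- function(pileup, reference, populations = NULL,
                         outdir = NULL, filter = filter_config(),
                         classification = classification_config(),
                         class_map = default_chromosome_classes(),
                         samples = NULL) {
  if (is.character(pileup)) pileup <- read_pileup(pileup, samples = samples)
  if (is.character(reference) && length(reference) == 1L &&
        file.exists(reference)) {
    reference <- read_reference(reference)
  }
  if (is.null(populations)) populations <- list(ALL = pileup$samples)
  bad <- setdiff(unlist(populations), pileup$samples)
  if (length(bad)) {
    stop(sprintf("populations name samples absent from the manifest: %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)

  cdps <- extract_cdps(pileup)
  units <- build_units(.pileup(pileup$samples, cdps$records$calls,
                               cdps$records$indels, cdps$n_cdps),
                       config = filter)
  pops <- list()
  for (nm in names(populations)) {
    st <- population_stats(cdps, units, populations[[nm]],
                           population_id = nm)
    dyn <- classify_positions(st, config = classification)
    mair <- compute_mair(dyn)
    vcg <- build_vcg(reference, mair)
    summ <- summarize_population(dyn, class_map = class_map)
    pops[[nm]] <- list(stats = st, dynamic = dyn, mair = mair, vcg = vcg,
                       summary = summ)
    if (!is.null(outdir)) {
      write_dynamic_tables(dyn, file.path(outdir, nm))
      write_dynamic_vcf(dyn, file.path(outdir, paste0(nm, ".vcf")),
                        reference = reference)
      data.table::fwrite(mair, file.path(outdir, paste0(nm, "_mair.tsv")),
                         sep = "\t")
      write_fasta(vcg$consensus, file.path(outdir, paste0("vcg_", nm, ".fa")))
      write_liftover(vcg$liftover,
                     file.path(outdir, paste0(nm, "_liftover.tsv")))
      jsonlite::write_json(
        list(population = nm,
             counts = pops[[nm]]$summary$counts,
             prob_hist = pops[[nm]]$summary$prob_hist,
             indel_length_hist = pops[[nm]]$summary$indel_length_hist),
        file.path(outdir, paste0(nm, "_summary.json")),
        dataframe = "columns", auto_unbox = TRUE, digits = NA)
    }
  }
  log <- list(
    package_version = as.character(utils::packageVersion("vcgtools")),
    n_samples = length(pileup$samples),
    n_positions = pileup$n_positions,
    n_cdps = cdps$n_cdps,
    reduction_ratio = reduction_ratio(cdps$n_total, cdps$n_cdps),
    n_units_retained = nrow(units),
    thresholds = list(min_reads = filter$min_reads, max_h2 = filter$max_h2,
                      max_h3 = filter$max_h3, max_h4 = filter$max_h4,
                      rare_max = classification$rare_max,
                      minor_min = classification$minor_min,
                      indel_high_min = classification$indel_high_min),
    populations = lapply(pops, function(p) list(
      n_dynamic = nrow(p$dynamic$positions),
      n_mair = nrow(p$mair),
      n_rare = nrow(extract_rare(p$dynamic)),
      edits_applied = nrow(p$vcg$report$kept),
      edits_dropped = nrow(p$vcg$report$dropped))))
  if (!is.null(outdir)) {
    write_cdp_bed(cdps, file.path(outdir, "cdps.bed"))
    jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(cdps = cdps, units = units, populations = pops, log = log),
            class = "vcg_run")
}

#' @export
print.vcg_run <- function(x, ...) {
  cat(sprintf("vcg_run: %d CDPs from %d positions (reduction %.2f%%)\n",
              x$log$n_cdps, x$log$n_positions,
              100 * x$log$reduction_ratio))
  for (nm in names(x$populations)) {
    p <- x$log$populations[[nm]]
    cat(sprintf("  %s: %d dynamic positions, %d MAIR edits, %d rare variations\n",
                nm, p$n_dynamic, p$n_mair, p$n_rare))
  }
  invisible(x)
}
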