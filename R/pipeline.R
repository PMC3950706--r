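# End-to-end orchestration: simulate or ingest -> filter -> call/ingest
# peaks -> exclude/select -> merge/compare -> summits -> annotate ->
# enrich, with stage-tagged logging to stderr and a JSON run manifest
# recording parameters, per-stage record counts and output checksums.

#' Build and validate a pipeline configuration
#'
#' Analysis defaults follow the standard constants of the occupancy
#' comparison: at most 2 reads per start, censoring above 7, >100
#' control tags for exclusion, FDR <= 0.001, TSS windows of +/- 1250 bp
#' (+/- 10 kb cross-species), 200 bp elongation, +/- 150 bp summit
#' windows, normalization to 20 million reads, fold tolerances 2, 3, 4.
#'
#' @param out_dir Output directory.
#' @param design Optional [simulation_design()]; when given, inputs are
#'   simulated and the file-path arguments are ignored.
#' @param tag_files Named vector of BED6 tag files (one per dataset).
#' @param control_files Named vector of control BED6 files.
#' @param peak_files Optional named vector of externally called peak
#'   files (TSV dialect); when absent, peaks are called internally.
#' @param gene_file Gene models TSV.
#' @param gene_sets_file Optional GMT for enrichment.
#' @param ortholog_file Optional one-to-one ortholog TSV.
#' @param bound_b_file Optional file listing bound genes of the second
#'   species (one id per line) for the cross-species Venn.
#' @param genome_file Optional genome FASTA for summit-window export.
#' @param genome_size Effective genome size for the caller (derived from
#'   the design when simulating).
#' @param max_per_start,censor_above Tag-filter thresholds.
#' @param control_threshold Control-tag exclusion threshold (strict >).
#' @param fdr FDR selection cutoff (inclusive).
#' @param tss_half_window,cross_species_half_window TSS window half-widths
#'   in bp.
#' @param extension Fragment length for elongation.
#' @param summit_half_width Summit window half-width in bp.
#' @param reference_reads Reference depth for normalization.
#' @param folds Fold tolerances for the Venn comparison.
#' @param caller_window,caller_step,caller_pvalue Caller parameters.
#' @param seed Seed for any stochastic stage.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, design = NULL, tag_files = NULL,
                       control_files = NULL, peak_files = NULL,
                       gene_file = NULL, gene_sets_file = NULL,
                       ortholog_file = NULL, bound_b_file = NULL,
                       genome_file = NULL, genome_size = NULL,
                       max_per_start = 2, censor_above = 7,
                       control_threshold = 100, fdr = 0.001,
                       tss_half_window = 1250,
                       cross_species_half_window = 10000,
                       extension = 200, summit_half_width = 150,
                       reference_reads = 2e7, folds = c(2, 3, 4),
                       caller_window = 300, caller_step = 100,
                       caller_pvalue = 1e-5, seed = 1) {
  .chk(!missing(out_dir) && is.character(out_dir) && length(out_dir) == 1,
       "out_dir is required")
  .chk(.is_scalar_num(fdr) && fdr >= 0 && fdr <= 1, "fdr must lie in [0, 1]")
  .chk(max_per_start >= 1 && censor_above >= max_per_start,
       "invalid filter thresholds")
  .chk(control_threshold >= 0, "control_threshold must be >= 0")
  .chk(all(folds >= 1), "fold tolerances must be >= 1")
  .chk(tss_half_window >= 0 && cross_species_half_window >= 0,
       "TSS half-windows must be >= 0")
  if (is.null(design)) {
    .chk(!is.null(tag_files) && !is.null(names(tag_files)),
         "either design or named tag_files must be given")
    for (f in c(tag_files, control_files, peak_files, gene_file,
                gene_sets_file, ortholog_file, bound_b_file, genome_file)) {
      .chk(file.exists(f), "input file not found: %s", f)
    }
    .chk(!is.null(gene_file), "gene_file is required when not simulating")
    .chk(!is.null(genome_size) || !is.null(peak_files),
         "genome_size is required to call peaks on file inputs")
  } else {
    .chk(inherits(design, "simulation_design"),
         "design must come from simulation_design()")
  }
  structure(list(out_dir = out_dir, design = design, tag_files = tag_files,
                 control_files = control_files, peak_files = peak_files,
                 gene_file = gene_file, gene_sets_file = gene_sets_file,
                 ortholog_file = ortholog_file, bound_b_file = bound_b_file,
                 genome_file = genome_file, genome_size = genome_size,
                 max_per_start = max_per_start, censor_above = censor_above,
                 control_threshold = control_threshold, fdr = fdr,
                 tss_half_window = tss_half_window,
                 cross_species_half_window = cross_species_half_window,
                 extension = extension,
                 summit_half_width = summit_half_width,
                 reference_reads = reference_reads, folds = folds,
                 caller_window = caller_window, caller_step = caller_step,
                 caller_pvalue = caller_pvalue, seed = seed),
            class = "run_config")
}

.log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full occupancy-comparison pipeline
#'
#' Executes simulate/ingest, tag filtering, peak calling or ingestion,
#' control exclusion, FDR selection, merging with fold-tolerance Venn
#' partitions, summit calling (with window FASTA export when a genome is
#' available), TSS annotation, metaprofile, optional cross-species Venn
#' and optional gene-set enrichment. Every intermediate is written under
#' `out_dir`; a deterministic JSON manifest records parameters, per-stage
#' record counts and MD5 checksums of every output, so re-running an
#' unchanged configuration is byte-reproducible.
#'
#' @param config A [run_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  .chk(inherits(config, "run_config"), "config must come from run_config()")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "inputs"
  manifest <- list(package = "peakconcord",
                   version = as.character(utils::packageVersion("peakconcord")),
                   parameters = config[setdiff(names(config),
                                               c("design", "out_dir"))],
                   stages = list())
  result <- tryCatch({
    # ---- inputs -------------------------------------------------------
    if (!is.null(config$design)) {
      .log_stage(stage, "simulating study (seed %s)",
                 format(config$design$seed))
      sim <- simulate_chipseq(config$design)
      write_simulation(sim, file.path(out, "simulated"))
      tags <- sim$tags
      controls <- sim$controls
      genes <- sim$genes
      orthologs <- sim$orthologs
      bound_b <- sim$truth$bound_b$gene_b
      genome <- sim$genome
      chrom_sizes <- sim$chrom_sizes
      genome_size <- sum(as.numeric(config$design$genome$length))
      gene_sets <- if (!is.null(config$gene_sets_file)) {
        read_gene_sets(config$gene_sets_file)
      } else NULL
      ext_peaks <- NULL
    } else {
      tags <- lapply(config$tag_files, read_tags)
      controls <- if (!is.null(config$control_files)) {
        lapply(config$control_files, read_tags)
      } else list()
      genes <- read_gene_models(config$gene_file)
      orthologs <- if (!is.null(config$ortholog_file)) {
        read_ortholog_map(config$ortholog_file)
      } else NULL
      bound_b <- if (!is.null(config$bound_b_file)) {
        readLines(config$bound_b_file)
      } else NULL
      genome <- if (!is.null(config$genome_file)) {
        Biostrings::readDNAStringSet(config$genome_file)
      } else NULL
      if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))
      chrom_sizes <- if (!is.null(genome)) {
        stats::setNames(Biostrings::width(genome), names(genome))
      } else NULL
      genome_size <- config$genome_size
      gene_sets <- if (!is.null(config$gene_sets_file)) {
        read_gene_sets(config$gene_sets_file)
      } else NULL
      ext_peaks <- if (!is.null(config$peak_files)) {
        mapply(read_peaks, config$peak_files, dataset_id = names(config$peak_files),
               MoreArgs = list(dialect = "tsv"), SIMPLIFY = FALSE)
      } else NULL
    }
    manifest$stages$inputs <- list(
      datasets = names(tags), controls = names(controls),
      n_tags = vapply(tags, nrow, integer(1)),
      n_genes = nrow(genes))

    # ---- tag filter ---------------------------------------------------
    stage <- "filter"
    filtered <- lapply(tags, filter_tags, max_per_start = config$max_per_start,
                       censor_above = config$censor_above)
    fcontrols <- lapply(controls, filter_tags,
                        max_per_start = config$max_per_start,
                        censor_above = config$censor_above)
    dir.create(file.path(out, "filtered"), showWarnings = FALSE)
    for (d in names(filtered)) {
      write_tags(filtered[[d]]$tags,
                 file.path(out, "filtered", paste0(d, ".bed")))
      .log_stage(stage, "%s: %d -> %d tags (%d duplicates, %d censored)", d,
                 filtered[[d]]$report$n_input,
                 filtered[[d]]$report$n_retained,
                 filtered[[d]]$report$n_duplicates_removed,
                 filtered[[d]]$report$n_censored)
    }
    for (cl in names(fcontrols)) {
      write_tags(fcontrols[[cl]]$tags,
                 file.path(out, "filtered", paste0("control_", cl, ".bed")))
    }
    reports <- lapply(filtered, `[[`, "report")
    jsonlite::write_json(
      lapply(reports, function(r) r[c("n_input", "n_retained",
                                      "n_duplicates_removed", "n_censored")]),
      file.path(out, "filtered", "filter_reports.json"),
      auto_unbox = TRUE, pretty = TRUE)
    # usable reads per dataset, the normalization denominator
    library_sizes <- vapply(filtered, function(f) f$report$n_retained,
                            integer(1))
    manifest$stages$filter <- reports
    ftags <- lapply(filtered, `[[`, "tags")
    fctags <- lapply(fcontrols, `[[`, "tags")

    # ---- peak calling / ingestion ------------------------------------
    stage <- "peaks"
    if (!is.null(ext_peaks)) {
      called <- ext_peaks
      .log_stage(stage, "ingested %d external peak set(s)", length(called))
    } else {
      .chk(!is.null(genome_size), "genome_size missing for the caller")
      params <- caller_params(genome_size = genome_size,
                              window = config$caller_window,
                              step = config$caller_step,
                              pvalue_cutoff = config$caller_pvalue,
                              fdr_cutoff = config$fdr)
      caller_control <- if (length(fctags)) fctags[[1L]] else NULL
      called <- lapply(names(ftags), function(d) {
        call_peaks(ftags[[d]], caller_control, params, dataset_id = d)
      })
      names(called) <- names(ftags)
      for (d in names(called)) {
        .log_stage(stage, "%s: %d candidate peaks", d, nrow(called[[d]]))
      }
    }
    dir.create(file.path(out, "peaks"), showWarnings = FALSE)
    for (d in names(called)) {
      write_peaks(called[[d]], file.path(out, "peaks",
                                         paste0(d, "_called.tsv")))
    }
    manifest$stages$peaks <- vapply(called, nrow, integer(1))

    # ---- exclusion + FDR selection -----------------------------------
    stage <- "select"
    selected <- lapply(names(called), function(d) {
      part <- exclude_by_control(called[[d]], fctags,
                                 threshold = config$control_threshold)
      sel <- filter_fdr(part$kept, cutoff = config$fdr)
      .log_stage(stage, "%s: %d excluded by control, %d pass fdr <= %s", d,
                 nrow(part$excluded), nrow(sel), format(config$fdr))
      write_peaks(part$excluded,
                  file.path(out, "peaks", paste0(d, "_excluded.tsv")))
      write_peaks(sel, file.path(out, "peaks", paste0(d, "_selected.tsv")))
      sel
    })
    names(selected) <- names(called)
    manifest$stages$select <- vapply(selected, nrow, integer(1))

    # ---- merge + fold-tolerance Venn ---------------------------------
    stage <- "compare"
    regions <- merge_peak_sets(selected, fdr_cutoff = config$fdr)
    regions <- region_counts(regions, ftags, library_sizes,
                             reference = config$reference_reads)
    .log_stage(stage, "%d merged regions", nrow(regions))
    dir.create(file.path(out, "compare"), showWarnings = FALSE)
    labels <- attr(regions, "count_labels")
    flat <- regions[, c("region_id", "chrom", "start", "end")]
    flat$contributors <- vapply(regions$contributors, paste,
                                character(1), collapse = ",")
    for (d in labels) flat[[paste0("count_", d)]] <- regions[[paste0("count_", d)]]
    for (k in config$folds) {
      mem <- fold_membership(regions, k)
      flat[[sprintf("membership_k%g", k)]] <-
        vapply(mem, paste, character(1), collapse = ",")
      vp <- venn_partition(regions, k)
      .write_tsv(data.frame(cell = names(vp$cells), n = vp$cells,
                            stringsAsFactors = FALSE),
                 file.path(out, "compare", sprintf("venn_k%g.tsv", k)),
                 comment = sprintf("Venn cells at fold tolerance k = %g", k))
    }
    .write_tsv(flat, file.path(out, "compare", "merged_regions.tsv"),
               comment = "merged regions; normalized counts; membership per fold tolerance")
    manifest$stages$compare <- list(n_regions = nrow(regions))

    # ---- summits ------------------------------------------------------
    stage <- "summits"
    pooled <- do.call(rbind, c(ftags, list(make.row.names = FALSE)))
    summits <- compute_summits(regions, pooled, extension = config$extension)
    bed <- data.frame(summits$chrom, summits$position,
                      summits$position + 1L, summits$region_id,
                      summits$height, ".")
    writeLines(c("# summit BED: 1-bp positions, score = pileup height",
                 do.call(paste, c(bed, list(sep = "\t")))),
               file.path(out, "compare", "summits.bed"))
    wins <- summit_windows(summits, half_width = config$summit_half_width,
                           chrom_sizes = chrom_sizes)
    if (!is.null(genome)) {
      Biostrings::writeXStringSet(
        extract_sequences(genome, wins),
        file.path(out, "compare", "summit_windows.fa"))
    }
    .log_stage(stage, "%d summits", nrow(summits))
    manifest$stages$summits <- list(n_summits = nrow(summits),
                                    n_flagged = sum(summits$flagged))

    # ---- annotation ---------------------------------------------------
    stage <- "annotate"
    dir.create(file.path(out, "annotation"), showWarnings = FALSE)
    assoc <- associate_peaks_tss(regions, genes,
                                 half_window = config$tss_half_window)
    .write_tsv(data.frame(region_id = regions$region_id[assoc$pairs$peak_index],
                          gene_id = assoc$pairs$gene_id,
                          stringsAsFactors = FALSE),
               file.path(out, "annotation", "region_gene_pairs.tsv"),
               comment = sprintf("region-TSS associations at +/- %d bp",
                                 config$tss_half_window))
    cls <- classify_locations(regions, genes,
                              half_window = config$tss_half_window)
    .write_tsv(data.frame(category = c("tss_proximal", "intragenic",
                                       "intergenic"),
                          n = c(cls$breakdown$n_tss_proximal,
                                cls$breakdown$n_intragenic,
                                cls$breakdown$n_intergenic),
                          fraction = as.numeric(cls$breakdown$fractions),
                          stringsAsFactors = FALSE),
               file.path(out, "annotation", "location_breakdown.tsv"),
               comment = "region location classes (priority: TSS > intragenic > intergenic)")
    bound <- bound_genes(regions, genes, half_window = config$tss_half_window)
    writeLines(bound, file.path(out, "annotation", "bound_genes.txt"))
    .log_stage(stage, "%d bound genes; TSS-proximal fraction %.3f",
               length(bound), cls$breakdown$fractions[["tss_proximal"]])
    prof <- tss_metaprofile(ftags[[1L]], genes,
                            library_size = library_sizes[[1L]],
                            extension = config$extension,
                            reference = config$reference_reads)
    .write_tsv(data.frame(offset = prof$bin_offsets,
                          mean_coverage = prof$values),
               file.path(out, "annotation", "tss_metaprofile.tsv"),
               comment = sprintf("mean coverage around %d TSSs, normalized to %g reads",
                                 prof$n_tss, config$reference_reads))
    hv <- NULL
    if (!is.null(orthologs) && !is.null(bound_b)) {
      bound_cross <- bound_genes(regions, genes,
                                 half_window = config$cross_species_half_window)
      hv <- homology_venn(bound_cross, bound_b, orthologs)
      .write_tsv(data.frame(cell = c("both", "a_only", "b_only",
                                     "a_specific", "b_specific"),
                            n = c(hv$n_both, hv$n_a_only, hv$n_b_only,
                                  hv$n_a_specific, hv$n_b_specific),
                            stringsAsFactors = FALSE),
                 file.path(out, "annotation", "homology_venn.tsv"),
                 comment = sprintf("cross-species bound-gene Venn at +/- %d bp",
                                   config$cross_species_half_window))
    }
    manifest$stages$annotate <- list(
      n_bound_genes = length(bound),
      breakdown = cls$breakdown[c("n_tss_proximal", "n_intragenic",
                                  "n_intergenic")])

    # ---- enrichment ---------------------------------------------------
    if (!is.null(gene_sets)) {
      stage <- "enrich"
      universe <- gene_universe(gene_sets, mode = "all",
                                all_genes = genes$gene_id)
      enr <- fisher_enrichment(intersect(bound, universe), universe,
                               gene_sets)
      .write_tsv(enr, file.path(out, "annotation", "enrichment.tsv"),
                 comment = "Fisher's exact gene-set enrichment with BH q-values")
      .log_stage(stage, "%d sets tested; min q = %.3g", nrow(enr),
                 min(enr$q_value))
      manifest$stages$enrich <- list(n_sets = nrow(enr))
    }
    TRUE
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  # ---- manifest -------------------------------------------------------
  files <- sort(list.files(out, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(out, files))
  manifest$checksums <- stats::setNames(as.character(sums), files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
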