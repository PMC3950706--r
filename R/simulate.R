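# Seeded synthetic-data generator. Emulates the statistical structure the
# pipeline assumes: uniform Poisson background tags, planted peaks with
# strand-shifted tag pileups and per-dataset enrichment folds (shared vs
# discordant classes), PCR-duplicate bursts at single start positions,
# background-only control libraries with optional single-position artifact
# hotspots (>100 tags), a gene annotation in which a controllable fraction
# of peaks fall in TSS windows, and a one-to-one ortholog map for a second
# synthetic species. Every draw goes through the design seed, so identical
# designs give identical outputs.

#' Describe a synthetic ChIP-Seq study design
#'
#' Defaults describe a three-dataset desk-scale study: a 1 Mb genome, 200
#' genes, 120 planted peaks of which 80% sit inside TSS windows, an
#' expected 60 tags per peak per dataset over a background of 0.004
#' tags/bp, shared peaks with per-dataset folds within 1.5x of each other
#' and discordant peaks with an 8-fold-down dataset, occasional
#' duplicate bursts of 10 reads at one start position, and two
#' 150-tag artifact hotspots in the first control library.
#'
#' @param genome Data frame `chrom, length`.
#' @param n_genes,n_peaks Numbers of genes and planted peaks.
#' @param frac_tss_peaks Probability a planted peak sits inside a TSS
#'   window (`+/- 1250` bp).
#' @param background_rate Background tags per bp per dataset (>= 0).
#' @param peak_depth Expected tags per peak per dataset at fold 1.
#' @param dataset_folds List with numeric vectors `shared` and
#'   `discordant` giving per-dataset enrichment multipliers; their names
#'   define the dataset labels.
#' @param frac_discordant Probability a planted peak is discordant.
#' @param duplicate_burst Numeric `c(prob, size)`: probability a
#'   background tag seeds a PCR burst, and the burst group size.
#' @param controls Labels of the control libraries.
#' @param control_hotspots Number of artifact hotspot positions planted in
#'   the first control.
#' @param hotspot_tags Tags per hotspot position (> 100 to model
#'   artifacts).
#' @param ortholog_frac Fraction of genes with a one-to-one partner in the
#'   second species.
#' @param cross_bound_concordance Probability the ortholog of a bound gene
#'   is bound in the second species.
#' @param cross_bound_rate Baseline boundness probability for the
#'   remaining second-species genes.
#' @param n_b_specific Second-species bound genes without an ortholog.
#' @param tag_jitter_sd SD (bp) of the Gaussian jitter added to planted
#'   tag 5' positions (fragment-length variability).
#' @param extension Fragment length assumed by the planted tag geometry:
#'   5' ends are uniform over `extension` bp upstream of the summit for
#'   `+` tags (downstream for `-`), i.e. a mean shift of half the
#'   elongation distance on each strand.
#' @param seed Integer seed; identical seeds give identical simulations.
#' @return A validated `simulation_design` list.
#' @export
simulation_design <- function(genome = data.frame(chrom = c("chr1", "chr2"),
                                                  length = c(800000L, 200000L),
                                                  stringsAsFactors = FALSE),
                              n_genes = 200, n_peaks = 120,
                              frac_tss_peaks = 0.8,
                              background_rate = 0.004, peak_depth = 60,
                              dataset_folds = list(
                                shared = c(endo = 1, wt = 1.2, mut = 0.9),
                                discordant = c(endo = 1, wt = 1, mut = 0.125)),
                              frac_discordant = 0.2,
                              duplicate_burst = c(prob = 0.02, size = 10),
                              controls = c("igg", "flag"),
                              control_hotspots = 2, hotspot_tags = 150,
                              ortholog_frac = 0.7,
                              cross_bound_concordance = 0.7,
                              cross_bound_rate = 0.1,
                              n_b_specific = 20,
                              tag_jitter_sd = 20, extension = 200,
                              seed = 1) {
  .chk(is.data.frame(genome) && all(c("chrom", "length") %in% names(genome)) &&
         all(genome$length > 0), "genome must be a data.frame(chrom, length > 0)")
  .chk(frac_tss_peaks >= 0 && frac_tss_peaks <= 1, "frac_tss_peaks in [0,1]")
  .chk(frac_discordant >= 0 && frac_discordant <= 1, "frac_discordant in [0,1]")
  .chk(background_rate >= 0, "background_rate must be >= 0")
  .chk(peak_depth >= 0, "peak_depth must be >= 0")
  .chk(is.list(dataset_folds) &&
         all(c("shared", "discordant") %in% names(dataset_folds)),
       "dataset_folds needs 'shared' and 'discordant' components")
  labels <- names(dataset_folds$shared)
  .chk(length(labels) >= 1 && identical(labels, names(dataset_folds$discordant)),
       "shared and discordant folds must name the same datasets")
  .chk(length(duplicate_burst) == 2 && duplicate_burst[1] >= 0 &&
         duplicate_burst[1] <= 1 && duplicate_burst[2] >= 1,
       "duplicate_burst must be c(prob in [0,1], size >= 1)")
  .chk(ortholog_frac >= 0 && ortholog_frac <= 1, "ortholog_frac in [0,1]")
  .chk(n_peaks == 0 || sum(frac_tss_peaks) <= 1, "invalid frac_tss_peaks")
  .chk(.is_scalar_num(seed), "seed must be a number")
  structure(list(genome = genome, n_genes = as.integer(n_genes),
                 n_peaks = as.integer(n_peaks),
                 frac_tss_peaks = frac_tss_peaks,
                 background_rate = background_rate, peak_depth = peak_depth,
                 dataset_folds = dataset_folds,
                 frac_discordant = frac_discordant,
                 duplicate_burst = unname(duplicate_burst),
                 controls = controls,
                 control_hotspots = as.integer(control_hotspots),
                 hotspot_tags = as.integer(hotspot_tags),
                 ortholog_frac = ortholog_frac,
                 cross_bound_concordance = cross_bound_concordance,
                 cross_bound_rate = cross_bound_rate,
                 n_b_specific = as.integer(n_b_specific),
                 tag_jitter_sd = tag_jitter_sd,
                 extension = as.integer(extension),
                 seed = seed),
            class = "simulation_design")
}

# Non-overlapping gene bodies on a per-chromosome slot grid.
.sim_genes <- function(design) {
  genome <- design$genome
  n <- design$n_genes
  per <- pmax(1L, as.integer(round(n * genome$length / sum(genome$length))))
  per[length(per)] <- max(1L, n - sum(per[-length(per)]))
  rows <- list()
  gi <- 0L
  for (ci in seq_len(nrow(genome))) {
    L <- genome$length[ci]
    g <- per[ci]
    slot <- L %/% g
    .chk(slot >= 1500, "genome too small for %d genes on %s", g,
         genome$chrom[ci])
    glen <- sample(1000:min(3000L, slot - 200L), g, replace = TRUE)
    offset <- vapply(slot - glen, function(m) sample.int(m, 1L), integer(1))
    start <- (seq_len(g) - 1L) * slot + offset
    rows[[ci]] <- data.frame(
      gene_id = sprintf("gA%04d", gi + seq_len(g)),
      chrom = genome$chrom[ci],
      strand = sample(c("+", "-"), g, replace = TRUE),
      start = as.integer(start),
      end = as.integer(start + glen),
      stringsAsFactors = FALSE)
    gi <- gi + g
  }
  genes <- do.call(rbind, rows)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes
}

# Plant peak summits: a Bernoulli(frac_tss_peaks) subset inside TSS windows
# of distinct genes, the rest in clear intergenic space, all mutually
# separated.
.sim_peaks <- function(design, genes) {
  n <- design$n_peaks
  empty <- data.frame(peak_id = character(), chrom = character(),
                      start = integer(), end = integer(), summit = integer(),
                      class = character(), tss_peak = logical(),
                      gene_id = character(), stringsAsFactors = FALSE)
  if (!n) return(empty)
  at_tss <- stats::runif(n) < design$frac_tss_peaks
  n_tss <- sum(at_tss)
  .chk(n_tss <= nrow(genes), "more TSS peaks requested than genes available")
  genome <- design$genome
  chrom <- character(n)
  summit <- integer(n)
  gene_id <- rep(NA_character_, n)
  host <- sample(nrow(genes), n_tss)
  tss_idx <- which(at_tss)
  chrom_len <- stats::setNames(genome$length, genome$chrom)
  for (j in seq_len(n_tss)) {
    g <- host[j]
    chrom[tss_idx[j]] <- genes$chrom[g]
    pos <- genes$tss[g] + sample(-1000:1000, 1L)
    summit[tss_idx[j]] <- min(max(pos, 250L),
                              chrom_len[[genes$chrom[g]]] - 250L)
    gene_id[tss_idx[j]] <- genes$gene_id[g]
  }
  # intergenic summits: keep clear of every TSS window and of other summits
  margin <- 1250L + 400L
  for (j in which(!at_tss)) {
    placed <- FALSE
    for (try in 1:2000) {
      ci <- sample.int(nrow(genome), 1L, prob = genome$length)
      pos <- sample.int(genome$length[ci] - 2000L, 1L) + 1000L
      same <- genes$chrom == genome$chrom[ci]
      if (any(abs(genes$tss[same] - pos) <= margin)) next
      prev <- summit[seq_len(n)] != 0L & chrom == genome$chrom[ci]
      if (any(abs(summit[prev] - pos) < 800L)) next
      chrom[j] <- genome$chrom[ci]
      summit[j] <- pos
      placed <- TRUE
      break
    }
    .chk(placed, "cannot fit %d non-overlapping peaks in this genome design",
         design$n_peaks)
  }
  cls <- ifelse(stats::runif(n) < design$frac_discordant,
                "discordant", "shared")
  data.frame(peak_id = sprintf("peak_%04d", seq_len(n)),
             chrom = chrom,
             start = as.integer(pmax(summit - 200L, 0L)),
             end = as.integer(summit + 200L),
             summit = summit, class = cls, tss_peak = at_tss,
             gene_id = gene_id, stringsAsFactors = FALSE)
}

# Background tags at a homogeneous Poisson rate over a genome.
.sim_background <- function(genome, rate) {
  rows <- lapply(seq_len(nrow(genome)), function(ci) {
    nbg <- stats::rpois(1L, rate * genome$length[ci])
    tag_frame(chrom = rep(genome$chrom[ci], nbg),
              five_prime = sample.int(genome$length[ci], nbg,
                                      replace = TRUE) - 1L,
              strand = sample(c("+", "-"), nbg, replace = TRUE))
  })
  do.call(rbind, rows)
}

#' Simulate a synthetic ChIP-Seq study
#'
#' @param design A [simulation_design()].
#' @param genome_sequence Whether to generate random genome sequence
#'   (needed only for summit-window FASTA export).
#' @return A list: `design`, `tags` (named list of tag frames, one per
#'   dataset), `controls` (named list of control tag frames), `genes`,
#'   `orthologs`, `genome` (a `DNAStringSet` or `NULL`), `chrom_sizes`,
#'   `library_sizes` (raw tag counts) and `truth`, a list of truth tables
#'   (`peaks`, `duplicates`, `hotspots`, `gene_binding`, `bound_b`).
#' @export
simulate_chipseq <- function(design, genome_sequence = TRUE) {
  .chk(inherits(design, "simulation_design"),
       "design must come from simulation_design()")
  .with_seed(design$seed, {
    genome <- design$genome
    chrom_sizes <- stats::setNames(as.integer(genome$length), genome$chrom)
    genes <- .sim_genes(design)
    peaks <- .sim_peaks(design, genes)
    labels <- names(design$dataset_folds$shared)
    fold_mat <- matrix(0, nrow(peaks), length(labels),
                       dimnames = list(NULL, labels))
    for (d in labels) {
      fold_mat[, d] <- ifelse(peaks$class == "shared",
                              design$dataset_folds$shared[[d]],
                              design$dataset_folds$discordant[[d]])
    }
    dup_rows <- list()
    tags <- list()
    for (d in labels) {
      bg <- .sim_background(genome, design$background_rate)
      planted <- list()
      for (i in seq_len(nrow(peaks))) {
        np <- stats::rpois(1L, design$peak_depth * fold_mat[i, d])
        if (!np) next
        strand <- sample(c("+", "-"), np, replace = TRUE)
        # fragment 5' ends uniform over the elongation distance upstream
        # (downstream for -), mean offset half the extension, so the
        # elongated pileup is triangular with its apex at the true summit
        offset <- sample.int(design$extension, np, replace = TRUE) - 1L
        shift <- ifelse(strand == "+", -offset, offset)
        fp <- peaks$summit[i] + shift +
          as.integer(round(stats::rnorm(np, 0, design$tag_jitter_sd)))
        fp <- pmin(pmax(fp, 0L), chrom_sizes[[peaks$chrom[i]]] - 1L)
        planted[[length(planted) + 1L]] <-
          tag_frame(chrom = rep(peaks$chrom[i], np), five_prime = fp,
                    strand = strand)
      }
      dtags <- rbind(bg, do.call(rbind, planted))
      # PCR-duplicate bursts: replicate a background start to burst size
      prob <- design$duplicate_burst[1]
      size <- as.integer(design$duplicate_burst[2])
      if (prob > 0 && size > 1 && nrow(bg)) {
        seed_idx <- which(stats::runif(nrow(bg)) < prob)
        if (length(seed_idx)) {
          extra <- bg[rep(seed_idx, each = size - 1L), , drop = FALSE]
          dtags <- rbind(dtags, extra)
          dup_rows[[d]] <- data.frame(dataset = d,
                                      chrom = bg$chrom[seed_idx],
                                      strand = bg$strand[seed_idx],
                                      five_prime = bg$five_prime[seed_idx],
                                      size = size, stringsAsFactors = FALSE)
        }
      }
      rownames(dtags) <- NULL
      tags[[d]] <- dtags
    }
    controls <- list()
    hot_rows <- list()
    for (ci in seq_along(design$controls)) {
      cl <- design$controls[ci]
      ctags <- .sim_background(genome, design$background_rate)
      if (ci == 1L && design$control_hotspots > 0 && nrow(peaks)) {
        nh <- min(design$control_hotspots, nrow(peaks))
        for (h in seq_len(nh)) {
          ctags <- rbind(ctags,
                         tag_frame(chrom = rep(peaks$chrom[h],
                                               design$hotspot_tags),
                                   five_prime = rep(peaks$summit[h],
                                                    design$hotspot_tags),
                                   strand = rep("+", design$hotspot_tags)))
        }
        hot_rows[[cl]] <- data.frame(control = cl,
                                     chrom = peaks$chrom[seq_len(nh)],
                                     strand = "+",
                                     five_prime = peaks$summit[seq_len(nh)],
                                     n_tags = design$hotspot_tags,
                                     peak_id = peaks$peak_id[seq_len(nh)],
                                     stringsAsFactors = FALSE)
      }
      rownames(ctags) <- NULL
      controls[[cl]] <- ctags
    }
    # truth: gene boundness by planted peaks at the two standard windows
    gene_binding <- data.frame(gene_id = genes$gene_id,
                               bound_1250 = FALSE, bound_10000 = FALSE,
                               stringsAsFactors = FALSE)
    for (hw in c(1250L, 10000L)) {
      col <- paste0("bound_", hw)
      for (gi in seq_len(nrow(genes))) {
        same <- peaks$chrom == genes$chrom[gi]
        if (!any(same)) next
        tssv <- genes$tss[gi]
        gene_binding[[col]][gi] <- any(
          peaks$start[same] < tssv + hw + 1L & peaks$end[same] > tssv - hw)
      }
    }
    # second species: one-to-one partners plus species-specific bound genes
    paired <- which(stats::runif(nrow(genes)) < design$ortholog_frac)
    orthologs <- data.frame(gene_a = genes$gene_id[paired],
                            gene_b = sub("^gA", "gB", genes$gene_id[paired]),
                            stringsAsFactors = FALSE)
    a_bound <- gene_binding$gene_id[gene_binding$bound_10000]
    p_b <- ifelse(orthologs$gene_a %in% a_bound,
                  design$cross_bound_concordance, design$cross_bound_rate)
    bound_b <- orthologs$gene_b[stats::runif(nrow(orthologs)) < p_b]
    if (design$n_b_specific > 0) {
      bound_b <- c(bound_b, sprintf("gBx%03d", seq_len(design$n_b_specific)))
    }
    genome_seq <- NULL
    if (genome_sequence) {
      genome_seq <- Biostrings::DNAStringSet(vapply(
        seq_len(nrow(genome)),
        function(ci) paste(sample(c("A", "C", "G", "T"), genome$length[ci],
                                  replace = TRUE), collapse = ""),
        character(1)))
      names(genome_seq) <- genome$chrom
    }
    truth_peaks <- peaks
    for (d in labels) truth_peaks[[paste0("fold_", d)]] <- fold_mat[, d]
    truth_peaks$control_artifact <-
      truth_peaks$peak_id %in% unlist(lapply(hot_rows, `[[`, "peak_id"))
    empty_dup <- data.frame(dataset = character(), chrom = character(),
                            strand = character(), five_prime = integer(),
                            size = integer(), stringsAsFactors = FALSE)
    empty_hot <- data.frame(control = character(), chrom = character(),
                            strand = character(), five_prime = integer(),
                            n_tags = integer(), peak_id = character(),
                            stringsAsFactors = FALSE)
    truth <- list(
      peaks = truth_peaks,
      duplicates = if (length(dup_rows)) {
        out <- do.call(rbind, dup_rows); rownames(out) <- NULL; out
      } else empty_dup,
      hotspots = if (length(hot_rows)) {
        out <- do.call(rbind, hot_rows); rownames(out) <- NULL; out
      } else empty_hot,
      gene_binding = gene_binding,
      bound_b = data.frame(gene_b = bound_b, stringsAsFactors = FALSE))
    list(design = design, tags = tags, controls = controls, genes = genes,
         orthologs = orthologs, genome = genome_seq,
         chrom_sizes = chrom_sizes,
         library_sizes = vapply(tags, nrow, integer(1)),
         truth = truth)
  })
}

#' Write a simulation to disk in the documented formats
#'
#' @param sim Output of [simulate_chipseq()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "tags"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "controls"), showWarnings = FALSE)
  for (d in names(sim$tags)) {
    write_tags(sim$tags[[d]], file.path(dir, "tags", paste0(d, ".bed")))
  }
  for (cl in names(sim$controls)) {
    write_tags(sim$controls[[cl]], file.path(dir, "controls",
                                             paste0(cl, ".bed")))
  }
  write_gene_models(sim$genes, file.path(dir, "genes.tsv"))
  write_ortholog_map(sim$orthologs, file.path(dir, "orthologs.tsv"))
  .write_tsv(data.frame(dataset = names(sim$library_sizes),
                        library_size = as.integer(sim$library_sizes),
                        stringsAsFactors = FALSE),
             file.path(dir, "library_sizes.tsv"),
             comment = "raw tag counts per dataset")
  if (!is.null(sim$genome)) {
    Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  }
  write_truth(sim$truth, file.path(dir, "truth"))
  invisible(dir)
}

#' Write truth tables as TSV
#'
#' @param truth Truth list from [simulate_chipseq()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("peaks", "duplicates", "hotspots", "gene_binding", "bound_b")) {
    .chk(nm %in% names(truth), "truth is missing component '%s'", nm)
    .write_tsv(truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
               comment = paste("synthetic truth:", nm))
  }
  invisible(dir)
}

#' Read truth tables written by [write_truth()]
#'
#' @param dir Directory holding the `truth_*.tsv` files.
#' @return Truth list with the original column types (lossless round
#'   trip).
#' @export
read_truth <- function(dir) {
  coerce <- function(df, ints = character(), dbls = character(),
                     lgls = character()) {
    for (cl in names(df)) {
      if (cl %in% ints) df[[cl]] <- as.integer(df[[cl]])
      else if (cl %in% dbls || grepl("^fold_", cl)) df[[cl]] <- as.numeric(df[[cl]])
      else if (cl %in% lgls) df[[cl]] <- as.logical(df[[cl]])
      else df[[cl]] <- as.character(df[[cl]])
    }
    df
  }
  peaks <- coerce(.read_tsv(file.path(dir, "truth_peaks.tsv")),
                  ints = c("start", "end", "summit"),
                  lgls = c("tss_peak", "control_artifact"))
  duplicates <- coerce(.read_tsv(file.path(dir, "truth_duplicates.tsv")),
                       ints = c("five_prime", "size"))
  hotspots <- coerce(.read_tsv(file.path(dir, "truth_hotspots.tsv")),
                     ints = c("five_prime", "n_tags"))
  gene_binding <- coerce(.read_tsv(file.path(dir, "truth_gene_binding.tsv")),
                         lgls = c("bound_1250", "bound_10000"))
  bound_b <- coerce(.read_tsv(file.path(dir, "truth_bound_b.tsv")))
  list(peaks = peaks, duplicates = duplicates, hotspots = hotspots,
       gene_binding = gene_binding, bound_b = bound_b)
}
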