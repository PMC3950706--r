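# Gene-centric annotation of peaks: TSS association, genomic-location
# classification, bound-gene derivation, cross-species ortholog Venn,
# TSS metaprofiles and per-TSS tag-count distributions.

# Closed TSS +/- half_window ranges, stored half-open, clipped at 0.
.tss_windows <- function(genes, half_window) {
  .chk(.is_scalar_num(half_window) && half_window >= 0,
       "half_window must be >= 0")
  half_window <- as.integer(half_window)
  data.frame(chrom = genes$chrom,
             start = pmax(genes$tss - half_window, 0L),
             end = genes$tss + half_window + 1L,
             stringsAsFactors = FALSE)
}

#' Associate peaks with TSS windows
#'
#' A peak associates with a gene when the peak interval intersects the
#' closed `TSS +/- half_window` range. The association is many-to-many.
#'
#' @param peaks A peak data frame.
#' @param genes Gene models from [read_gene_models()].
#' @param half_window Window half-width in bp (default 1250).
#' @return A list: `pairs` (data frame `peak_index, gene_id`, ordered by
#'   peak then gene), `gene_to_peaks` (named list gene_id -> sorted peak
#'   indices) and `peak_to_genes` (named list peak index -> gene ids).
#' @export
associate_peaks_tss <- function(peaks, genes, half_window = 1250) {
  validate_intervals(peaks)
  tw <- .tss_windows(genes, half_window)
  empty <- data.frame(peak_index = integer(), gene_id = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(peaks) || !nrow(genes)) {
    return(list(pairs = empty, gene_to_peaks = list(), peak_to_genes = list()))
  }
  hits <- GenomicRanges::findOverlaps(.to_granges(peaks), .to_granges(tw))
  pairs <- data.frame(peak_index = S4Vectors::queryHits(hits),
                      gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$peak_index, pairs$gene_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       gene_to_peaks = lapply(split(pairs$peak_index, pairs$gene_id), sort),
       peak_to_genes = lapply(split(pairs$gene_id, pairs$peak_index), sort))
}

#' Classify peak locations relative to gene models
#'
#' Priority rule making categories exclusive and exhaustive: a peak
#' overlapping any TSS window is `tss_proximal`; otherwise a peak
#' overlapping any gene body is `intragenic`; otherwise `intergenic`.
#'
#' @inheritParams associate_peaks_tss
#' @return A list: `category`, a factor (one level per peak), and
#'   `breakdown` with counts `n_tss_proximal`, `n_intragenic`,
#'   `n_intergenic` and the corresponding `fractions` (summing to 1).
#' @export
classify_locations <- function(peaks, genes, half_window = 1250) {
  validate_intervals(peaks)
  lv <- c("tss_proximal", "intragenic", "intergenic")
  if (!nrow(peaks)) {
    breakdown <- list(n_tss_proximal = 0L, n_intragenic = 0L,
                      n_intergenic = 0L,
                      fractions = stats::setNames(rep(NA_real_, 3), lv))
    return(list(category = factor(character(), levels = lv),
                breakdown = breakdown))
  }
  pk_gr <- .to_granges(peaks)
  at_tss <- IRanges::overlapsAny(pk_gr, .to_granges(.tss_windows(genes, half_window)))
  in_body <- IRanges::overlapsAny(pk_gr, .to_granges(genes))
  category <- factor(ifelse(at_tss, "tss_proximal",
                            ifelse(in_body, "intragenic", "intergenic")),
                     levels = lv)
  counts <- table(category)
  breakdown <- list(n_tss_proximal = as.integer(counts[["tss_proximal"]]),
                    n_intragenic = as.integer(counts[["intragenic"]]),
                    n_intergenic = as.integer(counts[["intergenic"]]),
                    fractions = as.numeric(counts) / nrow(peaks))
  names(breakdown$fractions) <- lv
  list(category = category, breakdown = breakdown)
}

#' Derive the set of bound genes
#'
#' A gene is bound when at least one peak intersects its
#' `TSS +/- half_window` range; each gene is reported once.
#'
#' @inheritParams associate_peaks_tss
#' @return Sorted character vector of bound gene ids.
#' @export
bound_genes <- function(peaks, genes, half_window = 1250) {
  assoc <- associate_peaks_tss(peaks, genes, half_window)
  sort(unique(assoc$pairs$gene_id))
}

#' Cross-species bound-gene Venn via one-to-one orthologs
#'
#' Each ortholog pair is tallied by whether its members are bound in
#' species A, species B, or both; bound genes without a one-to-one partner
#' are tallied as species-specific.
#'
#' @param bound_a,bound_b Character vectors of bound gene ids in the two
#'   species.
#' @param pairs One-to-one ortholog map (`gene_a, gene_b`), e.g. from
#'   [read_ortholog_map()].
#' @return A `homology_venn` list: `n_both`, `n_a_only`, `n_b_only`,
#'   `n_a_specific`, `n_b_specific`.
#' @export
homology_venn <- function(bound_a, bound_b, pairs) {
  .chk(all(c("gene_a", "gene_b") %in% names(pairs)),
       "pairs needs gene_a, gene_b columns")
  .chk(!anyDuplicated(pairs$gene_a) && !anyDuplicated(pairs$gene_b),
       "ortholog pairs must be one-to-one")
  bound_a <- unique(bound_a)
  bound_b <- unique(bound_b)
  a_in <- pairs$gene_a %in% bound_a
  b_in <- pairs$gene_b %in% bound_b
  structure(list(n_both = sum(a_in & b_in),
                 n_a_only = sum(a_in & !b_in),
                 n_b_only = sum(!a_in & b_in),
                 n_a_specific = sum(!(bound_a %in% pairs$gene_a)),
                 n_b_specific = sum(!(bound_b %in% pairs$gene_b))),
            class = "homology_venn")
}

#' @export
print.homology_venn <- function(x, ...) {
  cat("Cross-species bound-gene comparison (one-to-one orthologs)\n")
  cat(sprintf("  bound in both species:        %d pairs\n", x$n_both))
  cat(sprintf("  bound in species A only:      %d pairs\n", x$n_a_only))
  cat(sprintf("  bound in species B only:      %d pairs\n", x$n_b_only))
  cat(sprintf("  species-A-specific (no pair): %d genes\n", x$n_a_specific))
  cat(sprintf("  species-B-specific (no pair): %d genes\n", x$n_b_specific))
  invisible(x)
}

#' Average coverage profile around TSSs
#'
#' Per gene, elongated-tag coverage over `[TSS - flank, TSS + flank)` in
#' strand orientation (positive offsets downstream); the per-base mean over
#' genes (weighting each base by the genes whose window is valid there
#' after clipping at the chromosome start) is averaged within bins and
#' scaled by [normalization_factor()].
#'
#' @param tags Tag data frame (filtered).
#' @param genes Gene models.
#' @param library_size Usable-read count of the tag library.
#' @param flank Half-width of the profile in bp; must be divisible by
#'   `bin`.
#' @param bin Bin width in bp.
#' @param extension Fragment length for elongation.
#' @param reference Reference depth for normalization.
#' @return A `coverage_profile` list: `bin_offsets` (left edge of each bin
#'   relative to the TSS), `values`, `n_tss`, `library_size`.
#' @export
tss_metaprofile <- function(tags, genes, library_size, flank = 2500,
                            bin = 25, extension = 200, reference = 2e7) {
  validate_tags(tags)
  .chk(.is_scalar_num(flank) && flank >= bin, "flank must be >= bin")
  .chk(.is_scalar_num(bin) && bin >= 1 && flank %% bin == 0,
       "flank must be divisible by bin")
  flank <- as.integer(flank)
  bin <- as.integer(bin)
  width <- 2L * flank
  sums <- numeric(width)
  cnt <- numeric(width)
  for (i in seq_len(nrow(genes))) {
    tss <- genes$tss[i]
    ch <- genes$chrom[i]
    ctags <- tags[tags$chrom == ch, , drop = FALSE]
    if (genes$strand[i] == "+") {
      lo <- tss - flank
      hi <- tss + flank
      clo <- max(lo, 0L)
      if (clo >= hi) next
      cov <- tag_coverage(ctags, list(chrom = ch, start = clo, end = hi),
                          extension)
      idx <- (clo - lo + 1L):width
    } else {
      lo <- tss - flank + 1L
      hi <- tss + flank + 1L
      clo <- max(lo, 0L)
      if (clo >= hi) next
      cov <- rev(tag_coverage(ctags, list(chrom = ch, start = clo, end = hi),
                              extension))
      idx <- seq_len(hi - clo)
    }
    sums[idx] <- sums[idx] + cov
    cnt[idx] <- cnt[idx] + 1
  }
  per_base <- ifelse(cnt > 0, sums / cnt, 0)
  nb <- width %/% bin
  values <- vapply(seq_len(nb), function(b) {
    mean(per_base[((b - 1L) * bin + 1L):(b * bin)])
  }, numeric(1)) * normalization_factor(library_size, reference)
  structure(list(bin_offsets = seq.int(-flank, flank - bin, by = bin),
                 values = values, n_tss = nrow(genes),
                 library_size = library_size),
            class = "coverage_profile")
}

#' Per-TSS tag-count distributions
#'
#' For each labelled TSS set, counts tags (5' ends) inside each member
#' gene's `TSS +/- half_window` range and returns the empirical
#' distribution, ready for cumulative plotting and stochastic-dominance
#' comparison between sets (e.g. all TSSs vs bound TSSs).
#'
#' @param tags Tag data frame (e.g. RNA Pol II ChIP tags).
#' @param tss_sets Named list of gene-id vectors.
#' @param genes Gene models.
#' @param half_window Counting window half-width in bp.
#' @return Named list of data frames `tag_count, cum_fraction`, sorted by
#'   count.
#' @export
tss_count_distribution <- function(tags, tss_sets, genes,
                                   half_window = 1250) {
  validate_tags(tags)
  .chk(is.list(tss_sets) && !is.null(names(tss_sets)),
       "tss_sets must be a named list of gene-id vectors")
  tw <- .tss_windows(genes, half_window)
  counts_all <- .count_in_intervals(tags, tw)
  lapply(tss_sets, function(ids) {
    idx <- match(ids, genes$gene_id)
    .chk(!anyNA(idx), "unknown gene id(s) in TSS set")
    v <- sort(counts_all[idx])
    data.frame(tag_count = v,
               cum_fraction = seq_along(v) / length(v))
  })
}
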