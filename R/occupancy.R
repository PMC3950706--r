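# Multi-dataset occupancy comparison: merging FDR-selected peak sets into
# regions, depth-normalized per-region counts, fold-tolerance membership,
# Venn partitioning, and summit detection by elongated-tag pileup.

#' Merge FDR-selected peak sets across datasets
#'
#' Intervals from all datasets are pooled; each connected component of
#' their per-base union (overlapping or book-ended intervals) becomes one
#' merged region spanning the component.
#'
#' @param peak_sets Named list of peak data frames, one per dataset. All
#'   peaks must already pass `fdr <= fdr_cutoff` (apply [filter_fdr()]
#'   first); this precondition is asserted.
#' @param fdr_cutoff The cutoff the inputs are expected to satisfy.
#' @return A region data frame `region_id, chrom, start, end` with a
#'   list-column `contributors` naming the datasets whose peaks were
#'   merged into each region, ordered by chrom then start.
#' @export
merge_peak_sets <- function(peak_sets, fdr_cutoff = 0.001) {
  .chk(is.list(peak_sets) && !is.null(names(peak_sets)) &&
         all(nzchar(names(peak_sets))),
       "peak_sets must be a named list of peak data frames")
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  empty$contributors <- list()
  pooled <- list()
  for (nm in names(peak_sets)) {
    pk <- peak_sets[[nm]]
    validate_peaks(pk)
    if (!nrow(pk)) next
    .chk(!anyNA(pk$fdr) && all(pk$fdr <= fdr_cutoff),
         "peaks in '%s' exceed fdr %s; apply filter_fdr() first", nm,
         format(fdr_cutoff))
    pooled[[nm]] <- data.frame(chrom = pk$chrom, start = pk$start,
                               end = pk$end, dataset = nm,
                               stringsAsFactors = FALSE)
  }
  if (!length(pooled)) return(empty)
  all_pk <- do.call(rbind, pooled)
  gr <- .to_granges(all_pk)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  hits <- GenomicRanges::findOverlaps(gr, red)
  contrib <- split(all_pk$dataset[S4Vectors::queryHits(hits)],
                   S4Vectors::subjectHits(hits))
  regions <- .from_granges(red)
  regions$contributors <- unname(lapply(
    contrib[as.character(seq_len(nrow(regions)))],
    function(d) sort(unique(d))))
  ord <- order(regions$chrom, regions$start)
  regions <- regions[ord, , drop = FALSE]
  rownames(regions) <- NULL
  regions$region_id <- sprintf("region_%05d", seq_len(nrow(regions)))
  regions[, c("region_id", "chrom", "start", "end", "contributors")]
}

#' Fill depth-normalized per-dataset tag counts for merged regions
#'
#' @param regions Output of [merge_peak_sets()].
#' @param tag_sets Named list of (filtered) tag data frames covering every
#'   dataset in the analysis design.
#' @param library_sizes Named numeric vector of usable-read counts per
#'   dataset.
#' @param reference Reference depth for normalization (default 2e7).
#' @return `regions` with one `count_<dataset>` column per dataset
#'   (5'-in-region tag count times the library normalization factor) and a
#'   `count_labels` attribute naming the datasets.
#' @export
region_counts <- function(regions, tag_sets, library_sizes, reference = 2e7) {
  .chk(is.list(tag_sets) && !is.null(names(tag_sets)),
       "tag_sets must be a named list")
  labels <- names(tag_sets)
  used <- unique(unlist(regions$contributors, use.names = FALSE))
  missing <- setdiff(used, labels)
  .chk(length(missing) == 0, "tag_sets missing dataset(s): %s",
       paste(missing, collapse = ", "))
  .chk(all(labels %in% names(library_sizes)),
       "library_sizes must cover every dataset in tag_sets")
  .chk(all(library_sizes[labels] >= 1), "library sizes must be positive")
  for (d in labels) {
    validate_tags(tag_sets[[d]])
    raw <- .count_in_intervals(tag_sets[[d]], regions)
    regions[[paste0("count_", d)]] <-
      raw * normalization_factor(library_sizes[[d]], reference)
  }
  attr(regions, "count_labels") <- labels
  regions
}

#' Fold-tolerance membership of merged regions
#'
#' A dataset is called present in a region when its normalized count is
#' within a factor `k` of the region's maximum count:
#' `counts[d] >= max(counts) / k`. Regions with all-zero counts fall back
#' to their contributing datasets. Membership is monotone in `k`.
#'
#' @param regions Regions with counts filled by [region_counts()].
#' @param k Fold tolerance (`k >= 1`).
#' @return List of character vectors (dataset labels), one per region.
#' @export
fold_membership <- function(regions, k) {
  .chk(.is_scalar_num(k) && k >= 1, "k must be >= 1")
  labels <- attr(regions, "count_labels")
  .chk(!is.null(labels), "region counts not filled; run region_counts() first")
  cm <- as.matrix(regions[, paste0("count_", labels), drop = FALSE])
  m <- do.call(pmax, as.data.frame(cm))
  lapply(seq_len(nrow(regions)), function(i) {
    if (m[i] <= 0) {
      sort(regions$contributors[[i]])
    } else {
      labels[cm[i, ] >= m[i] / k]
    }
  })
}

#' Venn partition of merged regions at a fold tolerance
#'
#' @param regions Regions with counts filled.
#' @param k Fold tolerance.
#' @return A `venn_partition` list: `k`, and `cells`, a named integer
#'   vector keyed by the sorted dataset subset (labels joined with `&`).
#'   Cell counts sum to the number of regions.
#' @export
venn_partition <- function(regions, k) {
  mem <- fold_membership(regions, k)
  keys <- vapply(mem, function(s) paste(sort(s), collapse = "&"), character(1))
  tab <- table(keys)
  cells <- as.integer(tab)
  names(cells) <- names(tab)
  structure(list(k = k, cells = cells, n_regions = nrow(regions)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Venn partition at fold tolerance k = %s (%d regions)\n",
              format(x$k), x$n_regions))
  for (nm in names(x$cells)) cat(sprintf("  %-30s %d\n", nm, x$cells[[nm]]))
  invisible(x)
}

#' Locate summits of regions by pooled elongated-tag pileup
#'
#' For each region the per-base coverage of pooled elongated tags is
#' computed; the summit is the midpoint of the leftmost maximal plateau
#' (`position = floor((plateau_start + plateau_end - 1) / 2)` on the
#' half-open plateau). Regions with zero coverage are flagged and get the
#' region midpoint.
#'
#' @param regions Interval data frame (e.g. merged regions).
#' @param pooled_tags Tags pooled across all datasets (filtered,
#'   unnormalized).
#' @param extension Fragment length for elongation.
#' @return Data frame `chrom, position, height, plateau_start,
#'   plateau_end, flagged`, one row per region, plus the region's
#'   `region_id` when present.
#' @export
compute_summits <- function(regions, pooled_tags, extension = 200) {
  validate_intervals(regions)
  validate_tags(pooled_tags)
  n <- nrow(regions)
  position <- integer(n)
  height <- integer(n)
  ps <- integer(n)
  pe <- integer(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    ch <- regions$chrom[i]
    s <- regions$start[i]
    e <- regions$end[i]
    near <- pooled_tags[pooled_tags$chrom == ch &
                          pooled_tags$five_prime >= s - extension &
                          pooled_tags$five_prime <= e + extension, ,
                        drop = FALSE]
    cov <- tag_coverage(near, list(chrom = ch, start = s, end = e), extension)
    h <- max(cov)
    if (h == 0L) {
      position[i] <- as.integer((s + e - 1) %/% 2)
      height[i] <- 0L
      ps[i] <- s
      pe[i] <- e
      flagged[i] <- TRUE
    } else {
      runs <- rle(cov == h)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      j <- which(runs$values)[1L]
      ps[i] <- s + starts[j] - 1L
      pe[i] <- s + ends[j]
      position[i] <- as.integer((ps[i] + pe[i] - 1) %/% 2)
      height[i] <- h
    }
  }
  out <- data.frame(chrom = regions$chrom, position = position,
                    height = height, plateau_start = ps, plateau_end = pe,
                    flagged = flagged, stringsAsFactors = FALSE)
  if ("region_id" %in% names(regions)) {
    out <- cbind(region_id = regions$region_id, out,
                 stringsAsFactors = FALSE)
  }
  out
}

#' Fixed-width windows around summits
#'
#' Each window is the closed `position +/- half_width` range, stored
#' half-open as `[position - half_width, position + half_width + 1)` and
#' clipped at chromosome bounds; away from boundaries the width is
#' `2 * half_width + 1`.
#'
#' @param summits Output of [compute_summits()] (needs `chrom`,
#'   `position`).
#' @param half_width Window half-width in bp (default 150).
#' @param chrom_sizes Optional named vector of chromosome lengths for
#'   right-clipping.
#' @return Interval data frame suitable for [extract_sequences()].
#' @export
summit_windows <- function(summits, half_width = 150, chrom_sizes = NULL) {
  .chk(.is_scalar_num(half_width) && half_width >= 0,
       "half_width must be >= 0")
  half_width <- as.integer(half_width)
  start <- pmax(summits$position - half_width, 0L)
  end <- summits$position + half_width + 1L
  if (!is.null(chrom_sizes)) {
    .chk(all(summits$chrom %in% names(chrom_sizes)),
         "chrom_sizes must cover every summit chromosome")
    end <- pmin(end, as.integer(chrom_sizes[summits$chrom]))
  }
  data.frame(chrom = summits$chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}
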