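# Tag-level processing: the duplicate filter with censoring of
# over-amplified start positions, tag counting, strand-aware read
# elongation, per-base coverage and library-size normalization.

#' Filter tags by start-position multiplicity
#'
#' Tags are grouped by (chrom, strand, five_prime). Groups larger than
#' `censor_above` are censored entirely (treated as PCR artifacts and
#' dropped); remaining groups are capped at `max_per_start` retained tags.
#' Defaults reproduce the standard regime of at most two reads per start
#' position with censoring of positions carrying more than seven reads.
#'
#' @param tags A tag data frame.
#' @param max_per_start Maximum tags retained per start position.
#' @param censor_above Group size above which the whole position is dropped.
#' @return A list with `tags` (retained, sorted by chrom, five_prime,
#'   strand) and `report`, a filter-report list with fields
#'   `n_input`, `n_retained`, `n_duplicates_removed`, `n_censored` and a
#'   data frame `censored_positions`. Counts always satisfy
#'   `n_input = n_retained + n_duplicates_removed + n_censored`.
#' @export
filter_tags <- function(tags, max_per_start = 2, censor_above = 7) {
  validate_tags(tags)
  .chk(.is_scalar_num(max_per_start) && max_per_start >= 1,
       "max_per_start must be >= 1")
  .chk(.is_scalar_num(censor_above) && censor_above >= max_per_start,
       "censor_above must be >= max_per_start")
  n_input <- nrow(tags)
  empty_pos <- data.frame(chrom = character(), strand = character(),
                          five_prime = integer(), n_tags = integer(),
                          stringsAsFactors = FALSE)
  if (!n_input) {
    return(list(tags = tags,
                report = list(n_input = 0L, n_retained = 0L,
                              n_duplicates_removed = 0L, n_censored = 0L,
                              censored_positions = empty_pos)))
  }
  ord <- order(tags$chrom, tags$five_prime, tags$strand)
  t2 <- tags[ord, , drop = FALSE]
  key <- paste(t2$chrom, t2$strand, t2$five_prime, sep = "\r")
  grp <- rle(key)
  size <- grp$lengths
  censored <- size > censor_above
  keep_n <- ifelse(censored, 0L, pmin(size, as.integer(max_per_start)))
  first <- cumsum(c(1L, size[-length(size)]))
  keep_idx <- sequence(keep_n) + rep(first, keep_n) - 1L
  out <- t2[keep_idx, , drop = FALSE]
  rownames(out) <- NULL
  cens_first <- first[censored]
  cens_pos <- if (length(cens_first)) {
    data.frame(chrom = t2$chrom[cens_first], strand = t2$strand[cens_first],
               five_prime = t2$five_prime[cens_first],
               n_tags = size[censored], stringsAsFactors = FALSE)
  } else empty_pos
  n_censored <- sum(size[censored])
  report <- list(n_input = n_input,
                 n_retained = nrow(out),
                 n_duplicates_removed = n_input - nrow(out) - n_censored,
                 n_censored = as.integer(n_censored),
                 censored_positions = cens_pos)
  list(tags = out, report = report)
}

#' Elongate tags to fixed-length fragments
#'
#' A tag's 5' position anchors an `extension`-bp footprint in read
#' direction: `[five_prime, five_prime + extension)` on `+`,
#' `[five_prime - extension + 1, five_prime + 1)` on `-`, clipped at 0.
#'
#' @param tags A tag data frame.
#' @param extension Fragment length in bp (default 200).
#' @return Interval data frame with a `strand` column.
#' @export
elongate <- function(tags, extension = 200) {
  validate_tags(tags)
  .chk(.is_scalar_num(extension) && extension >= 1, "extension must be >= 1")
  extension <- as.integer(extension)
  plus <- tags$strand == "+"
  start <- ifelse(plus, tags$five_prime, tags$five_prime - extension + 1L)
  end <- ifelse(plus, tags$five_prime + extension, tags$five_prime + 1L)
  data.frame(chrom = tags$chrom,
             start = as.integer(pmax(start, 0L)),
             end = as.integer(end),
             strand = tags$strand,
             stringsAsFactors = FALSE)
}

#' Count tags in an interval
#'
#' @param tags A tag data frame.
#' @param interval A single interval (list or one-row data frame with
#'   `chrom`, `start`, `end`).
#' @param mode `"five_prime_in"` counts tags whose 5' end lies in
#'   `[start, end)`; `"overlap_extended"` counts tags whose elongated
#'   footprint intersects the interval.
#' @param extension Fragment length for `overlap_extended`.
#' @return Integer count.
#' @export
count_tags <- function(tags, interval,
                       mode = c("five_prime_in", "overlap_extended"),
                       extension = 200) {
  mode <- match.arg(mode)
  validate_tags(tags)
  interval <- .as_interval(interval)
  if (mode == "five_prime_in") {
    sum(tags$chrom == interval$chrom &
          tags$five_prime >= interval$start &
          tags$five_prime < interval$end)
  } else {
    ext <- elongate(tags, extension)
    sum(ext$chrom == interval$chrom &
          ext$start < interval$end &
          ext$end > interval$start)
  }
}

#' Per-base coverage of elongated tags over an interval
#'
#' @param tags A tag data frame.
#' @param interval A single interval.
#' @param extension Fragment length in bp.
#' @return Integer vector of length `end - start`; element `i` is the
#'   number of elongated tags covering base `start + i - 1`.
#' @export
tag_coverage <- function(tags, interval, extension = 200) {
  validate_tags(tags)
  interval <- .as_interval(interval)
  len <- as.integer(interval$end - interval$start)
  if (!nrow(tags)) return(integer(len))
  ext <- elongate(tags[tags$chrom == interval$chrom, , drop = FALSE],
                  extension)
  s <- pmax(ext$start, interval$start) - interval$start
  e <- pmin(ext$end, interval$end) - interval$start
  ok <- which(e > s)
  if (!length(ok)) return(integer(len))
  delta <- tabulate(s[ok] + 1L, nbins = len + 1L) -
    tabulate(e[ok] + 1L, nbins = len + 1L)
  as.integer(cumsum(delta)[seq_len(len)])
}

#' Library-size normalization factor
#'
#' Scales tag counts to a common reference depth (20 million usable reads
#' by default), so counts from libraries of different depth are comparable.
#'
#' @param library_size Number of usable reads in the library.
#' @param reference Reference depth (default 2e7).
#' @return `reference / library_size`.
#' @export
normalization_factor <- function(library_size, reference = 2e7) {
  .chk(.is_scalar_num(library_size) && library_size >= 1,
       "library_size must be a positive count")
  .chk(.is_scalar_num(reference) && reference >= 1,
       "reference must be a positive count")
  reference / library_size
}
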