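# Internal helpers shared across modules. All genomic coordinates in this
# package are 0-based half-open ([start, end)), the BED convention; the
# Bioconductor 1-based closed convention is entered only transiently inside
# .to_granges()/.from_granges().

.chk <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}

.is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Validate a tag data frame
#'
#' Tags are aligned sequencing reads reduced to chromosome, 5' position and
#' strand. A valid tag frame has character `chrom`, integer `five_prime >= 0`
#' and `strand` in `{"+", "-"}`.
#'
#' @param tags A data frame with columns `chrom`, `five_prime`, `strand`.
#' @return The input, invisibly, or an error describing the violation.
#' @export
validate_tags <- function(tags) {
  .chk(is.data.frame(tags), "tags must be a data.frame")
  .chk(all(c("chrom", "five_prime", "strand") %in% names(tags)),
       "tags must have columns chrom, five_prime, strand")
  if (nrow(tags)) {
    .chk(!anyNA(tags$five_prime) && all(tags$five_prime >= 0),
         "five_prime positions must be non-negative")
    .chk(all(tags$strand %in% c("+", "-")),
         "strand must be '+' or '-'")
  }
  invisible(tags)
}

#' Construct a tag data frame
#'
#' @param chrom Chromosome names.
#' @param five_prime 0-based coordinates of read 5' ends.
#' @param strand `"+"` or `"-"` per tag.
#' @return A validated data frame of tags.
#' @export
tag_frame <- function(chrom = character(), five_prime = integer(),
                      strand = character()) {
  df <- data.frame(chrom = as.character(chrom),
                   five_prime = as.integer(five_prime),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_tags(df)
  df
}

#' Validate an interval data frame
#'
#' Intervals are 0-based half-open `[start, end)` with `0 <= start < end`.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @return The input, invisibly.
#' @export
validate_intervals <- function(x) {
  .chk(is.data.frame(x), "intervals must be a data.frame")
  .chk(all(c("chrom", "start", "end") %in% names(x)),
       "intervals must have columns chrom, start, end")
  if (nrow(x)) {
    .chk(!anyNA(x$start) && !anyNA(x$end), "interval bounds must not be NA")
    .chk(all(x$start >= 0), "interval start must be >= 0")
    .chk(all(x$start < x$end), "intervals must satisfy start < end")
  }
  invisible(x)
}

# Coerce a single interval given as list or one-row data frame.
.as_interval <- function(interval) {
  if (is.data.frame(interval)) {
    .chk(nrow(interval) == 1L, "expected a single interval")
    interval <- as.list(interval[1L, c("chrom", "start", "end")])
  }
  .chk(all(c("chrom", "start", "end") %in% names(interval)),
       "interval needs chrom, start, end")
  .chk(interval$start >= 0 && interval$start < interval$end,
       "interval must satisfy 0 <= start < end")
  interval
}

# 0-based half-open -> GRanges (1-based closed) and back.
.to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

.from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# Count tags whose five_prime falls in each half-open interval
# (vectorised over intervals; the workhorse behind count_tags and friends).
.count_in_intervals <- function(tags, intervals) {
  counts <- integer(nrow(intervals))
  if (!nrow(tags) || !nrow(intervals)) return(counts)
  for (ch in unique(intervals$chrom)) {
    fp <- sort(tags$five_prime[tags$chrom == ch])
    if (!length(fp)) next
    idx <- which(intervals$chrom == ch)
    counts[idx] <- findInterval(intervals$end[idx] - 0.5, fp) -
      findInterval(intervals$start[idx] - 0.5, fp)
  }
  counts
}

# Deterministic TSV writer: '#' comment header, then a column-name row, then
# data. Doubles are rendered with %.17g so read/write round-trips bit-exactly.
.write_tsv <- function(df, path, comment = NULL) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- "NA"
      out
    } else if (is.logical(col)) {
      ifelse(is.na(col), "NA", ifelse(col, "TRUE", "FALSE"))
    } else {
      out <- as.character(col)
      out[is.na(col)] <- "NA"
      out
    }
  })
  lines <- character(0)
  if (!is.null(comment)) lines <- paste0("# ", comment)
  lines <- c(lines, paste(names(df), collapse = "\t"))
  if (nrow(df)) {
    body <- do.call(paste, c(cols, list(sep = "\t")))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

.read_tsv <- function(path, colClasses = NA) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = colClasses, stringsAsFactors = FALSE,
                    quote = "", na.strings = "NA")
}
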