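# Readers and writers for the file formats the pipeline touches: BED6 tags,
# narrowPeak / TSV peaks, gene models (TSV or minimal GTF), one-to-one
# ortholog maps, GMT gene sets and FASTA genomes. Coordinates are stored
# 0-based half-open throughout; 1-based GTF input is converted on read.

#' Read aligned tags from a BED6 file
#'
#' Each BED record is reduced to its 5' position: for `+` strand reads the
#' BED start, for `-` strand reads `end - 1` (the last covered base).
#' Record order is preserved.
#'
#' @param path Path to a BED6 file. Lines starting with `#`, `track` or
#'   `browser` are skipped.
#' @param dialect Input dialect; only `"bed6"` is supported.
#' @return A tag data frame (`chrom`, `five_prime`, `strand`).
#' @seealso [write_tags()]
#' @export
read_tags <- function(path, dialect = c("bed6")) {
  dialect <- match.arg(dialect)
  .chk(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track|browser)", lines)
  lineno <- which(keep)
  if (!length(lineno)) return(tag_frame())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop(sprintf("malformed BED6 line %d in %s (fewer than 6 fields)",
                 lineno[which(nf < 6L)[1L]], path), call. = FALSE)
  }
  m <- vapply(fields, function(f) f[1:6], character(6))
  start <- suppressWarnings(as.integer(m[2L, ]))
  end <- suppressWarnings(as.integer(m[3L, ]))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop(sprintf("malformed BED6 line %d in %s (non-integer coordinates)",
                 lineno[which(bad)[1L]], path), call. = FALSE)
  }
  strand <- m[6L, ]
  badstr <- !strand %in% c("+", "-")
  if (any(badstr)) {
    stop(sprintf("unknown strand symbol '%s' on line %d of %s",
                 strand[which(badstr)[1L]], lineno[which(badstr)[1L]], path),
         call. = FALSE)
  }
  tag_frame(chrom = m[1L, ],
            five_prime = ifelse(strand == "+", start, end - 1L),
            strand = strand)
}

#' Write tags as BED6
#'
#' Tags are emitted as 1-bp records anchored at the 5' end, so
#' `read_tags(write_tags(x))` reproduces `x` exactly.
#'
#' @param tags A tag data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tags <- function(tags, path) {
  validate_tags(tags)
  lines <- "# BED6; 1-bp records anchored at the read 5' end (0-based half-open)"
  if (nrow(tags)) {
    lines <- c(lines, paste(tags$chrom, tags$five_prime, tags$five_prime + 1L,
                            paste0("tag_", seq_len(nrow(tags))), 0L,
                            tags$strand, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Validate a peak data frame
#'
#' @param peaks Data frame with columns `chrom`, `start`, `end`, `score`,
#'   `fdr`, `tag_count`, `dataset_id`.
#' @return The input, invisibly.
#' @export
validate_peaks <- function(peaks) {
  .chk(is.data.frame(peaks), "peaks must be a data.frame")
  .chk(all(c("chrom", "start", "end", "score", "fdr", "tag_count",
             "dataset_id") %in% names(peaks)),
       "peaks must have columns chrom, start, end, score, fdr, tag_count, dataset_id")
  validate_intervals(peaks)
  if (nrow(peaks)) {
    ok <- is.na(peaks$fdr) | (peaks$fdr >= 0 & peaks$fdr <= 1)
    .chk(all(ok), "fdr must lie in [0, 1]")
    okc <- is.na(peaks$tag_count) | peaks$tag_count >= 0
    .chk(all(okc), "tag_count must be >= 0")
  }
  invisible(peaks)
}

#' Construct a peak data frame
#'
#' @param chrom,start,end Interval columns (0-based half-open).
#' @param score Caller score (e.g. -10*log10 p).
#' @param fdr False discovery rate as a fraction in \[0, 1\].
#' @param tag_count Tags supporting the peak (NA until counted).
#' @param dataset_id Label of the source dataset.
#' @return A validated peak data frame.
#' @export
peak_frame <- function(chrom = character(), start = integer(), end = integer(),
                       score = numeric(), fdr = numeric(),
                       tag_count = integer(), dataset_id = character()) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   score = as.numeric(score),
                   fdr = as.numeric(fdr),
                   tag_count = as.integer(tag_count),
                   dataset_id = as.character(dataset_id),
                   stringsAsFactors = FALSE)
  if (!n) df <- df[0, , drop = FALSE]
  validate_peaks(df)
  df
}

#' Read called peaks
#'
#' Two dialects are supported: the package's documented TSV (columns
#' `chrom start end score fdr tag_count [dataset_id]`, `fdr` a fraction) and
#' ENCODE narrowPeak (10 columns, no header; the `qValue` column is
#' interpreted on the scale named by `fdr_scale`).
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"narrowPeak"`.
#' @param fdr_scale How the file encodes its FDR column: `"fraction"`
#'   (default for TSV), `"neglog10"` (default for narrowPeak, i.e.
#'   `fdr = 10^-q`), or `"percent"` (divided by 100 on read).
#' @param dataset_id Dataset label to attach when the file carries none.
#' @return A peak data frame with 0-based half-open intervals and `fdr`
#'   as a fraction.
#' @export
read_peaks <- function(path, dialect = c("tsv", "narrowPeak"),
                       fdr_scale = NULL, dataset_id = NA_character_) {
  dialect <- match.arg(dialect)
  .chk(file.exists(path), "file not found: %s", path)
  if (is.null(fdr_scale)) {
    fdr_scale <- if (dialect == "narrowPeak") "neglog10" else "fraction"
  }
  fdr_scale <- match.arg(fdr_scale, c("fraction", "neglog10", "percent"))
  if (dialect == "narrowPeak") {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    .chk(ncol(df) >= 9L, "narrowPeak needs >= 9 columns; got %d", ncol(df))
    fdr <- .decode_fdr(df[[9L]], fdr_scale)
    out <- peak_frame(chrom = df[[1L]], start = df[[2L]], end = df[[3L]],
                      score = df[[5L]], fdr = fdr,
                      tag_count = rep(NA_integer_, nrow(df)),
                      dataset_id = rep(dataset_id, nrow(df)))
  } else {
    df <- .read_tsv(path)
    .chk(all(c("chrom", "start", "end") %in% names(df)),
         "TSV peaks need chrom, start, end columns")
    .chk("fdr" %in% names(df),
         "peak file %s lacks an 'fdr' column; supply a column mapping", path)
    n <- nrow(df)
    out <- peak_frame(chrom = df$chrom, start = df$start, end = df$end,
                      score = if ("score" %in% names(df)) df$score else rep(NA_real_, n),
                      fdr = .decode_fdr(df$fdr, fdr_scale),
                      tag_count = if ("tag_count" %in% names(df)) df$tag_count else rep(NA_integer_, n),
                      dataset_id = if ("dataset_id" %in% names(df)) df$dataset_id else rep(dataset_id, n))
  }
  out
}

.decode_fdr <- function(x, fdr_scale) {
  switch(fdr_scale,
         fraction = as.numeric(x),
         neglog10 = {
           .chk(all(x >= 0), "neglog10 FDR values must be >= 0")
           10^(-as.numeric(x))
         },
         percent = as.numeric(x) / 100)
}

#' Write peaks in the documented TSV dialect
#'
#' @param peaks A peak data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  validate_peaks(peaks)
  .write_tsv(peaks[, c("chrom", "start", "end", "score", "fdr", "tag_count",
                       "dataset_id")], path,
             comment = "peaks; coordinates 0-based half-open; fdr as fraction")
}

#' Read gene models
#'
#' TSV dialect: header `gene_id chrom strand start end` with 0-based
#' half-open gene bodies. GTF dialect: `gene` feature lines; 1-based closed
#' coordinates are converted. The TSS is `start` for `+` genes and `end - 1`
#' for `-` genes.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"gtf"`.
#' @return Data frame `gene_id, chrom, strand, start, end, tss`.
#' @export
read_gene_models <- function(path, dialect = c("tsv", "gtf")) {
  dialect <- match.arg(dialect)
  .chk(file.exists(path), "file not found: %s", path)
  if (dialect == "tsv") {
    df <- .read_tsv(path)
    .chk(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(df)),
         "gene model TSV needs gene_id, chrom, strand, start, end")
    genes <- data.frame(gene_id = as.character(df$gene_id),
                        chrom = as.character(df$chrom),
                        strand = as.character(df$strand),
                        start = as.integer(df$start),
                        end = as.integer(df$end),
                        stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    fields <- fields[vapply(fields, function(f) length(f) >= 9 && f[3] == "gene",
                            logical(1))]
    .chk(length(fields) > 0, "no 'gene' feature lines in %s", path)
    gid <- vapply(fields, function(f) {
      m <- regmatches(f[9], regexec('gene_id[ =]+"?([^";]+)"?', f[9]))[[1]]
      .chk(length(m) == 2L, "GTF attributes lack gene_id: %s", f[9])
      m[2]
    }, character(1))
    genes <- data.frame(gene_id = gid,
                        chrom = vapply(fields, `[`, character(1), 1L),
                        strand = vapply(fields, `[`, character(1), 7L),
                        start = as.integer(vapply(fields, `[`, character(1), 4L)) - 1L,
                        end = as.integer(vapply(fields, `[`, character(1), 5L)),
                        stringsAsFactors = FALSE)
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  .chk(length(dup) == 0, "duplicate gene_id: %s", paste(unique(dup), collapse = ", "))
  .chk(all(genes$strand %in% c("+", "-")), "gene strand must be '+' or '-'")
  validate_intervals(genes)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes
}

#' Write gene models in the TSV dialect
#' @param genes Gene model data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  .write_tsv(genes[, c("gene_id", "chrom", "strand", "start", "end")], path,
             comment = "gene models; gene body 0-based half-open; TSS = start (+) / end-1 (-)")
}

#' Read a one-to-one ortholog map
#'
#' @param path TSV with header `gene_a gene_b`. A gene appearing in more
#'   than one pair violates the one-to-one contract and is rejected.
#' @return Data frame `gene_a, gene_b`.
#' @export
read_ortholog_map <- function(path) {
  .chk(file.exists(path), "file not found: %s", path)
  df <- .read_tsv(path, colClasses = "character")
  .chk(all(c("gene_a", "gene_b") %in% names(df)),
       "ortholog map needs gene_a, gene_b columns")
  dup_a <- unique(df$gene_a[duplicated(df$gene_a)])
  dup_b <- unique(df$gene_b[duplicated(df$gene_b)])
  .chk(length(dup_a) == 0 && length(dup_b) == 0,
       "ortholog map is not one-to-one (duplicated: %s)",
       paste(c(dup_a, dup_b), collapse = ", "))
  df[, c("gene_a", "gene_b")]
}

#' Write an ortholog map
#' @param pairs Data frame `gene_a, gene_b`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ortholog_map <- function(pairs, path) {
  .write_tsv(pairs[, c("gene_a", "gene_b")], path,
             comment = "one-to-one ortholog pairs")
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: per line, set name, description, then member genes
#'   (tab-separated). Members are deduplicated; empty sets are rejected.
#' @return Named list of character vectors of member gene ids.
#' @export
read_gene_sets <- function(path) {
  .chk(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[`, character(1), 1L)
  .chk(!anyDuplicated(nm), "duplicate gene set name: %s",
       paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) {
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    .chk(length(members) > 0, "gene set '%s' has no members", f[1])
    members
  })
  names(sets) <- nm
  sets
}

#' Write gene sets as GMT
#' @param sets Named list of member vectors.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Extract genomic sequences for intervals
#'
#' Intervals are clipped at chromosome bounds; each record is named
#' `chrom:start-end` with the clipped half-open coordinates.
#'
#' @param fasta Path to a genome FASTA file, or a
#'   [Biostrings::DNAStringSet].
#' @param intervals Interval data frame (0-based half-open).
#' @return A `DNAStringSet`, one record per interval.
#' @export
extract_sequences <- function(fasta, intervals) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  validate_intervals(intervals)
  missing <- setdiff(unique(intervals$chrom), names(seqs))
  .chk(length(missing) == 0, "chromosome(s) absent from FASTA: %s",
       paste(missing, collapse = ", "))
  lens <- Biostrings::width(seqs)[match(intervals$chrom, names(seqs))]
  s <- pmax(intervals$start, 0L)
  e <- pmin(intervals$end, lens)
  .chk(all(s < e), "interval(s) fall entirely outside chromosome bounds")
  out <- Biostrings::subseq(seqs[intervals$chrom], start = s + 1L, end = e)
  names(out) <- sprintf("%s:%d-%d", intervals$chrom, s, e)
  out
}
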