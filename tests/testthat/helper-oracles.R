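# Independent brute-force oracles and random fixture builders. These stay
# deliberately naive (per-element loops, per-base boolean arrays,
# closed-form sums) so they cannot share bugs with the vectorised
# implementations they check.

random_tags <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000) {
  tag_frame(chrom = sample(chroms, n, replace = TRUE),
            five_prime = sample.int(max_pos, n, replace = TRUE) - 1L,
            strand = sample(c("+", "-"), n, replace = TRUE))
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                         dataset_id = "d1") {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  peak_frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample(50:500, n, replace = TRUE),
             score = round(stats::runif(n, 0, 100), 3),
             fdr = round(stats::runif(n), 6),
             tag_count = sample.int(200, n, replace = TRUE),
             dataset_id = dataset_id)
}

random_genes <- function(n, chroms = c("chr1", "chr2"), max_pos = 50000) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  g <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                  chrom = sample(chroms, n, replace = TRUE),
                  strand = sample(c("+", "-"), n, replace = TRUE),
                  start = start,
                  end = start + sample(500:5000, n, replace = TRUE),
                  stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g
}

# per-group application of the cap/censor rule
oracle_filter <- function(tags, max_per_start = 2, censor_above = 7) {
  key <- paste(tags$chrom, tags$strand, tags$five_prime, sep = "|")
  kept <- lapply(split(seq_len(nrow(tags)), key), function(idx) {
    if (length(idx) > censor_above) integer(0)
    else idx[seq_len(min(length(idx), max_per_start))]
  })
  tags[sort(unlist(kept, use.names = FALSE)), , drop = FALSE]
}

# per-tag membership check
oracle_count_5p <- function(tags, interval) {
  n <- 0L
  for (i in seq_len(nrow(tags))) {
    if (tags$chrom[i] == interval$chrom &&
        tags$five_prime[i] >= interval$start &&
        tags$five_prime[i] < interval$end) n <- n + 1L
  }
  n
}

oracle_elongate_one <- function(fp, strand, ext) {
  if (strand == "+") c(max(fp, 0L), fp + ext)
  else c(max(fp - ext + 1L, 0L), fp + 1L)
}

# per-base membership count over elongated footprints
oracle_coverage <- function(tags, interval, ext = 200) {
  cov <- integer(interval$end - interval$start)
  for (i in seq_len(nrow(tags))) {
    if (tags$chrom[i] != interval$chrom) next
    fe <- oracle_elongate_one(tags$five_prime[i], tags$strand[i], ext)
    for (b in seq_along(cov)) {
      pos <- interval$start + b - 1L
      if (pos >= fe[1] && pos < fe[2]) cov[b] <- cov[b] + 1L
    }
  }
  cov
}

# connected components of the per-base boolean union of intervals
oracle_merge <- function(intervals) {
  out <- list()
  for (ch in sort(unique(intervals$chrom))) {
    sub <- intervals[intervals$chrom == ch, , drop = FALSE]
    width <- max(sub$end) + 1L
    occ <- logical(width)
    for (i in seq_len(nrow(sub))) {
      occ[(sub$start[i] + 1L):sub$end[i]] <- TRUE
    }
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    if (length(on)) {
      out[[ch]] <- data.frame(chrom = ch, start = starts[on] - 1L,
                              end = ends[on], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# upper-tail hypergeometric by direct summation of choose() products
oracle_hyper_p <- function(k, K, n, N) {
  jmax <- min(n, K)
  if (k > jmax) return(0)
  sum(vapply(k:jmax, function(j) {
    exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n))
  }, numeric(1)))
}

# step-up BH by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# regions fixture with counts already filled (for fold/Venn tests)
make_regions <- function(count_matrix, contributors = NULL) {
  n <- nrow(count_matrix)
  labels <- colnames(count_matrix)
  regions <- data.frame(region_id = sprintf("r%03d", seq_len(n)),
                        chrom = "chr1",
                        start = (seq_len(n) - 1L) * 1000L,
                        end = (seq_len(n) - 1L) * 1000L + 500L,
                        stringsAsFactors = FALSE)
  regions$contributors <- if (is.null(contributors)) {
    replicate(n, labels, simplify = FALSE)
  } else contributors
  for (d in labels) regions[[paste0("count_", d)]] <- count_matrix[, d]
  attr(regions, "count_labels") <- labels
  regions
}

# truth peak intervals recast as FDR-passing peak sets, one per dataset
peaks_from_truth <- function(truth_peaks, labels) {
  sets <- lapply(labels, function(d) {
    peak_frame(chrom = truth_peaks$chrom, start = truth_peaks$start,
               end = truth_peaks$end, score = 100,
               fdr = 0, tag_count = NA_integer_, dataset_id = d)
  })
  names(sets) <- labels
  sets
}
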