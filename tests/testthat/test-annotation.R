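gene_row <- function(id, chrom, strand, start, end) {
  g <- data.frame(gene_id = id, chrom = chrom, strand = strand,
                  start = as.integer(start), end = as.integer(end),
                  stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g
}

test_that("peak-TSS association uses the closed +/- window", {
  g <- gene_row("g1", "chr1", "+", 2000, 6000)  # TSS 2000, window [750, 3251)
  near <- peak_frame("chr1", 3000L, 3500L, 1, 0, 1L, "d")
  far <- peak_frame("chr1", 3300L, 3500L, 1, 0, 1L, "d")
  expect_equal(associate_peaks_tss(near, g)$pairs$gene_id, "g1")
  expect_equal(nrow(associate_peaks_tss(far, g)$pairs), 0L)
  # exact boundary: a peak ending at TSS - 1250 misses, one base more hits
  edge <- peak_frame("chr1", 700L, 750L, 1, 0, 1L, "d")
  expect_equal(nrow(associate_peaks_tss(edge, g)$pairs), 0L)
  edge2 <- peak_frame("chr1", 700L, 751L, 1, 0, 1L, "d")
  expect_equal(nrow(associate_peaks_tss(edge2, g)$pairs), 1L)
})

test_that("association matches brute-force pairwise intersection", {
  set.seed(51)
  pk <- random_peaks(200, max_pos = 48000)
  g <- random_genes(50)
  got <- associate_peaks_tss(pk, g, half_window = 1250)$pairs
  want <- list()
  for (i in seq_len(nrow(pk))) {
    for (j in seq_len(nrow(g))) {
      if (pk$chrom[i] == g$chrom[j] &&
          pk$start[i] < g$tss[j] + 1250 + 1 &&
          pk$end[i] > g$tss[j] - 1250) {
        want[[length(want) + 1L]] <- data.frame(peak_index = i,
                                                gene_id = g$gene_id[j],
                                                stringsAsFactors = FALSE)
      }
    }
  }
  want <- do.call(rbind, want)
  want <- want[order(want$peak_index, want$gene_id), ]
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("location classes are exclusive, exhaustive and prioritized", {
  g <- gene_row("g1", "chr1", "+", 10000, 30000)
  # inside the TSS window AND the gene body -> TSS-proximal wins
  pk <- peak_frame(chrom = rep("chr1", 3),
                   start = c(10100L, 20000L, 50000L),
                   end = c(10400L, 20300L, 50300L),
                   score = 1, fdr = 0, tag_count = 1L, dataset_id = "d")
  cls <- classify_locations(pk, g)
  expect_equal(as.character(cls$category),
               c("tss_proximal", "intragenic", "intergenic"))
  expect_equal(cls$breakdown$n_tss_proximal +
                 cls$breakdown$n_intragenic + cls$breakdown$n_intergenic,
               nrow(pk))
  expect_equal(sum(cls$breakdown$fractions), 1)
  set.seed(52)
  pk2 <- random_peaks(200, max_pos = 48000)
  g2 <- random_genes(40)
  cls2 <- classify_locations(pk2, g2)
  # brute-force categories
  want <- vapply(seq_len(nrow(pk2)), function(i) {
    tssh <- FALSE; bodyh <- FALSE
    for (j in seq_len(nrow(g2))) {
      if (pk2$chrom[i] != g2$chrom[j]) next
      if (pk2$start[i] < g2$tss[j] + 1251 && pk2$end[i] > g2$tss[j] - 1250)
        tssh <- TRUE
      if (pk2$start[i] < g2$end[j] && pk2$end[i] > g2$start[j]) bodyh <- TRUE
    }
    if (tssh) "tss_proximal" else if (bodyh) "intragenic" else "intergenic"
  }, character(1))
  expect_equal(as.character(cls2$category), want)
})

test_that("bound genes have set semantics and are monotone in the window", {
  g <- rbind(gene_row("g1", "chr1", "+", 2000, 6000),
             gene_row("g2", "chr1", "-", 20000, 24000))
  pk <- peak_frame(chrom = rep("chr1", 2), start = c(1900L, 2500L),
                   end = c(2100L, 2800L), score = 1, fdr = 0,
                   tag_count = 1L, dataset_id = "d")
  expect_equal(bound_genes(pk, g, 1250), "g1")  # two peaks, one gene, once
  small <- bound_genes(pk, g, 1250)
  large <- bound_genes(pk, g, 10000)
  expect_true(all(small %in% large))
  set.seed(53)
  pk2 <- random_peaks(100, max_pos = 48000)
  g2 <- random_genes(30)
  want <- sort(unique(unlist(lapply(seq_len(nrow(g2)), function(j) {
    hit <- any(pk2$chrom == g2$chrom[j] &
                 pk2$start < g2$tss[j] + 1251 & pk2$end > g2$tss[j] - 1250)
    if (hit) g2$gene_id[j] else character(0)
  }))))
  expect_equal(bound_genes(pk2, g2, 1250), want)
})

test_that("homology Venn tallies pairs and species-specific genes", {
  pairs <- data.frame(gene_a = c("a1", "a3"), gene_b = c("b1", "b3"),
                      stringsAsFactors = FALSE)
  hv <- homology_venn(c("a1"), c("b1"), pairs)
  expect_equal(hv$n_both, 1L)
  expect_equal(hv$n_a_only + hv$n_b_only + hv$n_a_specific + hv$n_b_specific,
               0L)
  hv2 <- homology_venn(c("a2"), character(0), pairs)
  expect_equal(hv2$n_a_specific, 1L)
  expect_error(homology_venn("a1", "b1",
                             data.frame(gene_a = c("a1", "a1"),
                                        gene_b = c("b1", "b2"))),
               "one-to-one")
  set.seed(54)
  pairs2 <- data.frame(gene_a = sprintf("a%03d", 1:100),
                       gene_b = sprintf("b%03d", 1:100),
                       stringsAsFactors = FALSE)
  ba <- sample(c(pairs2$gene_a, sprintf("ax%02d", 1:10)), 40)
  bb <- sample(c(pairs2$gene_b, sprintf("bx%02d", 1:10)), 35)
  hv3 <- homology_venn(ba, bb, pairs2)
  both <- sum(pairs2$gene_a %in% ba & pairs2$gene_b %in% bb)
  expect_equal(hv3$n_both, both)
  expect_equal(hv3$n_a_only, sum(pairs2$gene_a %in% ba) - both)
  expect_equal(hv3$n_a_specific, sum(!(ba %in% pairs2$gene_a)))
  expect_true(hv3$n_both + hv3$n_a_only <= nrow(pairs2))
  # removing all pairs moves every bound gene to a species-specific cell
  none <- homology_venn(ba, bb, pairs2[0, ])
  expect_equal(none$n_a_specific, length(ba))
  expect_equal(none$n_b_specific, length(bb))
})

test_that("TSS metaprofile orients, averages and normalizes correctly", {
  g <- gene_row("g1", "chr1", "+", 5000, 9000)
  tags <- tag_frame("chr1", 5000L, "+")
  prof <- tss_metaprofile(tags, g, library_size = 2e7, flank = 500, bin = 25)
  # one tag elongated over offsets [0, 200) -> eight bins of exactly 1.0
  on <- prof$bin_offsets >= 0 & prof$bin_offsets < 200
  expect_equal(prof$values[on], rep(1.0, 8))
  expect_equal(prof$values[!on], rep(0, sum(!on)))
  # minus-strand gene: a tag downstream in gene orientation (lower
  # coordinates) lands at positive offsets
  gm <- gene_row("g2", "chr1", "-", 5000, 9000)  # TSS 8999
  tm <- tag_frame("chr1", 8999L, "-")
  pm <- tss_metaprofile(tm, gm, library_size = 2e7, flank = 500, bin = 25)
  onm <- pm$bin_offsets >= 0 & pm$bin_offsets < 200
  expect_equal(pm$values[onm], rep(1.0, 8))
  # zero tags give the zero profile
  p0 <- tss_metaprofile(tag_frame(), g, library_size = 2e7)
  expect_equal(p0$values, rep(0, length(p0$values)))
})

test_that("metaprofile is exactly invariant under tag+library duplication", {
  set.seed(55)
  tags <- random_tags(400, max_pos = 40000)
  g <- random_genes(20, max_pos = 35000)
  base <- tss_metaprofile(tags, g, library_size = 1234567)
  doubled <- tss_metaprofile(rbind(tags, tags), g,
                             library_size = 2L * 1234567L)
  expect_identical(base$values, doubled$values)
})

test_that("per-TSS tag-count distributions are cumulative and exact", {
  g <- gene_row("g1", "chr1", "+", 2000, 6000)
  tags <- tag_frame(rep("chr1", 5), c(1000L, 1500L, 2000L, 2500L, 3200L),
                    rep("+", 5))
  d <- tss_count_distribution(tags, list(all = "g1"), g)
  expect_equal(d$all, data.frame(tag_count = 5L, cum_fraction = 1.0))
  set.seed(56)
  g2 <- random_genes(30)
  tags2 <- random_tags(500, max_pos = 50000)
  d2 <- tss_count_distribution(tags2, list(all = g2$gene_id), g2)$all
  want <- sort(vapply(seq_len(nrow(g2)), function(j) {
    oracle_count_5p(tags2, list(chrom = g2$chrom[j],
                                start = max(g2$tss[j] - 1250L, 0L),
                                end = g2$tss[j] + 1251L))
  }, integer(1)))
  expect_equal(d2$tag_count, want)
  # a set enriched for high-count TSSs stochastically dominates
  counts_by_gene <- vapply(seq_len(nrow(g2)), function(j) {
    oracle_count_5p(tags2, list(chrom = g2$chrom[j],
                                start = max(g2$tss[j] - 1250L, 0L),
                                end = g2$tss[j] + 1251L))
  }, integer(1))
  top <- g2$gene_id[order(counts_by_gene, decreasing = TRUE)[1:10]]
  d3 <- tss_count_distribution(tags2, list(all = g2$gene_id, top = top), g2)
  expect_true(mean(d3$top$tag_count) >= mean(d3$all$tag_count))
})
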