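test_that("peak merging unions overlapping intervals across datasets", {
  same <- peaks_from_truth(data.frame(chrom = "chr1", start = 100L,
                                      end = 200L), c("d1", "d2", "d3"))
  reg <- merge_peak_sets(same)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 100L)
  expect_equal(reg$end, 200L)
  expect_equal(reg$contributors[[1]], c("d1", "d2", "d3"))

  disjoint <- list(
    d1 = peak_frame("chr1", 100L, 200L, 1, 0, 1L, "d1"),
    d2 = peak_frame("chr1", 300L, 400L, 1, 0, 1L, "d2"))
  reg2 <- merge_peak_sets(disjoint)
  expect_equal(nrow(reg2), 2L)
  expect_equal(reg2$contributors, list("d1", "d2"))

  # book-ended half-open intervals form one connected component
  adjacent <- list(
    d1 = peak_frame("chr1", 100L, 200L, 1, 0, 1L, "d1"),
    d2 = peak_frame("chr1", 200L, 300L, 1, 0, 1L, "d2"))
  adj <- merge_peak_sets(adjacent)
  expect_equal(nrow(adj), 1L)
  expect_equal(c(adj$start, adj$end), c(100L, 300L))
  # a one-base gap keeps regions separate
  gapped <- list(
    d1 = peak_frame("chr1", 100L, 200L, 1, 0, 1L, "d1"),
    d2 = peak_frame("chr1", 201L, 300L, 1, 0, 1L, "d2"))
  expect_equal(nrow(merge_peak_sets(gapped)), 2L)

  # unfiltered input is rejected
  bad <- list(d1 = peak_frame("chr1", 0L, 10L, 1, 0.5, 1L, "d1"))
  expect_error(merge_peak_sets(bad), "filter_fdr")
})

test_that("merged regions equal per-base union components on random input", {
  set.seed(41)
  sets <- lapply(c("d1", "d2", "d3"), function(d) {
    start <- sample.int(5000, 100) - 1L
    peak_frame(chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
               start = start, end = start + sample(20:300, 100, replace = TRUE),
               score = 1, fdr = 0, tag_count = 1L, dataset_id = d)
  })
  names(sets) <- c("d1", "d2", "d3")
  reg <- merge_peak_sets(sets)
  want <- oracle_merge(do.call(rbind, lapply(sets, function(p) {
    p[, c("chrom", "start", "end")]
  })))
  got <- reg[, c("chrom", "start", "end")]
  want <- want[order(want$chrom, want$start), ]
  rownames(got) <- NULL
  rownames(want) <- NULL
  expect_equal(got, want)
  # permutation invariance in dataset order
  reg_rev <- merge_peak_sets(rev(sets))
  expect_equal(reg_rev[, c("chrom", "start", "end")],
               reg[, c("chrom", "start", "end")])
  # idempotence: merging the merged intervals changes nothing
  again <- merge_peak_sets(list(
    all = peak_frame(reg$chrom, reg$start, reg$end, 1, 0, 1L, "all")))
  expect_equal(again[, c("chrom", "start", "end")],
               reg[, c("chrom", "start", "end")])
})

test_that("region counts are depth-normalized 5' counts", {
  reg <- merge_peak_sets(peaks_from_truth(
    data.frame(chrom = "chr1", start = 1000L, end = 2000L), c("d1", "d2")))
  tags <- list(d1 = tag_frame(rep("chr1", 10), seq(1000L, 1900L, by = 100L),
                              rep("+", 10)),
               d2 = tag_frame(rep("chr1", 10), seq(1000L, 1900L, by = 100L),
                              rep("+", 10)))
  reg <- region_counts(reg, tags, c(d1 = 2e7, d2 = 1e7))
  expect_equal(reg$count_d1, 10.0)
  expect_equal(reg$count_d2, 20.0)
  expect_error(region_counts(reg, tags[1], c(d1 = 2e7)), "missing dataset")
})

test_that("fold membership thresholds against the maximum count", {
  cm <- rbind(c(d1 = 100, d2 = 60, d3 = 30))
  reg <- make_regions(cm)
  expect_equal(fold_membership(reg, 2)[[1]], c("d1", "d2"))
  expect_equal(fold_membership(reg, 4)[[1]], c("d1", "d2", "d3"))
  zero <- make_regions(rbind(c(d1 = 0, d2 = 0, d3 = 0)),
                       contributors = list("d2"))
  expect_equal(fold_membership(zero, 2)[[1]], "d2")
  expect_error(fold_membership(reg, 0.5), ">= 1")
})

test_that("membership is monotone in k and Venn cells conserve regions", {
  set.seed(42)
  cm <- matrix(stats::rpois(500 * 3, 40) * stats::runif(1500, 0.2, 1),
               ncol = 3, dimnames = list(NULL, c("d1", "d2", "d3")))
  reg <- make_regions(cm)
  ks <- c(1, 1.5, 2, 3, 4, 8)
  mems <- lapply(ks, function(k) fold_membership(reg, k))
  for (i in seq_len(length(ks) - 1)) {
    for (r in seq_len(nrow(cm))) {
      expect_true(all(mems[[i]][[r]] %in% mems[[i + 1]][[r]]))
    }
  }
  for (k in ks) {
    vp <- venn_partition(reg, k)
    expect_equal(sum(vp$cells), nrow(cm))
    # brute-force tally of exact membership subsets
    keys <- vapply(fold_membership(reg, k),
                   function(s) paste(sort(s), collapse = "&"), character(1))
    expect_equal(sort(vp$cells), sort(c(table(keys))))
  }
  # the all-datasets cell never shrinks as tolerance grows
  all3 <- vapply(ks, function(k) {
    cells <- venn_partition(reg, k)$cells
    if ("d1&d2&d3" %in% names(cells)) cells[["d1&d2&d3"]] else 0L
  }, integer(1))
  expect_true(all(diff(all3) >= 0))
})

test_that("summits sit at the midpoint of the leftmost maximal plateau", {
  reg <- data.frame(chrom = "chr1", start = 900L, end = 1300L)
  one <- tag_frame("chr1", 1000L, "+")
  s1 <- compute_summits(reg, one)
  expect_equal(s1$position, 1099L)
  expect_equal(s1$height, 1L)
  expect_equal(c(s1$plateau_start, s1$plateau_end), c(1000L, 1200L))
  expect_false(s1$flagged)

  two <- tag_frame(c("chr1", "chr1"), c(1000L, 1100L), c("+", "+"))
  s2 <- compute_summits(reg, two)
  expect_equal(s2$position, 1149L)
  expect_equal(s2$height, 2L)

  s0 <- compute_summits(reg, tag_frame())
  expect_true(s0$flagged)
  expect_equal(s0$position, (900L + 1300L - 1L) %/% 2L)
  expect_equal(s0$height, 0L)
})

test_that("summit positions and heights match the per-base pileup oracle", {
  set.seed(43)
  for (rep_i in 1:3) {
    tags <- random_tags(300, chroms = "chr1", max_pos = 3000)
    reg <- data.frame(chrom = "chr1", start = 500L, end = 2500L)
    s <- compute_summits(reg, tags)
    cov <- oracle_coverage(tags, as.list(reg))
    expect_equal(s$height, max(cov))
    argmax <- reg$start + which(cov == max(cov)) - 1L
    expect_true(s$position %in% argmax)
    # leftmost plateau: no equal-height run starts before the reported one
    expect_equal(s$plateau_start, min(argmax[argmax >= min(argmax)]))
  }
})

test_that("summit windows are +/- half-width closed ranges with clipping", {
  s <- data.frame(chrom = "chr1", position = 1099L)
  w <- summit_windows(s)
  expect_equal(c(w$start, w$end), c(949L, 1250L))
  expect_equal(w$end - w$start, 301L)
  w0 <- summit_windows(data.frame(chrom = "chr1", position = 100L))
  expect_equal(c(w0$start, w0$end), c(0L, 251L))
  wr <- summit_windows(data.frame(chrom = "chr1", position = 990L),
                       chrom_sizes = c(chr1 = 1000L))
  expect_equal(wr$end, 1000L)
  set.seed(44)
  pos <- sample(500:5000, 20)
  ww <- summit_windows(data.frame(chrom = "chr1", position = pos))
  expect_true(all(ww$end - ww$start == 301L))
})
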