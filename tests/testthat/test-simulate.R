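small_design <- function(seed = 1, ...) {
  simulation_design(genome = data.frame(chrom = "chr1", length = 300000L),
                    n_genes = 60, n_peaks = 20, seed = seed, ...)
}

test_that("identical seeds reproduce the simulation exactly", {
  a <- simulate_chipseq(small_design(7), genome_sequence = FALSE)
  b <- simulate_chipseq(small_design(7), genome_sequence = FALSE)
  expect_identical(a$tags, b$tags)
  expect_identical(a$controls, b$controls)
  expect_identical(a$truth, b$truth)
  expect_identical(a$genes, b$genes)
  c_ <- simulate_chipseq(small_design(8), genome_sequence = FALSE)
  expect_false(identical(a$tags, c_$tags))
})

test_that("a null design yields empty tags and truth", {
  d <- simulation_design(n_peaks = 0, background_rate = 0,
                         control_hotspots = 0, seed = 2)
  sim <- simulate_chipseq(d, genome_sequence = FALSE)
  expect_true(all(vapply(sim$tags, nrow, integer(1)) == 0L))
  expect_equal(nrow(sim$truth$peaks), 0L)
  expect_equal(nrow(sim$truth$duplicates), 0L)
  expect_equal(nrow(sim$truth$hotspots), 0L)
})

test_that("truth tables round-trip losslessly through TSV", {
  sim <- simulate_chipseq(small_design(3), genome_sequence = FALSE)
  dir <- tempfile()
  write_truth(sim$truth, dir)
  back <- read_truth(dir)
  expect_identical(back, sim$truth)
  # empty truth writes headers only and still round-trips
  null_sim <- simulate_chipseq(
    simulation_design(n_peaks = 0, background_rate = 0,
                      control_hotspots = 0, seed = 4),
    genome_sequence = FALSE)
  dir2 <- tempfile()
  write_truth(null_sim$truth, dir2)
  expect_identical(read_truth(dir2), null_sim$truth)
})

test_that("planted peaks respect their TSS/intergenic class", {
  sim <- simulate_chipseq(small_design(5), genome_sequence = FALSE)
  tp <- sim$truth$peaks
  g <- sim$genes
  at_tss <- vapply(seq_len(nrow(tp)), function(i) {
    any(g$chrom == tp$chrom[i] &
          tp$start[i] < g$tss + 1251L & tp$end[i] > g$tss - 1250L)
  }, logical(1))
  expect_true(all(at_tss[tp$tss_peak]))
  expect_true(!any(at_tss[!tp$tss_peak]))
  # TSS-planted fraction behaves binomially around the design value
  fracs <- vapply(1:6, function(s) {
    mean(simulate_chipseq(small_design(s),
                          genome_sequence = FALSE)$truth$peaks$tss_peak)
  }, numeric(1))
  se <- sqrt(0.8 * 0.2 / 20)
  expect_lt(abs(mean(fracs) - 0.8), 3 * se / sqrt(6))
})

test_that("control hotspots exceed 100 tags; the rest stay below censoring", {
  sim <- simulate_chipseq(small_design(6), genome_sequence = FALSE)
  hot <- sim$truth$hotspots
  expect_equal(nrow(hot), 2L)
  ctrl <- sim$controls[[hot$control[1]]]
  for (i in seq_len(nrow(hot))) {
    n_at <- sum(ctrl$chrom == hot$chrom[i] &
                  ctrl$five_prime == hot$five_prime[i] &
                  ctrl$strand == hot$strand[i])
    expect_gt(n_at, 100L)
  }
  other <- ctrl[!(ctrl$five_prime %in% hot$five_prime), ]
  tab <- table(paste(other$chrom, other$strand, other$five_prime))
  expect_true(all(tab <= 7L))
})

test_that("background tag counts are Poisson-consistent across windows", {
  rejected <- 0L
  for (s in 1:10) {
    d <- simulation_design(genome = data.frame(chrom = "chr1",
                                               length = 200000L),
                           n_genes = 30, n_peaks = 0, background_rate = 0.01,
                           duplicate_burst = c(0, 1),
                           control_hotspots = 0, seed = 100 + s)
    sim <- simulate_chipseq(d, genome_sequence = FALSE)
    tags <- sim$tags[[1]]
    breaks <- seq(0, 200000, by = 10000)
    obs <- table(cut(tags$five_prime, breaks, right = FALSE))
    gof <- stats::chisq.test(as.integer(obs))
    if (gof$p.value < 0.01) rejected <- rejected + 1L
  }
  expect_lte(rejected, 1L)
})

test_that("planted summits are recovered by the elongation pileup", {
  sim <- simulate_chipseq(small_design(9, peak_depth = 70),
                          genome_sequence = FALSE)
  pooled <- do.call(rbind, lapply(sim$tags, function(t) filter_tags(t)$tags))
  rownames(pooled) <- NULL
  tp <- sim$truth$peaks
  s <- compute_summits(tp[, c("chrom", "start", "end")], pooled)
  err <- abs(s$position - tp$summit)
  expect_gte(mean(err <= 25), 0.9)
})

test_that("duplicate bursts are recorded and removed by the filter", {
  sim <- simulate_chipseq(small_design(10), genome_sequence = FALSE)
  dup <- sim$truth$duplicates
  expect_gt(nrow(dup), 0L)
  d1 <- dup[dup$dataset == names(sim$tags)[1], ]
  tags <- sim$tags[[1]]
  i <- 1L
  n_at <- sum(tags$chrom == d1$chrom[i] & tags$strand == d1$strand[i] &
                tags$five_prime == d1$five_prime[i])
  expect_gte(n_at, d1$size[i])
  filtered <- filter_tags(tags)$tags
  n_after <- sum(filtered$chrom == d1$chrom[i] &
                   filtered$strand == d1$strand[i] &
                   filtered$five_prime == d1$five_prime[i])
  expect_equal(n_after, 0L)  # burst of 10 exceeds the censor threshold
})

test_that("simulations write all documented formats", {
  sim <- simulate_chipseq(small_design(11))
  dir <- tempfile()
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "tags", "endo.bed")))
  expect_true(file.exists(file.path(dir, "controls", "igg.bed")))
  expect_true(file.exists(file.path(dir, "genes.tsv")))
  expect_true(file.exists(file.path(dir, "orthologs.tsv")))
  expect_true(file.exists(file.path(dir, "genome.fa")))
  back <- read_tags(file.path(dir, "tags", "endo.bed"))
  expect_identical(back, sim$tags$endo)
  genes_back <- read_gene_models(file.path(dir, "genes.tsv"))
  expect_identical(genes_back, sim$genes)
  pairs_back <- read_ortholog_map(file.path(dir, "orthologs.tsv"))
  expect_identical(pairs_back, sim$orthologs)
})
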