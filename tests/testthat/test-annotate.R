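test_that("peak centers follow the floor rule", {
  expect_equal(peak_center(tibble::tibble(start = 999L, end = 2000L)), 1499L)
  expect_equal(peak_center(tibble::tibble(start = 0L, end = 1L)), 0L)
  expect_equal(peak_center(tibble::tibble(start = 10L, end = 12L)), 11L)
})

test_that("promoter and TTS windows are strand-aware and clipped", {
  g <- function(strand, start, end) {
    read_fixture_genes(gene_lines("g1", "chr1", start, end, strand))$genes
  }
  # + strand, tss = 5000
  w <- promoter_windows(g("+", 5000, 9001))
  expect_equal(c(w$start, w$end), c(4000L, 5101L))
  # - strand gene ending at 5001 has tss = 5000; window mirrored
  w <- promoter_windows(g("-", 1000, 5001))
  expect_equal(c(w$start, w$end), c(4900L, 6001L))
  # clipping at the chromosome start
  w <- promoter_windows(g("+", 500, 2000))
  expect_equal(c(w$start, w$end), c(0L, 601L))

  # + strand, tts = 9000 for a gene spanning [5000, 9001)
  w <- tts_windows(g("+", 5000, 9001))
  expect_equal(c(w$start, w$end), c(8900L, 10001L))
  # - strand, tts = 9000 for a gene spanning [9000, 20000)
  w <- tts_windows(g("-", 9000, 20000))
  expect_equal(c(w$start, w$end), c(8000L, 9101L))
  # clipping at a known chromosome end
  w <- tts_windows(g("+", 5000, 9001), chrom_sizes = c(chr1 = 9500L))
  expect_equal(c(w$start, w$end), c(8900L, 9500L))
})

test_that("classification follows the category precedence and assigns genes", {
  gm <- read_fixture_genes(c(
    gene_lines("g1", "chr1", 10000, 15000, "+",
               exons = list(c(10000, 11000), c(13000, 15000)))
  ))
  classify <- function(center) {
    annotate_peaks(peaks_tbl("chr1", center - 50, center + 50), gm)
  }
  # 500 bp upstream of the TSS
  a <- classify(9500)
  expect_equal(a$category, "PROMOTER_TSS")
  expect_equal(a$gene_id, "g1")
  expect_equal(a$distance_to_tss, -500L)
  # inside exon 2, outside promoter/TTS windows
  expect_equal(classify(13500)$category, "EXON")
  # in the span but no exon: intron
  expect_equal(classify(12000)$category, "INTRON")
  # downstream of the TTS
  expect_equal(classify(15500)$category, "TTS")
  # far away: intergenic, nearest gene assigned
  far <- classify(60000)
  expect_equal(far$category, "INTERGENIC")
  expect_equal(far$gene_id, "g1")
  # promoter window wins over exon 1 which it overlaps
  expect_equal(classify(10050)$category, "PROMOTER_TSS")
})

test_that("annotation matches the per-gene brute-force oracle on random genomes", {
  for (seed in c(101, 202)) {
    cfg <- sim_config(seed = seed, n_chroms = 1, chrom_len = 100000L,
                      n_genes = 12, gene_len_range = c(500L, 1500L))
    ann <- simulate_annotation(cfg)
    set.seed(seed + 1)
    n <- 300
    centers <- sample.int(100000L, n) - 1L
    len <- sample.int(500L, n)
    pk <- peaks_tbl("chr1", pmax(centers - len %/% 2L, 0L),
                    pmax(centers - len %/% 2L, 0L) + len)
    got <- annotate_peaks(pk, ann$genes)
    exon_index <- oracle_exon_index(ann$genes$exons)
    for (i in seq_len(n)) {
      exp <- oracle_classify(got$center[i], "chr1", ann$genes$genes,
                             exon_index)
      expect_identical(got$category[i], exp$category)
      expect_identical(got$gene_id[i], exp$gene_id)
    }
  }
})

test_that("every peak gets exactly one category and shifts leave them unchanged", {
  cfg <- sim_config(seed = 55, n_chroms = 1, chrom_len = 150000L,
                    n_genes = 10)
  ann <- simulate_annotation(cfg)
  set.seed(56)
  centers <- sample.int(140000L, 200) - 1L
  pk <- peaks_tbl("chr1", centers, centers + 100L)
  a1 <- annotate_peaks(pk, ann$genes)
  expect_true(all(a1$category %in% CATEGORY_LEVELS))
  expect_equal(nrow(a1), 200)

  # translate genes and peaks by a constant offset
  off <- 5000L
  gm2 <- ann$genes
  for (part in c("genes", "transcripts", "exons")) {
    gm2[[part]]$start <- gm2[[part]]$start + off
    gm2[[part]]$end <- gm2[[part]]$end + off
  }
  gm2$genes$tss <- gm2$genes$tss + off
  gm2$genes$tts <- gm2$genes$tts + off
  pk2 <- dplyr::mutate(pk, start = start + off, end = end + off)
  a2 <- annotate_peaks(pk2, gm2)
  expect_equal(a2$category, a1$category)
  expect_equal(a2$gene_id, a1$gene_id)
  expect_equal(a2$distance_to_tss, a1$distance_to_tss)
})

test_that("annotation summaries report count and length proportions", {
  gm <- read_fixture_genes(gene_lines("g1", "chr1", 10000, 15000, "+"))
  pk <- peaks_tbl("chr1",
                  start = c(9500, 9600, 60000, 70000) - 50,
                  end = c(9500 + 50, 9600 + 50, 60150, 70150))
  pk$end <- as.integer(c(9550, 9650, 60250, 70250))
  pk$start <- as.integer(c(9450, 9550, 59950, 69950))
  # two promoter peaks of length 100, two intergenic of length 300
  summ <- summarize_annotation(annotate_peaks(pk, gm))
  prom <- summ[summ$category == "PROMOTER_TSS", ]
  inter <- summ[summ$category == "INTERGENIC", ]
  expect_equal(prom$prop_count, 0.5)
  expect_equal(inter$prop_count, 0.5)
  expect_equal(prom$prop_length, 0.25)
  expect_equal(inter$prop_length, 0.75)
  expect_equal(sum(summ$prop_count), 1, tolerance = 1e-9)
  expect_equal(sum(summ$prop_length), 1, tolerance = 1e-9)

  single <- summarize_annotation(annotate_peaks(pk[1, ], gm))
  expect_equal(single$prop_count[single$category == "PROMOTER_TSS"], 1)
  expect_error(summarize_annotation(annotate_peaks(pk[0, ], gm)), "empty")
})
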