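small_cfg <- function(seed = 1) {
  sim_config(seed = seed, n_chroms = 1, chrom_len = 300000L, n_genes = 20,
             peak_counts = c(H3K4me1 = 30, H3K4me3 = 25, H3K27me3 = 15,
                             ATAC = 25),
             n_profiles = 2, reps_per_profile = 1,
             screen = list(n_per_group = 4L, n_specific = 5L,
                           n_marine_absent = 1L, n_stream_absent = 1L,
                           n_unmarked = 1L, n_deletion = 2L, depth = 30,
                           marine_fw_tpm = 200, marine_sw_tpm = 100,
                           stream_fw_tpm = 0.5))
}

test_that("simulated annotations satisfy the gene-model invariants", {
  ann <- simulate_annotation(small_cfg())
  g <- ann$genes$genes
  expect_true(all(g$start >= 0 & g$start < g$end))
  expect_true(all(g$end <= ann$chrom_sizes[g$chrom]))
  # non-overlapping with >= 2 kb gaps
  expect_true(all(diff(g$start) - (g$end - g$start)[-nrow(g)] >= 2000))
  # strand-aware TSS/TTS
  plus <- g$strand == "+"
  expect_equal(g$tss[plus], g$start[plus])
  expect_equal(g$tss[!plus], g$end[!plus] - 1L)
  ex <- ann$genes$exons
  expect_true(all(ex$start >= g$start[match(ex$gene_id, g$gene_id)]))
  expect_true(all(ex$end <= g$end[match(ex$gene_id, g$gene_id)]))

  empty <- simulate_annotation(sim_config(seed = 2, n_genes = 0))
  expect_equal(nrow(empty$genes$genes), 0)
  expect_error(simulate_annotation(sim_config(chrom_len = 20000L,
                                              n_genes = 50)),
               "chrom_len")
})

test_that("peak truth categories agree with the classifier", {
  cfg <- small_cfg(3)
  ann <- simulate_annotation(cfg)
  pk <- simulate_peaks(cfg, ann)
  a <- purrr::map_dfr(unique(pk$peaks$mark), function(mk) {
    annotate_peaks(dplyr::filter(pk$peaks, mark == mk), ann$genes,
                   ann$chrom_sizes)
  })
  truth <- pk$truth[match(a$name, pk$truth$name), ]
  expect_equal(a$category, truth$true_category)

  # an all-promoter mark stays all-promoter
  cfg2 <- sim_config(seed = 4, n_chroms = 1, chrom_len = 300000L,
                     n_genes = 20,
                     peak_counts = c(H3K4me3 = 40),
                     category_weights = list(H3K4me3 = c(1, 0, 0, 0, 0)))
  ann2 <- simulate_annotation(cfg2)
  pk2 <- simulate_peaks(cfg2, ann2)
  a2 <- annotate_peaks(pk2$peaks, ann2$genes, ann2$chrom_sizes)
  expect_true(all(a2$category == "PROMOTER_TSS"))
})

test_that("the generator is deterministic and emits consistent truth tables", {
  cfg <- small_cfg(5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  truth <- readr::read_tsv(file.path(d1, "truth_screen.tsv"),
                           show_col_types = FALSE)
  expect_equal(nrow(truth), 5)
  expect_equal(sum(truth$class == "DELETION"), 2)
  expect_true(all(!is.na(truth$del_start[truth$class == "DELETION"])))
})

test_that("planted expression effects point in the expected directions", {
  cfg <- sim_config(seed = 6, n_chroms = 2, chrom_len = 1000000L,
                    n_genes = 300)
  ann <- simulate_annotation(cfg)
  pk <- simulate_peaks(cfg, ann)
  ex <- simulate_expression(cfg, ann, pk)
  tr <- ex$truth
  expect_gt(mean(tr$log_tpm[tr$active & !tr$repressive]),
            mean(tr$log_tpm[!tr$active & !tr$repressive]))
  # negative expression-dN/dS coupling
  rec <- dplyr::left_join(
    tibble::tibble(gene_id = tr$gene_id, tpm = exp(tr$log_tpm) - 1),
    ex$dnds, by = "gene_id")
  keep <- rec$dnds < 99
  expect_lt(suppressWarnings(
    cor(rec$tpm[keep], rec$dnds[keep], method = "spearman")), 0)

  # null effect: no planted difference in expectation
  cfg0 <- sim_config(seed = 6, n_chroms = 2, chrom_len = 1000000L,
                     n_genes = 300, delta_active = 0, delta_repressive = 0)
  ex0 <- simulate_expression(cfg0, ann, pk)
  t0 <- ex0$truth
  expect_gt(suppressWarnings(
    wilcox.test(t0$log_tpm[t0$active], t0$log_tpm[!t0$active])$p.value),
    0.001)
})

test_that("genotype simulation honors theta and produces parseable VCFs", {
  sizes <- c(chr1 = 200000L)
  nopk <- tibble::tibble(chrom = character(), start = integer(),
                         end = integer())
  cfg <- sim_config(seed = 8, theta_out = 0.004, theta_in = 0.004)
  gt <- simulate_genotypes(cfg, sizes, nopk)
  # site count close to theta * L
  expect_gt(nrow(gt$sites), 0.004 * 200000 * 0.7)
  expect_lt(nrow(gt$sites), 0.004 * 200000 * 1.3)
  expect_true(all(diff(gt$sites$pos) > 0))

  # theta = 0: no SNPs, no retained windows
  gt0 <- simulate_genotypes(sim_config(seed = 8, theta_out = 0,
                                       theta_in = 0), sizes, nopk)
  expect_equal(nrow(gt0$sites), 0)
  expect_equal(nrow(windowed_diversity(gt0, sizes)), 0)
})

test_that("screen scenarios refuse impossible plantings", {
  cfg <- small_cfg(9)
  cfg$screen$n_specific <- 19L
  cfg$screen$n_deletion <- 16L
  ann <- simulate_annotation(cfg)
  expect_error(simulate_screen_scenario(cfg, ann), "separated|enough")
})
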