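toy_screen_genes <- function() {
  read_fixture_genes(c(
    gene_lines("g1", "chr1", 50000, 55000, "+"),
    gene_lines("g2", "chr1", 100000, 104000, "-"),
    gene_lines("g3", "chrUn", 5000, 8000, "+")
  ))
}

toy_design <- function() {
  tibble::tibble(
    sample_id = c(paste0("mfw", 1:4), paste0("msw", 1:4), paste0("sfw", 1:4)),
    group = rep(c("MARINE_FW", "MARINE_SW", "STREAM_FW"), each = 4)
  )
}

tpm_row <- function(gene_id, mfw, msw, sfw) {
  vals <- as.list(c(mfw, msw, sfw))
  names(vals) <- c(paste0("mfw", 1:4), paste0("msw", 1:4), paste0("sfw", 1:4))
  tibble::tibble(gene_id = gene_id, !!!vals)
}

flat_cov <- function(depth = 30, len = 200000L) {
  tibble::tibble(chrom = c("chr1", "chrUn"), start = 0L,
                 end = len, depth = depth)
}

test_that("the three ecotype-specificity criteria follow the stated arithmetic", {
  gtpm <- dplyr::bind_rows(
    # mean marine 80 vs 8 x mean stream 9 = 72 -> c1 true; min SW 11 -> c2 true
    tpm_row("g1", rep(80, 4), c(12, 15, 11, 40), rep(9, 4)),
    # stream mean 0 and any marine expression -> c1 true; min SW 10 not > 10
    tpm_row("g2", rep(1, 4), c(10, 20, 20, 20), rep(0, 4)),
    # assembled-chromosome criterion fails on chrUn
    tpm_row("g3", rep(500, 4), rep(100, 4), rep(0, 4))
  )
  fl <- flag_ecotype_specific(gtpm, toy_design(), toy_screen_genes(),
                              assembled_chroms = "chr1")
  expect_equal(fl$c1, c(TRUE, TRUE, TRUE))
  expect_equal(fl$c2, c(TRUE, FALSE, TRUE))
  expect_equal(fl$c3, c(TRUE, TRUE, FALSE))
  expect_equal(fl$pass, c(TRUE, FALSE, FALSE))

  # raising the fold threshold never adds genes to the c1-pass set
  for (f in c(2, 4, 8, 16, 32)) {
    lo <- flag_ecotype_specific(gtpm, toy_design(), toy_screen_genes(),
                                assembled_chroms = "chr1", fold = f)
    hi <- flag_ecotype_specific(gtpm, toy_design(), toy_screen_genes(),
                                assembled_chroms = "chr1", fold = f * 2)
    expect_true(all(fl$gene_id[hi$c1] %in% fl$gene_id[lo$c1]))
  }
})

test_that("gene-body presence is a coverage-fraction rule", {
  genes <- toy_screen_genes()
  expect_true(gene_body_present(flat_cov(30), genes)[["g1"]])
  expect_false(gene_body_present(flat_cov(0), genes)[["g1"]])
  # 40% of the span covered at depth 10: absent under the 50% rule
  gaps <- tibble::tibble(chrom = "chr1", start = 50000L, end = 52000L,
                         depth = 10)
  expect_false(gene_body_present(gaps, genes$genes[1, ])[["g1"]])
  expect_error(gene_body_present(gaps, genes$genes[3, ]), "chrUn")
})

test_that("upstream mark search is strand-aware and mark-restricted", {
  genes <- toy_screen_genes()
  # peak spanning g1's TSS (50000, + strand)
  up <- upstream_marks(genes, peaks_tbl("chr1", 49800, 50300,
                                        mark = "H3K4me3"))
  expect_equal(up$gene_id, "g1")
  expect_equal(up$region_start, 49800L)
  # g2 is - strand with TSS 103999: upstream means larger coordinates
  up2 <- upstream_marks(genes, peaks_tbl("chr1", 108000, 108500,
                                         mark = "H3K4me1"))
  expect_equal(up2$gene_id, "g2")
  # wrong mark: ignored with a warning
  expect_warning(
    none <- upstream_marks(genes, peaks_tbl("chr1", 49800, 50300,
                                            mark = "H3K27me3")),
    "ignoring")
  expect_equal(nrow(none), 0)
  # out of range: 20 kb upstream with a 10 kb search
  far <- upstream_marks(genes, peaks_tbl("chr1", 30000, 30500,
                                         mark = "H3K4me3"))
  expect_equal(nrow(far), 0)
})

test_that("stream deletions are called from differential coverage", {
  region <- list(chrom = "chr1", start = 10000L, end = 11000L)
  marine <- flat_cov(30)
  # full deletion
  stream0 <- tibble::tibble(chrom = "chr1",
                            start = c(0L, 11000L), end = c(10000L, 200000L),
                            depth = 30)
  hit <- detect_candidate_indel(region, marine, stream0)
  expect_equal(hit$type, "DELETION_IN_STREAM")
  expect_equal(c(hit$start, hit$end), c(10000L, 11000L))
  # both covered: no call
  expect_null(detect_candidate_indel(region, marine, flat_cov(30)))
  # gap over 85% of the region: called, with the gap as the interval
  stream85 <- tibble::tibble(chrom = "chr1",
                             start = c(0L, 10850L),
                             end = c(10000L, 200000L), depth = 30)
  hit85 <- detect_candidate_indel(region, marine, stream85)
  expect_equal(c(hit85$start, hit85$end), c(10000L, 10850L))
  # gap over only 50%: below the 80% rule, no call
  stream50 <- tibble::tibble(chrom = "chr1",
                             start = c(0L, 10500L),
                             end = c(10000L, 200000L), depth = 30)
  expect_null(detect_candidate_indel(region, marine, stream50))
  # short region still evaluated, with a warning
  expect_warning(
    short <- detect_candidate_indel(list(chrom = "chr1", start = 10000L,
                                         end = 10030L), marine, stream0),
    "50 bp")
  expect_equal(short$type, "DELETION_IN_STREAM")
})

test_that("the cascade applies dispositions in order and conserves counts", {
  cfg <- sim_config(seed = 61, n_chroms = 2, chrom_len = 1000000L,
                    n_genes = 200)
  ann <- simulate_annotation(cfg)
  scn <- simulate_screen_scenario(cfg, ann)
  rec <- run_cascade(scn$gene_tpm, scn$design, ann$genes,
                     scn$assembled_chroms, scn$marine_cov, scn$stream_cov,
                     scn$peaks)
  counts <- attr(rec, "stage_counts")
  expect_equal(unname(counts["passed_criteria"]),
               sum(counts[DISPOSITION_LEVELS]))
  truth <- scn$truth
  expect_setequal(rec$gene_id[rec$disposition == "CANDIDATE_WITH_INDEL"],
                  truth$gene_id[truth$class == "DELETION"])
  expect_setequal(
    rec$gene_id[rec$disposition == "EXCLUDED_MARINE_GENEBODY_ABSENT"],
    truth$gene_id[truth$class == "MARINE_ABSENT"])
  expect_setequal(rec$gene_id[rec$disposition == "NO_UPSTREAM_MARKS"],
                  truth$gene_id[truth$class == "UNMARKED"])
  with_indel <- rec[rec$disposition == "CANDIDATE_WITH_INDEL", ]
  expect_false(any(is.na(with_indel$indel_start)))

  # no genes passing: empty output, zero tallies
  flat_tpm <- scn$gene_tpm
  for (s in scn$design$sample_id) flat_tpm[[s]] <- 1
  rec0 <- run_cascade(flat_tpm, scn$design, ann$genes, scn$assembled_chroms,
                      scn$marine_cov, scn$stream_cov, scn$peaks)
  expect_equal(nrow(rec0), 0)
  expect_true(all(attr(rec0, "stage_counts") == 0))
})
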