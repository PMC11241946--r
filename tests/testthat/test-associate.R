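make_expr <- function(...) {
  rows <- list(...)
  tibble::tibble(
    transcript_id = purrr::map_chr(rows, 1),
    gene_id = purrr::map_chr(rows, 2),
    gill1 = purrr::map_dbl(rows, 3)
  )
}

test_that("gene TPM is the sum over isoforms", {
  expr <- make_expr(list("t1", "g1", 3), list("t2", "g1", 4),
                    list("t3", "g2", 5), list("t4", "g3", 0),
                    list("t5", "g3", 0))
  agg <- aggregate_isoform_tpm(expr, "gill1")
  expect_equal(agg$tpm[agg$gene_id == "g1"], 7)
  expect_equal(agg$tpm[agg$gene_id == "g2"], 5)
  expect_equal(agg$tpm[agg$gene_id == "g3"], 0)
  expect_error(aggregate_isoform_tpm(expr, "liver9"), "liver9")
})

test_that("gene categories partition the gene set with GENE dominating", {
  gm <- read_fixture_genes(c(
    gene_lines("g1", "chr1", 10000, 15000, "+"),
    gene_lines("g2", "chr1", 40000, 45000, "+"),
    gene_lines("g3", "chr1", 80000, 85000, "+")
  ))
  # g1: one promoter peak AND one intergenic peak nearest to it -> GENE
  # g2: only an intergenic peak nearest -> INTERGENIC; g3: nothing
  pk <- peaks_tbl("chr1", c(9400, 20000, 43000 - 5000), c(9600, 20200, 38200))
  ann <- annotate_peaks(pk, gm)
  cats <- classify_genes(ann, gm)
  expect_equal(cats$category[cats$gene_id == "g1"], "GENE")
  expect_equal(cats$category[cats$gene_id == "g2"], "INTERGENIC")
  expect_equal(cats$category[cats$gene_id == "g3"], "NO_PEAKS")
  expect_equal(nrow(cats), 3)

  # genes on chromosomes the annotation never saw are excluded
  gm2 <- read_fixture_genes(c(
    gene_lines("g1", "chr1", 10000, 15000, "+"),
    gene_lines("g9", "chr9", 10000, 15000, "+")
  ))
  cats2 <- classify_genes(annotate_peaks(pk, gm2), gm2)
  expect_false("g9" %in% cats2$gene_id)
})

test_that("rank-sum comparison reproduces the exact small-sample p-value", {
  rec <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    category = rep(c("GENE", "NO_PEAKS"), each = 3),
    tpm = c(10, 20, 30, 1, 1.2, 1.4),
    log_tpm = log(c(10, 20, 30, 1, 1.2, 1.4) + 1),
    dnds = NA_real_, log_dnds = NA_real_
  )
  cmp <- compare_expression(rec)
  pair <- tidy(cmp)
  # complete separation of 3 vs 3: 2/choose(6,3) = 0.1 two-sided
  expect_equal(pair$p_value, 0.1)
  med <- cmp$groups
  expect_gt(med$median[med$category == "GENE"],
            med$median[med$category == "NO_PEAKS"])

  tied <- dplyr::mutate(rec, log_tpm = 1)
  expect_equal(tidy(compare_expression(tied))$p_value, 1.0)
})

test_that("rank-sum p-values are invariant to monotone transforms of TPM", {
  set.seed(99)
  rec <- tibble::tibble(
    gene_id = paste0("g", 1:80),
    category = rep(c("GENE", "NO_PEAKS"), each = 40),
    tpm = c(rlnorm(40, 1.5), rlnorm(40, 1.0))
  )
  p_raw <- suppressWarnings(
    wilcox.test(rec$tpm[1:40], rec$tpm[41:80])$p.value)
  rec$log_tpm <- log(rec$tpm + 1)
  rec$dnds <- NA_real_; rec$log_dnds <- NA_real_
  expect_equal(tidy(compare_expression(rec))$p_value, p_raw)
})

test_that("unreliable dN/dS estimates are excluded at the inclusive cutoff", {
  d <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                      dnds = c(0.2, 120, 99))
  expect_message(out <- filter_dnds(d), "removed 2")
  expect_equal(out$gene_id, "g1")
  expect_equal(nrow(filter_dnds(d[0, ])), 0)
  expect_error(filter_dnds(tibble::tibble(gene_id = "g", dnds = -1)),
               "negative")
})

test_that("dN/dS comparisons and the expression correlation behave on planted data", {
  set.seed(7)
  n <- 120
  rec <- tibble::tibble(
    gene_id = paste0("g", seq_len(n)),
    category = rep(c("GENE", "NO_PEAKS"), each = n / 2),
    log_tpm = rnorm(n, 2),
    dnds = c(rlnorm(n / 2, -2, 0.3), rlnorm(n / 2, -1, 0.3))
  )
  rec$tpm <- exp(rec$log_tpm) - 1
  rec$log_dnds <- log(rec$dnds + 1)
  cmp <- compare_dnds(rec)
  expect_lt(tidy(cmp)$p_value, 0.001)
  g <- glance(cmp)
  expect_equal(g$n, n)

  # monotone pairs give rho = +/- 1
  mono <- tibble::tibble(tpm = 1:10, dnds = (1:10)^2)
  anti <- tibble::tibble(tpm = 1:10, dnds = rev(1:10))
  expect_equal(correlate_expression_dnds(mono)$rho, 1)
  expect_equal(correlate_expression_dnds(anti)$rho, -1)
  expect_error(correlate_expression_dnds(mono[1:2, ]), ">= 3")
  expect_error(
    correlate_expression_dnds(tibble::tibble(tpm = c(1, 1, 1),
                                             dnds = c(1, 2, 3))),
    "constant")
})

test_that("records partition genes and integrate expression with dN/dS", {
  cfg <- sim_config(seed = 21, n_chroms = 1, chrom_len = 400000L,
                    n_genes = 25, peak_counts = c(H3K4me3 = 30))
  ann <- simulate_annotation(cfg)
  pk <- simulate_peaks(cfg, ann)
  ex <- simulate_expression(cfg, ann, pk)
  a <- annotate_peaks(pk$peaks, ann$genes, ann$chrom_sizes)
  rec <- suppressMessages(
    build_association(ann$genes, a, ex$expr, "gill1", ex$dnds))
  expect_equal(sort(rec$gene_id), sort(ann$genes$genes$gene_id))
  expect_true(all(table(rec$category) >= 0))
  expect_equal(nrow(rec),
               sum(table(factor(rec$category,
                                c("GENE", "INTERGENIC", "NO_PEAKS")))))
  expect_true(all(rec$dnds < 99, na.rm = TRUE))
})
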