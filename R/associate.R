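#' Gene-level TPM by summing isoforms
#'
#' Expression is quantified per transcript; gene-level analyses use the sum
#' of TPM over all isoforms of a gene.
#'
#' @param expr Expression tibble from [read_expression()].
#' @param sample Sample column to aggregate.
#' @return Tibble `gene_id`, `tpm`.
#' @export
aggregate_isoform_tpm <- function(expr, sample) {
  if (!sample %in% names(expr)) {
    abort(sprintf("sample '%s' not found in expression table", sample))
  }
  expr %>%
    group_by(.data$gene_id) %>%
    summarise(tpm = sum(.data[[sample]]), .groups = "drop")
}

#' Classify genes by where their peaks fall
#'
#' Three mutually exclusive categories per (mark, sample): `GENE` if at
#' least one peak of the mark has its center in the gene's promoter, exon,
#' intron or TTS windows; otherwise `INTERGENIC` if the gene is the
#' nearest gene to at least one intergenic peak; otherwise `NO_PEAKS`.
#' A gene with both genic and intergenic peaks is `GENE`.
#'
#' Genes on chromosomes where the annotation saw no peaks at all are
#' excluded rather than labelled `NO_PEAKS`, so absence of data is not
#' confused with absence of marks.
#'
#' @param annotations [annotate_peaks()] output restricted to one mark and
#'   one sample (enforced).
#' @param genes A `gene_models` object.
#' @return Tibble `gene_id`, `category` covering every retained gene.
#' @export
classify_genes <- function(annotations, genes) {
  stopifnot(inherits(genes, "gene_models"))
  if (dplyr::n_distinct(annotations$mark) > 1 ||
      dplyr::n_distinct(annotations$sample_id) > 1) {
    abort("classify_genes expects annotations from a single (mark, sample)")
  }
  genic <- unique(annotations$gene_id[annotations$category != "INTERGENIC"])
  interg <- unique(annotations$gene_id[annotations$category == "INTERGENIC"])
  g <- genes$genes %>% filter(.data$chrom %in% unique(annotations$chrom))
  g %>%
    transmute_category(genic, interg)
}

transmute_category <- function(g, genic, interg) {
  tibble(
    gene_id = g$gene_id,
    category = dplyr::case_when(
      g$gene_id %in% genic ~ "GENE",
      g$gene_id %in% interg ~ "INTERGENIC",
      TRUE ~ "NO_PEAKS"
    )
  )
}

#' Remove genes with unreliable dN/dS estimates
#'
#' When dS approaches zero the dN/dS ratio blows up; genes with
#' dN/dS >= 99 (inclusive) are excluded.
#'
#' @param dnds Tibble `gene_id`, `dnds` with non-negative values.
#' @param cutoff Exclusion threshold (inclusive), default 99.
#' @return The filtered tibble; the number of removals is reported via
#'   [rlang::inform()].
#' @export
filter_dnds <- function(dnds, cutoff = 99) {
  if (any(dnds$dnds < 0, na.rm = TRUE)) abort("negative dN/dS value")
  keep <- is.na(dnds$dnds) | dnds$dnds < cutoff
  if (sum(!keep) > 0) {
    inform(sprintf("filter_dnds: removed %d gene(s) with dN/dS >= %s",
                   sum(!keep), format(cutoff)))
  }
  dnds[keep, ]
}

#' Assemble per-gene association records
#'
#' Joins the gene category (from one mark/sample annotation), gene-level
#' TPM and optionally dN/dS into the record the comparison functions
#' consume. Natural-log transforms `ln(x + 1)` are precomputed.
#'
#' @param genes A `gene_models` object.
#' @param annotations One-mark, one-sample [annotate_peaks()] output.
#' @param expr Expression tibble ([read_expression()]).
#' @param sample Expression sample to use.
#' @param dnds Optional `gene_id`/`dnds` tibble; filtered through
#'   [filter_dnds()].
#' @return Tibble `gene_id`, `category`, `tpm`, `log_tpm`, `dnds`,
#'   `log_dnds`.
#' @export
build_association <- function(genes, annotations, expr, sample, dnds = NULL) {
  cats <- classify_genes(annotations, genes)
  tpm <- aggregate_isoform_tpm(expr, sample)
  rec <- cats %>%
    left_join(tpm, by = "gene_id") %>%
    filter(!is.na(.data$tpm)) %>%
    mutate(log_tpm = log(.data$tpm + 1))
  if (!is.null(dnds)) {
    dnds <- filter_dnds(dnds)
    rec <- rec %>%
      left_join(dnds, by = "gene_id") %>%
      mutate(log_dnds = log(.data$dnds + 1))
  } else {
    rec$dnds <- NA_real_
    rec$log_dnds <- NA_real_
  }
  rec
}

# Pairwise two-sided Wilcoxon rank-sum comparisons of `value` between gene
# categories. stats::wilcox.test picks the exact distribution for small
# untied samples and the tie-corrected normal approximation otherwise.
compare_groups <- function(values, groups, value_name, adjust = "none") {
  keep <- !is.na(values)
  values <- values[keep]
  groups <- groups[keep]
  lev <- intersect(c("GENE", "INTERGENIC", "NO_PEAKS"), unique(groups))
  counts <- table(factor(groups, levels = lev))
  if (sum(counts > 0) < 2) {
    abort("need at least two non-empty categories to compare")
  }
  summary <- tibble(
    category = lev,
    n = as.integer(counts[lev]),
    median = map_dbl(lev, function(l) median(values[groups == l]))
  )
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  res <- map_dfr(pairs, function(p) {
    x <- values[groups == p[1]]
    y <- values[groups == p[2]]
    if (length(x) == 0 || length(y) == 0) {
      warn(sprintf("skipping %s vs %s: empty group", p[1], p[2]))
      return(tibble(group1 = p[1], group2 = p[2],
                    statistic = NA_real_, p_value = NA_real_))
    }
    if (length(unique(c(x, y))) == 1) {
      # fully tied: no evidence either way
      return(tibble(group1 = p[1], group2 = p[2],
                    statistic = length(x) * length(y) / 2, p_value = 1))
    }
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    tibble(group1 = p[1], group2 = p[2],
           statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  res$p_value <- switch(adjust,
    none = res$p_value,
    holm = stats::p.adjust(res$p_value, method = "holm"),
    abort(sprintf("unknown adjustment '%s'", adjust))
  )
  structure(
    list(value = value_name, groups = summary, pairs = res,
         data = tibble(category = groups, value = values)),
    class = "regmark_comparison"
  )
}

#' @export
print.regmark_comparison <- function(x, ...) {
  cat(sprintf("<regmark_comparison> of %s across %d categories\n",
              x$value, nrow(x$groups)))
  print(x$groups)
  print(x$pairs)
  invisible(x)
}

#' Compare expression between gene categories
#'
#' Two-sided Wilcoxon rank-sum tests of `ln(TPM + 1)` for every pair of
#' gene categories, plus per-category n and median. Because the test is
#' rank-based, results are identical on TPM or any monotone transform of
#' it; the log scale is kept for reporting and plotting.
#'
#' @param records [build_association()] output.
#' @param adjust `"none"` (default: raw p-values, as the comparisons are
#'   typically reported) or `"holm"`.
#' @return A `regmark_comparison` object; see [tidy.regmark_comparison()].
#' @export
compare_expression <- function(records, adjust = "none") {
  compare_groups(records$log_tpm, records$category, "log_tpm", adjust)
}

#' Compare dN/dS between gene categories
#'
#' As [compare_expression()] but on `ln(dN/dS + 1)`; genes with missing
#' dN/dS are dropped.
#'
#' @inheritParams compare_expression
#' @export
compare_dnds <- function(records, adjust = "none") {
  compare_groups(records$log_dnds, records$category, "log_dnds", adjust)
}

#' Spearman correlation between expression and dN/dS
#'
#' @param records [build_association()] output; needs >= 3 genes with both
#'   TPM and dN/dS.
#' @return Tibble with `rho`, `p_value`, `n`.
#' @export
correlate_expression_dnds <- function(records) {
  d <- records %>% filter(!is.na(.data$tpm), !is.na(.data$dnds))
  if (nrow(d) < 3) abort("need >= 3 genes with both TPM and dN/dS")
  if (length(unique(d$tpm)) == 1 || length(unique(d$dnds)) == 1) {
    abort("correlation undefined: constant values")
  }
  ct <- suppressWarnings(cor.test(d$tpm, d$dnds, method = "spearman",
                                  alternative = "two.sided"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(d))
}
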