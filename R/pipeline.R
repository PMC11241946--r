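default_thresholds <- function() {
  list(promoter_up = 1000L, promoter_down = 100L, tts_up = 100L,
       tts_down = 1000L, window = 10000L, min_snps = 10L, bin = 5000L,
       dnds_cutoff = 99, fold = 8, min_tpm = 10, search = 10000L,
       min_depth = 2, min_frac = 0.5, del_frac = 0.8)
}

#' Run the full downstream pipeline from a configuration
#'
#' Orchestrates annotate, associate, diversity, cluster and screen
#' stages over plain-file inputs, running each stage only when its inputs
#' are configured. Every stage writes its result as TSV into `outdir`,
#' and a JSON run report records record counts and every filter tally —
#' the audit trail of the exclusion cascade. Output is deterministic:
#' re-running over the same inputs reproduces every file byte for byte.
#'
#' The configuration is a named list (or path to a YAML file) with
#' `outdir`, input paths (`genes`, `chrom_sizes`, `peaks` as a list of
#' `mark`/`path`/`sample_id` entries, `expression`, `tx2gene`,
#' `expr_sample`, `dnds`, `vcf`, `popmap`, `fragments` named paths,
#' `design`, `ecotype_expression`, `marine_cov`, `stream_cov`,
#' `screen_peaks`, `assembled_chroms`) and an optional `thresholds` list
#' overriding the defaults: promoter/TTS window extents, 10 kb diversity
#' window with a 10-SNP minimum, 5 kb coverage bins, dN/dS cutoff 99,
#' 8-fold / TPM 10 screen criteria, and the coverage-rule parameters.
#'
#' @param config Named list or YAML path.
#' @return The run report (named list), invisibly; also written as
#'   `report.json`.
#' @export
run_full <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  thr <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  if (any(unlist(thr[c("window", "min_snps", "bin", "fold", "min_tpm")]) <= 0)) {
    abort("thresholds must be positive")
  }
  outdir <- config$outdir %||% abort("config needs an 'outdir'")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  required_inputs <- function(stage, paths) {
    missing <- paths[!vapply(paths, file.exists, logical(1))]
    if (length(missing) > 0) {
      abort(sprintf("stage '%s': input file not found: %s", stage,
                    missing[[1]]))
    }
  }
  # validate all configured paths before any compute
  flat <- unlist(config[c("genes", "chrom_sizes", "expression", "tx2gene",
                          "dnds", "vcf", "popmap", "design",
                          "ecotype_expression", "marine_cov", "stream_cov",
                          "screen_peaks")])
  flat <- c(flat, vapply(config$peaks %||% list(), function(x) x$path,
                         character(1)),
            unlist(config$fragments %||% list()))
  required_inputs("input check", flat)

  report <- list(thresholds = thr)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  genes <- NULL
  if (!is.null(config$genes)) {
    genes <- stage("genes", read_gene_models(config$genes))
    report$n_genes <- nrow(genes$genes)
  }
  chrom_sizes <- if (!is.null(config$chrom_sizes))
    read_chrom_sizes(config$chrom_sizes) else NULL

  annotations <- NULL
  if (!is.null(config$peaks) && !is.null(genes)) {
    annotations <- stage("annotate", {
      map_dfr(config$peaks, function(pc) {
        pk <- read_peaks(pc$path, pc$mark, pc$sample_id %||% "sample1")
        annotate_peaks(pk, genes, chrom_sizes,
                       promoter_up = thr$promoter_up,
                       promoter_down = thr$promoter_down,
                       tts_up = thr$tts_up, tts_down = thr$tts_down)
      })
    })
    readr::write_tsv(annotations, file.path(outdir, "annotations.tsv"),
                     progress = FALSE)
    summ <- map_dfr(unique(annotations$mark), function(mk) {
      summarize_annotation(annotations %>% filter(.data$mark == mk)) %>%
        mutate(mark = mk)
    })
    readr::write_tsv(summ, file.path(outdir, "annotation_summary.tsv"),
                     progress = FALSE)
    report$annotation <- list(
      n_peaks = nrow(annotations),
      by_category = as.list(table(annotations$category)))
  }

  if (!is.null(config$expression) && !is.null(annotations)) {
    res <- stage("associate", {
      expr <- read_expression(config$expression, config$tx2gene)
      dnds <- if (!is.null(config$dnds)) read_dnds(config$dnds) else NULL
      n_dnds_raw <- if (!is.null(dnds)) nrow(dnds) else NA_integer_
      samp <- config$expr_sample %||% setdiff(names(expr),
                                              c("transcript_id", "gene_id"))[1]
      assoc <- map_dfr(unique(annotations$mark), function(mk) {
        ann1 <- annotations %>% filter(.data$mark == mk)
        build_association(genes, ann1, expr, samp, dnds) %>%
          mutate(mark = mk, sample = samp)
      })
      list(assoc = assoc, n_dnds_raw = n_dnds_raw,
           n_dnds_kept = if (!is.null(dnds))
             nrow(filter_dnds(dnds, thr$dnds_cutoff)) else NA_integer_)
    })
    readr::write_tsv(res$assoc, file.path(outdir, "association.tsv"),
                     progress = FALSE)
    comps <- map_dfr(unique(res$assoc$mark), function(mk) {
      a <- res$assoc %>% filter(.data$mark == mk)
      out <- tidy(compare_expression(a)) %>%
        mutate(mark = mk, value = "log_tpm")
      if (!all(is.na(a$dnds)) &&
          sum(!is.na(a$dnds)) >= 3) {
        out <- bind_rows(out, tidy(compare_dnds(a)) %>%
                           mutate(mark = mk, value = "log_dnds"))
      }
      out
    })
    readr::write_tsv(comps, file.path(outdir, "comparisons.tsv"),
                     progress = FALSE)
    report$association <- list(
      n_genes = nrow(res$assoc) / max(dplyr::n_distinct(res$assoc$mark), 1),
      n_dnds_raw = res$n_dnds_raw,
      n_dnds_removed = if (!is.na(res$n_dnds_raw))
        res$n_dnds_raw - res$n_dnds_kept else NA_integer_)
  }

  if (!is.null(config$vcf) && !is.null(chrom_sizes)) {
    report$diversity <- stage("diversity", {
      gm <- read_genotypes(config$vcf, config$popmap)
      wins <- suppressMessages(
        windowed_diversity(gm, chrom_sizes, window = thr$window,
                           min_snps = thr$min_snps))
      readr::write_tsv(wins, file.path(outdir, "diversity_windows.tsv"),
                       progress = FALSE)
      if (!is.null(annotations)) {
        ov <- map_dfr(unique(annotations$mark), function(mk) {
          pk <- annotations %>% filter(.data$mark == mk)
          tryCatch(
            as_tibble(compare_peak_overlap(wins, pk)) %>% mutate(mark = mk),
            error = function(e) tibble())
        })
        readr::write_tsv(ov, file.path(outdir, "diversity_vs_peaks.tsv"),
                         progress = FALSE)
      }
      list(n_sites = nrow(gm$sites), n_skipped_records = gm$n_skipped,
           n_windows = nrow(wins))
    })
  }

  if (!is.null(config$fragments) && !is.null(chrom_sizes)) {
    report$cluster <- stage("cluster", {
      covs <- map(config$fragments, function(f) {
        bin_fragments(read_fragments(f), chrom_sizes, bin = thr$bin)
      })
      cm <- correlation_matrix(covs)
      readr::write_tsv(
        as_tibble(unclass(cm), rownames = "sample_id"),
        file.path(outdir, "correlation_matrix.tsv"), progress = FALSE)
      write_dendrogram(cluster_samples(cm), file.path(outdir, "dendrogram.nwk"))
      list(n_samples = length(covs))
    })
  }

  if (!is.null(config$design) && !is.null(genes)) {
    report$screen <- stage("screen", {
      eexpr <- read_expression(config$ecotype_expression, config$tx2gene %||%
                                 config$ecotype_tx2gene)
      design <- readr::read_tsv(config$design, show_col_types = FALSE,
                                progress = FALSE)
      samples <- setdiff(names(eexpr), c("transcript_id", "gene_id"))
      gene_tpm <- eexpr %>%
        tidyr::pivot_longer(dplyr::all_of(samples), names_to = "sample_id",
                            values_to = "tpm") %>%
        group_by(.data$gene_id, .data$sample_id) %>%
        summarise(tpm = sum(.data$tpm), .groups = "drop") %>%
        tidyr::pivot_wider(names_from = "sample_id", values_from = "tpm")
      marine_cov <- read_coverage(config$marine_cov)
      stream_cov <- read_coverage(config$stream_cov)
      pk <- read_bed3(config$screen_peaks)
      if (!"mark" %in% names(pk)) {
        pk$mark <- "H3K4me1"
        pk$sample_id <- "screen"
      }
      assembled <- config$assembled_chroms %||% unique(genes$genes$chrom)
      rec <- run_cascade(gene_tpm, design, genes, assembled,
                         marine_cov, stream_cov, pk,
                         fold = thr$fold, min_tpm = thr$min_tpm,
                         search = thr$search, min_depth = thr$min_depth,
                         min_frac = thr$min_frac, del_frac = thr$del_frac)
      readr::write_tsv(rec, file.path(outdir, "screen.tsv"), progress = FALSE)
      as.list(attr(rec, "stage_counts"))
    })
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
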