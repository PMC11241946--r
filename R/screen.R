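#' Screen dispositions, in cascade order
#' @format Character vector of length 5.
#' @export
DISPOSITION_LEVELS <- c("EXCLUDED_MARINE_GENEBODY_ABSENT",
                        "EXCLUDED_STREAM_GENEBODY_ABSENT",
                        "NO_UPSTREAM_MARKS",
                        "CANDIDATE_WITH_INDEL",
                        "CANDIDATE_NO_INDEL")

#' Ecotype design groups
#' @format Character vector: marine fish under freshwater and seawater
#'   acclimation, and stream fish under freshwater.
#' @export
GROUP_LEVELS <- c("MARINE_FW", "MARINE_SW", "STREAM_FW")

check_design <- function(design) {
  design <- as_tibble(design[, c("sample_id", "group")])
  bad <- setdiff(unique(design$group), GROUP_LEVELS)
  if (length(bad) > 0) abort(sprintf("unknown design group '%s'", bad[[1]]))
  if (anyDuplicated(design$sample_id)) abort("duplicated sample in design")
  for (g in GROUP_LEVELS) {
    if (!any(design$group == g)) abort(sprintf("design group %s is empty", g))
  }
  design
}

#' Flag marine-ecotype-specific genes
#'
#' Applies the three screening criteria to gene-level TPM: (1) the mean
#' TPM of the freshwater-acclimated marine samples exceeds `fold` times
#' the mean of the freshwater-acclimated stream samples; (2) the minimum
#' TPM of the seawater-acclimated marine samples is above `min_tpm`; (3)
#' the gene lies on an assembled chromosome. Criterion 1 uses a strict
#' `>`, so any marine expression passes against a zero stream mean.
#'
#' @param gene_tpm Wide tibble: `gene_id` plus one TPM column per sample.
#' @param design Tibble `sample_id`, `group` with groups from
#'   [GROUP_LEVELS].
#' @param genes A `gene_models` object (for chromosome lookup).
#' @param assembled_chroms Character vector of assembled chromosome names.
#' @param fold Fold-change threshold for criterion 1 (default 8).
#' @param min_tpm Minimum-expression threshold for criterion 2 (default 10).
#' @return Tibble `gene_id`, `c1`, `c2`, `c3`, `pass`. Genes absent from
#'   the gene models are skipped with a warning.
#' @export
flag_ecotype_specific <- function(gene_tpm, design, genes, assembled_chroms,
                                  fold = 8, min_tpm = 10) {
  design <- check_design(design)
  missing_samp <- setdiff(design$sample_id, names(gene_tpm))
  if (length(missing_samp) > 0) {
    abort(sprintf("design sample '%s' not in expression table", missing_samp[[1]]))
  }
  g <- genes$genes
  unknown <- setdiff(gene_tpm$gene_id, g$gene_id)
  if (length(unknown) > 0) {
    warn(sprintf("skipping %d gene(s) absent from the gene models",
                 length(unknown)))
    gene_tpm <- gene_tpm %>% filter(.data$gene_id %in% g$gene_id)
  }
  grp <- function(gname) as.matrix(
    gene_tpm[, design$sample_id[design$group == gname], drop = FALSE])
  mfw <- rowMeans(grp("MARINE_FW"))
  sfw <- rowMeans(grp("STREAM_FW"))
  msw_min <- apply(grp("MARINE_SW"), 1, min)
  tibble(
    gene_id = gene_tpm$gene_id,
    c1 = mfw > fold * sfw,
    c2 = msw_min > min_tpm,
    c3 = g$chrom[match(gene_tpm$gene_id, g$gene_id)] %in% assembled_chroms
  ) %>%
    mutate(pass = .data$c1 & .data$c2 & .data$c3)
}

# Per-base depth over [start, end) from a run-length coverage track.
# Bases not covered by any run have depth 0.
depth_vector <- function(cov, chrom, start, end) {
  runs <- cov[cov$chrom == chrom, ]
  if (nrow(runs) == 0) {
    abort(sprintf("no coverage data for chromosome '%s'", chrom))
  }
  v <- numeric(end - start)
  runs <- runs[runs$end > start & runs$start < end, ]
  if (nrow(runs) > 0) {
    s <- pmax(runs$start, start) - start
    e <- pmin(runs$end, end) - start
    for (i in seq_len(nrow(runs))) v[(s[i] + 1):e[i]] <- runs$depth[i]
  }
  v
}

#' Is a gene body covered in an ecotype?
#'
#' Formalizes "gene body present" as a coverage rule: the gene span counts
#' as present when at least `min_frac` of its bases have read depth of at
#' least `min_depth`. This is a reproducible surrogate for calling
#' whole-gene absence by visual inspection of mapped reads.
#'
#' @param cov Coverage track tibble ([read_coverage()]).
#' @param genes A `gene_models` object or genes tibble; one row per gene.
#' @param min_depth Depth a base must reach to count as covered (default 2).
#' @param min_frac Fraction of covered bases required (default 0.5).
#' @return Named logical vector, one element per gene.
#' @export
gene_body_present <- function(cov, genes, min_depth = 2, min_frac = 0.5) {
  g <- if (inherits(genes, "gene_models")) genes$genes else genes
  out <- vapply(seq_len(nrow(g)), function(i) {
    v <- depth_vector(cov, g$chrom[i], g$start[i], g$end[i])
    mean(v >= min_depth) >= min_frac
  }, logical(1))
  setNames(out, g$gene_id)
}

#' Active marks upstream of a gene
#'
#' Looks for H3K4me1 and/or H3K4me3 peaks intersecting the strand-aware
#' upstream window `[TSS - search, TSS + 100)` of each gene and returns
#' the union of the intersecting peak intervals as candidate
#' cis-regulatory regions.
#'
#' @param genes A `gene_models` object or genes tibble.
#' @param peaks Peak tibble restricted to marks H3K4me1/H3K4me3 (other
#'   marks are ignored with a warning).
#' @param search Upstream search distance in bp (default 10000).
#' @return Tibble `gene_id`, `region_start`, `region_end`, one row per
#'   merged candidate region; genes without upstream marks are absent.
#' @export
upstream_marks <- function(genes, peaks, search = 10000L) {
  g <- if (inherits(genes, "gene_models")) genes$genes else genes
  search <- as.integer(search)
  other <- !peaks$mark %in% c("H3K4me1", "H3K4me3")
  if (any(other)) {
    warn(sprintf("ignoring %d peak(s) with marks other than H3K4me1/H3K4me3",
                 sum(other)))
    peaks <- peaks[!other, ]
  }
  if (nrow(peaks) == 0 || nrow(g) == 0) {
    return(tibble(gene_id = character(), region_start = integer(),
                  region_end = integer()))
  }
  plus <- g$strand == "+"
  win_start <- pmax(if_else(plus, g$tss - search, g$tss - 99L), 0L)
  win_end <- if_else(plus, g$tss + 100L, g$tss + search + 1L)
  wgr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(win_start + 1L, win_end))
  pgr <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(peaks$start + 1L, peaks$end))
  ov <- GenomicRanges::findOverlaps(wgr, pgr)
  if (length(ov) == 0) {
    return(tibble(gene_id = character(), region_start = integer(),
                  region_end = integer()))
  }
  map_dfr(unique(S4Vectors::queryHits(ov)), function(qi) {
    pj <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == qi]
    merged <- IRanges::reduce(IRanges::IRanges(peaks$start[pj] + 1L,
                                               peaks$end[pj]))
    tibble(gene_id = g$gene_id[qi],
           region_start = IRanges::start(merged) - 1L,
           region_end = IRanges::end(merged))
  }) %>% arrange(.data$gene_id, .data$region_start)
}

#' Detect an ecotype-specific deletion in a candidate region
#'
#' Compares per-base whole-genome coverage of the two ecotypes over a
#' candidate cis-regulatory region. A stream-specific deletion is called
#' when at least `del_frac` of the region's bases fall below `min_depth`
#' in the stream track while at least `del_frac` reach `min_depth` in the
#' marine track. The reported indel interval is the maximal zero-depth
#' run of the stream track (falling back to the maximal below-threshold
#' run when no base is strictly uncovered).
#'
#' @param region One-row tibble/list with `chrom`, `start`, `end`.
#' @param marine_cov,stream_cov Coverage tracks ([read_coverage()]).
#' @param min_depth Depth below which a base counts as missing (default 2).
#' @param del_frac Fraction of missing bases required (default 0.8).
#' @return `NULL`, or a list with `type` (`"DELETION_IN_STREAM"`),
#'   `chrom`, `start`, `end` of the inferred indel.
#' @export
detect_candidate_indel <- function(region, marine_cov, stream_cov,
                                   min_depth = 2, del_frac = 0.8) {
  chrom <- region$chrom
  start <- region$start
  end <- region$end
  if (end - start < 50) {
    warn(sprintf("candidate region %s:%d-%d is shorter than 50 bp",
                 chrom, start, end))
  }
  mv <- depth_vector(marine_cov, chrom, start, end)
  sv <- depth_vector(stream_cov, chrom, start, end)
  if (mean(sv < min_depth) >= del_frac && mean(mv >= min_depth) >= del_frac) {
    run <- longest_run(sv == 0)
    if (is.null(run)) run <- longest_run(sv < min_depth)
    list(type = "DELETION_IN_STREAM", chrom = chrom,
         start = start + run[1] - 1L, end = start + run[2])
  } else {
    NULL
  }
}

longest_run <- function(flag) {
  if (!any(flag)) return(NULL)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  best <- i[which.max(r$lengths[i])]
  c(starts[best], ends[best])
}

#' Run the full candidate-screen cascade
#'
#' Applies, in order, to every gene passing the three ecotype-specificity
#' criteria: (1) exclusion if the gene body is absent in the marine
#' ecotype; (2) exclusion if absent in the stream ecotype (marine-specific
#' expression then reflects gene presence/absence, not cis-regulation);
#' (3) requirement of H3K4me1/H3K4me3 marks upstream of the TSS; (4)
#' coverage-based detection of a stream deletion over the marked region.
#' Stage counts are attached as `attr(, "stage_counts")`.
#'
#' @param gene_tpm,design,genes,assembled_chroms,fold,min_tpm See
#'   [flag_ecotype_specific()].
#' @param marine_cov,stream_cov Whole-genome coverage tracks per ecotype.
#' @param peaks H3K4me1/H3K4me3 peak tibble.
#' @param search Upstream search distance in bp (default 10000).
#' @param min_depth,min_frac Gene-body presence rule parameters.
#' @param del_frac Deletion-call fraction ([detect_candidate_indel()]).
#' @return Tibble of screen records: `gene_id`, `c1`, `c2`, `c3`,
#'   `disposition`, candidate region and indel coordinates (`NA` when not
#'   applicable).
#' @export
run_cascade <- function(gene_tpm, design, genes, assembled_chroms,
                        marine_cov, stream_cov, peaks,
                        fold = 8, min_tpm = 10, search = 10000L,
                        min_depth = 2, min_frac = 0.5, del_frac = 0.8) {
  flags <- flag_ecotype_specific(gene_tpm, design, genes, assembled_chroms,
                                 fold = fold, min_tpm = min_tpm)
  passed <- flags %>% filter(.data$pass)
  g <- genes$genes
  empty <- tibble(
    gene_id = character(), c1 = logical(), c2 = logical(), c3 = logical(),
    disposition = character(),
    region_chrom = character(), region_start = integer(),
    region_end = integer(), indel_type = character(),
    indel_start = integer(), indel_end = integer()
  )
  counts <- c(passed_criteria = nrow(passed),
              setNames(rep(0L, length(DISPOSITION_LEVELS)), DISPOSITION_LEVELS))
  if (nrow(passed) == 0) {
    attr(empty, "stage_counts") <- counts
    return(empty)
  }
  gp <- g[match(passed$gene_id, g$gene_id), ]
  gm_sub <- list(genes = gp)
  marine_ok <- gene_body_present(marine_cov, gp, min_depth, min_frac)
  stream_ok <- gene_body_present(stream_cov, gp, min_depth, min_frac)
  regions <- upstream_marks(gp, peaks, search = search)

  rec <- map_dfr(seq_len(nrow(passed)), function(i) {
    gid <- passed$gene_id[i]
    base <- tibble(gene_id = gid, c1 = passed$c1[i], c2 = passed$c2[i],
                   c3 = passed$c3[i], disposition = NA_character_,
                   region_chrom = NA_character_, region_start = NA_integer_,
                   region_end = NA_integer_, indel_type = NA_character_,
                   indel_start = NA_integer_, indel_end = NA_integer_)
    if (!marine_ok[[gid]]) {
      base$disposition <- "EXCLUDED_MARINE_GENEBODY_ABSENT"
      return(base)
    }
    if (!stream_ok[[gid]]) {
      base$disposition <- "EXCLUDED_STREAM_GENEBODY_ABSENT"
      return(base)
    }
    reg <- regions %>% filter(.data$gene_id == gid)
    if (nrow(reg) == 0) {
      base$disposition <- "NO_UPSTREAM_MARKS"
      return(base)
    }
    chrom <- gp$chrom[i]
    base$disposition <- "CANDIDATE_NO_INDEL"
    base$region_chrom <- chrom
    base$region_start <- reg$region_start[1]
    base$region_end <- reg$region_end[1]
    for (j in seq_len(nrow(reg))) {
      hit <- detect_candidate_indel(
        list(chrom = chrom, start = reg$region_start[j], end = reg$region_end[j]),
        marine_cov, stream_cov, min_depth = min_depth, del_frac = del_frac)
      if (!is.null(hit)) {
        base$disposition <- "CANDIDATE_WITH_INDEL"
        base$region_start <- reg$region_start[j]
        base$region_end <- reg$region_end[j]
        base$indel_type <- hit$type
        base$indel_start <- hit$start
        base$indel_end <- hit$end
        break
      }
    }
    base
  })
  tab <- table(factor(rec$disposition, levels = DISPOSITION_LEVELS))
  counts[DISPOSITION_LEVELS] <- as.integer(tab)
  attr(rec, "stage_counts") <- counts
  rec
}
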