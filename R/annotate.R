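#' Peak center position
#'
#' The annotation unit is the peak center, defined as
#' `start + floor((end - start) / 2)` on the 0-based half-open interval.
#'
#' @param peaks Tibble with `start`, `end` columns (or a `gene_models`-free
#'   interval tibble).
#' @return Integer vector of center positions.
#' @examples
#' peak_center(tibble::tibble(start = 999L, end = 2000L))  # 1499
#' @export
peak_center <- function(peaks) {
  stopifnot(all(peaks$start < peaks$end))
  as.integer(peaks$start + (peaks$end - peaks$start) %/% 2L)
}

strand_window <- function(genes, anchor, up, down, chrom_sizes = NULL) {
  if (any(genes$strand == ".")) {
    abort(sprintf("gene '%s' is unstranded: promoter/TTS windows are undefined",
                  genes$gene_id[genes$strand == "."][1]))
  }
  plus <- genes$strand == "+"
  start <- if_else(plus, anchor - up, anchor - down)
  end <- if_else(plus, anchor + down + 1L, anchor + up + 1L)
  start <- pmax(start, 0L)
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[genes$chrom])
    end <- if_else(is.na(lim), end, pmin(end, as.integer(lim)))
  }
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = as.integer(start), end = as.integer(end),
         strand = genes$strand)
}

#' Promoter / TSS windows
#'
#' The promoter window runs from 1 kb upstream to 100 bp downstream of the
#' TSS, in gene orientation. For a `-` strand gene "upstream" points to
#' larger coordinates, so the window is mirrored. Windows are clipped at
#' position 0 and, when `chrom_sizes` is given, at the chromosome end.
#'
#' @param genes A `gene_models` object or its `$genes` tibble.
#' @param upstream,downstream Window extent in bp around the TSS.
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
promoter_windows <- function(genes, upstream = 1000L, downstream = 100L,
                             chrom_sizes = NULL) {
  g <- if (inherits(genes, "gene_models")) genes$genes else genes
  strand_window(g, g$tss, as.integer(upstream), as.integer(downstream),
                chrom_sizes)
}

#' Transcription-termination-site windows
#'
#' Mirror image of [promoter_windows()] anchored at the TTS: 100 bp
#' upstream to 1 kb downstream of the termination site, strand-aware.
#'
#' @inheritParams promoter_windows
#' @param upstream,downstream Window extent in bp around the TTS.
#' @export
tts_windows <- function(genes, upstream = 100L, downstream = 1000L,
                        chrom_sizes = NULL) {
  g <- if (inherits(genes, "gene_models")) genes$genes else genes
  strand_window(g, g$tts, as.integer(upstream), as.integer(downstream),
                chrom_sizes)
}

# Candidate regions for the four genic categories, in precedence order.
# Exons are the union across isoforms; the gene span stands in for INTRON
# (an exon hit outranks it, so span-minus-exon behaves as intron).
category_features <- function(gm, chrom_sizes = NULL,
                              promoter_up = 1000L, promoter_down = 100L,
                              tts_up = 100L, tts_down = 1000L) {
  g <- gm$genes
  ex_union <- gm$exons %>%
    group_by(.data$gene_id) %>%
    dplyr::group_modify(function(d, k) {
      r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
      tibble(chrom = d$chrom[1], start = IRanges::start(r) - 1L,
             end = IRanges::end(r))
    }) %>%
    ungroup()
  bind_rows(
    promoter_windows(g, promoter_up, promoter_down, chrom_sizes) %>%
      mutate(category = "PROMOTER_TSS", prec = 1L) %>% select(-"strand"),
    tts_windows(g, tts_up, tts_down, chrom_sizes) %>%
      mutate(category = "TTS", prec = 2L) %>% select(-"strand"),
    ex_union %>% mutate(category = "EXON", prec = 3L),
    g %>% select("gene_id", "chrom", "start", "end") %>%
      mutate(category = "INTRON", prec = 4L)
  )
}

#' Classify peaks into five genomic categories by their centers
#'
#' Each peak center is tested against every gene's promoter window, TTS
#' window, exon union and gene span; the first hit by the precedence
#' PROMOTER_TSS > TTS > EXON > INTRON wins, with ties across genes broken
#' by smaller absolute distance to the TSS and then by gene id. A center
#' in a gene span but outside all exons is intronic. Centers hitting
#' nothing are INTERGENIC and are assigned the gene with the nearest TSS
#' on the same chromosome (none on a gene-less chromosome).
#'
#' `distance_to_tss` is signed in gene orientation: negative means the
#' center lies upstream of the assigned gene's TSS.
#'
#' @param peaks Peak tibble ([read_peaks()]).
#' @param genes A `gene_models` object.
#' @param chrom_sizes Optional named chromosome lengths, used to clip
#'   promoter/TTS windows.
#' @param promoter_up,promoter_down,tts_up,tts_down Window extents in bp.
#' @return The peak tibble with `center`, `category`, `gene_id` and
#'   `distance_to_tss` columns appended, input order preserved.
#' @export
annotate_peaks <- function(peaks, genes, chrom_sizes = NULL,
                           promoter_up = 1000L, promoter_down = 100L,
                           tts_up = 100L, tts_down = 1000L) {
  stopifnot(inherits(genes, "gene_models"))
  out <- as_tibble(peaks)
  n <- nrow(out)
  if (n == 0) {
    return(out %>% mutate(center = integer(), category = character(),
                          gene_id = character(), distance_to_tss = integer()))
  }
  out$center <- peak_center(out)
  feats <- category_features(genes, chrom_sizes, promoter_up, promoter_down,
                             tts_up, tts_down)
  cgr <- GenomicRanges::GRanges(out$chrom,
                                IRanges::IRanges(out$center + 1L, width = 1L))
  fgr <- GenomicRanges::GRanges(feats$chrom,
                                IRanges::IRanges(feats$start + 1L, feats$end))
  hits <- GenomicRanges::findOverlaps(cgr, fgr)
  g <- genes$genes
  gi <- match(feats$gene_id[S4Vectors::subjectHits(hits)], g$gene_id)
  cand <- tibble(
    peak = S4Vectors::queryHits(hits),
    gene_id = feats$gene_id[S4Vectors::subjectHits(hits)],
    category = feats$category[S4Vectors::subjectHits(hits)],
    prec = feats$prec[S4Vectors::subjectHits(hits)]
  )
  cand$dist <- signed_tss_distance(out$center[cand$peak], g, gi)
  best <- cand %>%
    arrange(.data$peak, .data$prec, abs(.data$dist), .data$gene_id) %>%
    distinct(.data$peak, .keep_all = TRUE)

  out$category <- "INTERGENIC"
  out$gene_id <- NA_character_
  out$distance_to_tss <- NA_integer_
  out$category[best$peak] <- best$category
  out$gene_id[best$peak] <- best$gene_id
  out$distance_to_tss[best$peak] <- as.integer(best$dist)

  inter <- which(out$category == "INTERGENIC")
  if (length(inter) > 0 && nrow(g) > 0) {
    nn <- nearest_tss_gene(out$chrom[inter], out$center[inter], g)
    out$gene_id[inter] <- nn$gene_id
    out$distance_to_tss[inter] <- nn$dist
  }
  out
}

signed_tss_distance <- function(center, g, gi) {
  tss <- g$tss[gi]
  if_else(g$strand[gi] == "-", tss - center, center - tss)
}

# Nearest gene by unsigned center-to-TSS distance, ties to the smaller
# gene id; NA on chromosomes without genes.
nearest_tss_gene <- function(chrom, center, g) {
  res_gene <- rep(NA_character_, length(center))
  res_dist <- rep(NA_integer_, length(center))
  for (cr in unique(chrom)) {
    gc <- g[g$chrom == cr, ]
    idx <- which(chrom == cr)
    if (nrow(gc) == 0) next
    gc <- gc[order(gc$tss, gc$gene_id), ]
    for (i in idx) {
      d <- abs(center[i] - gc$tss)
      j <- which(d == min(d))
      j <- j[order(gc$gene_id[j])][1]
      res_gene[i] <- gc$gene_id[j]
      res_dist[i] <- as.integer(signed_tss_distance(center[i], gc, j))
    }
  }
  list(gene_id = res_gene, dist = res_dist)
}

#' Summarize an annotation by category counts and lengths
#'
#' The full length of a peak is attributed to its center's category.
#' Count and length proportions each sum to 1.
#'
#' @param annotations Output of [annotate_peaks()].
#' @return Tibble with one row per category present: `category`, `n`,
#'   `total_length`, `prop_count`, `prop_length`.
#' @export
summarize_annotation <- function(annotations) {
  if (nrow(annotations) == 0) abort("cannot summarize an empty annotation")
  annotations %>%
    mutate(category = factor(.data$category, levels = CATEGORY_LEVELS),
           len = .data$end - .data$start) %>%
    group_by(.data$category, .drop = FALSE) %>%
    summarise(n = dplyr::n(), total_length = sum(.data$len), .groups = "drop") %>%
    mutate(prop_count = .data$n / sum(.data$n),
           prop_length = if (sum(.data$total_length) > 0)
             .data$total_length / sum(.data$total_length) else 0,
           category = as.character(.data$category))
}
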