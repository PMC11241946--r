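#' Per-site nucleotide diversity within a population
#'
#' Unbiased per-site heterozygosity from allele counts: with `m` called
#' alleles of which `c` carry the alternate base,
#' `pi = 2 c (m - c) / (m (m - 1))`, the fraction of allele pairs that
#' differ. Sites with fewer than two called alleles are undefined (`NA`)
#' and are skipped (and counted) by the window accumulator.
#'
#' @param m Called allele count per site (integer vector).
#' @param c Alternate allele count per site, `0 <= c <= m`.
#' @return Numeric vector of per-site pi in `[0, 1]`.
#' @examples
#' site_pi(4, 2)  # 2/3: of the 6 allele pairs, 4 differ
#' @export
site_pi <- function(m, c) {
  stopifnot(all(c >= 0 & c <= m, na.rm = TRUE))
  out <- 2 * c * (m - c) / (m * (m - 1))
  out[m < 2] <- NA_real_
  out
}

#' Per-site between-population divergence
#'
#' With alternate-allele frequencies `p1 = c1/m1` and `p2 = c2/m2`,
#' `dxy = p1 (1 - p2) + p2 (1 - p1)`: the probability that one allele
#' drawn from each population differs. Symmetric in the two populations;
#' a population with zero called alleles makes the site undefined (`NA`).
#'
#' @param m1,c1 Called and alternate allele counts in population 1.
#' @param m2,c2 Same for population 2.
#' @return Numeric vector of per-site Dxy in `[0, 1]`.
#' @export
site_dxy <- function(m1, c1, m2, c2) {
  p1 <- c1 / m1
  p2 <- c2 / m2
  out <- p1 * (1 - p2) + p2 * (1 - p1)
  out[m1 < 1 | m2 < 1] <- NA_real_
  out
}

pop_allele_counts <- function(gm, population) {
  samples <- gm$popmap$sample_id[gm$popmap$population == population]
  sub <- gm$ac[, samples, drop = FALSE]
  list(
    m = as.integer(2L * rowSums(!is.na(sub))),
    c = as.integer(rowSums(sub, na.rm = TRUE))
  )
}

#' Windowed pi and Dxy along the genome
#'
#' Tiles every chromosome with non-overlapping windows (default 10 kb),
#' accumulates per-site pi for each population and per-site Dxy between
#' the two populations, and divides by the number of sites assumed
#' monitored in the window: the window length under the all-site
#' interpretation, or the accessible-base count when a mask is supplied.
#' Invariant (unrepresented) sites therefore contribute zeros, as in
#' all-site window scans. Windows with fewer than `min_snps` usable SNPs
#' are excluded. The trailing partial window of each chromosome is kept,
#' with its true length as denominator, and flagged `partial`.
#'
#' @param gm A `genotype_matrix` with exactly two populations.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param window Window size in bp (default 10000).
#' @param min_snps Minimum usable SNPs per retained window (default 10).
#' @param mask Optional accessibility mask, a tibble `chrom`, `start`,
#'   `end` of callable intervals; sites outside it are ignored and the
#'   denominator becomes the callable-base count.
#' @return Tibble with `chrom`, `start`, `end`, `n_snps`,
#'   `pi_<population>` for each population, `dxy`, `partial`.
#' @export
windowed_diversity <- function(gm, chrom_sizes, window = 10000L,
                               min_snps = 10L, mask = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- sort(unique(gm$popmap$population))
  if (length(pops) != 2) abort("windowed_diversity needs exactly two populations")
  window <- as.integer(window)

  sites <- gm$sites
  keep <- rep(TRUE, nrow(sites))
  if (!is.null(mask)) {
    sgr <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$pos + 1L, width = 1L))
    mgr <- GenomicRanges::GRanges(mask$chrom,
                                  IRanges::IRanges(mask$start + 1L, mask$end))
    keep <- GenomicRanges::countOverlaps(sgr, mgr) > 0
  }
  a1 <- pop_allele_counts(gm, pops[1])
  a2 <- pop_allele_counts(gm, pops[2])
  pi1 <- site_pi(a1$m, a1$c)
  pi2 <- site_pi(a2$m, a2$c)
  dxy <- site_dxy(a1$m, a1$c, a2$m, a2$c)
  usable <- keep & !is.na(pi1) & !is.na(pi2) & !is.na(dxy)
  n_skipped <- sum(keep & !usable)
  if (n_skipped > 0) {
    inform(sprintf("windowed_diversity: skipped %d site(s) with < 2 called alleles in a population",
                   n_skipped))
  }

  wins <- map_dfr(names(chrom_sizes), function(cr) {
    len <- as.integer(chrom_sizes[[cr]])
    starts <- seq(0L, len - 1L, by = window)
    tibble(chrom = cr, start = starts,
           end = pmin(starts + window, len))
  }) %>%
    mutate(partial = (.data$end - .data$start) < window)

  idx <- usable & sites$chrom %in% names(chrom_sizes)
  win_of <- paste0(sites$chrom, ":", sites$pos %/% window)
  key <- paste0(wins$chrom, ":", wins$start %/% window)
  agg <- tibble(win = win_of[idx], pi1 = pi1[idx], pi2 = pi2[idx],
                dxy = dxy[idx]) %>%
    group_by(.data$win) %>%
    summarise(n_snps = dplyr::n(), s_pi1 = sum(.data$pi1),
              s_pi2 = sum(.data$pi2), s_dxy = sum(.data$dxy),
              .groups = "drop")
  m <- match(key, agg$win)
  wins$n_snps <- if_else(is.na(m), 0L, agg$n_snps[m])
  s1 <- if_else(is.na(m), 0, agg$s_pi1[m])
  s2 <- if_else(is.na(m), 0, agg$s_pi2[m])
  sd_ <- if_else(is.na(m), 0, agg$s_dxy[m])

  L <- as.numeric(wins$end - wins$start)
  if (!is.null(mask)) {
    wgr <- GenomicRanges::GRanges(wins$chrom,
                                  IRanges::IRanges(wins$start + 1L, wins$end))
    mgr <- GenomicRanges::GRanges(mask$chrom,
                                  IRanges::IRanges(mask$start + 1L, mask$end))
    ov <- GenomicRanges::findOverlaps(wgr, mgr)
    ww <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(wgr)[S4Vectors::queryHits(ov)],
      IRanges::ranges(mgr)[S4Vectors::subjectHits(ov)]))
    L <- rep(0, nrow(wins))
    acc <- tapply(ww, S4Vectors::queryHits(ov), sum)
    L[as.integer(names(acc))] <- as.numeric(acc)
  }
  ok <- wins$n_snps >= min_snps & L > 0
  out <- wins[ok, ]
  out[[paste0("pi_", pops[1])]] <- s1[ok] / L[ok]
  out[[paste0("pi_", pops[2])]] <- s2[ok] / L[ok]
  out$dxy <- sd_[ok] / L[ok]
  out %>% select("chrom", "start", "end", "n_snps",
                 dplyr::starts_with("pi_"), "dxy", "partial")
}

#' Compare diversity inside versus outside peaks
#'
#' Flags each window `in_peak` when it overlaps at least one peak of the
#' mark by at least `min_overlap` bp (default 1), then runs two-sided
#' Wilcoxon rank-sum tests on pi and on Dxy between peak(+) and peak(-)
#' windows.
#'
#' @param windows [windowed_diversity()] output.
#' @param peaks Peak tibble for one mark.
#' @param population Which population's pi to test; defaults to the first
#'   `pi_` column.
#' @param min_overlap Minimum overlap in bp for `in_peak` (default 1).
#' @return A `peak_overlap_comparison`: tibble with one row per metric
#'   (`pi`, `dxy`): group sizes, medians, rank-sum statistic, p-value.
#'   The window tibble with its `in_peak` flag is attached as
#'   `attr(, "windows")`.
#' @export
compare_peak_overlap <- function(windows, peaks, population = NULL,
                                 min_overlap = 1L) {
  pi_cols <- grep("^pi_", names(windows), value = TRUE)
  pi_col <- if (is.null(population)) pi_cols[1] else paste0("pi_", population)
  if (!pi_col %in% names(windows)) {
    abort(sprintf("no column '%s' in windows", pi_col))
  }
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L, windows$end))
  pgr <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(peaks$start + 1L, peaks$end))
  # peaks on chromosomes without windows are simply non-overlapping;
  # silence the disjoint-seqlevels warning that comparison triggers
  windows$in_peak <- suppressWarnings(GenomicRanges::countOverlaps(
    wgr, pgr, minoverlap = as.integer(min_overlap)) > 0)
  if (all(windows$in_peak) || !any(windows$in_peak)) {
    abort("both peak(+) and peak(-) window groups must be non-empty")
  }
  one <- function(metric, v) {
    x <- v[windows$in_peak]
    y <- v[!windows$in_peak]
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    tibble(metric = metric, n_in = length(x), n_out = length(y),
           median_in = median(x), median_out = median(y),
           statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  res <- bind_rows(one("pi", windows[[pi_col]]), one("dxy", windows$dxy))
  attr(res, "windows") <- windows
  class(res) <- c("peak_overlap_comparison", class(res))
  res
}
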