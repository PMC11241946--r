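#' Bin fragment coverage over fixed genomic windows
#'
#' Tiles each chromosome with `bin`-sized windows and counts, for every
#' bin, the fragments overlapping it: a fragment spanning a bin boundary
#' increments both bins, mirroring extended-read coverage counting.
#' Fragments running past a chromosome end are clipped with a warning.
#'
#' @param fragments Tibble `chrom`, `start`, `end` ([read_fragments()]).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin Bin size in bp (default 5000).
#' @return Tibble `chrom`, `start`, `end`, `count` tiling the genome.
#' @export
bin_fragments <- function(fragments, chrom_sizes, bin = 5000L) {
  bin <- as.integer(bin)
  bins <- map_dfr(names(chrom_sizes), function(cr) {
    len <- as.integer(chrom_sizes[[cr]])
    starts <- seq(0L, len - 1L, by = bin)
    tibble(chrom = cr, start = starts, end = pmin(starts + bin, len),
           count = 0L)
  })
  fr <- fragments %>% filter(.data$chrom %in% names(chrom_sizes))
  if (nrow(fr) < nrow(fragments)) {
    warn(sprintf("dropped %d fragment(s) on unknown chromosomes",
                 nrow(fragments) - nrow(fr)))
  }
  if (nrow(fr) == 0) return(bins)
  lim <- unname(chrom_sizes[fr$chrom])
  if (any(fr$end > lim)) {
    warn(sprintf("clipped %d fragment(s) extending past a chromosome end",
                 sum(fr$end > lim)))
    fr$end <- pmin(fr$end, lim)
  }
  fr <- fr %>% filter(.data$start < .data$end)
  for (cr in unique(fr$chrom)) {
    f <- fr[fr$chrom == cr, ]
    first <- f$start %/% bin
    last <- (f$end - 1L) %/% bin
    idx <- unlist(map2(first, last, seq))
    tab <- tabulate(idx + 1L, nbins = sum(bins$chrom == cr))
    bins$count[bins$chrom == cr] <- tab
  }
  bins
}

#' Spearman correlation matrix of binned coverages
#'
#' Concatenates each sample's genome-wide bin counts into one vector and
#' computes all pairwise Spearman correlations.
#'
#' @param coverages Named list of [bin_fragments()] outputs with identical
#'   binning (>= 2 samples).
#' @param drop_zero_bins Drop bins with zero count in every sample before
#'   correlating (default `FALSE`: all bins kept).
#' @return Symmetric correlation matrix with samples in name order.
#' @export
correlation_matrix <- function(coverages, drop_zero_bins = FALSE) {
  if (length(coverages) < 2) abort("need >= 2 samples")
  if (is.null(names(coverages)) || any(!nzchar(names(coverages)))) {
    abort("coverages must be a named list")
  }
  ref <- coverages[[1]][, c("chrom", "start", "end")]
  for (nm in names(coverages)) {
    if (!identical(coverages[[nm]][, c("chrom", "start", "end")], ref)) {
      abort(sprintf("sample '%s' has different binning", nm))
    }
  }
  ord <- order(names(coverages))
  mat <- do.call(cbind, map(coverages[ord], "count"))
  colnames(mat) <- names(coverages)[ord]
  if (drop_zero_bins) mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  const <- apply(mat, 2, function(v) length(unique(v)) == 1)
  if (any(const)) {
    abort(sprintf("constant coverage vector for sample '%s': Spearman rho undefined",
                  colnames(mat)[const][1]))
  }
  cm <- cor(mat, method = "spearman")
  class(cm) <- c("regmark_corr", class(cm))
  cm
}

#' Average-linkage clustering of samples from a correlation matrix
#'
#' Clusters on the distance `1 - rho` with average linkage. Samples are
#' ordered by id before clustering, so the result (merge heights and
#' topology) does not depend on input order.
#'
#' @param cm Correlation matrix from [correlation_matrix()].
#' @return An [stats::hclust] object.
#' @export
cluster_samples <- function(cm) {
  if (nrow(cm) < 2) abort("need >= 2 samples to cluster")
  ord <- order(rownames(cm))
  d <- as.dist(1 - unclass(cm)[ord, ord])
  hclust(d, method = "average")
}

#' Write a dendrogram in Newick format
#' @param hc An [stats::hclust] object ([cluster_samples()]).
#' @param path Output `.nwk` path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
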