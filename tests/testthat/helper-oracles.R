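# Independent brute-force oracles. These re-derive expected results from
# first principles (per-gene window arithmetic, exhaustive allele-pair
# enumeration) without touching the package's interval machinery.

# Exon intervals grouped per gene, for the classification oracle.
oracle_exon_index <- function(exons) {
  split(exons[, c("start", "end")], exons$gene_id)
}

# Classify one peak center against every gene with straight-line window
# arithmetic. Each gene contributes its best (lowest-precedence-number)
# category; the winner is the lexicographic minimum of
# (precedence, |TSS distance|, gene_id), falling back to the nearest TSS
# for intergenic centers.
oracle_classify <- function(center, chrom, genes, exon_index,
                            pu = 1000, pd = 100, tu = 100, td = 1000) {
  g <- genes[genes$chrom == chrom, ]
  if (nrow(g) == 0) {
    return(list(category = "INTERGENIC", gene_id = NA_character_))
  }
  minus <- g$strand == "-"
  dist <- ifelse(minus, g$tss - center, center - g$tss)
  in_prom <- ifelse(minus,
                    center >= g$tss - pd & center <= g$tss + pu,
                    center >= g$tss - pu & center <= g$tss + pd)
  in_tts <- ifelse(minus,
                   center >= g$tts - td & center <= g$tts + tu,
                   center >= g$tts - tu & center <= g$tts + td)
  in_exon <- vapply(g$gene_id, function(id) {
    ex <- exon_index[[id]]
    !is.null(ex) && any(center >= ex$start & center < ex$end)
  }, logical(1))
  in_span <- center >= g$start & center < g$end
  prec <- rep(Inf, nrow(g))
  prec[in_span] <- 4
  prec[in_exon] <- 3
  prec[in_tts] <- 2
  prec[in_prom] <- 1
  if (all(is.infinite(prec))) {
    d <- abs(center - g$tss)
    j <- which(d == min(d))
    j <- j[order(g$gene_id[j])][1]
    return(list(category = "INTERGENIC", gene_id = g$gene_id[j]))
  }
  ord <- order(prec, abs(dist), g$gene_id)
  best <- ord[1]
  list(category = c("PROMOTER_TSS", "TTS", "EXON", "INTRON")[prec[best]],
       gene_id = g$gene_id[best])
}

# Expand allele counts into individual alleles (2 per called diploid).
oracle_alleles <- function(ac) {
  ac <- ac[!is.na(ac)]
  unlist(lapply(ac, function(a) c(rep(1, a), rep(0, 2 - a))))
}

# Per-site pi by enumerating every within-population allele pair.
oracle_site_pi <- function(ac) {
  a <- oracle_alleles(ac)
  m <- length(a)
  if (m < 2) return(NA_real_)
  pairs <- outer(a, a, "!=")
  sum(pairs[upper.tri(pairs)]) / choose(m, 2)
}

# Per-site Dxy by enumerating every between-population allele pair.
oracle_site_dxy <- function(ac1, ac2) {
  a1 <- oracle_alleles(ac1)
  a2 <- oracle_alleles(ac2)
  if (length(a1) < 1 || length(a2) < 1) return(NA_real_)
  sum(outer(a1, a2, "!=")) / (length(a1) * length(a2))
}

# Windowed pi/dxy by summing the enumeration oracles per window.
oracle_windowed <- function(gm, chrom_sizes, window = 10000, min_snps = 10) {
  pops <- sort(unique(gm$popmap$population))
  s1 <- gm$popmap$sample_id[gm$popmap$population == pops[1]]
  s2 <- gm$popmap$sample_id[gm$popmap$population == pops[2]]
  out <- NULL
  for (cr in names(chrom_sizes)) {
    len <- chrom_sizes[[cr]]
    for (ws in seq(0, len - 1, by = window)) {
      we <- min(ws + window, len)
      idx <- which(gm$sites$chrom == cr & gm$sites$pos >= ws &
                     gm$sites$pos < we)
      vals <- lapply(idx, function(i) {
        p1 <- oracle_site_pi(gm$ac[i, s1])
        p2 <- oracle_site_pi(gm$ac[i, s2])
        d <- oracle_site_dxy(gm$ac[i, s1], gm$ac[i, s2])
        if (is.na(p1) || is.na(p2) || is.na(d)) return(NULL)
        c(p1, p2, d)
      })
      vals <- do.call(rbind, vals)
      n <- if (is.null(vals)) 0 else nrow(vals)
      if (n < min_snps) next
      L <- we - ws
      out <- rbind(out, data.frame(
        chrom = cr, start = ws, end = we, n_snps = n,
        pi1 = sum(vals[, 1]) / L, pi2 = sum(vals[, 2]) / L,
        dxy = sum(vals[, 3]) / L, stringsAsFactors = FALSE))
    }
  }
  out
}

# Random genotype matrix (with missing data) built directly, for oracle
# comparisons and VCF round-trips.
random_genotype_matrix <- function(n_samples, n_sites, chrom_len,
                                   miss_rate = 0.1, chroms = "chrA") {
  ns <- n_samples
  samples <- sprintf("s%02d", seq_len(ns))
  pop <- rep(c("popA", "popB"), length.out = ns)
  sites <- data.frame(
    chrom = sample(chroms, n_sites, replace = TRUE),
    pos = sample.int(chrom_len, n_sites) - 1L
  )
  sites <- sites[order(sites$chrom, sites$pos), ]
  sites <- sites[!duplicated(sites), ]
  k <- nrow(sites)
  ac <- matrix(sample(0:2, k * ns, replace = TRUE), k, ns,
               dimnames = list(NULL, samples))
  ac[matrix(runif(k * ns) < miss_rate, k, ns)] <- NA_integer_
  regmark:::new_genotype_matrix(
    tibble::as_tibble(sites), ac,
    tibble::tibble(sample_id = samples, population = pop), 0L)
}

# Two disjoint sibling leaves in an hclust tree.
are_siblings <- function(hc, a, b) {
  ia <- match(a, hc$labels)
  ib <- match(b, hc$labels)
  any(apply(hc$merge, 1, function(r) setequal(r, c(-ia, -ib))))
}
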