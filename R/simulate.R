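#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults
#' describe a small two-chromosome genome whose statistical structure
#' mirrors the experimental design the pipeline analyzes: active marks
#' (H3K4me1, H3K4me3, ATAC) enriched at genes and shifting expression up
#' by `delta_active` on the ln(TPM+1) scale, the repressive H3K27me3
#' shifting it down, dN/dS negatively coupled to expression, per-site
#' polymorphism probability doubled inside peaks, and a three-group
#' marine/stream ecotype expression design with planted upstream
#' deletions.
#'
#' @param seed Integer seed; every generator call is deterministic given
#'   the config.
#' @param n_chroms,chrom_len Genome shape (default 2 x 1 Mb).
#' @param n_genes Number of genes, placed uniformly with >= 2 kb gaps.
#' @param gene_len_range,n_exon_range Per-gene length (bp) and exon count.
#' @param peak_counts Named integer vector: peaks to draw per mark.
#' @param category_weights Named list per mark of five category weights
#'   (PROMOTER_TSS, TTS, EXON, INTRON, INTERGENIC) biasing where peak
#'   centers land; active promoter marks are promoter-enriched,
#'   heterochromatin marks intergenic-enriched.
#' @param peak_len_range Peak length range in bp.
#' @param expr_mu,expr_sigma Baseline mean/sd of ln(TPM+1).
#' @param delta_active,delta_repressive Planted shifts of ln(TPM+1) for
#'   genes carrying genic active / H3K27me3 peaks.
#' @param expr_samples Names of expression samples to emit.
#' @param dnds_a,dnds_b,dnds_sigma dN/dS model
#'   `exp(a - b ln(TPM+1) + N(0, sigma))`: `b > 0` plants the negative
#'   expression--dN/dS correlation.
#' @param dnds_outlier_frac Fraction of genes given an inflated
#'   dN/dS >= 99 (the unreliable estimates the filter removes).
#' @param theta_out,theta_in Per-base polymorphism probability outside /
#'   inside peaks.
#' @param n_per_pop Diploid samples per population (default 4, as in a
#'   small two-ecotype resequencing panel).
#' @param beta_alpha Symmetric Beta parameter for population allele
#'   frequencies at polymorphic sites.
#' @param n_profiles,reps_per_profile,frag_depth Fragment-simulation
#'   shape for clustering: planted coverage profiles, replicates each,
#'   mean fragments per bin.
#' @param bin Bin size for fragment profiles (default 5000).
#' @param screen Named list for the screen scenario: group sizes
#'   (`n_per_group`), planted class counts (`n_specific`,
#'   `n_marine_absent`, `n_stream_absent`, `n_unmarked`, `n_deletion`),
#'   background depth, and marine/stream expression levels.
#' @return A `sim_config` list.
#' @export
sim_config <- function(
    seed = 1L,
    n_chroms = 2L, chrom_len = 1000000L,
    n_genes = 100L,
    gene_len_range = c(1000L, 5000L),
    n_exon_range = c(1L, 5L),
    peak_counts = c(H3K4me1 = 150L, H3K4me3 = 120L, H3K27me3 = 100L,
                    H3K9me3 = 80L, ATAC = 150L),
    category_weights = list(
      H3K4me1 = c(0.30, 0.10, 0.10, 0.20, 0.30),
      H3K4me3 = c(0.55, 0.10, 0.10, 0.10, 0.15),
      H3K27me3 = c(0.20, 0.10, 0.10, 0.20, 0.40),
      H3K9me3 = c(0.05, 0.05, 0.05, 0.15, 0.70),
      ATAC = c(0.45, 0.10, 0.10, 0.15, 0.20),
      IgG = c(0.2, 0.2, 0.2, 0.2, 0.2)
    ),
    peak_len_range = c(200L, 2000L),
    expr_mu = 1.5, expr_sigma = 1.0,
    delta_active = 1.0, delta_repressive = 1.0,
    expr_samples = "gill1",
    dnds_a = -1.0, dnds_b = 0.3, dnds_sigma = 0.5,
    dnds_outlier_frac = 0.01,
    theta_out = 0.005, theta_in = 0.010,
    n_per_pop = 4L, beta_alpha = 0.5,
    n_profiles = 3L, reps_per_profile = 2L, frag_depth = 20,
    bin = 5000L,
    screen = list(n_per_group = 4L, n_specific = 8L, n_marine_absent = 2L,
                  n_stream_absent = 2L, n_unmarked = 1L, n_deletion = 3L,
                  depth = 30, marine_fw_tpm = 200, marine_sw_tpm = 100,
                  stream_fw_tpm = 0.5)) {
  stopifnot(theta_out >= 0, theta_out <= 0.1, theta_in >= 0, theta_in <= 0.1,
            expr_sigma > 0, n_genes >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Independent sub-seed per generator so each simulate_* is reproducible on
# its own and the draws of one stage do not shift another's.
sim_seed <- function(cfg, offset) set.seed(cfg$seed * 1000L + offset)

sim_chrom_sizes <- function(cfg) {
  setNames(rep(as.integer(cfg$chrom_len), cfg$n_chroms),
           paste0("chr", seq_len(cfg$n_chroms)))
}

#' Simulate a gene annotation
#'
#' Places non-overlapping genes with uniform random gaps of at least 2 kb,
#' random strands, and 1-5 exons per gene (one transcript per gene; exon
#' boundaries drawn inside the span, first and last exon flush with the
#' gene ends).
#'
#' @param cfg A [sim_config()].
#' @return List with a `gene_models` object (`$genes` etc.) and
#'   `$chrom_sizes`.
#' @export
simulate_annotation <- function(cfg) {
  sim_seed(cfg, 1L)
  sizes <- sim_chrom_sizes(cfg)
  min_gap <- 2000L
  n_per <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  genes <- list(); txs <- list(); exs <- list()
  gid <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    n <- n_per[ci]
    if (n == 0) next
    len <- sample(seq(cfg$gene_len_range[1], cfg$gene_len_range[2]), n,
                  replace = TRUE)
    slack <- cfg$chrom_len - sum(len) - (n + 1L) * min_gap
    if (slack < 0) {
      abort(sprintf("genes do not fit on chr%d: increase chrom_len to >= %d",
                    ci, sum(len) + (n + 1L) * min_gap))
    }
    cuts <- sort(c(0, runif(n), 1))
    extra <- floor(diff(cuts) * slack)
    starts <- min_gap + cumsum(c(0L, len[-n] + min_gap)) +
      cumsum(extra[seq_len(n)])
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gene_id <- sprintf("g%04d", gid + seq_len(n))
    tx_id <- paste0(gene_id, ".t1")
    s <- as.integer(starts)
    e <- as.integer(starts + len)
    k <- sample(seq(cfg$n_exon_range[1], cfg$n_exon_range[2]), n,
                replace = TRUE)
    k <- pmax(pmin(k, (e - s) %/% 100L), 1L)
    ex_list <- map(seq_len(n), function(i) {
      if (k[i] == 1) return(cbind(s[i], e[i]))
      br <- sort(sample(seq(s[i] + 1L, e[i] - 1L), 2L * (k[i] - 1L)))
      cbind(c(s[i], br[seq(2, length(br), by = 2)]),
            c(br[seq(1, length(br), by = 2)], e[i]))
    })
    nex <- vapply(ex_list, nrow, integer(1))
    exm <- do.call(rbind, ex_list)
    genes[[ci]] <- tibble(gene_id = gene_id, chrom = names(sizes)[ci],
                          start = s, end = e, strand = strand)
    txs[[ci]] <- tibble(transcript_id = tx_id, gene_id = gene_id,
                        chrom = names(sizes)[ci], start = s, end = e,
                        strand = strand)
    exs[[ci]] <- tibble(gene_id = rep(gene_id, nex),
                        transcript_id = rep(tx_id, nex),
                        chrom = names(sizes)[ci],
                        start = as.integer(exm[, 1]),
                        end = as.integer(exm[, 2]),
                        strand = rep(strand, nex))
    gid <- gid + n
  }
  if (gid == 0) {
    gm <- new_gene_models(
      tibble(gene_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), tss = integer(),
             tts = integer(), n_transcripts = integer()),
      tibble(transcript_id = character(), gene_id = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character()),
      tibble(gene_id = character(), transcript_id = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character()))
    return(list(genes = gm, chrom_sizes = sizes))
  }
  g <- bind_rows(genes) %>%
    mutate(tss = if_else(.data$strand == "-", .data$end - 1L, .data$start),
           tts = if_else(.data$strand == "-", .data$start, .data$end - 1L),
           n_transcripts = 1L) %>%
    arrange(.data$chrom, .data$start, .data$gene_id)
  gm <- new_gene_models(g, bind_rows(txs) %>% arrange(.data$gene_id),
                        bind_rows(exs) %>%
                          arrange(.data$gene_id, .data$transcript_id,
                                  .data$start))
  list(genes = validate_gene_models(gm), chrom_sizes = sizes)
}

# Genome-wide category partition honoring the classification precedence:
# every base belongs to exactly one of the five categories.
category_partition <- function(gm, chrom_sizes) {
  gr <- function(df) GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1L, df$end),
    seqinfo = GenomeInfoDb::Seqinfo(names(chrom_sizes),
                                    as.integer(chrom_sizes)))
  genome <- GenomicRanges::GRanges(
    names(chrom_sizes), IRanges::IRanges(1L, as.integer(chrom_sizes)))
  if (nrow(gm$genes) == 0) {
    return(list(PROMOTER_TSS = GenomicRanges::GRanges(),
                TTS = GenomicRanges::GRanges(),
                EXON = GenomicRanges::GRanges(),
                INTRON = GenomicRanges::GRanges(),
                INTERGENIC = genome))
  }
  pr <- GenomicRanges::reduce(gr(promoter_windows(gm$genes,
                                                  chrom_sizes = chrom_sizes)))
  tt <- GenomicRanges::reduce(gr(tts_windows(gm$genes,
                                             chrom_sizes = chrom_sizes)))
  ex <- GenomicRanges::reduce(gr(gm$exons))
  sp <- GenomicRanges::reduce(gr(gm$genes))
  tt2 <- GenomicRanges::setdiff(tt, pr)
  ex2 <- GenomicRanges::setdiff(ex, GenomicRanges::union(pr, tt))
  in2 <- GenomicRanges::setdiff(sp, GenomicRanges::reduce(
    c(pr, tt, ex)))
  ig <- GenomicRanges::setdiff(genome, GenomicRanges::reduce(
    c(pr, tt, sp)))
  list(PROMOTER_TSS = pr, TTS = tt2, EXON = ex2, INTRON = in2,
       INTERGENIC = ig)
}

sample_positions <- function(region, n) {
  w <- IRanges::width(region)
  tot <- sum(w)
  offs <- sort(sample.int(tot, n, replace = TRUE))
  cw <- cumsum(w)
  seg <- findInterval(offs - 1L, c(0L, cw), rightmost.closed = FALSE)
  pos <- IRanges::start(region)[seg] - 1L + (offs - c(0L, cw)[seg]) - 1L
  tibble(chrom = as.character(GenomicRanges::seqnames(region))[seg],
         pos = as.integer(pos))
}

#' Simulate peaks per mark with known true categories
#'
#' Draws, for every mark, each peak's true genomic category from the
#' mark's bias weights, places the peak center uniformly within the
#' genome-wide region of that category, and extends a random peak length
#' symmetrically so that the stored center is exactly the annotation
#' center. Because the category partition uses the same precedence as the
#' classifier, the recorded truth matches [annotate_peaks()] output.
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return List: `$peaks` tibble across marks (`sample_id` `"sim1"`),
#'   `$truth` tibble (`name`, `mark`, `true_category`).
#' @export
simulate_peaks <- function(cfg, ann) {
  sim_seed(cfg, 2L)
  part <- category_partition(ann$genes, ann$chrom_sizes)
  avail <- vapply(part, function(r) sum(as.numeric(IRanges::width(r))),
                  numeric(1))
  out <- list(); truth <- list()
  for (mk in names(cfg$peak_counts)) {
    n <- cfg$peak_counts[[mk]]
    if (n == 0) next
    w <- cfg$category_weights[[mk]]
    names(w) <- CATEGORY_LEVELS
    if (any(w > 0 & avail == 0)) {
      warn(sprintf("%s: no genomic bases for %s; reweighting", mk,
                   paste(names(w)[w > 0 & avail == 0], collapse = ",")))
      w[avail == 0] <- 0
    }
    w <- w / sum(w)
    cats <- sample(CATEGORY_LEVELS, n, replace = TRUE, prob = w)
    lens <- sample(seq(cfg$peak_len_range[1], cfg$peak_len_range[2]), n,
                   replace = TRUE)
    rows <- map_dfr(CATEGORY_LEVELS, function(cat) {
      k <- sum(cats == cat)
      if (k == 0) return(NULL)
      ctr <- sample_positions(part[[cat]], k)
      ctr$true_category <- cat
      ctr
    })
    rows$len <- lens
    lim <- unname(sim_chrom_sizes(cfg)[rows$chrom])
    # keep the stored center equal to the sampled in-category base:
    # full length when it fits, otherwise the widest odd window around it
    start <- rows$pos - rows$len %/% 2L
    end <- start + rows$len
    clip <- start < 0L | end > lim
    h <- pmin(rows$len %/% 2L, rows$pos, lim - rows$pos - 1L)
    start[clip] <- (rows$pos - h)[clip]
    end[clip] <- (rows$pos + h + 1L)[clip]
    pk <- tibble(chrom = rows$chrom, start = as.integer(start),
                 end = as.integer(end),
                 name = sprintf("%s_p%04d", mk, seq_len(n)),
                 score = round(runif(n, 10, 1000), 1),
                 mark = mk, sample_id = "sim1")
    out[[mk]] <- pk %>% arrange(.data$chrom, .data$start)
    truth[[mk]] <- tibble(name = pk$name, mark = mk,
                          true_category = rows$true_category)
  }
  list(peaks = bind_rows(out), truth = bind_rows(truth))
}

gene_mark_flags <- function(gm, peaks, chrom_sizes) {
  if (nrow(peaks) == 0) {
    return(tibble(gene_id = gm$genes$gene_id, active = FALSE,
                  repressive = FALSE))
  }
  ann <- map_dfr(unique(peaks$mark), function(mk) {
    annotate_peaks(peaks %>% filter(.data$mark == mk), gm, chrom_sizes)
  })
  genic <- ann %>% filter(.data$category != "INTERGENIC")
  act <- unique(genic$gene_id[genic$mark %in% c("H3K4me1", "H3K4me3", "ATAC")])
  rep_ <- unique(genic$gene_id[genic$mark == "H3K27me3"])
  tibble(gene_id = gm$genes$gene_id,
         active = gm$genes$gene_id %in% act,
         repressive = gm$genes$gene_id %in% rep_)
}

#' Simulate expression and dN/dS with planted mark effects
#'
#' Gene-level `ln(TPM + 1)` is Normal with mean
#' `mu + delta_active * active - delta_repressive * repressive`, where a
#' gene is active/repressive when it carries a genic peak of an active
#' mark / of H3K27me3. TPM is split across the gene's isoforms with
#' uniform random weights. dN/dS is `exp(a - b ln(TPM+1) + noise)`
#' (negative coupling when `b > 0`), with a small fraction of genes given
#' inflated values >= 99 emulating unreliable estimates.
#'
#' @param cfg A [sim_config()].
#' @param ann [simulate_annotation()] output.
#' @param peaks [simulate_peaks()] output (`$peaks` tibble accepted too).
#' @return List: `$expr` per-transcript table, `$dnds` tibble,
#'   `$truth` per-gene tibble (`gene_id`, `active`, `repressive`,
#'   `log_tpm` per sample).
#' @export
simulate_expression <- function(cfg, ann, peaks) {
  sim_seed(cfg, 3L)
  if (is.list(peaks) && !is.data.frame(peaks)) peaks <- peaks$peaks
  gm <- ann$genes
  flags <- gene_mark_flags(gm, peaks, ann$chrom_sizes)
  n <- nrow(flags)
  mu <- cfg$expr_mu + cfg$delta_active * flags$active -
    cfg$delta_repressive * flags$repressive
  expr_cols <- list()
  log_tpm_ref <- NULL
  for (s in cfg$expr_samples) {
    lt <- rnorm(n, mu, cfg$expr_sigma)
    tpm <- pmax(exp(lt) - 1, 0)
    expr_cols[[s]] <- tpm
    if (is.null(log_tpm_ref)) log_tpm_ref <- log(tpm + 1)
  }
  tx <- gm$transcripts
  w <- runif(nrow(tx))
  tx_rows <- tibble(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
                    w = w) %>%
    group_by(.data$gene_id) %>% mutate(w = .data$w / sum(.data$w)) %>%
    ungroup()
  expr <- tx_rows %>% select("transcript_id", "gene_id")
  gi <- match(tx_rows$gene_id, flags$gene_id)
  for (s in cfg$expr_samples) expr[[s]] <- expr_cols[[s]][gi] * tx_rows$w
  dnds_val <- exp(cfg$dnds_a - cfg$dnds_b * log_tpm_ref +
                    rnorm(n, 0, cfg$dnds_sigma))
  n_out <- rbinom(1, n, cfg$dnds_outlier_frac)
  if (n_out > 0) {
    idx <- sample.int(n, n_out)
    dnds_val[idx] <- runif(n_out, 99, 200)
  }
  truth <- flags
  truth$log_tpm <- log_tpm_ref
  list(expr = expr,
       dnds = tibble(gene_id = flags$gene_id, dnds = dnds_val),
       truth = truth)
}

#' Simulate a two-population genotype matrix
#'
#' Every base is independently polymorphic with probability `theta_in`
#' inside any peak and `theta_out` elsewhere (no linkage). At a
#' polymorphic site each population's alternate-allele frequency is drawn
#' from a symmetric Beta(`beta_alpha`, `beta_alpha`) and diploid
#' genotypes are Binomial(2, p).
#'
#' @param cfg A [sim_config()].
#' @param chrom_sizes Named chromosome lengths.
#' @param peaks Peak tibble (may be empty) defining the elevated-theta
#'   regions.
#' @return A `genotype_matrix` with populations `marine` and `stream`.
#' @export
simulate_genotypes <- function(cfg, chrom_sizes, peaks) {
  sim_seed(cfg, 4L)
  sizes <- chrom_sizes
  pgr <- if (nrow(peaks) > 0) {
    GenomicRanges::reduce(GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end)))
  } else GenomicRanges::GRanges()
  sites <- map_dfr(names(sizes), function(cr) {
    len <- as.integer(sizes[[cr]])
    pk <- pgr[as.character(GenomicRanges::seqnames(pgr)) == cr]
    inpk <- integer(0)
    if (length(pk) > 0) {
      inpk <- unlist(map2(IRanges::start(pk) - 1L, IRanges::end(pk) - 1L, seq))
      inpk <- inpk[inpk >= 0 & inpk < len]
    }
    n_in <- length(inpk)
    n_out <- len - n_in
    k_in <- rbinom(1, n_in, cfg$theta_in)
    k_out <- rbinom(1, n_out, cfg$theta_out)
    pos_in <- if (k_in > 0) sample(inpk, k_in) else integer(0)
    outpk <- if (n_in > 0) setdiff(seq_len(len) - 1L, inpk) else seq_len(len) - 1L
    pos_out <- if (k_out > 0) sample(outpk, k_out) else integer(0)
    tibble(chrom = cr, pos = sort(unique(c(pos_in, pos_out))))
  })
  ns <- cfg$n_per_pop
  samples <- c(paste0("marine_", seq_len(ns)), paste0("stream_", seq_len(ns)))
  popmap <- tibble(sample_id = samples,
                   population = rep(c("marine", "stream"), each = ns))
  k <- nrow(sites)
  if (k == 0) {
    ac <- matrix(integer(), 0, 2L * ns, dimnames = list(NULL, samples))
    return(new_genotype_matrix(sites, ac, popmap, 0L))
  }
  p1 <- stats::rbeta(k, cfg$beta_alpha, cfg$beta_alpha)
  p2 <- stats::rbeta(k, cfg$beta_alpha, cfg$beta_alpha)
  ac <- cbind(
    matrix(rbinom(k * ns, 2, rep(p1, ns)), nrow = k),
    matrix(rbinom(k * ns, 2, rep(p2, ns)), nrow = k)
  )
  colnames(ac) <- samples
  new_genotype_matrix(sites, ac, popmap, 0L)
}

#' Simulate replicate fragment samples from planted coverage profiles
#'
#' Draws `n_profiles` genome-wide bin-intensity profiles (log-normal per
#' bin) and, for each profile, `reps_per_profile` fragment samples whose
#' per-bin fragment counts are Poisson around the shared profile.
#' Replicates of one profile are therefore strongly rank-correlated while
#' different profiles are not — the planted structure sample clustering
#' should recover.
#'
#' @param cfg A [sim_config()].
#' @param chrom_sizes Named chromosome lengths.
#' @return List: `$fragments` named list of fragment tibbles
#'   (`<profile>_r<rep>`), `$truth` tibble (`sample_id`, `profile`).
#' @export
simulate_fragments <- function(cfg, chrom_sizes) {
  sim_seed(cfg, 5L)
  bins <- bin_fragments(tibble(chrom = character(), start = integer(),
                               end = integer()), chrom_sizes, cfg$bin)
  nb <- nrow(bins)
  frags <- list(); truth <- list()
  for (p in seq_len(cfg$n_profiles)) {
    lambda <- exp(rnorm(nb, log(cfg$frag_depth), 1))
    for (r in seq_len(cfg$reps_per_profile)) {
      sid <- sprintf("prof%d_r%d", p, r)
      counts <- rpois(nb, lambda)
      idx <- rep.int(seq_len(nb), counts)
      if (length(idx) > 0) {
        width <- bins$end[idx] - bins$start[idx]
        fs <- bins$start[idx] + floor(runif(length(idx)) * pmax(width - 300L, 1L))
        fe <- pmin(fs + 300L, unname(chrom_sizes[bins$chrom[idx]]))
        frags[[sid]] <- tibble(chrom = bins$chrom[idx],
                               start = as.integer(fs),
                               end = as.integer(fe)) %>%
          arrange(.data$chrom, .data$start)
      } else {
        frags[[sid]] <- tibble(chrom = character(), start = integer(),
                               end = integer())
      }
      truth[[sid]] <- tibble(sample_id = sid, profile = p)
    }
  }
  list(fragments = frags, truth = bind_rows(truth))
}

#' Simulate the ecotype screen scenario with planted ground truth
#'
#' Chooses `n_specific` marine-specific genes and assigns them to planted
#' classes: gene body absent in the marine ecotype, absent in the stream
#' ecotype, no upstream marks, stream deletion over a marked upstream
#' region, or intact candidate. Marine-specific genes get high marine TPM
#' (passing both expression criteria) and near-zero stream TPM; all other
#' genes share a common baseline. Whole-genome coverage is uniform at the
#' configured depth except over the planted gaps. Upstream H3K4me1/H3K4me3
#' peaks are planted for every marked class.
#'
#' @param cfg A [sim_config()].
#' @param ann [simulate_annotation()] output.
#' @return List: `$gene_tpm` wide per-gene TPM table, `$expr`
#'   per-transcript table, `$design`, `$peaks` (H3K4me1/H3K4me3),
#'   `$marine_cov`, `$stream_cov`, `$truth` (gene_id, class, planted
#'   deletion interval), `$assembled_chroms`.
#' @export
simulate_screen_scenario <- function(cfg, ann) {
  sim_seed(cfg, 6L)
  sc <- cfg$screen
  gm <- ann$genes
  sizes <- ann$chrom_sizes
  g <- gm$genes
  n_needed <- sc$n_specific
  if (nrow(g) < n_needed) abort("not enough genes for the requested screen scenario")
  classes <- c(rep("MARINE_ABSENT", sc$n_marine_absent),
               rep("STREAM_ABSENT", sc$n_stream_absent),
               rep("UNMARKED", sc$n_unmarked),
               rep("DELETION", sc$n_deletion))
  if (length(classes) > n_needed) {
    abort("planted class counts exceed n_specific")
  }
  classes <- c(classes, rep("NO_INDEL", n_needed - length(classes)))
  # genes need room upstream for a planted peak (TSS >= 3 kb from the
  # chromosome ends), and planted genes are kept >= 25 kb apart so one
  # gene's planted peak or coverage gap cannot fall inside another
  # planted gene's upstream search window
  ok_up <- g$tss >= 3000L & g$tss <= unname(sizes[g$chrom]) - 3000L
  cand <- sample(which(ok_up))
  pick <- integer(0)
  for (i in cand) {
    same <- pick[g$chrom[pick] == g$chrom[i]]
    if (length(same) == 0 || min(abs(g$tss[same] - g$tss[i])) >= 25000L) {
      pick <- c(pick, i)
    }
    if (length(pick) == n_needed) break
  }
  if (length(pick) < n_needed) {
    abort("not enough well-separated genes to plant the screen scenario")
  }
  classes <- sample(classes)
  truth <- tibble(gene_id = g$gene_id[pick], class = classes,
                  del_chrom = NA_character_, del_start = NA_integer_,
                  del_end = NA_integer_)

  design <- tibble(
    sample_id = c(sprintf("marine_fw%d", seq_len(sc$n_per_group)),
                  sprintf("marine_sw%d", seq_len(sc$n_per_group)),
                  sprintf("stream_fw%d", seq_len(sc$n_per_group))),
    group = rep(GROUP_LEVELS, each = sc$n_per_group)
  )
  n <- nrow(g)
  base_lt <- rnorm(n, 1.0, 0.8)
  mk_tpm <- function(group) {
    v <- pmax(exp(base_lt + rnorm(n, 0, 0.2)) - 1, 0)
    spec <- match(truth$gene_id, g$gene_id)
    v[spec] <- switch(group,
      MARINE_FW = sc$marine_fw_tpm * exp(rnorm(length(spec), 0, 0.2)),
      MARINE_SW = sc$marine_sw_tpm * exp(rnorm(length(spec), 0, 0.2)),
      STREAM_FW = sc$stream_fw_tpm * runif(length(spec)))
    v
  }
  gene_tpm <- tibble(gene_id = g$gene_id)
  for (i in seq_len(nrow(design))) {
    gene_tpm[[design$sample_id[i]]] <- mk_tpm(design$group[i])
  }
  tx <- gm$transcripts
  expr <- tibble(transcript_id = tx$transcript_id, gene_id = tx$gene_id)
  gi <- match(tx$gene_id, gene_tpm$gene_id)
  tx_w <- tibble(gene_id = tx$gene_id, w = runif(nrow(tx))) %>%
    group_by(.data$gene_id) %>% mutate(w = .data$w / sum(.data$w)) %>% ungroup()
  for (s in design$sample_id) expr[[s]] <- gene_tpm[[s]][gi] * tx_w$w

  # planted upstream peaks (H3K4me1 or H3K4me3) for all marked classes
  marked <- truth$class != "UNMARKED"
  pk_rows <- list()
  gaps_marine <- list()
  gaps_stream <- list()
  for (i in seq_len(nrow(truth))) {
    gi2 <- match(truth$gene_id[i], g$gene_id)
    chrom <- g$chrom[gi2]
    if (marked[i]) {
      off <- sample(500:2000, 1)    # peak center this far upstream of TSS
      len <- sample(300:800, 1)
      ctr <- if (g$strand[gi2] == "+") g$tss[gi2] - off else g$tss[gi2] + off
      ps <- max(ctr - len %/% 2L, 0L)
      pe <- min(ps + len, unname(sizes[chrom]))
      pk_rows[[length(pk_rows) + 1L]] <- tibble(
        chrom = chrom, start = as.integer(ps), end = as.integer(pe),
        name = sprintf("up_%s", truth$gene_id[i]),
        score = 500, mark = sample(c("H3K4me1", "H3K4me3"), 1),
        sample_id = "sim1")
      if (truth$class[i] == "DELETION") {
        truth$del_chrom[i] <- chrom
        truth$del_start[i] <- as.integer(ps)
        truth$del_end[i] <- as.integer(pe)
        gaps_stream[[length(gaps_stream) + 1L]] <-
          tibble(chrom = chrom, start = as.integer(ps), end = as.integer(pe))
      }
    }
    if (truth$class[i] == "MARINE_ABSENT") {
      gaps_marine[[length(gaps_marine) + 1L]] <-
        tibble(chrom = chrom, start = g$start[gi2], end = g$end[gi2])
    }
    if (truth$class[i] == "STREAM_ABSENT") {
      gaps_stream[[length(gaps_stream) + 1L]] <-
        tibble(chrom = chrom, start = g$start[gi2], end = g$end[gi2])
    }
  }
  peaks <- if (length(pk_rows)) bind_rows(pk_rows) %>%
    arrange(.data$chrom, .data$start) else
      tibble(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), mark = character(),
             sample_id = character())
  cov_with_gaps <- function(gaps) {
    gapped <- if (length(gaps)) bind_rows(gaps) else NULL
    map_dfr(names(sizes), function(cr) {
      len <- as.integer(sizes[[cr]])
      if (is.null(gapped) || !any(gapped$chrom == cr)) {
        return(tibble(chrom = cr, start = 0L, end = len, depth = sc$depth))
      }
      gg <- GenomicRanges::reduce(GenomicRanges::GRanges(
        cr, IRanges::IRanges(gapped$start[gapped$chrom == cr] + 1L,
                             gapped$end[gapped$chrom == cr])))
      keep <- GenomicRanges::setdiff(
        GenomicRanges::GRanges(cr, IRanges::IRanges(1L, len)), gg)
      tibble(chrom = cr, start = IRanges::start(keep) - 1L,
             end = IRanges::end(keep), depth = sc$depth)
    })
  }
  list(gene_tpm = gene_tpm, expr = expr, design = design, peaks = peaks,
       marine_cov = cov_with_gaps(gaps_marine),
       stream_cov = cov_with_gaps(gaps_stream),
       truth = truth, assembled_chroms = names(sizes))
}

#' Write a complete synthetic dataset to disk
#'
#' Runs every generator stage and writes all files in the plain-text
#' formats the readers consume, so a full pipeline run needs nothing but
#' this directory. Output is byte-identical for a fixed config.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Named list of file paths (invisibly also written as
#'   `manifest.json`).
#' @export
simulate_dataset <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  ann <- simulate_annotation(cfg)
  pk <- simulate_peaks(cfg, ann)
  ex <- simulate_expression(cfg, ann, pk$peaks)
  gt <- simulate_genotypes(cfg, ann$chrom_sizes, pk$peaks)
  fr <- simulate_fragments(cfg, ann$chrom_sizes)
  scn <- simulate_screen_scenario(cfg, ann)

  write_gene_models(ann$genes, p("genes.gff3"))
  write_chrom_sizes(ann$chrom_sizes, p("chrom.sizes"))
  peak_files <- list()
  for (mk in unique(pk$peaks$mark)) {
    f <- p(sprintf("peaks_%s.bed", mk))
    write_peaks(pk$peaks %>% filter(.data$mark == mk), f)
    peak_files[[mk]] <- f
  }
  readr::write_tsv(pk$truth, p("truth_peak_categories.tsv"), progress = FALSE)
  write_expression(ex$expr, p("tpm.tsv"), p("tx2gene.tsv"))
  readr::write_tsv(ex$dnds, p("dnds.tsv"), progress = FALSE)
  readr::write_tsv(ex$truth, p("truth_expression.tsv"), progress = FALSE)
  write_genotypes(gt, p("genotypes.vcf"))
  readr::write_tsv(gt$popmap, p("popmap.tsv"), col_names = FALSE,
                   progress = FALSE)
  frag_files <- list()
  for (sid in names(fr$fragments)) {
    f <- p(sprintf("fragments_%s.bed", sid))
    writeLines(sprintf("%s\t%d\t%d", fr$fragments[[sid]]$chrom,
                       fr$fragments[[sid]]$start, fr$fragments[[sid]]$end), f)
    frag_files[[sid]] <- f
  }
  readr::write_tsv(fr$truth, p("truth_profiles.tsv"), progress = FALSE)
  write_expression(scn$expr, p("ecotype_tpm.tsv"))
  readr::write_tsv(scn$design, p("design.tsv"), progress = FALSE)
  write_peaks(scn$peaks, p("screen_peaks.bed"))
  write_coverage(scn$marine_cov, p("marine.bedgraph"))
  write_coverage(scn$stream_cov, p("stream.bedgraph"))
  readr::write_tsv(scn$truth, p("truth_screen.tsv"), progress = FALSE)
  manifest <- list(
    genes = p("genes.gff3"), chrom_sizes = p("chrom.sizes"),
    peaks = peak_files, peak_truth = p("truth_peak_categories.tsv"),
    tpm = p("tpm.tsv"), tx2gene = p("tx2gene.tsv"), dnds = p("dnds.tsv"),
    expression_truth = p("truth_expression.tsv"),
    vcf = p("genotypes.vcf"), popmap = p("popmap.tsv"),
    fragments = frag_files, profile_truth = p("truth_profiles.tsv"),
    ecotype_tpm = p("ecotype_tpm.tsv"), design = p("design.tsv"),
    screen_peaks = p("screen_peaks.bed"),
    marine_cov = p("marine.bedgraph"), stream_cov = p("stream.bedgraph"),
    screen_truth = p("truth_screen.tsv")
  )
  # the JSON manifest stores paths relative to outdir so the directory is
  # relocatable and byte-identical across runs
  rel <- purrr::map_depth(manifest, -1, basename)
  jsonlite::write_json(rel, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  manifest
}
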