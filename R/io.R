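#' Controlled vocabulary of chromatin marks
#'
#' Peak sets are labelled with the assay or antibody that produced them:
#' the four histone modifications profiled by CUT&Tag, open chromatin
#' (ATAC), and the IgG negative control.
#'
#' @format Character vector of length 6.
#' @export
MARK_LEVELS <- c("H3K4me1", "H3K4me3", "H3K27me3", "H3K9me3", "ATAC", "IgG")

#' Five-category genomic-feature vocabulary used by peak annotation
#' @format Character vector of length 5, in precedence order.
#' @export
CATEGORY_LEVELS <- c("PROMOTER_TSS", "TTS", "EXON", "INTRON", "INTERGENIC")

# ---- gene models -----------------------------------------------------------

new_gene_models <- function(genes, transcripts, exons) {
  structure(
    list(genes = genes, transcripts = transcripts, exons = exons),
    class = "gene_models"
  )
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf(
    "<gene_models> %d genes, %d transcripts, %d exons on %d sequence(s)\n",
    nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
    dplyr::n_distinct(x$genes$chrom)
  ))
  print(x$genes, ...)
  invisible(x)
}

#' @method as_tibble gene_models
#' @export
as_tibble.gene_models <- function(x, ...) x$genes

validate_gene_models <- function(gm) {
  g <- gm$genes
  stopifnot(all(g$start >= 0), all(g$start < g$end))
  bad <- setdiff(gm$exons$transcript_id, gm$transcripts$transcript_id)
  if (length(bad) > 0) {
    abort(sprintf("exon references unknown transcript '%s'", bad[[1]]))
  }
  gm
}

# Light structural check so malformed rows fail with their line number,
# which rtracklayer does not always report.
check_gff_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    ln <- which(body)[which(nf != 9)[1]]
    abort(sprintf("malformed GFF/GTF record at line %d of '%s': expected 9 tab-separated fields, found %d",
                  ln, path, nf[nf != 9][1]))
  }
  invisible(path)
}

#' Read gene models from GFF3 or GTF
#'
#' Parses gene/mRNA/exon features into a gene-level model: one record per
#' gene whose span is the union of its transcript spans, with a
#' strand-aware transcription start site (TSS) and termination site (TTS).
#' All coordinates are converted to the package-wide 0-based half-open
#' convention on ingest, so a GFF feature `101..200` becomes `[100, 200)`.
#'
#' For a `+` strand gene the TSS is the first base of the span and the TTS
#' the last; for a `-` strand gene the roles are mirrored. Downstream
#' annotation is gene-level: promoter and TTS windows are anchored on the
#' union span, not on individual isoforms.
#'
#' @param path Path to a GFF3 (`.gff`, `.gff3`) or GTF (`.gtf`) file.
#' @param format Override format detection; one of `"gff3"`, `"gtf"`.
#' @return A `gene_models` object: a list with tibbles `genes`
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`, `tss`, `tts`),
#'   `transcripts`, and `exons`.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\t.\tgene\t101\t200\t.\t+\t.\tID=g1",
#'   "chr1\t.\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
#'   "chr1\t.\texon\t101\t200\t.\t+\t.\tParent=t1"), gff)
#' read_gene_models(gff)$genes
#' @export
read_gene_models <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  check_gff_lines(path)
  format <- format %||%
    if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = format)
  md <- S4Vectors::mcols(gr)
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type)
  )
  if (format == "gtf") {
    df$transcript_id <- as.character(md$transcript_id)
    df$gene_id <- as.character(md$gene_id)
    ex <- df[df$type == "exon", ]
    if (nrow(ex) == 0) abort("no exon features found")
    if (anyNA(ex$transcript_id)) abort("exon feature lacking transcript_id attribute")
    tx2gene <- distinct(ex[, c("transcript_id", "gene_id")])
  } else {
    id <- as.character(md$ID)
    parent <- vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                     character(1))
    df$id <- id
    df$parent <- parent
    tx <- df[df$type %in% c("mRNA", "transcript"), ]
    ex <- df[df$type == "exon", ]
    if (nrow(ex) == 0) abort("no exon features found")
    if (anyNA(ex$parent)) {
      nm <- ex$id[which(is.na(ex$parent))[1]]
      abort(sprintf("exon feature '%s' has no Parent transcript",
                    if (is.na(nm)) "<unnamed>" else nm))
    }
    orphan <- setdiff(ex$parent, tx$id)
    if (length(orphan) > 0) {
      abort(sprintf("exon refers to unknown transcript '%s'", orphan[[1]]))
    }
    ex$transcript_id <- ex$parent
    tx2gene <- tibble(transcript_id = tx$id, gene_id = tx$parent)
    if (anyNA(tx2gene$gene_id)) {
      abort(sprintf("transcript '%s' has no Parent gene",
                    tx2gene$transcript_id[which(is.na(tx2gene$gene_id))[1]]))
    }
  }
  exons <- ex %>%
    left_join(tx2gene, by = "transcript_id",
              suffix = c(".drop", "")) %>%
    select("gene_id", "transcript_id", "chrom", "start", "end", "strand") %>%
    arrange(.data$gene_id, .data$transcript_id, .data$start)
  transcripts <- exons %>%
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") %>%
    select("transcript_id", "gene_id", "chrom", "start", "end", "strand") %>%
    arrange(.data$gene_id, .data$transcript_id)
  genes <- transcripts %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              n_transcripts = dplyr::n(), .groups = "drop") %>%
    mutate(
      tss = if_else(.data$strand == "-", .data$end - 1L, .data$start),
      tts = if_else(.data$strand == "-", .data$start, .data$end - 1L)
    ) %>%
    select("gene_id", "chrom", "start", "end", "strand", "tss", "tts",
           "n_transcripts") %>%
    arrange(.data$chrom, .data$start, .data$gene_id)
  validate_gene_models(new_gene_models(genes, transcripts, exons))
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_models()]: emits gene, mRNA and exon features with
#' `ID`/`Parent` links, converting the internal 0-based half-open
#' coordinates back to GFF's 1-based closed convention. Re-reading the file
#' reproduces the original object.
#'
#' @param gm A `gene_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gm, path) {
  stopifnot(inherits(gm, "gene_models"))
  fmt <- function(chrom, type, start, end, strand, attr) {
    sprintf("%s\t.\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, start + 1L, end,
            strand, attr)
  }
  g <- gm$genes
  tx <- gm$transcripts
  ex <- gm$exons
  lines <- c(
    "##gff-version 3",
    unlist(map(seq_len(nrow(g)), function(i) {
      gi <- g[i, ]
      txi <- tx[tx$gene_id == gi$gene_id, ]
      c(
        fmt(gi$chrom, "gene", gi$start, gi$end, gi$strand,
            paste0("ID=", gi$gene_id)),
        unlist(map(seq_len(nrow(txi)), function(j) {
          tj <- txi[j, ]
          exj <- ex[ex$transcript_id == tj$transcript_id, ]
          c(
            fmt(tj$chrom, "mRNA", tj$start, tj$end, tj$strand,
                paste0("ID=", tj$transcript_id, ";Parent=", tj$gene_id)),
            fmt(exj$chrom, "exon", exj$start, exj$end, exj$strand,
                paste0("Parent=", tj$transcript_id))
          )
        }))
      )
    }))
  )
  writeLines(lines, path)
  invisible(path)
}

# ---- peaks and plain interval files ---------------------------------------

read_bed3 <- function(path) {
  n <- length(readLines(path, n = 1L, warn = FALSE))
  if (n == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE, comment = "#")
  if (ncol(df) < 3) abort(sprintf("'%s': BED needs >= 3 columns", path))
  out <- tibble(chrom = as.character(df[[1]]),
                start = as.integer(df[[2]]),
                end = as.integer(df[[3]]))
  bad <- which(out$start >= out$end)
  if (length(bad) > 0) {
    abort(sprintf("'%s' line %d: start (%d) must be < end (%d)",
                  path, bad[1], out$start[bad[1]], out$end[bad[1]]))
  }
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  if (ncol(df) >= 5) out$score <- suppressWarnings(as.numeric(df[[5]]))
  out
}

#' Read called peaks from a BED or broadPeak file
#'
#' BED input is taken as already 0-based half-open. Column 4, when present,
#' is kept as the peak name and column 5 as the score (for broadPeak output
#' of macs2 this is the scaled score column). Each record becomes one peak
#' tagged with the chromatin mark and sample it came from.
#'
#' @param path BED3/BED5/broadPeak file; an empty file yields zero peaks.
#' @param mark One of [MARK_LEVELS].
#' @param sample_id Sample identifier the peaks belong to.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `mark`, `sample_id`.
#' @export
read_peaks <- function(path, mark, sample_id) {
  mark <- match.arg(mark, MARK_LEVELS)
  df <- read_bed3(path)
  if (!"name" %in% names(df)) df$name <- NA_character_
  if (!"score" %in% names(df)) df$score <- NA_real_
  df %>%
    select("chrom", "start", "end", "name", "score") %>%
    mutate(mark = mark, sample_id = sample_id)
}

#' Write peaks as BED5
#' @param peaks Peak tibble as returned by [read_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  nm <- if_else(is.na(peaks$name %||% NA_character_),
                paste0("peak_", seq_len(nrow(peaks))), peaks$name)
  sc <- peaks$score %||% rep(NA_real_, nrow(peaks))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", peaks$chrom, peaks$start, peaks$end,
                   nm, if_else(is.na(sc), "0", format(sc, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' Read fragment intervals (BED3)
#'
#' Fragments are the alignment-free input to coverage binning; convert BAM
#' to fragment BED externally, e.g. `bedtools bamtobed -bedpe`.
#'
#' @param path BED file with at least chrom/start/end.
#' @return Tibble `chrom`, `start`, `end`.
#' @export
read_fragments <- function(path) {
  read_bed3(path)[, c("chrom", "start", "end")]
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file (chrom, start, end, depth); 0-based half-open.
#' @return Tibble `chrom`, `start`, `end`, `depth`, runs sorted and
#'   non-overlapping within each chromosome.
#' @export
read_coverage <- function(path) {
  df <- read_bed3(path)
  if (!"name" %in% names(df)) abort(sprintf("'%s': bedGraph needs 4 columns", path))
  out <- tibble(chrom = df$chrom, start = df$start, end = df$end,
                depth = suppressWarnings(as.numeric(df$name)))
  if (anyNA(out$depth)) abort(sprintf("'%s': non-numeric depth value", path))
  if (any(out$depth < 0)) abort(sprintf("'%s': negative depth", path))
  out <- arrange(out, .data$chrom, .data$start)
  ov <- out %>% group_by(.data$chrom) %>%
    summarise(bad = any(.data$start < dplyr::lag(.data$end, default = -1L)),
              .groups = "drop")
  if (any(ov$bad)) abort(sprintf("'%s': overlapping runs on %s", path,
                                 ov$chrom[ov$bad][1]))
  out
}

#' Write a coverage track as bedGraph
#' @param cov Coverage tibble (`chrom`, `start`, `end`, `depth`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(cov, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", cov$chrom, cov$start, cov$end,
                     format(cov$depth, trim = TRUE, scientific = FALSE)), path)
  invisible(path)
}

#' Read chromosome sizes (two-column TSV: name, length)
#' @param path Path to a `.sizes`/`.genome` style file.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "length"),
                        col_types = "ci", progress = FALSE)
  setNames(df$length, df$chrom)
}

#' Write chromosome sizes
#' @param sizes Named integer vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}

# ---- genotypes -------------------------------------------------------------

new_genotype_matrix <- function(sites, ac, popmap, n_skipped = 0L) {
  structure(list(sites = sites, ac = ac, popmap = popmap,
                 n_skipped = as.integer(n_skipped)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d biallelic sites x %d samples (%d populations); %d records skipped on ingest\n",
              nrow(x$sites), ncol(x$ac),
              dplyr::n_distinct(x$popmap$population), x$n_skipped))
  invisible(x)
}

#' Read two-population genotypes from a VCF
#'
#' Keeps biallelic SNP records only: multi-allelic records and indels are
#' skipped and counted (`$n_skipped`). The 1-based VCF `POS` is converted
#' to a 0-based position. Per sample the stored value is the alternate
#' allele count (0, 1 or 2 for a diploid); genotypes containing `.` are
#' missing and drop out of allele totals, so missing data reduces the
#' number of called alleles at a site rather than removing the site.
#'
#' @param path VCF file (plain text or gzipped) with a GT FORMAT field.
#' @param pop_map Tibble/data frame with columns `sample_id`, `population`,
#'   a named character vector (names = samples), or a path to a two-column
#'   TSV. Must cover every sample in the VCF header.
#' @return A `genotype_matrix`: `sites` tibble (`chrom`, `pos`), integer
#'   matrix `ac` (sites x samples, `NA` = missing), `popmap` tibble, and
#'   the skip counter.
#' @export
read_genotypes <- function(path, pop_map) {
  if (is.character(pop_map) && length(pop_map) == 1 && file.exists(pop_map)) {
    pop_map <- readr::read_tsv(pop_map, col_names = c("sample_id", "population"),
                               col_types = "cc", progress = FALSE)
  }
  if (!is.data.frame(pop_map)) {
    pop_map <- tibble(sample_id = names(pop_map),
                      population = unname(pop_map))
  }
  pop_map <- as_tibble(pop_map[, c("sample_id", "population")])

  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) abort(sprintf("'%s': no #CHROM header line", path))
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10) abort(sprintf("'%s': VCF has no sample columns", path))
  samples <- cols[-(1:9)]
  missing <- setdiff(samples, pop_map$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("sample '%s' in VCF is absent from the population map",
                  missing[[1]]))
  }
  pop_map <- pop_map[match(samples, pop_map$sample_id), ]

  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(new_genotype_matrix(
      tibble(chrom = character(), pos = integer()),
      matrix(integer(), 0, length(samples), dimnames = list(NULL, samples)),
      pop_map, 0L))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cols))) {
    abort(sprintf("'%s' record %d: %d fields, expected %d", path,
                  which(nf != length(cols))[1], nf[nf != length(cols)][1],
                  length(cols)))
  }
  m <- do.call(rbind, fields)
  ref <- m[, 4]
  alt <- m[, 5]
  keep <- !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  gt_field <- function(x) sub(":.*$", "", x)
  gt <- apply(m[, -(1:9), drop = FALSE], 2, gt_field)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(m))
  alleles <- gsub("[|]", "/", gt)
  ac <- matrix(NA_integer_, nrow(m), length(samples),
               dimnames = list(NULL, samples))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  hit <- alleles %in% names(known)
  ac[hit] <- known[alleles[hit]]
  sites <- tibble(chrom = m[, 1], pos = as.integer(m[, 2]) - 1L)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, ]
  ac <- ac[ord, , drop = FALSE]
  if (anyDuplicated(paste(sites$chrom, sites$pos))) {
    abort(sprintf("'%s': duplicate site position", path))
  }
  new_genotype_matrix(sites, ac, pop_map, n_skipped)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits biallelic SNP records (REF=A, ALT=T placeholders) with diploid GT
#' fields; the inverse of [read_genotypes()] for objects produced by the
#' simulator.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  samples <- colnames(gm$ac)
  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(gm$sites), length(samples))
  ok <- !is.na(gm$ac)
  gt[ok] <- gt_map[gm$ac[ok] + 1L]
  recs <- sprintf("%s\t%d\t.\tA\tT\t.\tPASS\t.\tGT\t%s",
                  gm$sites$chrom, gm$sites$pos + 1L,
                  apply(gt, 1, paste, collapse = "\t"))
  if (nrow(gm$sites) == 0) recs <- character()
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    recs
  ), path)
  invisible(path)
}

# ---- expression ------------------------------------------------------------

#' Read a per-transcript TPM table
#'
#' @param path TSV whose first column is `transcript_id` and remaining
#'   columns are per-sample TPM values (header row of sample ids).
#' @param tx2gene Transcript-to-gene map: tibble with `transcript_id`,
#'   `gene_id`, or a path to a headerless two-column TSV. Every transcript
#'   in `path` must be mapped.
#' @return Tibble `transcript_id`, `gene_id`, then one numeric column per
#'   sample. Values are validated to be present and non-negative.
#' @export
read_expression <- function(path, tx2gene) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1] <- "transcript_id"
  df$transcript_id <- as.character(df$transcript_id)
  if (is.character(tx2gene)) {
    tx2gene <- readr::read_tsv(tx2gene, col_names = c("transcript_id", "gene_id"),
                               col_types = "cc", progress = FALSE)
  }
  tx2gene <- as_tibble(tx2gene[, c("transcript_id", "gene_id")])
  unmapped <- setdiff(df$transcript_id, tx2gene$transcript_id)
  if (length(unmapped) > 0) {
    abort(sprintf("transcript '%s' has no gene mapping", unmapped[[1]]))
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (is.logical(v) && all(is.na(v))) v <- as.numeric(v)
    if (!is.numeric(v)) abort(sprintf("column '%s' is not numeric", names(vals)[j]))
    if (anyNA(v)) {
      abort(sprintf("missing TPM at row %d, column '%s'",
                    which(is.na(v))[1], names(vals)[j]))
    }
    if (any(v < 0)) {
      abort(sprintf("negative TPM at row %d, column '%s'",
                    which(v < 0)[1], names(vals)[j]))
    }
  }
  out <- dplyr::bind_cols(
    tibble(transcript_id = df$transcript_id),
    tibble(gene_id = tx2gene$gene_id[match(df$transcript_id, tx2gene$transcript_id)]),
    vals
  )
  out
}

#' Write an expression table and its transcript-to-gene map
#' @param expr Expression tibble from [read_expression()].
#' @param path Output TSV for the TPM matrix.
#' @param tx2gene_path Optional output TSV for the transcript-gene map.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, tx2gene_path = NULL) {
  readr::write_tsv(expr %>% select(-"gene_id"), path, progress = FALSE)
  if (!is.null(tx2gene_path)) {
    readr::write_tsv(expr %>% select("transcript_id", "gene_id"), tx2gene_path,
                     col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}

#' Read a per-gene dN/dS table
#' @param path TSV with columns `gene_id`, `dnds` (header optional).
#' @return Tibble `gene_id`, `dnds`.
#' @export
read_dnds <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("gene", first, ignore.case = TRUE)
  df <- readr::read_tsv(path, col_names = c("gene_id", "dnds"),
                        col_types = "cd", skip = as.integer(has_header),
                        progress = FALSE)
  df
}
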