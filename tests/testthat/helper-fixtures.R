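# Small hand-built fixtures, written as text at test time.

write_gff_fixture <- function(lines, ext = ".gff3") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff_line <- function(chrom, type, start1, end1, strand, attrs) {
  sprintf("%s\t.\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, start1, end1,
          strand, attrs)
}

# One-transcript gene occupying [start, end) with given exons (0-based
# half-open), returned as GFF3 lines.
gene_lines <- function(gene_id, chrom, start, end, strand,
                       exons = list(c(start, end))) {
  tx <- paste0(gene_id, ".t1")
  c(gff_line(chrom, "gene", start + 1, end, strand, paste0("ID=", gene_id)),
    gff_line(chrom, "mRNA", start + 1, end, strand,
             paste0("ID=", tx, ";Parent=", gene_id)),
    vapply(exons, function(e) {
      gff_line(chrom, "exon", e[1] + 1, e[2], strand, paste0("Parent=", tx))
    }, character(1)))
}

read_fixture_genes <- function(...) {
  read_gene_models(write_gff_fixture(c(...)))
}

# Peaks tibble shorthand.
peaks_tbl <- function(chrom, start, end, mark = "H3K4me3",
                      sample_id = "s1") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end),
                 name = paste0("p", seq_along(start)), score = 1,
                 mark = mark, sample_id = sample_id)
}

write_vcf_fixture <- function(records, samples) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}
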