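# Toy variant-scoring fixtures.
#
# The genome is built so every pipeline step is hand-computable under the
# leaky-scanning oracle: reference UTRs use only A/C bases (no AUG/CUG/GUG
# candidates and no stop codons anywhere), so each designed SNV creates
# exactly one uAUG whose frame is fixed by the UTR length.

#' Write toy variant-scoring fixtures
#'
#' Generates a small genome FASTA, a BED6 file of 5'UTR exon regions, a
#' VCF of variants and a TIS-context CSV, designed so that oracle-based
#' pipeline outputs can be derived by hand:
#'
#' * `TX1` (+ strand, two exons, 20-nt spliced UTR): SNV creates a single
#'   out-of-frame uAUG (frame 1) with no downstream in-frame stop.
#' * `TX2` (+ strand, 22-nt UTR): the same SNV context but in-frame
#'   (frame 0), the case whose unshifted effect vanishes while the
#'   frameshifted scores are strongly negative.
#' * `TX3` (- strand, 20-nt UTR identical to TX1 in transcript space):
#'   exercises reverse-complement handling.
#' * one variant outside every UTR (must be excluded) and one
#'   multi-allelic record (must be split).
#'
#' The context CSV holds the 16 AUG contexts varying the -3 and +4 bases
#' (strengths increasing with the canonical Kozak weights) plus one
#' context with an unintended upstream AUG that must be filtered.
#'
#' @param dir output directory (created if needed).
#' @return named list of file paths (`fasta`, `bed`, `vcf`, `contexts`).
#' @export
write_toy_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utr1 <- "CACCACGCACCAACCAACCA" # 20 nt, no TIS candidates
  utr2 <- "CACCACGCACCAACCAACCAAC" # 22 nt: AUG created at pos 4 is in-frame
  dna <- function(x) gsub("U", "T", x, fixed = TRUE)
  revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }
  spacer <- function(n) strrep("T", n)
  # layout: TX1 exon1 [10,18), TX1 exon2 [28,40), TX2 [50,72), TX3 [80,100)
  contig <- paste0(
    spacer(10),
    substr(dna(utr1), 1, 8), # TX1 exon 1
    spacer(10),
    substr(dna(utr1), 9, 20), # TX1 exon 2
    spacer(10),
    dna(utr2), # TX2
    spacer(8),
    revcomp(dna(utr1)), # TX3 (minus strand)
    spacer(10)
  )
  stopifnot(nchar(contig) == 110)
  # designed SNVs at transcript position 5 (0-based), C -> U
  stopifnot(substr(contig, 16, 16) == "C", # TX1: genomic 1-based 16
            substr(contig, 56, 56) == "C", # TX2: 56
            substr(contig, 95, 95) == "G", # TX3 (- strand): 95
            substr(contig, 13, 13) == "C") # multi-allelic site
  fasta <- file.path(dir, "toy_genome.fa")
  writeLines(c(">chrT", contig), fasta)
  bed <- file.path(dir, "toy_utrs.bed")
  writeLines(c(
    "chrT\t10\t18\tTX1\t0\t+",
    "chrT\t28\t40\tTX1\t0\t+",
    "chrT\t50\t72\tTX2\t0\t+",
    "chrT\t80\t100\tTX3\t0\t-"
  ), bed)
  vcf <- file.path(dir, "toy_variants.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrT,length=110>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    "chrT\t16\ttx1_oof_aug\tC\tT\t.\tPASS\t.",
    "chrT\t56\ttx2_inframe_aug\tC\tT\t.\tPASS\t.",
    "chrT\t95\ttx3_minus_aug\tG\tA\t.\tPASS\t.",
    "chrT\t13\ttx1_multi\tC\tT,A\t.\tPASS\t.",
    "chrT\t3\toutside_utr\tT\tA\t.\tPASS\t."
  ), vcf)
  contexts <- file.path(dir, "toy_tis_contexts.csv")
  pwm <- default_kozak_pwm()
  grid <- tidyr::expand_grid(m3 = RNA_BASES, p4 = RNA_BASES)
  ctx <- tibble(
    codon = "AUG",
    upstream = paste0("CCC", grid$m3, "CC"),
    downstream = paste0(grid$p4, "C"),
    strength = stats::plogis(pwm["-3", grid$m3] + pwm["4", grid$p4] - 1)
  )
  ctx <- dplyr::bind_rows(ctx, tibble(
    codon = "AUG", upstream = "AAUGGG", downstream = "GG", strength = 0.9))
  readr::write_csv(ctx, contexts)
  list(fasta = fasta, bed = bed, vcf = vcf, contexts = contexts)
}
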