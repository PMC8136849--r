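test_that("BED regions load grouped per transcript with strand checks", {
  fx <- toy_fixture_dir()
  regions <- load_utr_regions(fx$bed)
  expect_equal(sort(unique(regions$transcript_id)), c("TX1", "TX2", "TX3"))
  tx1 <- regions[regions$transcript_id == "TX1", ]
  expect_equal(nrow(tx1), 2) # two exons, one record
  expect_equal(tx1$start, c(10, 28))
  expect_equal(tx1$end, c(18, 40))
  expect_equal(unique(tx1$strand), "+")
  expect_equal(regions$strand[regions$transcript_id == "TX3"], "-")
  # inconsistent strand within a transcript is rejected
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t5\tT\t0\t+", "chr1\t10\t15\tT\t0\t-"), bad)
  expect_error(load_utr_regions(bad), "inconsistent strand")
})

test_that("spliced extraction is strand-aware on a hand-spliced toy contig", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGTACGTAC"), fa)
  genome <- read_genome(fa)
  plus <- tibble::tibble(transcript_id = "p", chrom = "c1",
                         start = c(0, 6), end = c(4, 8), strand = "+")
  expect_equal(extract_utr_sequence(plus, genome), "ACGUGU")
  minus <- tibble::tibble(transcript_id = "m", chrom = "c1",
                          start = 0, end = 4, strand = "-")
  expect_equal(extract_utr_sequence(minus, genome), "ACGU") # revcomp of ACGT
  missing <- tibble::tibble(transcript_id = "x", chrom = "c9",
                            start = 0, end = 4, strand = "+")
  expect_error(extract_utr_sequence(missing, genome), "contig 'c9' missing")
  oob <- tibble::tibble(transcript_id = "x", chrom = "c1",
                        start = 5, end = 40, strand = "+")
  expect_error(extract_utr_sequence(oob, genome), "beyond the end")
})

test_that("variant injection handles identity, indels, strand and errors", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGTACGTAC"), fa)
  genome <- read_genome(fa)
  exons <- tibble::tibble(transcript_id = "p", chrom = "c1",
                          start = 0, end = 10, strand = "+")
  ref <- extract_utr_sequence(exons, genome)
  # empty variant set: round trip
  novar <- tibble::tibble(chrom = character(), pos = integer(),
                          id = character(), ref = character(),
                          alt = character())
  expect_equal(apply_variants(exons, genome, novar), ref)
  # alt == ref alleles: identity edit
  same <- tibble::tibble(chrom = "c1", pos = 3L, id = "v", ref = "G", alt = "G")
  expect_equal(apply_variants(exons, genome, same), ref)
  # 1-bp insertion lengthens the transcript by one
  ins <- tibble::tibble(chrom = "c1", pos = 4L, id = "v", ref = "T", alt = "TT")
  alt1 <- apply_variants(exons, genome, ins)
  expect_equal(nchar(alt1), nchar(ref) + 1)
  expect_equal(alt1, "ACGUUACGUAC")
  # SNV on a minus-strand transcript edits the reverse-complemented base
  mexons <- tibble::tibble(transcript_id = "m", chrom = "c1",
                           start = 0, end = 10, strand = "-")
  msnv <- tibble::tibble(chrom = "c1", pos = 10L, id = "v", ref = "C", alt = "A")
  # transcript is revcomp(ACGTACGTAC) = GTACGTACGT -> first base edited
  expect_equal(apply_variants(mexons, genome, msnv), "UUACGUACGU")
  # REF mismatch names expected and found
  bad <- tibble::tibble(chrom = "c1", pos = 1L, id = "v", ref = "G", alt = "C")
  expect_error(apply_variants(exons, genome, bad), "expected 'G'.*has 'A'")
  # variant spanning an exon boundary is rejected
  two <- tibble::tibble(transcript_id = "p", chrom = "c1",
                        start = c(0, 6), end = c(4, 8), strand = c("+", "+"))
  span <- tibble::tibble(chrom = "c1", pos = 4L, id = "v", ref = "TAC",
                         alt = "T")
  expect_error(apply_variants(two, genome, span), "spans an exon boundary")
  # overlapping variants are rejected
  ovl <- tibble::tibble(chrom = "c1", pos = c(2L, 3L), id = c("a", "b"),
                        ref = c("CG", "GT"), alt = c("C", "G"))
  expect_error(apply_variants(exons, genome, ovl), "overlapping variants")
})

test_that("multi-allelic VCF records are split into biallelic variants", {
  fx <- toy_fixture_dir()
  vars <- load_variants(fx$vcf)
  multi <- vars[vars$id == "tx1_multi", ]
  expect_equal(nrow(multi), 2)
  expect_setequal(multi$alt, c("T", "A"))
  expect_true(all(multi$ref == "C"))
})

test_that("a single-record VCF parses into a one-row table", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chrT,length=110>",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               "chrT\t3\tv1\tT\tA\t.\tPASS\t."), vcf)
  vars <- load_variants(vcf)
  expect_equal(nrow(vars), 1)
  expect_equal(vars$pos, 3L)
  expect_equal(vars$ref, "T")
})

test_that("the oracle pipeline reproduces hand-derived fold changes", {
  fx <- toy_fixture_dir()
  orc <- oracle_predictor(params_p09())
  eff <- run_vcf_pipeline(fx$vcf, fx$bed, fx$fasta, orc)
  # ordered by transcript then position; outside variant excluded
  expect_false("outside_utr" %in% eff$variant_id)
  # TX1: created out-of-frame uAUG with p = 0.9 -> log2(2.4/6) exactly
  tx1 <- eff[eff$variant_id == "tx1_oof_aug", ]
  expect_equal(tx1$mrl_ref, 6)
  expect_equal(tx1$mrl_alt, 2.4)
  expect_equal(tx1$log2fc, log2(2.4 / 6))
  # TX2: in-frame uAUG -> unshifted score zero, shifted scores strongly
  # negative (the frameshift trick exposes start codons hidden in-frame)
  tx2 <- eff[eff$variant_id == "tx2_inframe_aug", ]
  expect_equal(tx2$log2fc, 0)
  expect_equal(tx2$log2fc_shift1, log2(2.4 / 6))
  expect_equal(tx2$log2fc_shift2, log2(2.4 / 6))
  # TX3 encodes TX1's transcript on the minus strand: identical scores
  tx3 <- eff[eff$variant_id == "tx3_minus_aug", ]
  expect_equal(tx3$log2fc, tx1$log2fc)
  expect_equal(tx3$log2fc_shift1, tx1$log2fc_shift1)
  expect_equal(tx3$log2fc_shift2, tx1$log2fc_shift2)
  # identity substitutions score zero everywhere
  id_scores <- score_variants(orc, "CACCAACCA", "CACCAACCA")
  expect_equal(unlist(id_scores[, c("log2fc", "log2fc_shift1",
                                    "log2fc_shift2")], use.names = FALSE),
               c(0, 0, 0))
})

test_that("TX1 shift scores follow the oracle frame arithmetic", {
  fx <- toy_fixture_dir()
  orc <- oracle_predictor(params_p09())
  eff <- run_vcf_pipeline(fx$vcf, fx$bed, fx$fasta, orc)
  tx1 <- eff[eff$variant_id == "tx1_oof_aug", ]
  # uAUG at frame 1: shift 1 keeps it out of frame, shift 2 makes it
  # in-frame and the unshifted penalty disappears
  expect_equal(tx1$log2fc_shift1, log2(2.4 / 6))
  expect_equal(tx1$log2fc_shift2, 0)
})

test_that("an empty VCF/BED intersection yields an empty table", {
  fx <- toy_fixture_dir()
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chrT,length=110>",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               "chrT\t3\tv\tT\tA\t.\tPASS\t."), vcf)
  eff <- run_vcf_pipeline(vcf, fx$bed, fx$fasta, oracle_predictor())
  expect_equal(nrow(eff), 0)
  expect_true(all(c("transcript_id", "log2fc_shift2") %in% names(eff)))
})

test_that("variant-effect tables export as TSV with the full schema", {
  fx <- toy_fixture_dir()
  eff <- run_vcf_pipeline(fx$vcf, fx$bed, fx$fasta,
                          oracle_predictor(params_p09()))
  tmp <- tempfile(fileext = ".tsv")
  write_variant_effects(eff, tmp)
  back <- readr::read_tsv(tmp, show_col_types = FALSE)
  expect_equal(names(back),
               c("transcript_id", "variant_id", "chrom", "pos", "ref", "alt",
                 "mrl_ref", "mrl_alt", "log2fc", "log2fc_shift1",
                 "log2fc_shift2"))
  expect_equal(nrow(back), nrow(eff))
})
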