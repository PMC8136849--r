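#' Load 5'UTR exon regions from a BED file
#'
#' Reads a BED6+ file whose name column carries the transcript id and whose
#' rows (one per 5'UTR exon) are grouped per transcript. Coordinates stay in
#' BED convention (0-based, half-open). Strand and chromosome must be
#' consistent within a transcript; for minus-strand transcripts the 5' end
#' of the UTR is the highest genomic coordinate.
#'
#' @param bed_path path to a BED file with at least 6 columns.
#' @return tibble with columns `transcript_id`, `chrom`, `start`, `end`,
#'   `strand`, one row per exon, sorted by transcript then genomic start.
#' @export
load_utr_regions <- function(bed_path) {
  gr <- rtracklayer::import(bed_path, format = "bed")
  if (is.null(gr$name) || anyNA(gr$name)) {
    abort("BED name column (transcript id) is required")
  }
  tbl <- tibble(
    transcript_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # back to BED 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (any(!tbl$strand %in% c("+", "-"))) {
    abort("every 5'UTR exon needs an explicit strand (+/-)")
  }
  bad <- tbl |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$strand) == 1 &&
                       dplyr::n_distinct(.data$chrom) == 1,
                     .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(sprintf("inconsistent strand/chrom within transcript '%s'",
                  bad$transcript_id[1]))
  }
  tbl <- dplyr::arrange(tbl, .data$transcript_id, .data$start)
  overlap <- tbl |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(bad = any(.data$start[-1] < .data$end[-dplyr::n()]) ||
                       any(.data$end <= .data$start), .groups = "drop") |>
    dplyr::filter(.data$bad)
  if (nrow(overlap) > 0) {
    abort(sprintf("overlapping or malformed exon intervals in '%s'",
                  overlap$transcript_id[1]))
  }
  tbl
}

#' Read a reference genome FASTA
#'
#' @param fasta_path FASTA file path.
#' @return a named `DNAStringSet` (names truncated at the first whitespace).
#' @export
read_genome <- function(fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

# spliced forward-strand (genomic orientation) DNA sequence of a transcript
spliced_forward <- function(exons, genome) {
  chrom <- exons$chrom[1]
  if (!chrom %in% names(genome)) {
    abort(sprintf("contig '%s' missing from the genome FASTA", chrom))
  }
  contig <- genome[[chrom]]
  if (any(exons$end > length(contig))) {
    abort(sprintf("exon interval beyond the end of contig '%s'", chrom))
  }
  paste(vapply(seq_len(nrow(exons)), function(i) {
    as.character(Biostrings::subseq(contig, exons$start[i] + 1L, exons$end[i]))
  }, character(1)), collapse = "")
}

#' Extract the spliced, strand-aware 5'UTR sequence
#'
#' Exons are concatenated in genomic order and the result is
#' reverse-complemented for minus-strand transcripts, yielding the UTR in
#' transcript orientation (5' to 3', 3' end abutting the canonical start);
#' DNA is mapped to the RNA alphabet.
#'
#' @param exons tibble of one transcript's exon rows
#'   (as from [load_utr_regions()]).
#' @param genome a `DNAStringSet` from [read_genome()].
#' @return sequence string in the RNA alphabet.
#' @export
extract_utr_sequence <- function(exons, genome) {
  fwd <- spliced_forward(exons, genome)
  if (exons$strand[1] == "-") {
    fwd <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  }
  clean_utr(fwd)
}

#' Load variants from a VCF file
#'
#' Multi-allelic records are split into biallelic records. Positions are
#' 1-based genomic coordinates of the first REF base, as in the VCF
#' standard.
#'
#' @param vcf_path path to a VCF file (plain or bgzipped).
#' @return tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @export
load_variants <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) { # single-record VCF: a named vector comes back
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), id = character(),
                  ref = character(), alt = character()))
  }
  tbl <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                id = fix$ID, ref = toupper(fix$REF), alt = toupper(fix$ALT))
  tbl <- tidyr::separate_rows(tbl, "alt", sep = ",")
  tbl$id <- ifelse(is.na(tbl$id) | tbl$id == ".",
                   paste0(tbl$chrom, ":", tbl$pos, tbl$ref, ">", tbl$alt),
                   tbl$id)
  if (any(tbl$ref == "" | tbl$alt == "")) abort("empty REF or ALT allele")
  tbl
}

# map variants into the spliced forward-orientation sequence and inject
# them right-to-left so earlier edits do not displace later ones
inject_variants_forward <- function(exons, fwd_seq, variants) {
  exon_offsets <- c(0L, cumsum(exons$end - exons$start))
  coords <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    g0 <- v$pos - 1L # 0-based genomic start of REF
    g1 <- g0 + nchar(v$ref) # half-open end
    hit <- which(exons$start <= g0 & g0 < exons$end)
    if (length(hit) == 0) return(NULL) # outside the UTR: caller filtered
    if (g1 > exons$end[hit]) {
      abort(sprintf("variant %s spans an exon boundary", v$id))
    }
    s0 <- exon_offsets[hit] + (g0 - exons$start[hit]) # 0-based spliced
    list(s0 = s0, s1 = s0 + nchar(v$ref), ref = v$ref, alt = v$alt, id = v$id)
  })
  coords <- Filter(Negate(is.null), coords)
  if (length(coords) == 0) return(fwd_seq)
  ord <- order(vapply(coords, `[[`, numeric(1), "s0"), decreasing = TRUE)
  coords <- coords[ord]
  ends <- vapply(coords, `[[`, numeric(1), "s1")
  starts <- vapply(coords, `[[`, numeric(1), "s0")
  if (any(starts[-length(starts)] < ends[-1])) {
    abort("overlapping variants within one transcript; split or phase them upstream")
  }
  out <- fwd_seq
  for (cv in coords) {
    found <- substr(out, cv$s0 + 1L, cv$s1)
    if (found != cv$ref) {
      abort(sprintf("REF mismatch for %s: expected '%s', genome has '%s'",
                    cv$id, cv$ref, found))
    }
    out <- paste0(substr(out, 1L, cv$s0), cv$alt,
                  substr(out, cv$s1 + 1L, nchar(out)))
  }
  out
}

#' Inject variants into a transcript's 5'UTR
#'
#' Applies substitutions and indels jointly (right-to-left in spliced
#' coordinates, so upstream edits never displace downstream ones) in the
#' genomic orientation, then reorients for minus-strand transcripts. Every
#' REF allele is checked against the extracted sequence; variants spanning
#' an exon boundary and overlapping variants are rejected.
#'
#' @param exons one transcript's exon tibble.
#' @param genome a `DNAStringSet`.
#' @param variants tibble of variants (as from [load_variants()]) already
#'   restricted to this transcript's chromosome.
#' @return alternative UTR sequence (RNA alphabet, transcript orientation).
#' @export
apply_variants <- function(exons, genome, variants) {
  fwd <- spliced_forward(exons, genome)
  alt_fwd <- inject_variants_forward(exons, fwd, variants)
  if (exons$strand[1] == "-") {
    alt_fwd <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(alt_fwd)))
  }
  clean_utr(alt_fwd)
}

#' Score a reference/alternative sequence pair
#'
#' Predicts MRL for both sequences and reports `log2fc =
#' log2(mrl_alt / mrl_ref)` plus two simulated-frameshift scores obtained
#' by appending 1 and 2 masked zero positions at the 3' end of both
#' sequences, which displaces every real position's reading frame. A
#' near-zero unshifted score with strongly negative shifted scores flags
#' variants acting within the canonical frame (e.g. in-frame uAUG
#' creation).
#'
#' @param predictor anything implementing [mrl_predict()].
#' @param ref_seq,alt_seq sequence strings (>= 3 nt).
#' @param library optional library label.
#' @return one-row tibble: `mrl_ref`, `mrl_alt`, `log2fc`, `log2fc_shift1`,
#'   `log2fc_shift2`.
#' @export
score_variants <- function(predictor, ref_seq, alt_seq, library = NULL) {
  score_shift <- function(shift) {
    p <- mrl_predict(predictor, c(ref_seq, alt_seq), library = library,
                     shift = shift)
    if (any(p <= 0)) {
      abort("non-positive MRL prediction: log2 fold change undefined")
    }
    list(ref = p[1], alt = p[2], fc = log2(p[2] / p[1]))
  }
  s0 <- score_shift(0L)
  tibble(mrl_ref = s0$ref, mrl_alt = s0$alt, log2fc = s0$fc,
         log2fc_shift1 = score_shift(1L)$fc,
         log2fc_shift2 = score_shift(2L)$fc)
}

#' Run the VCF + BED + FASTA variant-effect pipeline
#'
#' Intersects variants with 5'UTR exon regions, keeps transcripts with at
#' least one intersecting variant, extracts the spliced strand-aware
#' reference UTRs, injects each variant (one row per transcript x variant
#' pair), and reports log2 MRL fold changes plus the two
#' simulated-frameshift scores. Rows are ordered by transcript id, then
#' genomic position. An empty intersection returns an empty table, not an
#' error.
#'
#' @param vcf_path,bed_path,fasta_path input files.
#' @param predictor anything implementing [mrl_predict()] (a trained
#'   `mrl_model` or the simulator [oracle_predictor()]).
#' @param library optional library label passed to the predictor.
#' @return tibble with columns `transcript_id`, `variant_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `mrl_ref`, `mrl_alt`, `log2fc`, `log2fc_shift1`,
#'   `log2fc_shift2`.
#' @export
run_vcf_pipeline <- function(vcf_path, bed_path, fasta_path, predictor,
                             library = NULL) {
  regions <- load_utr_regions(bed_path)
  variants <- load_variants(vcf_path)
  genome <- read_genome(fasta_path)
  empty <- tibble(transcript_id = character(), variant_id = character(),
                  chrom = character(), pos = integer(), ref = character(),
                  alt = character(), mrl_ref = numeric(), mrl_alt = numeric(),
                  log2fc = numeric(), log2fc_shift1 = numeric(),
                  log2fc_shift2 = numeric())
  if (nrow(variants) == 0 || nrow(regions) == 0) return(empty)
  rows <- list()
  for (tid in unique(regions$transcript_id)) {
    exons <- regions[regions$transcript_id == tid, ]
    hit <- variants$chrom == exons$chrom[1] &
      vapply(seq_len(nrow(variants)), function(i) {
        g0 <- variants$pos[i] - 1L
        any(exons$start <= g0 & g0 < exons$end)
      }, logical(1))
    vs <- variants[hit, ]
    if (nrow(vs) == 0) next
    ref_seq <- extract_utr_sequence(exons, genome)
    vs <- dplyr::arrange(vs, .data$pos)
    for (i in seq_len(nrow(vs))) {
      alt_seq <- apply_variants(exons, genome, vs[i, ])
      sc <- score_variants(predictor, ref_seq, alt_seq, library = library)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(transcript_id = tid, variant_id = vs$id[i],
               chrom = vs$chrom[i], pos = vs$pos[i], ref = vs$ref[i],
               alt = vs$alt[i]), sc)
    }
  }
  if (length(rows) == 0) return(empty)
  dplyr::arrange(dplyr::bind_rows(rows), .data$transcript_id, .data$pos)
}

#' Write a variant-effect table as TSV
#'
#' @param effects tibble from [run_vcf_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_effects <- function(effects, path) {
  readr::write_tsv(effects, path)
  invisible(path)
}
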