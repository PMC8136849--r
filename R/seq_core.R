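#' @importFrom rlang .data abort warn `%||%`
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

RNA_BASES <- c("A", "C", "G", "U")
STOP_CODONS <- c("UAA", "UAG", "UGA")

#' Validate and canonicalise 5'UTR sequences
#'
#' Sequences are stored uppercase in the RNA alphabet (A, C, G, U); T on input
#' is mapped to U. `N` is accepted as an ambiguity code and later one-hot
#' encodes to an all-zero row. Any other character is an error. The 3' end of
#' a 5'UTR sequence is taken to abut the canonical start codon; all
#' reading-frame logic in the package is anchored there.
#'
#' @param x character vector of sequences (DNA or RNA alphabet).
#' @return character vector of validated RNA-alphabet sequences.
#' @export
#' @examples
#' clean_utr(c("acgt", "AUGGN"))
clean_utr <- function(x) {
  if (!is.character(x)) abort("sequences must be a character vector")
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    i <- which(bad)[1]
    pos <- regexpr("[^ACGUN]", x[i])
    abort(sprintf(
      "invalid character '%s' at position %d of sequence %d",
      substr(x[i], pos, pos), pos, i
    ))
  }
  if (any(nchar(x) < 1)) abort("empty sequence after validation")
  x
}

#' One-hot encode a 5'UTR sequence
#'
#' Channel order is fixed as (A, C, G, U). `N` encodes as an all-zero row,
#' matching the zero-padding convention so that ambiguous bases contribute
#' nothing to downstream convolutions.
#'
#' @param seq a single sequence string (validated with [clean_utr()]).
#' @return an `L x 4` numeric matrix with columns named A, C, G, U.
#' @export
#' @examples
#' one_hot_encode("ACGU")
one_hot_encode <- function(seq) {
  seq <- clean_utr(seq)
  if (length(seq) != 1) abort("one_hot_encode() takes a single sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, RNA_BASES) # NA for N
  m <- matrix(0, nrow = length(chars), ncol = 4,
              dimnames = list(NULL, RNA_BASES))
  hit <- !is.na(idx)
  m[cbind(which(hit), idx[hit])] <- 1
  m
}

#' Pad one-hot sequences into a 3'-aligned batch
#'
#' All sequences in a batch are right-aligned so their 3' ends (the positions
#' abutting the canonical start codon) coincide; shorter sequences are padded
#' at the 5' end with all-zero rows that are flagged invalid in the mask.
#' This is what makes reading-frame positions comparable across a
#' variable-length batch.
#'
#' @param mats list of one-hot matrices (each `L_b x 4`), or a character
#'   vector of sequences which are encoded first.
#' @return a list of class `padded_batch` with elements
#'   `x` (`(Lmax*B) x 4` matrix, position-fastest row order), `lmax`, `b`,
#'   `lengths` (true lengths) and `mask` (`Lmax x B` logical; valid rows of
#'    sequence b are `(Lmax - lengths[b] + 1):Lmax`).
#' @export
pad_batch <- function(mats) {
  if (is.character(mats)) mats <- lapply(clean_utr(mats), one_hot_encode)
  if (length(mats) == 0) abort("pad_batch() needs at least one sequence")
  lens <- vapply(mats, nrow, integer(1))
  lmax <- max(lens)
  b <- length(mats)
  x <- matrix(0, nrow = lmax * b, ncol = 4)
  mask <- matrix(FALSE, nrow = lmax, ncol = b)
  for (i in seq_len(b)) {
    rows <- (lmax - lens[i] + 1):lmax
    x[rows + (i - 1L) * lmax, ] <- mats[[i]]
    mask[rows, i] <- TRUE
  }
  structure(list(x = x, lmax = lmax, b = b, lengths = lens, mask = mask),
            class = "padded_batch")
}

#' Strip padding from a batch
#'
#' Inverse of [pad_batch()]: recovers the per-sequence one-hot matrices.
#' @param batch a `padded_batch`.
#' @return list of one-hot matrices.
#' @export
unpad_batch <- function(batch) {
  stopifnot(inherits(batch, "padded_batch"))
  lapply(seq_len(batch$b), function(i) {
    rows <- (batch$lmax - batch$lengths[i] + 1):batch$lmax
    batch$x[rows + (i - 1L) * batch$lmax, , drop = FALSE]
  })
}

#' Reading frame of a position relative to the canonical start codon
#'
#' For a 0-based position `i` in a 5'UTR of length `L` (whose 3' end abuts
#' the canonical start codon), the frame is `(L - i) mod 3`. A codon starting
#' at `i` is in-frame with the canonical CDS iff the result is 0.
#'
#' @param i 0-based position(s).
#' @param L sequence length(s).
#' @return integer frame(s) in {0, 1, 2}.
#' @export
#' @examples
#' frame_index(0, 6) # an uAUG at 0 in a 6-nt UTR is in-frame
frame_index <- function(i, L) {
  if (any(i < 0 | i >= L)) abort("position out of range [0, L)")
  as.integer((L - i) %% 3)
}

all_kmers <- function(k) {
  grids <- rev(rep(list(RNA_BASES), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

#' Count k-mers, optionally split by reading frame
#'
#' Unframed counts are the occurrences of each of the `4^k` k-mers over all
#' `L - k + 1` windows. Framed counts assign each occurrence to the reading
#' frame of its first base (via [frame_index()]) and concatenate the three
#' frame blocks in order frame 0, 1, 2, yielding a `3 * 4^k` vector. Windows
#' containing `N` are not counted.
#'
#' @param seq a single sequence string.
#' @param k k-mer size (>= 1).
#' @param framed split counts by reading frame?
#' @return named integer vector of length `4^k` or `3 * 4^k` (framed names
#'   are prefixed `f0_`, `f1_`, `f2_`).
#' @export
#' @examples
#' kmer_counts("ACGUACG", 3)
kmer_counts <- function(seq, k, framed = FALSE) {
  seq <- clean_utr(seq)
  if (length(seq) != 1) abort("kmer_counts() takes a single sequence")
  if (k < 1) abort("k must be >= 1")
  kmers <- all_kmers(k)
  L <- nchar(seq)
  n_win <- max(L - k + 1L, 0L)
  tab_one <- function(words) {
    idx <- match(words, kmers) # NA for windows containing N
    tabulate(idx[!is.na(idx)], nbins = length(kmers))
  }
  if (n_win == 0L) {
    words <- character(0)
  } else {
    starts <- seq_len(n_win)
    words <- substring(seq, starts, starts + k - 1L)
  }
  if (!framed) {
    counts <- if (n_win == 0L) integer(length(kmers)) else tab_one(words)
    names(counts) <- kmers
    return(counts)
  }
  counts <- integer(3L * length(kmers))
  if (n_win > 0L) {
    fr <- frame_index(starts - 1L, L)
    for (j in 0:2) {
      counts[j * length(kmers) + seq_along(kmers)] <- tab_one(words[fr == j])
    }
  }
  names(counts) <- paste0(rep(paste0("f", 0:2, "_"), each = length(kmers)), kmers)
  counts
}

#' k-mer feature matrix for a set of sequences
#'
#' Row-binds [kmer_counts()] over a vector of sequences; the feature matrix
#' used by the k-mer random-forest baselines.
#'
#' @inheritParams kmer_counts
#' @param seqs character vector of sequences.
#' @return numeric matrix, one row per sequence.
#' @export
kmer_feature_matrix <- function(seqs, k, framed = FALSE) {
  seqs <- clean_utr(seqs)
  t(vapply(seqs, kmer_counts, numeric(ifelse(framed, 3, 1) * 4^k),
           k = k, framed = framed, USE.NAMES = FALSE))
}

#' Read a sequence/MRL table
#'
#' Reads a CSV or TSV file with columns `utr` (sequence), optionally `mrl`
#' (numeric) and `library` (string); sequences are validated and converted
#' to the RNA alphabet.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @return a tibble with at least a `utr` column.
#' @export
read_utr_table <- function(path) {
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!"utr" %in% names(tbl)) abort("table must have a 'utr' column")
  tbl$utr <- clean_utr(tbl$utr)
  as_tibble(tbl)
}

#' Read 5'UTR sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return tibble with columns `name` and `utr` (RNA alphabet).
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  tibble(name = names(ss), utr = clean_utr(unname(as.character(ss))))
}
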