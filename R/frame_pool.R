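#' Convolutional feature map with validity mask
#'
#' A light container for an `L x F` position-by-filter activation matrix
#' (positions ordered 5' to 3') together with a length-`L` logical mask
#' marking which positions are real sequence (as opposed to batch padding).
#'
#' @param values `L x F` numeric matrix.
#' @param mask logical vector of length `L`; defaults to all valid.
#' @return an object of class `conv_feature_map`.
#' @export
conv_feature_map <- function(values, mask = NULL) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- rep(TRUE, nrow(values))
  if (length(mask) != nrow(values)) abort("mask length must equal row count")
  structure(list(values = values, mask = as.logical(mask)),
            class = "conv_feature_map")
}

#' Slice a feature map by reading frame
#'
#' The map is first reversed along the position axis so that index 0 of the
#' reversed order is the 3'-most position (the one abutting the canonical
#' start codon); frame slice j then takes reversed indices j, j+3, j+6, ....
#' Anchoring at the 3' end guarantees that two positions at equal distance
#' mod 3 from the canonical start always share a slice, whatever the
#' sequence length or amount of 5' padding.
#'
#' @param map a [conv_feature_map()].
#' @return list of three `conv_feature_map`s (frames 0, 1, 2), masks sliced
#'   identically.
#' @export
frame_slices <- function(map) {
  stopifnot(inherits(map, "conv_feature_map"))
  L <- nrow(map$values)
  rev_idx <- L:1 # reversed order: first element is the 3'-most position
  lapply(0:2, function(j) {
    if (j + 1L > L) {
      return(conv_feature_map(map$values[0, , drop = FALSE], logical(0)))
    }
    take <- rev_idx[seq(j + 1L, L, by = 3)]
    conv_feature_map(map$values[take, , drop = FALSE], map$mask[take])
  })
}

masked_stats <- function(values, mask) {
  f <- ncol(values)
  v <- values[mask, , drop = FALSE]
  if (nrow(v) == 0) return(list(max = numeric(f), avg = numeric(f)))
  list(max = apply(v, 2, max), avg = colMeans(v))
}

#' Frame pooling
#'
#' Applies masked global max and average pooling separately within each of
#' the three reading-frame slices of a feature map and concatenates the
#' results in the fixed layout `[max f0 | max f1 | max f2 | avg f0 | avg f1
#' | avg f2]`, each block of length F. Invalid (padding) positions are
#' excluded entirely from both statistics so the output is invariant to 5'
#' zero-padding; a frame with no valid position pools to 0 for both
#' statistics. The output length is `6 * F` for any input length.
#'
#' @param map a [conv_feature_map()].
#' @return numeric vector of length `6 * ncol(map$values)`.
#' @export
frame_pool <- function(map) {
  slices <- frame_slices(map)
  stats <- lapply(slices, function(s) masked_stats(s$values, s$mask))
  c(unlist(lapply(stats, `[[`, "max"), use.names = FALSE),
    unlist(lapply(stats, `[[`, "avg"), use.names = FALSE))
}

#' Explicit-loop reference for frame pooling
#'
#' Identical contract to [frame_pool()], computed with per-position loops
#' and running accumulators, no slicing or vectorisation. Kept as an
#' independent reference implementation for testing.
#'
#' @inheritParams frame_pool
#' @return numeric vector of length `6 * F`.
#' @export
frame_pool_oracle <- function(map) {
  stopifnot(inherits(map, "conv_feature_map"))
  L <- nrow(map$values)
  f <- ncol(map$values)
  mx <- matrix(-Inf, 3, f)
  sm <- matrix(0, 3, f)
  ct <- integer(3)
  for (i in 0:(L - 1)) { # 0-based original position
    if (!map$mask[i + 1]) next
    j <- (L - 1 - i) %% 3 # slice after 3'-anchored reversal
    ct[j + 1] <- ct[j + 1] + 1L
    for (ff in seq_len(f)) {
      v <- map$values[i + 1, ff]
      if (v > mx[j + 1, ff]) mx[j + 1, ff] <- v
      sm[j + 1, ff] <- sm[j + 1, ff] + v
    }
  }
  out_max <- numeric(0)
  out_avg <- numeric(0)
  for (j in 1:3) {
    if (ct[j] == 0L) {
      out_max <- c(out_max, numeric(f))
      out_avg <- c(out_avg, numeric(f))
    } else {
      out_max <- c(out_max, mx[j, ])
      out_avg <- c(out_avg, sm[j, ] / ct[j])
    }
  }
  c(out_max, out_avg)
}

#' Masked global pooling
#'
#' Frame-unaware counterpart of [frame_pool()]: masked global max and
#' average over all valid positions, concatenated as `[max | avg]`
#' (length `2 * F`). Used by the global-pooling baseline architectures.
#'
#' @inheritParams frame_pool
#' @return numeric vector of length `2 * F`.
#' @export
global_pool <- function(map) {
  stopifnot(inherits(map, "conv_feature_map"))
  s <- masked_stats(map$values, map$mask)
  c(s$max, s$avg)
}
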