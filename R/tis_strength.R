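#' Upstream TIS context
#'
#' A start-codon context in the window convention of the large-scale
#' initiation-strength assays: AUG contexts carry a 6-nt upstream and 2-nt
#' downstream flank (the -6..+5 window, numbering the A of the codon +1);
#' alternative codons (CUG, GUG, ...) carry 3-nt upstream and 1-nt
#' downstream flanks (-3..+4).
#'
#' @param codon start codon string (e.g. "AUG", "CUG").
#' @param upstream,downstream flank strings (RNA alphabet).
#' @param strength optional measured relative strength.
#' @return one-row tibble of class `tis_context` fields.
#' @export
tis_context <- function(codon, upstream, downstream, strength = NA_real_) {
  codon <- clean_utr(codon)
  upstream <- clean_utr(upstream)
  downstream <- clean_utr(downstream)
  if (nchar(codon) != 3) abort("codon must be 3 nt")
  need <- if (codon == "AUG") c(6L, 2L) else c(3L, 1L)
  if (nchar(upstream) != need[1] || nchar(downstream) != need[2]) {
    abort(sprintf("%s contexts need %d nt upstream and %d nt downstream",
                  codon, need[1], need[2]))
  }
  tibble(codon = codon, upstream = upstream, downstream = downstream,
         strength = strength)
}

assemble_context <- function(codon, upstream, downstream, active,
                             inactive_codon = "AGG") {
  paste0(upstream, if (active) codon else inactive_codon, downstream)
}

#' Detect unintended AUGs in an assembled context window
#'
#' Contexts that inadvertently introduce an extra AUG (e.g. AAUGGGAUGGG)
#' leave the identity of the selected start codon ambiguous and are removed
#' from benchmarking. For an AUG context the central codon itself is not
#' counted in its active form; for non-AUG codons any AUG in the window
#' counts.
#'
#' @param codon,upstream,downstream context fields (see [tis_context()]).
#' @param active whether the central codon is in its active form (inactive
#'   form replaces it with AGG).
#' @return logical.
#' @export
#' @examples
#' has_unintended_aug("AUG", "AAUGGG", "GG", active = TRUE)  # TRUE
#' has_unintended_aug("AUG", "GCCACC", "GG", active = TRUE)  # FALSE
has_unintended_aug <- function(codon, upstream, downstream, active = TRUE) {
  window <- assemble_context(codon, upstream, downstream, active)
  m <- gregexpr("AUG", window, fixed = TRUE)[[1]]
  if (m[1] == -1) return(FALSE)
  pos <- as.integer(m) - 1L
  central <- nchar(upstream)
  if (codon == "AUG" && active) pos <- pos[pos != central]
  length(pos) > 0
}

context_passes_filter <- function(codon, upstream, downstream) {
  !has_unintended_aug(codon, upstream, downstream, active = TRUE) &&
    !has_unintended_aug(codon, upstream, downstream, active = FALSE)
}

#' Predicted effect of activating an upstream TIS context
#'
#' Embeds the context out-of-frame (the codon start fixed in the +1 frame,
#' `frame_index = 1`) in seeded random-base backgrounds whose total length
#' equals the predictor's receptive field, predicts MRL with the codon
#' active and deactivated (AGG), and averages the per-background MRL fold
#' change `predict(active) / predict(inactive)`. Strong contexts repress
#' MRL when activated, giving fold changes below 1.
#'
#' @inheritParams tis_context
#' @param predictor anything implementing [mrl_predict()].
#' @param n_backgrounds number of random backgrounds averaged over.
#' @param seed RNG seed for the backgrounds.
#' @param total_length background sequence length; defaults to the
#'   receptive field for an `mrl_model` (must be given for other
#'   predictors).
#' @param scale `"plain"` averages fold changes directly (default);
#'   `"log"` averages on the log scale (geometric mean).
#' @param return_draws also return the per-background fold changes.
#' @return mean MRL fold change (scalar), or with `return_draws = TRUE` a
#'   list with `effect` and the per-background `draws`.
#' @export
predicted_tis_effect <- function(predictor, codon, upstream, downstream,
                                 n_backgrounds = 100L, seed = 1L,
                                 total_length = NULL,
                                 scale = c("plain", "log"),
                                 return_draws = FALSE) {
  scale <- match.arg(scale)
  if (!context_passes_filter(codon, upstream, downstream)) {
    abort("context fails the unintended-AUG filter")
  }
  if (is.null(total_length)) {
    if (!inherits(predictor, "mrl_model")) {
      abort("total_length is required for non-model predictors")
    }
    total_length <- receptive_field(predictor)
  }
  w <- nchar(upstream) + 3L + nchar(downstream)
  if (total_length < w) abort("receptive field smaller than the context window")
  up <- nchar(upstream)
  # left-pad length a places the codon at 0-based i = a + up; fix the +1
  # frame: (L - i) %% 3 == 1; among feasible a choose the most central
  a_all <- 0:(total_length - w)
  a_ok <- a_all[(total_length - (a_all + up)) %% 3 == 1]
  if (length(a_ok) == 0) abort("no placement achieves the +1 frame")
  a <- a_ok[which.min(abs(a_ok - (total_length - w) / 2))]
  b <- total_length - w - a
  act <- assemble_context(codon, upstream, downstream, TRUE)
  inact <- assemble_context(codon, upstream, downstream, FALSE)
  fc <- with_local_seed(seed, {
    vapply(seq_len(n_backgrounds), function(i) {
      left <- paste(sample(RNA_BASES, a, replace = TRUE), collapse = "")
      right <- paste(sample(RNA_BASES, b, replace = TRUE), collapse = "")
      p <- mrl_predict(predictor,
                       c(paste0(left, act, right), paste0(left, inact, right)))
      p[1] / p[2]
    }, numeric(1))
  })
  effect <- if (scale == "plain") mean(fc) else 2^mean(log2(fc))
  if (return_draws) list(effect = effect, draws = fc) else effect
}

#' Benchmark predicted TIS effects against measured strengths
#'
#' Scores every context that passes the unintended-AUG filter (in both
#' active and inactive form) with [predicted_tis_effect()] and correlates
#' the predicted fold changes with the measured strengths. Stronger
#' contexts repress more, so the expected correlations are negative.
#'
#' @param data tibble of contexts with columns `codon`, `upstream`,
#'   `downstream`, `strength`.
#' @param predictor anything implementing [mrl_predict()].
#' @inheritParams predicted_tis_effect
#' @return list with `scores` (the input plus `effect`, `filtered`,
#'   `reason` columns), `pearson` and `spearman` (NA with constant or
#'   insufficient measurements), `n_used`.
#' @export
tis_benchmark <- function(data, predictor, n_backgrounds = 100L, seed = 1L,
                          total_length = NULL, scale = c("plain", "log")) {
  scale <- match.arg(scale)
  data <- as_tibble(data)
  stopifnot(all(c("codon", "upstream", "downstream", "strength") %in%
                  names(data)))
  data$filtered <- !mapply(context_passes_filter, data$codon, data$upstream,
                           data$downstream)
  data$reason <- ifelse(data$filtered, "unintended AUG in window", NA)
  data$effect <- NA_real_
  keep <- which(!data$filtered)
  for (k in seq_along(keep)) {
    i <- keep[k]
    data$effect[i] <- predicted_tis_effect(
      predictor, data$codon[i], data$upstream[i], data$downstream[i],
      n_backgrounds = n_backgrounds, seed = seed + i,
      total_length = total_length, scale = scale)
  }
  used <- dplyr::filter(data, !.data$filtered, !is.na(.data$strength))
  if (nrow(used) < 3) abort("need at least 3 measured, unfiltered contexts")
  pear <- sp <- NA_real_
  if (stats::sd(used$strength) > 0 && stats::sd(used$effect) > 0) {
    pear <- stats::cor(used$effect, used$strength, method = "pearson")
    sp <- stats::cor(used$effect, used$strength, method = "spearman")
  }
  list(scores = data, pearson = pear, spearman = sp, n_used = nrow(used))
}

#' Read a TIS context table
#'
#' CSV with columns `codon`, `upstream`, `downstream`, `strength`.
#' @param path CSV path.
#' @return tibble of contexts.
#' @export
read_tis_contexts <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("codon", "upstream", "downstream", "strength") %in%
                  names(tbl)))
  tbl$codon <- clean_utr(tbl$codon)
  tbl$upstream <- clean_utr(tbl$upstream)
  tbl$downstream <- clean_utr(tbl$downstream)
  as_tibble(tbl)
}
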