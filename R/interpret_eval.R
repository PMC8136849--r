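#' Gradient-based contribution scores
#'
#' Computes the exact gradient of the scalar MRL prediction with respect to
#' the one-hot input by backpropagation through the built network, either
#' raw (`raw_gradient`, usable as hypothetical contribution scores) or
#' multiplied elementwise by the one-hot input (`gradient_x_input`, which
#' zeroes all channels where the input is zero). Only differentiable
#' predictors (built `mrl_model`s) are supported; the simulator oracle is
#' not differentiable.
#'
#' @param model an `mrl_model`.
#' @param seq a single sequence string.
#' @param flavor `"gradient_x_input"` or `"raw_gradient"`.
#' @param library optional library label.
#' @return an `L x 4` matrix (channels A, C, G, U) with attribute `flavor`.
#' @export
gradient_contributions <- function(model, seq,
                                   flavor = c("gradient_x_input",
                                              "raw_gradient"),
                                   library = NULL) {
  flavor <- match.arg(flavor)
  if (!inherits(model, "mrl_model")) {
    abort("contribution scores need a differentiable predictor (mrl_model)")
  }
  seq <- clean_utr(seq)
  if (length(seq) != 1) abort("gradient_contributions() takes one sequence")
  X <- one_hot_encode(seq)
  L <- nrow(X)
  mask <- matrix(TRUE, L, 1)
  idx <- lib_index(model, library, 1L)
  fw <- nn_forward(model$params, model$config, X, L, 1L, mask,
                   lib_idx = idx, training = FALSE)
  g <- nn_backward(model$params, model$config, fw, X, L, 1L, mask,
                   lib_idx = idx, dpred = 1, want_input_grad = TRUE)$input
  out <- if (flavor == "gradient_x_input") g * X else g
  dimnames(out) <- list(NULL, RNA_BASES)
  attr(out, "flavor") <- flavor
  out
}

#' Write a contribution matrix as TSV
#'
#' Position-by-channel scores in a sequence-logo-ready layout.
#' @param scores matrix from [gradient_contributions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contributions <- function(scores, path) {
  df <- as_tibble(as.data.frame(scores))
  df <- dplyr::mutate(df, position = dplyr::row_number(), .before = 1)
  readr::write_tsv(df, path)
  invisible(path)
}

#' In-silico saturation mutagenesis
#'
#' Scores every single-base substitution of a sequence (3 alternatives per
#' position; the reference base is excluded) as
#' `log2(predict(mutant) / predict(reference))` and summarises each
#' position by the mean of the absolute log2 fold changes — the
#' per-position expected impact of a variant when the alternative base is
#' unknown.
#'
#' @param predictor anything implementing [mrl_predict()].
#' @param seq a single sequence string (no ambiguity codes).
#' @param library optional library label.
#' @param batch_size predictor batch size.
#' @return object of class `saturation_result`: list with `scores`
#'   (tibble: `position` 1-based, `ref_base`, `alt_base`, `log2fc`) and
#'   `profile` (tibble: `position`, `ref_base`, `mean_abs_log2fc`).
#' @export
saturation_mutagenesis <- function(predictor, seq, library = NULL,
                                   batch_size = 192L) {
  seq <- clean_utr(seq)
  if (length(seq) != 1) abort("saturation_mutagenesis() takes one sequence")
  if (grepl("N", seq, fixed = TRUE)) abort("sequence must not contain N")
  L <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  grid <- tidyr::expand_grid(position = seq_len(L), alt_base = RNA_BASES)
  grid$ref_base <- chars[grid$position]
  grid <- dplyr::filter(grid, .data$alt_base != .data$ref_base)
  muts <- vapply(seq_len(nrow(grid)), function(i) {
    s <- chars
    s[grid$position[i]] <- grid$alt_base[i]
    paste(s, collapse = "")
  }, character(1))
  p_ref <- mrl_predict(predictor, seq, library = library)
  preds <- numeric(length(muts))
  for (s in seq(1L, length(muts), by = batch_size)) {
    i <- s:min(s + batch_size - 1L, length(muts))
    preds[i] <- mrl_predict(predictor, muts[i], library = library)
  }
  if (p_ref <= 0 || any(preds <= 0)) {
    abort("non-positive MRL prediction: log2 fold change undefined")
  }
  grid$log2fc <- log2(preds / p_ref)
  profile <- grid |>
    dplyr::group_by(.data$position, .data$ref_base) |>
    dplyr::summarise(mean_abs_log2fc = mean(abs(.data$log2fc)),
                     .groups = "drop")
  structure(list(scores = grid[, c("position", "ref_base", "alt_base",
                                   "log2fc")],
                 profile = profile, seq = seq),
            class = "saturation_result")
}

#' @export
print.saturation_result <- function(x, ...) {
  cat(sprintf("<saturation_result> %d positions, peak mean |log2FC| %.3f\n",
              nrow(x$profile), max(x$profile$mean_abs_log2fc)))
  invisible(x)
}

#' Plot a saturation mutagenesis result
#'
#' Heatmap of the per-substitution log2 fold changes across positions.
#'
#' @param object a `saturation_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot saturation_result
#' @export
autoplot.saturation_result <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$position, .data$alt_base,
                               fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "5'UTR position", y = "alternative base",
                  fill = "log2 FC") +
    ggplot2::theme_minimal()
}

#' Bootstrap comparison of two predictors
#'
#' Resamples (prediction A, prediction B, observation) triplets jointly
#' with replacement and computes, per replicate, the difference in
#' correlation with the observations. The confidence interval is
#' `mean +/- multiplier * SD` over replicates — standard deviations, not
#' standard errors, so the interval does not shrink with more replicates —
#' and the default multiplier 3.54 corresponds to the multiple-testing-
#' corrected interval used when many model pairs are compared.
#'
#' @param pred_a,pred_b,observed equal-length numeric vectors (n >= 10).
#' @param n_boot bootstrap replicates.
#' @param multiplier half-width of the interval in SD units.
#' @param seed RNG seed.
#' @param method correlation method (`"pearson"` or `"spearman"`).
#' @return one-row tibble: `metric_a`, `metric_b`, `mean_diff`, `sd_diff`,
#'   `ci_halfwidth`, `significant`, `n_boot`, `multiplier`.
#' @export
bootstrap_compare <- function(pred_a, pred_b, observed, n_boot = 100L,
                              multiplier = 3.54, seed = 1L,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(observed)
  if (length(pred_a) != n || length(pred_b) != n) abort("length mismatch")
  if (n < 10) abort("need at least 10 observations")
  if (stats::sd(observed) == 0 || stats::sd(pred_a) == 0 ||
      stats::sd(pred_b) == 0) {
    abort("constant vector: correlation undefined")
  }
  diffs <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(r) {
      i <- sample.int(n, n, replace = TRUE)
      stats::cor(pred_a[i], observed[i], method = method) -
        stats::cor(pred_b[i], observed[i], method = method)
    }, numeric(1))
  })
  m <- mean(diffs)
  s <- stats::sd(diffs)
  hw <- multiplier * s
  tibble(metric_a = stats::cor(pred_a, observed, method = method),
         metric_b = stats::cor(pred_b, observed, method = method),
         mean_diff = m, sd_diff = s, ci_halfwidth = hw,
         significant = (m - hw) > 0 | (m + hw) < 0,
         n_boot = n_boot, multiplier = multiplier)
}

#' Translation efficiency from ribosome profiling counts
#'
#' `TE = RPF / RNA` per gene; genes with fewer than `min_rpf` ribosome-
#' protected-fragment reads, or without RNA-seq coverage, are flagged
#' excluded (outlier control).
#'
#' @param rpf_counts,rna_counts non-negative count vectors.
#' @param min_rpf minimum RPF reads to keep a gene.
#' @return tibble: `rpf`, `rna`, `te` (NA when excluded), `excluded`.
#' @export
translation_efficiency <- function(rpf_counts, rna_counts, min_rpf = 10) {
  if (length(rpf_counts) != length(rna_counts)) abort("length mismatch")
  if (any(rpf_counts < 0) || any(rna_counts < 0)) abort("negative counts")
  excl <- rpf_counts < min_rpf | rna_counts <= 0
  tibble(rpf = rpf_counts, rna = rna_counts,
         te = ifelse(excl, NA_real_, rpf_counts / rna_counts),
         excluded = excl)
}

#' Preprocess replicate or per-tissue expression values
#'
#' `tripseq` mode drops rows where any replicate falls below `tpm_min` and
#' averages replicates; `ptr` mode takes the per-row median across tissues,
#' ignoring missing values (rows with no values at all are excluded).
#'
#' @param values numeric matrix or data frame, one row per transcript.
#' @param tpm_min minimum per-replicate TPM (tripseq mode).
#' @param mode `"tripseq"` or `"ptr"`.
#' @return numeric vector, NA for excluded rows.
#' @export
preprocess_expression <- function(values, tpm_min = 1,
                                  mode = c("tripseq", "ptr")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (mode == "tripseq") {
    keep <- apply(values, 1, function(r) all(!is.na(r)) && all(r >= tpm_min))
    out <- ifelse(keep, rowMeans(values), NA_real_)
  } else {
    out <- apply(values, 1, function(r) {
      if (all(is.na(r))) NA_real_ else stats::median(r, na.rm = TRUE)
    })
  }
  as.numeric(out)
}
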