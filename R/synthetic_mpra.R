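#' Leaky-scanning simulator parameters
#'
#' Parameters of the generative model used to synthesise MPRA-like
#' sequence/MRL datasets with the frame-dependent structure that
#' frame-aware models exploit. A 40S subunit scans the 5'UTR from the cap;
#' at each candidate upstream start codon (AUG/CUG/GUG) it initiates with
#' probability `p = plogis(init_slope * context_score + init_intercept) *
#' codon_strength[codon]` — a leaky-scanning model in which weak contexts
#' are skipped more often. Initiation at a uORF (a uTIS with an in-frame
#' stop before the canonical start) allows reinitiation downstream with
#' probability `reinit_prob`, otherwise the ribosome drops off with a low
#' mean load `mu_uorf`. Initiation at a non-uORF uTIS is absorbing: it
#' yields `mu_main` when in-frame with the CDS (an N-terminal extension)
#' and `mu_oof` when out-of-frame. Mass reaching the canonical start yields
#' `mu_main`.
#'
#' The default Kozak position weight matrix puts its weight on the two
#' dominant context positions (-3 and +4, with A/G favoured at -3 and G at
#' +4, numbering the A of the codon as +1) and zero elsewhere; the codon
#' strengths order AUG >> CUG > GUG.
#'
#' @param kozak_pwm 11 x 4 numeric matrix (window positions -6..+5, channel
#'   order A, C, G, U) of additive context weights.
#' @param codon_strength named multipliers for candidate codons.
#' @param init_slope,init_intercept logistic parameters mapping context
#'   score to initiation probability.
#' @param reinit_prob probability of reinitiation after translating a uORF.
#' @param mu_main,mu_oof,mu_uorf mean ribosome loads of the three outcomes
#'   (`mu_main > mu_oof > mu_uorf > 0`).
#' @param noise_sd Gaussian measurement noise SD on simulated MRL.
#' @param library_affines list of `c(scale, bias)` per library, applied to
#'   noisy MRL to emulate library-specific measurement scales.
#' @return an object of class `scanning_params`.
#' @export
scanning_params <- function(kozak_pwm = default_kozak_pwm(),
                            codon_strength = c(AUG = 1.0, CUG = 0.3, GUG = 0.15),
                            init_slope = 1.0, init_intercept = -1.0,
                            reinit_prob = 0.5,
                            mu_main = 6, mu_oof = 2, mu_uorf = 1,
                            noise_sd = 0.3,
                            library_affines = list(c(scale = 1, bias = 0))) {
  stopifnot(nrow(kozak_pwm) == 11, ncol(kozak_pwm) == 4,
            reinit_prob >= 0, reinit_prob <= 1, noise_sd >= 0)
  if (!(mu_main > mu_oof && mu_oof > mu_uorf && mu_uorf > 0)) {
    warn("default preset expects mu_main > mu_oof > mu_uorf > 0")
  }
  structure(list(kozak_pwm = kozak_pwm, codon_strength = codon_strength,
                 init_slope = init_slope, init_intercept = init_intercept,
                 reinit_prob = reinit_prob, mu_main = mu_main,
                 mu_oof = mu_oof, mu_uorf = mu_uorf, noise_sd = noise_sd,
                 library_affines = library_affines),
            class = "scanning_params")
}

#' @rdname scanning_params
#' @export
default_kozak_pwm <- function() {
  pwm <- matrix(0, nrow = 11, ncol = 4, dimnames = list(
    as.character(c(-6:-1, 1:3, 4:5)), RNA_BASES))
  pwm["-3", ] <- c(A = 2.0, C = -0.6, G = 1.4, U = -1.0)
  pwm["4", ] <- c(A = 0.2, C = -0.4, G = 1.6, U = -0.8)
  pwm
}

#' Kozak context score of a candidate start codon
#'
#' Sums the PWM weights over the -6..+5 window around a codon at 0-based
#' position `i` (the A of the codon is position +1); window positions that
#' fall outside the sequence contribute 0.
#'
#' @param seq sequence string (RNA alphabet).
#' @param i 0-based codon start position(s).
#' @param pwm 11 x 4 weight matrix.
#' @return numeric score(s).
#' @export
kozak_context_score <- function(seq, i, pwm = default_kozak_pwm()) {
  L <- nchar(seq)
  vapply(i, function(pos) {
    offs <- -6:4 # sequence offsets of window rows 1..11
    idx <- pos + offs # 0-based
    ok <- idx >= 0 & idx < L
    if (!any(ok)) return(0)
    ch <- substring(seq, idx[ok] + 1, idx[ok] + 1)
    base_i <- match(ch, RNA_BASES)
    rows <- which(ok)
    sum(pwm[cbind(rows[!is.na(base_i)], base_i[!is.na(base_i)])])
  }, numeric(1))
}

#' Annotate candidate upstream initiation sites
#'
#' Finds every AUG/CUG/GUG occurrence in a 5'UTR, listed 5' to 3', with its
#' reading frame (via [frame_index()], optionally displaced by a simulated
#' frameshift), Kozak context score, initiation probability under the given
#' parameters, and uORF status (an in-frame stop codon entirely contained
#' strictly before the canonical start).
#'
#' @param seq sequence string.
#' @param params a [scanning_params()].
#' @param shift frame displacement (simulated frameshift; does not alter
#'   uORF status, which is frame-internal).
#' @return tibble with columns `pos` (0-based), `codon`, `frame`,
#'   `context_score`, `p_init`, `is_uorf`.
#' @export
scan_annotate <- function(seq, params = scanning_params(), shift = 0L) {
  sc <- scan_candidates(clean_utr(seq), params, shift)
  tibble(pos = sc$pos, codon = sc$codon, frame = sc$frame,
         context_score = sc$context_score, p_init = sc$p_init,
         is_uorf = sc$is_uorf)
}

# lean vector version of scan_annotate (hot path of the simulator)
scan_candidates <- function(seq, params, shift = 0L) {
  L <- nchar(seq)
  if (L < 3) abort("sequence must be at least 3 nt")
  codons <- names(params$codon_strength)
  pos <- integer(0)
  codon <- character(0)
  for (cd in codons) {
    m <- gregexpr(cd, seq, fixed = TRUE)[[1]]
    if (m[1] != -1) {
      pos <- c(pos, as.integer(m) - 1L)
      codon <- c(codon, rep(cd, length(m)))
    }
  }
  if (length(pos) == 0) {
    return(list(pos = integer(), codon = character(), frame = integer(),
                context_score = numeric(), p_init = numeric(),
                is_uorf = logical()))
  }
  ord <- order(pos)
  pos <- pos[ord]
  codon <- codon[ord]
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  base_i <- match(chars, RNA_BASES) # NA for N
  pwm <- params$kozak_pwm
  score <- vapply(pos, function(p) {
    idx <- p + (-6:4) # 0-based window positions for PWM rows 1..11
    ok <- which(idx >= 0 & idx < L)
    bi <- base_i[idx[ok] + 1L]
    keep <- !is.na(bi)
    sum(pwm[cbind(ok[keep], bi[keep])])
  }, numeric(1))
  is_uorf <- vapply(pos, function(p) {
    j <- p + 3L
    while (j + 3L <= L) {
      if (substr(seq, j + 1L, j + 3L) %in% STOP_CODONS) return(TRUE)
      j <- j + 3L
    }
    FALSE
  }, logical(1))
  list(pos = pos, codon = codon,
       frame = as.integer((L + shift - pos) %% 3),
       context_score = score,
       p_init = stats::plogis(params$init_slope * score +
                                params$init_intercept) *
         unname(params$codon_strength[codon]),
       is_uorf = is_uorf)
}

#' Expected (noise-free) MRL under the leaky-scanning model
#'
#' Sequential absorption 5' to 3': the scanning subunit reaches candidate
#' `i` with the residual probability left by upstream candidates; a uORF
#' initiation reinitiates with probability `reinit_prob` (else contributes
#' `mu_uorf`), a non-uORF initiation absorbs fully (contributing `mu_main`
#' in-frame, `mu_oof` out-of-frame), and residual mass reaching the
#' canonical start contributes `mu_main`. Returns the probability-weighted
#' mean load.
#'
#' @inheritParams scan_annotate
#' @return expected MRL (scalar).
#' @export
#' @examples
#' oracle_mrl(strrep("C", 30)) # no candidates: exactly mu_main
oracle_mrl <- function(seq, params = scanning_params(), shift = 0L) {
  ann <- scan_candidates(clean_utr(seq), params, shift = shift)
  mass <- 1
  ev <- 0
  for (r in seq_along(ann$pos)) {
    p <- ann$p_init[r]
    if (ann$is_uorf[r]) {
      ev <- ev + mass * p * (1 - params$reinit_prob) * params$mu_uorf
      mass <- mass * (1 - p * (1 - params$reinit_prob))
    } else {
      mu <- if (ann$frame[r] == 0L) params$mu_main else params$mu_oof
      ev <- ev + mass * p * mu
      mass <- mass * (1 - p)
    }
  }
  ev + mass * params$mu_main
}

#' Wrap the simulator as a plug-in predictor
#'
#' Returns an object implementing [mrl_predict()] that maps sequences to
#' noise-free expected MRL under the leaky-scanning model; simulated
#' frameshifts displace the frame computation just as 3' zero-padding does
#' for a convolutional model, and a library label applies that library's
#' affine. Used as an exactly computable stand-in predictor when testing
#' scoring pipelines.
#'
#' @param params a [scanning_params()].
#' @return an object of class `mrl_oracle`.
#' @export
oracle_predictor <- function(params = scanning_params()) {
  structure(list(params = params), class = "mrl_oracle")
}

#' @export
mrl_predict.mrl_oracle <- function(predictor, seqs, library = NULL, shift = 0L) {
  vals <- vapply(clean_utr(seqs), oracle_mrl, numeric(1),
                 params = predictor$params, shift = shift, USE.NAMES = FALSE)
  if (!is.null(library)) {
    li <- as.integer(as.character(library)) + 1L
    if (length(li) == 1) li <- rep(li, length(vals))
    aff <- predictor$params$library_affines
    vals <- vapply(seq_along(vals), function(i) {
      a <- aff[[li[i]]]
      a[[1]] * vals[i] + a[[2]]
    }, numeric(1))
  }
  vals
}

#' Simulate an MPRA-like dataset
#'
#' Draws i.i.d. uniform-base random 5'UTRs (fixed length or uniform over a
#' length range), computes noise-free MRL under the leaky-scanning model,
#' adds Gaussian measurement noise and applies the library's affine scale.
#' Fully reproducible from `(params, seed)`.
#'
#' @param n number of sequences.
#' @param length fixed length (scalar) or inclusive range `c(min, max)`.
#' @param params a [scanning_params()].
#' @param library 0-based library index selecting the affine in
#'   `params$library_affines`.
#' @param seed RNG seed.
#' @return tibble with columns `utr`, `mrl`, `library`.
#' @export
#' @examples
#' simulate_mpra(5, 50, seed = 1)
simulate_mpra <- function(n, length = 50, params = scanning_params(),
                          library = 0L, seed = 1L) {
  if (n < 1) abort("n must be >= 1")
  if (!(base::length(length) %in% c(1L, 2L)) || any(length < 3)) {
    abort("length must be a scalar >= 3 or a range c(min, max)")
  }
  aff <- params$library_affines[[library + 1L]]
  with_local_seed(seed, {
    lens <- if (base::length(length) == 2L) {
      sample(length[1]:length[2], n, replace = TRUE)
    } else rep(as.integer(length), n)
    seqs <- vapply(lens, function(l) {
      paste(sample(RNA_BASES, l, replace = TRUE), collapse = "")
    }, character(1))
    mu <- vapply(seqs, oracle_mrl, numeric(1), params = params,
                 USE.NAMES = FALSE)
    mrl <- aff[[1]] * (mu + rnorm(n, 0, params$noise_sd)) + aff[[2]]
    tibble(utr = seqs, mrl = mrl, library = as.character(library))
  })
}

#' Mean ribosome load from polysome fractions
#'
#' Abundance-weighted mean ribosome number:
#' `sum(ribosomes * counts) / sum(counts)`.
#'
#' @param counts per-fraction transcript abundances (non-negative, summing
#'   to a positive total).
#' @param ribosomes per-fraction ribosome numbers.
#' @return scalar MRL.
#' @export
#' @examples
#' mrl_from_polysome_fractions(c(10, 10), c(1, 2)) # 1.5
mrl_from_polysome_fractions <- function(counts, ribosomes) {
  if (length(counts) != length(ribosomes)) abort("length mismatch")
  if (any(counts < 0) || any(ribosomes < 0)) abort("negative input")
  tot <- sum(counts)
  if (tot <= 0) abort("total counts must be positive")
  sum(ribosomes * counts) / tot
}
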