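test_that("candidate annotation finds uTIS with frame and uORF status", {
  p <- scanning_params()
  ann <- scan_annotate("AUGUAACCC", p)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$pos, 0L)
  expect_equal(ann$frame, 0L) # L = 9, distance 9 divisible by 3
  expect_true(ann$is_uorf)   # UAA at 3 in its own frame
  # uAUG at 1 in a 50-nt UTR: frame (50 - 1) mod 3 = 1, out-of-frame
  s50 <- paste0("C", "AUG", strrep("C", 46))
  ann50 <- scan_annotate(s50, p)
  expect_equal(ann50$frame, 1L)
  expect_false(ann50$is_uorf)
  # no candidate triplets at all
  expect_equal(nrow(scan_annotate(strrep("CA", 10), p)), 0)
  # overlapping candidates of different codons are all reported
  annov <- scan_annotate("CAUGUGCCC", p) # AUG at 1, GUG at 3
  expect_equal(annov$pos, c(1L, 3L))
  expect_equal(annov$codon, c("AUG", "GUG"))
})

test_that("the Kozak context score uses the -6..+5 window with silent flanks", {
  pwm <- default_kozak_pwm()
  # codon at position 6 of CCCACCAUGGC: -3 base is A, +4 base is G
  s <- "CCCACCAUGGC"
  expect_equal(kozak_context_score(s, 6, pwm),
               pwm["-3", "A"] + pwm["4", "G"])
  # missing flanks contribute zero: bare AUG at the sequence start
  expect_equal(kozak_context_score("AUGGC", 0, pwm), pwm["4", "G"])
  expect_equal(kozak_context_score("AUG", 0, pwm), 0)
})

test_that("oracle MRL reproduces hand-computed expectations", {
  # no candidates: all scanning mass reaches the canonical start
  expect_equal(oracle_mrl(strrep("C", 30)), scanning_params()$mu_main)
  # single out-of-frame non-uORF uAUG with p = 0.9: 0.9*2 + 0.1*6 = 2.4
  p09 <- params_p09()
  expect_equal(oracle_mrl("CACCAUGCACCAACCAACCA", p09), 2.4)
  # single uORF with p = 0.8, r = 0.5: 0.6*6 + 0.4*1 = 4.0
  p08 <- scanning_params(init_slope = 0, init_intercept = qlogis(0.8),
                         reinit_prob = 0.5)
  expect_equal(oracle_mrl("AUGUAACCC", p08), 4.0)
  # in-frame non-uORF uAUG yields mu_main: indistinguishable from none
  s_if <- paste0("CAC", "AUG", strrep("C", 6)) # L = 12, frame 0 at pos 3
  expect_equal(oracle_mrl(s_if, p09), scanning_params()$mu_main)
})

test_that("stronger contexts never raise MRL at an out-of-frame uTIS", {
  base <- "CACCAUGCACCAACCAACCA" # single frame-1 uAUG at 4
  intercepts <- seq(-3, 3, by = 0.5)
  vals <- vapply(intercepts, function(b) {
    oracle_mrl(base, scanning_params(init_slope = 0, init_intercept = b))
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12)) # p increases, MRL never increases
})

test_that("moving an out-of-frame uAUG in-frame raises oracle MRL", {
  params <- scanning_params()
  withr::with_seed(37, {
    n_checked <- 0
    while (n_checked < 30) {
      s <- random_rna(50)
      ann <- scan_annotate(s, params)
      cand <- dplyr::filter(ann, .data$codon == "AUG", .data$frame == 2,
                            !.data$is_uorf)
      if (nrow(cand) == 0) next
      i <- cand$pos[1]
      s2 <- paste0(substr(s, 1, i + 3), "C", substr(s, i + 4, 50))
      ann2 <- scan_annotate(s2, params)
      moved <- dplyr::filter(ann2, .data$pos == i)
      if (nrow(moved) != 1 || moved$frame != 0 || moved$is_uorf) next
      # the insertion also displaces the frames of any other candidate 5' of
      # it; keep only cases where the target is the sole affected candidate
      if (nrow(ann2) != nrow(ann)) next
      others <- ann$pos != i
      key1 <- paste(ann$codon, ann$frame, ann$is_uorf)[others]
      key2 <- paste(ann2$codon, ann2$frame, ann2$is_uorf)[ann2$pos != i]
      if (!identical(key1, key2)) next
      n_checked <- n_checked + 1
      expect_gt(oracle_mrl(s2, params), oracle_mrl(s, params))
    }
  })
})

test_that("simulated noise is centred on the oracle value", {
  n <- 10000
  ds <- simulate_mpra(n, 50, seed = 55)
  mu <- vapply(ds$utr, oracle_mrl, numeric(1), USE.NAMES = FALSE)
  resid <- ds$mrl - mu
  sigma <- scanning_params()$noise_sd
  expect_lt(abs(mean(resid)), 3 * sigma / sqrt(n))
  expect_equal(sd(resid), sigma, tolerance = 0.05)
})

test_that("dataset generation is reproducible and honours its knobs", {
  a <- simulate_mpra(50, 50, seed = 7)
  b <- simulate_mpra(50, 50, seed = 7)
  expect_identical(a, b)
  expect_true(all(nchar(a$utr) == 50))
  v <- simulate_mpra(200, c(25, 100), seed = 8)
  expect_true(all(nchar(v$utr) >= 25 & nchar(v$utr) <= 100))
  expect_gt(dplyr::n_distinct(nchar(v$utr)), 20)
  # noise-free mode: labels equal the oracle exactly
  p0 <- scanning_params(noise_sd = 0)
  nf <- simulate_mpra(10, 50, params = p0, seed = 9)
  expect_equal(nf$mrl,
               vapply(nf$utr, oracle_mrl, numeric(1), params = p0,
                      USE.NAMES = FALSE))
  # library affine rescales the labels
  p2 <- scanning_params(noise_sd = 0,
                        library_affines = list(c(1, 0), c(2, 1)))
  l0 <- simulate_mpra(10, 50, params = p2, library = 0, seed = 10)
  l1 <- simulate_mpra(10, 50, params = p2, library = 1, seed = 10)
  expect_equal(l1$mrl, 2 * l0$mrl + 1)
  expect_error(simulate_mpra(0, 50), "n must be")
})

test_that("polysome-fraction MRL is the abundance-weighted mean", {
  expect_equal(mrl_from_polysome_fractions(c(0, 100, 0), c(0, 1, 2)), 1)
  expect_equal(mrl_from_polysome_fractions(c(10, 10), c(1, 2)), 1.5)
  cnt <- c(5, 20, 30, 10)
  rib <- c(0, 1, 2, 5)
  expect_equal(mrl_from_polysome_fractions(3 * cnt, rib),
               mrl_from_polysome_fractions(cnt, rib))
  expect_error(mrl_from_polysome_fractions(c(0, 0), c(1, 2)), "positive")
  expect_error(mrl_from_polysome_fractions(c(1, 2, 3), c(1, 2)), "mismatch")
})

test_that("the oracle predictor honours simulated frameshifts", {
  orc <- oracle_predictor(params_p09())
  s_oof <- "CACCAUGCACCAACCAACCA" # frame-1 uAUG at position 4
  expect_equal(mrl_predict(orc, s_oof), 2.4)
  # shifting by 2 moves the frame-1 codon to frame 0: MRL returns to mu_main
  expect_equal(mrl_predict(orc, s_oof, shift = 2), 6)
  expect_equal(mrl_predict(orc, s_oof, shift = 1), 2.4)
})
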