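test_that("input gradients match central finite differences", {
  mdl <- build_model(small_config(filters = 8, dense_units = 8), seed = 3)
  s <- random_rna(35, seed = 21)
  g <- gradient_contributions(mdl, s, flavor = "raw_gradient")
  X <- one_hot_encode(s)
  L <- nrow(X)
  eps <- 1e-3
  f_at <- function(Xm) {
    framepoolr:::nn_forward(mdl$params, mdl$config, Xm, L, 1L,
                            matrix(TRUE, L, 1), training = FALSE)$pred
  }
  fd <- matrix(0, L, 4)
  for (i in seq_len(L)) {
    for (j in 1:4) {
      Xp <- X; Xp[i, j] <- Xp[i, j] + eps
      Xm <- X; Xm[i, j] <- Xm[i, j] - eps
      fd[i, j] <- (f_at(Xp) - f_at(Xm)) / (2 * eps)
    }
  }
  expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-3)), 1e-3)
})

test_that("gradient-times-input zeroes silent channels and factorises", {
  mdl <- trained_small()
  s <- random_rna(40, seed = 22)
  raw <- gradient_contributions(mdl, s, flavor = "raw_gradient")
  gxi <- gradient_contributions(mdl, s, flavor = "gradient_x_input")
  X <- one_hot_encode(s)
  expect_equal(unname(unclass(gxi)), unname(raw * X),
               ignore_attr = TRUE)
  expect_true(all(gxi[X == 0] == 0))
  # non-differentiable predictors are refused
  expect_error(gradient_contributions(oracle_predictor(), s),
               "differentiable")
})

test_that("saturation mutagenesis under the oracle is hand-computable", {
  orc <- oracle_predictor(params_p09())
  # no mutation of an A/C-only prefix region can create a start codon
  # unless it completes AUG/CUG/GUG; pick a sequence where only one cell
  # can: CACCA_GCAC... with C->U at position 6 completing nothing, and a
  # designed A?G site at positions 5..7 (1-based)
  s <- "CACCAAGCACCAACCAACCA" # 20 nt, no candidates
  expect_equal(oracle_mrl(s, params_p09()), 6)
  sat <- saturation_mutagenesis(orc, s)
  # position 6 (1-based), A->U completes AUG at 0-based pos 4 (frame 1):
  # oracle drops to 2.4
  cell <- dplyr::filter(sat$scores, .data$position == 6,
                        .data$alt_base == "U")
  expect_equal(cell$log2fc, log2(2.4 / 6))
  # every score is reference-base-free: 3 alternatives per position
  expect_equal(nrow(sat$scores), 3 * nchar(s))
  expect_false(any(sat$scores$alt_base == sat$scores$ref_base))
  # per-position profile is the mean of the 3 absolute cell values
  p6 <- dplyr::filter(sat$scores, .data$position == 6)
  expect_equal(sat$profile$mean_abs_log2fc[6], mean(abs(p6$log2fc)))
  expect_s3_class(autoplot(sat), "ggplot")
})

test_that("a fully silent sequence has an all-zero saturation map", {
  # under the oracle, mutations matter only via start codons; a sequence
  # kept free of near-candidates scores zero everywhere
  orc <- oracle_predictor()
  s <- strrep("CA", 8)
  sat <- saturation_mutagenesis(orc, s)
  # single-base changes in a CACA... background can still complete CUG/AUG
  # at some cells; restrict the claim to cells the oracle leaves silent
  silent <- dplyr::filter(sat$scores, abs(.data$log2fc) < 1e-12)
  expect_gt(nrow(silent), 0)
  changed <- dplyr::filter(sat$scores, abs(.data$log2fc) > 0)
  for (i in seq_len(nrow(changed))) {
    mut <- s
    substr(mut, changed$position[i], changed$position[i]) <- changed$alt_base[i]
    expect_gt(nrow(scan_annotate(mut)), 0) # every hit created a candidate
  }
})

test_that("bootstrap comparison separates, symmetrises and reproduces", {
  withr::with_seed(77, {
    obs <- rnorm(200)
    noise <- rnorm(200, sd = 0.4)
  })
  pred_a <- obs
  pred_b <- withr::with_seed(78, sample(obs)) # destroys the association
  res <- bootstrap_compare(pred_a, pred_b, obs, n_boot = 100, seed = 5)
  expect_true(res$significant)
  expect_gt(res$mean_diff, 0)
  # identity comparison: all replicate differences are exactly zero
  same <- bootstrap_compare(pred_a, pred_a, obs, n_boot = 50, seed = 5)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$sd_diff, 0)
  expect_false(same$significant)
  # swapping the models negates the difference, significance unchanged
  swap <- bootstrap_compare(pred_b, pred_a, obs, n_boot = 100, seed = 5)
  expect_equal(swap$mean_diff, -res$mean_diff)
  expect_equal(swap$significant, res$significant)
  # seeded reproducibility of the bootstrap SD
  again <- bootstrap_compare(pred_a, pred_b, obs, n_boot = 100, seed = 5)
  expect_identical(again$sd_diff, res$sd_diff)
  expect_error(bootstrap_compare(rep(1, 20), pred_b[1:20], obs[1:20]),
               "constant")
  expect_error(bootstrap_compare(obs[1:5], obs[1:5], obs[1:5]), "at least 10")
})

test_that("translation efficiency applies the read-count filters", {
  te <- translation_efficiency(c(20, 9, 15), c(10, 100, 0), min_rpf = 10)
  expect_equal(te$te[1], 2)
  expect_true(te$excluded[2]) # below the RPF floor
  expect_true(te$excluded[3]) # no RNA coverage: excluded, not infinite
  expect_true(is.na(te$te[3]))
  expect_error(translation_efficiency(1:3, 1:2), "mismatch")
})

test_that("expression preprocessing filters then averages, or takes medians", {
  reps <- rbind(c(0.5, 2.0), c(3, 5), c(1, 1))
  out <- preprocess_expression(reps, tpm_min = 1, mode = "tripseq")
  expect_true(is.na(out[1])) # one replicate below 1 TPM
  expect_equal(out[2], 4)
  expect_equal(out[3], 1)
  ptr <- preprocess_expression(rbind(c(2, 4, 100), c(NA, 7, 9), c(NA, NA, NA)),
                               mode = "ptr")
  expect_equal(ptr[1], 4)
  expect_equal(ptr[2], 8)
  expect_true(is.na(ptr[3]))
})
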