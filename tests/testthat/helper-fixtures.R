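# Shared, memoized fixtures. Expensive objects (simulated datasets, trained
# models) are built once per test run and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# leaky-scanning parameters with a context-independent initiation
# probability of exactly 0.9 for AUG (hand-computable oracle values)
params_p09 <- function() {
  scanning_params(init_slope = 0, init_intercept = qlogis(0.9))
}

small_config <- function(pooling = "frame", filters = 16, dense_units = 8,
                         n_layers = 3, n_libraries = 0) {
  model_config(
    replicate(n_layers, list(filters = filters, kernel = 7, dilation = 1),
              simplify = FALSE),
    pooling = pooling, dense_units = dense_units, n_libraries = n_libraries)
}

random_rna <- function(L, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

toy_fixture_dir <- function() {
  memo("toy_fixtures", {
    dir <- file.path(tempdir(), "framepoolr-fixtures")
    write_toy_fixtures(dir)
  })
}

# study-condition simulator data (fixed 50 nt, sigma = 0.3)
sim_train_20k <- function() memo("sim_train_20k", simulate_mpra(20000, 50, seed = 701))
sim_test_2k <- function() memo("sim_test_2k", simulate_mpra(2000, 50, seed = 702))

# full frame-pooling preset trained at study conditions (shared between the
# simulator-recovery check and the frame-sensitivity property)
trained_framepool <- function() {
  memo("trained_framepool", {
    train_mrl(sim_train_20k(), build_model("framepool", seed = 42),
              max_epochs = 3, patience = NULL, val_count = 2000, seed = 42)
  })
}

trained_globalpool <- function() {
  memo("trained_globalpool", {
    train_mrl(sim_train_20k(), build_model("global_pool", seed = 42),
              max_epochs = 3, patience = NULL, val_count = 2000, seed = 42)
  })
}

# small trained model for gradient and interpretation checks
trained_small <- function() {
  memo("trained_small", {
    ds <- simulate_mpra(1500, 50, seed = 31)
    train_mrl(ds, build_model(small_config(filters = 8, dense_units = 8),
                              seed = 7),
              max_epochs = 2, patience = NULL, val_count = 0, seed = 7)
  })
}
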