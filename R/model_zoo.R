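#' Declarative model architecture configuration
#'
#' Describes a convolutional MRL-prediction architecture: a stack of
#' same-length 1-d convolutions (ReLU, optional identity residual additions
#' wherever input and output channel counts match), frame or global
#' max+average pooling, one ReLU dense layer with dropout on its outputs, a
#' final linear scalar layer, and (optionally) a per-library affine scaling
#' of the scalar output for multi-library training.
#'
#' @param conv_layers list of `list(filters, kernel, dilation)` per layer;
#'   kernels must be odd so that same-padding preserves length.
#' @param residual use identity residual additions between layers whose
#'   channel counts match?
#' @param pooling `"frame"` (pooled width `6 * filters`) or `"global"`
#'   (pooled width `2 * filters`).
#' @param dense_units units in the dense layer.
#' @param dropout_rate dropout rate on the dense layer outputs, in `[0, 1)`;
#'   active only during training.
#' @param n_libraries number of libraries for output scaling (0 = none).
#' @return a `model_config` object.
#' @export
model_config <- function(conv_layers, residual = TRUE, pooling = c("frame", "global"),
                         dense_units = 64, dropout_rate = 0.2, n_libraries = 0) {
  pooling <- match.arg(pooling)
  conv_layers <- lapply(conv_layers, function(cl) {
    cl <- as.list(cl)
    stopifnot(all(c("filters", "kernel", "dilation") %in% names(cl)))
    if (cl$kernel %% 2 == 0) abort("kernel size must be odd")
    cl
  })
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate must be in [0, 1)")
  structure(list(conv_layers = conv_layers, residual = residual,
                 pooling = pooling, dense_units = dense_units,
                 dropout_rate = dropout_rate,
                 n_libraries = as.integer(n_libraries)),
            class = "model_config")
}

#' Named architecture presets
#'
#' * `framepool`: 3 conv layers (128 filters, kernel 7, undilated), frame
#'   pooling, dense 64, dropout 0.2 — the main architecture (282,625
#'   learnable weights).
#' * `framepool_combined`: as `framepool` plus a 2-library output scaling
#'   layer (4 additional weights).
#' * `global_pool`: as `framepool` but conventional global max+average
#'   pooling (no frame information).
#' * `dilated`: as `global_pool` with dilations (1, 2, 4); receptive field 43.
#' * `more_dilated`: adds a fourth conv layer with dilation 8.
#'
#' @param name preset name.
#' @param filters,dense_units optional overrides for reduced-size variants
#'   of the same topology (used e.g. in quick experiments); defaults are the
#'   full-size presets.
#' @return a [model_config()].
#' @export
preset_config <- function(name = c("framepool", "framepool_combined",
                                   "global_pool", "dilated", "more_dilated"),
                          filters = 128, dense_units = 64) {
  name <- match.arg(name)
  layer <- function(d) list(filters = filters, kernel = 7, dilation = d)
  switch(name,
    framepool = model_config(list(layer(1), layer(1), layer(1)),
                             pooling = "frame", dense_units = dense_units),
    framepool_combined = model_config(list(layer(1), layer(1), layer(1)),
                                      pooling = "frame",
                                      dense_units = dense_units,
                                      n_libraries = 2),
    global_pool = model_config(list(layer(1), layer(1), layer(1)),
                               pooling = "global", dense_units = dense_units),
    dilated = model_config(list(layer(1), layer(2), layer(4)),
                           pooling = "global", dense_units = dense_units),
    more_dilated = model_config(list(layer(1), layer(2), layer(4), layer(8)),
                                pooling = "global", dense_units = dense_units)
  )
}

#' Count learnable parameters of an architecture
#'
#' Closed-form summation per layer: each conv layer contributes
#' `in_ch * kernel * filters + filters`, the dense layer
#' `pooled_width * dense_units + dense_units`, the output layer
#' `dense_units + 1`, and library scaling `2 * n_libraries`.
#' Identity residual additions contribute nothing.
#'
#' @param config a [model_config()] or a built model.
#' @return integer parameter count.
#' @export
#' @examples
#' count_parameters(preset_config("framepool")) # 282625
count_parameters <- function(config) {
  if (inherits(config, "mrl_model")) config <- config$config
  stopifnot(inherits(config, "model_config"))
  n <- 0L
  c_in <- 4L
  for (cl in config$conv_layers) {
    n <- n + c_in * cl$kernel * cl$filters + cl$filters
    c_in <- cl$filters
  }
  n <- n + pooled_width(config) * config$dense_units + config$dense_units
  n <- n + config$dense_units + 1L
  n + 2L * config$n_libraries
}

#' Receptive field of the final convolutional layer
#'
#' `1 + sum over layers of (kernel - 1) * dilation`: the longest stretch of
#' input positions that can influence a single activation in the last conv
#' layer, and hence the longest upstream ORF the architecture can detect as
#' a unit.
#'
#' @inheritParams count_parameters
#' @return integer receptive field in nucleotides.
#' @export
#' @examples
#' receptive_field(preset_config("framepool")) # 19
#' receptive_field(preset_config("dilated"))   # 43
receptive_field <- function(config) {
  if (inherits(config, "mrl_model")) config <- config$config
  stopifnot(inherits(config, "model_config"))
  as.integer(1L + sum(vapply(config$conv_layers,
                             function(cl) (cl$kernel - 1L) * cl$dilation,
                             numeric(1))))
}

#' Build an (untrained) MRL predictor
#'
#' Instantiates the architecture with Glorot-uniform weight initialisation
#' (zero biases; library scales initialised to 1 and biases to 0) from an
#' explicit seed.
#'
#' @param config a [model_config()] or preset name string.
#' @param seed integer RNG seed for initialisation.
#' @param libraries character vector of library labels (required iff
#'   `n_libraries > 0`).
#' @return an object of class `mrl_model`.
#' @export
build_model <- function(config, seed = 1L, libraries = NULL) {
  if (is.character(config)) config <- preset_config(config)
  stopifnot(inherits(config, "model_config"))
  if (config$n_libraries > 0) {
    if (is.null(libraries)) libraries <- as.character(seq_len(config$n_libraries) - 1L)
    if (length(libraries) != config$n_libraries) {
      abort("length(libraries) must equal n_libraries")
    }
  }
  params <- with_local_seed(seed, nn_init_params(config))
  structure(list(config = config, params = params, libraries = libraries,
                 trained = FALSE, history = NULL, seed = seed),
            class = "mrl_model")
}

#' @export
print.mrl_model <- function(x, ...) {
  cat(sprintf(
    "<mrl_model> %s pooling, %d conv layer(s), %s parameters, receptive field %d nt%s\n",
    x$config$pooling, length(x$config$conv_layers),
    format(count_parameters(x), big.mark = ","), receptive_field(x),
    if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

lib_index <- function(model, library, n) {
  if (model$config$n_libraries == 0) return(NULL)
  if (is.null(library)) abort("this model requires a library label")
  library <- as.character(library)
  if (length(library) == 1) library <- rep(library, n)
  idx <- match(library, model$libraries)
  if (anyNA(idx)) {
    abort(sprintf("unknown library label '%s'",
                  library[which(is.na(idx))[1]]))
  }
  idx
}

# Low-level batched forward pass over sequences; shift appends `shift`
# masked all-zero positions at the 3' end of every sequence, displacing all
# real positions' reading frames by `shift` (the simulated-frameshift trick).
predict_batch <- function(model, seqs, library = NULL, shift = 0L) {
  if (any(nchar(seqs) < 3)) abort("sequences must be at least 3 nt")
  batch <- pad_batch(seqs)
  L <- batch$lmax
  B <- batch$b
  X <- batch$x
  mask <- batch$mask
  if (shift > 0) {
    L2 <- L + shift
    X2 <- matrix(0, L2 * B, 4)
    mask2 <- matrix(FALSE, L2, B)
    keep <- as.vector(outer(seq_len(L), (0:(B - 1)) * L2, "+"))
    X2[keep, ] <- X
    mask2[seq_len(L), ] <- mask
    X <- X2; mask <- mask2; L <- L2
  }
  idx <- lib_index(model, library, B)
  nn_forward(model$params, model$config, X, L, B, mask,
             lib_idx = idx, training = FALSE)$pred
}

#' Predict mean ribosome load for a table of sequences
#'
#' @param data a data frame with a `utr` column and, for library-scaled
#'   models, a `library` column.
#' @param model a trained (or initialised) `mrl_model`, or an
#'   [oracle_predictor()].
#' @param batch_size sequences per padded batch.
#' @param shift simulate a reading-frame shift of this many positions
#'   (0, 1 or 2) by appending masked zero positions at the 3' end.
#' @return the input tibble with an added `mrl_pred` column.
#' @export
predict_mrl <- function(data, model, batch_size = 128L, shift = 0L) {
  data <- as_tibble(data)
  if (!"utr" %in% names(data)) abort("data must have a 'utr' column")
  seqs <- clean_utr(data$utr)
  lib <- if ("library" %in% names(data)) as.character(data$library) else NULL
  n <- length(seqs)
  preds <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    i <- s:min(s + batch_size - 1L, n)
    preds[i] <- mrl_predict(model, seqs[i],
                            library = if (is.null(lib)) NULL else lib[i],
                            shift = shift)
  }
  data$mrl_pred <- preds
  data
}

#' Predictor interface
#'
#' Generic shared by trained models and the leaky-scanning simulator oracle:
#' maps sequences (plus optional library label and simulated frameshift) to
#' MRL predictions. Scoring pipelines ([score_variants()],
#' [predicted_tis_effect()], [saturation_mutagenesis()]) accept anything
#' implementing this generic.
#'
#' @param predictor an `mrl_model` or `mrl_oracle`.
#' @param seqs character vector of sequences.
#' @param library optional library label(s).
#' @param shift simulated frameshift (non-negative integer).
#' @return numeric vector of MRL predictions.
#' @export
mrl_predict <- function(predictor, seqs, library = NULL, shift = 0L) {
  UseMethod("mrl_predict")
}

#' @export
mrl_predict.mrl_model <- function(predictor, seqs, library = NULL, shift = 0L) {
  predict_batch(predictor, seqs, library = library, shift = shift)
}

#' @export
mrl_predict.function <- function(predictor, seqs, library = NULL, shift = 0L) {
  predictor(seqs, library = library, shift = shift)
}

#' Save / load a model archive
#'
#' The archive is a single JSON file holding the configuration, library
#' labels and all weights (flattened, with dimensions), so models round-trip
#' across sessions without binary formats.
#'
#' @param model an `mrl_model`.
#' @param path file path (`.json`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mrl_model"))
  obj <- list(
    config = unclass(model$config),
    libraries = model$libraries,
    trained = model$trained,
    seed = model$seed,
    params = lapply(model$params, function(p) {
      list(dim = dim(p) %||% length(p), values = as.numeric(p))
    })
  )
  # I(17) significant digits: doubles round-trip bit-exactly through JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- model_config(
    conv_layers = lapply(seq_len(nrow(obj$config$conv_layers)), function(i) {
      as.list(obj$config$conv_layers[i, ])
    }),
    residual = obj$config$residual, pooling = obj$config$pooling,
    dense_units = obj$config$dense_units,
    dropout_rate = obj$config$dropout_rate,
    n_libraries = obj$config$n_libraries
  )
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) > 1) array(p$values, dim = p$dim) else p$values
  })
  structure(list(config = cfg, params = params,
                 libraries = obj$libraries, trained = obj$trained,
                 history = NULL, seed = obj$seed),
            class = "mrl_model")
}
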