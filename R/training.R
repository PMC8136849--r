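#' Split off a validation set
#'
#' Seeded random disjoint split into training and validation subsets.
#'
#' @param data tibble with one row per sequence.
#' @param val_count number of validation rows (must be < `nrow(data)`;
#'   0 returns all data as training with an empty validation set).
#' @param seed RNG seed.
#' @return list with tibbles `train` and `val`.
#' @export
split_validation <- function(data, val_count, seed = 1L) {
  data <- as_tibble(data)
  n <- nrow(data)
  if (val_count >= n) abort("val_count must be smaller than the dataset")
  if (val_count == 0) return(list(train = data, val = data[0, ]))
  idx <- with_local_seed(seed, sample.int(n, val_count))
  list(train = data[-idx, ], val = data[idx, ])
}

# Early-stopping bookkeeping: given the validation losses so far and the
# patience, report the best epoch and whether training should stop
# ("improvement" = strictly lower validation loss).
early_stop_state <- function(val_losses, patience) {
  best <- which.min(val_losses)
  list(best_epoch = best,
       stop = !is.null(patience) &&
         (length(val_losses) - best) >= patience)
}

mse_loss <- function(pred, y) mean((pred - y)^2)

encode_all <- function(seqs) lapply(seqs, one_hot_encode)

assemble_batch <- function(mats, lens) {
  lmax <- max(lens)
  b <- length(mats)
  x <- matrix(0, lmax * b, 4)
  mask <- matrix(FALSE, lmax, b)
  for (i in seq_len(b)) {
    rows <- (lmax - lens[i] + 1):lmax
    x[rows + (i - 1L) * lmax, ] <- mats[[i]]
    mask[rows, i] <- TRUE
  }
  list(x = x, lmax = lmax, b = b, mask = mask)
}

predict_encoded <- function(model, mats, lens, lib_idx = NULL,
                            batch_size = 128L) {
  n <- length(mats)
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    i <- s:min(s + batch_size - 1L, n)
    bt <- assemble_batch(mats[i], lens[i])
    out[i] <- nn_forward(model$params, model$config, bt$x, bt$lmax, bt$b,
                         bt$mask, lib_idx = lib_idx[i],
                         training = FALSE)$pred
  }
  out
}

#' Train an MRL predictor
#'
#' Mini-batch training with the Adam optimizer (default parameters) and
#' mean-squared-error loss. Batches are padded at the 5' end to the longest
#' sequence in the batch. With `patience` set, training stops once the
#' validation loss has not improved for that many consecutive epochs and
#' the weights with the lowest validation loss are returned; with
#' `patience = NULL` training runs for exactly `max_epochs` and the final
#' weights are returned.
#'
#' @param data tibble with columns `utr`, `mrl` and, for library-scaled
#'   models, `library`.
#' @param model an `mrl_model` from [build_model()] (untrained or warm).
#' @param max_epochs upper bound on epochs.
#' @param patience early-stopping patience in epochs, or `NULL` for
#'   fixed-epoch training.
#' @param val_count validation rows split off from `data` (ignored when
#'   `val_data` is given); may be 0 only with `patience = NULL`.
#' @param val_data optional explicit validation tibble.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param seed RNG seed controlling the validation split, shuffling,
#'   and dropout.
#' @param bucket_by_length sort each shuffled epoch into length-homogeneous
#'   batches (an efficiency toggle for variable-length data; the model
#'   contract makes results padding-invariant, so this only reduces padded
#'   positions).
#' @param verbose print per-epoch losses.
#' @return the trained `mrl_model`, with a `history` tibble
#'   (`epoch`, `train_loss`, `val_loss`) attached.
#' @export
train_mrl <- function(data, model, max_epochs = 20L, patience = 3L,
                      val_count = 2000L, val_data = NULL, batch_size = 128L,
                      lr = 0.001, seed = 1L, bucket_by_length = FALSE,
                      verbose = FALSE) {
  data <- as_tibble(data)
  stopifnot(all(c("utr", "mrl") %in% names(data)), all(is.finite(data$mrl)))
  if (is.null(val_data)) {
    if (val_count == 0 && !is.null(patience)) {
      abort("early stopping requires a validation set")
    }
    sp <- split_validation(data, val_count, seed = seed)
    train <- sp$train
    val <- sp$val
  } else {
    train <- data
    val <- as_tibble(val_data)
  }
  train$utr <- clean_utr(train$utr)
  mats <- encode_all(train$utr)
  lens <- nchar(train$utr)
  y <- train$mrl
  lib_idx <- lib_index(model, if ("library" %in% names(train)) train$library
                       else NULL, nrow(train))
  have_val <- nrow(val) > 0
  if (have_val) {
    val$utr <- clean_utr(val$utr)
    vmats <- encode_all(val$utr)
    vlens <- nchar(val$utr)
    vlib <- lib_index(model, if ("library" %in% names(val)) val$library
                      else NULL, nrow(val))
  }
  n <- nrow(train)
  state <- adam_init(model$params)
  params <- model$params
  history <- tibble(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  best_params <- params
  val_losses <- numeric(0)
  with_local_seed(seed + 1L, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      if (bucket_by_length) {
        # stable sort by length inside the shuffled order: batches become
        # near-homogeneous in length while epoch composition stays random
        ord <- ord[order(lens[ord])]
      }
      batch_losses <- numeric(0)
      for (s in seq(1L, n, by = batch_size)) {
        i <- ord[s:min(s + batch_size - 1L, n)]
        bt <- assemble_batch(mats[i], lens[i])
        fw <- nn_forward(params, model$config, bt$x, bt$lmax, bt$b, bt$mask,
                         lib_idx = lib_idx[i], training = TRUE)
        loss <- mse_loss(fw$pred, y[i])
        if (!is.finite(loss)) {
          abort(sprintf("non-finite loss at epoch %d (batch starting %d)",
                        epoch, s))
        }
        batch_losses <- c(batch_losses, loss)
        dpred <- 2 * (fw$pred - y[i]) / bt$b
        grads <- nn_backward(params, model$config, fw, bt$x, bt$lmax, bt$b,
                             bt$mask, lib_idx = lib_idx[i], dpred = dpred)
        up <- adam_step(params, grads, state, lr = lr)
        params <- up$params
        state <- up$state
      }
      vloss <- NA_real_
      if (have_val) {
        model_now <- model
        model_now$params <- params
        vpred <- predict_encoded(model_now, vmats, vlens, vlib)
        vloss <- mse_loss(vpred, val$mrl)
      }
      history <- dplyr::add_row(history, epoch = epoch,
                                train_loss = mean(batch_losses),
                                val_loss = vloss)
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %s", epoch,
                        mean(batch_losses),
                        ifelse(is.na(vloss), "-", sprintf("%.4f", vloss))))
      }
      if (have_val && !is.null(patience)) {
        val_losses <- c(val_losses, vloss)
        es <- early_stop_state(val_losses, patience)
        if (es$best_epoch == epoch) best_params <- params
        if (es$stop) break
      }
    }
  })
  model$params <- if (have_val && !is.null(patience)) best_params else params
  model$trained <- TRUE
  model$history <- history
  model
}

#' Train a two-library combined model
#'
#' Concatenates two datasets (tagging them with library labels `"0"` and
#' `"1"` if absent), shuffles across both libraries within each epoch, and
#' trains a model with a per-library affine scaling on the scalar output so
#' that one shared trunk serves both measurement scales.
#'
#' @param data_a,data_b tibbles with `utr` and `mrl` columns.
#' @param model an `mrl_model` with `n_libraries = 2`.
#' @param ... passed to [train_mrl()].
#' @return trained `mrl_model`.
#' @export
train_combined <- function(data_a, data_b, model, ...) {
  if (model$config$n_libraries != 2) {
    abort("train_combined() needs a model with n_libraries = 2")
  }
  data_a <- as_tibble(data_a)
  data_b <- as_tibble(data_b)
  if (!"library" %in% names(data_a)) data_a$library <- model$libraries[1]
  if (!"library" %in% names(data_b)) data_b$library <- model$libraries[2]
  train_mrl(dplyr::bind_rows(data_a, data_b), model, ...)
}

#' Save a training run directory
#'
#' Writes a reproducibility snapshot: `config.json` (architecture +
#' training metadata), `history.csv` (per-epoch losses) and
#' `weights.json` (the model archive, via [save_model()]).
#'
#' @param model a trained `mrl_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_training_run <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(config = unclass(model$config), seed = model$seed,
         libraries = model$libraries,
         n_parameters = count_parameters(model),
         receptive_field = receptive_field(model)),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(model$history)) {
    readr::write_csv(model$history, file.path(dir, "history.csv"))
  }
  save_model(model, file.path(dir, "weights.json"))
  invisible(dir)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted MRL model
#'
#' One row per parameter tensor with its shape and size.
#' @param x an `mrl_model`.
#' @param ... unused.
#' @return a tibble with columns `tensor`, `shape`, `n`.
#' @method tidy mrl_model
#' @export
tidy.mrl_model <- function(x, ...) {
  tibble(
    tensor = names(x$params),
    shape = vapply(x$params, function(p) {
      paste(dim(p) %||% length(p), collapse = "x")
    }, character(1)),
    n = vapply(x$params, length, integer(1))
  )
}

#' Glance at a fitted MRL model
#'
#' @param x an `mrl_model`.
#' @param ... unused.
#' @return one-row tibble: pooling type, layer count, parameter count,
#'   receptive field, epochs run and best validation loss (NA if untrained).
#' @method glance mrl_model
#' @export
glance.mrl_model <- function(x, ...) {
  tibble(
    pooling = x$config$pooling,
    n_conv_layers = length(x$config$conv_layers),
    n_parameters = count_parameters(x),
    receptive_field = receptive_field(x),
    trained = x$trained,
    epochs = if (is.null(x$history)) NA_integer_ else nrow(x$history),
    best_val_loss = if (is.null(x$history) || all(is.na(x$history$val_loss)))
      NA_real_ else min(x$history$val_loss, na.rm = TRUE)
  )
}

#' Plot the training history of a fitted model
#'
#' @param object an `mrl_model` with a training history.
#' @param ... unused.
#' @return a ggplot object with per-epoch train/validation loss curves.
#' @method autoplot mrl_model
#' @export
autoplot.mrl_model <- function(object, ...) {
  if (is.null(object$history)) abort("model has no training history")
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "mean squared error", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
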