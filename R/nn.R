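# Internal neural-network engine.
#
# Batches are laid out as (Lmax*B) x C matrices with position-fastest row
# order (row = p + (b-1)*Lmax, p in 1..Lmax), 3' ends aligned at p = Lmax.
# Convolutions are computed as sums over kernel taps, each tap a single
# BLAS GEMM over shifted row ranges; this keeps everything in double
# precision with exact zero contributions from padded rows, which is what
# makes predictions bitwise-invariant to the amount of 5' padding.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

glorot_uniform <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -limit, limit), dim = dims)
}

nn_init_params <- function(config) {
  params <- list()
  c_in <- 4L
  for (i in seq_along(config$conv_layers)) {
    cl <- config$conv_layers[[i]]
    k <- cl$kernel
    f <- cl$filters
    params[[paste0("conv", i, "_W")]] <-
      glorot_uniform(k * c_in, k * f, c(k, c_in, f))
    params[[paste0("conv", i, "_b")]] <- numeric(f)
    c_in <- f
  }
  pw <- pooled_width(config)
  params$dense_W <- glorot_uniform(pw, config$dense_units,
                                   c(pw, config$dense_units))
  params$dense_b <- numeric(config$dense_units)
  params$out_W <- glorot_uniform(config$dense_units, 1,
                                 c(config$dense_units, 1))
  params$out_b <- 0
  if (config$n_libraries > 0) {
    params$lib_scale <- rep(1, config$n_libraries)
    params$lib_bias <- rep(0, config$n_libraries)
  }
  params
}

pooled_width <- function(config) {
  f_last <- config$conv_layers[[length(config$conv_layers)]]$filters
  if (config$pooling == "frame") 6L * f_last else 2L * f_last
}

tap_ranges <- function(L, B, k, dilation) {
  center <- (k + 1L) %/% 2L
  lapply(seq_len(k), function(o) {
    s <- (o - center) * dilation
    p_t <- seq.int(max(1L, 1L - s), min(L, L - s))
    if (length(p_t) == 0L || p_t[1] > p_t[length(p_t)]) return(NULL)
    offs <- rep((0:(B - 1L)) * L, each = length(p_t))
    list(tgt = rep(p_t, B) + offs, src = rep(p_t + s, B) + offs)
  })
}

# im2col layout: column block o holds the input shifted by tap o, so the
# whole convolution is one GEMM against the (k*c_in) x f weight matrix
conv_im2col <- function(X, taps, k, c_in, n_rows) {
  Xcol <- matrix(0, n_rows, k * c_in)
  for (o in seq_len(k)) {
    tp <- taps[[o]]
    if (is.null(tp)) next
    Xcol[tp$tgt, (o - 1L) * c_in + seq_len(c_in)] <- X[tp$src, , drop = FALSE]
  }
  Xcol
}

conv_weight_mat <- function(W) {
  d <- dim(W) # (k, c_in, f)
  matrix(aperm(W, c(2, 1, 3)), d[1] * d[2], d[3])
}

conv_tap_forward <- function(Xcol, Wmat, bias, n_rows) {
  Xcol %*% Wmat + rep(bias, each = n_rows)
}

conv_tap_backward <- function(dZ, Xcol, Wmat, taps, k, c_in, n_rows_x) {
  dXcol <- dZ %*% t(Wmat)
  dX <- matrix(0, n_rows_x, c_in)
  for (o in seq_len(k)) {
    tp <- taps[[o]]
    if (is.null(tp)) next
    cols <- (o - 1L) * c_in + seq_len(c_in)
    dX[tp$src, ] <- dX[tp$src, , drop = FALSE] +
      dXcol[tp$tgt, cols, drop = FALSE]
  }
  dWmat <- crossprod(Xcol, dZ)
  dW <- aperm(array(dWmat, c(c_in, k, ncol(dZ))), c(2, 1, 3))
  list(dX = dX, dW = dW, db = colSums(dZ))
}

# positions (1-based, padded coords) belonging to each frame slice;
# slice j = (Lmax - p) %% 3, identical for every sequence in a 3'-aligned batch
frame_positions <- function(L) {
  lapply(0:2, function(j) which((L - seq_len(L)) %% 3 == j))
}

pool_forward <- function(H, L, B, mask, pooling) {
  groups <- if (pooling == "frame") frame_positions(L) else list(seq_len(L))
  blocks_max <- list()
  blocks_avg <- list()
  cache <- list()
  f <- ncol(H)
  for (g in seq_along(groups)) {
    pos <- groups[[g]]
    m <- length(pos)
    maskg <- mask[pos, , drop = FALSE]
    counts <- colSums(maskg)
    mx <- matrix(-Inf, B, f)
    idxT <- matrix(0L, B, f)
    sums <- matrix(0, B, f)
    for (t in seq_len(m)) {
      rows <- pos[t] + (0:(B - 1L)) * L
      Ht <- H[rows, , drop = FALSE]
      Ht_inf <- Ht
      if (!all(maskg[t, ])) Ht_inf[!maskg[t, ], ] <- -Inf
      better <- Ht_inf > mx
      if (any(better)) {
        mx[better] <- Ht_inf[better]
        idxT[better] <- t
      }
      sums <- sums + Ht * maskg[t, ]
    }
    avg <- sums / pmax(counts, 1L)
    empty <- counts == 0L
    if (any(empty)) {
      mx[empty, ] <- 0
      avg[empty, ] <- 0
    }
    blocks_max[[g]] <- mx
    blocks_avg[[g]] <- avg
    cache[[g]] <- list(pos = pos, maskg = maskg, counts = counts, idxT = idxT)
  }
  P <- do.call(cbind, c(blocks_max, blocks_avg))
  list(P = P, cache = cache, f = f, n_groups = length(groups))
}

pool_backward <- function(dP, pf, L, B) {
  f <- pf$f
  ng <- pf$n_groups
  dH <- matrix(0, L * B, f)
  for (g in seq_len(ng)) {
    cc <- pf$cache[[g]]
    dMx <- dP[, (g - 1L) * f + seq_len(f), drop = FALSE]
    dAvg <- dP[, (ng + g - 1L) * f + seq_len(f), drop = FALSE]
    wA <- dAvg / pmax(cc$counts, 1L)
    wA[cc$counts == 0L, ] <- 0
    for (t in seq_along(cc$pos)) {
      rows <- cc$pos[t] + (0:(B - 1L)) * L
      sel <- cc$idxT == t
      add <- wA * cc$maskg[t, ]
      if (any(sel)) add[sel] <- add[sel] + dMx[sel]
      dH[rows, ] <- dH[rows, , drop = FALSE] + add
    }
  }
  dH
}

nn_forward <- function(params, config, X, L, B, mask, lib_idx = NULL,
                       training = FALSE, drop_mask = NULL) {
  invalid <- which(!as.vector(mask))
  cache <- list(conv = list(), invalid = invalid)
  H <- X
  c_in <- 4L
  for (i in seq_along(config$conv_layers)) {
    cl <- config$conv_layers[[i]]
    W <- params[[paste0("conv", i, "_W")]]
    taps <- tap_ranges(L, B, cl$kernel, cl$dilation)
    Xcol <- conv_im2col(H, taps, cl$kernel, c_in, L * B)
    Wmat <- conv_weight_mat(W)
    Z <- conv_tap_forward(Xcol, Wmat, params[[paste0("conv", i, "_b")]], L * B)
    A <- Z
    A[A < 0] <- 0
    if (length(invalid)) A[invalid, ] <- 0
    out <- if (config$residual && c_in == cl$filters) A + H else A
    cache$conv[[i]] <- list(Xcol = Xcol, Wmat = Wmat, Z = Z, taps = taps,
                            c_in = c_in,
                            res = config$residual && c_in == cl$filters)
    H <- out
    c_in <- cl$filters
  }
  pf <- pool_forward(H, L, B, mask, config$pooling)
  D_z <- pf$P %*% params$dense_W + rep(params$dense_b, each = B)
  D <- D_z
  D[D < 0] <- 0
  if (training && config$dropout_rate > 0) {
    if (is.null(drop_mask)) {
      drop_mask <- matrix(
        rbinom(B * config$dense_units, 1, 1 - config$dropout_rate),
        B, config$dense_units) / (1 - config$dropout_rate)
    }
    Dd <- D * drop_mask
  } else {
    drop_mask <- NULL
    Dd <- D
  }
  z <- drop(Dd %*% params$out_W) + params$out_b
  if (config$n_libraries > 0) {
    if (is.null(lib_idx)) abort("library index required for a scaled model")
    pred <- params$lib_scale[lib_idx] * z + params$lib_bias[lib_idx]
  } else {
    pred <- z
  }
  cache$pf <- pf
  cache$D_z <- D_z
  cache$D <- D
  cache$Dd <- Dd
  cache$drop_mask <- drop_mask
  cache$z <- z
  cache$H_last <- H
  list(pred = pred, cache = cache)
}

# Backward pass from d(pred); returns parameter gradients and optionally the
# gradient with respect to the one-hot input.
nn_backward <- function(params, config, fw, X, L, B, mask, lib_idx = NULL,
                        dpred, want_input_grad = FALSE) {
  cc <- fw$cache
  grads <- list()
  if (config$n_libraries > 0) {
    grads$lib_scale <- vapply(seq_len(config$n_libraries), function(l) {
      sum(dpred[lib_idx == l] * cc$z[lib_idx == l])
    }, numeric(1))
    grads$lib_bias <- vapply(seq_len(config$n_libraries), function(l) {
      sum(dpred[lib_idx == l])
    }, numeric(1))
    dz <- dpred * params$lib_scale[lib_idx]
  } else {
    dz <- dpred
  }
  grads$out_W <- crossprod(cc$Dd, matrix(dz, ncol = 1))
  grads$out_b <- sum(dz)
  dDd <- matrix(dz, ncol = 1) %*% t(params$out_W)
  dD <- if (!is.null(cc$drop_mask)) dDd * cc$drop_mask else dDd
  dDz <- dD * (cc$D_z > 0)
  grads$dense_W <- crossprod(cc$pf$P, dDz)
  grads$dense_b <- colSums(dDz)
  dP <- dDz %*% t(params$dense_W)
  dH <- pool_backward(dP, cc$pf, L, B)
  for (i in rev(seq_along(config$conv_layers))) {
    lc <- cc$conv[[i]]
    cl <- config$conv_layers[[i]]
    dA <- dH
    dZ <- dA * (lc$Z > 0)
    if (length(cc$invalid)) dZ[cc$invalid, ] <- 0
    bk <- conv_tap_backward(dZ, lc$Xcol, lc$Wmat, lc$taps, cl$kernel,
                            lc$c_in, L * B)
    grads[[paste0("conv", i, "_W")]] <- bk$dW
    grads[[paste0("conv", i, "_b")]] <- bk$db
    dH <- if (lc$res) bk$dX + dA else bk$dX
  }
  if (want_input_grad) grads$input <- dH
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.001, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * as.numeric(g)
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * as.numeric(g)^2
    upd <- lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + eps)
    p <- params[[nm]]
    p[] <- as.numeric(p) - as.numeric(upd) # keep the original shape
    params[[nm]] <- p
  }
  list(params = params, state = state)
}
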