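# Minimal feedforward regressor (fully connected, rectified hidden layers,
# linear output, squared-error loss, Adam updates, early stopping on a
# held-out validation split). Written directly in matrix algebra so that
# training is deterministic under a seed and cheap to embed in tests.

mlp_init <- function(p, hidden, y_center = 0) {
  sizes <- c(p, hidden, 1L)
  layers <- lapply(seq_len(length(sizes) - 1L), function(l) {
    list(W = matrix(rnorm(sizes[l] * sizes[l + 1L],
                          sd = sqrt(2 / sizes[l])),
                    nrow = sizes[l]),
         b = rep(0, sizes[l + 1L]))
  })
  # start the output at the target mean so the net learns deviations
  layers[[length(layers)]]$b <- y_center
  layers
}

mlp_forward <- function(layers, x) {
  a <- list(x)
  n_l <- length(layers)
  for (l in seq_len(n_l)) {
    z <- a[[l]] %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(a[[l]]), length(layers[[l]]$b),
             byrow = TRUE)
    a[[l + 1L]] <- if (l < n_l) pmax(z, 0) else z
  }
  a
}

# dense, feature-scaled minibatch slice from a (possibly sparse) matrix
mlp_slice <- function(x, idx, center, scale) {
  xb <- as.matrix(x[idx, , drop = FALSE])
  sweep(sweep(xb, 2, center, "-"), 2, scale, "/")
}

mlp_fit <- function(x, y, hidden = c(64, 32), learning_rate = 1e-2,
                    max_epochs = 40, batch_size = 256, val_fraction = 0.1,
                    patience = 6, weight_decay = 1e-3, val_groups = NULL,
                    mse_slack = 1.5, clip = NULL, seed = 1) {
  stopifnot(nrow(x) == length(y), length(hidden) >= 1, learning_rate > 0)
  withr::with_seed(seed, {
    n <- nrow(x)
    p <- ncol(x)
    center <- Matrix::colMeans(x)
    v <- Matrix::colMeans(x^2) - center^2
    scale <- sqrt(pmax(v, 0))
    scale[scale < 1e-8] <- 1
    n_val <- max(1L, round(val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    xv <- mlp_slice(x, val_idx, center, scale)
    yv <- y[val_idx]
    # calibration monitor: per-group mean residual over (a subsample of)
    # the cells the model is deployed on; groups with too few monitored
    # cells are ignored
    bias_idx <- NULL
    if (!is.null(val_groups)) {
      bias_idx <- if (length(tr_idx) > 20000) {
        sort(sample(tr_idx, 20000))
      } else {
        tr_idx
      }
      xb_mon <- mlp_slice(x, bias_idx, center, scale)
      yb_mon <- y[bias_idx]
      gb_mon <- val_groups[bias_idx]
      tab_mon <- table(gb_mon)
      keep_mon <- gb_mon %in% names(tab_mon)[tab_mon >= 20]
    }
    group_bias <- function(layers) {
      if (is.null(bias_idx) || !any(keep_mon)) return(NA_real_)
      pb <- mlp_forward(layers, xb_mon)
      pred <- drop(pb[[length(pb)]])
      # deployment clips predictions, so the monitor must too
      if (!is.null(clip)) pred <- pmin(pmax(pred, clip[1]), clip[2])
      # trimmed mean: robust to the small old-embryo contaminant tail
      max(abs(tapply(pred[keep_mon] - yb_mon[keep_mon], gb_mon[keep_mon],
                     mean, trim = 0.05)))
    }
    layers <- mlp_init(p, hidden, y_center = mean(y))
    mom <- lapply(layers, function(l) {
      list(mW = 0 * l$W, vW = 0 * l$W, mb = 0 * l$b, vb = 0 * l$b)
    })
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    p0 <- mlp_forward(layers, xv)
    v0 <- drop(p0[[length(p0)]])
    snapshots <- list(list(val = mean((v0 - yv)^2),
                           bias = group_bias(layers), layers = layers,
                           epoch = 0L))
    best <- snapshots[[1]]
    stale <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(tr_idx)
      for (s in seq(1L, length(ord), by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1L, length(ord))]
        xb <- mlp_slice(x, idx, center, scale)
        yb <- y[idx]
        a <- mlp_forward(layers, xb)
        nb <- length(idx)
        delta <- 2 * (a[[length(a)]] - yb) / nb
        if (!all(is.finite(delta))) {
          stop("non-finite training loss at epoch ", epoch,
               " (learning rate ", learning_rate, ", hidden ",
               paste(hidden, collapse = "x"), ")")
        }
        step <- step + 1L
        for (l in rev(seq_along(layers))) {
          gW <- crossprod(a[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(layers[[l]]$W)) * (a[[l]] > 0)
          }
          m <- mom[[l]]
          m$mW <- b1 * m$mW + (1 - b1) * gW
          m$vW <- b2 * m$vW + (1 - b2) * gW^2
          m$mb <- b1 * m$mb + (1 - b1) * gb
          m$vb <- b2 * m$vb + (1 - b2) * gb^2
          mom[[l]] <- m
          corr1 <- 1 - b1^step
          corr2 <- 1 - b2^step
          # decoupled weight decay on the weights (not the biases)
          layers[[l]]$W <- layers[[l]]$W * (1 - learning_rate *
                                              weight_decay) -
            learning_rate * (m$mW / corr1) / (sqrt(m$vW / corr2) + eps)
          layers[[l]]$b <- layers[[l]]$b -
            learning_rate * (m$mb / corr1) / (sqrt(m$vb / corr2) + eps)
        }
      }
      pv <- mlp_forward(layers, xv)
      vhat <- drop(pv[[length(pv)]])
      val_mse <- mean((vhat - yv)^2)
      if (!is.finite(val_mse)) {
        stop("non-finite validation loss at epoch ", epoch,
             " (learning rate ", learning_rate, ")")
      }
      snap <- list(val = val_mse, bias = group_bias(layers),
                   layers = layers, epoch = epoch)
      mins <- vapply(snapshots, function(s) s$val, numeric(1))
      bias_min <- suppressWarnings(
        min(vapply(snapshots, function(s) s$bias, numeric(1)),
            na.rm = TRUE))
      improved <- val_mse < min(mins) - 1e-6 ||
        (!is.na(snap$bias) && is.finite(bias_min) &&
           snap$bias < bias_min - 1e-6)
      if (improved) {
        snapshots[[length(snapshots) + 1L]] <- snap
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
    # among epochs whose validation MSE is within `mse_slack` of the
    # best, prefer the one with the smallest per-group bias: absolute
    # ages should be calibrated per collection window, not only accurate
    # on average
    vals <- vapply(snapshots, function(s) s$val, numeric(1))
    biases <- vapply(snapshots, function(s) s$bias, numeric(1))
    cand <- which(vals <= mse_slack * min(vals) & !is.na(biases))
    best <- if (length(cand)) {
      snapshots[[cand[which.min(biases[cand])]]]
    } else {
      snapshots[[which.min(vals)]]
    }
    list(layers = best$layers, center = center,
         scale = scale, hidden = hidden, learning_rate = learning_rate,
         val_mse = best$val, val_bias = best$bias,
         best_epoch = best$epoch)
  })
}

mlp_predict <- function(fit, x, block = 4096L) {
  n <- nrow(x)
  out <- numeric(n)
  for (s in seq(1L, n, by = block)) {
    idx <- s:min(s + block - 1L, n)
    xb <- mlp_slice(x, idx, fit$center, fit$scale)
    a <- mlp_forward(fit$layers, xb)
    out[idx] <- a[[length(a)]][, 1]
  }
  out
}
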