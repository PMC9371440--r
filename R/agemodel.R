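# ---- partitioning -------------------------------------------------------

strat_folds <- function(strata, k, seed = NULL) {
  with_seed_or_not(seed, {
    lab <- integer(length(strata))
    for (s in unique(strata)) {
      idx <- which(strata == s)
      lab[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
    lab
  })
}

#' Partition cells evenly with respect to collection time
#'
#' Cells are split into `n_partitions` groups balanced within every
#' collection window (partition sizes per window differ by at most one),
#' the design used to hold out an evaluation partition while training on
#' the rest.
#'
#' @param window_index collection-window index per cell.
#' @param n_partitions number of partitions (>= 2).
#' @param seed integer seed.
#' @return integer partition label (1..n_partitions) per cell.
#' @export
partition_cells <- function(window_index, n_partitions = 11, seed = 1) {
  stopifnot(n_partitions >= 2)
  tab <- table(window_index)
  if (any(tab < n_partitions)) {
    stop("every window needs at least n_partitions cells; windows ",
         paste(names(tab)[tab < n_partitions], collapse = ", "),
         " have fewer")
  }
  strat_folds(window_index, n_partitions, seed)
}

# ---- feature selection --------------------------------------------------

#' Select features most correlated with collection time
#'
#' Ranks features by the absolute Pearson correlation between their
#' normalized value and the collection-window center hour, computed on
#' training cells only. Zero-variance features are excluded; ties are
#' broken by feature id.
#'
#' @param x normalized feature x cell matrix (training cells).
#' @param centers window center hour per training cell.
#' @param n_features how many features to keep.
#' @return character vector of selected feature ids, best first.
#' @export
select_time_features <- function(x, centers, n_features) {
  stopifnot(ncol(x) == length(centers))
  if (n_features > nrow(x)) stop("n_features exceeds available features")
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  n <- length(centers)
  y <- centers
  rmean <- Matrix::rowMeans(x)
  rvar <- Matrix::rowMeans(x^2) - rmean^2
  sy <- mean(y^2) - mean(y)^2
  if (sy <= 0) stop("collection centers are constant; cannot rank features")
  sxy <- as.numeric(x %*% y) / n - rmean * mean(y)
  r <- sxy / sqrt(pmax(rvar, 0) * sy)
  r[rvar <= 1e-12] <- NA
  if (all(is.na(r))) stop("all features have zero variance")
  ord <- order(-abs(r), ids, na.last = TRUE)
  ord <- ord[!is.na(r[ord])]
  ids[head(ord, n_features)]
}

# ---- model fitting ------------------------------------------------------

age_prep <- function(counts, modality, preprocess, scale_factor = 1e4,
                     pseudocount = 1) {
  if (!preprocess) {
    return(list(x = as_dgc(counts),
                recipe = list(raw = TRUE, modality = modality)))
  }
  list(x = normalize_counts(counts, modality, scale_factor, pseudocount),
       recipe = list(raw = FALSE, modality = modality,
                     scale_factor = scale_factor,
                     pseudocount = pseudocount, log = TRUE))
}

new_age_model <- function(kind, feature_ids, recipe, fit, windows,
                          cv_record, extra = list()) {
  structure(c(list(kind = kind, feature_ids = feature_ids,
                   preprocessing = recipe, fit = fit,
                   training_windows = windows,
                   max_age = max(windows$end_h), cv_record = cv_record),
              extra),
            class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat("age_model (", x$kind, "): ", length(x$feature_ids),
      " features, predictions clipped to [0, ", x$max_age, "] h\n",
      sep = "")
  invisible(x)
}

#' Fit a lasso regressor of developmental age on a profile
#'
#' L1-penalized linear regression of the collection-window center hour on
#' the normalized profile, with the penalty chosen by cross-validation
#' stratified by window. Preprocessing (depth normalization, log, feature
#' selection) is frozen into the model and replayed at prediction time.
#'
#' @param counts feature x cell count matrix (training cells).
#' @param window_index collection-window index per training cell.
#' @param windows collection-window table supplying center hours.
#' @param modality `"rna"` or `"atac"`.
#' @param n_features number of time-correlated features to keep (capped at
#'   the number available).
#' @param lambda optional penalty grid for [glmnet::cv.glmnet()]; must be
#'   non-empty if given.
#' @param n_folds cross-validation folds.
#' @param seed integer seed (fold assignment).
#' @param preprocess set `FALSE` to treat `counts` as an already-prepared
#'   design matrix and skip normalization/feature selection.
#' @return an `age_model`.
#' @export
fit_lasso_age <- function(counts, window_index, windows, modality = "rna",
                          n_features = 2000, lambda = NULL, n_folds = 10,
                          seed = 1, preprocess = TRUE) {
  if (!is.null(lambda) && length(lambda) == 0) {
    stop("lambda grid must be non-empty")
  }
  y <- windows$center_h[match(window_index, windows$index)]
  if (anyNA(y)) stop("window_index contains values absent from windows")
  prep <- age_prep(counts, modality, preprocess)
  feats <- if (preprocess) {
    select_time_features(prep$x, y, min(n_features, nrow(prep$x)))
  } else {
    rownames(prep$x) %||% as.character(seq_len(nrow(prep$x)))
  }
  x <- Matrix::t(prep$x[feats, , drop = FALSE])
  if (ncol(x) == 1) x <- cbind(x, `.aug0` = 0)  # glmnet needs >= 2 cols
  foldid <- strat_folds(window_index, n_folds, seed)
  cv <- glmnet::cv.glmnet(x, y, alpha = 1, foldid = foldid,
                          lambda = lambda)
  new_age_model("lasso", feats, prep$recipe, cv, windows,
                data.frame(lambda = cv$lambda, cv_mse = cv$cvm),
                extra = list(lambda_min = cv$lambda.min,
                             augmented = length(feats) == 1))
}

default_nn_grid <- function() {
  g <- expand.grid(h1 = c(64, 128), learning_rate = c(1e-2, 1e-3))
  lapply(seq_len(nrow(g)), function(i) {
    list(hidden = c(g$h1[i], g$h1[i] / 2),
         learning_rate = g$learning_rate[i])
  })
}

#' Fit a neural-network regressor of developmental age
#'
#' Feedforward network (rectified hidden layers, linear output) trained on
#' squared-error loss with Adam and early stopping on an internal
#' validation split. When more than one hyperparameter configuration is
#' supplied, the best is chosen by window-stratified k-fold
#' cross-validation MSE and the model is refit on all training cells.
#'
#' @inheritParams fit_lasso_age
#' @param hyper_grid list of configurations, each a list with `hidden`
#'   (vector of layer widths) and `learning_rate`; default
#'   \{64, 128\} first-layer widths crossed with \{1e-2, 1e-3\}.
#' @param max_epochs,batch_size training-loop controls passed to the
#'   optimizer.
#' @return an `age_model` with the cross-validation record attached.
#' @export
fit_nn_age <- function(counts, window_index, windows, modality = "rna",
                       n_features = 2000, hyper_grid = NULL, n_folds = 10,
                       seed = 1, preprocess = TRUE, max_epochs = 40,
                       batch_size = 256) {
  grid <- hyper_grid %||% default_nn_grid()
  if (!length(grid)) stop("hyper_grid must be non-empty")
  y <- windows$center_h[match(window_index, windows$index)]
  if (anyNA(y)) stop("window_index contains values absent from windows")
  prep <- age_prep(counts, modality, preprocess)
  feats <- if (preprocess) {
    select_time_features(prep$x, y, min(n_features, nrow(prep$x)))
  } else {
    rownames(prep$x) %||% as.character(seq_len(nrow(prep$x)))
  }
  x <- Matrix::t(prep$x[feats, , drop = FALSE])
  cv_record <- NULL
  best_cfg <- grid[[1]]
  if (length(grid) > 1) {
    foldid <- strat_folds(window_index, n_folds, seed)
    scores <- vapply(seq_along(grid), function(g) {
      cfg <- grid[[g]]
      fold_mse <- vapply(seq_len(n_folds), function(f) {
        tr <- foldid != f
        fit <- mlp_fit(x[tr, , drop = FALSE], y[tr],
                       hidden = cfg$hidden,
                       learning_rate = cfg$learning_rate,
                       max_epochs = max_epochs, batch_size = batch_size,
                       val_groups = window_index[tr],
                       seed = seed + 1000L * g + f)
        mean((mlp_predict(fit, x[!tr, , drop = FALSE]) - y[!tr])^2)
      }, numeric(1))
      mean(fold_mse)
    }, numeric(1))
    cv_record <- data.frame(
      config = vapply(grid, function(cfg) {
        paste0("h", paste(cfg$hidden, collapse = "x"),
               "_lr", cfg$learning_rate)
      }, character(1)),
      cv_mse = scores)
    best_cfg <- grid[[which.min(scores)]]
  }
  fit <- mlp_fit(x, y, hidden = best_cfg$hidden,
                 learning_rate = best_cfg$learning_rate,
                 max_epochs = max_epochs, batch_size = batch_size,
                 val_groups = window_index,
                 clip = c(0, max(windows$end_h)), seed = seed)
  new_age_model("nn", feats, prep$recipe, fit, windows, cv_record,
                extra = list(hyper = best_cfg))
}

# ---- prediction and evaluation ------------------------------------------

#' Predict developmental age from profiles
#'
#' Replays the preprocessing frozen at fit time, applies the regressor,
#' and clips predictions to the embryogenesis span seen in training.
#' Features outside `model$feature_ids` are ignored; missing model
#' features raise an error listing them.
#'
#' @param model an `age_model`.
#' @param counts feature x cell count matrix.
#' @return predicted age in hours per cell.
#' @export
predict_age <- function(model, counts) {
  stopifnot(inherits(model, "age_model"))
  ids <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  missing <- setdiff(model$feature_ids, ids)
  if (length(missing)) {
    stop("input lacks ", length(missing), " model feature(s): ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...")
  }
  x <- if (model$preprocessing$raw) {
    as_dgc(counts)
  } else {
    normalize_counts(counts, model$preprocessing$modality,
                     model$preprocessing$scale_factor,
                     model$preprocessing$pseudocount)
  }
  xs <- Matrix::t(x[model$feature_ids, , drop = FALSE])
  pred <- if (model$kind == "lasso") {
    if (isTRUE(model$augmented)) xs <- cbind(xs, `.aug0` = 0)
    as.numeric(predict(model$fit, newx = xs, s = "lambda.min"))
  } else {
    mlp_predict(model$fit, xs)
  }
  pmin(pmax(pred, 0), model$max_age)
}

#' Evaluate age predictions against collection windows
#'
#' `mse` is the mean squared difference to the window center (the training
#' target). `proportion_correct` is, by default, the fraction of cells
#' whose predicted age falls inside their originating collection window
#' (bounds inclusive); `mode = "nearest"` instead scores a cell correct
#' when its own window center is the nearest of all centers.
#'
#' @param predicted predicted ages (hours) per cell.
#' @param window_index collection-window index per cell.
#' @param windows collection-window table.
#' @param mode `"membership"` or `"nearest"`.
#' @return list with `mse`, `proportion_correct`,
#'   `per_window_mean_error` (mean predicted minus center, per window).
#' @export
evaluate_age <- function(predicted, window_index, windows,
                         mode = c("membership", "nearest")) {
  mode <- match.arg(mode)
  if (length(predicted) != length(window_index)) {
    stop("predicted and window_index must have equal length")
  }
  m <- match(window_index, windows$index)
  if (anyNA(m)) stop("window_index contains values absent from windows")
  center <- windows$center_h[m]
  mse <- mean((predicted - center)^2)
  correct <- if (mode == "membership") {
    predicted >= windows$start_h[m] & predicted <= windows$end_h[m]
  } else {
    nearest <- vapply(predicted, function(p) {
      windows$index[which.min(abs(windows$center_h - p))]
    }, numeric(1))
    nearest == window_index
  }
  err <- tapply(predicted - center, window_index, mean)
  list(mse = mse, proportion_correct = mean(correct),
       per_window_mean_error = err)
}

#' Predict the age of bulk samples
#'
#' Each bulk profile (feature totals for one sample) is pushed through the
#' model's per-cell preprocessing as a single pseudo-cell, then through
#' the regressor.
#'
#' @param model an `age_model`.
#' @param bulk feature x sample matrix of totals (or a named vector for
#'   one sample).
#' @return predicted age in hours per sample.
#' @export
predict_bulk_age <- function(model, bulk) {
  if (is.null(dim(bulk))) {
    bulk <- matrix(bulk, ncol = 1, dimnames = list(names(bulk), "bulk"))
  }
  tot <- colSums(as.matrix(bulk))
  if (any(tot == 0)) {
    stop("bulk sample(s) with zero total counts: ",
         paste(colnames(bulk)[tot == 0], collapse = ", "))
  }
  predict_age(model, bulk)
}

#' Fraction of cells predicted at least as old as a threshold
#'
#' Applied to the cells of one collection window, this quantifies
#' old-embryo contamination: the proportion of nuclei whose predicted age
#' reaches `age_threshold` hours.
#'
#' @param predicted_ages predicted ages of the window's cells.
#' @param age_threshold hours.
#' @return proportion in \[0, 1\].
#' @export
contamination_fraction <- function(predicted_ages, age_threshold = 4) {
  if (!length(predicted_ages)) stop("no cells supplied")
  mean(predicted_ages >= age_threshold)
}

#' Drop cells older than an inferred-age cutoff
#'
#' Predictions near the end of the sampled span suffer edge effects, so
#' cells with inferred age above `max_age_h` (strictly) are excluded from
#' windowed analyses.
#'
#' @param predicted_ages predicted ages per cell.
#' @param max_age_h retention cutoff (default 18 h); ages equal to the
#'   cutoff are kept.
#' @param cells optional data.frame or vector to subset.
#' @return logical keep-mask, or the subset of `cells` when supplied.
#' @export
filter_by_age <- function(predicted_ages, max_age_h = 18, cells = NULL) {
  keep <- !is.na(predicted_ages) & predicted_ages <= max_age_h
  if (is.null(cells)) return(keep)
  if (is.data.frame(cells)) cells[keep, , drop = FALSE] else cells[keep]
}

#' Classify nuclei as XX or XY from the chrX read fraction
#'
#' Fits a two-component one-dimensional Gaussian mixture to the proportion
#' of chrX-mapped reads per nucleus and hard-assigns each nucleus by
#' posterior; the higher-mean component is labelled XX (two X copies give
#' roughly twice the chrX read share).
#'
#' @param fractions chrX read fraction per cell, in \[0, 1\].
#' @param seed integer seed.
#' @return list with `sex` (character per cell), `means`, `sd`,
#'   `proportions` (mixture weights, XX first).
#' @export
classify_sex_gmm <- function(fractions, seed = 1) {
  if (length(fractions) < 2) stop("need at least two cells")
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  if (length(unique(fractions)) < 2) {
    stop("degenerate input: all chrX fractions identical")
  }
  fit <- withr::with_seed(seed, suppressWarnings(
    tryCatch(mclust::Mclust(fractions, G = 2, verbose = FALSE),
             error = function(e) NULL)))
  if (!is.null(fit) && length(unique(fit$classification)) == 2) {
    mu <- fit$parameters$mean
    cls <- fit$classification
    sdv <- sqrt(fit$parameters$variance$sigmasq)
    pro <- fit$parameters$pro
  } else {
    # fallback for tiny or pathological inputs: two-centre assignment
    ctr <- range(fractions)
    cls <- ifelse(abs(fractions - ctr[1]) <= abs(fractions - ctr[2]),
                  1L, 2L)
    mu <- c(mean(fractions[cls == 1]), mean(fractions[cls == 2]))
    sdv <- rep(sd(fractions), 2)
    pro <- tabulate(cls, 2) / length(cls)
  }
  xx_comp <- which.max(mu)
  sex <- ifelse(cls == xx_comp, "XX", "XY")
  ordc <- c(xx_comp, setdiff(seq_along(mu), xx_comp))
  list(sex = sex,
       means = setNames(mu[ordc], c("XX", "XY")),
       sd = setNames(rep_len(sdv, 2)[ordc], c("XX", "XY")),
       proportions = setNames(rep_len(pro, 2)[ordc], c("XX", "XY")))
}
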