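# ---- motif deviations ---------------------------------------------------

#' Motif accessibility deviations per cluster
#'
#' A simplified chromVAR-style deviation: for each TF motif and cluster,
#' the observed fraction of the cluster's reads falling in motif-hit
#' peaks is compared with the fraction expected under the pooled
#' (all-cluster) profile, `(obs - exp) / exp`, and z-scored against
#' `n_background` random peak sets matched on the decile of pooled peak
#' accessibility. Synthetic peaks carry no sequence composition, so the
#' background matches accessibility only; the interface admits a full
#' GC-matched drop-in.
#'
#' @param cluster_access cluster x peak accessibility (counts or summed
#'   reads).
#' @param motif_hits peak x TF binary hit table; motifs with zero hits
#'   are dropped with a warning.
#' @param n_background background sets per motif.
#' @param seed integer seed for background sampling.
#' @return TF x cluster matrix of deviation z-scores, with the raw
#'   deviations and the background record attached as attributes `raw`
#'   and `background`.
#' @export
motif_deviation <- function(cluster_access, motif_hits,
                            n_background = 50, seed = 1) {
  A <- as.matrix(cluster_access)
  H <- as.matrix(motif_hits) > 0
  stopifnot(ncol(A) == nrow(H))
  n_hits <- colSums(H)
  if (any(n_hits == 0)) {
    warning("dropping motif(s) with no hit peaks: ",
            paste(colnames(H)[n_hits == 0], collapse = ", "))
    H <- H[, n_hits > 0, drop = FALSE]
  }
  if (!ncol(H)) stop("no motif has any hit peaks")
  row_tot <- rowSums(A)
  if (any(row_tot <= 0)) stop("cluster(s) with zero total accessibility")
  pooled <- colSums(A) / sum(A)          # expected read share per peak
  dev_of <- function(ind) {
    obs <- (A %*% ind) / row_tot         # clusters x sets
    expd <- as.numeric(pooled %*% ind)
    sweep(sweep(obs, 2, expd, "-"), 2, expd, "/")
  }
  D <- t(dev_of(H))                      # TF x clusters
  decile <- as.integer(cut(rank(pooled, ties.method = "first"),
                           breaks = 10, labels = FALSE))
  by_dec <- split(seq_along(pooled), decile)
  withr::with_seed(seed, {
    n_tf <- ncol(H)
    bg <- Matrix::Matrix(0, nrow(H), n_tf * n_background, sparse = TRUE)
    col <- 0L
    for (j in seq_len(n_tf)) {
      cnt <- table(factor(decile[H[, j]], levels = names(by_dec)))
      for (b in seq_len(n_background)) {
        col <- col + 1L
        pick <- unlist(lapply(names(by_dec), function(d) {
          k <- cnt[[d]]
          if (k == 0) return(integer())
          pool <- by_dec[[d]]
          pool[sample.int(length(pool), min(k, length(pool)))]
        }))
        bg[pick, col] <- 1
      }
    }
    Db <- dev_of(as.matrix(bg))          # clusters x (tf*background)
    z <- D
    for (j in seq_len(n_tf)) {
      cols <- ((j - 1L) * n_background + 1L):(j * n_background)
      m <- rowMeans(Db[, cols, drop = FALSE])
      s <- apply(Db[, cols, drop = FALSE], 1, sd)
      zj <- (D[j, ] - m) / s
      zj[s < 1e-12] <- ifelse(abs(D[j, ] - m)[s < 1e-12] < 1e-12, 0,
                              NA_real_)
      z[j, ] <- zj
    }
    dimnames(z) <- list(colnames(H), rownames(A))
    attr(z, "raw") <- D
    attr(z, "background") <- list(n_background = n_background,
                                  matching = "pooled-accessibility decile",
                                  seed = seed)
    z
  })
}

#' Most variable motifs across clusters
#'
#' Ranks motifs by the variance of their deviation across clusters and
#' returns the top `n`; ties break by motif id, and a constant motif
#' (variance 0) ranks last.
#'
#' @param deviations TF x cluster deviation matrix.
#' @param n how many motifs.
#' @return character vector of motif ids.
#' @export
top_variable_motifs <- function(deviations, n) {
  if (n > nrow(deviations)) stop("n exceeds the number of motifs")
  v <- apply(deviations, 1, var)
  ids <- rownames(deviations) %||% as.character(seq_len(nrow(deviations)))
  ids[head(order(-v, ids), n)]
}

#' Correlate TF expression with motif-associated accessibility
#'
#' Across linked RNA/ATAC cluster pairs, the correlation between a TF's
#' expression (RNA side) and its motif deviation (ATAC side): shifted
#' positive for activators, negative for repressors.
#'
#' @param linked_pairs data.frame with `atac_cluster`, `rna_cluster`
#'   (e.g. the linked rows of [link_clusters()] output); at least 3
#'   pairs.
#' @param expression TF x RNA-cluster expression matrix.
#' @param deviations TF x ATAC-cluster deviation matrix.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return named numeric vector of correlations per TF (`NA` where the
#'   TF's expression has zero variance across the pairs).
#' @export
expr_motif_correlation <- function(linked_pairs, expression, deviations,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(linked_pairs) < 3) {
    stop("need at least 3 linked cluster pairs")
  }
  tfs <- intersect(rownames(expression), rownames(deviations))
  e <- expression[tfs, as.character(linked_pairs$rna_cluster),
                  drop = FALSE]
  d <- deviations[tfs, as.character(linked_pairs$atac_cluster),
                  drop = FALSE]
  out <- vapply(seq_along(tfs), function(i) {
    if (var(e[i, ]) < 1e-18) return(NA_real_)
    cor(e[i, ], d[i, ], method = method)
  }, numeric(1))
  setNames(out, tfs)
}

# ---- germ-layer x time interaction model --------------------------------

ols_interaction <- function(y, expr, z) {
  X <- cbind(1, expr, expr * z)
  if (qr(X)$rank < 3L) return(NULL)
  dfree <- length(y) - 3L
  if (dfree <= 0L) return(NULL)
  xtx_inv <- tryCatch(chol2inv(chol(crossprod(X))),
                      error = function(e) NULL)
  if (is.null(xtx_inv)) return(NULL)
  beta <- drop(xtx_inv %*% crossprod(X, y))
  res <- y - drop(X %*% beta)
  s2 <- sum(res^2) / dfree
  se3 <- sqrt(max(s2 * xtx_inv[3, 3], 0))
  tstat <- if (se3 > 0) {
    beta[3] / se3
  } else if (abs(beta[3]) > 0) {
    sign(beta[3]) * Inf   # perfect fit with a non-zero effect
  } else {
    0                     # identically-zero response: no evidence
  }
  c(effect = beta[3], p = 2 * pt(-abs(tstat), dfree))
}

#' Germ-layer-by-time model of TF motif activity
#'
#' For every (TF, germ layer g, time window w), an ordinary least squares
#' fit over the clusters of window w predicts the TF's motif deviation
#' from its expression plus an expression-by-layer interaction
#' (`deviation ~ expression + expression : 1[layer == g]`); the
#' interaction coefficient is the effect, its t-test gives the p value,
#' and Benjamini-Hochberg correction is applied jointly over all tests.
#' Windows with fewer than `min_clusters` clusters are skipped — with few
#' clusters the effect estimates are driven by outliers.
#'
#' @param deviations TF x cluster deviation matrix.
#' @param expression TF x cluster expression matrix (same clusters).
#' @param cluster_meta data.frame `cluster`, `window`, `germ_layer`.
#' @param min_clusters minimum clusters per tested window.
#' @param p_threshold adjusted-p significance cutoff.
#' @return data.frame `tf`, `germ_layer`, `window`, `effect`, `p`,
#'   `p_adj`, `significant`, `sign`; skipped tests (with reasons) in
#'   attribute `skipped`.
#' @export
germlayer_time_model <- function(deviations, expression, cluster_meta,
                                 min_clusters = 4, p_threshold = 1e-3) {
  cl <- intersect(colnames(deviations), colnames(expression))
  cl <- intersect(cl, cluster_meta$cluster)
  if (length(cl) < min_clusters) stop("too few clusters shared by inputs")
  meta <- cluster_meta[match(cl, cluster_meta$cluster), ]
  layers <- unique(meta$germ_layer)
  if (length(layers) < 2) stop("need at least 2 germ layers")
  tfs <- intersect(rownames(deviations), rownames(expression))
  rows <- list()
  skipped <- list()
  for (w in sort(unique(meta$window))) {
    in_w <- meta$window == w
    if (sum(in_w) < min_clusters) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(window = w, reason = "fewer clusters than min_clusters")
      next
    }
    layer_w <- meta$germ_layer[in_w]
    for (g in intersect(layers, unique(layer_w))) {
      z <- as.numeric(layer_w == g)
      if (all(z == 1) || all(z == 0)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(window = w, reason = paste0("layer ", g,
                                                 " not contrastable"))
        next
      }
      for (tf in tfs) {
        fit <- ols_interaction(deviations[tf, cl[in_w]],
                               expression[tf, cl[in_w]], z)
        if (is.null(fit)) {
          skipped[[length(skipped) + 1L]] <-
            data.frame(window = w,
                       reason = paste0("singular design for ", tf,
                                       " in layer ", g))
          next
        }
        rows[[length(rows) + 1L]] <-
          data.frame(tf = tf, germ_layer = g, window = w,
                     effect = fit[["effect"]], p = fit[["p"]],
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no testable (tf, layer, window) combinations")
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < p_threshold
  out$sign <- sign(out$effect)
  attr(out, "skipped") <- if (length(skipped)) {
    do.call(rbind, skipped)
  } else {
    NULL
  }
  out
}

#' Keep TFs with sustained, sign-consistent effects
#'
#' Retains (TF, germ layer) pairs showing at least `min_run` consecutive
#' time windows with a significant, same-sign effect, and reports the
#' first window of the run — the window from which the TF initiates its
#' activity. With `attribute = "top"` (default), each (TF, window) is
#' first attributed to its single strongest significant layer, which
#' suppresses the mirror-image contrasts that one-vs-rest layer tests
#' produce in the complementary layers.
#'
#' @param effects output of [germlayer_time_model()].
#' @param min_run minimum run length (windows).
#' @param attribute `"top"` or `"all"`.
#' @return data.frame `tf`, `germ_layer`, `start_window`, `run_length`,
#'   `sign`.
#' @export
consecutive_window_filter <- function(effects, min_run = 3,
                                      attribute = c("top", "all")) {
  attribute <- match.arg(attribute)
  sig <- effects[effects$significant, , drop = FALSE]
  if (attribute == "top" && nrow(sig)) {
    key <- paste(sig$tf, sig$window)
    sig <- do.call(rbind, lapply(split(sig, key), function(d) {
      d[which.max(abs(d$effect)), , drop = FALSE]
    }))
  }
  out <- list()
  if (nrow(sig)) {
    for (grp in split(sig, paste(sig$tf, sig$germ_layer, sep = "\r"))) {
      grp <- grp[order(grp$window), ]
      run_id <- cumsum(c(1, diff(grp$window) != 1 |
                            diff(grp$sign) != 0))
      for (r in split(grp, run_id)) {
        if (nrow(r) >= min_run) {
          out[[length(out) + 1L]] <-
            data.frame(tf = r$tf[1], germ_layer = r$germ_layer[1],
                       start_window = r$window[1], run_length = nrow(r),
                       sign = r$sign[1], stringsAsFactors = FALSE)
          break  # report the earliest qualifying run
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(tf = character(), germ_layer = character(),
                      start_window = integer(), run_length = integer(),
                      sign = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$tf, res$germ_layer), ]
  rownames(res) <- NULL
  res
}
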