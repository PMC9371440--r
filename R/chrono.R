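# ---- temporal_profile class ---------------------------------------------

new_temporal_profile <- function(values, bin_edges, normalization) {
  stopifnot(ncol(values) == length(bin_edges) - 1L)
  colnames(values) <- format(bin_edges[-length(bin_edges)], trim = TRUE)
  structure(list(values = values, bin_edges = bin_edges,
                 normalization = normalization),
            class = "temporal_profile")
}

#' @export
print.temporal_profile <- function(x, ...) {
  cat("temporal_profile: ", nrow(x$values), " features x ",
      ncol(x$values), " bins (", x$bin_edges[1], "-",
      x$bin_edges[length(x$bin_edges)], " h, ",
      round(diff(x$bin_edges[1:2]) * 60, 3), " min each); ",
      sum(colSums(!is.na(x$values)) == 0), " empty bin(s)\n", sep = "")
  invisible(x)
}

# ---- binning ------------------------------------------------------------

#' Assign cells to fine time bins by predicted age
#'
#' Bins of `increment_min` minutes tile `range_h`; a cell's bin is
#' `floor((age - start) * 60 / increment_min)` (0-based). Ages outside the
#' range get `NA`; an age exactly at the right edge is closed into the
#' last bin.
#'
#' @param ages predicted (or true) ages in hours.
#' @param increment_min bin width in minutes; must divide the range.
#' @param range_h length-2 vector, the covered span in hours.
#' @return integer bin index per cell (0-based) with the bin edges (hours)
#'   attached as attribute `bin_edges`.
#' @export
fine_bins <- function(ages, increment_min, range_h = c(0, 2)) {
  if (increment_min <= 0) stop("increment_min must be positive")
  span_min <- (range_h[2] - range_h[1]) * 60
  n_bins <- span_min / increment_min
  if (abs(n_bins - round(n_bins)) > 1e-8) {
    stop("increment_min must divide the range")
  }
  n_bins <- as.integer(round(n_bins))
  bin <- floor((ages - range_h[1]) * 60 / increment_min)
  bin[ages < range_h[1] | ages > range_h[2]] <- NA
  bin[!is.na(bin) & bin == n_bins] <- n_bins - 1L  # close right edge
  structure(as.integer(bin),
            bin_edges = range_h[1] + seq(0, n_bins) * increment_min / 60)
}

#' Pseudobulk temporal profile over fine time bins
#'
#' Counts are summed over the member cells of each bin, depth-normalized
#' to `scale_factor` per bin total, and (optionally) log-transformed after
#' adding `pseudocount`: `value = log(pseudocount + sum * sf / total)`.
#' Bins without cells are flagged missing (`NA`), not zero — early fine
#' bins are often empty at realistic sampling depth.
#'
#' @param counts feature x cell count matrix.
#' @param bins bin index per cell from [fine_bins()] (or any integer
#'   vector with a `bin_edges` attribute; `NA` cells are dropped).
#' @param scale_factor,pseudocount,log normalization record.
#' @return a `temporal_profile` (features x bins).
#' @export
pseudobulk_profile <- function(counts, bins, scale_factor = 1e4,
                               pseudocount = 1, log = TRUE) {
  edges <- attr(bins, "bin_edges")
  if (is.null(edges)) stop("bins must carry a bin_edges attribute")
  n_bins <- length(edges) - 1L
  keep <- !is.na(bins)
  if (!any(keep)) stop("all bins are empty: no cells fall in the range")
  x <- as_dgc(counts)[, keep, drop = FALSE]
  b <- bins[keep]
  ind <- Matrix::sparseMatrix(i = seq_along(b), j = b + 1L, x = 1,
                              dims = c(length(b), n_bins))
  sums <- as.matrix(x %*% ind)
  n_cells <- as.integer(Matrix::colSums(ind))
  tot <- colSums(sums)
  vals <- sweep(sums, 2, ifelse(tot > 0, scale_factor / tot, 0), "*")
  if (log) vals <- base::log(pseudocount + vals)
  vals[, n_cells == 0] <- NA_real_
  rownames(vals) <- rownames(counts)
  prof <- new_temporal_profile(vals, edges,
                               list(scale_factor = scale_factor,
                                    pseudocount = pseudocount, log = log))
  prof$n_cells <- n_cells
  prof
}

# ---- smoothing ----------------------------------------------------------

moving_average_na <- function(v, window_bins) {
  k <- (window_bins - 1L) %/% 2L
  n <- ncol(v)
  num <- matrix(0, nrow(v), n)
  den <- matrix(0, nrow(v), n)
  for (s in -k:k) {
    src <- seq_len(n) + s
    ok <- src >= 1 & src <= n
    val <- v[, src[ok], drop = FALSE]
    fin <- is.finite(val)
    val[!fin] <- 0
    num[, ok] <- num[, ok] + val
    den[, ok] <- den[, ok] + fin
  }
  out <- num / den
  out[den == 0] <- NA_real_
  dimnames(out) <- dimnames(v)
  out
}

#' Smooth a temporal profile with a centered moving average
#'
#' Missing (empty) bins are skipped, not treated as zero; a window of 1 is
#' the identity.
#'
#' @param profile a `temporal_profile`.
#' @param window_bins odd window width in bins.
#' @return a `temporal_profile` of identical shape.
#' @export
smooth_profile <- function(profile, window_bins = 5) {
  stopifnot(inherits(profile, "temporal_profile"))
  if (window_bins < 1 || window_bins %% 2 != 1) {
    stop("window_bins must be an odd positive integer")
  }
  if (window_bins == 1) return(profile)
  out <- profile
  out$values <- moving_average_na(profile$values, window_bins)
  out
}

# ---- region aggregation -------------------------------------------------

#' Aggregate accessibility over linked regions, per gene
#'
#' For each gene, sums the depth-normalized accessibility of its linked
#' peaks within each time bin (used, e.g., to follow accessibility at
#' pioneer-factor-bound regions alongside the target gene's expression).
#' Values are kept on the normalized linear scale.
#'
#' @param atac_counts peak x cell count matrix.
#' @param region_sets named list: gene id -> character vector of peak ids.
#'   Genes with no valid peaks are dropped with a warning.
#' @param bins bin index per cell from [fine_bins()].
#' @param scale_factor depth-normalization target per bin.
#' @return a `temporal_profile` (genes x bins).
#' @export
aggregate_region_accessibility <- function(atac_counts, region_sets, bins,
                                           scale_factor = 1e4) {
  peaks <- rownames(atac_counts)
  region_sets <- lapply(region_sets, intersect, x = peaks)
  empty <- vapply(region_sets, length, integer(1)) == 0
  if (any(empty)) {
    warning("dropping gene(s) with no matching peaks: ",
            paste(names(region_sets)[empty], collapse = ", "))
    region_sets <- region_sets[!empty]
  }
  if (!length(region_sets)) stop("no gene has a non-empty region set")
  prof <- pseudobulk_profile(atac_counts, bins,
                             scale_factor = scale_factor, log = FALSE)
  g <- rep(seq_along(region_sets),
           vapply(region_sets, length, integer(1)))
  p <- match(unlist(region_sets), peaks)
  ind <- Matrix::sparseMatrix(i = g, j = p, x = 1,
                              dims = c(length(region_sets), length(peaks)))
  vals <- as.matrix(ind %*% prof$values)
  rownames(vals) <- names(region_sets)
  out <- new_temporal_profile(vals, prof$bin_edges, prof$normalization)
  out$n_cells <- prof$n_cells
  out
}

# ---- onset estimation and temporal clustering ---------------------------

#' Onset time of a temporal profile
#'
#' The left edge of the first bin at which the smoothed profile reaches
#' half of its maximum. A monotonically decreasing profile therefore has
#' its onset at the first bin; an all-zero profile has no onset and raises
#' an error.
#'
#' @param values numeric vector over bins (may contain `NA` for empty
#'   bins).
#' @param bin_edges bin edges in hours (`length(values) + 1`).
#' @param smooth_window odd moving-average width used before thresholding.
#' @return onset in hours.
#' @export
onset_time <- function(values, bin_edges, smooth_window = 5) {
  sm <- drop(moving_average_na(matrix(values, nrow = 1), smooth_window))
  mx <- suppressWarnings(max(sm, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0) {
    stop("profile has no positive maximum; onset undefined")
  }
  hit <- which(!is.na(sm) & sm >= mx / 2)
  bin_edges[hit[1]]
}

#' @rdname onset_time
#' @param profile a `temporal_profile`; onsets are computed per feature
#'   (`NA` where undefined).
#' @export
onset_times <- function(profile, smooth_window = 5) {
  stopifnot(inherits(profile, "temporal_profile"))
  apply(profile$values, 1, function(v) {
    tryCatch(onset_time(v, profile$bin_edges, smooth_window),
             error = function(e) NA_real_)
  })
}

#' Cluster features by their temporal profile
#'
#' k-means on smoothed, per-feature z-normalized profiles; clusters are
#' relabeled by ascending median onset time so that cluster 1 always
#' switches on first.
#'
#' @param profile a `temporal_profile`.
#' @param k number of clusters (>= 2).
#' @param seed integer seed.
#' @param smooth_window odd moving-average width applied before
#'   clustering.
#' @return integer cluster label per feature (named), ordered by onset.
#' @export
temporal_gene_clusters <- function(profile, k, seed = 1,
                                   smooth_window = 5) {
  stopifnot(inherits(profile, "temporal_profile"), k >= 2)
  if (k > nrow(profile$values)) stop("k exceeds the number of features")
  sm <- moving_average_na(profile$values, smooth_window)
  if (anyNA(sm)) stop("profiles contain empty bins; restrict the range ",
                      "or smooth more broadly before clustering")
  mu <- rowMeans(sm)
  sig <- apply(sm, 1, sd)
  sig[sig < 1e-12] <- 1
  z <- (sm - mu) / sig
  km <- withr::with_seed(seed, tryCatch(
    kmeans(z, centers = k, nstart = 10, iter.max = 100),
    error = function(e) {
      stop("k-means failed (", conditionMessage(e),
           "); profiles may have fewer than k distinct shapes")
    }))
  onset <- onset_times(new_temporal_profile(sm, profile$bin_edges,
                                            profile$normalization),
                       smooth_window = 1)
  med <- tapply(onset, km$cluster, median, na.rm = TRUE)
  relabel <- match(seq_len(k), order(med))
  setNames(relabel[km$cluster], rownames(profile$values))
}
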