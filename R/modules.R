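# ---- gene selection and scaling ----------------------------------------

profile_values <- function(profile) {
  if (inherits(profile, "temporal_profile")) profile$values else
    as.matrix(profile)
}

#' Most variable genes over time bins
#'
#' Ranks genes by the variance of their profile across bins (missing bins
#' ignored) and returns the top `n`; ties break by gene id.
#'
#' @param profile a `temporal_profile` (or plain genes x bins matrix).
#' @param n how many genes.
#' @return character vector of gene ids.
#' @export
select_variable_genes <- function(profile, n) {
  v <- profile_values(profile)
  if (n > nrow(v)) stop("n exceeds the number of genes")
  vars <- apply(v, 1, var, na.rm = TRUE)
  ids <- rownames(v) %||% as.character(seq_len(nrow(v)))
  ids[head(order(-vars, ids), n)]
}

#' Min-max scale each gene's profile over time
#'
#' Rescales every gene to `[0, 1]` across bins so that genes with very
#' different dynamic ranges become comparable before distance-based
#' clustering. Genes with zero range are dropped with a warning.
#'
#' @param profile a `temporal_profile`.
#' @return a `temporal_profile` of scaled values.
#' @export
normalize_over_time <- function(profile) {
  stopifnot(inherits(profile, "temporal_profile"))
  v <- profile$values
  lo <- apply(v, 1, min, na.rm = TRUE)
  hi <- apply(v, 1, max, na.rm = TRUE)
  rng <- hi - lo
  drop_g <- !is.finite(rng) | rng <= 0
  if (any(drop_g)) {
    warning("dropping zero-range gene(s): ",
            paste(head(rownames(v)[drop_g], 10), collapse = ", "),
            if (sum(drop_g) > 10) ", ...")
  }
  if (all(drop_g)) stop("all genes have zero range")
  out <- profile
  out$values <- (v[!drop_g, , drop = FALSE] - lo[!drop_g]) / rng[!drop_g]
  out$normalization$minmax <- TRUE
  out
}

# ---- dynamic time warping ----------------------------------------------

#' Dynamic-time-warping distance between two series
#'
#' Classic DTW dynamic program with absolute-difference local cost and
#' unit steps (match, insert, delete); symmetric in its arguments. An
#' optional Sakoe-Chiba band constrains the warping path to
#' `|i - j| <= band`.
#'
#' @param x,y numeric series (non-empty, finite).
#' @param band optional band half-width in bins; `NULL` for
#'   unconstrained.
#' @return the DTW distance (>= 0).
#' @export
dtw_distance <- function(x, y, band = NULL) {
  if (!length(x) || !length(y)) stop("series must be non-empty")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("series must be finite")
  }
  b <- as.integer(band %||% -1L)
  if (b >= 0 && b < abs(length(x) - length(y))) {
    stop("band is narrower than the length difference; no path exists")
  }
  dtw_dist_cpp(as.numeric(x), as.numeric(y), b)
}

#' Pairwise DTW distances between the rows of a matrix
#'
#' @param values genes x bins matrix of finite values.
#' @inheritParams dtw_distance
#' @return symmetric distance matrix.
#' @export
dtw_pairwise <- function(values, band = NULL) {
  v <- as.matrix(values)
  if (!all(is.finite(v))) stop("profiles must be finite for DTW")
  d <- dtw_pairwise_cpp(v, as.integer(band %||% -1L))
  dimnames(d) <- list(rownames(v), rownames(v))
  d
}

#' Temporal gene modules by DTW clustering
#'
#' Average-linkage hierarchical clustering on the pairwise DTW distance
#' matrix of (min-max scaled) temporal profiles, cut at `k` modules;
#' modules are relabeled by ascending median onset so that module 1
#' switches on first.
#'
#' @param profile a `temporal_profile` of scaled values
#'   ([normalize_over_time()]).
#' @param k number of modules (>= 2, <= genes).
#' @param band optional Sakoe-Chiba band for the DTW.
#' @param smooth_window odd window used by the onset estimator.
#' @return object of class `temporal_modules`: list with `modules`
#'   (data.frame `feature`, `module`, `onset_h`), `means` (module x bin
#'   mean curves), `k`.
#' @export
dtw_cluster <- function(profile, k, band = NULL, smooth_window = 5) {
  stopifnot(inherits(profile, "temporal_profile"), k >= 2)
  v <- profile$values
  if (k > nrow(v)) stop("k exceeds the number of genes")
  if (!all(is.finite(v))) stop("profiles must be finite for DTW")
  d <- dtw_pairwise(v, band)
  hc <- hclust(as.dist(d), method = "average")
  cl <- cutree(hc, k = k)
  onset <- onset_times(profile, smooth_window = smooth_window)
  med <- tapply(onset, cl, median, na.rm = TRUE)
  relabel <- match(seq_len(k), order(med))
  module <- relabel[cl]
  modules <- data.frame(feature = rownames(v), module = module,
                        onset_h = onset, stringsAsFactors = FALSE)
  means <- module_summary(profile, module)
  structure(list(modules = modules, means = means, k = k),
            class = "temporal_modules")
}

#' @export
print.temporal_modules <- function(x, ...) {
  cat("temporal_modules:", x$k, "modules over",
      nrow(x$modules), "genes; sizes:",
      paste(table(x$modules$module), collapse = ", "), "\n")
  invisible(x)
}

#' Mean curve of each module
#'
#' @param profile a `temporal_profile`.
#' @param modules module label per gene (vector aligned with the profile
#'   rows, or the `modules` data.frame of [dtw_cluster()]).
#' @return module x bin matrix of per-bin arithmetic means.
#' @export
module_summary <- function(profile, modules) {
  v <- profile_values(profile)
  if (is.data.frame(modules)) {
    lab <- modules$module[match(rownames(v), modules$feature)]
  } else {
    lab <- modules
  }
  stopifnot(length(lab) == nrow(v))
  levs <- sort(unique(lab))
  out <- do.call(rbind, lapply(levs, function(m) {
    colMeans(v[lab == m, , drop = FALSE])
  }))
  rownames(out) <- levs
  out
}

# ---- expression vs accessibility lag ------------------------------------

equal_count_curve <- function(df, n_bins) {
  stopifnot(all(c("age", "value") %in% names(df)))
  df <- df[order(df$age), , drop = FALSE]
  n <- nrow(df)
  if (n < n_bins) stop("fewer observations (", n, ") than bins")
  grp <- floor((seq_len(n) - 1) * n_bins / n) + 1
  data.frame(age = tapply(df$value * 0 + df$age, grp, mean),
             value = tapply(df$value, grp, mean))
}

minmax <- function(v) {
  r <- range(v)
  if (diff(r) <= 0) stop("flat curve: min-max scaling undefined")
  (v - r[1]) / diff(r)
}

#' Lag between an expression curve and a gene activity curve
#'
#' Both inputs are binned into `n_bins` equal-count partitions by
#' inferred age, averaged per bin, min-max scaled to `[0, 1]`, and
#' aligned by cross-correlation; the reported lag is the shift maximizing
#' the correlation, converted to hours. A positive lag means
#' accessibility precedes expression (pioneer-like ordering); when the
#' best correlation stays below `min_corr`, the estimate is flagged low
#' confidence.
#'
#' @param expression,activity data.frames with columns `age` (hours) and
#'   `value`, one row per cell (or observation).
#' @param n_bins number of equal-count partitions.
#' @param max_shift maximum shift searched, in bins (default
#'   `n_bins %/% 3`).
#' @param min_corr confidence threshold on the peak cross-correlation.
#' @return list with `lag_h`, `lag_bins`, `max_corr`, `low_confidence`.
#' @export
lag_compare <- function(expression, activity, n_bins = 100,
                        max_shift = NULL, min_corr = 0.5) {
  e <- equal_count_curve(expression, n_bins)
  a <- equal_count_curve(activity, n_bins)
  ev <- minmax(e$value)
  av <- minmax(a$value)
  max_shift <- max_shift %||% (n_bins %/% 3)
  shifts <- -max_shift:max_shift
  cc <- vapply(shifts, function(s) {
    if (s >= 0) {
      x <- ev[(1 + s):n_bins]; y <- av[1:(n_bins - s)]
    } else {
      x <- ev[1:(n_bins + s)]; y <- av[(1 - s):n_bins]
    }
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) return(-Inf)
    cor(x, y)
  }, numeric(1))
  best <- order(-cc, abs(shifts))[1]
  span <- (diff(range(e$age)) + diff(range(a$age))) / 2
  hours_per_bin <- span / (n_bins - 1)
  list(lag_h = shifts[best] * hours_per_bin,
       lag_bins = shifts[best],
       max_corr = cc[best],
       low_confidence = cc[best] < min_corr)
}
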