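`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce any matrix-like input to a column-compressed double sparse matrix,
# preserving dimnames
as_dgc <- function(x) {
  if (is(x, "dgCMatrix")) return(x)
  if (is(x, "sparseMatrix")) {
    return(as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix"))
  }
  as(as(as(Matrix::Matrix(as.matrix(x)), "dMatrix"), "generalMatrix"),
     "CsparseMatrix")
}

#' Normalize a count matrix
#'
#' Per-cell depth normalization followed by a log transform, the standard
#' preprocessing applied before age regression and profile construction:
#' counts are scaled so that each cell sums to `scale_factor`, a pseudocount
#' is added, and the natural log is taken. ATAC-like input is binarized
#' before normalization (per-site duplicate reads carry little signal at
#' single-nucleus depth).
#'
#' @param counts feature x cell matrix of non-negative counts (sparse or
#'   dense; rows are genes or peaks, columns are cells).
#' @param modality `"rna"` or `"atac"`; ATAC counts are binarized first.
#' @param scale_factor per-cell target total after depth normalization.
#' @param pseudocount added before the log; with the default 1 a zero count
#'   maps to zero and sparsity is preserved.
#' @param log if `FALSE`, return depth-normalized values without the log.
#' @return a `dgCMatrix` of the same dimensions (dense if `pseudocount != 1`
#'   and `log = TRUE`, because zeros no longer map to zero).
#' @export
normalize_counts <- function(counts, modality = c("rna", "atac"),
                             scale_factor = 1e4, pseudocount = 1,
                             log = TRUE) {
  modality <- match.arg(modality)
  x <- as_dgc(counts)
  if (any(x@x < 0)) stop("counts must be non-negative")
  if (modality == "atac" && length(x@x)) x@x[] <- 1
  tot <- Matrix::colSums(x)
  f <- ifelse(tot > 0, scale_factor / tot, 0)
  if (length(x@x)) x@x <- x@x * rep.int(f, diff(x@p))
  if (log) {
    if (pseudocount == 1) {
      if (length(x@x)) x@x <- log1p(x@x)
    } else {
      if (pseudocount <= 0) stop("pseudocount must be > 0 when log = TRUE")
      x <- as_dgc(log(pseudocount + as.matrix(x)) - log(pseudocount))
      # shift so that zero counts still map to zero values
    }
  }
  x
}

# deterministic seeded evaluation that restores the caller's RNG state;
# seed = NULL means "use the current RNG stream"
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

stop_missing_file <- function(path) {
  stop("required atlas file is missing or unreadable: ", path, call. = FALSE)
}
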