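# ---- gene activity ------------------------------------------------------

#' Gene activity scores from accessibility
#'
#' The accessibility-derived proxy for expression: for each gene, the sum
#' of reads in peaks overlapping the union of the gene body and the
#' `flank_bp` flanking the transcription start site on both sides. A peak
#' is counted in full whenever it overlaps the region at all (fragment
#' truncation is not recoverable from a peak-count matrix). Genes with no
#' overlapping peaks are kept as all-zero rows.
#'
#' @param atac_counts peak x cell count matrix; rownames are peak ids.
#' @param peaks data.frame `peak_id`, `chrom`, `start`, `end` (0-based
#'   half-open), matching the rows of `atac_counts`.
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`; the TSS is the interval start on the `+`
#'   strand and `end - 1` on the `-` strand.
#' @param flank_bp flank around the TSS (default 2 kb).
#' @param chromosomes optional chromosome universe; genes on chromosomes
#'   outside it are dropped with a warning.
#' @return sparse gene x cell matrix of activity scores, with the flank
#'   recorded in attribute `flank_bp`.
#' @export
gene_activity_scores <- function(atac_counts, peaks, genes,
                                 flank_bp = 2000, chromosomes = NULL) {
  stopifnot(nrow(atac_counts) == nrow(peaks))
  if (!is.null(chromosomes)) {
    bad <- !(genes$chrom %in% chromosomes)
    if (any(bad)) {
      warning("dropping gene(s) on unknown chromosome(s): ",
              paste(genes$gene_id[bad], collapse = ", "))
      genes <- genes[!bad, , drop = FALSE]
    }
  }
  if (!nrow(genes)) stop("no genes left to score")
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  # per gene: gene body plus the TSS flank, both 0-based half-open
  reg <- rbind(
    data.frame(gene = seq_len(nrow(genes)), chrom = genes$chrom,
               start = genes$start, end = genes$end),
    data.frame(gene = seq_len(nrow(genes)), chrom = genes$chrom,
               start = pmax(tss - flank_bp, 0L), end = tss + flank_bp))
  reg <- reg[reg$end > reg$start, , drop = FALSE]
  seqlev <- union(unique(peaks$chrom), unique(reg$chrom))
  reg_gr <- GenomicRanges::GRanges(
    seqnames = factor(reg$chrom, levels = seqlev),
    ranges = IRanges::IRanges(start = reg$start + 1L, end = reg$end))
  pk_gr <- GenomicRanges::GRanges(
    seqnames = factor(peaks$chrom, levels = seqlev),
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  ov <- GenomicRanges::findOverlaps(pk_gr, reg_gr)
  pairs <- unique(data.frame(peak = S4Vectors::queryHits(ov),
                             gene = reg$gene[S4Vectors::subjectHits(ov)]))
  ind <- Matrix::sparseMatrix(i = pairs$gene, j = pairs$peak, x = 1,
                              dims = c(nrow(genes), nrow(peaks)))
  scores <- ind %*% as_dgc(atac_counts)
  rownames(scores) <- genes$gene_id
  colnames(scores) <- colnames(atac_counts)
  attr(scores, "flank_bp") <- flank_bp
  scores
}

# ---- cluster profiles ---------------------------------------------------

#' Aggregate a count matrix into normalized cluster profiles
#'
#' Counts are summed per cluster, depth-normalized to `scale_factor` per
#' cluster total, and log-transformed after a pseudocount — the
#' cluster-level inputs of the NNLS decomposition.
#'
#' @param counts feature x cell matrix.
#' @param clusters cluster label per cell; every declared cluster must be
#'   non-empty.
#' @param scale_factor,pseudocount,log normalization record.
#' @return cluster x feature matrix (rows are clusters).
#' @export
cluster_profiles <- function(counts, clusters, scale_factor = 1e4,
                             pseudocount = 1, log = TRUE) {
  stopifnot(ncol(counts) == length(clusters))
  cl <- if (is.factor(clusters)) clusters else factor(clusters)
  if (any(table(cl) == 0)) {
    stop("empty cluster(s): ",
         paste(levels(cl)[table(cl) == 0], collapse = ", "))
  }
  ind <- Matrix::sparseMatrix(i = seq_along(cl), j = as.integer(cl),
                              x = 1,
                              dims = c(length(cl), nlevels(cl)))
  sums <- as.matrix(as_dgc(counts) %*% ind)
  tot <- colSums(sums)
  vals <- sweep(sums, 2, ifelse(tot > 0, scale_factor / tot, 0), "*")
  if (log) vals <- base::log(pseudocount + vals)
  out <- t(vals)
  rownames(out) <- levels(cl)
  colnames(out) <- rownames(counts)
  out
}

# ---- NNLS ---------------------------------------------------------------

#' Decompose target profiles as non-negative mixtures of source profiles
#'
#' For every target cluster profile t, solves `min ||t - S' beta||` with
#' `beta >= 0` over the source profiles S (Lawson-Hanson NNLS), then
#' rescales the coefficients to sum to one so they read as mixture
#' proportions. Features with zero variance across the sources are
#' dropped first.
#'
#' @param targets,sources cluster x feature matrices on a shared gene
#'   space (column names are matched).
#' @return list with `mixture` (targets x sources, rows summing to 1 or
#'   all-zero), `coefficients` (unscaled), `residuals` (per target).
#' @export
nnls_decompose <- function(targets, sources) {
  feats <- intersect(colnames(targets), colnames(sources))
  if (!length(feats)) stop("targets and sources share no features")
  S <- sources[, feats, drop = FALSE]
  Tm <- targets[, feats, drop = FALSE]
  keep <- apply(S, 2, var) > 1e-12
  if (!any(keep)) stop("all shared features have zero variance")
  S <- S[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]
  C <- t(S)
  coefs <- matrix(0, nrow(Tm), nrow(S),
                  dimnames = list(rownames(Tm), rownames(S)))
  resid <- numeric(nrow(Tm))
  for (i in seq_len(nrow(Tm))) {
    d <- Tm[i, ]
    if (all(d == 0)) {
      warning("all-zero target profile: ", rownames(Tm)[i])
      resid[i] <- 0
      next
    }
    fit <- pracma::lsqnonneg(C, d)
    coefs[i, ] <- fit$x
    resid[i] <- sqrt(fit$resid.norm)
  }
  rs <- rowSums(coefs)
  mixture <- coefs / ifelse(rs > 0, rs, 1)
  list(mixture = mixture, coefficients = coefs, residuals = resid)
}

#' Link clusters across modalities from bidirectional NNLS mixtures
#'
#' A pair is linked when its mixture coefficient strictly exceeds
#' `threshold` in both directions (or in a single direction with
#' `rule = "either"`); the combined score is the mean of the two
#' directional coefficients, and each cluster's best partner is the pair
#' with the highest combined score.
#'
#' @param coef_rna_from_atac RNA x ATAC mixture matrix (RNA profiles
#'   decomposed over ATAC-derived gene activity profiles).
#' @param coef_atac_from_rna ATAC x RNA mixture matrix (opposite
#'   direction).
#' @param threshold linkage threshold (strict).
#' @param rule `"both"` (default) or `"either"`.
#' @return data.frame `atac_cluster`, `rna_cluster`,
#'   `coef_rna_from_atac`, `coef_atac_from_rna`, `combined`, `linked`,
#'   `best_for_atac`, `best_for_rna`.
#' @export
link_clusters <- function(coef_rna_from_atac, coef_atac_from_rna,
                          threshold = 0.1, rule = c("both", "either")) {
  rule <- match.arg(rule)
  rna <- rownames(coef_rna_from_atac)
  atac <- rownames(coef_atac_from_rna)
  stopifnot(setequal(colnames(coef_rna_from_atac), atac),
            setequal(colnames(coef_atac_from_rna), rna))
  out <- expand.grid(atac_cluster = atac, rna_cluster = rna,
                     stringsAsFactors = FALSE)
  out$coef_rna_from_atac <-
    coef_rna_from_atac[cbind(out$rna_cluster, out$atac_cluster)]
  out$coef_atac_from_rna <-
    coef_atac_from_rna[cbind(out$atac_cluster, out$rna_cluster)]
  out$combined <- (out$coef_rna_from_atac + out$coef_atac_from_rna) / 2
  out$linked <- if (rule == "both") {
    out$coef_rna_from_atac > threshold & out$coef_atac_from_rna > threshold
  } else {
    out$coef_rna_from_atac > threshold | out$coef_atac_from_rna > threshold
  }
  best_a <- tapply(out$combined, out$atac_cluster, max)
  best_r <- tapply(out$combined, out$rna_cluster, max)
  out$best_for_atac <- out$combined == best_a[out$atac_cluster]
  out$best_for_rna <- out$combined == best_r[out$rna_cluster]
  out
}
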