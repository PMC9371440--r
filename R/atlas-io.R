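write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_checked <- function(path, ...) {
  if (!file.exists(path)) stop_missing_file(path)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Write a synthetic atlas to a directory of plain-text files
#'
#' Count matrices go to MatrixMarket files (features in rows), metadata to
#' TSV, peaks to BED (0-based half-open), and the generator configuration
#' to a deparsed text file, so that [read_atlas()] reproduces the object.
#'
#' @param atlas an `embryo_atlas` from [simulate_atlas()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "embryo_atlas"))
  dir.create(file.path(dir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  Matrix::writeMM(atlas$rna$counts, file.path(dir, "rna.mtx"))
  Matrix::writeMM(atlas$atac$counts, file.path(dir, "atac.mtx"))
  write_tsv(rbind(atlas$rna$cells, atlas$atac$cells),
            file.path(dir, "cells.tsv"))
  write_tsv(atlas$rna$features, file.path(dir, "genes.tsv"))
  pk <- atlas$atac$features
  # four-column BED, 0-based half-open
  write.table(pk[, c("chrom", "start", "end", "peak_id")],
              file.path(dir, "peaks.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_tsv(atlas$windows, file.path(dir, "windows.tsv"))
  mh <- as.data.frame(as.matrix(atlas$motif_hits))
  mh <- cbind(peak_id = rownames(atlas$motif_hits), mh)
  write_tsv(mh, file.path(dir, "motif_hits.tsv"))
  write_tsv(atlas$kinetics$genes,
            file.path(dir, "truth", "kinetics_genes.tsv"))
  write_tsv(atlas$kinetics$peaks,
            file.path(dir, "truth", "kinetics_peaks.tsv"))
  lt <- atlas$lineage_tree
  lt$epoch_width <- attr(atlas$lineage_tree, "epoch_width") %||% 2
  write_tsv(lt, file.path(dir, "truth", "lineage_tree.tsv"))
  tt <- atlas$tf_truth %||%
    data.frame(tf = character(), type = character(),
               germ_layer = character(), start_window = integer())
  write_tsv(tt, file.path(dir, "truth", "tf_truth.tsv"))
  write_tsv(atlas$peak_gene, file.path(dir, "truth", "peak_gene.tsv"))
  cfg <- atlas$config
  cfg$seed <- atlas$seed
  dput(cfg, file.path(dir, "config.txt"), control = c("all", "digits17"))
  invisible(dir)
}

read_mtx_checked <- function(path, rownames, colnames) {
  if (!file.exists(path)) stop_missing_file(path)
  m <- as_dgc(Matrix::readMM(path))
  if (nrow(m) != length(rownames) || ncol(m) != length(colnames)) {
    stop("matrix dimensions in ", path,
         " do not match the feature/cell metadata")
  }
  dimnames(m) <- list(rownames, colnames)
  m
}

#' Read an atlas written by [write_atlas()]
#'
#' @param dir directory containing the atlas files. A missing or
#'   inconsistent file raises an error naming its path.
#' @return an `embryo_atlas` object.
#' @export
read_atlas <- function(dir) {
  cfg_path <- file.path(dir, "config.txt")
  if (!file.exists(cfg_path)) stop_missing_file(cfg_path)
  cfg <- dget(cfg_path)
  seed <- cfg$seed
  cfg$seed <- NULL
  cells <- read_tsv_checked(file.path(dir, "cells.tsv"))
  genes <- read_tsv_checked(file.path(dir, "genes.tsv"))
  bed_path <- file.path(dir, "peaks.bed")
  if (!file.exists(bed_path)) stop_missing_file(bed_path)
  gr <- rtracklayer::import(bed_path, format = "bed")
  peaks <- data.frame(peak_id = gr$name,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE)
  peaks <- peaks[, c("peak_id", "chrom", "start", "end")]
  windows <- read_tsv_checked(file.path(dir, "windows.tsv"))
  mh_df <- read_tsv_checked(file.path(dir, "motif_hits.tsv"))
  motif_hits <- as_dgc(as.matrix(mh_df[, -1, drop = FALSE]))
  rownames(motif_hits) <- mh_df$peak_id
  kin_g <- read_tsv_checked(file.path(dir, "truth", "kinetics_genes.tsv"),
                            colClasses = list(lineage_mask = "character"))
  kin_p <- read_tsv_checked(file.path(dir, "truth", "kinetics_peaks.tsv"),
                            colClasses = list(lineage_mask = "character"))
  kin_g$lineage_mask[is.na(kin_g$lineage_mask)] <- ""
  kin_p$lineage_mask[is.na(kin_p$lineage_mask)] <- ""
  lt <- read_tsv_checked(file.path(dir, "truth", "lineage_tree.tsv"))
  ew <- lt$epoch_width[1]
  lt$epoch_width <- NULL
  attr(lt, "epoch_width") <- ew
  tt <- read_tsv_checked(file.path(dir, "truth", "tf_truth.tsv"))
  if (nrow(tt) == 0) tt <- NULL
  pg <- read_tsv_checked(file.path(dir, "truth", "peak_gene.tsv"))
  rna_cells <- cells[cells$modality == "rna", , drop = FALSE]
  atac_cells <- cells[cells$modality == "atac", , drop = FALSE]
  rownames(rna_cells) <- NULL
  rownames(atac_cells) <- NULL
  rna <- read_mtx_checked(file.path(dir, "rna.mtx"),
                          genes$gene_id, rna_cells$cell_id)
  atac <- read_mtx_checked(file.path(dir, "atac.mtx"),
                           peaks$peak_id, atac_cells$cell_id)
  structure(list(
    rna = list(counts = rna, cells = rna_cells, features = genes),
    atac = list(counts = atac, cells = atac_cells, features = peaks),
    windows = windows,
    kinetics = list(genes = kin_g, peaks = kin_p),
    lineage_tree = lt,
    motif_hits = motif_hits,
    tf_truth = tt,
    peak_gene = pg,
    config = cfg,
    seed = seed
  ), class = "embryo_atlas")
}
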