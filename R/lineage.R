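# ---- windowing ----------------------------------------------------------

#' Partition cells into non-overlapping inferred time windows
#'
#' Window label is `floor(age / width_h)` (left-closed); cells with
#' inferred age strictly above `max_age_h` are excluded (`NA`), since
#' predictions near the end of the sampled span suffer edge effects.
#'
#' @param ages inferred ages in hours.
#' @param width_h window width; must divide `max_age_h`.
#' @param max_age_h retention cutoff.
#' @return integer window label per cell (0-based), `NA` for excluded.
#' @export
window_partition <- function(ages, width_h = 2, max_age_h = 18) {
  if (width_h <= 0) stop("width_h must be positive")
  r <- max_age_h / width_h
  if (abs(r - round(r)) > 1e-8) stop("width_h must divide max_age_h")
  lab <- floor(ages / width_h)
  lab[is.na(ages) | ages > max_age_h] <- NA
  as.integer(lab)
}

# ---- embeddings ---------------------------------------------------------

# PCA scores of a cells x features matrix (densifies; per-window cell
# counts are modest)
pca_scores <- function(x, d, center = TRUE) {
  x <- as.matrix(x)
  d <- min(d, nrow(x) - 1L, ncol(x))
  pc <- prcomp(x, rank. = d, center = center, scale. = FALSE)
  pc$x
}

# TF-IDF transform of binarized accessibility (latent semantic indexing)
tfidf_transform <- function(counts) {
  x <- as_dgc(counts)
  if (length(x@x)) x@x[] <- 1
  tot <- Matrix::colSums(x)
  f <- ifelse(tot > 0, 1 / tot, 0)
  if (length(x@x)) x@x <- x@x * rep.int(f, diff(x@p))
  idf <- base::log(1 + ncol(x) / (Matrix::rowSums(x > 0) + 1))
  x * idf
}

embed_counts <- function(counts, modality, n_components) {
  m <- if (modality == "atac") {
    tfidf_transform(counts)
  } else {
    normalize_counts(counts, "rna")
  }
  pca_scores(Matrix::t(m), n_components)
}

#' Cluster the cells of one inferred time window
#'
#' Standard reduction plus community detection: PCA of log-normalized
#' expression (RNA) or TF-IDF + SVD of binarized accessibility (ATAC),
#' a k-nearest-neighbor graph in the reduced space, and Louvain modularity
#' communities.
#'
#' @param counts feature x cell count matrix for the window's cells.
#' @param modality `"rna"` or `"atac"`.
#' @param n_components embedding dimensionality.
#' @param n_neighbors neighbors for the kNN graph (lowered with a warning
#'   when the window has fewer cells).
#' @param resolution Louvain resolution.
#' @param seed integer seed.
#' @return integer cluster label per cell (1-based, named by cell).
#' @export
cluster_window <- function(counts, modality = c("rna", "atac"),
                           n_components = 30, n_neighbors = 15,
                           resolution = 1, seed = 1) {
  modality <- match.arg(modality)
  n <- ncol(counts)
  if (n < 2) stop("need at least 2 cells to cluster")
  if (n_neighbors >= n) {
    warning("n_neighbors >= number of cells; lowering to ", n - 1L)
    n_neighbors <- n - 1L
  }
  emb <- embed_counts(counts, modality, n_components)
  nn <- knn_indices(emb, emb, n_neighbors, exclude_self = TRUE)
  edges <- cbind(rep(seq_len(n), each = n_neighbors), as.vector(t(nn)))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges,
                                                    directed = FALSE))
  comm <- withr::with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  setNames(as.integer(igraph::membership(comm)),
           colnames(counts) %||% as.character(seq_len(n)))
}

#' Jointly embed cells of two adjacent inferred time windows
#'
#' Cells from the parent and child windows are concatenated over their
#' shared feature space and reduced together, so that nearest-neighbor
#' queries across the window boundary are meaningful.
#'
#' @param parent_counts,child_counts feature x cell count matrices.
#' @param modality `"rna"` or `"atac"`.
#' @param n_components embedding dimensionality (capped with a warning at
#'   the number of cells).
#' @param seed integer seed (reserved; the reduction is deterministic).
#' @return list with `coords` (cells x components) and `origin`
#'   (`"parent"`/`"child"` per row).
#' @export
coembed_adjacent <- function(parent_counts, child_counts,
                             modality = c("rna", "atac"),
                             n_components = 30, seed = 1) {
  modality <- match.arg(modality)
  shared <- intersect(rownames(parent_counts), rownames(child_counts))
  if (!length(shared)) stop("parent and child share no features")
  combined <- cbind(as_dgc(parent_counts)[shared, , drop = FALSE],
                    as_dgc(child_counts)[shared, , drop = FALSE])
  n <- ncol(combined)
  if (n_components >= n) {
    warning("n_components >= number of cells; capping at ", n - 1L)
    n_components <- n - 1L
  }
  coords <- embed_counts(combined, modality, n_components)
  list(coords = coords,
       origin = rep(c("parent", "child"),
                    c(ncol(parent_counts), ncol(child_counts))))
}

# k nearest rows of `ref` for each row of `query` (Euclidean); ties are
# broken by ascending reference index so results are order-deterministic
knn_indices <- function(query, ref, k, exclude_self = FALSE) {
  qn <- rowSums(query^2)
  rn <- rowSums(ref^2)
  d2 <- outer(qn, rn, "+") - 2 * tcrossprod(query, ref)
  if (exclude_self) diag(d2) <- Inf
  t(apply(d2, 1, function(row) {
    order(row, seq_along(row))[seq_len(k)]
  }))
}

# ---- linking ------------------------------------------------------------

#' Edge weights between parent and child cell states
#'
#' For every child-window cell, find its `k_neighbors` nearest
#' parent-window cells in the joint embedding; the weight of the edge
#' (parent state -> child state) is the median, over the child state's
#' cells, of the proportion of those neighbors belonging to the parent
#' state. States with fewer than `min_cells` members are excluded
#' (medians over tiny states are unstable).
#'
#' @param embedding output of [coembed_adjacent()] (or any list with
#'   `coords` and `origin`).
#' @param parent_states,child_states state label per parent / child cell,
#'   in the order the cells were given to the embedding.
#' @param k_neighbors neighbors per child cell.
#' @param min_cells minimum state size to participate.
#' @return data.frame `parent_state`, `child_state`, `weight`,
#'   `n_child_cells`.
#' @export
link_edge_weights <- function(embedding, parent_states, child_states,
                              k_neighbors = 30, min_cells = 20) {
  stopifnot(k_neighbors >= 1)
  P <- embedding$coords[embedding$origin == "parent", , drop = FALSE]
  C <- embedding$coords[embedding$origin == "child", , drop = FALSE]
  if (nrow(P) != length(parent_states) ||
      nrow(C) != length(child_states)) {
    stop("state labels do not match the embedding's cell counts")
  }
  if (nrow(P) == 0) stop("no parent cells present")
  ptab <- table(parent_states)
  keep_p <- parent_states %in% names(ptab)[ptab >= min_cells]
  if (!any(keep_p)) stop("no parent state reaches min_cells")
  P <- P[keep_p, , drop = FALSE]
  ps <- factor(parent_states[keep_p])
  ctab <- table(child_states)
  small_c <- names(ctab)[ctab < min_cells]
  if (length(small_c)) {
    warning("skipping child state(s) below min_cells: ",
            paste(small_c, collapse = ", "))
  }
  k <- min(k_neighbors, nrow(P))
  nn <- knn_indices(C, P, k)
  # per child cell, proportion of neighbors in each parent state
  prop <- matrix(0, nrow(C), nlevels(ps),
                 dimnames = list(NULL, levels(ps)))
  for (j in seq_len(nlevels(ps))) {
    prop[, j] <- rowSums(matrix(ps[nn] == levels(ps)[j],
                                nrow = nrow(C))) / k
  }
  out <- list()
  for (cs in setdiff(names(ctab), small_c)) {
    rows <- child_states == cs
    w <- apply(prop[rows, , drop = FALSE], 2, median)
    out[[cs]] <- data.frame(parent_state = levels(ps), child_state = cs,
                            weight = as.numeric(w),
                            n_child_cells = sum(rows),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble a lineage DAG from per-window-pair edge weights
#'
#' For each child state, only its maximum-weight incoming edge is kept,
#' and only if the weight strictly exceeds `threshold`; edges always point
#' from the earlier window to the later one, so the graph is acyclic by
#' construction and every child has in-degree at most one.
#'
#' @param weights a data.frame (or list of data.frames, one per adjacent
#'   window pair) with columns `parent_window`, `parent_state`,
#'   `child_window`, `child_state`, `weight`.
#' @param threshold retention threshold (strict).
#' @return object of class `lineage_dag`: list with `nodes`, `edges`,
#'   `threshold`, and an igraph `graph`.
#' @export
build_lineage_dag <- function(weights, threshold = 0.2) {
  if (is.data.frame(weights)) weights <- list(weights)
  w <- do.call(rbind, weights)
  need <- c("parent_window", "parent_state", "child_window",
            "child_state", "weight")
  if (!all(need %in% names(w))) {
    stop("weights need columns: ", paste(need, collapse = ", "))
  }
  if (any(w$weight < 0 | w$weight > 1)) {
    stop("weights must lie in [0, 1]")
  }
  if (any(w$child_window - w$parent_window != 1)) {
    stop("edges may only connect consecutive windows")
  }
  node_id <- function(win, st) sprintf("W%d|%s", win, st)
  key <- node_id(w$child_window, w$child_state)
  picked <- do.call(rbind, lapply(split(w, key), function(d) {
    d[which.max(d$weight), , drop = FALSE]
  }))
  edges <- picked[picked$weight > threshold, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- unique(rbind(
    data.frame(window = w$parent_window, state = w$parent_state),
    data.frame(window = w$child_window, state = w$child_state)))
  nodes <- nodes[order(nodes$window, nodes$state), , drop = FALSE]
  rownames(nodes) <- NULL
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = node_id(edges$parent_window,
                                  edges$parent_state),
                   to = node_id(edges$child_window, edges$child_state),
                   weight = edges$weight),
    directed = TRUE,
    vertices = data.frame(name = node_id(nodes$window, nodes$state),
                          window = nodes$window, state = nodes$state))
  stopifnot(igraph::is_dag(g))
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 graph = g),
            class = "lineage_dag")
}

#' @export
print.lineage_dag <- function(x, ...) {
  cat("lineage_dag:", nrow(x$nodes), "states,", nrow(x$edges),
      "edges (max-weight incoming edge per state, weight >",
      x$threshold, ")\n")
  invisible(x)
}
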