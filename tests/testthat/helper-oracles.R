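# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the code paths they check.

# DTW by exhaustive enumeration of all monotone warping paths
dtw_oracle <- function(x, y) {
  n <- length(x)
  m <- length(y)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + abs(x[i] - y[j])
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
    invisible()
  }
  walk(1, 1, 0)
  best
}

# Benjamini-Hochberg step-up by the literal definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(vapply(i:m, function(j) m * p[o[j]] / j,
                                   numeric(1))))
  }
  adj
}

# nearest-neighbor linkage weights by explicit loops
link_weights_oracle <- function(P, C, parent_states, child_states, k) {
  k <- min(k, nrow(P))
  states_p <- sort(unique(parent_states))
  res <- list()
  prop <- matrix(0, nrow(C), length(states_p),
                 dimnames = list(NULL, states_p))
  for (i in seq_len(nrow(C))) {
    d <- sqrt(colSums((t(P) - C[i, ])^2))
    nb <- order(d, seq_along(d))[seq_len(k)]
    for (s in states_p) {
      prop[i, s] <- sum(parent_states[nb] == s) / k
    }
  }
  for (cs in sort(unique(child_states))) {
    rows <- which(child_states == cs)
    for (s in states_p) {
      res[[length(res) + 1]] <- data.frame(
        parent_state = s, child_state = cs,
        weight = median(prop[rows, s]))
    }
  }
  do.call(rbind, res)
}

# gene activity by per-gene, per-peak interval arithmetic (0-based
# half-open; any overlap counts the whole peak)
gene_activity_oracle <- function(counts, peaks, genes, flank) {
  out <- matrix(0, nrow(genes), ncol(counts),
                dimnames = list(genes$gene_id, colnames(counts)))
  for (g in seq_len(nrow(genes))) {
    tss <- if (genes$strand[g] == "+") genes$start[g] else genes$end[g] - 1
    regions <- list(c(genes$start[g], genes$end[g]),
                    c(max(tss - flank, 0), tss + flank))
    for (p in seq_len(nrow(peaks))) {
      if (peaks$chrom[p] != genes$chrom[g]) next
      hit <- any(vapply(regions, function(r) {
        peaks$start[p] < r[2] && peaks$end[p] > r[1]
      }, logical(1)))
      if (hit) out[g, ] <- out[g, ] + as.numeric(counts[p, ])
    }
  }
  out
}

# grid search over the mixture simplex (with a free non-negative overall
# scale) for 2-3 sources
nnls_grid_oracle <- function(target, sources, step = 0.01) {
  k <- nrow(sources)
  stopifnot(k %in% c(2, 3))
  cand <- list()
  for (w1 in seq(0, 1, by = step)) {
    if (k == 2) {
      cand[[length(cand) + 1]] <- c(w1, 1 - w1)
    } else {
      for (w2 in seq(0, 1 - w1, by = step)) {
        cand[[length(cand) + 1]] <- c(w1, w2, 1 - w1 - w2)
      }
    }
  }
  best <- NULL
  best_err <- Inf
  for (w in cand) {
    u <- drop(w %*% sources)
    cc <- sum(u * target) / sum(u * u)
    if (!is.finite(cc) || cc < 0) cc <- 0
    err <- sum((target - cc * u)^2)
    if (err < best_err) {
      best_err <- err
      best <- w
    }
  }
  best
}

# plain evaluate_age recomputation
evaluate_age_oracle <- function(pred, widx, windows) {
  n <- length(pred)
  se <- numeric(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    w <- windows[windows$index == widx[i], ]
    se[i] <- (pred[i] - w$center_h)^2
    ok[i] <- pred[i] >= w$start_h && pred[i] <= w$end_h
  }
  list(mse = mean(se), proportion_correct = mean(ok))
}

# adjusted Rand index (used to score planted-partition recovery)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# bare temporal_profile constructor for hand-built matrices
make_profile <- function(values, bin_edges) {
  structure(list(values = values, bin_edges = bin_edges,
                 normalization = list(scale_factor = 1e4,
                                      pseudocount = 1, log = TRUE)),
            class = "temporal_profile")
}
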