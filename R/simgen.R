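#' Construct a table of timed collection windows
#'
#' @param start_h,end_h numeric vectors of window boundaries in hours.
#' @return data.frame with columns `index` (0-based), `start_h`, `end_h`,
#'   `center_h`. The center hour is the supervision label used by the age
#'   regressors.
#' @export
collection_windows <- function(start_h, end_h) {
  if (length(start_h) != length(end_h)) {
    stop("start_h and end_h must have equal length")
  }
  if (any(end_h <= start_h)) stop("each window must satisfy start_h < end_h")
  data.frame(
    index = seq_along(start_h) - 1L,
    start_h = as.numeric(start_h),
    end_h = as.numeric(end_h),
    center_h = (as.numeric(start_h) + as.numeric(end_h)) / 2
  )
}

#' Default overlapping collection-window schedule
#'
#' Eleven overlapping windows covering 0--20 h of embryogenesis: 2-hour
#' collections during the rapid early stages, 4-hour collections from 3 h
#' onward. Consecutive windows overlap, which is what lets the age model
#' interpolate between window centers.
#'
#' @return see [collection_windows()].
#' @export
default_window_schedule <- function() {
  collection_windows(
    start_h = c(0, 1, 2, 3, 5, 7, 9, 11, 13, 15, 16),
    end_h   = c(2, 3, 4, 7, 9, 11, 13, 15, 17, 19, 20)
  )
}

#' Sample true nuclear ages for one embryo collection
#'
#' Non-contaminant nuclei get ages uniform within the window. Contaminants
#' model carry-over of older embryos (which contribute disproportionately
#' many nuclei): their ages are uniform on `(end_h, max_age]`.
#'
#' @param window one row of a window table (list or data.frame with
#'   `start_h`, `end_h`).
#' @param n number of nuclei to draw.
#' @param contamination_rate probability that a nucleus is an old-embryo
#'   contaminant; must be `< 1`.
#' @param max_age upper bound of contaminant ages, hours.
#' @param seed optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @return data.frame with `true_age_h` and `is_contaminant`.
#' @export
sample_collection <- function(window, n, contamination_rate = 0,
                              max_age = 20, seed = NULL) {
  stopifnot(n >= 1, contamination_rate >= 0, contamination_rate < 1)
  if (contamination_rate > 0 && window$end_h >= max_age) {
    stop("contamination_rate > 0 but the contaminant age interval (",
         window$end_h, ", ", max_age, "] is empty")
  }
  with_seed_or_not(seed, {
    is_cont <- runif(n) < contamination_rate
    age <- numeric(n)
    age[!is_cont] <- runif(sum(!is_cont), window$start_h, window$end_h)
    age[is_cont] <- runif(sum(is_cont), window$end_h, max_age)
    data.frame(true_age_h = age, is_contaminant = is_cont)
  })
}

#' Expected expression of a feature at a given age
#'
#' Four kinetic classes cover the qualitative behaviours seen across
#' embryogenesis: `maternal` transcripts decay exponentially from
#' fertilization, `zygotic` genes switch on along a logistic centred at
#' `onset_h` with steepness `rate`, `transient` genes pulse as a Gaussian
#' bump at `onset_h` with width `1/rate`, and `constant` genes are flat.
#'
#' @param params a list or one-row data.frame with fields `class`,
#'   `onset_h`, `rate`, `amplitude` (and `access_lead_h` for
#'   [accessibility_mean()]).
#' @param age_h vector of ages in hours, within `[0, 20]`.
#' @return expected counts (same length as `age_h`).
#' @export
expression_mean <- function(params, age_h) {
  if (any(age_h < 0) || any(age_h > 20)) stop("age_h must lie in [0, 20]")
  amp <- params$amplitude
  rate <- params$rate
  if (amp < 0) stop("amplitude must be >= 0")
  if (rate <= 0) stop("rate must be > 0")
  switch(as.character(params$class),
    maternal  = amp * exp(-rate * age_h),
    zygotic   = amp / (1 + exp(-rate * (age_h - params$onset_h))),
    transient = amp * exp(-0.5 * (rate * (age_h - params$onset_h))^2),
    constant  = rep(amp, length(age_h)),
    stop("unknown kinetic class: ", params$class)
  )
}

#' Expected accessibility of a feature at a given age
#'
#' Identical functional form to [expression_mean()], with the onset shifted
#' earlier by `access_lead_h` (floored at 0). A positive lead models
#' pioneer-factor behaviour: chromatin opens before the linked gene is
#' expressed.
#'
#' @inheritParams expression_mean
#' @export
accessibility_mean <- function(params, age_h) {
  p <- as.list(params)
  lead <- p$access_lead_h %||% 0
  if (lead < 0) stop("access_lead_h must be >= 0")
  if (p$class %in% c("zygotic", "transient")) {
    p$onset_h <- max(p$onset_h - lead, 0)
  }
  expression_mean(p, age_h)
}

#' Build a lineage tree of cell states over developmental epochs
#'
#' States live in consecutive epochs of width `epoch_width` hours; each
#' state in epoch `e` has exactly one parent in epoch `e - 1`, assigned by
#' proportional position so the tree branches as the state count grows.
#' Once at least `length(layers)` states exist, top-level branches are
#' labelled with germ layers, inherited by descendants; earlier epochs are
#' `"unspecified"`.
#'
#' @param n_states_per_epoch integer vector, number of states per epoch
#'   (non-decreasing recommended, not required).
#' @param epoch_width epoch width in hours.
#' @param layers germ-layer labels to distribute over branches.
#' @return data.frame with `state`, `epoch`, `pos`, `parent`, `germ_layer`.
#' @export
make_lineage_tree <- function(n_states_per_epoch, epoch_width = 2,
                              layers = c("ectoderm", "mesoderm", "endoderm")) {
  stopifnot(length(n_states_per_epoch) >= 1, all(n_states_per_epoch >= 1),
            epoch_width > 0)
  rows <- list()
  prev <- NULL
  for (e in seq_along(n_states_per_epoch)) {
    n <- n_states_per_epoch[e]
    pos <- seq_len(n) - 1L
    state <- sprintf("E%d_S%d", e - 1L, pos)
    if (is.null(prev)) {
      parent <- rep(NA_character_, n)
    } else {
      parent <- prev$state[floor(pos * nrow(prev) / n) + 1L]
    }
    if (n >= length(layers)) {
      if (is.null(prev) || all(prev$germ_layer == "unspecified")) {
        layer <- layers[floor(pos * length(layers) / n) + 1L]
      } else {
        layer <- prev$germ_layer[match(parent, prev$state)]
      }
    } else {
      layer <- rep("unspecified", n)
    }
    prev <- data.frame(state = state, epoch = e - 1L, pos = pos,
                       parent = parent, germ_layer = layer,
                       stringsAsFactors = FALSE)
    rows[[e]] <- prev
  }
  tree <- do.call(rbind, rows)
  attr(tree, "epoch_width") <- epoch_width
  tree
}

#' @rdname make_lineage_tree
#' @export
default_lineage_tree <- function(epoch_width = 2) {
  make_lineage_tree(c(1, 1, 3, 3, 6, 6, 6, 6, 12, 12),
                    epoch_width = epoch_width)
}

# all states in the subtree rooted at `state` (including itself)
lineage_descendants <- function(tree, state) {
  out <- state
  frontier <- state
  repeat {
    kids <- tree$state[!is.na(tree$parent) & tree$parent %in% frontier]
    kids <- setdiff(kids, out)
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# epoch index for an age, clamped to the last epoch
age_to_epoch <- function(age_h, tree) {
  w <- attr(tree, "epoch_width") %||% 2
  pmin(floor(age_h / w), max(tree$epoch))
}

#' Configuration for the synthetic atlas generator
#'
#' Defaults emulate the study conditions of a whole-embryogenesis atlas:
#' 11 overlapping collection windows over 0--20 h, sparse RNA-like counts
#' (median depth target 399 UMIs per cell) and deeper ATAC-like counts
#' (target 5206 reads per cell), negative-binomial overdispersion, 3%
#' old-embryo contamination of windows that have room for it, a branching
#' lineage tree with germ-layer labels, pioneer accessibility leads of
#' 0.5 h on a subset of zygotic genes, and a bimodal chrX read fraction
#' determined by planted sex.
#'
#' @param windows collection-window table ([default_window_schedule()]).
#' @param cells_per_window_rna,cells_per_window_atac nuclei per window for
#'   each modality.
#' @param n_genes,n_peaks feature counts (TF genes are added on top of
#'   `n_genes`).
#' @param rna_depth,atac_depth per-cell depth targets (expected totals).
#' @param dispersion negative-binomial dispersion (`mu + dispersion * mu^2`
#'   variance); 0 gives the Poisson limit.
#' @param lib_sigma sdlog of the log-normal per-cell depth factor.
#' @param contamination_rate per-window contaminant probabilities; `NULL`
#'   means 0.03 wherever the window leaves room (`end_h < max_age`), else 0.
#' @param max_age end of embryogenesis, hours.
#' @param lineage lineage tree ([make_lineage_tree()]).
#' @param class_probs sampling probabilities of the four kinetic classes.
#' @param lineage_frac fraction of genes restricted to a random lineage
#'   subtree.
#' @param pioneer_frac fraction of zygotic genes whose linked peaks gain
#'   accessibility `access_lead_h` hours before expression onset.
#' @param access_lead_h the pioneer lead, hours.
#' @param n_tfs,tf_classes number of TF genes and how many are activators /
#'   repressors / nulls.
#' @param tf_effect multiplicative accessibility effect of an active TF at
#'   its motif peaks.
#' @param tf_motif_frac fraction of peaks hit by each TF motif.
#' @param chrX means/sd of the chrX read-fraction law for XX and XY nuclei.
#' @param kinetics optional pre-specified kinetic table overriding the
#'   generated gene kinetics (validated against the lineage tree).
#' @param chroms chromosome names over which features are laid out.
#' @return a validated config list for [simulate_atlas()].
#' @export
atlas_config <- function(windows = default_window_schedule(),
                         cells_per_window_rna = 1820,
                         cells_per_window_atac = 300,
                         n_genes = 1000,
                         n_peaks = 2500,
                         rna_depth = 399,
                         atac_depth = 5206,
                         dispersion = 0.5,
                         lib_sigma = 0.35,
                         contamination_rate = NULL,
                         max_age = 20,
                         lineage = default_lineage_tree(),
                         class_probs = c(maternal = 0.20, zygotic = 0.35,
                                         transient = 0.15, constant = 0.30),
                         lineage_frac = 0.3,
                         pioneer_frac = 0.3,
                         access_lead_h = 0.5,
                         n_tfs = 20,
                         tf_classes = c(activator = 5, repressor = 5,
                                        null = 10),
                         tf_effect = 1,
                         tf_motif_frac = 0.08,
                         chrX = list(xx_mean = 0.04, xy_mean = 0.02,
                                     sd = 0.004),
                         kinetics = NULL,
                         chroms = c("chr2L", "chr2R", "chr3L", "chr3R",
                                    "chrX")) {
  if (is.null(contamination_rate)) {
    contamination_rate <- ifelse(windows$end_h < max_age, 0.03, 0)
  }
  cfg <- list(windows = windows,
              cells_per_window_rna = cells_per_window_rna,
              cells_per_window_atac = cells_per_window_atac,
              n_genes = n_genes, n_peaks = n_peaks,
              rna_depth = rna_depth, atac_depth = atac_depth,
              dispersion = dispersion, lib_sigma = lib_sigma,
              contamination_rate = contamination_rate, max_age = max_age,
              lineage = lineage, class_probs = class_probs,
              lineage_frac = lineage_frac, pioneer_frac = pioneer_frac,
              access_lead_h = access_lead_h, n_tfs = n_tfs,
              tf_classes = tf_classes, tf_effect = tf_effect,
              tf_motif_frac = tf_motif_frac, chrX = chrX,
              kinetics = kinetics, chroms = chroms)
  validate_atlas_config(cfg)
  cfg
}

validate_atlas_config <- function(cfg) {
  if (cfg$n_genes < 1 || cfg$n_peaks < 1) {
    stop("config must specify at least one gene and one peak")
  }
  if (sum(cfg$tf_classes) != cfg$n_tfs) {
    stop("tf_classes must sum to n_tfs")
  }
  if (length(cfg$contamination_rate) == 1) {
    cfg$contamination_rate <- rep(cfg$contamination_rate,
                                  nrow(cfg$windows))
  }
  if (length(cfg$contamination_rate) != nrow(cfg$windows)) {
    stop("contamination_rate must have one value per window")
  }
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (!is.null(cfg$kinetics)) {
    k <- cfg$kinetics
    need <- c("feature_id", "class", "onset_h", "rate", "amplitude",
              "lineage_mask", "access_lead_h")
    if (!all(need %in% names(k))) {
      stop("kinetics table must have columns: ", paste(need, collapse = ", "))
    }
    masks <- unlist(strsplit(k$lineage_mask[k$lineage_mask != ""], ","))
    unknown <- setdiff(masks, cfg$lineage$state)
    if (length(unknown)) {
      stop("kinetics lineage_mask refers to states absent from the lineage ",
           "tree: ", paste(unique(unknown), collapse = ", "))
    }
  }
  invisible(cfg)
}

# draw per-gene kinetic parameters
generate_kinetics <- function(cfg, n, prefix = "gene") {
  cls <- sample(names(cfg$class_probs), n, replace = TRUE,
                prob = cfg$class_probs)
  # genes keep switching on until the end of embryogenesis (terminal
  # differentiation), so onsets span the whole sampled range
  onset <- runif(n, 0.5, 19)
  rate <- numeric(n)
  rate[cls == "maternal"] <- runif(sum(cls == "maternal"), 0.2, 1)
  rate[cls == "zygotic"] <- runif(sum(cls == "zygotic"), 1.5, 6)
  rate[cls == "transient"] <- runif(sum(cls == "transient"), 0.8, 2.5)
  rate[cls == "constant"] <- 1
  onset[cls %in% c("maternal", "constant")] <- 0
  amp <- rlnorm(n, meanlog = 1, sdlog = 1)
  lead <- numeric(n)
  zy <- which(cls == "zygotic")
  if (length(zy)) {
    pio <- sample(zy, round(cfg$pioneer_frac * length(zy)))
    lead[pio] <- cfg$access_lead_h
  }
  mask <- rep("", n)
  cand <- cfg$lineage$state[cfg$lineage$epoch > 0]
  if (cfg$lineage_frac > 0 && length(cand)) {
    pick <- sample(n, round(cfg$lineage_frac * n))
    roots <- sample(cand, length(pick), replace = TRUE)
    mask[pick] <- vapply(roots, function(s) {
      paste(lineage_descendants(cfg$lineage, s), collapse = ",")
    }, character(1))
  }
  data.frame(feature_id = sprintf("%s%04d", prefix, seq_len(n)),
             class = cls, onset_h = onset, rate = rate, amplitude = amp,
             lineage_mask = mask, access_lead_h = lead,
             stringsAsFactors = FALSE)
}

# lay gene bodies along synthetic chromosomes (0-based half-open)
generate_gene_models <- function(ids, chroms) {
  n <- length(ids)
  chrom <- chroms[((seq_len(n) - 1L) %% length(chroms)) + 1L]
  idx_on_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- 5000L + (idx_on_chrom - 1L) * 10000L
  data.frame(gene_id = ids, chrom = chrom, start = start,
             end = start + 2000L,
             strand = ifelse(seq_len(n) %% 2 == 1, "+", "-"),
             stringsAsFactors = FALSE)
}

# sample cell-level records for one modality
generate_cells <- function(cfg, n_per_window, modality) {
  out <- vector("list", nrow(cfg$windows))
  for (i in seq_len(nrow(cfg$windows))) {
    w <- cfg$windows[i, ]
    draw <- sample_collection(w, n_per_window,
                              contamination_rate = cfg$contamination_rate[i],
                              max_age = cfg$max_age)
    draw$window_index <- w$index
    out[[i]] <- draw
  }
  cells <- do.call(rbind, out)
  n <- nrow(cells)
  cells$cell_id <- sprintf("%s_%06d", modality, seq_len(n))
  epoch <- age_to_epoch(cells$true_age_h, cfg$lineage)
  cells$lineage <- vapply(epoch, function(e) {
    s <- cfg$lineage$state[cfg$lineage$epoch == e]
    s[sample.int(length(s), 1)]
  }, character(1))
  cells$germ_layer <- cfg$lineage$germ_layer[match(cells$lineage,
                                                  cfg$lineage$state)]
  cells$sex <- ifelse(runif(n) < 0.5, "XX", "XY")
  mu <- ifelse(cells$sex == "XX", cfg$chrX$xx_mean, cfg$chrX$xy_mean)
  cells$chrX_fraction <- pmin(pmax(rnorm(n, mu, cfg$chrX$sd), 0), 1)
  cells$modality <- modality
  cells[, c("cell_id", "modality", "window_index", "true_age_h", "lineage",
            "germ_layer", "is_contaminant", "chrX_fraction", "sex")]
}

# expected-count matrix (cells x features) under the planted kinetics
kinetic_mean_matrix <- function(kin, ages, states, mean_fun) {
  m <- matrix(0, nrow = length(ages), ncol = nrow(kin))
  for (j in seq_len(nrow(kin))) {
    mu <- mean_fun(kin[j, ], ages)
    if (nzchar(kin$lineage_mask[j])) {
      ok <- states %in% strsplit(kin$lineage_mask[j], ",")[[1]]
      mu[!ok] <- 0
    }
    m[, j] <- mu
  }
  colnames(m) <- kin$feature_id
  m
}

# scale rows to per-cell depth targets, add noise, sparsify (features x cells)
draw_counts <- function(mean_mat, depth, lib_sigma, dispersion) {
  n <- nrow(mean_mat)
  target <- depth * exp(rnorm(n, 0, lib_sigma))
  rs <- rowSums(mean_mat)
  rs[rs <= 0] <- 1
  mean_mat <- mean_mat * (target / rs)
  k <- length(mean_mat)
  cnt <- if (dispersion > 0) {
    rnbinom(k, mu = as.numeric(mean_mat), size = 1 / dispersion)
  } else {
    rpois(k, as.numeric(mean_mat))
  }
  cnt <- matrix(cnt, nrow = n, dimnames = dimnames(mean_mat))
  as_dgc(t(cnt))
}

#' Simulate a multi-window, two-modality embryo atlas with planted truth
#'
#' Generates RNA-like and ATAC-like sparse count matrices over the
#' configured collection windows. Every latent quantity downstream modules
#' try to recover is recorded: true nuclear ages and contamination flags,
#' lineage states and germ layers, kinetic parameters (including pioneer
#' accessibility leads), peak-gene links, motif hit tables, TF truth
#' (activator/repressor/null, germ layer, start window), and planted sex
#' with its chrX read fraction.
#'
#' @param config list from [atlas_config()].
#' @param seed integer seed; identical config + seed reproduce the atlas
#'   exactly.
#' @return an object of class `embryo_atlas`: a list with elements `rna`
#'   and `atac` (each `counts` feature x cell sparse matrix, `cells`,
#'   `features`), `windows`, `kinetics` (`genes`, `peaks`), `lineage_tree`,
#'   `motif_hits` (peak x TF 0/1 sparse), `tf_truth`, `peak_gene`,
#'   `config`, `seed`.
#' @export
simulate_atlas <- function(config = atlas_config(), seed = 1) {
  cfg <- config
  validate_atlas_config(cfg)
  if (length(cfg$contamination_rate) == 1) {
    cfg$contamination_rate <- rep(cfg$contamination_rate, nrow(cfg$windows))
  }
  withr::with_seed(seed, {
    ## gene kinetics (regular genes + TF genes)
    kin_g <- cfg$kinetics %||% generate_kinetics(cfg, cfg$n_genes)
    tf_truth <- NULL
    if (cfg$n_tfs > 0) {
      layers <- setdiff(unique(cfg$lineage$germ_layer), "unspecified")
      if (!length(layers)) layers <- "unspecified"
      tf_ids <- sprintf("TF%02d", seq_len(cfg$n_tfs))
      type <- rep(names(cfg$tf_classes), cfg$tf_classes)
      start_w <- sample(2:6, cfg$n_tfs, replace = TRUE)
      tf_truth <- data.frame(
        tf = tf_ids, type = type,
        germ_layer = sample(layers, cfg$n_tfs, replace = TRUE),
        start_window = start_w, stringsAsFactors = FALSE)
      tf_layer_mask <- vapply(seq_len(cfg$n_tfs), function(i) {
        st <- cfg$lineage$state[
          cfg$lineage$germ_layer == tf_truth$germ_layer[i]]
        paste(st, collapse = ",")
      }, character(1))
      kin_tf <- data.frame(
        feature_id = tf_ids, class = "zygotic",
        onset_h = 2 * start_w, rate = runif(cfg$n_tfs, 2, 4),
        amplitude = rlnorm(cfg$n_tfs, 1, 0.5),
        lineage_mask = tf_layer_mask, access_lead_h = 0,
        stringsAsFactors = FALSE)
      kin_g <- rbind(kin_g, kin_tf)
    }
    genes <- generate_gene_models(kin_g$feature_id, cfg$chroms)

    ## peaks: up to 2 linked peaks per gene + intergenic background
    per_gene <- min(2L, max(1L, cfg$n_peaks %/% nrow(genes)))
    n_linked <- per_gene * nrow(genes)
    if (n_linked > cfg$n_peaks) {
      stop("n_peaks too small for one linked peak per gene")
    }
    offs <- c(-1500L, 300L)[seq_len(per_gene)]
    link_gene <- rep(seq_len(nrow(genes)), each = per_gene)
    pk_start <- pmax(genes$start[link_gene] + rep(offs, nrow(genes)), 0L)
    n_bg <- cfg$n_peaks - n_linked
    kin_p <- kin_g[link_gene, ]
    peak_ids <- sprintf("peak%05d", seq_len(cfg$n_peaks))
    peaks <- data.frame(
      peak_id = peak_ids,
      chrom = c(genes$chrom[link_gene],
                sample(cfg$chroms, n_bg, replace = TRUE)),
      start = c(pk_start,
                2000000L + 1000L * seq_len(n_bg)),
      stringsAsFactors = FALSE)
    peaks$end <- peaks$start + 400L
    peak_gene <- data.frame(peak_id = peak_ids,
                            gene_id = c(genes$gene_id[link_gene],
                                        rep(NA_character_, n_bg)),
                            stringsAsFactors = FALSE)
    if (n_bg > 0) {
      kin_bg <- generate_kinetics(cfg, n_bg, prefix = "bgpk")
      kin_p <- rbind(kin_p, kin_bg)
    }
    kin_p$feature_id <- peak_ids
    rownames(kin_p) <- NULL

    ## motif hit table
    motif_hits <- Matrix::Matrix(0, nrow = cfg$n_peaks,
                                 ncol = max(cfg$n_tfs, 1), sparse = TRUE)
    rownames(motif_hits) <- peak_ids
    if (cfg$n_tfs > 0) {
      colnames(motif_hits) <- tf_truth$tf
      n_hit <- max(1L, round(cfg$tf_motif_frac * cfg$n_peaks))
      for (i in seq_len(cfg$n_tfs)) {
        motif_hits[sample.int(cfg$n_peaks, n_hit), i] <- 1
      }
    }

    ## RNA modality
    rna_cells <- generate_cells(cfg, cfg$cells_per_window_rna, "rna")
    m_rna <- kinetic_mean_matrix(kin_g, rna_cells$true_age_h,
                                 rna_cells$lineage, expression_mean)
    rna_counts <- draw_counts(m_rna, cfg$rna_depth, cfg$lib_sigma,
                              cfg$dispersion)
    colnames(rna_counts) <- rna_cells$cell_id
    rm(m_rna)

    ## ATAC modality (accessibility kinetics + TF motif modulation)
    atac_cells <- generate_cells(cfg, cfg$cells_per_window_atac, "atac")
    m_atac <- kinetic_mean_matrix(kin_p, atac_cells$true_age_h,
                                  atac_cells$lineage, accessibility_mean)
    if (cfg$n_tfs > 0 && cfg$tf_effect > 0) {
      for (i in seq_len(cfg$n_tfs)) {
        if (tf_truth$type[i] == "null") next
        active <- atac_cells$germ_layer == tf_truth$germ_layer[i] &
          atac_cells$true_age_h >= 2 * tf_truth$start_window[i]
        if (!any(active)) next
        pk <- which(motif_hits[, i] > 0)
        f <- if (tf_truth$type[i] == "activator") {
          1 + cfg$tf_effect
        } else {
          1 / (1 + cfg$tf_effect)
        }
        m_atac[active, pk] <- m_atac[active, pk] * f
      }
    }
    atac_counts <- draw_counts(m_atac, cfg$atac_depth, cfg$lib_sigma,
                               cfg$dispersion)
    colnames(atac_counts) <- atac_cells$cell_id
    rm(m_atac)

    structure(list(
      rna = list(counts = rna_counts, cells = rna_cells, features = genes),
      atac = list(counts = atac_counts, cells = atac_cells,
                  features = peaks),
      windows = cfg$windows,
      kinetics = list(genes = kin_g, peaks = kin_p),
      lineage_tree = cfg$lineage,
      motif_hits = motif_hits,
      tf_truth = tf_truth,
      peak_gene = peak_gene,
      config = cfg,
      seed = seed
    ), class = "embryo_atlas")
  })
}

#' @export
print.embryo_atlas <- function(x, ...) {
  cat("embryo_atlas:",
      ncol(x$rna$counts), "RNA cells x", nrow(x$rna$counts), "genes;",
      ncol(x$atac$counts), "ATAC cells x", nrow(x$atac$counts), "peaks;",
      nrow(x$windows), "collection windows; seed", x$seed, "\n")
  invisible(x)
}

#' Simulate a cluster-level TF activity panel with planted regulators
#'
#' Produces the inputs of the germ-layer-by-time TF model directly at
#' cluster resolution: a TF x cluster expression matrix and a TF x cluster
#' motif-deviation matrix over `n_windows` time windows, with planted
#' activators (deviation rises with the TF's expression in one germ layer
#' from a start window onward), repressors (deviation falls), and nulls
#' (deviation is pure noise).
#'
#' @param n_windows number of consecutive 2-h inferred time windows.
#' @param clusters_per_layer clusters per germ layer per window.
#' @param layers germ-layer labels.
#' @param n_activators,n_repressors,n_null TF counts per planted type.
#' @param effect absolute deviation change per unit expression when active.
#' @param noise_sd standard deviation of the deviation noise.
#' @param expr_range uniform range of cluster-level TF expression.
#' @param coupling `"interaction"` (default) couples deviation to
#'   expression only in the planted germ layer from the start window
#'   onward — the structure the germ-layer-by-time model detects;
#'   `"global"` couples deviation to expression in every cluster — the
#'   structure the expression-deviation correlation reads out (an
#'   activator's motif accessibility tracks its expression wherever it is
#'   expressed).
#' @param seed integer seed.
#' @return list with `expression`, `deviations` (both TF x cluster),
#'   `cluster_meta` (`cluster`, `window`, `germ_layer`) and `tf_truth`.
#' @export
simulate_tf_panel <- function(n_windows = 9, clusters_per_layer = 3,
                              layers = c("ectoderm", "mesoderm",
                                         "endoderm"),
                              n_activators = 5, n_repressors = 5,
                              n_null = 10, effect = 2, noise_sd = 0.05,
                              expr_range = c(0.5, 2),
                              coupling = c("interaction", "global"),
                              seed = 1) {
  coupling <- match.arg(coupling)
  stopifnot(n_windows >= 4, clusters_per_layer >= 1, length(layers) >= 2)
  withr::with_seed(seed, {
    meta <- expand.grid(window = seq_len(n_windows) - 1L,
                        germ_layer = layers,
                        rep = seq_len(clusters_per_layer),
                        stringsAsFactors = FALSE)
    meta$cluster <- sprintf("W%d_%s_%d", meta$window,
                            substr(meta$germ_layer, 1, 4), meta$rep)
    meta <- meta[, c("cluster", "window", "germ_layer")]
    n_tf <- n_activators + n_repressors + n_null
    tf <- sprintf("TF%02d", seq_len(n_tf))
    type <- c(rep("activator", n_activators),
              rep("repressor", n_repressors), rep("null", n_null))
    planted <- type != "null"
    start_w <- rep(NA_integer_, n_tf)
    start_w[planted] <- sample(1:(n_windows - 3), sum(planted),
                               replace = TRUE)
    layer <- rep(NA_character_, n_tf)
    layer[planted] <- sample(layers, sum(planted), replace = TRUE)
    truth <- data.frame(tf = tf, type = type, germ_layer = layer,
                        start_window = start_w, stringsAsFactors = FALSE)
    nc <- nrow(meta)
    expr <- matrix(runif(n_tf * nc, expr_range[1], expr_range[2]),
                   nrow = n_tf, dimnames = list(tf, meta$cluster))
    dev <- matrix(rnorm(n_tf * nc, 0, noise_sd),
                  nrow = n_tf, dimnames = list(tf, meta$cluster))
    for (i in which(planted)) {
      on <- if (coupling == "global") {
        rep(TRUE, nc)
      } else {
        meta$germ_layer == truth$germ_layer[i] &
          meta$window >= truth$start_window[i]
      }
      b <- if (truth$type[i] == "activator") effect else -effect
      dev[i, on] <- dev[i, on] + b * expr[i, on]
    }
    list(expression = expr, deviations = dev, cluster_meta = meta,
         tf_truth = truth)
  })
}
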