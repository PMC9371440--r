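# Heavy fixtures are built once per test run and cached; every fixture is
# generated in code under a fixed seed.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small atlas for unit-level checks (seconds to build)
small_atlas <- function() {
  cached("small_atlas", function() {
    cfg <- atlas_config(cells_per_window_rna = 120,
                        cells_per_window_atac = 40,
                        n_genes = 150, n_peaks = 360)
    simulate_atlas(cfg, seed = 42)
  })
}

# the full-scale study atlas (~20,000 RNA cells, 11 windows) plus trained
# lasso and NN age models with an 11-way partition (train on 10, hold out
# the 11th)
study_atlas <- function() {
  cached("study_atlas", function() simulate_atlas(atlas_config(), seed = 1))
}

study_models <- function() {
  cached("study_models", function() {
    at <- study_atlas()
    cells <- at$rna$cells
    part <- partition_cells(cells$window_index, 11, seed = 1)
    train <- part != 11
    lasso <- fit_lasso_age(at$rna$counts[, train],
                           cells$window_index[train], at$windows,
                           n_features = 2000, n_folds = 10, seed = 1)
    nn <- fit_nn_age(at$rna$counts[, train], cells$window_index[train],
                     at$windows, n_features = 2000,
                     hyper_grid = list(list(hidden = c(64, 32),
                                            learning_rate = 3e-3)),
                     seed = 1, max_epochs = 40)
    list(partition = part, lasso = lasso, nn = nn)
  })
}

# kinetic table for a ZGA-focused simulation: mostly stable background,
# 50 zygotic genes with onsets tiling 0.5-2 h and a 0.5 h pioneer lead
zga_kinetics <- function(lead = 0.5) {
  data.frame(
    feature_id = sprintf("g%03d", 1:400),
    class = c(rep("constant", 250), rep("maternal", 100),
              rep("zygotic", 50)),
    onset_h = c(rep(0, 350), seq(0.5, 2, length.out = 50)),
    rate = c(rep(1, 250), rep(0.5, 100), rep(6, 50)),
    amplitude = c(rep(2, 350), rep(4, 50)),
    lineage_mask = "",
    access_lead_h = c(rep(0, 350), rep(lead, 50)))
}

no_tf <- c(activator = 0, repressor = 0, null = 0)

zga_atlas <- function() {
  cached("zga_atlas", function() {
    cfg <- atlas_config(windows = collection_windows(0, 3),
                        cells_per_window_rna = 12000,
                        cells_per_window_atac = 9000,
                        n_genes = 400, n_peaks = 810,
                        contamination_rate = 0,
                        lineage = make_lineage_tree(1, epoch_width = 20),
                        lineage_frac = 0, n_tfs = 0, tf_classes = no_tf,
                        kinetics = zga_kinetics())
    simulate_atlas(cfg, seed = 7)
  })
}

# 12-state binary lineage tree over 4 windows with inherited markers
lineage_atlas <- function() {
  cached("lineage_atlas", function() {
    tree <- make_lineage_tree(c(2, 2, 4, 4), epoch_width = 2)
    kin <- do.call(rbind, lapply(seq_len(nrow(tree)), function(i) {
      data.frame(feature_id = sprintf("mk_%s_%02d", tree$state[i], 1:15),
                 class = "constant", onset_h = 0, rate = 1, amplitude = 6,
                 lineage_mask = paste(
                   embryochron:::lineage_descendants(tree, tree$state[i]),
                   collapse = ","),
                 access_lead_h = 0)
    }))
    kin <- rbind(kin,
                 data.frame(feature_id = sprintf("base%03d", 1:120),
                            class = "constant", onset_h = 0, rate = 1,
                            amplitude = 2, lineage_mask = "",
                            access_lead_h = 0))
    cfg <- atlas_config(windows = collection_windows(c(0, 2, 4, 6),
                                                     c(2, 4, 6, 8)),
                        cells_per_window_rna = 800,
                        cells_per_window_atac = 50,
                        n_genes = nrow(kin), n_peaks = 600,
                        rna_depth = 600, contamination_rate = 0,
                        lineage = tree, lineage_frac = 0, n_tfs = 0,
                        tf_classes = no_tf, kinetics = kin)
    list(atlas = simulate_atlas(cfg, seed = 11), tree = tree)
  })
}

# 10 matched cluster pairs sharing kinetic programs across modalities
matched_cluster_atlas <- function() {
  cached("matched_cluster_atlas", function() {
    tree <- make_lineage_tree(10, epoch_width = 20)
    kin <- do.call(rbind, lapply(1:10, function(i) {
      data.frame(feature_id = sprintf("mk_S%d_%02d", i - 1, 1:30),
                 class = "constant", onset_h = 0, rate = 1, amplitude = 5,
                 lineage_mask = sprintf("E0_S%d", i - 1),
                 access_lead_h = 0)
    }))
    kin <- rbind(kin,
                 data.frame(feature_id = sprintf("base%03d", 1:100),
                            class = "constant", onset_h = 0, rate = 1,
                            amplitude = 1, lineage_mask = "",
                            access_lead_h = 0))
    cfg <- atlas_config(windows = collection_windows(0, 20),
                        cells_per_window_rna = 1500,
                        cells_per_window_atac = 1500,
                        n_genes = nrow(kin), n_peaks = 810,
                        rna_depth = 500, atac_depth = 2000,
                        contamination_rate = 0, lineage = tree,
                        lineage_frac = 0, n_tfs = 0, tf_classes = no_tf,
                        kinetics = kin)
    simulate_atlas(cfg, seed = 21)
  })
}

# pulse-dominated kinetics where the age map is strongly nonlinear
pulse_atlas <- function() {
  cached("pulse_atlas", function() {
    n_g <- 40
    kin <- data.frame(
      feature_id = sprintf("g%03d", 1:n_g),
      class = rep(c("transient", "zygotic"), c(30, 10)),
      onset_h = c(rep(seq(2, 18, by = 2), length.out = 30),
                  rep(c(5, 15), 5)),
      rate = c(rep(1.5, 30), rep(6, 10)),
      amplitude = 8, lineage_mask = "", access_lead_h = 0)
    cfg <- atlas_config(cells_per_window_rna = 700,
                        cells_per_window_atac = 20, n_genes = n_g,
                        n_peaks = 120, rna_depth = 800,
                        contamination_rate = 0,
                        lineage = make_lineage_tree(1, epoch_width = 20),
                        lineage_frac = 0, n_tfs = 0, tf_classes = no_tf,
                        kinetics = kin)
    simulate_atlas(cfg, seed = 2)
  })
}

# run the full window-cluster / coembed / link / DAG pipeline on an atlas
# with known lineage states; returns recovered truth-level edges
recover_lineage_edges <- function(atlas, tree, k_neighbors = 30,
                                  threshold = 0.2) {
  cells <- atlas$rna$cells
  wl <- window_partition(cells$true_age_h, 2, max(tree$epoch + 1) * 2)
  labs <- rep(NA_integer_, nrow(cells))
  majority <- list()
  for (wi in sort(unique(wl[!is.na(wl)]))) {
    idx <- which(wl == wi)
    cl <- cluster_window(atlas$rna$counts[, idx], "rna",
                         n_components = 20, seed = 1 + wi)
    labs[idx] <- cl
    tab <- table(cl, cells$lineage[idx])
    majority[[as.character(wi)]] <-
      setNames(colnames(tab)[apply(tab, 1, which.max)], rownames(tab))
  }
  weights <- list()
  wins <- sort(unique(wl[!is.na(wl)]))
  for (wi in wins[-length(wins)]) {
    pi <- which(wl == wi)
    ci <- which(wl == wi + 1)
    em <- coembed_adjacent(atlas$rna$counts[, pi],
                           atlas$rna$counts[, ci], "rna",
                           n_components = 20)
    wt <- link_edge_weights(em, labs[pi], labs[ci],
                            k_neighbors = k_neighbors)
    wt$parent_window <- wi
    wt$child_window <- wi + 1
    weights[[length(weights) + 1]] <- wt
  }
  dag <- build_lineage_dag(weights, threshold = threshold)
  edges <- dag$edges
  edges$p_true <- mapply(function(w, s) majority[[as.character(w)]][
    as.character(s)], edges$parent_window, edges$parent_state)
  edges$c_true <- mapply(function(w, s) majority[[as.character(w)]][
    as.character(s)], edges$child_window, edges$child_state)
  list(dag = dag, edges = edges)
}
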