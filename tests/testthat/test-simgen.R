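test_that("default window schedule covers embryogenesis with overlaps", {
  w <- default_window_schedule()
  expect_equal(nrow(w), 11)
  expect_equal(w$start_h[1], 0)
  expect_equal(max(w$end_h), 20)
  expect_equal(w$center_h, (w$start_h + w$end_h) / 2)
  expect_equal(w$center_h[1], 1.0)
  # first three windows are 2 h, the rest 4 h
  expect_equal(w$end_h - w$start_h, c(2, 2, 2, rep(4, 8)))
  # every consecutive pair overlaps
  expect_true(all(w$start_h[-1] < w$end_h[-11]))
  expect_error(collection_windows(2, 2), "start_h < end_h")
})

test_that("sample_collection respects window bounds and contamination", {
  w <- list(start_h = 0, end_h = 2)
  pure <- sample_collection(w, 1000, contamination_rate = 0, seed = 3)
  expect_true(all(pure$true_age_h >= 0 & pure$true_age_h <= 2))
  expect_false(any(pure$is_contaminant))

  draw <- sample_collection(w, 10000, contamination_rate = 0.03,
                            max_age = 20, seed = 1)
  frac <- mean(draw$is_contaminant)
  # binomial oracle: 0.03 +/- 3 * sqrt(p(1-p)/n)
  expect_lt(abs(frac - 0.03), 3 * sqrt(0.03 * 0.97 / 10000))
  expect_true(all(draw$true_age_h[draw$is_contaminant] > 2))
  expect_true(all(draw$true_age_h[draw$is_contaminant] <= 20))

  a <- sample_collection(w, 4, contamination_rate = 0, seed = 7)
  b <- sample_collection(w, 4, contamination_rate = 0, seed = 7)
  expect_identical(a, b)

  expect_error(sample_collection(list(start_h = 16, end_h = 20), 10,
                                 contamination_rate = 0.03, max_age = 20),
               "empty")
})

test_that("kinetic means follow their closed forms", {
  mat <- list(class = "maternal", onset_h = 0, rate = 0.5, amplitude = 7)
  expect_equal(expression_mean(mat, 0), 7)
  expect_equal(expression_mean(mat, 4), 7 * exp(-2))

  zyg <- list(class = "zygotic", onset_h = 8, rate = 2, amplitude = 10)
  expect_equal(expression_mean(zyg, 8), 5)
  # ten logistic widths before onset: essentially silent
  expect_lt(expression_mean(zyg, 8 - 10 / 2), 1e-4 * 10)

  tra <- list(class = "transient", onset_h = 6, rate = 1, amplitude = 3)
  expect_equal(expression_mean(tra, 6), 3)
  expect_equal(expression_mean(tra, 7), 3 * exp(-0.5))

  con <- list(class = "constant", onset_h = 0, rate = 1, amplitude = 2)
  expect_equal(expression_mean(con, c(1, 19)), c(2, 2))

  expect_error(expression_mean(list(class = "bogus", onset_h = 0,
                                    rate = 1, amplitude = 1), 1),
               "unknown kinetic class")
})

test_that("accessibility lead shifts the onset and floors at zero", {
  zyg <- list(class = "zygotic", onset_h = 2, rate = 4, amplitude = 6,
              access_lead_h = 0)
  ages <- seq(0, 5, by = 0.25)
  expect_equal(accessibility_mean(zyg, ages), expression_mean(zyg, ages))

  zyg$access_lead_h <- 0.5
  expect_equal(accessibility_mean(zyg, 1.5), 3)  # shifted half-max

  zyg$access_lead_h <- 5  # larger than the onset: floored at age 0
  expect_equal(accessibility_mean(zyg, 0), 3)
})

test_that("lineage trees branch consistently and assign germ layers", {
  tree <- default_lineage_tree()
  expect_true(all(is.na(tree$parent[tree$epoch == 0])))
  kids <- tree[tree$epoch > 0, ]
  expect_true(all(kids$parent %in% tree$state))
  # parents always live one epoch earlier
  pe <- tree$epoch[match(kids$parent, tree$state)]
  expect_equal(pe, kids$epoch - 1L)
  expect_setequal(unique(tree$germ_layer),
                  c("unspecified", "ectoderm", "mesoderm", "endoderm"))
})

test_that("simulate_atlas hits depth targets and is seed-reproducible", {
  at <- small_atlas()
  expect_s3_class(at, "embryo_atlas")
  expect_true(all(at$rna$counts@x >= 0))
  expect_true(all(at$rna$counts@x == round(at$rna$counts@x)))
  med_rna <- median(Matrix::colSums(at$rna$counts))
  expect_lt(abs(med_rna - 399) / 399, 0.25)
  med_atac <- median(Matrix::colSums(at$atac$counts))
  expect_lt(abs(med_atac - 5206) / 5206, 0.25)
  # non-contaminants lie inside their window
  cells <- at$rna$cells
  w <- at$windows[match(cells$window_index, at$windows$index), ]
  inside <- cells$true_age_h >= w$start_h & cells$true_age_h <= w$end_h
  expect_true(all(inside[!cells$is_contaminant]))
  expect_true(all(cells$true_age_h[cells$is_contaminant] > w$end_h[
    cells$is_contaminant]))
  expect_true(all(cells$chrX_fraction >= 0 & cells$chrX_fraction <= 1))

  again <- simulate_atlas(at$config, seed = 42)
  expect_equal(at, again)
})

test_that("simulated counts match the closed-form kinetic means", {
  # >= 10,000 cells at a single age; empirical feature means must match
  # the planted mean ratios within Monte-Carlo error
  kin <- data.frame(feature_id = c("a", "b", "c"),
                    class = c("constant", "zygotic", "maternal"),
                    onset_h = c(0, 9, 0), rate = c(1, 2, 0.2),
                    amplitude = c(4, 8, 6), lineage_mask = "",
                    access_lead_h = 0)
  cfg <- atlas_config(windows = collection_windows(9.999, 10.001),
                      cells_per_window_rna = 12000,
                      cells_per_window_atac = 10,
                      n_genes = 3, n_peaks = 6, rna_depth = 300,
                      dispersion = 0.3, lib_sigma = 0,
                      contamination_rate = 0,
                      lineage = make_lineage_tree(1, epoch_width = 20),
                      lineage_frac = 0, n_tfs = 0, tf_classes = no_tf,
                      kinetics = kin)
  at <- simulate_atlas(cfg, seed = 8)
  mu <- vapply(seq_len(3), function(j) {
    expression_mean(kin[j, ], 10)
  }, numeric(1))
  emp <- Matrix::rowMeans(at$rna$counts)
  expect_equal(as.numeric(emp / sum(emp)), mu / sum(mu), tolerance = 0.02)
})

test_that("inconsistent configs are rejected", {
  expect_error(atlas_config(n_genes = 0), "at least one gene")
  bad_kin <- data.frame(feature_id = "g1", class = "constant",
                        onset_h = 0, rate = 1, amplitude = 1,
                        lineage_mask = "NOT_A_STATE", access_lead_h = 0)
  expect_error(atlas_config(kinetics = bad_kin), "absent from the lineage")
})

test_that("atlas round-trips through the on-disk layout", {
  at <- small_atlas()
  dir <- withr::local_tempdir()
  write_atlas(at, dir)
  # BED convention: 0-based half-open, tab-separated, name in column 4
  bed <- readLines(file.path(dir, "peaks.bed"))
  pk1 <- at$atac$features[1, ]
  expect_equal(bed[1], sprintf("%s\t%d\t%d\t%s", pk1$chrom, pk1$start,
                               pk1$end, pk1$peak_id))
  back <- read_atlas(dir)
  for (field in setdiff(names(at), "config")) {
    expect_equal(back[[field]], at[[field]], tolerance = 1e-7,
                 info = field)
  }
  expect_equal(back$config[order(names(back$config))],
               at$config[order(names(at$config))], tolerance = 1e-7)

  file.remove(file.path(dir, "rna.mtx"))
  expect_error(read_atlas(dir), "rna.mtx")
})

test_that("tf panel plants the advertised structure", {
  pan <- simulate_tf_panel(seed = 5)
  expect_equal(dim(pan$expression), dim(pan$deviations))
  expect_equal(ncol(pan$expression), nrow(pan$cluster_meta))
  expect_equal(table(pan$tf_truth$type)[["null"]], 10)
  # planted runs leave room for >= 3 consecutive windows
  planted <- pan$tf_truth[pan$tf_truth$type != "null", ]
  expect_true(all(planted$start_window <= max(pan$cluster_meta$window) - 2))
  expect_equal(pan, simulate_tf_panel(seed = 5))
})
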