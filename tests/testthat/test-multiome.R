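test_that("gene_activity_scores matches the interval-overlap oracle", {
  # toy from the activity-score definition: gene body [1000, 2000) on +,
  # flank 2000 -> region [0, 3000); peaks at [500,600) and [2900,3100)
  # count, the peak at [3200,3300) does not
  peaks <- data.frame(peak_id = c("p1", "p2", "p3"),
                      chrom = "chr2L",
                      start = c(500, 2900, 3200),
                      end = c(600, 3100, 3300))
  genes <- data.frame(gene_id = "gA", chrom = "chr2L", start = 1000,
                      end = 2000, strand = "+")
  cnt <- Matrix::Matrix(matrix(c(3, 5, 7, 2, 4, 6), nrow = 3,
                               dimnames = list(peaks$peak_id,
                                               c("c1", "c2"))),
                        sparse = TRUE)
  sc <- gene_activity_scores(cnt, peaks, genes, flank_bp = 2000)
  expect_equal(as.numeric(sc["gA", ]), c(3 + 5, 2 + 4))

  # minus-strand gene: flank centred on end - 1
  gm <- data.frame(gene_id = "gB", chrom = "chr2L", start = 1000,
                   end = 2000, strand = "-")
  scm <- gene_activity_scores(cnt, peaks, gm, flank_bp = 1500)
  # TSS = 1999; flank region [499, 3499): all three peaks overlap
  expect_equal(as.numeric(scm["gB", ]), c(3 + 5 + 7, 2 + 4 + 6))

  # no overlapping peaks: all-zero row is kept
  gz <- data.frame(gene_id = "gC", chrom = "chr3R", start = 10,
                   end = 500, strand = "+")
  scz <- gene_activity_scores(cnt, peaks, gz, flank_bp = 100)
  expect_equal(as.numeric(scz["gC", ]), c(0, 0))

  expect_warning(
    gene_activity_scores(cnt, peaks, rbind(genes, gz), flank_bp = 100,
                         chromosomes = "chr2L"), "unknown chromosome")

  # random instance against the naive oracle
  set.seed(31)
  pk <- data.frame(peak_id = sprintf("q%02d", 1:25),
                   chrom = sample(c("chr2L", "chrX"), 25, TRUE),
                   start = sample.int(20000, 25))
  pk$end <- pk$start + sample(200:800, 25, TRUE)
  gn <- data.frame(gene_id = sprintf("h%02d", 1:8),
                   chrom = sample(c("chr2L", "chrX"), 8, TRUE),
                   start = sample.int(18000, 8))
  gn$end <- gn$start + 1500
  gn$strand <- sample(c("+", "-"), 8, TRUE)
  cc <- Matrix::Matrix(matrix(rpois(25 * 4, 3), nrow = 25,
                              dimnames = list(pk$peak_id,
                                              paste0("c", 1:4))),
                       sparse = TRUE)
  expect_equal(as.matrix(gene_activity_scores(cc, pk, gn, 2000)),
               gene_activity_oracle(cc, pk, gn, 2000))
})

test_that("cluster_profiles is a depth-normalized per-cluster pseudobulk", {
  cnt <- Matrix::Matrix(matrix(c(2, 8, 2, 8, 5, 5), nrow = 2,
                               dimnames = list(c("g1", "g2"),
                                               paste0("c", 1:3))),
                        sparse = TRUE)
  # a single-cell cluster gives that cell's normalized profile
  pr <- cluster_profiles(cnt, c("a", "a", "b"))
  expect_equal(unname(pr["b", ]), log(1 + c(5, 5) / 10 * 1e4))
  # two identical cells profile like one (depth normalization)
  expect_equal(unname(pr["a", ]), log(1 + c(4, 16) / 20 * 1e4))
  # permutation invariance
  pr2 <- cluster_profiles(cnt[, c(3, 1, 2)], c("b", "a", "a"))
  expect_equal(pr2[rownames(pr), ], pr)
  expect_error(cluster_profiles(cnt, factor(c("a", "a", "b"),
                                            levels = c("a", "b", "c"))),
               "empty cluster")
})

test_that("nnls_decompose matches exact and grid-search oracles", {
  set.seed(32)
  S <- rbind(s1 = c(4, 0, 2, 0, 1, 0), s2 = c(0, 3, 0, 5, 0, 2))
  colnames(S) <- paste0("g", 1:6)
  # target equal to one source: coefficient 1 there
  d1 <- nnls_decompose(S["s1", , drop = FALSE], S)
  expect_equal(unname(d1$mixture[1, ]), c(1, 0))
  # orthogonal non-negative mixture 0.3/0.7 recovered exactly
  tgt <- rbind(t1 = 0.3 * S["s1", ] + 0.7 * S["s2", ])
  d2 <- nnls_decompose(tgt, S)
  expect_equal(unname(d2$mixture[1, ]), c(0.3, 0.7), tolerance = 1e-8)
  expect_equal(unname(d2$mixture[1, ]),
               nnls_grid_oracle(tgt[1, ], S), tolerance = 0.011)
  # zero target: zeros with a warning
  ztgt <- rbind(z = rep(0, 6))
  colnames(ztgt) <- colnames(S)
  expect_warning(d0 <- nnls_decompose(ztgt, S), "all-zero")
  expect_equal(unname(d0$mixture[1, ]), c(0, 0))

  # random 3-source toys vs the 0.01-step simplex grid, within 0.02
  for (rep in 1:4) {
    S3 <- matrix(abs(rnorm(3 * 12)), nrow = 3,
                 dimnames = list(paste0("s", 1:3), paste0("g", 1:12)))
    w <- c(0.2, 0.5, 0.3)
    tg <- rbind(t = drop(w %*% S3) + abs(rnorm(12, 0, 0.02)))
    colnames(tg) <- colnames(S3)
    fit <- nnls_decompose(tg, S3)
    grid <- nnls_grid_oracle(tg[1, ], S3)
    expect_lt(max(abs(fit$mixture[1, ] - grid)), 0.02)
  }
  # residual never exceeds the all-zero solution's residual
  S4 <- matrix(abs(rnorm(2 * 10)), nrow = 2,
               dimnames = list(c("a", "b"), paste0("g", 1:10)))
  tg4 <- rbind(t = abs(rnorm(10)))
  colnames(tg4) <- colnames(S4)
  f4 <- nnls_decompose(tg4, S4)
  expect_lte(f4$residuals[1], sqrt(sum(tg4^2)))
  expect_true(all(f4$coefficients >= 0))
})

test_that("link_clusters applies the strict both-direction rule", {
  r_from_a <- matrix(c(0.5, 0, 0, 0.5), 2,
                     dimnames = list(c("r1", "r2"), c("a1", "a2")))
  a_from_r <- matrix(c(0.5, 0, 0, 0.5), 2,
                     dimnames = list(c("a1", "a2"), c("r1", "r2")))
  lk <- link_clusters(r_from_a, a_from_r, 0.1)
  expect_equal(sum(lk$linked), 2)
  expect_true(all(lk$atac_cluster[lk$linked] ==
                    sub("r", "a", lk$rna_cluster[lk$linked])))

  # one direction below threshold: not linked
  a_from_r2 <- a_from_r; a_from_r2["a1", "r1"] <- 0.05
  r_from_a2 <- r_from_a; r_from_a2["r1", "a1"] <- 0.3
  lk2 <- link_clusters(r_from_a2, a_from_r2, 0.1)
  expect_false(lk2$linked[lk2$atac_cluster == "a1" &
                            lk2$rna_cluster == "r1"])
  lk2e <- link_clusters(r_from_a2, a_from_r2, 0.1, rule = "either")
  expect_true(lk2e$linked[lk2e$atac_cluster == "a1" &
                            lk2e$rna_cluster == "r1"])

  # exactly the threshold is excluded (strict)
  r_from_a3 <- r_from_a; r_from_a3["r1", "a1"] <- 0.1
  lk3 <- link_clusters(r_from_a3, a_from_r, 0.1)
  expect_false(lk3$linked[lk3$atac_cluster == "a1" &
                            lk3$rna_cluster == "r1"])
})
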