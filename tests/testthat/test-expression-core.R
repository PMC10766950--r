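test_that("read_counts builds a validated container and rejects bad input", {
  d <- withr::local_tempdir()
  cf <- file.path(d, "counts.tsv"); mf <- file.path(d, "meta.tsv")
  write.table(data.frame(gene_id = c("a", "b", "c"), s1 = c(1, 2, 3), s2 = c(4, 5, 6)),
              cf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = c("s1", "s2"), tissue = "DRG",
                         genotype = c("FD", "Control"), sex = "F"),
              mf, sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- read_counts(cf, mf)
  expect_equal(dim(cm$counts), c(3L, 2L))

  write.table(data.frame(gene_id = c("a", "a", "c"), s1 = 1:3, s2 = 4:6),
              cf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_counts(cf, mf), "duplicate gene ids: a")

  write.table(data.frame(gene_id = c("a", "b"), s1 = 1:2, s3 = 3:4),
              cf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_counts(cf, mf), "missing from metadata: s3")
})

test_that("round trip through write_counts preserves the container", {
  set.seed(1)
  cm <- toy_counts(matrix(rpois(20, 10), 5, 4,
                          dimnames = list(paste0("g", 1:5), NULL)),
                   rep(c("FD", "Control"), 2))
  d <- withr::local_tempdir()
  paths <- write_counts(cm, d)
  cm2 <- read_counts(paths["counts"], paths["meta"])
  expect_equal(cm2$counts, cm$counts)
  expect_equal(cm2$sample_meta$genotype, cm$sample_meta$genotype)
})

test_that("CPM columns sum to one million", {
  set.seed(2)
  m <- matrix(rpois(60, 30), 6, 10)
  expect_equal(unname(colSums(cpm(m))), rep(1e6, 10), tolerance = 1e-9)
})

test_that("median-CPM filter keeps genes expressed in at least one genotype", {
  # 4 genes x 4 samples (2 FD, 2 Control), library sizes 100 each so that
  # CPM = 1e4 * count. Hand-computed median CPM per genotype:
  #   g1: FD (0,0) Ctrl (0,0)      -> drop (all zero)
  #   g2: FD (50,46) Ctrl (0,0)    -> keep ("at least one genotype")
  #   g3: FD (0,0) Ctrl (2,4)      -> keep via Control
  #   g4: FD (50,54) Ctrl (98,96)  -> keep
  counts <- rbind(g1 = c(0, 0, 0, 0),
                  g2 = c(50, 46, 0, 0),
                  g3 = c(0, 0, 2, 4),
                  g4 = c(50, 54, 98, 96))
  # columns sum to 100 by construction, so CPM = 1e4 * count
  cm <- toy_counts(counts, c("FD", "FD", "Control", "Control"))
  kept <- rownames(filter_expressed(cm, min_cpm = 0.1)$counts)
  expect_setequal(kept, c("g2", "g3", "g4"))
  # idempotence
  f1 <- filter_expressed(cm, 0.1)
  expect_identical(filter_expressed(f1, 0.1)$counts, f1$counts)
  # designated full-length features bypass the filter
  cm_fl <- toy_counts(counts, c("FD", "FD", "Control", "Control"), fl = "g1")
  expect_true("g1" %in% rownames(filter_expressed(cm_fl, 0.1)$counts))
  # a genotype with no samples errors
  cm_one <- toy_counts(counts[, 1:2], c("FD", "FD"))
  expect_error(filter_expressed(cm_one), "no Control samples")
})

test_that("size factors follow median-of-ratios with its closed forms", {
  # identical columns -> all ones
  m <- matrix(c(5, 9, 5, 9, 5, 9), 2, 3, dimnames = list(c("a", "b"), NULL))
  expect_equal(unname(size_factors(m)), rep(1, 3))
  # hand computation: geometric means sqrt(200), sqrt(1800); ratio columns
  # are (1/sqrt(2), sqrt(2)) in both genes
  m2 <- matrix(c(10, 30, 20, 60), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # scale equivariance of factor ratios: tripling a column triples its
  # factor relative to the others (the geometric-mean reference rescales,
  # so only ratios are identified)
  set.seed(3)
  m3 <- matrix(rpois(50, 40) + 1, 10, 5)
  sf <- size_factors(m3)
  m3b <- m3; m3b[, 2] <- m3b[, 2] * 3
  sfb <- size_factors(m3b)
  expect_equal(sfb[2] / sfb[1], 3 * sf[2] / sf[1], tolerance = 1e-12)
  # independent oracle: the reference median-of-ratios implementation
  # (odd gene count: the linear-scale and log-scale medians coincide there)
  m5 <- matrix(rpois(55, 40) + 1, 11, 5)
  expect_equal(unname(size_factors(m5)),
               unname(suppressMessages(DESeq2::estimateSizeFactorsForMatrix(m5))),
               tolerance = 1e-10)
  # gene reordering leaves factors unchanged
  rownames(m3) <- paste0("g", 1:10)
  expect_equal(size_factors(m3[sample(10), ]), size_factors(m3))
  # no all-nonzero gene -> error
  m4 <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_error(size_factors(m4), "pseudo-reference")
})

test_that("full-length ELP1 profile reports percent of control and t-tests", {
  # noise-free: control 100 CPM, FD 31 CPM at library size 1e6
  lib <- 1e6
  counts <- rbind(ELP1_FL = rep(c(31, 100), each = 4), filler = 0)
  counts["filler", ] <- lib - colSums(counts)
  cm <- toy_counts(counts, rep(c("FD", "Control"), each = 4), fl = "ELP1_FL")
  prof <- elp1_profile(cm, structure(list(cpm = cpm(cm$counts)), class = "fd_norm"))
  expect_equal(prof$by_tissue$pct_of_control, 31, tolerance = 1e-9)
  expect_equal(prof$by_tissue$p, 0)
  # FD identical to Control -> 100%, t = 0, FDR = 1
  counts2 <- rbind(ELP1_FL = c(9, 10, 11, 10, 9, 10, 11, 10), filler = 0)
  counts2["filler", ] <- 1e4 - colSums(counts2)
  cm2 <- toy_counts(counts2, rep(c("FD", "Control"), each = 4), fl = "ELP1_FL")
  prof2 <- elp1_profile(cm2)
  expect_equal(prof2$by_tissue$pct_of_control, 100, tolerance = 1e-9)
  expect_equal(prof2$by_tissue$t, 0, tolerance = 1e-9)
  expect_equal(prof2$by_tissue$fdr, 1, tolerance = 1e-9)
})

test_that("planted DRG reduction is recovered with strong significance", {
  sim <- generate_bulk(tissues = "DRG", n_genes = 400,
                       driver_reduction = c(DRG = 0.31),
                       module_spec = list(), deg_spec = list(n = 0, fc = 2),
                       seed = 101)
  cm <- filter_expressed(sim$counts)
  prof <- elp1_profile(cm)
  expect_gt(prof$by_tissue$pct_of_control, 26)
  expect_lt(prof$by_tissue$pct_of_control, 36)
  expect_lt(prof$by_tissue$fdr, 0.001)
})

test_that("profile p-values are uniform under permuted genotype labels", {
  set.seed(42)
  n <- 12
  lib <- 5000
  counts <- rbind(ELP1_FL = rpois(2 * n, 50), filler = 0)
  counts["filler", ] <- lib - colSums(counts)
  ps <- replicate(200, {
    gt <- sample(rep(c("FD", "Control"), n))
    cm <- toy_counts(counts, gt, fl = "ELP1_FL")
    elp1_profile(cm)$by_tissue$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
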