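# scRNA fixture shared across tests.
sc_fixture <- function(seed = 5, n_cells = 240, dropout = 0.1) {
  sc <- generate_scrna(n_cells = n_cells, dropout = dropout, seed = seed)
  qc <- qc_filter_cells(sc$counts)
  norm <- log2(sweep(qc, 2, colSums(qc), "/") * 1e6 + 1)
  norm <- norm[apply(norm, 1, function(x) diff(range(x))) > 0, ]
  list(sc = sc, norm = norm,
       truth = sc$truth$sc_cluster_labels[colnames(norm)])
}

test_that("QC filtering trims the stated percentile tails", {
  # 100 cells with distinct feature counts: cell i expresses i+4 genes
  n <- 100
  counts <- matrix(0, 110, n, dimnames = list(paste0("g", 1:110), paste0("c", 1:n)))
  for (i in seq_len(n)) counts[seq_len(i + 4), i] <- 1
  expect_equal(ncol(qc_filter_cells(counts, tail = 0.025)), 96)
  # identical feature counts: nothing removed
  eq <- matrix(1, 50, 50)
  expect_equal(ncol(qc_filter_cells(eq)), 50)
  # tail = 0 is the identity
  expect_identical(qc_filter_cells(counts, tail = 0), counts)
  expect_error(qc_filter_cells(counts[, 1:10]), "40 cells")
})

test_that("MCA places exclusive genes near their cluster and conserves inertia", {
  f <- sc_fixture(seed = 71)
  emb <- mca_embed(f$norm, d = 20)
  # a marker exclusive to cluster A sits among that cluster's nearest genes
  a_cells <- names(f$truth)[f$truth == "A"]
  centA <- colMeans(emb$cell_coords[a_cells, ])
  d2 <- rowSums(sweep(emb$gene_coords, 2, centA)^2)
  top5 <- names(sort(d2))[1:5]
  expect_gt(sum(grepl("^mkA", top5)), 0)
  # duplicate cells project to identical coordinates
  dup <- cbind(f$norm, dupcell = f$norm[, 1])
  emb2 <- mca_embed(dup, d = 10)
  expect_equal(emb2$cell_coords["dupcell", ],
               emb2$cell_coords[colnames(f$norm)[1], ], tolerance = 1e-9)
  # total inertia equals the chi-square statistic of the fuzzy table / n
  Xs <- (f$norm - apply(f$norm, 1, min)) /
    apply(f$norm, 1, function(x) diff(range(x)))
  FF <- rbind(Xs, 1 - Xs)
  chi <- suppressWarnings(chisq.test(FF)$statistic)
  expect_equal(unname(emb$total_inertia), unname(chi / sum(FF)),
               tolerance = 1e-8)
  expect_error(mca_embed(rbind(f$norm, const = 1)), "constant")
})

test_that("clustering recovers the three planted clusters", {
  f <- sc_fixture(seed = 5)
  emb <- mca_embed(f$norm, d = 30)
  labs <- cluster_cells(emb, k_nn = 20, resolution = 0.2, seed = 3)
  expect_equal(length(unique(labs)), 3)
  expect_gt(ari(labs, f$truth), 0.9)
  # cell order does not change the partition (up to label names)
  perm <- sample(ncol(f$norm))
  emb_p <- mca_embed(f$norm[, perm], d = 30)
  labs_p <- cluster_cells(emb_p, k_nn = 20, resolution = 0.2, seed = 3)
  expect_equal(ari(labs_p[names(labs)], labs), 1)
  # near-zero resolution collapses a connected graph to one community
  one <- cluster_cells(emb, k_nn = 40, resolution = 1e-9, seed = 3,
                       snn_prune = 0)
  expect_equal(length(unique(one)), 1L)
})

test_that("cluster signatures are top-n nearest genes with planted markers inside", {
  f <- sc_fixture(seed = 5)
  emb <- mca_embed(f$norm, d = 30)
  labs <- cluster_cells(emb, seed = 3)
  sigs <- cluster_signature(emb, labs, top_n = 200)
  expect_true(all(lengths(sigs) == 200))
  for (cl in names(sigs)) {
    maj <- names(which.max(table(f$truth[names(labs)[labs == cl]])))
    mk <- intersect(f$sc$truth$sc_markers[[maj]], rownames(f$norm))
    expect_gte(mean(mk %in% sigs[[cl]]), 0.8)
  }
  # top_n = 1 returns the single nearest gene
  expect_length(cluster_signature(emb, labs, top_n = 1)[[1]], 1)
  expect_warning(all_g <- cluster_signature(emb, labs, top_n = 1e6), "top_n")
  expect_equal(lengths(all_g)[[1]], nrow(f$norm))
  # clusters with identical members give identical signatures
  labs_dup <- labs; labs_dup[] <- 1
  s_dup <- cluster_signature(emb, c(labs_dup, setNames(1, "none")), top_n = 50)
  expect_length(unique(s_dup), 1)
})

test_that("marker reconciliation replaces matched types and retains unmatched", {
  bg <- paste0("g", 1:100)
  sig <- list(`1` = paste0("g", 1:20))
  authors <- list(typeA = paste0("g", 1:10),       # inside the signature
                  typeB = paste0("g", 90:99))      # zero overlap
  rec <- reconcile_markers(authors, sig, bg)
  expect_equal(unname(rec$provenance["typeA"]), "replaced_by_cluster_signature")
  expect_identical(rec$markers$typeA, sig[["1"]])
  expect_equal(unname(rec$provenance["typeB"]), "retained_author")
  expect_identical(rec$markers$typeB, authors$typeB)
})

test_that("perturbed author markers are repaired by the cluster signatures", {
  sc <- generate_scrna(n_cells = 240, dropout = 0.1,
                       perturb_author_frac = 0.3, seed = 72)
  qc <- qc_filter_cells(sc$counts)
  norm <- log2(sweep(qc, 2, colSums(qc), "/") * 1e6 + 1)
  norm <- norm[apply(norm, 1, function(x) diff(range(x))) > 0, ]
  emb <- mca_embed(norm, d = 30)
  labs <- cluster_cells(emb, seed = 3)
  sigs <- cluster_signature(emb, labs, top_n = 200)
  rec <- reconcile_markers(sc$author_markers, sigs, rownames(norm))
  expect_true(all(rec$provenance == "replaced_by_cluster_signature"))
  for (ty in names(sc$truth$sc_markers)) {
    mk <- intersect(sc$truth$sc_markers[[ty]], rownames(norm))
    expect_gte(mean(mk %in% rec$markers[[ty]]), 0.9)
  }
})

test_that("DEG-marker enrichment flags planted overlaps and stays calibrated", {
  bg <- paste0("g", 1:1000)
  markers <- list(pep = paste0("g", 1:40), myel = paste0("g", 41:80),
                  th = paste0("g", 81:120))
  # 14 of 44 convergent DEGs planted inside two marker sets (8 + 6)
  degs <- list(conv = c(paste0("g", 1:8), paste0("g", 41:46),
                        paste0("g", 201:230)))
  res <- enrich_degs_in_markers(degs, markers, bg)
  expect_true(all(res$significant[res$marker_set %in% c("pep", "myel")]))
  expect_false(res$significant[res$marker_set == "th"])
  # identity: a DEG set equal to a marker set is its row's most significant
  res2 <- enrich_degs_in_markers(list(hit = markers$pep), markers, bg)
  expect_equal(res2$marker_set[which.min(res2$p)], "pep")
  # FDR equals the brute-force BH oracle
  expect_equal(res$fdr, bh_brute(res$p), tolerance = 1e-12)
  # permuted marker labels give uniform p-values; the discrete upper-tail p
  # is smoothed with the standard randomized-p construction
  # P(X >= k) - U * P(X = k), which is exactly uniform under the null
  set.seed(73)
  ps <- replicate(400, {
    fake <- list(m = sample(bg, 40))
    r <- enrich_degs_in_markers(list(d = sample(bg, 40)), fake, bg)
    r$p - runif(1) * dhyper(r$overlap, 40, 960, 40)
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  # the raw discrete p-values are conservative, never anti-conservative
  raw <- replicate(200, {
    fake <- list(m = sample(bg, 40))
    enrich_degs_in_markers(list(d = sample(bg, 40)), fake, bg)$p
  })
  expect_lte(mean(raw < 0.05), 0.07)
})
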