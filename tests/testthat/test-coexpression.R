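# Expression fixture: blocks of genes sharing latent factors.
block_expr <- function(block_sizes, n = 30, loading = 1, noise = 0.75,
                       factor_cor = 0, seed = 1) {
  # loading of length 2 is treated as a per-gene uniform range (hub gradient)
  set.seed(seed)
  f1 <- rnorm(n)
  factors <- lapply(seq_along(block_sizes), function(b) {
    if (b == 1) f1 else factor_cor * f1 + sqrt(1 - factor_cor^2) * rnorm(n)
  })
  rows <- list()
  for (b in seq_along(block_sizes)) {
    for (g in seq_len(block_sizes[b])) {
      l <- if (length(loading) == 2) runif(1, loading[1], loading[2]) else loading
      rows[[length(rows) + 1]] <- l * factors[[b]] + rnorm(n, 0, noise)
    }
  }
  x <- do.call(rbind, rows)
  dimnames(x) <- list(sprintf("b%d_g%02d", rep(seq_along(block_sizes), block_sizes),
                              unlist(lapply(block_sizes, seq_len))),
                      sprintf("s%02d", seq_len(n)))
  list(x = x, factors = factors,
       block = rep(seq_along(block_sizes), block_sizes))
}

test_that("signed adjacency matches its closed forms", {
  # exact correlations 1 and -1
  x <- rbind(a = 1:10, b = 2 * (1:10) + 3, c = -(1:10))
  a <- signed_adjacency(x, beta = 6)
  expect_equal(a["a", "b"], 1)
  expect_equal(a["a", "c"], 0)
  # exact correlation 0.6 at beta 6 -> 0.8^6
  set.seed(31)
  v <- vectors_with_cor(0.6)
  a2 <- signed_adjacency(rbind(p = v$x, q = v$y), beta = 6)
  expect_equal(a2["p", "q"], 0.8^6, tolerance = 1e-12)
  expect_true(all(diag(a) == 1))
  expect_error(signed_adjacency(rbind(a = 1:10, z = rep(2, 10)), 6),
               "zero-variance genes: z")
})

test_that("TOM matches the hand-computed 3-node case and its properties", {
  expect_equal(tom_matrix(diag(3)), diag(3))
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  # k_i = 1; L_12 = 0.25; TOM_12 = (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  expect_equal(tom_matrix(a)[1, 2], 0.5)
  set.seed(32)
  r <- matrix(runif(100), 10); r <- (r + t(r)) / 2; diag(r) <- 1
  tm <- tom_matrix(r)
  expect_true(isSymmetric(tm))
  expect_true(all(tm >= 0 & tm <= 1 + 1e-12))
  expect_equal(unname(diag(tm)), rep(1, 10))
})

test_that("soft power selection reaches the scale-free target and honors overrides", {
  expect_identical(pick_soft_power(matrix(0, 2, 2), override = 6), 6)
  expect_identical(pick_soft_power(matrix(0, 2, 2), override = 7), 7)
  # modular expression: some beta should reach R^2 >= 0.8
  f <- block_expr(c(40, 40, 40), n = 40, noise = 1.2, seed = 33)
  beta <- pick_soft_power(f$x)
  fits <- attr(beta, "fits")
  expect_gte(max(fits$r2), 0.8)
  expect_equal(unclass(beta), fits$power[fits$r2 >= 0.8][1], ignore_attr = TRUE)
})

test_that("two planted blocks are detected as two modules with high accuracy", {
  f <- block_expr(c(50, 50), n = 30, seed = 34)   # within-block r ~ 0.8
  tm <- tom_matrix(signed_adjacency(f$x, 6))
  mods <- detect_modules(tm, f$x, min_size = 30)
  found <- setdiff(unique(mods$assignment), "unassigned")
  expect_length(found, 2)
  # membership accuracy under the best label matching
  acc <- max(mean(mods$assignment[f$block == 1] == "M1") +
               mean(mods$assignment[f$block == 2] == "M2"),
             mean(mods$assignment[f$block == 1] == "M2") +
               mean(mods$assignment[f$block == 2] == "M1")) / 2
  expect_gte(acc, 0.95)
  # detection is invariant to gene order and to sample-wise mean shifts
  perm <- sample(nrow(f$x))
  x_shift <- f$x + matrix(rnorm(ncol(f$x)), nrow(f$x), ncol(f$x), byrow = TRUE)
  mods2 <- detect_modules(tom_matrix(signed_adjacency(x_shift[perm, ], 6)),
                          x_shift[perm, ], min_size = 30)
  expect_equal(mods2$assignment[names(mods$assignment)], mods$assignment)
})

test_that("modules with eigengene correlation 0.9 are merged", {
  f <- block_expr(c(40, 40), n = 40, noise = 0.3, factor_cor = 0.95, seed = 35)
  tm <- tom_matrix(signed_adjacency(f$x, 6))
  mods <- detect_modules(tm, f$x, min_size = 30, merge_cut = 0.25)
  found <- setdiff(unique(mods$assignment), "unassigned")
  expect_length(found, 1)   # 1 - cor(e1, e2) < 0.25 forces the merge
})

test_that("eigengenes recover the common signal and dominate other projections", {
  f <- block_expr(c(60), n = 40, noise = 0.5, seed = 36)
  tm <- tom_matrix(signed_adjacency(f$x, 6))
  mods <- detect_modules(tm, f$x, min_size = 30)
  e <- mods$eigengenes[, 1]
  expect_gte(abs(cor(e, f$factors[[1]])), 0.95)
  # sign convention: positively aligned with members on average
  expect_gte(mean(cor(e, t(f$x))), 0)
  expect_equal(sum(e^2), 1, tolerance = 1e-8)
  # first PC explains at least as much variance as any random unit vector
  xs <- t(scale(t(f$x)))
  v_pc <- sum((xs %*% e)^2)
  set.seed(1)
  for (i in 1:20) {
    u <- rnorm(length(e)); u <- u / sqrt(sum(u^2))
    expect_gte(v_pc + 1e-8, sum((xs %*% u)^2))
  }
})

test_that("tiny inputs degrade to unassigned with a warning", {
  f <- block_expr(c(10), n = 20, seed = 37)
  tm <- tom_matrix(signed_adjacency(f$x, 6))
  expect_warning(mods <- detect_modules(tm, f$x, min_size = 30), "unassigned")
  expect_true(all(mods$assignment == "unassigned"))
})

test_that("Zsummary separates preserved modules from random gene sets", {
  # two planted modules with hub gradients in a 200-gene universe; the test
  # dataset keeps each gene's loading (preserved hub structure), fresh noise
  set.seed(38)
  n <- 35
  block <- rep(1:2, each = 40)
  loadings <- runif(80, 0.5, 1.6)
  draw <- function(factors) {
    x <- rbind(t(sapply(1:80, function(i)
      loadings[i] * factors[[block[i]]] + rnorm(n, 0, 0.6))),
      matrix(rnorm(120 * n), 120, n))
    dimnames(x) <- list(c(sprintf("m%d_g%02d", block, sequence(c(40, 40))),
                          sprintf("bg_%03d", 1:120)),
                        sprintf("s%02d", 1:n))
    x
  }
  factors <- list(rnorm(n), rnorm(n))
  ref <- draw(factors)
  test <- draw(factors)
  tm <- tom_matrix(signed_adjacency(ref[1:80, ], 6))
  mods <- detect_modules(tm, ref[1:80, ], min_size = 30)
  pres <- preservation_zsummary(mods, ref, test, beta = 6, n_perm = 50, seed = 1)
  expect_true(all(pres$z_summary > 10))
  expect_equal(pres$z_summary, (pres$z_density + pres$z_connectivity) / 2)
  # identical test set: density evidence alone already clears the bar
  pres_id <- preservation_zsummary(mods, ref, ref, beta = 6, n_perm = 50, seed = 1)
  expect_true(all(pres_id$z_summary > 10))
  # random "modules" in unrelated data stay mostly below the weak bar
  set.seed(39)
  noise_expr <- matrix(rnorm(80 * 35), 80, 35,
                       dimnames = dimnames(ref[1:80, ]))
  rand_z <- replicate(10, {
    fake <- mods
    fake$assignment[] <- "unassigned"
    fake$assignment[sample(80, 30)] <- "R1"
    preservation_zsummary(fake, noise_expr, noise_expr +
                            matrix(rnorm(80 * 35), 80, 35),
                          beta = 6, n_perm = 50)$z_summary
  })
  expect_gte(mean(abs(rand_z) < 2), 0.9)
})
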