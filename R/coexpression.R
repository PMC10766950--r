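#' Signed weighted co-expression adjacency
#'
#' a_ij = ((1 + cor(x_i, x_j)) / 2)^beta, so anti-correlated genes get
#' adjacency near zero (a signed network) and the soft power beta sharpens
#' the topology toward scale-freeness.
#'
#' @param expr genes x samples matrix (at least 4 samples).
#' @param beta soft-thresholding power, >= 1.
#' @return genes x genes symmetric adjacency in [0, 1] with unit diagonal.
#' @export
signed_adjacency <- function(expr, beta) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 4) stop_fd("need at least 4 samples")
  if (beta < 1) stop_fd("beta must be >= 1")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop_fd("zero-variance genes: ",
            paste(rownames(expr)[sds == 0], collapse = ", "))
  a <- ((1 + stats::cor(t(expr))) / 2)^beta
  diag(a) <- 1
  a
}

#' Pick the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the connectivity distribution is binned (10 bins)
#' and log10 p(k) is regressed on log10 k; the scale-free fit index is the
#' R-squared of that line when the slope is negative (else 0). The smallest
#' power reaching `target_r2` is returned, or the power with maximal fit if
#' none reaches it. Published per-tissue powers can be supplied via
#' `override` and are returned untouched, which is how the shipped defaults
#' (cortex 5, DRG 6, MED 5, SC 6, TG 7) enter the pipeline.
#'
#' @param expr genes x samples matrix (>= 30 genes).
#' @param candidates candidate powers (default 1:20).
#' @param target_r2 target scale-free fit (default 0.8).
#' @param override if non-NULL, returned directly (config/tissue default).
#' @return the selected power, with the fit table as attribute `"fits"`.
#' @export
pick_soft_power <- function(expr, candidates = 1:20, target_r2 = 0.8,
                            override = NULL) {
  if (!is.null(override)) return(override)
  expr <- as.matrix(expr)
  if (nrow(expr) < 30) stop_fd("need at least 30 genes to assess topology")
  sim <- (1 + stats::cor(t(expr))) / 2
  diag(sim) <- 0
  fits <- vapply(candidates, function(beta) {
    k <- colSums(sim^beta)
    scale_free_r2(k)
  }, numeric(1))
  hit <- which(fits >= target_r2)
  beta <- if (length(hit)) candidates[hit[1]] else candidates[which.max(fits)]
  attr(beta, "fits") <- data.frame(power = candidates, r2 = fits)
  beta
}

scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(0)
  cuts <- cut(k, breaks = n_bins)
  k_mean <- tapply(k, cuts, mean)
  p_k <- tapply(k, cuts, length) / length(k)
  ok <- !is.na(k_mean) & p_k > 0
  if (sum(ok) < 3) return(0)
  fit <- stats::lm(log10(p_k[ok]) ~ log10(k_mean[ok]))
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] >= 0) 0 else r2
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with the
#' sum over u distinct from i and j and k_i the whole-network connectivity of
#' i; genes sharing many strong neighbors get high overlap even when their
#' direct adjacency is moderate.
#'
#' @param adjacency symmetric matrix in [0, 1] with unit diagonal.
#' @return symmetric TOM in [0, 1] with unit diagonal.
#' @export
tom_matrix <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-8)) stop_fd("adjacency must be symmetric")
  if (any(a < -1e-12) || any(a > 1 + 1e-12)) stop_fd("adjacency must lie in [0, 1]")
  k <- rowSums(a) - diag(a)
  # (A^2)_ij counts u = i and u = j (each contributing a_ij when diag = 1)
  L <- a %*% a - 2 * a
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity 1 - TOM
#' with a deterministic static cut at `cut_height_frac` of the maximal merge
#' height. Clusters smaller than `min_size` become "unassigned". Each
#' module's eigengene is the first principal component of the standardized
#' member expression (unit norm, sign fixed so the mean correlation with
#' member genes is non-negative). Modules whose eigengenes have
#' dissimilarity 1 - cor below `merge_cut` are merged iteratively, closest
#' pair first.
#'
#' @param tom topological overlap matrix.
#' @param expr genes x samples expression used for eigengenes (same genes).
#' @param min_size minimal module size (default 30).
#' @param merge_cut eigengene dissimilarity threshold for merging
#'   (default 0.25).
#' @param cut_height_frac static tree-cut height as a fraction of the
#'   maximal merge height (default 0.99).
#' @return `fd_modules`: `assignment` (gene -> module id, "unassigned"
#'   allowed), `eigengenes` (samples x modules, unit columns), `min_size`,
#'   `merge_cut`.
#' @export
detect_modules <- function(tom, expr, min_size = 30, merge_cut = 0.25,
                           cut_height_frac = 0.99) {
  expr <- as.matrix(expr)
  genes <- rownames(expr)
  if (nrow(expr) < min_size) {
    warning("fewer than min_size genes in total; all unassigned")
    return(structure(list(assignment = stats::setNames(rep("unassigned", nrow(expr)), genes),
                          eigengenes = matrix(0, ncol(expr), 0,
                                              dimnames = list(colnames(expr), NULL)),
                          min_size = min_size, merge_cut = merge_cut),
                     class = "fd_modules"))
  }
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  labels <- stats::cutree(tree, h = cut_height_frac * max(tree$height))
  sizes <- table(labels)
  keep <- names(sizes)[sizes >= min_size]
  assignment <- rep("unassigned", length(labels))
  # name modules by decreasing size for stable, order-free ids
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  for (i in seq_along(keep))
    assignment[labels == as.integer(keep[i])] <- paste0("M", i)
  names(assignment) <- genes

  eg <- compute_eigengenes(expr, assignment)
  # iterative merge, closest eigengene pair first
  repeat {
    mods <- colnames(eg)
    if (length(mods) < 2) break
    cc <- stats::cor(eg)
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (1 - cc[mx[1], mx[2]] >= merge_cut) break
    m_keep <- mods[min(mx)]; m_drop <- mods[max(mx)]
    assignment[assignment == m_drop] <- m_keep
    eg <- compute_eigengenes(expr, assignment)
  }
  # relabel by final size
  mods <- setdiff(unique(assignment), "unassigned")
  mods <- mods[order(-table(factor(assignment, levels = mods))[mods], mods)]
  relab <- stats::setNames(paste0("M", seq_along(mods)), mods)
  assignment[assignment != "unassigned"] <- relab[assignment[assignment != "unassigned"]]
  eg <- compute_eigengenes(expr, assignment)
  structure(list(assignment = assignment, eigengenes = eg,
                 min_size = min_size, merge_cut = merge_cut),
            class = "fd_modules")
}

# First principal component of the standardized member expression per module,
# unit-norm, sign-aligned to the members.
compute_eigengenes <- function(expr, assignment) {
  mods <- setdiff(unique(assignment), "unassigned")
  mods <- mods[order(mods)]
  eg <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), mods))
  for (m in mods) {
    x <- expr[assignment == m, , drop = FALSE]
    xs <- t(scale(t(x)))
    sv <- svd(xs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (mean(stats::cor(e, t(x))) < 0) e <- -e
    eg[, m] <- e
  }
  eg
}

#' @export
print.fd_modules <- function(x, ...) {
  tab <- table(x$assignment)
  cat("fd_modules:", sum(names(tab) != "unassigned"), "modules;",
      if ("unassigned" %in% names(tab)) tab[["unassigned"]] else 0, "unassigned genes\n")
  print(tab)
  invisible(x)
}

#' Module preservation between two expression datasets (Zsummary)
#'
#' For each reference module, compares (1) the mean intramodular signed
#' adjacency in the test network (density) and (2) the correlation of
#' intramodular connectivity between reference and test networks, against a
#' permutation null in which the module assignment is randomized in the test
#' network (random gene sets of equal size from the shared universe).
#' Zsummary is the mean of the two Z scores; below 2 a module is not
#' considered preserved, above 10 preservation is strong.
#'
#' @param modules `fd_modules` detected in the reference dataset.
#' @param ref_expr,test_expr genes x samples matrices sharing gene ids.
#' @param beta soft power for adjacency in both networks (default 6).
#' @param n_perm permutation null size (default 100).
#' @param seed RNG seed.
#' @return data.frame: module, size (shared genes), z_density,
#'   z_connectivity, z_summary. Modules with fewer than 5 shared genes get
#'   NA.
#' @export
preservation_zsummary <- function(modules, ref_expr, test_expr, beta = 6,
                                  n_perm = 100, seed = NULL) {
  check_seed(seed)
  shared <- intersect(rownames(ref_expr), rownames(test_expr))
  if (length(shared) < 10) stop_fd("too few shared genes between datasets")
  ref_expr <- as.matrix(ref_expr)[shared, , drop = FALSE]
  test_expr <- as.matrix(test_expr)[shared, , drop = FALSE]
  mods <- setdiff(unique(modules$assignment), "unassigned")
  mods <- mods[order(mods)]

  set_adj <- function(expr, idx) ((1 + stats::cor(t(expr[idx, , drop = FALSE]))) / 2)^beta
  set_density <- function(expr, idx) {
    a <- set_adj(expr, idx); diag(a) <- NA
    mean(a, na.rm = TRUE)
  }
  set_kim <- function(expr, idx) {
    a <- set_adj(expr, idx); diag(a) <- 0
    rowSums(a)
  }
  safe_cor <- function(x, y)
    if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else 0
  zof <- function(o, nl) {
    s <- stats::sd(nl)
    if (s < 1e-12) return(0)
    (o - mean(nl)) / s
  }

  out <- data.frame(module = mods, size = NA_integer_, z_density = NA_real_,
                    z_connectivity = NA_real_, z_summary = NA_real_)
  for (i in seq_along(mods)) {
    members <- intersect(names(modules$assignment)[modules$assignment == mods[i]], shared)
    out$size[i] <- length(members)
    if (length(members) < 5) next
    idx <- match(members, shared)
    obs_dens <- set_density(test_expr, idx)
    k_ref <- set_kim(ref_expr, idx)
    obs_conn <- safe_cor(k_ref, set_kim(test_expr, idx))
    # null: module assignment permuted in the test network only, so the
    # reference connectivity pattern is paired with random test gene sets
    null <- replicate(n_perm, {
      ridx <- sample(length(shared), length(members))
      c(set_density(test_expr, ridx),
        safe_cor(k_ref, set_kim(test_expr, ridx)))
    })
    z_d <- zof(obs_dens, null[1, ])
    z_c <- zof(obs_conn, null[2, ])
    out$z_density[i] <- z_d
    out$z_connectivity[i] <- z_c
    out$z_summary[i] <- (z_d + z_c) / 2
  }
  class(out) <- c("fd_preservation", "data.frame")
  out
}
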