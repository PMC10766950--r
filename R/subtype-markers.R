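#' QC filter on cells by RNA feature count
#'
#' Removes cells whose number of detected features falls below the lower
#' `tail` percentile or above the upper `1 - tail` percentile. Percentiles
#' use (n+1)p linear interpolation (quantile type 6), so 100 cells with
#' distinct feature counts retain 96 at the default 2.5% tails.
#'
#' @param counts genes x cells count matrix.
#' @param tail tail probability filtered on each side (default 0.025).
#' @return the matrix restricted to retained cells.
#' @export
qc_filter_cells <- function(counts, tail = 0.025) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 40) stop_fd("need at least 40 cells for tail filtering")
  if (tail == 0) return(counts)
  nfeat <- colSums(counts > 0)
  lo <- stats::quantile(nfeat, tail, type = 6, names = FALSE)
  hi <- stats::quantile(nfeat, 1 - tail, type = 6, names = FALSE)
  counts[, nfeat >= lo & nfeat <= hi, drop = FALSE]
}

#' Multiple correspondence analysis embedding of cells and genes
#'
#' Each gene's normalized expression is min-max scaled to [0, 1] and fuzzy
#' double coded as (x, 1 - x), giving a 2*genes x cells indicator-style
#' table. Correspondence analysis (SVD of the chi-square-standardized
#' residual matrix) projects cells and genes into a shared space; gene
#' coordinates come from the positive coding rows. Deterministic up to the
#' fixed sign convention (largest-magnitude cell loading positive per axis).
#'
#' @param norm_expr genes x cells normalized (log-CPM) matrix; no constant
#'   genes.
#' @param d number of axes (default 30, capped at min(cells, 2*genes) - 1).
#' @return `fd_mca`: `cell_coords` (cells x d), `gene_coords` (genes x d),
#'   `inertia` per axis, `total_inertia`.
#' @export
mca_embed <- function(norm_expr, d = 30) {
  X <- as.matrix(norm_expr)
  rng <- apply(X, 1, function(x) diff(range(x)))
  if (any(rng == 0))
    stop_fd("constant genes: ", paste(rownames(X)[rng == 0], collapse = ", "))
  Xs <- (X - apply(X, 1, min)) / rng
  FF <- rbind(Xs, 1 - Xs)
  tot <- sum(FF)
  P <- FF / tot
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  d <- min(d, ncol(X) - 1L, 2L * nrow(X) - 1L)
  sv <- svd(S, nu = d, nv = d)
  dv <- sv$d[seq_len(d)]
  U <- sv$u; V <- sv$v
  for (j in seq_len(d)) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  cell_coords <- sweep(V, 1, sqrt(cc), "/") %*% diag(dv, d)
  row_coords <- sweep(U, 1, sqrt(r), "/") %*% diag(dv, d)
  gene_coords <- row_coords[seq_len(nrow(X)), , drop = FALSE]
  dimnames(cell_coords) <- list(colnames(X), paste0("MCA", seq_len(d)))
  dimnames(gene_coords) <- list(rownames(X), paste0("MCA", seq_len(d)))
  structure(list(cell_coords = cell_coords, gene_coords = gene_coords,
                 inertia = sv$d^2, total_inertia = sum(S^2)),
            class = "fd_mca")
}

#' @export
print.fd_mca <- function(x, ...) {
  cat("fd_mca:", nrow(x$cell_coords), "cells,", nrow(x$gene_coords),
      "genes in", ncol(x$cell_coords), "axes; leading inertia",
      signif(x$inertia[1], 4), "\n")
  invisible(x)
}

#' Cluster cells on a shared-nearest-neighbor graph
#'
#' Builds a k-nearest-neighbor graph (Euclidean distance in the embedding
#' space), weights edges by the Jaccard index of the two cells'
#' neighborhoods, and runs modularity community detection (Leiden) at the
#' given resolution.
#'
#' @param embedding `fd_mca` (or a cells x d coordinate matrix).
#' @param k_nn neighbors per cell (default 20).
#' @param resolution modularity resolution (default 0.2); in the limit
#'   resolution -> 0 a connected graph collapses to one community.
#' @param snn_prune SNN edges with Jaccard weight below this are dropped
#'   (default 1/15, the conventional pruning level for SNN graphs).
#' @param seed RNG seed for the community search.
#' @return named integer vector: cell -> cluster label.
#' @export
cluster_cells <- function(embedding, k_nn = 20, resolution = 0.2,
                          snn_prune = 1/15, seed = 1) {
  coords <- if (inherits(embedding, "fd_mca")) embedding$cell_coords else as.matrix(embedding)
  n <- nrow(coords)
  if (n < k_nn + 1) stop_fd("need at least k_nn + 1 cells")
  dd <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) {
    # deterministic neighbor choice: distance then index
    setdiff(order(dd[i, ], seq_len(n)), i)[seq_len(k_nn)]
  })
  pair_i <- rep(seq_len(n), each = k_nn)
  pair_j <- unlist(nb)
  em <- unique(cbind(pmin(pair_i, pair_j), pmax(pair_i, pair_j)))
  jac <- vapply(seq_len(nrow(em)), function(e) {
    a <- c(nb[[em[e, 1]]], em[e, 1]); b <- c(nb[[em[e, 2]]], em[e, 2])
    shared <- length(intersect(a, b))
    shared / (2 * (k_nn + 1) - shared)
  }, numeric(1))
  keep <- jac >= snn_prune
  g <- igraph::graph_from_edgelist(em[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = jac[keep])
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               weights = igraph::E(g)$weight,
                               n_iterations = 5)
  labels <- igraph::membership(cl)
  stats::setNames(as.integer(labels), rownames(coords))
}

#' Top-n nearest-gene signature per cluster in MCA space
#'
#' The cluster center is the mean of its member-cell coordinates; genes are
#' ranked by Euclidean distance to the center (ties by gene id) and the
#' nearest `top_n` form the cluster signature.
#'
#' @param embedding `fd_mca`.
#' @param labels named cluster labels from [cluster_cells()].
#' @param top_n signature size (default 200).
#' @return named list: cluster -> character vector of genes.
#' @export
cluster_signature <- function(embedding, labels, top_n = 200) {
  gc <- embedding$gene_coords
  if (top_n > nrow(gc)) {
    warning("top_n exceeds gene count; returning all genes")
    top_n <- nrow(gc)
  }
  cells <- rownames(embedding$cell_coords)
  out <- list()
  for (cl in sort(unique(labels))) {
    members <- cells[cells %in% names(labels)[labels == cl]]
    center <- colMeans(embedding$cell_coords[members, , drop = FALSE])
    dist2 <- rowSums(sweep(gc, 2, center)^2)
    ord <- order(dist2, rownames(gc))
    out[[as.character(cl)]] <- rownames(gc)[ord][seq_len(top_n)]
  }
  out
}

#' Reconcile author-provided cell-type markers with cluster signatures
#'
#' Each unsupervised cluster is matched to the author cell type whose marker
#' set overlaps its MCA signature most significantly (hypergeometric test).
#' Significant matches (p < alpha) replace the author markers with the
#' cluster signature; each cluster maps to at most one type and vice versa
#' (best-p assignment, ties by name). Author types with no significant
#' overlap are retained verbatim.
#'
#' @param author_markers named list: cell type -> author marker genes.
#' @param cluster_signatures named list: cluster -> signature genes.
#' @param background gene universe for the hypergeometric test (all genes
#'   surviving scRNA QC).
#' @param alpha significance threshold (default 0.05).
#' @return `fd_markers`: named list `markers` (cell type -> genes),
#'   `provenance` (cell type -> "replaced_by_cluster_signature" or
#'   "retained_author"), `matches` data.frame.
#' @export
reconcile_markers <- function(author_markers, cluster_signatures, background,
                              alpha = 0.05) {
  pairs <- expand.grid(cluster = names(cluster_signatures),
                       type = names(author_markers),
                       stringsAsFactors = FALSE)
  pairs$p <- vapply(seq_len(nrow(pairs)), function(i) {
    hypergeom_overlap(intersect(cluster_signatures[[pairs$cluster[i]]], background),
                      intersect(author_markers[[pairs$type[i]]], background),
                      background)$p
  }, numeric(1))
  pairs <- pairs[pairs$p < alpha, , drop = FALSE]
  pairs <- pairs[order(pairs$p, pairs$type, pairs$cluster), , drop = FALSE]
  markers <- list(); provenance <- character(); matches <- pairs[0, ]
  used_cl <- used_ty <- character()
  for (i in seq_len(nrow(pairs))) {
    cl <- pairs$cluster[i]; ty <- pairs$type[i]
    if (cl %in% used_cl || ty %in% used_ty) next
    markers[[ty]] <- cluster_signatures[[cl]]
    provenance[ty] <- "replaced_by_cluster_signature"
    used_cl <- c(used_cl, cl); used_ty <- c(used_ty, ty)
    matches <- rbind(matches, pairs[i, ])
  }
  for (ty in setdiff(names(author_markers), used_ty)) {
    markers[[ty]] <- author_markers[[ty]]
    provenance[ty] <- "retained_author"
  }
  structure(list(markers = markers, provenance = provenance, matches = matches),
            class = "fd_markers")
}

#' @export
print.fd_markers <- function(x, ...) {
  cat("fd_markers:", length(x$markers), "cell types (",
      sum(x$provenance == "replaced_by_cluster_signature"), "replaced,",
      sum(x$provenance == "retained_author"), "retained )\n")
  invisible(x)
}

#' Enrichment of DEG sets in neuronal-subtype marker sets
#'
#' Upper-tail hypergeometric test for every (DEG set, marker set) pair with
#' BH-FDR across the whole matrix; cells with FDR >= `fdr_cut` are flagged
#' non-significant.
#'
#' @param deg_sets named list of DEG id vectors.
#' @param marker_sets named list of marker gene vectors (or `fd_markers`).
#' @param background expressed-gene universe.
#' @param fdr_cut significance flag threshold (default 0.1).
#' @return data.frame: deg_set, marker_set, overlap, p, fdr, significant.
#' @export
enrich_degs_in_markers <- function(deg_sets, marker_sets, background,
                                   fdr_cut = 0.1) {
  if (inherits(marker_sets, "fd_markers")) marker_sets <- marker_sets$markers
  grid <- expand.grid(deg_set = names(deg_sets), marker_set = names(marker_sets),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ov <- hypergeom_overlap(intersect(deg_sets[[grid$deg_set[i]]], background),
                            intersect(marker_sets[[grid$marker_set[i]]], background),
                            background)
    data.frame(deg_set = grid$deg_set[i], marker_set = grid$marker_set[i],
               n_deg = ov$n_A, n_marker = ov$n_B, overlap = ov$overlap,
               p = ov$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr_cut
  out
}
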