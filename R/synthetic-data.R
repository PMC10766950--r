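#' Default driver reductions per tissue
#'
#' Fractions of the control-level full-length ELP1 signal retained in FD
#' samples, per tissue; the defaults are the tissue-specific reductions the
#' pipeline is designed to detect (about 31-54% of control, lowest in the
#' PNS ganglia).
#'
#' @return named numeric vector on (0, 1).
#' @export
default_driver_reduction <- function() {
  c(DRG = 0.3097, TG = 0.3951, MED = 0.4456, cortex = 0.5445, SC = 0.4462)
}

#' Generate ground-truthed bulk RNA-seq counts
#'
#' Simulates NB-distributed gene counts (Var = mu + alpha * mu^2) for one or
#' more tissues with 12 control + 13 FD samples each by default. Planted
#' structure, all recorded in the returned truth object:
#' \itemize{
#'   \item two designated full-length driver features ("ELP1_FL_human",
#'     "Elp1_FL_mouse") whose CPM sum is the driver signal; their FD mean is
#'     `driver_reduction[tissue]` times the control mean;
#'   \item DEGs at configurable linear fold changes;
#'   \item co-expression modules driven by per-sample latent factors, one of
#'     which tracks the (log) driver signal so its genes are dose-responsive;
#'     the gene "Elp1" is placed in that module;
#'   \item a hidden batch confounder acting multiplicatively (log scale) on a
#'     random fraction of genes;
#'   \item log-normal library size factors (sdlog `lib_sigma`).
#' }
#'
#' @param tissues tissue names (default the five study tissues).
#' @param n_control,n_fd samples per genotype per tissue (default 12 and 13).
#' @param n_genes background gene count, >= 200 (default 2000); module,
#'   driver and DEG features are drawn from/added to this universe.
#' @param driver_reduction named fraction-of-control per tissue, each in
#'   (0, 1).
#' @param deg_spec named numeric vector gene -> linear fold change (> 0), or
#'   list(n =, fc =) to plant `n` DEGs at the given fold change(s) on
#'   adequately expressed background genes; NULL for 40 DEGs at FC 2.0 and
#'   0.5.
#' @param module_spec list of lists with `n_genes` (>= 30) and
#'   `driver_tracking` (logical); NULL for a default of three 60-gene
#'   modules, the first tracking the driver.
#' @param confounder_spec list(frac_genes, strength, n_batches); NULL for
#'   30% of genes, log-sd 0.4, 2 batches.
#' @param nb_dispersion NB dispersion alpha (default 0.05), scalar or
#'   per-gene.
#' @param driver_noise_sd log-normal noise on the per-sample driver signal
#'   (default 0.05; 0 makes the driver noiseless up to NB sampling).
#' @param lib_sigma sdlog of library size factors (default 0.3).
#' @param module_strength range of module gene loadings (default
#'   c(0.6, 0.85); against the NB noise at the default base expression this
#'   puts true gene-eigengene correlations near 0.9).
#' @param seed RNG seed; identical seeds give identical output.
#' @return list(counts = `fd_counts` over all tissues, truth = `fd_truth`).
#' @export
generate_bulk <- function(tissues = c("DRG", "TG", "MED", "cortex", "SC"),
                          n_control = 12, n_fd = 13, n_genes = 2000,
                          driver_reduction = default_driver_reduction(),
                          deg_spec = NULL, module_spec = NULL,
                          confounder_spec = NULL,
                          nb_dispersion = 0.05, driver_noise_sd = 0.05,
                          lib_sigma = 0.3,
                          module_strength = c(0.6, 0.85), seed = 1) {
  if (n_genes < 200) stop_fd("n_genes must be >= 200")
  driver_reduction <- driver_reduction[tissues]
  if (anyNA(driver_reduction))
    stop_fd("driver_reduction must name every tissue")
  if (any(driver_reduction <= 0 | driver_reduction >= 1))
    stop_fd("driver_reduction values must lie in (0, 1)")
  check_seed(seed)

  genes <- sprintf("g%04d", seq_len(n_genes))
  if (is.null(module_spec))
    module_spec <- list(list(n_genes = 60, driver_tracking = TRUE),
                        list(n_genes = 60, driver_tracking = FALSE),
                        list(n_genes = 60, driver_tracking = FALSE))
  sizes <- vapply(module_spec, `[[`, numeric(1), "n_genes")
  if (any(sizes < 30))
    stop_fd("every module must have >= 30 genes (minimum module size downstream)")
  if (sum(sizes) > n_genes - 50)
    stop_fd("modules exceed the gene universe")
  module_assignment <- stats::setNames(rep("unassigned", n_genes), genes)
  at <- 1L
  for (m in seq_along(module_spec)) {
    idx <- at:(at + sizes[m] - 1L)
    module_assignment[idx] <- paste0("PM", m)
    at <- at + sizes[m]
  }
  tracking <- which(vapply(module_spec, function(m)
    isTRUE(m$driver_tracking), logical(1)))
  # the Elp1 gene itself sits in the (first) driver-tracking module
  if (length(tracking)) {
    first_track <- which(module_assignment == paste0("PM", tracking[1]))[1]
    genes[first_track] <- "Elp1"
    names(module_assignment) <- genes
  }

  if (is.null(confounder_spec))
    confounder_spec <- list(frac_genes = 0.3, strength = 0.4, n_batches = 2)

  fl_features <- c("ELP1_FL_human", "Elp1_FL_mouse")
  all_genes <- c(fl_features, genes)
  base <- stats::setNames(exp(stats::rnorm(n_genes, log(40), 1.2)), genes)
  free <- genes[module_assignment == "unassigned"]
  # a near-silent tail (background genes only) exercises the CPM filter
  low <- sample(free, round(0.05 * n_genes))
  base[low] <- stats::runif(length(low), 0.001, 0.01)

  if (is.null(deg_spec)) deg_spec <- list(n = 40, fc = c(2.0, 0.5))
  if (is.list(deg_spec) && !is.null(deg_spec$n)) {
    # plant DEGs on adequately expressed background genes
    pool <- setdiff(free[base[free] >= 10], low)
    if (length(pool) < deg_spec$n) stop_fd("too few expressed free genes for deg_spec")
    deg_spec <- stats::setNames(rep(deg_spec$fc, length.out = deg_spec$n),
                                pool[seq_len(deg_spec$n)])
  }
  if (any(deg_spec <= 0)) stop_fd("planted fold changes must be > 0")
  bad_deg <- setdiff(names(deg_spec), genes)
  if (length(bad_deg)) stop_fd("deg_spec genes outside universe: ",
                               paste(bad_deg, collapse = ", "))
  base_fl <- stats::setNames(c(120, 80), fl_features)
  loading <- stats::setNames(stats::runif(n_genes, module_strength[1],
                                          module_strength[2]), genes)
  alpha <- rep(nb_dispersion, length.out = length(all_genes))

  conf_genes <- sample(genes, round(confounder_spec$frac_genes * n_genes))
  conf_effect <- stats::setNames(stats::rnorm(length(conf_genes), 0,
                                              confounder_spec$strength), conf_genes)

  counts_list <- list(); meta_list <- list(); batch_all <- character()
  for (tis in tissues) {
    n_s <- n_control + n_fd
    genotype <- c(rep("Control", n_control), rep("FD", n_fd))
    sex <- c(rep(c("M", "F"), length.out = n_control),
             rep(c("M", "F", "F"), length.out = n_fd))
    sample_id <- sprintf("%s_%s_%02d", tis, genotype, c(seq_len(n_control), seq_len(n_fd)))
    batch <- character(n_s)
    for (gt in c("Control", "FD"))   # balance batches within genotype
      batch[genotype == gt] <- rep(paste0("B", seq_len(confounder_spec$n_batches)),
                                   length.out = sum(genotype == gt))

    driver <- ifelse(genotype == "FD", driver_reduction[[tis]], 1) *
      exp(stats::rnorm(n_s, 0, driver_noise_sd))
    lib <- exp(stats::rnorm(n_s, 0, lib_sigma))

    log_mu <- matrix(rep(log(base), n_s), ncol = n_s,
                     dimnames = list(genes, sample_id))
    # module latent factors
    for (m in seq_along(module_spec)) {
      members <- genes[module_assignment == paste0("PM", m)]
      f <- if (m %in% tracking) drop(scale(log(driver))) else stats::rnorm(n_s)
      log_mu[members, ] <- log_mu[members, ] +
        outer(loading[members], f)
    }
    # planted DEG fold changes in FD
    fd_cols <- genotype == "FD"
    log_mu[names(deg_spec), fd_cols] <-
      log_mu[names(deg_spec), fd_cols] + log(deg_spec)
    # hidden batch confounder
    b2 <- batch != "B1"
    log_mu[conf_genes, b2] <- log_mu[conf_genes, b2] + conf_effect
    # library sizes
    mu <- sweep(exp(log_mu), 2, lib, "*")
    mu_fl <- outer(base_fl, driver) * rep(lib, each = 2)
    dimnames(mu_fl) <- list(fl_features, sample_id)
    mu_all <- rbind(mu_fl, mu)

    cnt <- matrix(stats::rnbinom(length(mu_all), mu = mu_all,
                                 size = rep(1 / alpha, ncol(mu_all))),
                  nrow = nrow(mu_all), dimnames = dimnames(mu_all))
    counts_list[[tis]] <- cnt
    meta_list[[tis]] <- data.frame(sample_id = sample_id, tissue = tis,
                                   genotype = genotype, sex = sex, batch = batch,
                                   stringsAsFactors = FALSE)
    batch_all <- c(batch_all, stats::setNames(batch, sample_id))
  }
  counts <- do.call(cbind, counts_list)
  meta <- do.call(rbind, meta_list)
  cm <- fd_counts(counts, meta, fl_features)
  dose_genes <- if (length(tracking))
    genes[module_assignment %in% paste0("PM", tracking)] else character()
  truth <- structure(list(planted_degs = deg_spec,
                          dose_responsive_genes = dose_genes,
                          module_assignment = module_assignment,
                          driver_reduction = driver_reduction,
                          confounders = stats::setNames(meta$batch, meta$sample_id),
                          confounded_genes = conf_genes,
                          ppi_edges = NULL,
                          sc_cluster_labels = NULL, sc_markers = NULL),
                     class = "fd_truth")
  list(counts = cm, truth = truth)
}

#' Generate a STRING-format PPI edge list with planted topology
#'
#' Plants a mediator chain from the driver to a hub (`chain_length` edges,
#' high scores), gives the hub at least `hub_degree` edges with scores >=
#' 400, and adds random background edges among the remaining signature
#' genes with scores spanning 1-1000 so that confidence thresholding is
#' exercised. The driver connects to the network only through the chain, so
#' the planted BFS distance from driver to hub equals `chain_length`.
#'
#' @param signature_genes gene ids available as nodes (>= chain_length +
#'   hub_degree + 2).
#' @param driver driver gene id (default "Elp1"); included in the node set.
#' @param chain_length number of edges on the driver-to-hub path
#'   (default 3).
#' @param hub_degree minimum planted hub degree (default 6).
#' @param n_background random background edges (default 40).
#' @param seed RNG seed.
#' @return data.frame (protein1, protein2, combined_score in 1..1000) with
#'   attribute `truth`: list(mediators, hub, chain_length, planted_edges).
#' @export
generate_ppi <- function(signature_genes, driver = "Elp1", chain_length = 3,
                         hub_degree = 6, n_background = 40, seed = 1) {
  check_seed(seed)
  signature_genes <- setdiff(unique(signature_genes), driver)
  need <- chain_length + hub_degree + 2
  if (length(signature_genes) < need)
    stop_fd("need at least ", need, " signature genes")
  mediators <- signature_genes[seq_len(chain_length - 1)]
  hub <- signature_genes[chain_length]
  chain_nodes <- c(driver, mediators, hub)
  chain <- cbind(chain_nodes[-length(chain_nodes)], chain_nodes[-1])
  chain_scores <- sample(700:950, nrow(chain), replace = TRUE)
  spokes <- signature_genes[chain_length + seq_len(hub_degree - 1)]
  spoke_edges <- cbind(hub, spokes)
  spoke_scores <- sample(400:900, length(spokes), replace = TRUE)
  rest <- setdiff(signature_genes, c(mediators, hub))
  bg <- unique(t(replicate(n_background * 2, sort(sample(rest, 2)))))
  bg <- bg[seq_len(min(n_background, nrow(bg))), , drop = FALSE]
  bg_scores <- sample(1:1000, nrow(bg), replace = TRUE)

  edges <- data.frame(protein1 = c(chain[, 1], spoke_edges[, 1], bg[, 1]),
                      protein2 = c(chain[, 2], spoke_edges[, 2], bg[, 2]),
                      combined_score = as.integer(c(chain_scores, spoke_scores,
                                                    bg_scores)),
                      stringsAsFactors = FALSE)
  key <- apply(edges[, 1:2], 1, function(x) paste(sort(x), collapse = "|"))
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- tapply(edges$combined_score, key, function(s) length(unique(s)) > 1)
    if (any(conflict))
      stop_fd("duplicate edge with conflicting score: ",
              paste(names(conflict)[conflict], collapse = ", "))
    edges <- edges[!dup, , drop = FALSE]
  }
  attr(edges, "truth") <- list(mediators = mediators, hub = hub,
                               chain_length = chain_length,
                               planted_edges = rbind(chain, spoke_edges))
  edges
}

#' Write an edge table in STRING protein-links format
#'
#' @param edges data.frame (protein1, protein2, combined_score).
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_string_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a toy scRNA-seq dataset with known cluster markers
#'
#' NB-distributed counts for a configurable set of cell clusters; each
#' cluster's marker genes have their mean elevated `effect`-fold in that
#' cluster. Dropout is simulated by independent zeroing of count entries.
#' The author-style marker table can be perturbed (a fraction of markers
#' replaced by random non-marker genes) to exercise the
#' marker-reconciliation rule downstream.
#'
#' @param n_cells total cells (split evenly by default; every cluster must
#'   end with >= 20 cells).
#' @param clusters named list: each element list(markers = character,
#'   effect = fold elevation, prop = cell fraction). Defaults to three
#'   clusters with 40 exclusive markers each, effect 10 — the order of
#'   separation real neuronal subtypes show.
#' @param n_genes gene universe size including markers (default 300).
#' @param dropout zeroing probability (default 0.1).
#' @param nb_dispersion NB alpha (default 0.3).
#' @param perturb_author_frac fraction of author markers replaced by random
#'   genes (default 0).
#' @param seed RNG seed.
#' @return list(counts genes x cells, labels, author_markers, truth).
#' @export
generate_scrna <- function(n_cells = 300, clusters = NULL, n_genes = 300,
                           dropout = 0.1, nb_dispersion = 0.3,
                           perturb_author_frac = 0, seed = 1) {
  check_seed(seed)
  if (is.null(clusters)) {
    clusters <- list(
      A = list(markers = sprintf("mkA_%02d", 1:40), effect = 10, prop = 1 / 3),
      B = list(markers = sprintf("mkB_%02d", 1:40), effect = 10, prop = 1 / 3),
      C = list(markers = sprintf("mkC_%02d", 1:40), effect = 10, prop = 1 / 3))
  }
  if (length(clusters) < 2) stop_fd("need at least 2 clusters")
  markers <- lapply(clusters, `[[`, "markers")
  all_markers <- unname(unlist(markers))
  n_bg <- n_genes - length(all_markers)
  if (n_bg < 10) stop_fd("n_genes too small for the marker sets")
  genes <- c(all_markers, sprintf("sg%04d", seq_len(n_bg)))
  bad <- setdiff(all_markers, genes)
  if (length(bad)) stop_fd("marker genes absent from gene universe: ",
                           paste(bad, collapse = ", "))

  props <- vapply(clusters, function(cl) cl$prop %||% (1 / length(clusters)),
                  numeric(1))
  n_per <- round(n_cells * props / sum(props))
  n_per[length(n_per)] <- n_cells - sum(n_per[-length(n_per)])
  if (any(n_per < 20)) stop_fd("every cluster must have >= 20 cells")

  base <- exp(stats::rnorm(length(genes), log(2), 0.8))
  names(base) <- genes
  labels <- rep(names(clusters), n_per)
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  lib <- exp(stats::rnorm(n_cells, 0, 0.3))
  mu <- matrix(base, nrow = length(genes), ncol = n_cells,
               dimnames = list(genes, cell_ids))
  for (cl in names(clusters)) {
    eff <- clusters[[cl]]$effect %||% 8
    mu[markers[[cl]], labels == cl] <- mu[markers[[cl]], labels == cl] * eff
  }
  mu <- sweep(mu, 2, lib, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  if (dropout > 0) {
    drop_mask <- matrix(stats::runif(length(counts)) < dropout, nrow = nrow(counts))
    counts[drop_mask] <- 0
  }

  author <- markers
  if (perturb_author_frac > 0) {
    pool <- setdiff(genes, all_markers)
    for (cl in names(author)) {
      k <- round(perturb_author_frac * length(author[[cl]]))
      if (k > 0)
        author[[cl]] <- c(author[[cl]][seq_len(length(author[[cl]]) - k)],
                          sample(pool, k))
    }
  }
  truth <- structure(list(planted_degs = NULL, dose_responsive_genes = NULL,
                          module_assignment = NULL, driver_reduction = NULL,
                          confounders = NULL, ppi_edges = NULL,
                          sc_cluster_labels = stats::setNames(labels, cell_ids),
                          sc_markers = markers),
                     class = "fd_truth")
  list(counts = counts, labels = stats::setNames(labels, cell_ids),
       author_markers = author, truth = truth)
}

#' Write a scRNA count matrix as MatrixMarket plus gene/cell TSVs
#'
#' @param counts genes x cells matrix.
#' @param dir output directory (`matrix.mtx`, `genes.tsv`, `barcodes.tsv`).
#' @return invisibly, the directory.
#' @export
write_scrna <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a scRNA count matrix written by [write_scrna()]
#'
#' @param dir directory with `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return dense genes x cells matrix.
#' @export
read_scrna <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}
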