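#' Pipeline configuration with the published analysis parameters
#'
#' Collects every tunable threshold of the pipeline with its default:
#' DEG gates (FDR < 0.1, linear FC > 1.2 or < 0.8), dose-response
#' correlation floor 0.8, STRING confidence cutoff 0.4, minimum module size
#' 30, eigengene merge cut 0.25, per-tissue soft powers (cortex 5, DRG 6,
#' MED 5, SC 6, TG 7), hub degree 5, top-200 MCA signatures, 2.5% scRNA QC
#' tails, 20-NN graph at resolution 0.2, and preservation thresholds
#' (weak 2, strong 10).
#'
#' @param ... overrides for any listed field.
#' @return `fd_config` list.
#' @export
fd_config <- function(...) {
  cfg <- list(fdr_cut = 0.1, fc_up = 1.2, fc_down = 0.8, r_min = 0.8,
              ppi_score_cut = 0.4, min_module_size = 30, merge_cut = 0.25,
              soft_powers = c(cortex = 5, DRG = 6, MED = 5, SC = 6, TG = 7),
              hub_min_degree = 5, marker_top_n = 200, sc_qc_tail = 0.025,
              knn = 20, resolution = 0.2,
              preservation = c(weak = 2, strong = 10),
              min_cpm = 0.1, sv_n_perm = 20, sv_alpha = 0.1,
              preservation_n_perm = 100,
              n_genes = 1200, n_control = 12, n_fd = 13,
              tissues = c("DRG", "TG"),
              seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop_fd("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$fc_down < 1, cfg$fc_up > 1, cfg$fdr_cut > 0)
  class(cfg) <- "fd_config"
  cfg
}

#' Run the analysis pipeline end to end on synthetic or supplied data
#'
#' Stages, in dependency order, per tissue: synthetic data generation (or
#' reading of supplied counts), expression filtering and normalization,
#' full-length ELP1 profiling, surrogate-variable estimation, NB Wald
#' differential expression with the DEG gates, co-expression modules on the
#' SV-residualized matrix, dose-responsive gene selection, FD signature
#' assembly, PPI network statistics, and cross-tissue convergence. Every
#' output TSV carries a parameter header and an FNV-1a content hash;
#' rerunning with the same config and seed reproduces the tables
#' byte-identically.
#'
#' @param config `fd_config`.
#' @param out_dir run directory for output tables; NULL for no files.
#' @param counts optional `fd_counts` to analyze instead of synthetic data.
#' @param string_edges optional STRING edge data.frame or file path; a
#'   planted network is generated per tissue when missing.
#' @return `fd_run`: per-tissue results plus convergence tables.
#' @export
fd_run_pipeline <- function(config = fd_config(), out_dir = NULL,
                            counts = NULL, string_edges = NULL) {
  set.seed(config$seed)
  if (is.null(counts)) {
    sim <- generate_bulk(tissues = config$tissues, n_control = config$n_control,
                         n_fd = config$n_fd, n_genes = config$n_genes,
                         seed = config$seed)
    cm_all <- sim$counts; truth <- sim$truth
  } else {
    cm_all <- counts; truth <- NULL
  }

  per_tissue <- list()
  for (tis in unique(cm_all$sample_meta$tissue)) {
    idx <- cm_all$sample_meta$tissue == tis
    cm <- fd_counts(cm_all$counts[, idx, drop = FALSE],
                    cm_all$sample_meta[idx, , drop = FALSE],
                    cm_all$fl_features)
    cm <- filter_expressed(cm, config$min_cpm)
    norm <- normalize_counts(cm)
    prof <- elp1_profile(cm, norm)
    svs <- estimate_svs(norm$log2_norm, cm$sample_meta$genotype,
                        n_perm = config$sv_n_perm, alpha = config$sv_alpha,
                        seed = config$seed)
    fit <- fit_nb(cm, svs)
    de <- wald_fdr(fit)
    degs <- call_degs(de, config$fdr_cut, config$fc_up, config$fc_down)

    cleaned <- residualize(norm$log2_norm, svs, cm$sample_meta$genotype)
    cleaned <- cleaned[setdiff(rownames(cleaned), cm$fl_features), , drop = FALSE]
    keep <- apply(cleaned, 1, stats::sd) > 0
    cleaned <- cleaned[keep, , drop = FALSE]
    beta <- pick_soft_power(cleaned,
                            override = unname(config$soft_powers[tis]))
    adj <- signed_adjacency(cleaned, beta %||% 6)
    modules <- detect_modules(tom_matrix(adj), cleaned,
                              min_size = config$min_module_size,
                              merge_cut = config$merge_cut)
    fl_cpm <- prof$fl_cpm
    selected <- if (ncol(modules$eigengenes) > 0)
      select_modules(modules$eigengenes, fl_cpm, config$r_min) else
      stats::setNames(numeric(0), character(0))
    dose <- dose_responsive_genes(selected, modules, cleaned, config$r_min)
    sig <- assemble_signature(degs, dose, tissue = tis)

    edges <- string_edges
    if (is.null(edges)) {
      edges <- generate_ppi(sig$gene, driver = "Elp1",
                            seed = config$seed + match(tis, config$tissues))
    } else if (is.character(edges)) {
      edges <- utils::read.delim(edges, stringsAsFactors = FALSE)
    }
    ef <- tempfile(fileext = ".tsv")
    write_string_edges(edges, ef)
    graph <- load_string_edges(ef, config$ppi_score_cut)
    unlink(ef)
    net <- induced_network(graph, sig$gene, driver = "Elp1")
    cat_vec <- stats::setNames(sig$category, sig$gene)
    hubs <- network_hubs(net, config$hub_min_degree, cat_vec)
    dists <- distances_from_driver(net, "Elp1")

    per_tissue[[tis]] <- list(counts = cm, norm = norm, profile = prof,
                              svs = svs, de = de, degs = degs,
                              modules = modules, power = beta,
                              dose = dose, signature = sig,
                              network = net, hubs = hubs, distances = dists)
  }

  convergence <- NULL
  if (length(per_tissue) >= 2) {
    deg_sets <- lapply(per_tissue, function(x)
      x$degs$gene[x$degs$status != "ns"])
    bgs <- lapply(per_tissue, function(x) rownames(x$counts$counts))
    overlaps <- pairwise_deg_overlaps(deg_sets, bgs)
    tt <- names(per_tissue)[1:2]
    shared <- intersect(deg_sets[[tt[1]]], deg_sets[[tt[2]]])
    fcA <- stats::setNames(per_tissue[[tt[1]]]$degs$log2_fc, per_tissue[[tt[1]]]$degs$gene)
    fcB <- stats::setNames(per_tissue[[tt[2]]]$degs$log2_fc, per_tissue[[tt[2]]]$degs$gene)
    fc_conc <- fc_concordance(shared, fcA, fcB)
    dist_conc <- distance_concordance(per_tissue[[tt[1]]]$distances,
                                      per_tissue[[tt[2]]]$distances, shared)
    common <- intersect(names(fcA), names(fcB))
    sA <- signed_score(stats::setNames(per_tissue[[tt[1]]]$degs$p,
                                       per_tissue[[tt[1]]]$degs$gene)[common],
                       fcA[common])
    sB <- signed_score(stats::setNames(per_tissue[[tt[2]]]$degs$p,
                                       per_tissue[[tt[2]]]$degs$gene)[common],
                       fcB[common])
    rrho <- rrho_map(sA, sB)
    convergence <- list(overlaps = overlaps, shared_degs = shared,
                        fc_concordance = fc_conc,
                        distance_concordance = dist_conc, rrho = rrho)
  }

  run <- structure(list(config = config, tissues = per_tissue,
                        convergence = convergence, truth = truth),
                   class = "fd_run")
  if (!is.null(out_dir)) write_run_tables(run, out_dir)
  run
}

# Write the run's summary tables with parameter headers and content hashes.
write_run_tables <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- run$config
  hdr <- paste0("# fdtx run; seed=", cfg$seed, "; fdr_cut=", cfg$fdr_cut,
                "; fc_up=", cfg$fc_up, "; fc_down=", cfg$fc_down,
                "; r_min=", cfg$r_min, "; ppi_score_cut=", cfg$ppi_score_cut)
  emit <- function(df, name) {
    body <- utils::capture.output(
      utils::write.table(df, sep = "\t", quote = FALSE, row.names = FALSE))
    lines <- c(hdr, paste0("# content_hash=", fnv1a_hash(body)), body)
    writeLines(lines, file.path(out_dir, name))
  }
  for (tis in names(run$tissues)) {
    x <- run$tissues[[tis]]
    emit(as.data.frame(x$degs), paste0("degs_", tis, ".tsv"))
    emit(as.data.frame(x$signature), paste0("signature_", tis, ".tsv"))
    emit(x$hubs, paste0("hubs_", tis, ".tsv"))
    emit(data.frame(gene = names(x$distances$status),
                    status = x$distances$status,
                    distance = x$distances$distances),
         paste0("distances_", tis, ".tsv"))
    emit(data.frame(gene = names(x$modules$assignment),
                    module = x$modules$assignment),
         paste0("modules_", tis, ".tsv"))
  }
  prof <- do.call(rbind, lapply(run$tissues, function(x) x$profile$by_tissue))
  emit(prof, "elp1_profile.tsv")
  if (!is.null(run$convergence))
    emit(run$convergence$overlaps, "deg_overlaps.tsv")
  invisible(out_dir)
}

#' @export
print.fd_run <- function(x, ...) {
  cat("fd_run:", length(x$tissues), "tissue(s)\n")
  for (tis in names(x$tissues)) {
    d <- x$tissues[[tis]]$degs
    cat("  ", tis, ": ", sum(d$status != "ns"), " DEGs, ",
        nrow(x$tissues[[tis]]$dose$genes), " dose-responsive, signature ",
        nrow(x$tissues[[tis]]$signature), " genes\n", sep = "")
  }
  invisible(x)
}

#' Summary report of a pipeline run
#'
#' DEG counts per tissue, signature composition, hub counts, distance
#' histograms, ELP1 percent-of-control, and cross-tissue overlap counts —
#' all percentages via the half-even two-decimal convention.
#'
#' @param run `fd_run` (or a run directory written by [fd_run_pipeline()]).
#' @return `fd_report` list of data.frames.
#' @export
fd_report <- function(run) {
  if (is.character(run)) stop_fd("pass the fd_run object; directory reload not supported")
  tiss <- names(run$tissues)
  deg_counts <- data.frame(
    tissue = tiss,
    n_deg = vapply(run$tissues, function(x) sum(x$degs$status != "ns"), numeric(1)),
    n_up = vapply(run$tissues, function(x) sum(x$degs$status == "up"), numeric(1)),
    n_down = vapply(run$tissues, function(x) sum(x$degs$status == "down"), numeric(1)),
    n_dose = vapply(run$tissues, function(x) nrow(x$dose$genes), numeric(1)),
    n_signature = vapply(run$tissues, function(x) nrow(x$signature), numeric(1)),
    pct_elp1 = vapply(run$tissues, function(x)
      round(x$profile$by_tissue$pct_of_control[1], 2), numeric(1)),
    row.names = NULL)
  deg_counts$pct_connected <- vapply(run$tissues, function(x)
    x$distances$pct_connected_to_driver, numeric(1))
  hub_tab <- do.call(rbind, lapply(tiss, function(t)
    cbind(tissue = t, run$tissues[[t]]$hubs)))
  structure(list(deg_counts = deg_counts, hubs = hub_tab,
                 overlaps = run$convergence$overlaps,
                 histograms = lapply(run$tissues, function(x) x$distances$histogram)),
            class = "fd_report")
}

#' @export
print.fd_report <- function(x, ...) {
  cat("Pipeline report\n")
  print(x$deg_counts, row.names = FALSE)
  invisible(x)
}
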