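#' Read gene sets from a GMT file
#'
#' @param path GMT file (term, description, tab-separated genes).
#' @return named list of gene id vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_fd("GMT file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Fisher's exact gene-set enrichment against an explicit background
#'
#' One-sided Fisher's exact test (enrichment direction) on the 2x2
#' in-query/in-term table over the background universe, BH-FDR across
#' terms. Terms with no background overlap are skipped (recorded in the
#' `skipped` attribute). Significant enrichment is FDR < 0.1.
#'
#' @param query gene ids, a subset of `background`.
#' @param gene_sets named list of term gene vectors (e.g. [read_gmt()]).
#' @param background background gene universe.
#' @param fdr_sig significance threshold recorded in `significant`
#'   (default 0.1).
#' @return `fd_enrich` data.frame: term, term_size, overlap, overlap_genes
#'   (comma-joined), p, fdr, significant, kept_after_pruning.
#' @export
fisher_enrich <- function(query, gene_sets, background, fdr_sig = 0.1) {
  query <- unique(query); background <- unique(background)
  out_q <- setdiff(query, background)
  if (length(out_q))
    stop_fd("query genes outside background: ",
            paste(utils::head(out_q, 10), collapse = ", "))
  N <- length(background)
  skipped <- character()
  rows <- list()
  for (term in names(gene_sets)) {
    tset <- intersect(gene_sets[[term]], background)
    if (!length(tset)) { skipped <- c(skipped, term); next }
    ov <- intersect(query, tset)
    a <- length(ov); b <- length(query) - a
    cc <- length(tset) - a; d <- N - a - b - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2),
                            alternative = "greater")$p.value
    rows[[term]] <- data.frame(term = term, term_size = length(tset),
                               overlap = a,
                               overlap_genes = paste(sort(ov), collapse = ","),
                               p = p, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop_fd("no term overlaps the background")
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr_sig
  out$kept_after_pruning <- TRUE
  out <- out[order(out$fdr, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("fd_enrich", "data.frame")
  out
}

#' Prune redundant enrichment terms by overlap score
#'
#' Terms are visited in ascending FDR order; a term is kept only when its
#' overlap score with every already-kept term stays below `overlap_cut`.
#' The overlap score is the overlap coefficient |A n B| / min(|A|, |B|)
#' computed on the terms' overlap gene sets, a proxy for semantic
#' similarity.
#'
#' @param table `fd_enrich` table.
#' @param overlap_cut redundancy threshold, typically 0.1 or 0.2.
#' @return the table with `kept_after_pruning` updated.
#' @export
prune_redundant <- function(table, overlap_cut = 0.2) {
  tab <- table[order(table$fdr, table$p, table$term), , drop = FALSE]
  sets <- strsplit(tab$overlap_genes, ",", fixed = TRUE)
  sets <- lapply(sets, function(s) s[nzchar(s)])
  kept <- logical(nrow(tab))
  kept_sets <- list()
  for (i in seq_len(nrow(tab))) {
    ok <- TRUE
    for (ks in kept_sets) {
      denom <- min(length(sets[[i]]), length(ks))
      score <- if (denom == 0) 0 else length(intersect(sets[[i]], ks)) / denom
      if (score >= overlap_cut) { ok <- FALSE; break }
    }
    kept[i] <- ok
    if (ok) kept_sets[[length(kept_sets) + 1L]] <- sets[[i]]
  }
  tab$kept_after_pruning <- kept
  tab
}
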