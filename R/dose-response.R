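#' Select co-expression modules whose eigengene tracks full-length ELP1
#'
#' Criterion (1) of the dose-responsive screen: the Pearson correlation
#' between a module eigengene and the per-sample full-length ELP1 CPM must be
#' no less than `r_min`. The criterion is signed by default, following the
#' asymmetric wording of the rule (criterion (2) uses an absolute value,
#' criterion (1) does not); set `use_abs = TRUE` for an absolute-value
#' variant.
#'
#' @param eigengenes samples x modules matrix.
#' @param elp1_fl_cpm per-sample full-length ELP1 CPM (same samples).
#' @param r_min correlation threshold (default 0.8).
#' @param use_abs apply the threshold to |r| instead of r (default FALSE).
#' @return named numeric vector: selected module -> r.
#' @export
select_modules <- function(eigengenes, elp1_fl_cpm, r_min = 0.8, use_abs = FALSE) {
  eigengenes <- as.matrix(eigengenes)
  if (nrow(eigengenes) != length(elp1_fl_cpm))
    stop_fd("eigengenes and driver must cover identical samples")
  if (stats::sd(elp1_fl_cpm) == 0) stop_fd("driver expression is constant")
  if (ncol(eigengenes) == 0) return(stats::setNames(numeric(0), character(0)))
  r <- drop(stats::cor(eigengenes, elp1_fl_cpm))
  names(r) <- colnames(eigengenes)
  crit <- if (use_abs) abs(r) else r
  r[crit >= r_min]
}

#' ELP1 dose-responsive genes
#'
#' Criterion (2): among members of the selected modules, keep genes whose
#' normalized expression has |Pearson r| >= `r_min` with their module
#' eigengene.
#'
#' @param selected named vector from [select_modules()].
#' @param modules `fd_modules` with assignment and eigengenes.
#' @param expr genes x samples normalized expression.
#' @param r_min threshold on |gene-eigengene r| (default 0.8).
#' @return `fd_dose`: data.frame `genes` (gene, module, r) and the module
#'   selection.
#' @export
dose_responsive_genes <- function(selected, modules, expr, r_min = 0.8) {
  expr <- as.matrix(expr)
  rows <- list()
  for (m in names(selected)) {
    members <- names(modules$assignment)[modules$assignment == m]
    members <- intersect(members, rownames(expr))
    if (!length(members)) next
    r <- drop(stats::cor(t(expr[members, , drop = FALSE]), modules$eigengenes[, m]))
    keep <- abs(r) >= r_min
    if (any(keep))
      rows[[m]] <- data.frame(gene = members[keep], module = m, r = r[keep],
                              stringsAsFactors = FALSE)
  }
  genes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), module = character(), r = numeric())
  rownames(genes) <- NULL
  structure(list(genes = genes, selected_modules = selected, r_min = r_min),
            class = "fd_dose")
}

#' @export
print.fd_dose <- function(x, ...) {
  cat("fd_dose:", nrow(x$genes), "dose-responsive genes in",
      length(x$selected_modules), "selected module(s) (r_min =", x$r_min, ")\n")
  invisible(x)
}

#' Assemble a tissue FD signature: DEGs union dose-responsive genes
#'
#' @param degs `fd_degs` table (or character vector of DEG ids with an
#'   optional `status` attribute).
#' @param dose `fd_dose` result for the same tissue.
#' @param tissue optional tissue label carried in the output.
#' @return `fd_signature` data.frame: gene, category in
#'   \{deg_up, deg_down, dose_responsive, both\}, and fold change/FDR where
#'   known.
#' @export
assemble_signature <- function(degs, dose, tissue = NA_character_) {
  if (is.data.frame(degs)) {
    deg_tab <- degs[degs$status %in% c("up", "down"), , drop = FALSE]
    deg_ids <- deg_tab$gene
    deg_dir <- stats::setNames(deg_tab$status, deg_tab$gene)
    fc <- stats::setNames(deg_tab$fc, deg_tab$gene)
    fdr <- stats::setNames(deg_tab$fdr, deg_tab$gene)
  } else {
    deg_ids <- as.character(degs)
    deg_dir <- stats::setNames(rep(NA_character_, length(deg_ids)), deg_ids)
    fc <- fdr <- stats::setNames(rep(NA_real_, length(deg_ids)), deg_ids)
  }
  dose_ids <- dose$genes$gene
  all_ids <- union(deg_ids, dose_ids)
  category <- ifelse(all_ids %in% deg_ids & all_ids %in% dose_ids, "both",
              ifelse(all_ids %in% dose_ids, "dose_responsive",
                     ifelse(deg_dir[all_ids] == "up", "deg_up", "deg_down")))
  out <- data.frame(gene = all_ids,
                    category = category,
                    fc = fc[all_ids],
                    fdr = fdr[all_ids],
                    tissue = tissue,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("fd_signature", "data.frame")
  out
}

#' @export
print.fd_signature <- function(x, ...) {
  cat("FD signature:", nrow(x), "genes (",
      paste(names(table(x$category)), table(x$category), collapse = ", "), ")\n")
  invisible(x)
}
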