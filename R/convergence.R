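#' Hypergeometric overlap of two gene sets
#'
#' Upper-tail hypergeometric test: p = P(X >= k) for X ~
#' Hypergeom(N, |A|, |B|), with N the non-redundant background size and k
#' the observed overlap. The four values entering the test are the two list
#' sizes, the overlap and the background.
#'
#' @param setA,setB character vectors, subsets of `background`.
#' @param background character vector of background genes.
#' @return `fd_overlap`: sizes, overlap k, N, p, shared genes.
#' @export
hypergeom_overlap <- function(setA, setB, background) {
  setA <- unique(setA); setB <- unique(setB); background <- unique(background)
  outA <- setdiff(setA, background); outB <- setdiff(setB, background)
  if (length(outA) || length(outB))
    stop_fd("sets not contained in background: ",
            paste(utils::head(c(outA, outB), 10), collapse = ", "))
  k <- length(intersect(setA, setB))
  N <- length(background)
  p <- stats::phyper(k - 1, length(setA), N - length(setA), length(setB),
                     lower.tail = FALSE)
  structure(list(n_A = length(setA), n_B = length(setB), overlap = k,
                 background = N, p = p, shared = sort(intersect(setA, setB))),
            class = "fd_overlap")
}

#' @export
print.fd_overlap <- function(x, ...) {
  cat("overlap:", x$overlap, "of", x$n_A, "x", x$n_B, "on background", x$background,
      "; p =", signif(x$p, 4), "\n")
  invisible(x)
}

#' All pairwise DEG-set overlaps across tissues
#'
#' For every tissue pair the background is the non-redundant union of the
#' two tissues' expressed genes; hypergeometric p-values are BH-corrected
#' across pairs. The pairwise intersection counts double as UpSet-style
#' plot input.
#'
#' @param deg_sets named list of DEG id vectors per tissue.
#' @param backgrounds named list of expressed-gene vectors per tissue.
#' @return data.frame: tissueA, tissueB, n_A, n_B, overlap, background, p,
#'   fdr.
#' @export
pairwise_deg_overlaps <- function(deg_sets, backgrounds) {
  tiss <- names(deg_sets)
  if (length(tiss) < 2) stop_fd("need at least 2 tissues")
  pairs <- utils::combn(tiss, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    bg <- union(backgrounds[[a]], backgrounds[[b]])
    ov <- hypergeom_overlap(intersect(deg_sets[[a]], bg),
                            intersect(deg_sets[[b]], bg), bg)
    data.frame(tissueA = a, tissueB = b, n_A = ov$n_A, n_B = ov$n_B,
               overlap = ov$overlap, background = ov$background, p = ov$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out
}

#' Fold-change concordance of shared DEGs between two tissues
#'
#' @param shared_degs gene ids present in both fold-change vectors.
#' @param fcA,fcB named log2 fold-change vectors.
#' @return list: r (Pearson), p (two-sided), n, slope, intercept; r is NA
#'   with fewer than 3 shared genes.
#' @export
fc_concordance <- function(shared_degs, fcA, fcB) {
  shared_degs <- intersect(intersect(shared_degs, names(fcA)), names(fcB))
  if (length(shared_degs) < 3)
    return(list(r = NA_real_, p = NA_real_, n = length(shared_degs),
                slope = NA_real_, intercept = NA_real_))
  x <- fcA[shared_degs]; y <- fcB[shared_degs]
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::coef(stats::lm(y ~ x))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared_degs),
       slope = unname(fit[2]), intercept = unname(fit[1]))
}

#' Concordance of driver distances between two networks
#'
#' Pearson correlation of shortest distances from the driver for genes with
#' non-zero connectivity (a finite distance) in both networks.
#'
#' @param netA,netB `fd_netsummary` objects (or named distance vectors with
#'   NA for isolated/unreachable genes).
#' @param genes optional gene subset (e.g. convergent DEGs).
#' @return list: r, p, n, genes used.
#' @export
distance_concordance <- function(netA, netB, genes = NULL) {
  dA <- if (inherits(netA, "fd_netsummary")) netA$distances else netA
  dB <- if (inherits(netB, "fd_netsummary")) netB$distances else netB
  shared <- intersect(names(dA), names(dB))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  shared <- shared[!is.na(dA[shared]) & !is.na(dB[shared])]
  if (length(shared) < 3)
    return(list(r = NA_real_, p = NA_real_, n = length(shared), genes = shared))
  ct <- stats::cor.test(dA[shared], dB[shared], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared), genes = shared)
}

#' Rank-rank hypergeometric overlap map
#'
#' Both gene lists are ranked by a signed significance score (by convention
#' -log10(p) * sign(log2 FC), most upregulated first; ties broken by gene
#' id). For each pair of rank thresholds (i*step, j*step) a 2x2 table of
#' membership above/below the thresholds is formed and its log odds ratio
#' (natural log, Haldane-Anscombe 0.5 correction) is stored, positive for
#' concordant enrichment, along with a chi-squared p-value.
#'
#' @param scoresA,scoresB named numeric vectors over the same gene universe,
#'   no NAs.
#' @param step rank step; default max(1, round(sqrt(N))).
#' @return `fd_rrho`: `log_or` and `chisq_p` matrices (thresholds on A in
#'   rows, on B in columns), `step`, `metric`.
#' @export
rrho_map <- function(scoresA, scoresB, step = NULL) {
  genes <- names(scoresA)
  if (is.null(genes) || !setequal(genes, names(scoresB)))
    stop_fd("scoresA and scoresB must be named over the same gene universe")
  if (anyNA(scoresA) || anyNA(scoresB)) stop_fd("scores must not contain NA")
  N <- length(genes)
  if (is.null(step)) step <- max(1, round(sqrt(N)))
  ordA <- genes[order(-scoresA[genes], genes)]
  ordB <- genes[order(-scoresB[genes], genes)]
  n_thr <- ceiling(N / step)
  thr <- pmin(seq_len(n_thr) * step, N)
  rankB <- stats::setNames(seq_len(N), ordB)
  posB_of_A <- rankB[ordA]       # B-rank of genes in A order
  log_or <- chisq_p <- matrix(NA_real_, n_thr, n_thr,
                              dimnames = list(thr, thr))
  for (i in seq_len(n_thr)) {
    inA <- posB_of_A[seq_len(thr[i])]
    for (j in seq_len(n_thr)) {
      a <- sum(inA <= thr[j])
      b <- thr[i] - a
      cc <- thr[j] - a
      d <- N - a - b - cc
      log_or[i, j] <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5)))
      tab <- matrix(c(a, b, cc, d), 2)
      chisq_p[i, j] <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1 else
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
  }
  structure(list(log_or = log_or, chisq_p = chisq_p, step = step, n = N,
                 metric = "signed -log10(p) ranking; natural-log odds ratios"),
            class = "fd_rrho")
}

#' @export
print.fd_rrho <- function(x, ...) {
  cat("fd_rrho:", nrow(x$log_or), "x", ncol(x$log_or), "map (step", x$step,
      "of", x$n, "genes); median diagonal log OR =",
      signif(stats::median(diag(x$log_or)), 4), "\n")
  invisible(x)
}

#' Signed significance score for RRHO ranking
#'
#' @param p per-gene p-values.
#' @param log2_fc per-gene log2 fold changes (sign source).
#' @return -log10(p) * sign(log2_fc), named like the inputs.
#' @export
signed_score <- function(p, log2_fc) {
  s <- -log10(pmax(p, 1e-300)) * sign(log2_fc)
  names(s) <- names(p) %||% names(log2_fc)
  s
}
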