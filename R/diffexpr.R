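#' Fit per-gene negative-binomial GLMs for differential expression
#'
#' Fits, for every gene, an NB log-link GLM of counts on genotype plus any
#' surrogate variables, with offset log(size factor). The NB variance is
#' parameterized as Var = mu + alpha * mu^2. Gene-wise dispersions are
#' estimated by method of moments on normalized counts, floored at 1e-8, and
#' shrunk 50/50 (log scale) toward a log-log mean-dispersion trend fitted
#' across genes. Coefficients are estimated by IRLS (tolerance 1e-8, at most
#' 100 iterations); genes that fail to converge are flagged and receive NA
#' p-values downstream.
#'
#' @param cm `fd_counts` (already filtered).
#' @param svs optional `fd_svs` or samples x k matrix of covariates.
#' @param size_factors optional; computed by median-of-ratios when missing.
#' @param shrink_weight weight of the trend in the log-scale dispersion
#'   shrinkage (default 0.5).
#' @return `fd_nbfit` with per-gene coefficients, standard errors,
#'   dispersions, base means and convergence flags.
#' @export
fit_nb <- function(cm, svs = NULL, size_factors = NULL, shrink_weight = 0.5) {
  counts <- cm$counts
  meta <- cm$sample_meta
  if (is.null(size_factors)) size_factors <- fdtx::size_factors(cm)
  sv <- if (is.null(svs)) NULL else if (inherits(svs, "fd_svs")) svs$sv else as.matrix(svs)
  genotype <- factor(meta$genotype, levels = c("Control", "FD"))
  X <- stats::model.matrix(~ genotype)
  colnames(X) <- c("Intercept", "genotypeFD")
  if (!is.null(sv) && ncol(sv) > 0) X <- cbind(X, sv)
  if (qr(X)$rank < ncol(X)) stop_fd("design matrix is not full rank")

  disp <- estimate_dispersions(counts, size_factors, shrink_weight)
  off <- log(size_factors)
  G <- nrow(counts); p <- ncol(X)
  beta <- matrix(NA_real_, G, p, dimnames = list(rownames(counts), colnames(X)))
  se <- beta
  converged <- rep(FALSE, G)
  norm_counts <- sweep(counts, 2, size_factors, "/")
  base_mean <- rowMeans(norm_counts)

  for (g in seq_len(G)) {
    y <- counts[g, ]
    if (all(y == 0)) next
    a <- disp[g]
    b <- qr.coef(qr(X), log(pmax(y, 0.5)) - off)
    b[is.na(b)] <- 0
    ok <- FALSE
    for (it in seq_len(100)) {
      eta <- off + drop(X %*% b)
      eta <- pmin(pmax(eta, -30), 30)
      mu <- exp(eta)
      w <- mu / (1 + a * mu)
      z <- (eta - off) + (y - mu) / mu
      fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
      if (is.null(fit) || anyNA(fit$coefficients)) break
      b_new <- fit$coefficients
      if (max(abs(b_new - b)) < 1e-8) { b <- b_new; ok <- TRUE; break }
      b <- b_new
    }
    beta[g, ] <- b
    if (ok) {
      mu <- exp(pmin(pmax(off + drop(X %*% b), -30), 30))
      w <- mu / (1 + a * mu)
      info <- crossprod(X * sqrt(w))
      cov <- tryCatch(solve(info), error = function(e) NULL)
      if (!is.null(cov) && all(diag(cov) > 0)) {
        se[g, ] <- sqrt(diag(cov))
        converged[g] <- TRUE
      }
    }
  }
  structure(list(beta = beta, se = se, dispersion = disp,
                 base_mean = base_mean, converged = converged,
                 design = X, size_factors = size_factors,
                 coef_name = "genotypeFD",
                 meta = list(dispersion_method = "MoM + 50/50 log-trend shrinkage",
                             shrink_weight = shrink_weight)),
            class = "fd_nbfit")
}

# Method-of-moments gene-wise dispersion with log-log trend shrinkage.
estimate_dispersions <- function(counts, size_factors, shrink_weight = 0.5,
                                 floor = 1e-8) {
  y <- sweep(counts, 2, size_factors, "/")
  m <- rowMeans(y)
  v <- apply(y, 1, stats::var)
  raw <- ifelse(m > 0, (v - m) / m^2, NA_real_)
  raw <- pmax(raw, floor)
  raw[is.na(raw)] <- floor
  use <- m > 0 & raw > floor
  if (sum(use) >= 10) {
    tr_fit <- stats::lm(log(raw[use]) ~ log(m[use]))
    trend <- exp(cbind(1, log(pmax(m, 1e-8))) %*% stats::coef(tr_fit))[, 1]
    out <- exp((1 - shrink_weight) * log(raw) + shrink_weight * log(pmax(trend, floor)))
  } else {
    out <- raw
  }
  out <- pmax(out, floor)
  names(out) <- rownames(counts)
  out
}

#' @export
print.fd_nbfit <- function(x, ...) {
  cat("fd_nbfit:", nrow(x$beta), "genes,", ncol(x$design), "coefficients;",
      sum(x$converged), "converged\n")
  invisible(x)
}

#' Wald tests and BH-FDR from a fitted NB model
#'
#' Two-sided normal p-values on beta/se for the genotype coefficient, with
#' Benjamini-Hochberg step-up FDR across all tested genes.
#'
#' @param fit `fd_nbfit`.
#' @return `fd_de` data.frame: gene, base_mean, log2_fc (FD vs Control), se,
#'   wald_stat, p, fdr, dispersion.
#' @export
wald_fdr <- function(fit) {
  cn <- fit$coef_name
  b <- fit$beta[, cn]
  s <- fit$se[, cn]
  stat <- ifelse(fit$converged, b / s, NA_real_)
  p <- ifelse(!is.na(stat) & b == 0, 1, 2 * stats::pnorm(-abs(stat)))
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- bh_adjust(p[ok])
  res <- data.frame(gene = rownames(fit$beta),
                    base_mean = fit$base_mean,
                    log2_fc = b / log(2),
                    se = s / log(2),
                    wald_stat = stat,
                    p = p, fdr = fdr,
                    dispersion = fit$dispersion,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("fd_de", "data.frame")
  res
}

#' Call DEGs with the FDR and linear fold-change gates
#'
#' A gene is upregulated when FDR < `fdr_cut` and its linear fold change
#' exceeds `fc_up`, downregulated when FDR < `fdr_cut` and the fold change is
#' below `fc_down`; otherwise not significant. The gates act on the linear
#' scale (1.2 and 0.8 are asymmetric in log space) exactly as stated.
#'
#' @param de `fd_de` from [wald_fdr()].
#' @param fdr_cut FDR threshold (default 0.1).
#' @param fc_up upregulation gate on linear FC (default 1.2).
#' @param fc_down downregulation gate on linear FC (default 0.8).
#' @return the table with `fc` and `status` columns, sorted by |log2 FC|
#'   descending.
#' @export
call_degs <- function(de, fdr_cut = 0.1, fc_up = 1.2, fc_down = 0.8) {
  fc <- 2^de$log2_fc
  status <- rep("ns", nrow(de))
  sig <- !is.na(de$fdr) & de$fdr < fdr_cut
  status[sig & fc > fc_up] <- "up"
  status[sig & fc < fc_down] <- "down"
  out <- de
  out$fc <- fc
  out$status <- status
  out <- out[order(-abs(out$log2_fc), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fd_degs", "data.frame")
  out
}

#' @export
print.fd_degs <- function(x, ...) {
  cat("DEG table:", sum(x$status == "up"), "up,", sum(x$status == "down"),
      "down of", nrow(x), "genes\n")
  print(utils::head(as.data.frame(x)[, c("gene", "log2_fc", "fdr", "status")], 10),
        row.names = FALSE)
  invisible(x)
}

#' Cross-tissue matrix of the strongest fold changes, clipped for display
#'
#' Selects the `n` most upregulated and `n` most downregulated genes by
#' greatest fold change across tissues and clips log2 fold changes to the
#' display range.
#'
#' @param de_list named list of `fd_de`/`fd_degs` tables, one per tissue.
#' @param n genes per direction (default 25).
#' @param clip two-element display range for log2 FC (default c(-1.5, 2));
#'   values beyond the range are clipped to the nearer bound.
#' @return genes x tissues matrix of clipped log2 fold changes.
#' @export
top_fc_table <- function(de_list, n = 25, clip = c(-1.5, 2)) {
  genes <- Reduce(union, lapply(de_list, function(d) d$gene))
  lfc <- sapply(de_list, function(d) d$log2_fc[match(genes, d$gene)])
  rownames(lfc) <- genes
  hi <- apply(lfc, 1, max, na.rm = TRUE)
  lo <- apply(lfc, 1, min, na.rm = TRUE)
  top_up <- rownames(lfc)[order(-hi)][seq_len(min(n, nrow(lfc)))]
  top_dn <- rownames(lfc)[order(lo)][seq_len(min(n, nrow(lfc)))]
  sel <- unique(c(top_up, rev(top_dn)))
  out <- lfc[sel, , drop = FALSE]
  out[out > clip[2]] <- clip[2]
  out[out < clip[1]] <- clip[1]
  out
}
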