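#' Estimate surrogate variables by residual SVD with permutation selection
#'
#' Hidden confounders unrelated to genotype are estimated in two steps: the
#' protected covariate (genotype) is regressed out of every gene, and the
#' residual matrix is decomposed by SVD. The number of surrogate variables k
#' is chosen by permutation parallel analysis (Buja-Eyuboglu): component i is
#' retained while its residual eigenvalue exceeds the upper `alpha` quantile
#' of the i-th eigenvalues obtained from `n_perm` matrices whose residuals are
#' permuted independently within each gene. Retention is sequential; the
#' first failing component stops the count.
#'
#' @param log_expr filtered, normalized expression, genes x samples (log
#'   scale).
#' @param genotype factor/character of length ncol(log_expr).
#' @param max_k cap on k; must be < n_samples - 2.
#' @param n_perm permutations for the eigenvalue null (default 20).
#' @param alpha upper tail probability for the eigenvalue threshold
#'   (default 0.1).
#' @param seed RNG seed for the permutations.
#' @return `fd_svs`: `sv` (samples x k, orthogonal, zero-mean columns,
#'   first nonzero loading positive), `k`, `variance_explained`.
#' @export
estimate_svs <- function(log_expr, genotype, max_k = NULL, n_perm = 20,
                         alpha = 0.1, seed = NULL) {
  log_expr <- as.matrix(log_expr)
  n <- ncol(log_expr)
  if (n < 4) stop_fd("need at least 4 samples to estimate surrogate variables")
  if (length(genotype) != n) stop_fd("genotype length must match sample count")
  if (is.null(max_k)) max_k <- n - 3L
  if (max_k >= n - 2) stop_fd("max_k must be smaller than n_samples - 2")
  check_seed(seed)

  design <- stats::model.matrix(~ factor(genotype))
  # residuals of the per-gene genotype regression, all genes at once
  qrD <- qr(design)
  resid <- t(qr.resid(qrD, t(log_expr)))
  sv_obj <- svd(resid, nu = 0)
  ev <- sv_obj$d^2 / sum(sv_obj$d^2)

  # Buja-Eyuboglu null: permute the raw matrix within genes, re-residualize,
  # and compare eigenvalue *proportions* so observed and null matrices carry
  # identical per-gene variance and rank deficiency.
  perm_ev <- matrix(0, n_perm, length(ev))
  for (b in seq_len(n_perm)) {
    permuted <- t(apply(log_expr, 1, sample))
    permuted <- t(qr.resid(qrD, t(permuted)))
    d2 <- svd(permuted, nu = 0, nv = 0)$d^2
    perm_ev[b, ] <- d2 / sum(d2)
  }
  thresh <- apply(perm_ev, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  k <- 0L
  for (i in seq_len(min(max_k, length(ev)))) {
    if (ev[i] > thresh[i]) k <- i else break
  }

  if (k > 0) {
    sv <- sv_obj$v[, seq_len(k), drop = FALSE]
    # sign convention: first nonzero loading positive
    for (j in seq_len(k)) {
      nz <- which(abs(sv[, j]) > 1e-12)[1]
      if (!is.na(nz) && sv[nz, j] < 0) sv[, j] <- -sv[, j]
    }
    rownames(sv) <- colnames(log_expr)
    colnames(sv) <- paste0("SV", seq_len(k))
    ve <- ev[seq_len(k)] / sum(ev)
  } else {
    sv <- matrix(0, n, 0, dimnames = list(colnames(log_expr), NULL))
    ve <- numeric(0)
  }
  structure(list(sv = sv, k = k, variance_explained = ve,
                 eigenvalues = ev, thresholds = thresh),
            class = "fd_svs")
}

#' @export
print.fd_svs <- function(x, ...) {
  cat("fd_svs: k =", x$k, "surrogate variable(s)")
  if (x$k > 0)
    cat("; variance explained:", paste(signif(x$variance_explained, 3), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Remove surrogate-variable effects while protecting covariates of interest
#'
#' Fits, per gene, a least-squares model on the protected covariates plus the
#' surrogate variables, and subtracts only the surrogate-variable
#' contribution. The genotype signal is untouched, producing a cleaned matrix
#' whose variance is mainly due to the genotype difference, suitable for
#' co-expression analysis.
#'
#' @param log_expr genes x samples matrix.
#' @param svs `fd_svs` (or a samples x k matrix) from the same samples.
#' @param protect protected covariate(s): vector or samples x p matrix
#'   (genotype, typically). An intercept is always protected.
#' @return matrix of the same shape as `log_expr`.
#' @export
residualize <- function(log_expr, svs, protect) {
  log_expr <- as.matrix(log_expr)
  sv <- if (inherits(svs, "fd_svs")) svs$sv else as.matrix(svs)
  n <- ncol(log_expr)
  if (nrow(sv) != n && ncol(sv) != 0)
    stop_fd("surrogate variables were estimated on different samples")
  if (ncol(sv) == 0) return(log_expr)
  prot <- if (is.null(dim(protect))) {
    stats::model.matrix(~ factor(protect))[, -1, drop = FALSE]
  } else as.matrix(protect)
  design <- cbind(Intercept = 1, prot, sv)
  qrD <- qr(design)
  if (qrD$rank < ncol(design)) {
    keep <- qrD$pivot[seq_len(qrD$rank)]
    stop_fd("rank-deficient design; collinear columns: ",
            paste(colnames(design)[setdiff(seq_len(ncol(design)), keep)],
                  collapse = ", "))
  }
  beta <- t(qr.coef(qrD, t(log_expr)))      # genes x p
  sv_cols <- (ncol(design) - ncol(sv) + 1):ncol(design)
  cleaned <- log_expr - beta[, sv_cols, drop = FALSE] %*% t(sv)
  dimnames(cleaned) <- dimnames(log_expr)
  cleaned
}
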