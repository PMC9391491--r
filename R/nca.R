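# Network component analysis: topology-constrained factorization of a log2
# expression compendium E ~ A %*% P, where A carries regulator -> gene
# interaction strengths restricted to an annotated support and P carries
# per-condition regulator activities.  Solved by constrained alternating
# least squares (a deliberate substitution for Robust NCA / Iterative
# Sub-NCA: downstream consumers only need A and P).  Fold changes are read
# off as A times the spread between high- and low-activity condition sets.

#' Preprocess a signed regulatory topology
#'
#' Splits dual regulators (those with both activating and repressing edges)
#' into two sign-homogeneous rows (`<reg>_pos`, `<reg>_neg`); edges with
#' ambiguous sign (0) are duplicated into both rows.
#'
#' @param edges data.frame with columns `regulator`, `gene`, `sign`
#'   (+1, -1, or 0 for ambiguous).
#' @return Signed regulator x gene sparsity matrix (entries in -1/0/+1) of
#'   class `topology_mask`.
#' @export
preprocess_topology <- function(edges) {
  stopifnot(nrow(edges) > 0, all(c("regulator", "gene", "sign") %in% names(edges)))
  rows <- list()
  for (reg in unique(edges$regulator)) {
    sub <- edges[edges$regulator == reg, ]
    pos <- sub$gene[sub$sign >= 0]   # + and ambiguous
    neg <- sub$gene[sub$sign <= 0]   # - and ambiguous
    has_pos <- any(sub$sign > 0)
    has_neg <- any(sub$sign < 0)
    ambiguous_only <- !has_pos && !has_neg
    if ((has_pos && has_neg) || ambiguous_only) {
      if (length(pos) > 0) rows[[paste0(reg, "_pos")]] <- list(genes = pos, sign = 1)
      if (length(neg) > 0) rows[[paste0(reg, "_neg")]] <- list(genes = neg, sign = -1)
    } else if (has_pos) {
      rows[[reg]] <- list(genes = pos, sign = 1)
    } else {
      rows[[reg]] <- list(genes = neg, sign = -1)
    }
  }
  genes <- unique(edges$gene)
  Z <- matrix(0, length(rows), length(genes),
              dimnames = list(names(rows), genes))
  for (r in names(rows)) Z[r, rows[[r]]$genes] <- rows[[r]]$sign
  structure(Z, class = c("topology_mask", "matrix", "array"))
}

#' Constrained alternating least squares NCA
#'
#' Minimizes `||E - A %*% P||^2` subject to `A` vanishing outside the support
#' of the topology mask.  The P-step solves unconstrained least squares given
#' `A`; the A-step solves, per gene, least squares restricted to that gene's
#' allowed regulators.  Both steps are exact block minimizations, so the
#' residual is non-increasing.  After convergence each activity row of `P` is
#' standardized to unit variance with the reciprocal scale absorbed into `A`
#' (resolving the scaling indeterminacy so fold changes are comparable).
#'
#' @param E Genes x conditions matrix of log2 expression.
#' @param mask Regulator x gene mask from [preprocess_topology()] (or any
#'   signed matrix with gene columns matching rows of `E`).
#' @param max_iter,tol Iteration cap and relative residual-change tolerance.
#' @param seed Integer seed (initialization is deterministic — A starts at the
#'   mask signs — but the seed is fixed for reproducibility of any
#'   tie-breaking).
#' @return List of class `nca_fit` with `A`, `P`, `residual` (final RSS) and
#'   `residual_path`.
#' @export
solve_nca <- function(E, mask, max_iter = 200, tol = 1e-12, seed = 1) {
  E <- as.matrix(E)
  Z <- unclass(mask)
  if (any(rowSums(Z != 0) == 0))
    stop_domain("solve_nca: mask has an all-zero regulator row")
  genes <- rownames(E) %||% as.character(seq_len(nrow(E)))
  if (!is.null(colnames(Z))) {
    if (!setequal(colnames(Z), genes))
      stop_domain("solve_nca: mask gene columns do not match rows of E")
    Z <- Z[, genes, drop = FALSE]
  } else if (ncol(Z) != nrow(E)) {
    stop_domain("solve_nca: mask width does not match number of genes")
  }
  k <- nrow(Z)
  if (qr(t(Z != 0) * 1)$rank < k)
    warning("solve_nca: support pattern may be non-identifiable")
  set.seed(seed)
  # initialize at the mask signs, with a small seeded jitter on the support
  # to break the column symmetry of dense masks (a pure sign start traps
  # alternating least squares in a rank-deficient subspace)
  support <- t(Z != 0)
  A <- t(Z) * 1
  A[support] <- A[support] * (1 + 0.05 * stats::runif(sum(support)))
  rss <- Inf
  path <- numeric(0)
  for (iter in seq_len(max_iter)) {
    # P-step: unconstrained LS given A
    P <- tryCatch(qr.solve(A, E), error = function(e)
      MASS_ginv(crossprod(A)) %*% crossprod(A, E))
    # A-step: per gene, restrict to allowed regulators
    for (g in seq_len(nrow(E))) {
      idx <- which(support[g, ])
      X <- t(P[idx, , drop = FALSE])
      a <- tryCatch(qr.solve(X, E[g, ]), error = function(e)
        as.numeric(MASS_ginv(crossprod(X)) %*% crossprod(X, E[g, ])))
      A[g, ] <- 0
      A[g, idx] <- a
    }
    new_rss <- sum((E - A %*% P)^2)
    path <- c(path, new_rss)
    if (is.finite(rss) && abs(rss - new_rss) <= tol * max(rss, 1)) {
      rss <- new_rss
      break
    }
    rss <- new_rss
  }
  P <- tryCatch(qr.solve(A, E), error = function(e)
    MASS_ginv(crossprod(A)) %*% crossprod(A, E))
  # absorb activity scale into A
  for (j in seq_len(k)) {
    s <- stats::sd(P[j, ])
    if (s > 0) {
      P[j, ] <- P[j, ] / s
      A[, j] <- A[, j] * s
    }
  }
  rss <- sum((E - A %*% P)^2)
  rownames(P) <- rownames(Z)
  colnames(A) <- rownames(Z)
  rownames(A) <- genes
  structure(list(A = A, P = P, residual = rss, residual_path = path),
            class = "nca_fit")
}

# Tiny Moore-Penrose fallback (avoids importing MASS for one corner case).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' High/low activity extremes of a regulator
#'
#' The high set contains conditions with activity above mean + sd, unioned
#' with the top 10 activities (so at least 10 conditions always enter); the
#' low set is the mirror image.  Returns the mean activity of each set.
#'
#' @param p Activity row for one regulator (>= 10 conditions).
#' @return List with `P_high`, `P_low` and the index sets `high`, `low`.
#' @export
activity_extremes <- function(p) {
  n <- length(p)
  if (n < 10) stop_domain("activity_extremes: need >= 10 conditions")
  m <- mean(p); s <- stats::sd(p)
  ord <- order(p, decreasing = TRUE)
  high <- union(which(p > m + s), ord[1:10])
  low <- union(which(p < m - s), rev(ord)[1:10])
  list(P_high = mean(p[high]), P_low = mean(p[low]), high = high, low = low)
}

#' Regulator-on-gene fold change
#'
#' `FC_ij = A_ij * (P_high,j - P_low,j)` (log2 scale).
#'
#' @param fit An `nca_fit` from [solve_nca()].
#' @return Genes x regulators matrix of log2 fold changes.
#' @export
nca_fold_change <- function(fit) {
  spread <- apply(fit$P, 1, function(p) {
    e <- activity_extremes(p)
    e$P_high - e$P_low
  })
  sweep(fit$A, 2, spread, `*`)
}
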