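# Global population structure: identity-by-state similarity with classical
# MDS, genotype PCA, a windowed local-vs-global canonical-correlation scan,
# and maximum-likelihood EM estimation of individual admixture proportions
# under the binomial observation model g_ij ~ Binomial(2, sum_k q_ik f_kj).

#' Identity-by-state similarity matrix
#'
#' `IBS(i, j)` is the mean over co-called SNPs of the shared allele count
#' divided by 2, i.e. `1 - |d_i - d_j| / 2` averaged. Pairs with no
#' co-called SNPs get `NA`.
#'
#' @param x a `geno_cohort` (>= 2 samples).
#' @return symmetric matrix with unit diagonal.
#' @export
ibs_matrix <- function(x) {
  g <- x$geno
  if (nrow(g) < 2) stop("ibs_matrix needs >= 2 samples")
  called <- !is.na(g)
  i0 <- (!is.na(g) & g == 0L) + 0
  i1 <- (!is.na(g) & g == 1L) + 0
  i2 <- (!is.na(g) & g == 2L) + 0
  # sum over co-called SNPs of |d_i - d_j| via dosage-indicator products
  diff_sum <- i0 %*% t(i1) + i1 %*% t(i0) + i1 %*% t(i2) + i2 %*% t(i1) +
    2 * (i0 %*% t(i2) + i2 %*% t(i0))
  n_cc <- (called + 0) %*% t(called + 0)
  ibs <- 1 - diff_sum / (2 * n_cc)
  ibs[n_cc == 0] <- NA_real_
  diag(ibs) <- 1
  dimnames(ibs) <- list(x$samples$sample_id, x$samples$sample_id)
  ibs
}

#' Classical (metric) MDS of an IBS matrix
#'
#' Embeds `D = 1 - IBS` by double-centering and eigendecomposition
#' (Torgerson scaling, via `stats::cmdscale`); coordinates are
#' eigenvectors scaled by the square root of their eigenvalues, ordered by
#' eigenvalue.
#'
#' @param ibs complete symmetric IBS matrix.
#' @param n_dims dimensions to extract (default 4).
#' @return list with `points` (samples x n_dims), `eig`, and the input
#'   `ibs`.
#' @export
classical_mds <- function(ibs, n_dims = 4) {
  if (anyNA(ibs)) stop("IBS matrix has missing entries")
  d <- 1 - ibs
  fit <- stats::cmdscale(d, k = n_dims, eig = TRUE)
  if (fit$eig[1] < 0) stop("degenerate IBS input: negative leading eigenvalue")
  list(points = fit$points, eig = fit$eig, ibs = ibs)
}

#' Genotype principal component analysis
#'
#' Variants are centered by mean dosage and scaled by
#' `sqrt(2 * p * (1 - p))` with `p` the sample counted-allele frequency
#' (the usual genotype standardization); missing entries are mean-imputed
#' (standardized to 0) before decomposition. Monomorphic variants are
#' dropped. Each component's loading vector is sign-fixed so its
#' largest-magnitude entry is positive.
#'
#' @param x a `geno_cohort`.
#' @param markers optional `marker_set` restricting the variants used.
#' @param n_comp components to return (default `min(10, n - 1)`).
#' @return list with `scores`, `eig` (eigenvalues of the sample
#'   covariance), `loadings`, `center`, `scale`, `variant_idx`,
#'   `n_dropped_monomorphic`.
#' @export
pca_genotypes <- function(x, markers = NULL, n_comp = NULL) {
  idx <- if (is.null(markers)) seq_len(ncol(x$geno)) else markers$variant_idx
  g <- x$geno[, idx, drop = FALSE]
  n <- nrow(g)
  if (n < 2) stop("PCA needs >= 2 samples")
  p <- allele_freq(g)
  poly <- !is.na(p) & p > 0 & p < 1
  g <- g[, poly, drop = FALSE]
  idx <- idx[poly]
  p <- p[poly]
  center <- 2 * p
  scl <- sqrt(2 * p * (1 - p))
  xs <- sweep(sweep(g, 2, center, "-"), 2, scl, "/")
  xs[is.na(xs)] <- 0
  if (is.null(n_comp)) n_comp <- min(10L, n - 1L)
  n_comp <- min(n_comp, n - 1L, ncol(xs))
  sv <- svd(xs, nu = n_comp, nv = n_comp)
  # sign convention: largest-magnitude loading entry positive
  for (c in seq_len(n_comp)) {
    peak <- which.max(abs(sv$v[, c]))
    if (sv$v[peak, c] < 0) {
      sv$v[, c] <- -sv$v[, c]
      sv$u[, c] <- -sv$u[, c]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_comp)], n_comp)
  rownames(scores) <- x$samples$sample_id
  list(scores = scores, eig = sv$d[seq_len(n_comp)]^2 / (n - 1),
       loadings = sv$v, center = center, scale = scl, variant_idx = idx,
       n_dropped_monomorphic = sum(!poly))
}

#' Largest squared canonical correlation between two score matrices
#'
#' Columns are centered and orthonormalized (QR with rank detection); the
#' largest singular value of the cross-product of the two orthonormal bases
#' is the largest canonical correlation. Invariant to invertible linear
#' transforms of either matrix; bounded in [0, 1].
#'
#' @param a,b numeric matrices with the same row (sample) order.
#' @return the squared largest canonical correlation.
#' @export
cca_rho2 <- function(a, b) {
  if (nrow(a) != nrow(b)) stop("row counts differ")
  qa <- ortho_basis(a)
  qb <- ortho_basis(b)
  s <- svd(crossprod(qa, qb), nu = 0, nv = 0)$d[1]
  min(1, s^2)
}

ortho_basis <- function(m) {
  m <- sweep(m, 2, colMeans(m), "-")
  qr_m <- qr(m)
  rank <- qr_m$rank
  if (rank < ncol(m)) {
    message("rank-deficient matrix reduced from ", ncol(m), " to ", rank,
            " columns")
  }
  qr.Q(qr_m)[, seq_len(rank), drop = FALSE]
}

#' Windowed local-vs-global ancestry scan
#'
#' Tiles each autosome into half-open windows of `window_mb` megabases
#' anchored at position 0. In every window with at least `n_snps_min`
#' SNPs, computes a local PCA (same standardization as [pca_genotypes()])
#' and the squared largest canonical correlation between its top `n_pcs`
#' score columns and the top `n_pcs` global PC scores. Windows below the
#' SNP minimum are skipped.
#'
#' @param x a `geno_cohort`.
#' @param global_scores matrix of global PC scores (same sample order).
#' @param window_mb window size in Mb (default 20).
#' @param n_pcs PCs on each side of the canonical correlation (default 10).
#' @param n_snps_min minimum SNPs per analyzed window (default 50; a
#'   10-PC local basis needs comfortably more SNPs than PCs).
#' @return data frame: `chrom`, `start_bp`, `end_bp`, `n_snps`, `rho2`.
#' @export
local_global_scan <- function(x, global_scores, window_mb = 20, n_pcs = 10,
                              n_snps_min = 50) {
  v <- x$variants
  auto <- is_autosome(v$chrom)
  gpcs <- global_scores[, seq_len(min(n_pcs, ncol(global_scores))),
                        drop = FALSE]
  win_bp <- window_mb * 1e6
  out <- list()
  for (ch in unique(v$chrom[auto])) {
    on_ch <- which(v$chrom == ch)
    wid <- v$pos[on_ch] %/% win_bp
    for (w in unique(wid)) {
      snps <- on_ch[wid == w]
      if (length(snps) < n_snps_min) next
      sub <- subset_cohort(x, variants = snps)
      lp <- pca_genotypes(sub, n_comp = n_pcs)
      k <- min(n_pcs, ncol(lp$scores))
      rho2 <- cca_rho2(lp$scores[, seq_len(k), drop = FALSE], gpcs)
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_bp = w * win_bp, end_bp = (w + 1) * win_bp,
        n_snps = length(snps), rho2 = rho2, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer(),
                      rho2 = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Maximum-likelihood admixture estimation by EM
#'
#' Fits the admixture model `g_ij ~ Binomial(2, pi_ij)`,
#' `pi_ij = sum_k q_ik f_kj`, by EM: the E-step attributes each observed
#' allele to an ancestral population, the M-step re-estimates the admixture
#' proportions `Q` (rows on the simplex) and population frequencies `F`
#' (clipped to `[1e-6, 1 - 1e-6]`). Missing genotypes contribute no
#' likelihood terms. The log-likelihood is non-decreasing across
#' iterations; the best of `n_restarts` random restarts is returned.
#' Component labels are arbitrary (label switching is handled only in
#' evaluation, see [align_admixture()]).
#'
#' @param x a `geno_cohort`.
#' @param markers optional `marker_set` (the model assumes linkage
#'   equilibrium, so pass a pruned set).
#' @param K number of ancestral populations (>= 1).
#' @param n_restarts random restarts (default 3).
#' @param seed RNG seed; restart r uses `seed + r - 1`.
#' @param tol stop when the log-likelihood gain drops below this.
#' @param max_iter iteration cap per restart.
#' @return an `ancestry_model` list: `K`, `Q`, `F`, `loglik` (best), `trace`
#'   (per-iteration log-likelihoods of the best restart), `n_restarts`,
#'   `seed`, `converged`.
#' @export
admixture_em <- function(x, markers = NULL, K, n_restarts = 3, seed = 1,
                         tol = 1e-4, max_iter = 300) {
  idx <- if (is.null(markers)) seq_len(ncol(x$geno)) else markers$variant_idx
  g <- x$geno[, idx, drop = FALSE]
  n <- nrow(g)
  m <- ncol(g)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K (", K, ") exceeds sample count (", n, ")")
  called <- !is.na(g)
  g0 <- ifelse(called, g, 0)           # counted-allele copies
  g2 <- ifelse(called, 2 - g, 0)       # other-allele copies
  n_called2 <- 2 * rowSums(called)
  const <- log(2) * sum(g == 1L, na.rm = TRUE)  # binomial coefficients
  p_hat <- allele_freq(g)

  if (K == 1) {
    f <- matrix(pmin(pmax(p_hat, 1e-6), 1 - 1e-6), 1, m)
    ll <- sum(g0 * log(f[rep(1, n), , drop = FALSE]) +
                g2 * log(1 - f[rep(1, n), , drop = FALSE])) + const
    return(structure(list(K = 1L, Q = matrix(1, n, 1), F = f, loglik = ll,
                          trace = ll, n_restarts = 0L, seed = seed,
                          converged = TRUE),
                     class = "ancestry_model"))
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- NULL
    sub_seed <- seed + r - 1
    # restart 1 starts from a spectral (PCA + k-means) guess, later
    # restarts from random points
    init <- if (r == 1) "spectral" else "random"
    for (attempt in 1:3) {
      set.seed(sub_seed)
      fit <- em_one_run(g0, g2, n_called2, p_hat, K, tol, max_iter, const,
                        init)
      if (is.finite(fit$loglik)) break
      warning("non-finite log-likelihood; restarting with a new sub-seed")
      sub_seed <- sub_seed + 1000L
      init <- "random"
    }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(list(K = as.integer(K), Q = best$Q, F = best$F,
                 loglik = best$loglik, trace = best$trace,
                 n_restarts = as.integer(n_restarts), seed = seed,
                 converged = best$converged),
            class = "ancestry_model")
}

em_one_run <- function(g0, g2, n_called2, p_hat, K, tol, max_iter, const,
                       init = "random") {
  n <- nrow(g0)
  m <- ncol(g0)
  if (init == "spectral") {
    start <- em_spectral_start(g0, g2, p_hat, K)
    Q <- start$Q
    F <- start$F
  } else {
    Q <- rdirichlet(n, rep(1, K))
    F <- matrix(pmin(pmax(rep(p_hat, each = K) +
                            stats::runif(K * m, -0.2, 0.2), 0.05), 0.95),
                K, m)
  }
  trace <- numeric(0)
  converged <- FALSE
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    P <- Q %*% F
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    ll <- sum(g0 * log(P) + g2 * log(1 - P)) + const
    trace <- c(trace, ll)
    if (!is.finite(ll)) break
    # E/M in matrix form: with A = g0 / P and B = g2 / (1 - P), the
    # expected population-k allele counts reduce to crossproducts
    A <- g0 / P
    B <- g2 / (1 - P)
    RA <- A %*% t(F)                    # n x K
    RB <- B %*% t(1 - F)
    CA <- crossprod(A, Q)               # m x K
    CB <- crossprod(B, Q)
    Q <- Q * (RA + RB) / n_called2
    Q <- Q / rowSums(Q)                 # exact simplex projection
    f_num <- F * t(CA)
    f_den <- f_num + (1 - F) * t(CB)
    F <- pmin(pmax(f_num / pmax(f_den, 1e-300), 1e-6), 1 - 1e-6)
    if (it > 1 && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(Q = Q, F = F, loglik = trace[length(trace)], trace = trace,
       converged = converged)
}

# spectral starting point: k-means on the leading principal components of
# the standardized dosage matrix; cluster members start at 90% ancestry
# from their cluster, and F at the cluster allele frequencies
em_spectral_start <- function(g0, g2, p_hat, K) {
  n <- nrow(g0)
  m <- ncol(g0)
  called <- (g0 + g2) > 0
  scl <- sqrt(pmax(2 * p_hat * (1 - p_hat), 1e-8))
  xs <- sweep(sweep(ifelse(called, g0, NA), 2, 2 * p_hat, "-"), 2, scl, "/")
  xs[is.na(xs)] <- 0
  d <- min(max(K - 1, 1), n - 1)
  sv <- svd(xs, nu = d, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(d)], d)
  km <- stats::kmeans(scores, centers = K, nstart = 5)
  Q <- matrix(0.1 / max(K - 1, 1), n, K)
  Q[cbind(seq_len(n), km$cluster)] <- 0.9
  Q <- Q / rowSums(Q)
  F <- matrix(NA_real_, K, m)
  for (k in seq_len(K)) {
    rows <- km$cluster == k
    if (sum(rows) == 0) {
      F[k, ] <- p_hat
    } else {
      F[k, ] <- colSums(g0[rows, , drop = FALSE]) /
        pmax(colSums((g0 + g2)[rows, , drop = FALSE]), 1)
    }
  }
  F <- pmin(pmax(F, 0.01), 0.99)
  list(Q = Q, F = F)
}

#' Align admixture components to a reference by correlation matching
#'
#' Finds the component permutation maximizing the summed signed
#' correlation between columns of `Q` and `Q_ref` (exhaustive over
#' permutations; K up to 7). Signed correlation is required: on the
#' 2-component simplex the two permutations have identical absolute
#' correlations, and only the sign identifies the matching labels.
#'
#' @param model an `ancestry_model` (or a Q matrix).
#' @param q_ref reference proportions, same rows.
#' @return list with permuted `Q`, the `permutation`, and mean absolute
#'   error `mae` against the reference.
#' @export
align_admixture <- function(model, q_ref) {
  Q <- if (inherits(model, "ancestry_model")) model$Q else model
  K <- ncol(Q)
  if (K > 7) stop("alignment supports K <= 7")
  cors <- suppressWarnings(stats::cor(Q, q_ref))
  cors[is.na(cors)] <- 0
  perms <- permn(K)
  score <- vapply(perms, function(pm) {
    sum(cors[cbind(pm, seq_len(K))])
  }, numeric(1))
  pm <- perms[[which.max(score)]]
  Qp <- Q[, pm, drop = FALSE]
  list(Q = Qp, permutation = pm, mae = mean(abs(Qp - q_ref)))
}

permn <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in permn(k - 1)) {
      tail <- seq_len(k)[-i][rest]
      out[[length(out) + 1]] <- c(i, tail)
    }
  }
  out
}

#' Order samples along an ancestry continuum
#'
#' Samples sorted by a chosen admixture component, descending; ties broken
#' by sample id for a stable, reproducible order.
#'
#' @param model an `ancestry_model`.
#' @param component population index to sort on.
#' @param sample_ids optional ids for tie-breaking (default row order).
#' @return integer permutation of sample indices.
#' @export
continuum_sort <- function(model, component, sample_ids = NULL) {
  if (component < 1 || component > model$K) {
    stop("component must be in 1..", model$K)
  }
  q <- model$Q[, component]
  if (is.null(sample_ids)) sample_ids <- seq_along(q)
  order(-q, sample_ids)
}

#' Admixture fit summaries across K
#'
#' One [admixture_em()] fit per K; reports best log-likelihood and free
#' parameter count (`N (K - 1) + K M`). No automatic selection is applied.
#'
#' @param x a `geno_cohort`.
#' @param markers optional `marker_set`.
#' @param k_range values of K (default 2:7).
#' @param ... passed to [admixture_em()].
#' @return data frame: `K`, `loglik`, `n_parameters`; the fitted models as
#'   attribute `models`.
#' @export
loglik_by_k <- function(x, markers = NULL, k_range = 2:7, ...) {
  n <- nrow(x$geno)
  m <- if (is.null(markers)) ncol(x$geno) else length(markers$variant_idx)
  fits <- lapply(k_range, function(k) admixture_em(x, markers, K = k, ...))
  out <- data.frame(
    K = k_range,
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    n_parameters = n * (k_range - 1) + k_range * m
  )
  attr(out, "models") <- fits
  out
}
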