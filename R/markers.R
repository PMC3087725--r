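# Analysis marker sets: sliding-window LD pruning and delta-statistic
# selection of ancestry-informative markers (AIMs).

#' Squared dosage correlation between two variants
#'
#' Squared Pearson correlation over samples with both calls present.
#' Returns `NA` if fewer than two complete pairs or either variant is
#' monomorphic on the overlap (pruning treats that as 0).
#'
#' @param x,y dosage vectors.
#' @return r-squared, or `NA` when undefined.
#' @export
genotype_r2 <- function(x, y) {
  both <- !is.na(x) & !is.na(y)
  if (sum(both) < 2) return(NA_real_)
  xs <- x[both]
  ys <- y[both]
  if (stats::var(xs) == 0 || stats::var(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)^2
}

#' Sliding-window LD pruning
#'
#' Greedy within-window pruning: per chromosome, scan windows of
#' `window_snps` consecutive retained-or-not variants, removing one member
#' of every retained pair with `r^2 > r2_max` until none remains, then
#' advance `step_snps` and repeat to the end of the genome; passes repeat
#' until stable and a final stride-1 sweep enforces the contract at window
#' offsets the stride skips, so [prune_violations()] on the result is 0 by
#' construction. The removed member of a pair is the one with higher
#' missingness, then lower MAF, then later position. Undefined pairwise
#' r-squared counts as no LD.
#'
#' @param x a `geno_cohort` with variants sorted by (chrom, pos).
#' @param window_snps window width in SNPs (>= 2).
#' @param step_snps window shift in SNPs.
#' @param r2_max maximum retained pairwise r-squared.
#' @return a `marker_set` list: `name`, `variant_idx` (increasing), `rsid`,
#'   `provenance`.
#' @export
ld_prune <- function(x, window_snps = 50, step_snps = 5, r2_max = 0.2) {
  if (window_snps < 2) stop("window_snps must be >= 2")
  v <- x$variants
  g <- x$geno
  miss <- colMeans(is.na(g))
  p <- allele_freq(g)
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, ncol(g))
  # Windows slide over the currently retained sequence and passes repeat
  # until a full pass removes nothing. A final stride-1 sweep covers window
  # offsets the stride skips, so the no-high-LD-pair contract holds for
  # every window of the retained sequence, not just those on the stride
  # grid.
  prune_pass <- function(keep, stride) {
    repeat {
      removed_any <- FALSE
      for (ch in unique(v$chrom)) {
        s <- 1L
        repeat {
          idx <- which(keep & v$chrom == ch)
          if (s > length(idx) - 1L) break
          win <- idx[s:min(s + window_snps - 1L, length(idx))]
          while (length(win) >= 2) {
            worst <- find_high_ld_pair(g, win, r2_max)
            if (is.null(worst)) break
            victim <- pick_victim(worst[1], worst[2], miss, maf)
            keep[victim] <- FALSE
            win <- setdiff(win, victim)
            removed_any <- TRUE
          }
          s <- s + stride
        }
      }
      if (!removed_any) break
    }
    keep
  }
  keep <- prune_pass(keep, step_snps)
  keep <- prune_pass(keep, 1L)
  marker_set(
    name = "ld_pruned",
    variant_idx = which(keep),
    rsid = v$rsid[keep],
    provenance = list(method = "ld_prune",
                      parameters = list(window_snps = window_snps,
                                        step_snps = step_snps,
                                        r2_max = r2_max),
                      n_before = ncol(g), n_after = sum(keep))
  )
}

# exact complete-pairs r2 matrix for a window, via masked crossproducts
# (equivalent to per-pair Pearson correlation over co-called samples)
pairwise_r2_matrix <- function(sub) {
  called <- !is.na(sub)
  x0 <- ifelse(called, sub, 0)
  cmat <- called + 0
  n <- crossprod(cmat)                    # co-called counts
  sx <- crossprod(x0, cmat)               # sum of x over co-called pairs
  sxx <- crossprod(x0^2, cmat)
  sxy <- crossprod(x0)
  cov_xy <- sxy - sx * t(sx) / pmax(n, 1)
  var_x <- sxx - sx^2 / pmax(n, 1)
  denom <- var_x * t(var_x)
  r2 <- cov_xy^2 / denom
  r2[denom <= 0 | n < 2] <- 0             # undefined pairs: treated as no LD
  diag(r2) <- 0
  r2
}

# highest-r2 offending pair among `win` columns, or NULL when none exceeds
find_high_ld_pair <- function(g, win, r2_max) {
  r2 <- pairwise_r2_matrix(g[, win, drop = FALSE])
  if (max(r2) <= r2_max) return(NULL)
  hit <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
  c(win[hit[1]], win[hit[2]])
}

pick_victim <- function(a, b, miss, maf) {
  if (miss[a] != miss[b]) return(if (miss[a] > miss[b]) a else b)
  if (maf[a] != maf[b]) return(if (maf[a] < maf[b]) a else b)
  max(a, b)  # later position (variants sorted by position)
}

marker_set <- function(name, variant_idx, rsid, provenance) {
  stopifnot(!is.unsorted(variant_idx, strictly = TRUE))
  structure(list(name = name, variant_idx = variant_idx, rsid = rsid,
                 provenance = provenance), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set '", x$name, "': ", length(x$variant_idx), " of ",
      x$provenance$n_before, " variants (", x$provenance$method, ")\n",
      sep = "")
  invisible(x)
}

#' Write a marker set as one rsid per line
#'
#' @param ms a `marker_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_marker_set <- function(ms, path) {
  writeLines(ms$rsid, path)
  invisible(path)
}

#' Delta statistic of ancestry informativeness
#'
#' Sum over the two alleles of the absolute frequency difference between
#' two reference panels, which equals `2 |p1 - p2|` for the counted allele;
#' bounded in [0, 2] and invariant to which allele is counted.
#'
#' @param freq_panel1,freq_panel2 per-SNP counted-allele frequencies on
#'   harmonized alleles.
#' @return numeric vector of delta scores (`NA` where either frequency is).
#' @export
delta_statistic <- function(freq_panel1, freq_panel2) {
  stopifnot(length(freq_panel1) == length(freq_panel2))
  abs(freq_panel1 - freq_panel2) +
    abs((1 - freq_panel1) - (1 - freq_panel2))
}

#' Select ancestry-informative markers
#'
#' Keeps variants with `delta >= delta_min`, then LD-prunes the survivors.
#' The default `delta_min` of 0.3 is a package choice exposed for tuning,
#' not an estimate from any particular panel pair.
#'
#' @param x a `geno_cohort`.
#' @param delta per-SNP delta scores (see [delta_statistic()]).
#' @param delta_min minimum delta retained.
#' @param window_snps,step_snps,r2_max pruning parameters.
#' @return a `marker_set` with two-step provenance.
#' @export
select_aims <- function(x, delta, delta_min = 0.3, window_snps = 50,
                        step_snps = 5, r2_max = 0.2) {
  stopifnot(length(delta) == ncol(x$geno))
  keep <- !is.na(delta) & delta >= delta_min
  if (!any(keep)) stop("no variants pass delta_min = ", delta_min)
  sub <- subset_cohort(x, variants = keep)
  pruned <- ld_prune(sub, window_snps, step_snps, r2_max)
  idx <- which(keep)[pruned$variant_idx]
  marker_set(
    name = "aims",
    variant_idx = idx,
    rsid = x$variants$rsid[idx],
    provenance = list(method = "delta_filter+ld_prune",
                      parameters = list(delta_min = delta_min,
                                        window_snps = window_snps,
                                        step_snps = step_snps,
                                        r2_max = r2_max),
                      n_before = ncol(x$geno),
                      n_after_delta = sum(keep),
                      n_after = length(idx))
  )
}

#' Count residual high-LD pairs after pruning
#'
#' Exhaustive post-scan of the retained sequence: for every window of
#' `window_snps` consecutive retained variants on a chromosome, counts
#' pairs with `r^2 > r2_max`. A correct pruning returns 0.
#'
#' @param x a `geno_cohort`.
#' @param ms a `marker_set` produced from `x`.
#' @param window_snps,r2_max the pruning parameters to audit against.
#' @return integer count of violating pairs.
#' @export
prune_violations <- function(x, ms, window_snps = 50, r2_max = 0.2) {
  v <- x$variants[ms$variant_idx, , drop = FALSE]
  g <- x$geno[, ms$variant_idx, drop = FALSE]
  bad <- 0L
  # every within-window pair appears exactly once as (anchor, one of the
  # next window_snps - 1 retained variants on the chromosome)
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    for (s in seq_along(idx)[-length(idx)]) {
      win <- idx[s:min(s + window_snps - 1L, length(idx))]
      r2 <- pairwise_r2_matrix(g[, win, drop = FALSE])[1, -1]
      bad <- bad + sum(r2 > r2_max)
    }
  }
  bad
}
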