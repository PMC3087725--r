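# Pairwise linkage disequilibrium from unphased genotypes via the two-locus
# EM, D' with a profile-likelihood confidence interval, haplotype blocks by
# the confidence-interval (strong-LD pair fraction) rule, and per-group
# block/haplotype comparison.

# dosage pair -> 3x3 count table (rows dosage at locus 1: 0,1,2)
pair_count_table <- function(x1, x2) {
  both <- !is.na(x1) & !is.na(x2)
  table(factor(x1[both], levels = 0:2), factor(x2[both], levels = 0:2))
}

#' Two-locus haplotype frequencies by EM
#'
#' Estimates the four haplotype frequencies (order: 11, 10, 01, 00 in
#' counted-allele coding) from a 3x3 genotype count table. Only the double
#' heterozygote has ambiguous phase; the EM starts from
#' linkage-equilibrium frequencies and iterates to relative tolerance 1e-9
#' (at most 1000 iterations). The log-likelihood is non-decreasing.
#'
#' @param tab 3x3 matrix of genotype counts, `tab[a+1, b+1]` = individuals
#'   with dosage `a` at locus 1 and `b` at locus 2.
#' @return list: `h` (frequency 4-vector on the simplex), `loglik`,
#'   `trace`, `n` (individuals).
#' @export
two_locus_em <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n < 1) stop("empty genotype table")
  # allele frequencies from margins
  pa <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)
  pb <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  h <- c(pa * pb, pa * (1 - pb), (1 - pa) * pb, (1 - pa) * (1 - pb))
  h <- pmax(h, 1e-12)
  h <- h / sum(h)
  trace <- numeric(0)
  for (it in 1:1000) {
    trace <- c(trace, two_locus_loglik(tab, h))
    # E-step: phase weight of the double heterozygote
    denom <- h[1] * h[4] + h[2] * h[3]
    w <- if (denom > 0) h[1] * h[4] / denom else 0.5
    dh <- tab[2, 2]
    c11 <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + w * dh
    c10 <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1] + (1 - w) * dh
    c01 <- 2 * tab[1, 3] + tab[2, 3] + tab[1, 2] + (1 - w) * dh
    c00 <- 2 * tab[1, 1] + tab[2, 1] + tab[1, 2] + w * dh
    h_new <- c(c11, c10, c01, c00) / (2 * n)
    if (max(abs(h_new - h)) < 1e-9 * max(h, 1e-12)) {
      h <- h_new
      break
    }
    h <- h_new
  }
  trace <- c(trace, two_locus_loglik(tab, h))
  list(h = h, loglik = trace[length(trace)], trace = trace, n = n)
}

# multinomial log-likelihood of a 3x3 genotype table given haplotype
# frequencies h = (p11, p10, p01, p00)
two_locus_loglik <- function(tab, h) {
  probs <- genotype_class_probs(h)
  keep <- tab > 0
  sum(tab[keep] * log(pmax(probs[keep], 1e-300)))
}

genotype_class_probs <- function(h) {
  p11 <- h[1]; p10 <- h[2]; p01 <- h[3]; p00 <- h[4]
  m <- matrix(0, 3, 3)   # [a+1, b+1]
  m[3, 3] <- p11^2
  m[3, 2] <- 2 * p11 * p10
  m[3, 1] <- p10^2
  m[2, 3] <- 2 * p11 * p01
  m[2, 2] <- 2 * (p11 * p00 + p10 * p01)
  m[2, 1] <- 2 * p10 * p00
  m[1, 3] <- p01^2
  m[1, 2] <- 2 * p01 * p00
  m[1, 1] <- p00^2
  m
}

#' Pairwise D' with a profile-likelihood confidence interval
#'
#' Computes EM haplotype frequencies, `D = p11 - pA pB`, `D' = |D| / D_max`
#' with the sign-appropriate margin bound, and `r^2`. The confidence
#' interval profiles the multinomial likelihood over `D'` on the grid
#' `0, 0.001, ..., 1` with margins fixed, normalizes it to unit mass, and
#' takes the 2.5th / 97.5th mass percentiles (for the default 95%
#' confidence).
#'
#' @param tab 3x3 genotype count table (see [two_locus_em()]).
#' @param confidence interval mass (default 0.95).
#' @return a `pairwise_ld` list: `h`, `D`, `dprime`, `r2`, `ci_low`,
#'   `ci_high`, `n_informative`; `NULL` if either locus is monomorphic.
#' @export
dprime_ci <- function(tab, confidence = 0.95) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n < 1) return(NULL)
  pa <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)
  pb <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) return(NULL)
  em <- two_locus_em(tab)
  h <- em$h
  D <- h[1] - pa * pb
  d_max <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
           else min(pa * pb, (1 - pa) * (1 - pb))
  dprime <- if (d_max > 0) abs(D) / d_max else 0
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))

  grid <- seq(0, 1, by = 0.001)
  d_signed <- sign(ifelse(D == 0, 1, D)) * grid * d_max
  # haplotype frequencies along the profile, margins fixed; |D| <= D_max by
  # construction so boundary values are clamped at 0
  p11 <- pmax(pa * pb + d_signed, 0)
  p10 <- pmax(pa * (1 - pb) - d_signed, 0)
  p01 <- pmax((1 - pa) * pb - d_signed, 0)
  p00 <- pmax((1 - pa) * (1 - pb) + d_signed, 0)
  tot <- p11 + p10 + p01 + p00
  p11 <- p11 / tot; p10 <- p10 / tot; p01 <- p01 / tot; p00 <- p00 / tot
  # genotype-class log-probabilities along the grid (columns follow the
  # column-major layout of the 3x3 table: a = 0,1,2 within b = 0,1,2)
  probs <- cbind(
    p00^2, 2 * p10 * p00, p10^2,
    2 * p01 * p00, 2 * (p11 * p00 + p10 * p01), 2 * p11 * p10,
    p01^2, 2 * p11 * p01, p11^2
  )
  counts <- as.vector(tab)
  keep <- counts > 0
  ll <- log(pmax(probs[, keep, drop = FALSE], 1e-300)) %*% counts[keep]
  lik <- exp(ll - max(ll))
  mass <- cumsum(lik) / sum(lik)
  tail_lo <- (1 - confidence) / 2
  ci_low <- grid[which(mass >= tail_lo)[1]]
  ci_high <- grid[which(mass >= 1 - tail_lo)[1]]
  structure(list(h = h, D = D, dprime = dprime, r2 = r2, ci_low = ci_low,
                 ci_high = ci_high, n_informative = n),
            class = "pairwise_ld")
}

#' Pairwise LD table for a variant region
#'
#' @param x a `geno_cohort`.
#' @param region integer vector of variant indices (sorted).
#' @param maf_min informative-pair MAF gate (default 0.05).
#' @return long data frame of pairwise `dprime_ci()` results; variants
#'   below the MAF gate are excluded as uninformative.
#' @export
pairwise_ld <- function(x, region, maf_min = 0.05) {
  p <- allele_freq(x$geno[, region, drop = FALSE])
  informative <- !is.na(p) & pmin(p, 1 - p) >= maf_min
  idx <- region[informative]
  out <- list()
  if (length(idx) >= 2) {
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1):length(idx)) {
        pl <- dprime_ci(pair_count_table(x$geno[, idx[a]], x$geno[, idx[b]]))
        if (is.null(pl)) next
        out[[length(out) + 1]] <- data.frame(
          idx1 = idx[a], idx2 = idx[b],
          rsid1 = x$variants$rsid[idx[a]], rsid2 = x$variants$rsid[idx[b]],
          D = pl$D, dprime = pl$dprime, r2 = pl$r2, ci_low = pl$ci_low,
          ci_high = pl$ci_high, n = pl$n_informative,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(idx1 = integer(), idx2 = integer(),
                      rsid1 = character(), rsid2 = character(),
                      D = numeric(), dprime = numeric(), r2 = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Confidence-interval haplotype blocks
#'
#' Pair classification on the D' confidence interval: strong LD when
#' `ci_low >= 0.70` and `ci_high >= 0.98`; strong recombination when
#' `ci_high < 0.90`. A candidate block is a span whose outermost pair is in
#' strong LD and in which at least 95% of informative pairs (strong LD or
#' strong recombination) are strong. Candidates are accepted greedily by
#' bp span, longest first (ties leftmost), discarding overlaps.
#'
#' @param x a `geno_cohort`.
#' @param region integer vector of variant indices (sorted, one
#'   chromosome).
#' @param params list overriding `ci_low_strong` (0.70), `ci_high_strong`
#'   (0.98), `ci_high_recomb` (0.90), `frac_strong` (0.95), `maf_min`
#'   (0.05), `min_snps` (2).
#' @return list of blocks, each with `first`, `last` (variant indices),
#'   `snps` (all region indices inside), `n_snps`, `frac_strong`.
#' @export
gabriel_blocks <- function(x, region, params = list()) {
  pd <- modifyList(list(ci_low_strong = 0.70, ci_high_strong = 0.98,
                        ci_high_recomb = 0.90, frac_strong = 0.95,
                        maf_min = 0.05, min_snps = 2), params)
  region <- sort(region)
  if (length(region) < 2) return(list())
  if (length(unique(x$variants$chrom[region])) > 1) {
    stop("block region must lie on one chromosome")
  }
  ld <- pairwise_ld(x, region, maf_min = pd$maf_min)
  if (!nrow(ld)) return(list())
  strong <- ld$ci_low >= pd$ci_low_strong & ld$ci_high >= pd$ci_high_strong
  recomb <- ld$ci_high < pd$ci_high_recomb
  inf_idx <- sort(unique(c(ld$idx1, ld$idx2)))

  candidates <- list()
  for (r in which(strong)) {
    i <- ld$idx1[r]
    j <- ld$idx2[r]
    inside <- ld$idx1 >= i & ld$idx2 <= j
    n_strong <- sum(strong & inside)
    n_inf <- sum((strong | recomb) & inside)
    if (n_inf == 0) next
    frac <- n_strong / n_inf
    n_snps <- sum(inf_idx >= i & inf_idx <= j)
    if (frac >= pd$frac_strong && n_snps >= pd$min_snps) {
      candidates[[length(candidates) + 1]] <- list(
        first = i, last = j, frac_strong = frac,
        span_bp = x$variants$pos[j] - x$variants$pos[i]
      )
    }
  }
  if (!length(candidates)) return(list())
  spans <- vapply(candidates, function(cc) cc$span_bp, numeric(1))
  firsts <- vapply(candidates, function(cc) cc$first, numeric(1))
  ord <- order(-spans, firsts)
  accepted <- list()
  taken <- logical(ncol(x$geno))
  for (ci in ord) {
    cc <- candidates[[ci]]
    span <- cc$first:cc$last
    if (any(taken[span])) next
    taken[span] <- TRUE
    snps <- region[region >= cc$first & region <= cc$last]
    accepted[[length(accepted) + 1]] <- list(
      chrom = x$variants$chrom[cc$first], first = cc$first, last = cc$last,
      snps = snps, n_snps = length(snps), frac_strong = cc$frac_strong,
      span_bp = cc$span_bp
    )
  }
  ord2 <- order(vapply(accepted, function(b) b$first, numeric(1)))
  accepted[ord2]
}

#' Haplotype frequencies within a block by multi-locus EM
#'
#' Exact EM over the unresolved phases of all samples with complete calls
#' in the block (samples with any missing call in the block are dropped).
#' Initialization is the product of single-locus margins; iteration to
#' relative tolerance 1e-9 or 1000 iterations. Haplotypes at frequency
#' >= 0.01 are reported, sorted by frequency.
#'
#' @param x a `geno_cohort`.
#' @param block_idx variant indices of the block (at most 12 SNPs).
#' @return list: `haplotypes` data frame (`hap` allele string, `freq`),
#'   `h_full` (all frequencies, named by haplotype string), `loglik`,
#'   `trace`, `n_used`.
#' @export
block_haplotypes <- function(x, block_idx) {
  L <- length(block_idx)
  if (L > 12) {
    stop("block has ", L, " SNPs; exact EM is limited to 12 - partition it")
  }
  g <- x$geno[, block_idx, drop = FALSE]
  complete <- rowSums(is.na(g)) == 0
  g <- g[complete, , drop = FALSE]
  n <- nrow(g)
  if (n == 0) stop("no samples with complete calls in block")

  # haplotype id: bitmask, bit l set = counted allele at SNP l
  n_hap <- 2^L
  p_marg <- colMeans(g) / 2
  hap_bits <- matrix(0L, n_hap, L)
  for (l in seq_len(L)) {
    hap_bits[, l] <- bitwAnd(seq_len(n_hap) - 1L, 2L^(l - 1L)) > 0
  }
  h <- apply(hap_bits, 1, function(bits) {
    prod(ifelse(bits == 1, p_marg, 1 - p_marg))
  })
  h <- pmax(h, 1e-12)
  h <- h / sum(h)

  # compatible unordered haplotype pairs per distinct genotype row
  key <- apply(g, 1, paste, collapse = ",")
  distinct <- !duplicated(key)
  pair_sets <- lapply(which(distinct), function(i) compatible_pairs(g[i, ]))
  names(pair_sets) <- key[distinct]
  counts <- table(key)

  trace <- numeric(0)
  for (it in 1:1000) {
    ll <- 0
    num <- numeric(n_hap)
    for (kk in names(pair_sets)) {
      pairs <- pair_sets[[kk]]
      w <- h[pairs[, 1]] * h[pairs[, 2]] * ifelse(pairs[, 1] == pairs[, 2], 1, 2)
      tot <- sum(w)
      ll <- ll + counts[[kk]] * log(max(tot, 1e-300))
      w <- w / max(tot, 1e-300)
      cnt <- counts[[kk]]
      for (rr in seq_len(nrow(pairs))) {
        num[pairs[rr, 1]] <- num[pairs[rr, 1]] + cnt * w[rr]
        num[pairs[rr, 2]] <- num[pairs[rr, 2]] + cnt * w[rr]
      }
    }
    trace <- c(trace, ll)
    h_new <- num / (2 * n)
    if (max(abs(h_new - h)) < 1e-9 * max(h)) {
      h <- h_new
      break
    }
    h <- h_new
  }

  hap_string <- vapply(seq_len(n_hap), function(hh) {
    bits <- hap_bits[hh, ]
    paste(ifelse(bits == 1, x$variants$counted[block_idx],
                 other_allele(x$variants[block_idx, , drop = FALSE])),
          collapse = "")
  }, character(1))
  names(h) <- hap_string
  keep <- h >= 0.01
  tab <- data.frame(hap = hap_string[keep], freq = h[keep],
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$freq), ]
  rownames(tab) <- NULL
  list(haplotypes = tab, h_full = h, loglik = trace[length(trace)],
       trace = trace, n_used = n)
}

# unordered haplotype-id pairs compatible with a complete genotype vector
compatible_pairs <- function(geno_row) {
  L <- length(geno_row)
  het <- which(geno_row == 1L)
  base <- sum(2L^(which(geno_row == 2L) - 1L))
  if (!length(het)) {
    id <- base + 1L
    return(matrix(c(id, id), 1))
  }
  n_conf <- 2^(length(het) - 1)
  out <- matrix(0L, n_conf * 2, 2)  # generous; deduplicated below
  row <- 0L
  for (conf in 0:(2^length(het) - 1)) {
    bits <- bitwAnd(conf, 2L^(seq_along(het) - 1L)) > 0
    hap1 <- base + sum(2L^(het[bits] - 1L))
    hap2 <- base + sum(2L^(het[!bits] - 1L))
    pr <- sort(c(hap1, hap2)) + 1L
    row <- row + 1L
    out[row, ] <- pr
  }
  unique(out[seq_len(row), , drop = FALSE])
}

#' Per-group block detection and haplotype comparison
#'
#' Runs [gabriel_blocks()] and [block_haplotypes()] per group over the same
#' region and summarizes block counts, spans and whether a focal variant
#' falls inside a block in each group. Groups below the minimum size are
#' excluded with a warning.
#'
#' @param x a `geno_cohort`.
#' @param region variant indices (one chromosome).
#' @param focal_rsid optional variant name to locate within blocks.
#' @param min_group minimum samples per analyzed group (default 20).
#' @param params passed to [gabriel_blocks()].
#' @return list with per-group `blocks` and `haplotypes`, and a `summary`
#'   data frame.
#' @export
compare_groups <- function(x, region, focal_rsid = NULL, min_group = 20,
                           params = list()) {
  groups <- unique(x$samples$group)
  sizes <- table(x$samples$group)[groups]
  small <- names(sizes)[sizes < min_group]
  if (length(small)) {
    warning("groups below ", min_group, " samples excluded: ",
            paste(small, collapse = ", "))
  }
  groups <- setdiff(groups, small)
  if (length(groups) < 2) stop("need >= 2 groups of sufficient size")
  focal_idx <- if (!is.null(focal_rsid)) {
    match(focal_rsid, x$variants$rsid)
  } else NA_integer_
  res <- list()
  summary_rows <- list()
  for (gname in groups) {
    sub <- subset_cohort(x, samples = x$samples$group == gname)
    blocks <- gabriel_blocks(sub, region, params)
    haps <- lapply(blocks, function(b) {
      if (b$n_snps <= 12) block_haplotypes(sub, b$snps) else NULL
    })
    in_block <- if (!is.na(focal_idx)) {
      any(vapply(blocks, function(b) {
        focal_idx >= b$first && focal_idx <= b$last
      }, logical(1)))
    } else NA
    res[[gname]] <- list(blocks = blocks, haplotypes = haps)
    summary_rows[[gname]] <- data.frame(
      group = gname, n_samples = sum(x$samples$group == gname),
      n_blocks = length(blocks),
      mean_span_bp = if (length(blocks)) {
        mean(vapply(blocks, function(b) b$span_bp, numeric(1)))
      } else NA_real_,
      focal_in_block = in_block, stringsAsFactors = FALSE
    )
  }
  list(groups = res, summary = do.call(rbind, summary_rows))
}
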