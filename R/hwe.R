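#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: conditioning on the observed allele counts, the
#' number of heterozygotes `h` follows the hypergeometric-type distribution
#' `P(h) proportional to 2^h / (n_AA! n_AB! n_BB!)` over all `h` with the
#' same parity as the rare-allele count. The p-value is the total mass of
#' all configurations no more probable than the observed one (the PLINK
#' convention). Monomorphic input returns 1.
#'
#' Probabilities are computed by the numerically stable ratio recurrence
#' `P(h + 2) = P(h) * 4 hom_rare(h) hom_common(h) / ((h + 2)(h + 1))`,
#' then normalized.
#'
#' @param n_aa,n_ab,n_bb genotype counts (equal-length vectors allowed);
#'   `n_ab` is the heterozygote count.
#' @return p-values in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(length(n_aa) == length(n_ab), length(n_ab) == length(n_bb))
  mapply(hwe_exact_one, n_aa, n_ab, n_bb)
}

hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("negative genotype count")
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("empty genotype table")
  r <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)  # rare-allele count
  if (r == 0) return(1)
  dist <- hwe_het_distribution(n, r)
  p_obs <- dist$prob[match(n_ab, dist$het)]
  if (is.na(p_obs)) stop("heterozygote count ", n_ab,
                         " impossible for these margins")
  # tolerance absorbs float noise at exact real-arithmetic ties
  p <- sum(dist$prob[dist$prob <= p_obs * (1 + 1e-9)])
  min(p, 1)
}

# exact distribution of the heterozygote count given n genotypes and r
# copies of the rare allele
hwe_het_distribution <- function(n, r) {
  h_min <- r %% 2
  hs <- seq.int(h_min, r, by = 2L)
  probs <- numeric(length(hs))
  probs[1] <- 1
  if (length(hs) > 1) {
    for (i in seq_len(length(hs) - 1L)) {
      h <- hs[i]
      hom_rare <- (r - h) / 2
      hom_common <- n - (r + h) / 2
      probs[i + 1] <- probs[i] * 4 * hom_rare * hom_common /
        ((h + 2) * (h + 1))
    }
  }
  list(het = hs, prob = probs / sum(probs))
}

#' Per-SNP HWE exact p-values for a cohort
#'
#' Counts genotypes per variant from the dosage matrix and applies
#' [hwe_exact_test()]. X-chromosome variants get `NA` (hemizygous males
#' break the diploid sampling model).
#'
#' @param x a `geno_cohort`.
#' @return numeric vector of p-values, one per variant.
#' @export
hwe_scan <- function(x) {
  g <- x$geno
  n2 <- colSums(g == 2L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n0 <- colSums(g == 0L, na.rm = TRUE)
  p <- rep(NA_real_, ncol(g))
  ok <- is_autosome(x$variants$chrom) & (n0 + n1 + n2) > 0
  p[ok] <- hwe_exact_test(n2[ok], n1[ok], n0[ok])
  p
}
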