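# Sample- and SNP-level quality control with exact exclusion accounting.
# The cascade evaluates each filter on the data surviving the previous
# steps and records a ledger row (step, axis, n_before, n_excluded,
# n_after) whose arithmetic must chain exactly.

#' QC thresholds
#'
#' Defaults follow common SNP-array practice for clinical cohorts: 5%
#' missingness caps on both axes, MAF 0.01, HWE exact p 0.001, and an
#' inbreeding-coefficient outlier limit of four standard deviations.
#' `batch_p_min` is applied after Bonferroni correction over tested SNPs;
#' `diff_missing_p_min` is a raw per-SNP threshold (the flagged count, not a
#' family-wise rate, is the quantity of interest there). `pihat_max = NULL`
#' disables the relatedness step (run [ibd_estimate()] on pruned markers for
#' suspect pairs instead; all-pairs IBD inside the cascade is quadratic in
#' samples).
#'
#' @param sample_missing_max,snp_missing_max maximum missing fraction.
#' @param maf_min minimum minor-allele frequency.
#' @param hwe_p_min minimum HWE exact p-value.
#' @param diff_missing_p_min raw threshold for the differential-missingness
#'   Fisher test.
#' @param batch_p_min family-wise level for the batch-effect scan.
#' @param inbreeding_sd_limit outlier limit on |F - mean(F)| in SDs.
#' @param pihat_max optional relatedness cap (exclude one of each pair).
#' @param diff_flag diagnosis flag defining the differential-missingness
#'   classes.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(sample_missing_max = 0.05,
                          snp_missing_max = 0.05,
                          maf_min = 0.01,
                          hwe_p_min = 0.001,
                          diff_missing_p_min = 1e-5,
                          batch_p_min = 0.05,
                          inbreeding_sd_limit = 4,
                          pihat_max = NULL,
                          diff_flag = NULL) {
  th <- as.list(environment())
  probs <- c("sample_missing_max", "snp_missing_max", "maf_min",
             "hwe_p_min", "diff_missing_p_min", "batch_p_min")
  for (p in probs) {
    if (th[[p]] <= 0 || th[[p]] >= 1) stop(p, " must be in (0, 1)")
  }
  if (th$inbreeding_sd_limit <= 0) stop("inbreeding_sd_limit must be > 0")
  class(th) <- "qc_thresholds"
  th
}

#' Missing-call fractions per sample and per SNP
#'
#' Denominators are the full variant (resp. sample) count of the input,
#' regardless of any other filter.
#'
#' @param x a `geno_cohort` or dosage matrix.
#' @return list of `sample` and `snp` missing fractions.
#' @export
call_rates <- function(x) {
  g <- if (inherits(x, "geno_cohort")) x$geno else x
  if (length(g) == 0) stop("empty genotype matrix")
  list(sample = rowMeans(is.na(g)), snp = colMeans(is.na(g)))
}

#' Fisher exact test of differential missingness per SNP
#'
#' Two-sided Fisher exact test on the 2x2 table (missing/called x flagged
#' class) at every SNP. SNPs with zero calls overall get `NA`.
#'
#' @param x a `geno_cohort` or dosage matrix.
#' @param flag per-sample logical; both classes must be non-empty.
#' @return numeric vector of p-values per SNP.
#' @export
differential_missingness <- function(x, flag) {
  g <- if (inherits(x, "geno_cohort")) x$geno else x
  flag <- as.logical(flag)
  if (!any(flag) || all(flag)) stop("both flag classes must be non-empty")
  miss <- is.na(g)
  m1 <- colSums(miss[flag, , drop = FALSE])
  m0 <- colSums(miss[!flag, , drop = FALSE])
  n1 <- sum(flag)
  n0 <- sum(!flag)
  vapply(seq_len(ncol(g)), function(j) {
    if (m1[j] + m0[j] == n1 + n0) return(NA_real_)  # zero calls
    if (m1[j] + m0[j] == 0) return(1)
    tab <- matrix(c(m1[j], n1 - m1[j], m0[j], n0 - m0[j]), 2)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
}

#' Genotype concordance between replicate pairs
#'
#' Pairs a replicate-flagged sample with its source (id without the `_rep`
#' suffix, or explicit `pairs`). Concordance is the fraction of SNPs called
#' in both members with equal dosage; pairs with no co-called SNPs get `NA`.
#'
#' @param x a `geno_cohort`.
#' @param pairs optional 2-column matrix of sample ids.
#' @return list with per-pair data frame and `mean`, `sd` of concordance.
#' @export
batch_concordance <- function(x, pairs = NULL) {
  if (is.null(pairs)) {
    reps <- x$samples$sample_id[x$samples$is_replicate]
    src <- sub("_rep$", "", reps)
    keep <- src %in% x$samples$sample_id & src != reps
    pairs <- cbind(src[keep], reps[keep])
  }
  if (is.null(dim(pairs)) || nrow(pairs) == 0) {
    warning("no replicate pairs found")
    return(list(pairs = data.frame(), mean = NA_real_, sd = NA_real_))
  }
  conc <- apply(pairs, 1, function(pr) {
    a <- x$geno[match(pr[1], x$samples$sample_id), ]
    b <- x$geno[match(pr[2], x$samples$sample_id), ]
    both <- !is.na(a) & !is.na(b)
    if (!any(both)) return(NA_real_)
    mean(a[both] == b[both])
  })
  df <- data.frame(id1 = pairs[, 1], id2 = pairs[, 2], concordance = conc,
                   stringsAsFactors = FALSE)
  list(pairs = df, mean = mean(conc, na.rm = TRUE),
       sd = stats::sd(conc, na.rm = TRUE))
}

#' Chi-square scan for batch effects on allele counts
#'
#' Per SNP, a chi-square test of the (counted allele, other allele) x batch
#' contingency table. The flagged set applies a Bonferroni-corrected
#' threshold over the tested SNPs.
#'
#' @param x a `geno_cohort`.
#' @param batch_p_min family-wise level (see [qc_thresholds()]).
#' @return list of `p` (per SNP; `NA` where untestable) and `flagged`
#'   (logical).
#' @export
batch_effect_scan <- function(x, batch_p_min = 0.05) {
  batches <- x$samples$batch
  ub <- unique(batches)
  if (length(ub) < 2) stop("batch_effect_scan needs >= 2 batches")
  g <- x$geno
  counted <- sapply(ub, function(b) {
    colSums(g[batches == b, , drop = FALSE], na.rm = TRUE)
  })
  called <- sapply(ub, function(b) {
    colSums(!is.na(g[batches == b, , drop = FALSE]))
  })
  total <- 2 * called
  other <- total - counted
  p <- rep(NA_real_, ncol(g))
  for (j in seq_len(ncol(g))) {
    tab <- rbind(counted[j, ], other[j, ])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2 || any(rowSums(tab) == 0)) {
      p[j] <- 1  # monomorphic or single informative batch: no deviation
      next
    }
    exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - exp_tab)^2 / exp_tab)
    p[j] <- stats::pchisq(stat, df = ncol(tab) - 1, lower.tail = FALSE)
  }
  tested <- sum(!is.na(p))
  flagged <- !is.na(p) & p < batch_p_min / max(tested, 1)
  list(p = p, flagged = flagged)
}

#' Per-sample inbreeding coefficient
#'
#' `F = (O - E) / (n_called - E)` where `O` is the observed homozygote count
#' over the sample's called autosomal SNPs and `E = sum(1 - 2 p_j (1 - p_j))`
#' the expectation under HWE at the cohort's sample allele frequencies.
#' Fully homozygous samples give `F = 1`; all-missing samples `NA`.
#'
#' @param x a `geno_cohort`.
#' @return numeric vector of F, one per sample.
#' @export
inbreeding_coefficient <- function(x) {
  auto <- is_autosome(x$variants$chrom)
  g <- x$geno[, auto, drop = FALSE]
  p <- allele_freq(g)
  het_exp <- 2 * p * (1 - p)
  called <- !is.na(g)
  O <- rowSums(g != 1L, na.rm = TRUE)
  n_called <- rowSums(called)
  E <- called %*% ifelse(is.na(het_exp), 0, 1 - het_exp)
  f <- (O - E) / (n_called - E)
  f[n_called == 0] <- NA_real_
  as.numeric(f)
}

#' X-heterozygosity sex check
#'
#' Computes the inbreeding-style F statistic on X-chromosome variants;
#' hemizygous males show no heterozygotes (`F` near 1), females at HWE `F`
#' near 0. Inferred male if `F > 0.8`, female if `F < 0.2`, otherwise
#' undetermined. A mismatch is a determined inference that contradicts a
#' declared sex.
#'
#' @param x a `geno_cohort` with X-chromosome variants.
#' @param min_x_snps minimum X variants required (default 20).
#' @return data frame with `sample_id`, `x_het_f`, `inferred`, `mismatch`.
#' @export
sex_check <- function(x, min_x_snps = 20) {
  on_x <- !is_autosome(x$variants$chrom)
  if (sum(on_x) == 0) {
    warning("no X variants; sex undetermined for all samples")
    return(data.frame(sample_id = x$samples$sample_id, x_het_f = NA_real_,
                      inferred = "undetermined", mismatch = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (sum(on_x) < min_x_snps) {
    stop("sex_check needs >= ", min_x_snps, " X variants, found ",
         sum(on_x))
  }
  gx <- x$geno[, on_x, drop = FALSE]
  p <- allele_freq(gx)
  called <- !is.na(gx)
  O <- rowSums(gx != 1L, na.rm = TRUE)
  n_called <- rowSums(called)
  E <- called %*% ifelse(is.na(p), 0, 1 - 2 * p * (1 - p))
  f <- as.numeric((O - E) / (n_called - E))
  f[n_called == 0] <- NA_real_
  inferred <- ifelse(is.na(f), "undetermined",
                     ifelse(f > 0.8, "male",
                            ifelse(f < 0.2, "female", "undetermined")))
  declared <- x$samples$sex
  mismatch <- inferred != "undetermined" & declared != "unknown" &
    inferred != declared
  data.frame(sample_id = x$samples$sample_id, x_het_f = f,
             inferred = inferred, mismatch = mismatch,
             stringsAsFactors = FALSE)
}

#' Method-of-moments IBD estimation for sample pairs
#'
#' For each pair, identity-by-state counts over co-called autosomal SNPs are
#' inverted to IBD-state probabilities (z0, z1, z2) using the expected IBS
#' distribution given allele frequencies, then projected onto the simplex.
#' `pihat = z1 / 2 + z2`. Pairs with fewer than 100 co-called SNPs are
#' flagged unreliable.
#'
#' @param x a `geno_cohort`.
#' @param freqs per-SNP counted-allele frequencies in (0, 1); defaults to
#'   the cohort's sample frequencies.
#' @param pairs optional 2-column matrix of sample ids; defaults to all
#'   pairs.
#' @return data frame, one row per pair.
#' @export
ibd_estimate <- function(x, freqs = NULL, pairs = NULL) {
  auto <- is_autosome(x$variants$chrom)
  g <- x$geno[, auto, drop = FALSE]
  if (is.null(freqs)) freqs <- allele_freq(g)
  else freqs <- freqs[auto]
  ok <- !is.na(freqs) & freqs > 0 & freqs < 1
  g <- g[, ok, drop = FALSE]
  p <- freqs[ok]
  q <- 1 - p
  # expected IBS-state probabilities per SNP by IBD state
  e_ibs0_ibd0 <- 2 * p^2 * q^2
  e_ibs1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e_ibs1_ibd1 <- 2 * p^2 * q + 2 * p * q^2
  ids <- x$samples$sample_id
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ids, 2))
  }
  out <- data.frame(id1 = pairs[, 1], id2 = pairs[, 2], ibs0 = NA_integer_,
                    ibs1 = NA_integer_, ibs2 = NA_integer_, z0 = NA_real_,
                    z1 = NA_real_, z2 = NA_real_, pihat = NA_real_,
                    n_snps = NA_integer_, unreliable = TRUE,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(pairs))) {
    a <- g[match(pairs[r, 1], ids), ]
    b <- g[match(pairs[r, 2], ids), ]
    both <- !is.na(a) & !is.na(b)
    ibs <- 2L - abs(a[both] - b[both])
    n <- length(ibs)
    i0 <- sum(ibs == 0L)
    i1 <- sum(ibs == 1L)
    i2 <- n - i0 - i1
    E00 <- sum(e_ibs0_ibd0[both])
    E10 <- sum(e_ibs1_ibd0[both])
    E11 <- sum(e_ibs1_ibd1[both])
    z0 <- if (E00 > 0) i0 / E00 else 0
    z1 <- if (E11 > 0) (i1 - z0 * E10) / E11 else 0
    z2 <- 1 - z0 - z1
    z <- pmax(c(z0, z1, z2), 0)
    z <- z / sum(z)
    out[r, c("ibs0", "ibs1", "ibs2")] <- c(i0, i1, i2)
    out[r, c("z0", "z1", "z2")] <- z
    out$pihat[r] <- z[2] / 2 + z[3]
    out$n_snps[r] <- n
    out$unreliable[r] <- n < 100
  }
  out
}

# ---- cascade -------------------------------------------------------------

ledger_row <- function(step, axis, n_before, n_excluded) {
  data.frame(step = step, axis = axis, n_before = n_before,
             n_excluded = n_excluded, n_after = n_before - n_excluded,
             stringsAsFactors = FALSE)
}

#' Check ledger conservation and chaining
#'
#' Every row must satisfy `n_after = n_before - n_excluded` and consecutive
#' rows on the same axis must chain (`n_after` of one equals `n_before` of
#' the next).
#'
#' @param ledger a cascade ledger data frame.
#' @return `TRUE` invisibly; stops on the first violation.
#' @export
ledger_check <- function(ledger) {
  bad <- ledger$n_after != ledger$n_before - ledger$n_excluded
  if (any(bad)) stop("ledger conservation violated at step ",
                     ledger$step[which(bad)[1]])
  for (ax in unique(ledger$axis)) {
    rows <- ledger[ledger$axis == ax, ]
    if (nrow(rows) > 1) {
      chained <- rows$n_before[-1] == rows$n_after[-nrow(rows)]
      if (!all(chained)) stop("ledger chain broken on axis ", ax,
                              " at step ", rows$step[which(!chained)[1] + 1])
    }
  }
  invisible(TRUE)
}

#' Replay an exclusion cascade from recorded counts
#'
#' Pure ledger arithmetic: starts from `n_start` and applies the named
#' exclusion counts in order, returning a ledger that passes
#' [ledger_check()].
#'
#' @param n_start starting count.
#' @param exclusions named integer vector of per-step exclusions.
#' @param axis ledger axis label.
#' @return a ledger data frame.
#' @export
replay_ledger <- function(n_start, exclusions, axis = "SNP") {
  rows <- vector("list", length(exclusions))
  n <- n_start
  for (i in seq_along(exclusions)) {
    rows[[i]] <- ledger_row(names(exclusions)[i], axis, n, exclusions[[i]])
    n <- n - exclusions[[i]]
  }
  ledger <- do.call(rbind, rows)
  ledger_check(ledger)
  ledger
}

#' Run the full QC cascade
#'
#' Sample filters first (replicate removal, call rate, sex mismatch), then
#' SNP filters (call rate, MAF, batch deviation, differential missingness,
#' HWE), then inbreeding-outlier samples last. Each step is evaluated on
#' the data surviving the previous steps; steps whose inputs are absent
#' (no replicates, single batch, no diagnosis flag, no X data) are recorded
#' with zero exclusions.
#'
#' @param x a `geno_cohort`.
#' @param thresholds a [qc_thresholds()] list.
#' @return list with the filtered `cohort` and the `ledger`.
#' @export
apply_cascade <- function(x, thresholds = qc_thresholds()) {
  th <- thresholds
  ledger <- list()
  step <- function(name, axis, keep) {
    n_before <- length(keep)
    n_excl <- sum(!keep)
    ledger[[length(ledger) + 1]] <<- ledger_row(name, axis, n_before, n_excl)
    if (all(!keep)) stop("QC step '", name, "' excluded every ", axis)
    keep
  }

  # -- sample axis --
  keep_s <- step("replicate_samples", "sample", !x$samples$is_replicate)
  x <- subset_cohort(x, samples = keep_s)

  cr <- call_rates(x)
  keep_s <- step("sample_call_rate", "sample",
                 cr$sample <= th$sample_missing_max)
  x <- subset_cohort(x, samples = keep_s)

  n_x_snps <- sum(!is_autosome(x$variants$chrom))
  if (n_x_snps >= 20 && any(x$samples$sex != "unknown")) {
    sc <- sex_check(x)
    keep_s <- step("sex_mismatch", "sample", !sc$mismatch)
  } else {
    keep_s <- step("sex_mismatch", "sample", rep(TRUE, nrow(x$geno)))
  }
  x <- subset_cohort(x, samples = keep_s)

  # -- SNP axis --
  cr <- call_rates(x)
  keep_v <- step("snp_call_rate", "SNP", cr$snp <= th$snp_missing_max)
  x <- subset_cohort(x, variants = keep_v)

  p <- allele_freq(x)
  maf <- pmin(p, 1 - p)
  keep_v <- step("maf", "SNP", !is.na(maf) & maf >= th$maf_min)
  x <- subset_cohort(x, variants = keep_v)

  if (length(unique(x$samples$batch)) > 1) {
    bs <- batch_effect_scan(x, th$batch_p_min)
    keep_v <- step("batch_effect", "SNP", !bs$flagged)
  } else {
    keep_v <- step("batch_effect", "SNP", rep(TRUE, ncol(x$geno)))
  }
  x <- subset_cohort(x, variants = keep_v)

  flag <- if (!is.null(th$diff_flag)) has_diagnosis(x$samples, th$diff_flag)
          else NULL
  if (!is.null(flag) && any(flag) && !all(flag)) {
    dm <- differential_missingness(x, flag)
    keep_v <- step("differential_missingness", "SNP",
                   is.na(dm) | dm >= th$diff_missing_p_min)
  } else {
    keep_v <- step("differential_missingness", "SNP",
                   rep(TRUE, ncol(x$geno)))
  }
  x <- subset_cohort(x, variants = keep_v)

  hp <- hwe_scan(x)
  keep_v <- step("hwe", "SNP", is.na(hp) | hp >= th$hwe_p_min)
  x <- subset_cohort(x, variants = keep_v)

  # -- inbreeding outliers last --
  f <- inbreeding_coefficient(x)
  dev <- abs(f - mean(f, na.rm = TRUE))
  lim <- th$inbreeding_sd_limit * stats::sd(f, na.rm = TRUE)
  keep_s <- step("inbreeding_outlier", "sample",
                 is.na(dev) | lim == 0 | dev <= lim)
  x <- subset_cohort(x, samples = keep_s)

  ledger <- do.call(rbind, ledger)
  ledger_check(ledger)
  list(cohort = x, ledger = ledger)
}
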