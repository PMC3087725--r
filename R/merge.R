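# Multi-cohort merge with allele harmonization. Variants are matched by
# rsid, restricted to those present in every cohort, and each later cohort's
# alleles are reconciled to the first cohort's orientation: a counted/other
# swap recodes dosages d -> 2 - d, a strand flip complements both alleles,
# and the two can combine. Strand-ambiguous A/T and C/G variants cannot be
# disambiguated without frequency matching and are dropped.

.complement <- c(A = "T", C = "G", G = "C", T = "A")

flip_strand <- function(allele) {
  out <- .complement[allele]
  ifelse(is.na(out), allele, out)
}

#' Merge cohorts on shared variants
#'
#' Restricts to rsids present in all cohorts, harmonizes allele orientation
#' to the first cohort, and concatenates samples. Sample ids are prefixed
#' with the cohort label when they collide across cohorts. Positions and
#' chromosome come from the first cohort.
#'
#' Per-variant reconciliation against cohort 1's (counted, other) pair:
#' identical -> keep; swapped -> recode `d -> 2 - d`; complement of identical
#' -> strand flip (counted `n_flipped`); complement of swapped -> flip and
#' recode; anything else -> drop into `n_dropped_mismatch`. Variants that
#' are strand-ambiguous in cohort 1 (A/T or C/G) are dropped up front into
#' `n_dropped_ambiguous`.
#'
#' @param cohorts list of two or more `geno_cohort` objects.
#' @param labels cohort labels used for provenance and id de-collision;
#'   defaults to `cohort1`, `cohort2`, ...
#' @return a list with the merged `cohort` and a `report` (fields
#'   `n_samples_combined`, `n_variants_shared`, `n_flipped`,
#'   `n_dropped_ambiguous`, `n_dropped_mismatch`).
#' @export
merge_cohorts <- function(cohorts, labels = NULL) {
  if (length(cohorts) < 2) stop("need at least 2 cohorts")
  if (is.null(labels)) labels <- paste0("cohort", seq_along(cohorts))
  stopifnot(length(labels) == length(cohorts))
  for (co in cohorts) validate_cohort(co)

  shared <- Reduce(intersect, lapply(cohorts, function(co) co$variants$rsid))
  ref <- cohorts[[1]]
  ref_idx <- match(shared, ref$variants$rsid)
  ref_v <- ref$variants[ref_idx, , drop = FALSE]

  ref_counted <- ref_v$counted
  ref_other <- other_allele(ref_v)
  ambiguous <- flip_strand(ref_counted) == ref_other
  n_flipped <- 0L
  mismatch <- rep(FALSE, length(shared))

  genos <- vector("list", length(cohorts))
  genos[[1]] <- ref$geno[, ref_idx, drop = FALSE]
  for (ci in seq_along(cohorts)[-1]) {
    co <- cohorts[[ci]]
    idx <- match(shared, co$variants$rsid)
    v <- co$variants[idx, , drop = FALSE]
    g <- co$geno[, idx, drop = FALSE]
    counted <- v$counted
    other <- other_allele(v)
    same <- counted == ref_counted & other == ref_other
    swapped <- counted == ref_other & other == ref_counted
    flip_same <- flip_strand(counted) == ref_counted &
      flip_strand(other) == ref_other
    flip_swap <- flip_strand(counted) == ref_other &
      flip_strand(other) == ref_counted
    # ambiguous variants look "same & swapped" at once; they are dropped
    recode <- !ambiguous & !same & swapped
    flipped <- !ambiguous & !same & !swapped & (flip_same | flip_swap)
    recode_flip <- !ambiguous & !same & !swapped & !flip_same & flip_swap
    bad <- !ambiguous & !(same | swapped | flip_same | flip_swap)
    mismatch <- mismatch | bad
    n_flipped <- n_flipped + sum(flipped)
    if (any(recode) || any(recode_flip)) {
      cols <- which(recode | recode_flip)
      g[, cols] <- 2L - g[, cols, drop = FALSE]
    }
    genos[[ci]] <- g
  }

  keep <- !ambiguous & !mismatch
  merged_geno <- do.call(rbind, lapply(genos, function(g) {
    g[, keep, drop = FALSE]
  }))
  variants <- ref_v[keep, , drop = FALSE]

  all_ids <- unlist(lapply(cohorts, function(co) co$samples$sample_id))
  collide <- anyDuplicated(all_ids) > 0
  samples <- do.call(rbind, lapply(seq_along(cohorts), function(ci) {
    s <- cohorts[[ci]]$samples
    if (collide) s$sample_id <- paste(labels[ci], s$sample_id, sep = ":")
    s$cohort <- labels[ci]
    s
  }))

  ord <- order(chrom_rank(variants$chrom), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  merged_geno <- merged_geno[, ord, drop = FALSE]

  report <- list(
    n_samples_combined = nrow(samples),
    n_variants_shared = length(shared),
    n_flipped = n_flipped,
    n_dropped_ambiguous = sum(ambiguous),
    n_dropped_mismatch = sum(mismatch)
  )
  list(cohort = new_cohort(merged_geno, variants, samples), report = report)
}
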