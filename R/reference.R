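# Published accounting for the motivating clinical cohort (an admixed
# three-group biobank sample genotyped on the Affymetrix 6.0 array). The
# genotypes themselves are not deposited; only the printed exclusion counts
# and group sizes are public, and they serve as fixed reference inputs for
# ledger-arithmetic checks.

#' Reported SNP-level QC exclusion counts for the reference biobank cohort
#'
#' Starting from the rsID-mapped SNP count, the reported cascade excludes
#' SNPs for call rate, minor-allele frequency, batch-associated deviation,
#' differential missingness by diagnosis, and HWE failure, in that order.
#'
#' @return list with `n_start` (905,384) and the named `exclusions` vector.
#' @export
biobank_snp_exclusions <- function() {
  list(
    n_start = 905384L,
    exclusions = c(
      snp_call_rate = 60869L,
      maf = 10889L,
      batch_effect = 1236L,
      differential_missingness = 217L,
      hwe = 2587L
    )
  )
}

#' Replay the reference cohort's SNP QC ledger
#'
#' Runs [replay_ledger()] on the reported counts; the final `n_after` is the
#' analysis SNP count (829,586).
#'
#' @return a ledger data frame.
#' @export
biobank_qc_ledger <- function() {
  ref <- biobank_snp_exclusions()
  replay_ledger(ref$n_start, ref$exclusions, axis = "SNP")
}

#' Reported per-group sample sizes for the reference biobank cohort
#'
#' @return named integer vector: African-American, European-American and
#'   Hispanic group sizes after QC.
#' @export
biobank_group_sizes <- function() {
  c(african_american = 324L, european_american = 326L, hispanic = 327L)
}
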