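# Additive single-SNP association of log-BMI residuals, with optional
# principal-component adjustment for population structure. The default is
# the two-stage procedure (residualize log-BMI on age and sex within group,
# then regress the standardized residual on dosage); a joint model is
# available for comparison.

#' Standardized log-BMI residuals within a group
#'
#' Least squares of `log(BMI)` on intercept + age + sex within the group
#' (sex coded female/unknown-sex-dropped 0, male 1); residuals are
#' standardized to mean 0, SD 1 (denominator n - 1). Samples missing BMI,
#' age or declared sex are dropped and counted.
#'
#' @param x a `geno_cohort`.
#' @param group group label to analyze.
#' @return list: `residuals` (named by sample id), `n_dropped`,
#'   `degenerate` (TRUE when BMI had no variance; residuals all zero).
#' @export
bmi_residuals <- function(x, group) {
  s <- x$samples
  in_group <- s$group == group
  ok <- in_group & !is.na(s$bmi) & !is.na(s$age) & s$sex != "unknown"
  n_dropped <- sum(in_group) - sum(ok)
  if (sum(ok) < 10) {
    stop("group '", group, "' has ", sum(ok),
         " complete cases; need >= 10")
  }
  y <- log(s$bmi[ok])
  sex01 <- as.numeric(s$sex[ok] == "male")
  degenerate <- stats::var(y) == 0
  if (degenerate) {
    res <- rep(0, length(y))
  } else {
    fit <- stats::lm(y ~ s$age[ok] + sex01)
    r <- stats::residuals(fit)
    sd_r <- stats::sd(r)
    res <- if (sd_r > 0) (r - mean(r)) / sd_r else rep(0, length(r))
  }
  names(res) <- s$sample_id[ok]
  list(residuals = res, n_dropped = n_dropped, degenerate = degenerate)
}

#' Additive single-SNP association of a residual trait
#'
#' Per SNP: least squares of the residual on intercept + dosage, plus the
#' first `n_pcs` principal-component scores when `pcs` is given; two-sided
#' t-test on the dosage coefficient. Samples with a missing genotype at a
#' SNP are dropped for that SNP only. Monomorphic SNPs return `NA` effect
#' estimates, flagged in the `note` column.
#'
#' @param x a `geno_cohort`.
#' @param residuals named numeric vector (names = sample ids define the
#'   analysis set and alignment).
#' @param markers optional `marker_set` restricting the SNPs tested.
#' @param pcs optional PCA result or score matrix for structure adjustment.
#' @param n_pcs PC covariates used when `pcs` is given (default 2).
#' @return data frame: `rsid`, `chrom`, `pos`, `n_used`, `beta`, `se`, `t`,
#'   `p`, `covariates`, `note`.
#' @export
snp_association <- function(x, residuals, markers = NULL, pcs = NULL,
                            n_pcs = 2) {
  idx <- if (is.null(markers)) seq_len(ncol(x$geno)) else markers$variant_idx
  rows <- match(names(residuals), x$samples$sample_id)
  if (anyNA(rows)) stop("residual names not all present in cohort")
  g <- x$geno[rows, idx, drop = FALSE]
  y <- as.numeric(residuals)
  covar <- NULL
  covar_label <- "none"
  if (!is.null(pcs)) {
    sc <- if (is.list(pcs)) pcs$scores else pcs
    k <- min(n_pcs, ncol(sc))
    covar <- sc[rows, seq_len(k), drop = FALSE]
    covar_label <- paste0("PC1-", k)
  }
  m <- length(idx)
  out <- data.frame(
    rsid = x$variants$rsid[idx], chrom = x$variants$chrom[idx],
    pos = x$variants$pos[idx], n_used = NA_integer_, beta = NA_real_,
    se = NA_real_, t = NA_real_, p = NA_real_, covariates = covar_label,
    note = "", stringsAsFactors = FALSE
  )
  for (j in seq_len(m)) {
    d <- g[, j]
    use <- !is.na(d)
    n_used <- sum(use)
    out$n_used[j] <- n_used
    if (n_used < 3 || stats::var(d[use]) == 0) {
      out$note[j] <- "monomorphic"
      next
    }
    X <- cbind(1, d[use])
    if (!is.null(covar)) X <- cbind(X, covar[use, , drop = FALSE])
    df_resid <- n_used - ncol(X)
    if (df_resid < 1) {
      out$note[j] <- "insufficient_df"
      next
    }
    ols <- ols_t(X, y[use], df_resid)
    out$beta[j] <- ols$beta
    out$se[j] <- ols$se
    out$t[j] <- ols$t
    out$p[j] <- ols$p
  }
  out
}

#' Group-wise BMI association
#'
#' Convenience wrapper running [bmi_residuals()] and [snp_association()]
#' for one group. `method = "two_stage"` (default) is the residual
#' procedure; `method = "joint"` fits `log(BMI) ~ dosage + age + sex
#' (+ PCs)` directly per SNP.
#'
#' @param x a `geno_cohort`.
#' @param group group label.
#' @param markers,pcs,n_pcs see [snp_association()].
#' @param method `"two_stage"` or `"joint"`.
#' @return data frame as [snp_association()], with a `group` column.
#' @export
bmi_association <- function(x, group, markers = NULL, pcs = NULL,
                            n_pcs = 2, method = c("two_stage", "joint")) {
  method <- match.arg(method)
  if (method == "two_stage") {
    br <- bmi_residuals(x, group)
    out <- snp_association(x, br$residuals, markers, pcs, n_pcs)
  } else {
    s <- x$samples
    ok <- s$group == group & !is.na(s$bmi) & !is.na(s$age) &
      s$sex != "unknown"
    if (sum(ok) < 10) stop("group '", group, "' has < 10 complete cases")
    y <- log(s$bmi[ok])
    base_covar <- cbind(age = s$age[ok],
                        sex = as.numeric(s$sex[ok] == "male"))
    if (!is.null(pcs)) {
      sc <- if (is.list(pcs)) pcs$scores else pcs
      k <- min(n_pcs, ncol(sc))
      base_covar <- cbind(base_covar, sc[ok, seq_len(k), drop = FALSE])
    }
    # reuse the per-SNP engine with the joint covariates absorbed:
    # regress y on dosage + all covariates directly
    idx <- if (is.null(markers)) seq_len(ncol(x$geno)) else markers$variant_idx
    g <- x$geno[ok, idx, drop = FALSE]
    out <- data.frame(
      rsid = x$variants$rsid[idx], chrom = x$variants$chrom[idx],
      pos = x$variants$pos[idx], n_used = NA_integer_, beta = NA_real_,
      se = NA_real_, t = NA_real_, p = NA_real_,
      covariates = paste0("age+sex",
                          if (!is.null(pcs)) paste0("+PC1-", n_pcs) else ""),
      note = "", stringsAsFactors = FALSE
    )
    for (j in seq_along(idx)) {
      d <- g[, j]
      use <- !is.na(d)
      out$n_used[j] <- sum(use)
      if (sum(use) < 3 || stats::var(d[use]) == 0) {
        out$note[j] <- "monomorphic"
        next
      }
      X <- cbind(1, d[use], base_covar[use, , drop = FALSE])
      df_resid <- sum(use) - ncol(X)
      if (df_resid < 1) {
        out$note[j] <- "insufficient_df"
        next
      }
      ols <- ols_t(X, y[use], df_resid)
      out$beta[j] <- ols$beta
      out$se[j] <- ols$se
      out$t[j] <- ols$t
      out$p[j] <- ols$p
    }
  }
  out$group <- group
  out[, c("group", setdiff(names(out), "group"))]
}

# OLS t-test on the second column (the dosage term)
ols_t <- function(X, y, df_resid) {
  xtx_inv <- solve(crossprod(X))
  beta_hat <- xtx_inv %*% crossprod(X, y)
  resid <- y - X %*% beta_hat
  sigma2 <- sum(resid^2) / df_resid
  beta <- beta_hat[2]
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  tval <- beta / se
  list(beta = beta, se = se, t = tval,
       p = 2 * stats::pt(abs(tval), df_resid, lower.tail = FALSE))
}

#' Genomic inflation factor
#'
#' `lambda = median(chi^2) / 0.456` where the per-SNP chi-square is the
#' squared t statistic (1 df); the denominator is the median of the null
#' chi-square(1) distribution.
#'
#' @param assoc an association result data frame (uses column `t`), or a
#'   numeric vector of chi-square statistics.
#' @return the inflation factor.
#' @export
genomic_lambda <- function(assoc) {
  chisq <- if (is.data.frame(assoc)) assoc$t^2 else assoc
  stats::median(chisq, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
}
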