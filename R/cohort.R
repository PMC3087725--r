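#' Genotype cohort container
#'
#' A cohort bundles three aligned tables: an N x M dosage matrix (`geno`),
#' a variant table (`variants`, one row per column of `geno`) and a sample
#' table (`samples`, one row per row of `geno`). Dosages count copies of the
#' variant's counted allele, so each entry is 0, 1, 2 or `NA` (missing call).
#' Missingness is never imputed implicitly; operations that impute (genotype
#' PCA) say so.
#'
#' @param geno integer matrix, samples x variants, values in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `rsid`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`, `counted`. `counted` names the allele whose
#'   copies the dosage counts (by convention `allele_a` after harmonization).
#' @param samples data.frame with columns `sample_id`, `group`, `sex`
#'   (`"male"`, `"female"` or `"unknown"`), `age`, `bmi`, `diagnoses`
#'   (semicolon-separated flags, `""` for none), `batch`, `is_replicate`.
#' @return an object of class `geno_cohort`.
#' @export
new_cohort <- function(geno, variants, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  samples <- fill_sample_defaults(samples)
  obj <- structure(
    list(geno = geno, variants = variants, samples = samples),
    class = "geno_cohort"
  )
  validate_cohort(obj)
  rownames(obj$geno) <- obj$samples$sample_id
  colnames(obj$geno) <- obj$variants$rsid
  obj
}

fill_sample_defaults <- function(samples) {
  n <- nrow(samples)
  defaults <- list(
    group = rep("all", n), sex = rep("unknown", n),
    age = rep(NA_real_, n), bmi = rep(NA_real_, n),
    diagnoses = rep("", n), batch = rep("b1", n),
    is_replicate = rep(FALSE, n)
  )
  for (col in names(defaults)) {
    if (is.null(samples[[col]])) samples[[col]] <- defaults[[col]]
  }
  samples
}

#' Validate a cohort's invariants
#'
#' Checks dosage range, table/matrix alignment, unique sample and variant
#' identifiers, sorted positions within chromosome, and non-negative ages.
#'
#' @param x a `geno_cohort`.
#' @return `x`, invisibly; stops with a message on the first violation.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "geno_cohort"))
  g <- x$geno
  bad <- g[!is.na(g)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (nrow(g) != nrow(x$samples)) {
    stop("geno rows (", nrow(g), ") != sample table rows (", nrow(x$samples), ")")
  }
  if (ncol(g) != nrow(x$variants)) {
    stop("geno columns (", ncol(g), ") != variant table rows (", nrow(x$variants), ")")
  }
  if (anyDuplicated(x$samples$sample_id)) stop("duplicate sample_id")
  if (anyDuplicated(x$variants$rsid)) stop("duplicate rsid")
  v <- x$variants
  if (nrow(v) > 1) {
    ord <- order(chrom_rank(v$chrom), v$pos)
    if (!identical(ord, seq_len(nrow(v)))) {
      stop("variants must be sorted by (chrom, pos)")
    }
  }
  age <- x$samples$age
  if (any(!is.na(age) & age < 0)) stop("age must be >= 0 where present")
  invisible(x)
}

# numeric rank for chromosome labels; autosomes 1..22, then X
chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.numeric(chrom))
  r[toupper(chrom) == "X"] <- 23
  if (anyNA(r)) stop("unsupported chromosome label: ",
                     paste(unique(chrom[is.na(r)]), collapse = ", "))
  r
}

#' Is a chromosome label an autosome?
#'
#' @param chrom vector of chromosome labels (1-22, X).
#' @return logical vector; FALSE for X.
#' @export
is_autosome <- function(chrom) chrom_rank(chrom) <= 22

#' @export
print.geno_cohort <- function(x, ...) {
  cat("geno_cohort:", nrow(x$geno), "samples x", ncol(x$geno), "variants\n")
  cat("  groups:", paste(names(table(x$samples$group)), collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a cohort by samples and/or variants
#'
#' @param x a `geno_cohort`.
#' @param samples logical/integer index over samples (default: all).
#' @param variants logical/integer index over variants (default: all).
#' @return the subset `geno_cohort`.
#' @export
subset_cohort <- function(x, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(x$geno)) else samples
  vi <- if (is.null(variants)) seq_len(ncol(x$geno)) else variants
  new_cohort(
    x$geno[si, vi, drop = FALSE],
    x$variants[vi, , drop = FALSE],
    x$samples[si, , drop = FALSE]
  )
}

#' Counted-allele frequency per variant
#'
#' @param x a `geno_cohort` or a dosage matrix.
#' @return numeric vector of counted-allele frequencies (NaN where no calls).
#' @export
allele_freq <- function(x) {
  g <- if (inherits(x, "geno_cohort")) x$geno else x
  colMeans(g, na.rm = TRUE) / 2
}

#' Attach a sample-metadata table to a cohort
#'
#' Reads a tab-delimited table with header columns `sample_id`, `group`,
#' `sex`, `age`, `bmi`, `diagnoses` (semicolon-separated list), `batch`,
#' `replicate`, and joins it to the cohort's sample table on `sample_id`.
#'
#' @param x a `geno_cohort`.
#' @param path path to the metadata file.
#' @return the cohort with updated sample table.
#' @export
attach_metadata <- function(x, path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "sex", "age", "bmi", "diagnoses",
            "batch", "replicate")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  }
  idx <- match(x$samples$sample_id, meta$sample_id)
  if (anyNA(idx)) {
    stop("metadata missing entries for ",
         sum(is.na(idx)), " sample(s), e.g. ",
         x$samples$sample_id[which(is.na(idx))[1]])
  }
  m <- meta[idx, ]
  x$samples$group <- m$group
  x$samples$sex <- m$sex
  x$samples$age <- as.numeric(m$age)
  x$samples$bmi <- as.numeric(m$bmi)
  x$samples$diagnoses <- ifelse(is.na(m$diagnoses), "", m$diagnoses)
  x$samples$batch <- as.character(m$batch)
  x$samples$is_replicate <- as.logical(m$replicate)
  validate_cohort(x)
}

#' Write the sample-metadata table
#'
#' @param x a `geno_cohort`.
#' @param path output path (tab-delimited, with header).
#' @return `path`, invisibly.
#' @export
write_metadata <- function(x, path) {
  s <- x$samples
  out <- data.frame(
    sample_id = s$sample_id, group = s$group, sex = s$sex, age = s$age,
    bmi = s$bmi, diagnoses = s$diagnoses, batch = s$batch,
    replicate = s$is_replicate, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Does a sample carry a given diagnosis flag?
#'
#' @param samples a cohort sample table.
#' @param flag diagnosis name to look up in the semicolon-separated list.
#' @return logical vector, one entry per sample.
#' @export
has_diagnosis <- function(samples, flag) {
  vapply(strsplit(samples$diagnoses, ";", fixed = TRUE),
         function(d) flag %in% trimws(d), logical(1))
}
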