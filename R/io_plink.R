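# PLINK binary (.bed/.bim/.fam) and text (.ped/.map) genotype I/O.
# The 2-bit .bed codec is implemented from the format definition: magic bytes
# 0x6c 0x1b, mode byte 0x01 (SNP-major), then ceil(N/4) bytes per variant with
# per-sample codes 00 = two copies of allele A1, 01 = missing, 10 = het,
# 11 = zero copies of A1. A1 is the counted allele.

.bed_magic <- as.raw(c(0x6c, 0x1b))
.code_to_dosage <- c(2L, NA_integer_, 1L, 0L)   # indexed by code + 1

sex_to_fam <- function(sex) c(male = 1L, female = 2L, unknown = 0L)[sex]
fam_to_sex <- function(code) {
  out <- rep("unknown", length(code))
  out[code == 1] <- "male"
  out[code == 2] <- "female"
  out
}

#' Read a PLINK fileset
#'
#' Reads either a binary `.bed`/`.bim`/`.fam` triplet or a text `.ped`/`.map`
#' pair sharing `path_prefix`. The binary reader recovers the counted (A1)
#' allele exactly. The text format does not carry allele orientation, so the
#' text reader orients each variant to its minor allele (ties broken
#' alphabetically); see `write_plink()`.
#'
#' Sample metadata beyond id/sex is not part of PLINK filesets; the family id
#' column doubles as the group label. Use [attach_metadata()] to join the
#' full metadata table.
#'
#' @param path_prefix path without extension.
#' @return a `geno_cohort`.
#' @export
read_plink <- function(path_prefix) {
  if (file.exists(paste0(path_prefix, ".bed"))) {
    read_plink_binary(path_prefix)
  } else if (file.exists(paste0(path_prefix, ".ped"))) {
    read_plink_text(path_prefix)
  } else {
    stop("no .bed or .ped file at prefix ", path_prefix)
  }
}

read_plink_binary <- function(path_prefix) {
  fam_path <- paste0(path_prefix, ".fam")
  fam <- if (length(readLines(fam_path)) == 0) {
    data.frame(fid = character(0), iid = character(0), pat = integer(0),
               mat = integer(0), sex = integer(0), pheno = integer(0))
  } else {
    utils::read.table(fam_path, stringsAsFactors = FALSE,
                      col.names = c("fid", "iid", "pat", "mat",
                                    "sex", "pheno"))
  }
  bim <- utils::read.table(paste0(path_prefix, ".bim"),
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "rsid", "cm", "pos",
                                         "a1", "a2"))
  n <- nrow(fam)
  m <- nrow(bim)
  bed_path <- paste0(path_prefix, ".bed")
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:2], .bed_magic)) {
    stop("not a PLINK .bed file (magic-number mismatch): ", bed_path)
  }
  if (as.integer(raw[3]) != 1L) {
    stop("only SNP-major .bed files are supported: ", bed_path)
  }
  bpv <- ceiling(n / 4)          # bytes per variant
  payload <- raw[-(1:3)]
  if (length(payload) != bpv * m) {
    stop("truncated or oversized .bed payload: expected ", bpv * m,
         " bytes, found ", length(payload))
  }
  geno <- matrix(NA_integer_, n, m)
  if (n > 0 && m > 0) {
    bytes <- matrix(as.integer(payload), nrow = bpv, ncol = m)
    for (off in 0:3) {                     # sample slots within each byte
      if (off + 1L > n) break
      rows <- seq.int(off + 1L, n, by = 4L)
      byte_rows <- (rows - 1L) %/% 4L + 1L
      codes <- (bytes[byte_rows, , drop = FALSE] %/% 4L^off) %% 4L
      geno[rows, ] <- .code_to_dosage[codes + 1L]
    }
  }
  variants <- data.frame(
    rsid = bim$rsid, chrom = as.character(bim$chrom), pos = as.integer(bim$pos),
    allele_a = bim$a1, allele_b = bim$a2, counted = bim$a1,
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = fam$iid, group = as.character(fam$fid),
    sex = fam_to_sex(fam$sex), stringsAsFactors = FALSE
  )
  new_cohort(geno, variants, samples)
}

read_plink_text <- function(path_prefix) {
  map <- utils::read.table(paste0(path_prefix, ".map"),
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "rsid", "cm", "pos"))
  ped_lines <- readLines(paste0(path_prefix, ".ped"))
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  m <- nrow(map)
  n <- length(ped_lines)
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  meta <- matrix("", n, 6)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m) {
      stop(".ped line ", i, " has ", length(f), " fields; expected ",
           6 + 2 * m)
    }
    meta[i, ] <- f[1:6]
    al <- f[-(1:6)]
    a1[i, ] <- al[seq(1, 2 * m - 1, by = 2)]
    a2[i, ] <- al[seq(2, 2 * m, by = 2)]
  }
  geno <- matrix(NA_integer_, n, m)
  variants <- data.frame(
    rsid = map$rsid, chrom = as.character(map$chrom),
    pos = as.integer(map$pos),
    allele_a = NA_character_, allele_b = NA_character_,
    counted = NA_character_, stringsAsFactors = FALSE
  )
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    obs <- obs[obs != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2) {
      stop("variant ", map$rsid[j], " has >2 alleles in .ped")
    }
    if (length(alleles) == 0) alleles <- c("0", "0")
    counts <- table(factor(obs, levels = alleles))
    # counted allele = minor (tie -> alphabetical first)
    counted <- alleles[which.min(counts)]
    other <- if (length(alleles) == 2) setdiff(alleles, counted) else counted
    miss <- a1[, j] == "0" | a2[, j] == "0"
    d <- (a1[, j] == counted) + (a2[, j] == counted)
    d[miss] <- NA_integer_
    geno[, j] <- as.integer(d)
    variants$allele_a[j] <- counted
    variants$allele_b[j] <- other
    variants$counted[j] <- counted
  }
  samples <- data.frame(
    sample_id = meta[, 2], group = meta[, 1], sex = fam_to_sex(as.integer(meta[, 5])),
    stringsAsFactors = FALSE
  )
  new_cohort(geno, variants, samples)
}

#' Write a PLINK fileset
#'
#' `format = "binary"` writes `.bed`/`.bim`/`.fam` with bit-exact dosage
#' recovery on re-read. `format = "text"` writes `.ped`/`.map`; because that
#' format carries no allele orientation, re-reading recovers dosages exactly
#' only when each variant's counted allele is its minor allele.
#'
#' @param x a `geno_cohort`.
#' @param path_prefix output path without extension.
#' @param format `"binary"` (default) or `"text"`.
#' @return `path_prefix`, invisibly.
#' @export
write_plink <- function(x, path_prefix, format = c("binary", "text")) {
  format <- match.arg(format)
  validate_cohort(x)
  if (anyDuplicated(x$variants$rsid)) stop("duplicate rsid; refusing to write")
  if (format == "binary") write_plink_binary(x, path_prefix)
  else write_plink_text(x, path_prefix)
  invisible(path_prefix)
}

write_plink_binary <- function(x, path_prefix) {
  n <- nrow(x$geno)
  m <- ncol(x$geno)
  fam <- data.frame(
    fid = x$samples$group, iid = x$samples$sample_id,
    pat = rep(0L, n), mat = rep(0L, n),
    sex = unname(sex_to_fam(x$samples$sex)), pheno = rep(-9L, n)
  )
  utils::write.table(fam, paste0(path_prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(
    chrom = x$variants$chrom, rsid = x$variants$rsid, cm = 0L,
    pos = x$variants$pos, a1 = x$variants$counted,
    a2 = other_allele(x$variants)
  )
  utils::write.table(bim, paste0(path_prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code_of <- function(d) {
    out <- integer(length(d))
    out[is.na(d)] <- 1L
    out[!is.na(d) & d == 1L] <- 2L
    out[!is.na(d) & d == 0L] <- 3L
    out
  }
  bpv <- ceiling(n / 4)
  payload <- matrix(0L, max(bpv, 0), max(m, 0))
  if (n > 0 && m > 0) {
    codes <- matrix(code_of(x$geno), n, m)
    for (off in 0:3) {
      if (off + 1L > n) break
      rows <- seq.int(off + 1L, n, by = 4L)
      byte_rows <- (rows - 1L) %/% 4L + 1L
      payload[byte_rows, ] <- payload[byte_rows, , drop = FALSE] +
        codes[rows, , drop = FALSE] * 4L^off
    }
  }
  con <- file(paste0(path_prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(.bed_magic, as.raw(0x01), as.raw(as.vector(payload))), con)
}

other_allele <- function(variants) {
  ifelse(variants$counted == variants$allele_a,
         variants$allele_b, variants$allele_a)
}

write_plink_text <- function(x, path_prefix) {
  map <- data.frame(chrom = x$variants$chrom, rsid = x$variants$rsid,
                    cm = 0L, pos = x$variants$pos)
  utils::write.table(map, paste0(path_prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(x$geno)
  counted <- x$variants$counted
  other <- other_allele(x$variants)
  lines <- character(n)
  for (i in seq_len(n)) {
    d <- x$geno[i, ]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, counted, other))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, counted, other))
    lines[i] <- paste(c(x$samples$group[i], x$samples$sample_id[i], 0, 0,
                        sex_to_fam(x$samples$sex[i]), -9,
                        as.vector(rbind(a1, a2))), collapse = " ")
  }
  writeLines(lines, paste0(path_prefix, ".ped"))
}

#' Read a VCF into a cohort
#'
#' Parses GT fields of diploid records. The ALT allele is the counted
#' allele, so `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`, `./. -> NA`. Phase
#' separators are ignored (`0|1` and `0/1` are the same dosage).
#' Multi-allelic records are skipped and counted in the
#' `n_skipped_multiallelic` attribute.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a `geno_cohort` with attribute `n_skipped_multiallelic`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  fmt <- v@gt[, "FORMAT"]
  no_gt <- !vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(k) "GT" %in% k, logical(1))
  if (any(no_gt)) {
    stop("record without GT format key: ", fix$CHROM[which(no_gt)[1]], ":",
         fix$POS[which(no_gt)[1]])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  # normalize phased separators and count ALT alleles
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage_of <- function(s) {
    out <- rep(NA_integer_, length(s))
    out[s == "0/0"] <- 0L
    out[s %in% c("0/1", "1/0")] <- 1L
    out[s == "1/1"] <- 2L
    out
  }
  geno <- t(apply(gt_clean, 2, dosage_of))
  if (is.null(dim(geno))) geno <- matrix(geno, ncol = nrow(fix))
  variants <- data.frame(
    rsid = ifelse(is.na(fix$ID) | fix$ID == ".",
                  paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    allele_a = fix$ALT, allele_b = fix$REF, counted = fix$ALT,
    stringsAsFactors = FALSE
  )
  samples <- data.frame(sample_id = colnames(gt), stringsAsFactors = FALSE)
  out <- new_cohort(geno, variants, samples)
  attr(out, "n_skipped_multiallelic") <- n_multi
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
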