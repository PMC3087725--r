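# Synthetic admixed cohorts with known ground truth.
#
# Ancestral allele frequencies are drawn uniformly and per-population
# frequencies drift from them under a Balding-Nichols Beta model with one
# drift (FST-like) parameter per population. Individual admixture is
# Dirichlet. Genotypes are either unlinked draws from the individual's
# mixed frequency (global mode) or assembled from haplotypes whose ancestry
# switches along each chromosome as a Markov process (local mode), with
# optional haplotype-pool LD blocks. Nuisances are injected in a fixed,
# documented order so the ground truth of every corruption is well defined:
# LD pools -> MCAR missingness -> diagnosis-linked missingness -> batch
# corruption -> duplicates/relatives -> sex-label mismatches -> phenotype.

#' Build and validate a simulation configuration
#'
#' Defaults emulate a three-group admixed clinical cohort: two ancestral
#' populations at moderate drift, one group mostly derived from each, and a
#' third admixed across both; a log-normal BMI with age and sex effects; a
#' small X-like chromosome (males hemizygous) to exercise the sex check.
#' Nuisance injections default to off except a 1% MCAR missing rate.
#'
#' @param n_samples named integer vector: samples per group.
#' @param m_variants total autosomal SNP count.
#' @param n_chromosomes autosomes to spread SNPs over.
#' @param chrom_length_bp autosome length in bp.
#' @param K_true number of ancestral populations.
#' @param fst per-population drift parameter in (0, 1).
#' @param alpha Dirichlet concentration: one vector used for all groups, or
#'   a named list with one vector per group.
#' @param ancestry_mode `"global"` (one admixture proportion genome-wide) or
#'   `"local"` (ancestry switches along chromosomes).
#' @param switch_rate_per_mb local-ancestry segment break rate per Mb.
#' @param ld_block_size SNPs per haplotype-pool block; 0 = linkage
#'   equilibrium.
#' @param n_haplotypes_per_pool haplotypes per population per block.
#' @param missing_rate MCAR missing-call rate.
#' @param diff_missing list(flag, extra_rate, snp_fraction): extra missing
#'   rate at a random SNP subset for samples carrying the diagnosis flag.
#' @param diag_prevalence prevalence of the simulated diagnosis flag.
#' @param batch_distortion list(n_batches, n_bad_snps, rate): in the last
#'   batch, at `n_bad_snps` random SNPs, calls are corrupted at `rate`.
#' @param n_duplicates replicate sample pairs to append.
#' @param n_parent_child_pairs first-degree relative pairs to append.
#' @param sex_mismatch_rate fraction of samples whose declared sex is
#'   flipped relative to their genetic sex.
#' @param n_x_snps SNPs on the X-like chromosome.
#' @param beta_age,beta_sex,causal_snps,sigma_env,bmi_mu log-BMI model:
#'   `log(BMI) = bmi_mu + beta_age * age_std + beta_sex * male +
#'   sum(beta_j * dosage_j) + N(0, sigma_env^2)`. `causal_snps` is a
#'   two-column matrix (variant index, effect in residual-SD units).
#' @param seed RNG seed; identical configs give identical cohorts.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_samples = c(AA = 324, EA = 326, HA = 327),
                       m_variants = 10000,
                       n_chromosomes = 4,
                       chrom_length_bp = 1.2e8,
                       K_true = 2,
                       fst = rep(0.15, K_true),
                       alpha = list(AA = c(3.2, 0.8),
                                    EA = c(0.25, 4.75),
                                    HA = c(0.7, 1.3)),
                       ancestry_mode = c("global", "local"),
                       switch_rate_per_mb = 0.1,
                       ld_block_size = 0,
                       n_haplotypes_per_pool = 8,
                       missing_rate = 0.01,
                       diff_missing = list(flag = "dx1", extra_rate = 0,
                                           snp_fraction = 0),
                       diag_prevalence = 0.3,
                       batch_distortion = list(n_batches = 1, n_bad_snps = 0,
                                               rate = 0),
                       n_duplicates = 0,
                       n_parent_child_pairs = 0,
                       sex_mismatch_rate = 0,
                       n_x_snps = 0,
                       beta_age = 0.05, beta_sex = 0.1,
                       causal_snps = NULL,
                       sigma_env = 0.2, bmi_mu = log(28),
                       seed = 1L) {
  ancestry_mode <- match.arg(ancestry_mode)
  cfg <- as.list(environment())
  if (is.null(names(cfg$n_samples))) {
    names(cfg$n_samples) <- paste0("g", seq_along(cfg$n_samples))
  }
  if (!is.list(cfg$alpha)) {
    cfg$alpha <- stats::setNames(
      rep(list(cfg$alpha), length(cfg$n_samples)), names(cfg$n_samples))
  }
  if (!is.null(cfg$causal_snps)) {
    cfg$causal_snps <- matrix(cfg$causal_snps, ncol = 2)
  }
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    all(cfg$n_samples >= 1), cfg$m_variants >= 1, cfg$K_true >= 1,
    length(cfg$fst) == cfg$K_true,
    all(cfg$fst > 0 & cfg$fst < 1) || all(cfg$fst >= 0 & cfg$fst < 1),
    cfg$missing_rate >= 0, cfg$missing_rate <= 1,
    cfg$sex_mismatch_rate >= 0, cfg$sex_mismatch_rate <= 1,
    cfg$switch_rate_per_mb >= 0, cfg$ld_block_size >= 0
  )
  for (a in cfg$alpha) {
    if (length(a) != cfg$K_true) {
      stop("each alpha vector must have length K_true = ", cfg$K_true)
    }
    if (any(a <= 0)) stop("alpha entries must be positive")
  }
  if (!setequal(names(cfg$alpha), names(cfg$n_samples))) {
    stop("alpha list names must match group names")
  }
  if (!is.null(cfg$causal_snps)) {
    idx <- cfg$causal_snps[, 1]
    if (any(idx < 1 | idx > cfg$m_variants)) {
      stop("causal_snp index out of range 1..", cfg$m_variants)
    }
  }
  invisible(cfg)
}

#' Draw population allele frequencies under the drift model
#'
#' Ancestral frequency `p_j ~ Uniform(0.05, 0.95)` per SNP; population `k`'s
#' frequency `~ Beta(p_j (1 - F_k) / F_k, (1 - p_j)(1 - F_k) / F_k)`, so the
#' Beta mean is `p_j` and its variance `F_k p_j (1 - p_j)`. All frequencies
#' are clipped to `[0.01, 0.99]`. `F_k -> 0` degenerates to `p_j` itself.
#'
#' @param cfg a `sim_config` (uses `K_true`, `fst`; the SNP count may be
#'   overridden with `m`).
#' @param m number of SNPs (default `cfg$m_variants + cfg$n_x_snps`).
#' @return `K x m` matrix of population frequencies with the ancestral
#'   vector as attribute `ancestral`.
#' @export
simulate_frequencies <- function(cfg, m = cfg$m_variants + cfg$n_x_snps) {
  p_anc <- stats::runif(m, 0.05, 0.95)
  freqs <- matrix(NA_real_, cfg$K_true, m)
  for (k in seq_len(cfg$K_true)) {
    f <- cfg$fst[k]
    if (f < 1e-9) {
      freqs[k, ] <- p_anc
    } else {
      freqs[k, ] <- stats::rbeta(m, p_anc * (1 - f) / f,
                                 (1 - p_anc) * (1 - f) / f)
    }
  }
  freqs <- pmin(pmax(freqs, 0.01), 0.99)
  attr(freqs, "ancestral") <- p_anc
  freqs
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# consecutive runs of `size` SNPs within each chromosome; returns an integer
# block id per variant (0 = unblocked when size == 0)
block_ids <- function(chrom, size) {
  if (size <= 0) return(rep(0L, length(chrom)))
  ids <- integer(length(chrom))
  nxt <- 1L
  for (ch in unique(chrom)) {
    j <- which(chrom == ch)
    within <- (seq_along(j) - 1L) %/% size
    ids[j] <- nxt + within
    nxt <- nxt + max(within) + 1L
  }
  ids
}

#' Simulate an admixed cohort with ground truth
#'
#' See the package vignette for the generative model and the fixed nuisance
#' order. Identical configurations (including seed) give identical output.
#'
#' @param cfg a `sim_config`.
#' @return list with `cohort` (a `geno_cohort`) and `truth` (fields
#'   `q_true`, `freqs_true`, `local_ancestry`, `excluded_truth`,
#'   `phenotype_params`, `causal_dosages`).
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  groups <- names(cfg$n_samples)
  n0 <- sum(cfg$n_samples)
  K <- cfg$K_true

  variants <- make_variant_table(cfg)
  auto <- which(is_autosome(variants$chrom))
  xidx <- which(!is_autosome(variants$chrom))
  m_all <- nrow(variants)

  freqs <- simulate_frequencies(cfg, m = m_all)

  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n0)),
    group = rep(groups, times = cfg$n_samples),
    sex = sample(c("male", "female"), n0, replace = TRUE),
    age = pmin(pmax(round(stats::rnorm(n0, 52, 14)), 18), 90),
    bmi = NA_real_,
    diagnoses = ifelse(stats::runif(n0) < cfg$diag_prevalence,
                       cfg$diff_missing$flag, ""),
    batch = paste0("b", (seq_len(n0) - 1L) %%
                     max(1L, cfg$batch_distortion$n_batches) + 1L),
    is_replicate = FALSE,
    stringsAsFactors = FALSE
  )

  q_true <- matrix(NA_real_, n0, K)
  for (g in groups) {
    rows <- which(samples$group == g)
    q_true[rows, ] <- rdirichlet(length(rows), cfg$alpha[[g]])
  }

  drawn <- draw_genotypes(cfg, variants, freqs, q_true, samples$sex,
                          auto, xidx)
  geno <- drawn$geno
  local_anc <- drawn$local_ancestry

  truth <- list(
    q_true = q_true, freqs_true = freqs, local_ancestry = local_anc,
    excluded_truth = list(), phenotype_params = NULL, causal_dosages = NULL
  )

  # true dosages at causal SNPs, kept before any corruption
  if (!is.null(cfg$causal_snps)) {
    cidx <- auto[cfg$causal_snps[, 1]]
    truth$causal_dosages <- geno[, cidx, drop = FALSE]
  }

  # --- nuisance order: MCAR missingness ---
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(geno)) < cfg$missing_rate
    geno[mask] <- NA_integer_
  }

  # --- diagnosis-linked differential missingness ---
  dm <- cfg$diff_missing
  if (dm$extra_rate > 0 && dm$snp_fraction > 0) {
    n_dm <- max(1L, floor(dm$snp_fraction * length(auto)))
    dm_snps <- sort(sample(auto, n_dm))
    flagged <- which(has_diagnosis(samples, dm$flag))
    sub <- geno[flagged, dm_snps, drop = FALSE]
    sub[stats::runif(length(sub)) < dm$extra_rate] <- NA_integer_
    geno[flagged, dm_snps] <- sub
    truth$excluded_truth$diff_missing_snps <- variants$rsid[dm_snps]
  }

  # --- batch genotype corruption (last batch) ---
  # modeled as a cluster-calling shift: at an affected SNP, a fraction of
  # the bad batch's calls collapses onto the minor-allele homozygote
  # cluster, displacing that batch's allele frequency at any MAF
  bd <- cfg$batch_distortion
  if (bd$n_bad_snps > 0 && bd$rate > 0 && bd$n_batches > 1) {
    bad_snps <- sort(sample(auto, bd$n_bad_snps))
    bad_batch <- paste0("b", bd$n_batches)
    rows <- which(samples$batch == bad_batch)
    for (j in bad_snps) {
      p_j <- mean(geno[, j], na.rm = TRUE) / 2
      target <- if (is.finite(p_j) && p_j < 0.5) 2L else 0L
      hit <- rows[stats::runif(length(rows)) < bd$rate]
      ok <- hit[!is.na(geno[hit, j])]
      geno[ok, j] <- target
    }
    truth$excluded_truth$batch_snps <- variants$rsid[bad_snps]
    truth$excluded_truth$bad_batch <- bad_batch
  }

  # --- duplicates (exact copies, replicate-flagged, other batch) ---
  if (cfg$n_duplicates > 0) {
    src <- sample(seq_len(n0), cfg$n_duplicates)
    dup_geno <- geno[src, , drop = FALSE]
    dup_samples <- samples[src, ]
    dup_samples$sample_id <- paste0(samples$sample_id[src], "_rep")
    dup_samples$is_replicate <- TRUE
    if (bd$n_batches > 1) {
      bnum <- as.integer(sub("b", "", dup_samples$batch))
      dup_samples$batch <- paste0("b", bnum %% bd$n_batches + 1L)
    }
    geno <- rbind(geno, dup_geno)
    samples <- rbind(samples, dup_samples)
    q_true <- rbind(q_true, q_true[src, , drop = FALSE])
    truth$excluded_truth$duplicate_pairs <-
      cbind(samples$sample_id[src], dup_samples$sample_id)
  }

  # --- parent-child pairs (one transmitted allele guarantees IBS >= 1) ---
  if (cfg$n_parent_child_pairs > 0) {
    par_rows <- sample(which(!samples$is_replicate), cfg$n_parent_child_pairs)
    for (pr in par_rows) {
      pi_mate <- drop(q_true[pr, , drop = FALSE] %*% freqs)  # mate from same admixture
      d_par <- geno[pr, ]
      transmitted <- stats::rbinom(m_all, 1, ifelse(is.na(d_par),
                                                    pi_mate, d_par / 2))
      untransmitted <- stats::rbinom(m_all, 1, pi_mate)
      child <- as.integer(transmitted + untransmitted)
      child_sex <- sample(c("male", "female"), 1)
      if (length(xidx)) {  # keep X coding consistent with declared sex
        child[xidx] <- if (child_sex == "male") {
          2L * stats::rbinom(length(xidx), 1, pi_mate[xidx])
        } else {
          as.integer(stats::rbinom(length(xidx), 2, pi_mate[xidx]))
        }
      }
      geno <- rbind(geno, child)
      child_row <- samples[pr, ]
      child_row$sample_id <- paste0(samples$sample_id[pr], "_child")
      child_row$sex <- child_sex
      child_row$age <- max(18, samples$age[pr] - 28)
      child_row$is_replicate <- FALSE
      samples <- rbind(samples, child_row)
      q_true <- rbind(q_true, q_true[pr, , drop = FALSE])
      truth$excluded_truth$parent_child_pairs <-
        rbind(truth$excluded_truth$parent_child_pairs,
              c(samples$sample_id[pr], child_row$sample_id))
    }
  }

  # --- sex-label mismatches ---
  if (cfg$sex_mismatch_rate > 0) {
    flip <- which(stats::runif(nrow(samples)) < cfg$sex_mismatch_rate)
    samples$sex[flip] <- ifelse(samples$sex[flip] == "male",
                                "female", "male")
    truth$excluded_truth$sex_mismatch_ids <- samples$sample_id[flip]
  }

  truth$q_true <- q_true   # includes rows appended for duplicates/children
  rownames(geno) <- samples$sample_id
  cohort <- new_cohort(geno, variants, samples)

  # --- phenotype (from pre-corruption causal dosages) ---
  ph <- simulate_phenotype(cohort, cfg, causal_dosages = causal_dosage_rows(
    truth$causal_dosages, cohort$samples$sample_id))
  cohort$samples <- ph$samples
  truth$phenotype_params <- ph$params

  list(cohort = cohort, truth = truth)
}

# align stored causal dosages (captured before duplicates/children were
# appended) to the final sample list: the first rows map one-to-one, exact
# replicate copies share their source's genotype, and children fall back to
# NA (mean-imputed in the phenotype model)
causal_dosage_rows <- function(causal, sample_ids) {
  if (is.null(causal)) return(NULL)
  out <- matrix(NA_real_, length(sample_ids), ncol(causal))
  out[seq_len(nrow(causal)), ] <- causal
  reps <- grepl("_rep$", sample_ids)
  src <- match(sub("_rep$", "", sample_ids[reps]), sample_ids)
  out[which(reps), ] <- out[src, , drop = FALSE]
  out
}

make_variant_table <- function(cfg) {
  m_per <- diff(round(seq(0, cfg$m_variants, length.out =
                            cfg$n_chromosomes + 1)))
  vs <- list()
  for (ch in seq_len(cfg$n_chromosomes)) {
    mc <- m_per[ch]
    if (mc == 0) next
    pos <- sort(sample.int(cfg$chrom_length_bp, mc))
    vs[[ch]] <- data.frame(
      rsid = sprintf("rs%d_%d", ch, seq_len(mc)),
      chrom = as.character(ch), pos = pos, stringsAsFactors = FALSE
    )
  }
  if (cfg$n_x_snps > 0) {
    pos <- sort(sample.int(1.5e8, cfg$n_x_snps))
    vs[[cfg$n_chromosomes + 1L]] <- data.frame(
      rsid = sprintf("rsX_%d", seq_len(cfg$n_x_snps)),
      chrom = "X", pos = pos, stringsAsFactors = FALSE
    )
  }
  v <- do.call(rbind, vs)
  pairs <- matrix(c("A", "C", "A", "G", "C", "T", "G", "T", "A", "T",
                    "C", "G"), ncol = 2, byrow = TRUE)
  pick <- sample(nrow(pairs), nrow(v), replace = TRUE,
                 prob = c(0.23, 0.23, 0.23, 0.23, 0.04, 0.04))
  v$allele_a <- pairs[pick, 1]
  v$allele_b <- pairs[pick, 2]
  v$counted <- v$allele_a
  v
}

# genotype assembly for all modes; returns geno (N x M) and, in local mode,
# per-haplotype ancestry labels at autosomal SNPs
draw_genotypes <- function(cfg, variants, freqs, q_true, sexes, auto, xidx) {
  n <- nrow(q_true)
  m_all <- nrow(variants)
  K <- cfg$K_true
  geno <- matrix(NA_integer_, n, m_all)
  local_anc <- NULL

  haplotype_mode <- cfg$ancestry_mode == "local" || cfg$ld_block_size > 0

  if (!haplotype_mode) {
    p <- q_true %*% freqs[, auto, drop = FALSE]
    geno[, auto] <- stats::rbinom(n * length(auto), 2, p)
  } else {
    chrom_a <- variants$chrom[auto]
    pos_a <- variants$pos[auto]
    blocks <- block_ids(chrom_a, cfg$ld_block_size)
    pools <- NULL
    if (cfg$ld_block_size > 0) {
      # Pool haplotypes follow an infinite-sites model on a random
      # genealogy: each SNP mutates once on a random clade, so every
      # within-pool pair is compatible with at most three gametes (D' = 1
      # in the pool) -- the defining structure of a haplotype block. Pool
      # allele frequencies are set by clade sizes, not the drift draw.
      pools <- lapply(seq_len(max(blocks)), function(b) {
        j <- which(blocks == b)
        lapply(seq_len(K), function(k) {
          make_block_pool(cfg$n_haplotypes_per_pool, length(j))
        })
      })
    }
    anc1 <- matrix(NA_integer_, n, length(auto))
    anc2 <- matrix(NA_integer_, n, length(auto))
    hap_geno <- matrix(0L, n, length(auto))
    for (i in seq_len(n)) {
      for (h in 1:2) {
        anc <- draw_hap_ancestry(cfg, chrom_a, pos_a, q_true[i, ])
        if (h == 1) anc1[i, ] <- anc else anc2[i, ] <- anc
        hap_geno[i, ] <- hap_geno[i, ] +
          draw_hap_alleles(cfg, anc, freqs, auto, blocks, pools)
      }
    }
    geno[, auto] <- hap_geno
    if (cfg$ancestry_mode == "local") {
      local_anc <- list(hap1 = anc1, hap2 = anc2)
    }
  }

  if (length(xidx)) {
    px <- q_true %*% freqs[, xidx, drop = FALSE]
    male <- sexes == "male"
    gx <- matrix(NA_integer_, n, length(xidx))
    if (any(!male)) {
      gx[!male, ] <- stats::rbinom(sum(!male) * length(xidx), 2,
                                   px[!male, , drop = FALSE])
    }
    if (any(male)) {
      gx[male, ] <- 2L * stats::rbinom(sum(male) * length(xidx), 1,
                                       px[male, , drop = FALSE])
    }
    geno[, xidx] <- gx
  }
  list(geno = geno, local_ancestry = local_anc)
}

# one haplotype's ancestry label per autosomal SNP. Local mode: exponential
# segment lengths (Poisson breakpoints at switch_rate_per_mb), each segment's
# ancestry drawn iid from q so q is the chain's stationary distribution.
# Global mode (reached only with LD pools): one ancestry draw per pool block,
# matching the genome-wide Binomial model in expectation.
draw_hap_ancestry <- function(cfg, chrom, pos, q) {
  K <- length(q)
  anc <- integer(length(chrom))
  for (ch in unique(chrom)) {
    j <- which(chrom == ch)
    if (cfg$ancestry_mode == "local") {
      len_mb <- max(pos[j]) / 1e6
      if (cfg$switch_rate_per_mb <= 0) {
        anc[j] <- sample.int(K, 1, prob = q)
      } else {
        n_breaks <- stats::rpois(1, cfg$switch_rate_per_mb * len_mb)
        breaks <- sort(stats::runif(n_breaks, 0, len_mb)) * 1e6
        seg <- findInterval(pos[j], breaks) + 1L
        seg_anc <- sample.int(K, n_breaks + 1L, replace = TRUE, prob = q)
        anc[j] <- seg_anc[seg]
      }
    } else {
      blocks <- block_ids(chrom[j], max(1L, cfg$ld_block_size))
      nb <- max(blocks)
      banc <- sample.int(K, nb, replace = TRUE, prob = q)
      anc[j] <- banc[blocks]
    }
  }
  anc
}

# haplotype pool for one block and population: H haplotypes related by a
# random bifurcating genealogy; each SNP's counted allele marks one clade
make_block_pool <- function(H, m_block) {
  clades <- random_clades(seq_len(H))[-1]   # drop the root (monomorphic)
  hap <- matrix(0L, H, m_block)
  pick <- sample.int(length(clades), m_block, replace = TRUE)
  for (j in seq_len(m_block)) {
    hap[clades[[pick[j]]], j] <- 1L
  }
  hap
}

# all proper clades of a random recursive bipartition of `leaves`
random_clades <- function(leaves) {
  if (length(leaves) <= 1) return(list(leaves))
  split <- sample(c(TRUE, FALSE), length(leaves), replace = TRUE)
  if (all(split) || all(!split)) {
    flip <- sample.int(length(leaves), 1)
    split[flip] <- !split[flip]
  }
  c(list(leaves),
    random_clades(leaves[split]), random_clades(leaves[!split]))
}

draw_hap_alleles <- function(cfg, anc, freqs, auto, blocks, pools) {
  m <- length(anc)
  if (is.null(pools)) {
    return(stats::rbinom(m, 1, freqs[cbind(anc, auto)]))
  }
  allele <- integer(m)
  for (b in seq_len(max(blocks))) {
    j <- which(blocks == b)
    k <- anc[j[1]]   # block ancestry = ancestry at block's first SNP
    row <- sample.int(cfg$n_haplotypes_per_pool, 1)
    allele[j] <- pools[[b]][[k]][row, ]
  }
  allele
}

#' Attach a simulated log-normal BMI phenotype
#'
#' `log(BMI) = bmi_mu + beta_age * age_std + beta_sex * male +
#' sum_j beta_j * dosage_j + N(0, sigma_env^2)`, stored on the natural
#' scale. Age is standardized within the cohort; sex codes female/unknown 0,
#' male 1. Causal dosages default to the cohort's observed calls
#' (missing entries mean-imputed); `simulate_cohort()` passes the true
#' pre-corruption dosages instead.
#'
#' @param cohort a `geno_cohort` with ages and sexes populated.
#' @param cfg a `sim_config`.
#' @param causal_dosages optional matrix of dosages at `cfg$causal_snps`.
#' @return list with the updated `samples` table and `params` echo.
#' @export
simulate_phenotype <- function(cohort, cfg, causal_dosages = NULL) {
  s <- cohort$samples
  n <- nrow(s)
  age_std <- as.numeric(scale(s$age))
  if (any(!is.finite(age_std))) age_std[!is.finite(age_std)] <- 0
  male <- as.numeric(s$sex == "male")
  eta <- cfg$bmi_mu + cfg$beta_age * age_std + cfg$beta_sex * male
  if (!is.null(cfg$causal_snps)) {
    auto <- which(is_autosome(cohort$variants$chrom))
    if (is.null(causal_dosages)) {
      causal_dosages <- cohort$geno[, auto[cfg$causal_snps[, 1]],
                                    drop = FALSE]
    }
    for (j in seq_len(nrow(cfg$causal_snps))) {
      d <- causal_dosages[, j]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      eta <- eta + cfg$causal_snps[j, 2] * d
    }
  }
  noise <- if (cfg$sigma_env > 0) stats::rnorm(n, 0, cfg$sigma_env) else 0
  s$bmi <- exp(eta + noise)
  list(samples = s,
       params = list(bmi_mu = cfg$bmi_mu, beta_age = cfg$beta_age,
                     beta_sex = cfg$beta_sex, causal_snps = cfg$causal_snps,
                     sigma_env = cfg$sigma_env))
}
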