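#' Configuration for the synthetic GWAS generator
#'
#' Collects and validates the parameters of the paired exposure/outcome
#' summary-statistics simulation. Defaults describe the birth-weight /
#' amblyopia setting the package is built around: 18 true instruments, a
#' protective causal effect of -0.73 log-odds per exposure SD, a continuous
#' exposure GWAS of 262,966 individuals and a binary outcome GWAS of 862
#' cases / 416,168 controls.
#'
#' @param n_instruments Number of SNPs with a true effect on the exposure.
#' @param n_null_snps Number of SNPs with no exposure effect.
#' @param theta True causal effect (log-odds of outcome per exposure unit).
#' @param tau SD of the true instrument-exposure effects.
#' @param n_exposure Exposure GWAS sample size (continuous trait).
#' @param n_cases,n_controls Outcome GWAS case/control counts.
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct effects centred on
#'   zero) or `"directional"` (half-normal direct effects).
#' @param pleiotropy_sd SD of the direct (pleiotropic) outcome effects.
#' @param maf_range Length-2 interval within (0, 0.5] for minor-allele
#'   frequencies.
#' @param n_ld_blocks Number of LD blocks; each block is 3 co-located SNPs
#'   (within 1 Mb) sharing pairwise r2 `ld_r2`.
#' @param ld_r2 Within-block squared correlation.
#' @param palindromic_fraction Fraction of SNPs given A/T or C/G allele pairs.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_instruments = 18, n_null_snps = 82,
                              theta = -0.73, tau = 0.02,
                              n_exposure = 262966,
                              n_cases = 862, n_controls = 416168,
                              pleiotropy_mode = c("none", "balanced", "directional"),
                              pleiotropy_sd = 0.01,
                              maf_range = c(0.05, 0.5),
                              n_ld_blocks = 0, ld_r2 = 0.8,
                              palindromic_fraction = 0.2, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (n_instruments < 1) stop("n_instruments must be >= 1", call. = FALSE)
  if (n_null_snps < 0) stop("n_null_snps must be >= 0", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]", call. = FALSE)
  if (palindromic_fraction < 0 || palindromic_fraction > 1)
    stop("palindromic_fraction must be in [0, 1]", call. = FALSE)
  if (n_exposure < 2 || n_cases < 1 || n_controls < 1)
    stop("sample sizes must be positive", call. = FALSE)
  if (n_ld_blocks < 0 || ld_r2 < 0 || ld_r2 > 1)
    stop("invalid LD block specification", call. = FALSE)
  if (pleiotropy_sd < 0) stop("pleiotropy_sd must be >= 0", call. = FALSE)
  structure(list(n_instruments = as.integer(n_instruments),
                 n_null_snps = as.integer(n_null_snps),
                 theta = theta, tau = tau,
                 n_exposure = as.integer(n_exposure),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 maf_range = as.numeric(maf_range),
                 n_ld_blocks = as.integer(n_ld_blocks),
                 ld_r2 = ld_r2,
                 palindromic_fraction = palindromic_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Allele pairs: the 4 palindromic ordered pairs and the 8 non-palindromic ones.
PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2, byrow = TRUE)
NONPAL_PAIRS <- matrix(c("A", "C", "C", "A", "A", "G", "G", "A",
                         "T", "C", "C", "T", "T", "G", "G", "T"),
                       ncol = 2, byrow = TRUE)

#' Simulate paired exposure/outcome GWAS summary statistics
#'
#' Generates an exposure table, an outcome table, an LD table and the ground
#' truth, under a simple summary-statistic model: for SNP j with minor-allele
#' frequency p_j drawn uniformly from `maf_range`, the true exposure effect is
#' b_j ~ N(0, tau^2) for instruments and 0 otherwise; the exposure standard
#' error is the large-sample value for a standardized continuous trait,
#' SE_Xj = 1/sqrt(2 p_j (1-p_j) n_exposure), and the observed effect is
#' beta_Xj ~ N(b_j, SE_Xj^2). For the binary outcome with case fraction
#' K = n_cases/(n_cases+n_controls), SE_Yj = 1/sqrt(2 p_j (1-p_j) N K (1-K))
#' (logistic score-test approximation) and
#' beta_Yj ~ N(theta b_j + a_j, SE_Yj^2), where a_j is the direct
#' (pleiotropic) effect chosen by `pleiotropy_mode`. P-values are two-sided
#' normal. LD blocks are groups of three SNPs co-located within 1 Mb sharing
#' pairwise r2 `ld_r2`; all other pairs have r2 = 0.
#'
#' To exercise harmonization, a `palindromic_fraction` of SNPs receive A/T or
#' C/G allele pairs, and every second outcome record has its alleles written
#' in swapped order with the effect sign and EAF flipped accordingly (the
#' underlying association is unchanged). Reported EAF equals the MAF with the
#' effect allele minor, except those flipped records report 1 - MAF.
#'
#' @param config A [simulation_config()].
#' @return A list with components `exposure` and `outcome` (each a
#'   `sumstats_table`), `ld` (an `ld_table`) and `truth` (class
#'   `simulation_truth`: `theta`, per-SNP `b` and `a` vectors, `instrument`
#'   and `swapped` flags, `seed`).
#' @examples
#' sim <- simulate_summary_stats(simulation_config(n_instruments = 5,
#'                                                 n_null_snps = 5, seed = 7))
#' head(sim$exposure$data)
#' @export
simulate_summary_stats <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  m <- config$n_instruments + config$n_null_snps
  instrument <- seq_len(m) <= config$n_instruments

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  b <- ifelse(instrument, stats::rnorm(m, 0, config$tau), 0)

  se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
  beta_x <- stats::rnorm(m, b, se_x)
  p_x <- 2 * stats::pnorm(-abs(beta_x / se_x))

  n_outcome <- config$n_cases + config$n_controls
  K <- config$n_cases / n_outcome
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * n_outcome * K * (1 - K))
  a <- switch(config$pleiotropy_mode,
              none = rep(0, m),
              balanced = stats::rnorm(m, 0, config$pleiotropy_sd),
              directional = abs(stats::rnorm(m, 0, config$pleiotropy_sd)))
  beta_y <- stats::rnorm(m, config$theta * b + a, se_y)
  p_y <- 2 * stats::pnorm(-abs(beta_y / se_y))

  # Genomic layout: LD-block members share a chromosome within 1 Mb; every
  # other SNP sits 20 Mb from its nearest same-chromosome neighbour, far
  # outside any clumping window.
  chr <- character(m); pos <- integer(m)
  block_id <- rep(NA_integer_, m)
  n_block_snps <- min(3L * config$n_ld_blocks, m)
  if (config$n_ld_blocks > 0)
    block_id[seq_len(n_block_snps)] <- rep(seq_len(config$n_ld_blocks),
                                           each = 3L)[seq_len(n_block_snps)]
  for (j in seq_len(m)) {
    if (!is.na(block_id[j])) {
      k <- block_id[j]
      within <- sum(!is.na(block_id[seq_len(j)]) &
                      block_id[seq_len(j)] == k)  # 1-based index in block
      chr[j] <- as.character((k - 1L) %% 22L + 1L)
      pos[j] <- 1000000L + (within - 1L) * 10000L +
        ((k - 1L) %/% 22L) * 5000000L
    } else {
      chr[j] <- as.character((j - 1L) %% 22L + 1L)
      pos[j] <- 100000000L + ((j - 1L) %/% 22L) * 20000000L
    }
  }

  n_pal <- round(config$palindromic_fraction * m)
  pal_idx <- if (n_pal > 0) sample.int(m, n_pal) else integer(0)
  ea <- character(m); oa <- character(m)
  pick <- sample.int(4L, m, replace = TRUE)
  pick_np <- sample.int(8L, m, replace = TRUE)
  for (j in seq_len(m)) {
    if (j %in% pal_idx) {
      ea[j] <- PALINDROMIC_PAIRS[pick[j], 1]; oa[j] <- PALINDROMIC_PAIRS[pick[j], 2]
    } else {
      ea[j] <- NONPAL_PAIRS[pick_np[j], 1]; oa[j] <- NONPAL_PAIRS[pick_np[j], 2]
    }
  }

  ids <- sprintf("rs%06d", seq_len(m))
  exposure_df <- data.frame(variant_id = ids, chr = chr, pos = pos,
                            effect_allele = ea, other_allele = oa,
                            eaf = maf, beta = beta_x, se = se_x, pvalue = p_x,
                            stringsAsFactors = FALSE)

  # Swapped outcome records: deterministic half (even row index) so the
  # harmonization truth is reproducible irrespective of RNG state.
  swapped <- seq_len(m) %% 2L == 0L
  out_ea <- ifelse(swapped, oa, ea)
  out_oa <- ifelse(swapped, ea, oa)
  out_beta <- ifelse(swapped, -beta_y, beta_y)
  out_eaf <- ifelse(swapped, 1 - maf, maf)
  outcome_df <- data.frame(variant_id = ids, chr = chr, pos = pos,
                           effect_allele = out_ea, other_allele = out_oa,
                           eaf = out_eaf, beta = out_beta, se = se_y,
                           pvalue = p_y, stringsAsFactors = FALSE)

  # Pairwise LD entries within blocks.
  la <- character(0); lb <- character(0); lr <- numeric(0)
  if (config$n_ld_blocks > 0) {
    for (k in seq_len(config$n_ld_blocks)) {
      members <- which(!is.na(block_id) & block_id == k)
      if (length(members) >= 2) {
        cmb <- utils::combn(members, 2)
        la <- c(la, ids[cmb[1, ]]); lb <- c(lb, ids[cmb[2, ]])
        lr <- c(lr, rep(config$ld_r2, ncol(cmb)))
      }
    }
  }

  exposure <- new_sumstats_table(exposure_df,
    study_metadata("simulated_exposure", "continuous", n_total = config$n_exposure))
  outcome <- new_sumstats_table(outcome_df,
    study_metadata("simulated_outcome", "binary",
                   n_cases = config$n_cases, n_controls = config$n_controls))
  truth <- structure(list(theta = config$theta, b = b, a = a,
                          instrument = instrument, swapped = swapped,
                          variant_id = ids, maf = maf, seed = config$seed),
                     class = "simulation_truth")
  list(exposure = exposure, outcome = outcome,
       ld = ld_table(la, lb, lr), truth = truth)
}

#' Write a simulated dataset to an output directory
#'
#' Writes `exposure.tsv`, `outcome.tsv`, `ld.tsv` and `truth.json`.
#'
#' @param sim Result of [simulate_summary_stats()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  utils::write.table(sim$ld$entries, file.path(dir, "ld.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(unclass(sim$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
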