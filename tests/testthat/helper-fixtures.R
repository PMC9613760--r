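# Build a sumstats_table directly from vectors, bypassing file I/O.
make_table <- function(variant_id, chr = "1", pos = seq_along(variant_id) * 1e6,
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, beta = 0.1, se = 0.02,
                       pvalue = 2 * pnorm(-abs(beta / se)),
                       metadata = study_metadata("test", "continuous",
                                                 n_total = 1000)) {
  n <- length(variant_id)
  df <- data.frame(variant_id = variant_id,
                   chr = rep_len(as.character(chr), n),
                   pos = as.integer(rep_len(pos, n)),
                   effect_allele = rep_len(effect_allele, n),
                   other_allele = rep_len(other_allele, n),
                   eaf = rep_len(eaf, n), beta = rep_len(beta, n),
                   se = rep_len(se, n), pvalue = rep_len(pvalue, n),
                   stringsAsFactors = FALSE)
  perimr:::new_sumstats_table(df, metadata)
}

# Write a canonical nine-column TSV and return its path.
write_sumstats_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Minimal well-formed sumstats data.frame for file-based tests.
sumstats_df <- function(n = 3, ids = sprintf("rs%d", seq_len(n))) {
  data.frame(variant_id = ids, chr = "1", pos = seq_len(n) * 1000L,
             effect_allele = "A", other_allele = "G", eaf = 0.25,
             beta = 0.1, se = 0.02, pvalue = 2 * pnorm(-5),
             stringsAsFactors = FALSE)
}

# Harmonized ratio fixture assembled directly (variant_id/theta/se/weight).
make_ratios <- function(theta, se) {
  data.frame(variant_id = sprintf("rs%d", seq_along(theta)),
             theta = theta, se = se, weight = 1 / se^2,
             stringsAsFactors = FALSE)
}

# Harmonized-dataset stand-in from effect vectors.
make_harmonized <- function(beta_x, se_x, beta_y, se_y) {
  pairs <- data.frame(variant_id = sprintf("rs%d", seq_along(beta_x)),
                      effect_allele = "A", other_allele = "G",
                      beta_x = beta_x, se_x = se_x, beta_y = beta_y,
                      se_y = se_y, eaf_x = 0.3, eaf_y = 0.3,
                      action = "none", palindromic = FALSE,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 dropped = data.frame(variant_id = character(),
                                      reason = character())),
            class = "harmonized_dataset")
}

# One-row association record for harmonize_pair tests.
assoc <- function(id = "rs1", ea = "A", oa = "G", eaf = 0.3,
                  beta = 0.1, se = 0.02) {
  data.frame(variant_id = id, chr = "1", pos = 1000L, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pvalue = 2 * pnorm(-abs(beta / se)), stringsAsFactors = FALSE)
}
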