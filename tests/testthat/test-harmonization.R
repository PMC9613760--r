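test_that("palindromic detection: exactly the 4 complementary pairs", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ea = bases, oa = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ea != pairs$oa, ]
  pal <- is_palindromic(pairs$ea, pairs$oa)
  expect_equal(sum(pal), 4)
  expect_setequal(paste0(pairs$ea[pal], pairs$oa[pal]),
                  c("AT", "TA", "CG", "GC"))
})

test_that("allele-order swap negates the outcome effect and mirrors its EAF", {
  h <- harmonize_pair(assoc(ea = "A", oa = "G", beta = 0.02, eaf = 0.3),
                      assoc(ea = "G", oa = "A", beta = -0.5, eaf = 0.7))
  expect_equal(h$action, "swapped")
  expect_equal(h$beta_y, 0.5)
  expect_equal(h$eaf_y, 0.3)
  expect_equal(c(h$effect_allele, h$other_allele), c("A", "G"))

  # identity case
  h0 <- harmonize_pair(assoc(ea = "A", oa = "G"), assoc(ea = "A", oa = "G"))
  expect_equal(h0$action, "none")
})

test_that("strand flips relabel without or with the swap correction", {
  # A/C vs T/G: pure strand flip, effect untouched
  h <- harmonize_pair(assoc(ea = "A", oa = "C", beta = 0.1),
                      assoc(ea = "T", oa = "G", beta = 0.4, eaf = 0.3))
  expect_equal(h$action, "strand_flipped")
  expect_equal(h$beta_y, 0.4)
  # A/C vs G/T: flipped and swapped
  h2 <- harmonize_pair(assoc(ea = "A", oa = "C"),
                       assoc(ea = "G", oa = "T", beta = 0.4, eaf = 0.3))
  expect_equal(h2$action, "swapped_and_flipped")
  expect_equal(h2$beta_y, -0.4)
  expect_equal(h2$eaf_y, 0.7)
  # irreconcilable alleles
  d <- harmonize_pair(assoc(ea = "A", oa = "C"), assoc(ea = "A", oa = "G"))
  expect_equal(d$reason, "allele_mismatch")
  expect_error(harmonize_pair(assoc(id = "rs1"), assoc(id = "rs2")),
               "different variants")
})

test_that("palindromic SNPs: intermediate or missing EAF drops, frequencies orient otherwise", {
  # intermediate frequency: uninformative, dropped
  d <- harmonize_pair(assoc(ea = "A", oa = "T", eaf = 0.50),
                      assoc(ea = "A", oa = "T", eaf = 0.50))
  expect_equal(d$reason, "palindromic_intermediate")
  d2 <- harmonize_pair(assoc(ea = "C", oa = "G", eaf = NA),
                       assoc(ea = "C", oa = "G", eaf = 0.1))
  expect_equal(d2$reason, "palindromic_intermediate")
  # band edges are inclusive
  d3 <- harmonize_pair(assoc(ea = "A", oa = "T", eaf = 0.42),
                       assoc(ea = "A", oa = "T", eaf = 0.1))
  expect_equal(d3$reason, "palindromic_intermediate")

  # discordant frequencies: outcome on the other strand, effect negated
  h <- harmonize_pair(assoc(ea = "C", oa = "G", eaf = 0.10),
                      assoc(ea = "C", oa = "G", beta = 0.3, eaf = 0.91))
  expect_equal(h$beta_y, -0.3)
  expect_equal(h$eaf_y, 0.09)
  expect_true(h$palindromic)
  expect_true(h$eaf_x < 0.42 && h$eaf_y < 0.42)

  # concordant frequencies: kept as aligned
  h2 <- harmonize_pair(assoc(ea = "C", oa = "G", eaf = 0.10),
                       assoc(ea = "C", oa = "G", beta = 0.3, eaf = 0.12))
  expect_equal(h2$beta_y, 0.3)
  expect_equal(h2$action, "none")

  # swapped label order plus concordance after the swap correction
  h3 <- harmonize_pair(assoc(ea = "A", oa = "T", eaf = 0.2),
                       assoc(ea = "T", oa = "A", beta = -0.4, eaf = 0.8))
  expect_equal(h3$action, "swapped")
  expect_equal(h3$beta_y, 0.4)
  expect_equal(h3$eaf_y, 0.2)

  # strict mode drops every palindromic SNP
  d4 <- harmonize_pair(assoc(ea = "C", oa = "G", eaf = 0.10),
                       assoc(ea = "C", oa = "G", eaf = 0.12),
                       strict_palindromic = TRUE)
  expect_equal(d4$reason, "palindromic_strict")
})

test_that("harmonize_tables reproduces the generator's truth flags", {
  sim <- simulate_summary_stats(simulation_config(n_instruments = 40,
    n_null_snps = 0, palindromic_fraction = 0.3, maf_range = c(0.05, 0.35),
    seed = 44))
  h <- harmonize_tables(sim$truth$variant_id, sim$exposure, sim$outcome)
  expect_equal(nrow(h$pairs) + nrow(h$dropped), 40)
  tr_swap <- sim$truth$swapped[match(h$pairs$variant_id,
                                     sim$truth$variant_id)]
  expect_equal(h$pairs$action == "swapped", tr_swap)
  # harmonized outcome effects equal the generator's pre-swap effects
  idx <- match(h$pairs$variant_id, sim$outcome$data$variant_id)
  raw <- ifelse(tr_swap, -sim$outcome$data$beta[idx],
                sim$outcome$data$beta[idx])
  expect_equal(h$pairs$beta_y, raw)
})

test_that("harmonization is an involution and never keeps intermediate palindromes", {
  sim <- simulate_summary_stats(simulation_config(n_instruments = 30,
    n_null_snps = 0, palindromic_fraction = 0.4, seed = 13))
  h1 <- suppressMessages(
    harmonize_tables(sim$truth$variant_id, sim$exposure, sim$outcome))
  # no surviving palindromic pair has an EAF inside the band
  pal <- h1$pairs[h1$pairs$palindromic, ]
  if (nrow(pal) > 0) {
    expect_true(all(pal$eaf_x < 0.42 | pal$eaf_x > 0.58))
    expect_true(all(pal$eaf_y < 0.42 | pal$eaf_y > 0.58))
  }
  # feed the harmonized pairs back in as both tables: identity
  as_table <- function(pairs, meta) {
    df <- data.frame(variant_id = pairs$variant_id, chr = "1",
                     pos = seq_len(nrow(pairs)), effect_allele = pairs$effect_allele,
                     other_allele = pairs$other_allele, eaf = pairs$eaf_y,
                     beta = pairs$beta_y, se = pairs$se_y,
                     pvalue = 2 * pnorm(-abs(pairs$beta_y / pairs$se_y)),
                     stringsAsFactors = FALSE)
    perimr:::new_sumstats_table(df, meta)
  }
  tab <- as_table(h1$pairs, sim$outcome$metadata)
  h2 <- harmonize_tables(h1$pairs$variant_id, tab, tab)
  expect_true(all(h2$pairs$action == "none"))
  expect_equal(h2$pairs$beta_y, h1$pairs$beta_y)

  # instrument absent from the outcome GWAS recorded as missing_in_outcome
  out_cut <- sim$outcome
  gone <- sim$truth$variant_id[1]
  out_cut$data <- out_cut$data[out_cut$data$variant_id != gone, ]
  h3 <- suppressMessages(harmonize_tables(
    sim$truth$variant_id[1:5], sim$exposure, out_cut))
  expect_true(gone %in%
                h3$dropped$variant_id[h3$dropped$reason == "missing_in_outcome"])
})

test_that("Wald ratios are invariant to which record carried the swap", {
  ex <- assoc(ea = "A", oa = "G", beta = 0.05, eaf = 0.3)
  out <- assoc(ea = "A", oa = "G", beta = -0.4, eaf = 0.3, se = 0.1)
  # swap the outcome record
  out_sw <- out
  out_sw$effect_allele <- "G"; out_sw$other_allele <- "A"
  out_sw$beta <- -out_sw$beta; out_sw$eaf <- 1 - out_sw$eaf
  # swap the exposure record instead
  ex_sw <- ex
  ex_sw$effect_allele <- "G"; ex_sw$other_allele <- "A"
  ex_sw$beta <- -ex_sw$beta; ex_sw$eaf <- 1 - ex_sw$eaf
  h_out <- harmonize_pair(ex, out_sw)
  h_ex <- harmonize_pair(ex_sw, out)
  expect_equal(h_out$beta_y / h_out$beta_x, h_ex$beta_y / h_ex$beta_x)
  expect_equal(h_out$beta_y / h_out$beta_x, out$beta / ex$beta)
})
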