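# Independent per-stage RNG streams derived from the single run seed, so that
# adding a stage never perturbs another stage's randomness.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483629)
}

default_run_config <- function() {
  list(io = list(exposure = NULL, outcome = NULL, ld = NULL, exclusion = NULL,
                 column_map = NULL,
                 exposure_metadata = NULL, outcome_metadata = NULL),
       simulate = NULL,
       selection = list(pval_threshold = 1e-6, r2 = 0.001, window_kb = 10000,
                        no_exclude = FALSE, exclude_ids = NULL),
       harmonization = list(intermediate_band = c(0.42, 0.58),
                            strict_palindromic = FALSE),
       mr = list(n_boot = 1000, floor_dispersion = FALSE, level = 0.95),
       power = list(r_squared = NULL, alpha = 0.05, odds_ratio = NULL),
       seed = 1L, out_dir = NULL)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline run configuration
#'
#' Reads a JSON configuration with sections `io`, `simulate`, `selection`,
#' `harmonization`, `mr`, `power`, plus top-level `seed` and `out_dir`, and
#' fills defaults for everything unspecified. Exactly one of the `io`
#' exposure/outcome paths or the `simulate` block must be present.
#'
#' @param path Path to a JSON file.
#' @return A validated config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  normalize_config(cfg)
}

normalize_config <- function(config) {
  cfg <- merge_config(default_run_config(), config)
  has_io <- !is.null(cfg$io$exposure) || !is.null(cfg$io$outcome)
  has_sim <- !is.null(cfg$simulate)
  if (has_io == has_sim)
    stop("config must contain exactly one of io exposure/outcome paths or a simulate block",
         call. = FALSE)
  if (has_io && (is.null(cfg$io$exposure) || is.null(cfg$io$outcome)))
    stop("io mode needs both exposure and outcome paths", call. = FALSE)
  cfg
}

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

metadata_from_list <- function(x, fallback_name) {
  if (is.null(x)) stop("trait metadata required for io mode", call. = FALSE)
  study_metadata(if (is.null(x$trait_name)) fallback_name else x$trait_name,
                 x$trait_type,
                 n_total = x$n_total, n_cases = x$n_cases,
                 n_controls = x$n_controls)
}

#' Run the full MR pipeline
#'
#' Orchestrates simulate/read, instrument selection, harmonization, the MR
#' estimator battery and (for binary outcomes with an `r_squared` supplied)
#' the power calculation, from one configuration. When `out_dir` is set the
#' run writes `report.json`, `instruments.tsv`, `harmonized.tsv`,
#' `dropped.tsv`, `results.tsv`, `results.json` and `scatter-export.tsv`;
#' partial outputs are removed if any stage fails. Identical config and seed
#' give an identical report.
#'
#' @param config A config list (see [read_run_config()]); may be a partial
#'   list, defaults are filled in.
#' @return The run report, invisibly when `out_dir` is set: per-stage counts,
#'   the selection audit, harmonization actions/drops, all MR estimates,
#'   diagnostics, the power result and the echoed configuration.
#' @examples
#' rep <- run_pipeline(list(simulate = list(n_instruments = 8, n_null_snps = 4,
#'                                          tau = 0.08),
#'                          mr = list(n_boot = 50), seed = 3))
#' rep$estimates
#' @export
run_pipeline <- function(config) {
  cfg <- normalize_config(config)
  out_dir <- cfg$out_dir
  written <- character(0)
  ok <- FALSE
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    on.exit(if (!ok && length(written) > 0) unlink(written), add = TRUE)
  }

  # --- inputs -----------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- derive_seed(cfg$seed, "simulate")
    sim <- stage_run("simulate", do.call(simulation_config, sim_args))
    data <- stage_run("simulate", simulate_summary_stats(sim))
    exposure <- data$exposure; outcome <- data$outcome; ld <- data$ld
    truth <- data$truth
  } else {
    exposure <- stage_run("read", read_sumstats(cfg$io$exposure,
      metadata_from_list(cfg$io$exposure_metadata, "exposure"),
      column_map = cfg$io$column_map))
    outcome <- stage_run("read", read_sumstats(cfg$io$outcome,
      metadata_from_list(cfg$io$outcome_metadata, "outcome"),
      column_map = cfg$io$column_map))
    ld <- if (!is.null(cfg$io$ld)) stage_run("read", read_ld_table(cfg$io$ld))
          else ld_table()
    truth <- NULL
  }
  exclusions <- character(0)
  if (!isTRUE(cfg$selection$no_exclude)) {
    if (!is.null(cfg$io$exclusion))
      exclusions <- stage_run("read", read_exclusion_list(cfg$io$exclusion))
    if (!is.null(cfg$selection$exclude_ids))
      exclusions <- unique(c(exclusions, cfg$selection$exclude_ids))
  }

  # --- selection --------------------------------------------------------
  instruments <- stage_run("select",
    select_instruments(exposure, ld, exclusions,
                       pval_threshold = cfg$selection$pval_threshold,
                       r2_threshold = cfg$selection$r2,
                       window_kb = cfg$selection$window_kb))

  # --- harmonization ----------------------------------------------------
  harmonized <- stage_run("harmonize",
    harmonize_tables(instruments, exposure, outcome,
                     intermediate_band = cfg$harmonization$intermediate_band,
                     strict_palindromic = cfg$harmonization$strict_palindromic))

  # --- mr ---------------------------------------------------------------
  mr <- stage_run("mr",
    run_all_methods(harmonized, n_boot = cfg$mr$n_boot,
                    seed = derive_seed(cfg$seed, "mr"),
                    floor_dispersion = cfg$mr$floor_dispersion,
                    level = cfg$mr$level))

  # --- power ------------------------------------------------------------
  power <- NULL
  if (!is.null(cfg$power$r_squared) &&
      outcome$metadata$trait_type == "binary") {
    or_input <- cfg$power$odds_ratio
    if (is.null(or_input))
      or_input <- mr$estimates$or[mr$estimates$method == "ivw_random"]
    pw <- stage_run("power",
      binary_outcome_power(outcome$metadata$n_total,
                           outcome$metadata$n_cases / outcome$metadata$n_total,
                           or_input, cfg$power$r_squared, cfg$power$alpha))
    power <- c(unclass(pw), list(odds_ratio = or_input,
                                 r_squared = cfg$power$r_squared,
                                 alpha = cfg$power$alpha))
  }

  # --- report -----------------------------------------------------------
  audit <- instruments$audit
  stages <- list(
    input = list(n_exposure_variants = nrow(exposure$data),
                 n_outcome_variants = nrow(outcome$data),
                 n_dropped_at_read = nrow(exposure$dropped) +
                   nrow(outcome$dropped)),
    selection = list(n_candidates = nrow(audit),
                     n_retained = length(instruments$selected),
                     n_dropped = as.list(table(
                       audit$status[audit$status != "retained"]))),
    harmonization = list(n_in = length(instruments$selected),
                         n_retained = nrow(harmonized$pairs),
                         n_dropped = as.list(table(harmonized$dropped$reason))),
    mr = list(n_snp = nrow(harmonized$pairs)))
  cfg_echo <- cfg
  cfg_echo$out_dir <- NULL  # keep the report independent of where it lands
  report <- list(package = "perimr",
                 version = as.character(utils::packageVersion("perimr")),
                 seed = cfg$seed,
                 config = cfg_echo,
                 stages = stages,
                 selection_audit = audit,
                 f_statistics = as.list(instruments$f_statistics),
                 harmonization_actions = as.list(table(harmonized$pairs$action)),
                 estimates = mr$estimates,
                 diagnostics = mr$diagnostics,
                 power = power,
                 truth = if (!is.null(truth)) unclass(truth) else NULL)

  if (!is.null(out_dir)) {
    wfile <- function(name) {
      p <- file.path(out_dir, name); written <<- c(written, p); p
    }
    jsonlite::write_json(report, wfile("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    f_col <- unname(instruments$f_statistics[audit$variant_id])
    utils::write.table(
      data.frame(variant_id = audit$variant_id,
                 F = ifelse(is.na(f_col), "", formatC(f_col, digits = 17,
                                                      format = "g")),
                 status = audit$status,
                 index_snp = ifelse(is.na(audit$index_snp), "",
                                    audit$index_snp)),
      wfile("instruments.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    fmt_full <- function(df) {  # %.17g round-trips doubles exactly
      for (col in names(df))
        if (is.double(df[[col]])) {
          na <- is.na(df[[col]])
          df[[col]] <- formatC(df[[col]], digits = 17, format = "g")
          df[[col]][na] <- "NA"
        }
      df
    }
    utils::write.table(fmt_full(harmonized$pairs), wfile("harmonized.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(harmonized$dropped, wfile("dropped.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res <- data.frame(Exposure = exposure$metadata$trait_name,
                      Method = mr$estimates$method,
                      `Number of SNP` = mr$estimates$n_snp,
                      Beta = mr$estimates$beta, SE = mr$estimates$se,
                      `p value` = mr$estimates$pvalue, check.names = FALSE)
    utils::write.table(res, wfile("results.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(list(estimates = mr$estimates,
                              diagnostics = mr$diagnostics, power = power),
                         wfile("results.json"), auto_unbox = TRUE, digits = NA,
                         null = "null")
    utils::write.table(fmt_full(harmonized$pairs[, c("variant_id", "beta_x",
                                                     "se_x", "beta_y",
                                                     "se_y")]),
                       wfile("scatter-export.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ok <- TRUE
    return(invisible(report))
  }
  ok <- TRUE
  report
}
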