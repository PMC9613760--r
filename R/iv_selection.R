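new_instrument_set <- function(selected, audit, f_statistics = NULL) {
  structure(list(selected = selected, audit = audit,
                 f_statistics = f_statistics),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %d selected of %d candidates\n",
              length(x$selected), nrow(x$audit)))
  print(table(x$audit$status))
  invisible(x)
}

audit_frame <- function(variant_id, status, index_snp = NA_character_) {
  data.frame(variant_id = variant_id,
             status = rep_len(status, length(variant_id)),
             index_snp = rep_len(index_snp, length(variant_id)),
             stringsAsFactors = FALSE)
}

#' Filter exposure associations by p-value
#'
#' Retains variants whose exposure p-value is strictly below `threshold`
#' (default 1e-6, the genome-wide criterion used for instrument discovery in
#' this pipeline). All input variants are accounted for in the audit.
#'
#' @param table Exposure `sumstats_table`.
#' @param threshold Significance threshold in (0, 1); comparison is strict.
#' @return An `instrument_set` with `selected` IDs and an audit assigning
#'   every variant `retained` or `dropped_pvalue`.
#' @export
filter_by_pvalue <- function(table, threshold = 1e-6) {
  stopifnot(inherits(table, "sumstats_table"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  keep <- table$data$pvalue < threshold
  audit <- audit_frame(table$data$variant_id,
                       ifelse(keep, "retained", "dropped_pvalue"))
  new_instrument_set(table$data$variant_id[keep], audit)
}

#' Greedy LD clumping
#'
#' Prunes the candidate set so that retained instruments are approximately
#' independent: candidates are visited in ascending p-value order (ties broken
#' by chromosome, position, then variant ID, so the result is invariant to
#' input row order); each visited SNP becomes an index SNP and removes every
#' remaining candidate on the same chromosome within `window_kb` of it whose
#' r2 with it is at or above `r2_threshold`. A pair absent from the LD table
#' has r2 = 0 and is never clumped.
#'
#' @param candidates An `instrument_set` (or character vector of IDs).
#' @param table Exposure `sumstats_table` providing chr/pos/p-value.
#' @param ld An `ld_table` (may be empty).
#' @param r2_threshold Inclusive r2 cut-off (default 0.001).
#' @param window_kb Window in kilobases (default 10,000 kb = 10 Mb).
#' @return An `instrument_set`; clumped variants are audited
#'   `dropped_clump` with their index SNP.
#' @export
clump <- function(candidates, table, ld = ld_table(),
                  r2_threshold = 0.001, window_kb = 10000) {
  ids <- if (inherits(candidates, "instrument_set")) candidates$selected else candidates
  stopifnot(inherits(table, "sumstats_table"), inherits(ld, "ld_table"))
  idx <- match(ids, table$data$variant_id)
  if (anyNA(idx))
    stop(sprintf("candidate(s) absent from table: %s",
                 paste(ids[is.na(idx)], collapse = ", ")), call. = FALSE)
  df <- table$data[idx, c("variant_id", "chr", "pos", "pvalue")]
  ord <- order(df$pvalue, df$chr, df$pos, df$variant_id)
  df <- df[ord, , drop = FALSE]

  window_bp <- window_kb * 1000
  status <- stats::setNames(rep(NA_character_, nrow(df)), df$variant_id)
  index_of <- stats::setNames(rep(NA_character_, nrow(df)), df$variant_id)
  selected <- character(0)
  for (i in seq_len(nrow(df))) {
    id <- df$variant_id[i]
    if (!is.na(status[id])) next
    status[id] <- "retained"
    selected <- c(selected, id)
    if (i < nrow(df)) {
      for (j in seq(i + 1L, nrow(df))) {
        other <- df$variant_id[j]
        if (!is.na(status[other])) next
        if (df$chr[j] == df$chr[i] &&
            abs(df$pos[j] - df$pos[i]) <= window_bp &&
            ld_lookup(ld, id, other) >= r2_threshold) {
          status[other] <- "dropped_clump"
          index_of[other] <- id
        }
      }
    }
  }
  audit <- audit_frame(df$variant_id, unname(status[df$variant_id]),
                       unname(index_of[df$variant_id]))
  new_instrument_set(selected, audit)
}

#' Remove excluded variants from the instrument set
#'
#' Drops any candidate on the exclusion list (e.g. instruments with a known
#' direct association with the outcome, curated upstream). IDs on the list but
#' not among candidates trigger a warning and are otherwise ignored. Passing
#' an empty list is the identity, which also serves as the sensitivity-run
#' mode that skips exclusion altogether.
#'
#' @param candidates An `instrument_set` or character vector of IDs.
#' @param exclusions Character vector of variant IDs (see
#'   [read_exclusion_list()]).
#' @return An `instrument_set`; removed variants are audited
#'   `dropped_excluded`.
#' @export
apply_exclusions <- function(candidates, exclusions) {
  ids <- if (inherits(candidates, "instrument_set")) candidates$selected else candidates
  exclusions <- unique(exclusions)
  absent <- setdiff(exclusions, ids)
  if (length(absent) > 0)
    warning(sprintf("exclusion ID(s) not among candidates: %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
  hit <- ids %in% exclusions
  audit <- audit_frame(ids, ifelse(hit, "dropped_excluded", "retained"))
  new_instrument_set(ids[!hit], audit)
}

#' Per-instrument F-statistics
#'
#' Instrument strength computed as the squared z-score, F_j = (beta_j/se_j)^2.
#' (The textbook (n-2) R^2/(1-R^2) form needs the per-SNP R^2, which GWAS
#' summary rows do not carry; for a single SNP the squared z-score is its
#' large-sample equivalent.) Values below ~10 conventionally flag weak
#' instruments.
#'
#' @param selected An `instrument_set` or character vector of IDs.
#' @param table Exposure `sumstats_table`.
#' @return Named numeric vector of F-statistics.
#' @export
f_statistics <- function(selected, table) {
  ids <- if (inherits(selected, "instrument_set")) selected$selected else selected
  stopifnot(inherits(table, "sumstats_table"))
  idx <- match(ids, table$data$variant_id)
  if (anyNA(idx))
    stop(sprintf("variant(s) absent from table: %s",
                 paste(ids[is.na(idx)], collapse = ", ")), call. = FALSE)
  stats::setNames((table$data$beta[idx] / table$data$se[idx])^2, ids)
}

#' Full instrument-selection stage
#'
#' Convenience wrapper chaining [filter_by_pvalue()], [clump()] and
#' [apply_exclusions()], then attaching [f_statistics()]. The merged audit
#' partitions the full input variant set: each variant is `retained`,
#' `dropped_pvalue`, `dropped_clump` (with its index SNP), or
#' `dropped_excluded`.
#'
#' @param table Exposure `sumstats_table`.
#' @param ld An `ld_table` (default empty: no clumping drops).
#' @param exclusions Character vector of IDs to exclude (default none).
#' @param pval_threshold,r2_threshold,window_kb Stage parameters.
#' @return An `instrument_set` with `f_statistics` populated.
#' @export
select_instruments <- function(table, ld = ld_table(), exclusions = character(),
                               pval_threshold = 1e-6, r2_threshold = 0.001,
                               window_kb = 10000) {
  s1 <- filter_by_pvalue(table, pval_threshold)
  s2 <- clump(s1, table, ld, r2_threshold, window_kb)
  s3 <- apply_exclusions(s2, exclusions)
  audit <- s1$audit
  rownames(audit) <- audit$variant_id
  a2 <- s2$audit[s2$audit$status != "retained", , drop = FALSE]
  audit[a2$variant_id, c("status", "index_snp")] <-
    a2[, c("status", "index_snp")]
  a3 <- s3$audit[s3$audit$status != "retained", , drop = FALSE]
  audit[a3$variant_id, "status"] <- a3$status
  rownames(audit) <- NULL
  new_instrument_set(s3$selected, audit,
                     f_statistics = f_statistics(s3$selected, table))
}
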