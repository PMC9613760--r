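# Canonical column order for summary-statistics tables.
SUMSTATS_COLS <- c("variant_id", "chr", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue")

#' Study metadata for one GWAS
#'
#' Describes the trait behind a summary-statistics table. For binary traits the
#' case/control split is required and must sum to the total sample size; for
#' continuous traits only the total is used.
#'
#' @param trait_name Character label for the trait.
#' @param trait_type Either `"continuous"` or `"binary"`.
#' @param n_total Total GWAS sample size.
#' @param n_cases,n_controls Case and control counts (binary traits only).
#'
#' @return An object of class `study_metadata`.
#' @examples
#' study_metadata("amblyopia", "binary", n_cases = 862, n_controls = 416168)
#' @export
study_metadata <- function(trait_name, trait_type = c("continuous", "binary"),
                           n_total = NULL, n_cases = NULL, n_controls = NULL) {
  trait_type <- match.arg(trait_type)
  if (trait_type == "binary") {
    if (is.null(n_cases) || is.null(n_controls))
      stop("binary traits require n_cases and n_controls", call. = FALSE)
    if (is.null(n_total)) n_total <- n_cases + n_controls
    if (n_cases + n_controls != n_total)
      stop("n_cases + n_controls must equal n_total for binary traits",
           call. = FALSE)
  } else {
    if (is.null(n_total)) stop("continuous traits require n_total", call. = FALSE)
  }
  structure(list(trait_name = trait_name, trait_type = trait_type,
                 n_total = as.integer(n_total),
                 n_cases = if (is.null(n_cases)) NA_integer_ else as.integer(n_cases),
                 n_controls = if (is.null(n_controls)) NA_integer_ else as.integer(n_controls)),
            class = "study_metadata")
}

new_sumstats_table <- function(data, metadata, dropped = NULL) {
  if (is.null(dropped))
    dropped <- data.frame(variant_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  structure(list(data = data, metadata = metadata, dropped = dropped),
            class = "sumstats_table")
}

#' @export
print.sumstats_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d variants (%d dropped at read)\n",
              x$metadata$trait_name, x$metadata$trait_type,
              nrow(x$data), nrow(x$dropped)))
  print(utils::head(x$data))
  invisible(x)
}

# Validate one parsed summary-stats data.frame; returns list(data, dropped).
validate_sumstats <- function(df, warn_pz = TRUE) {
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)

  dup <- unique(df$variant_id[duplicated(df$variant_id)])
  if (length(dup) > 0)
    stop(sprintf("duplicated variant_id in summary statistics: %s",
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)

  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(df))
  bad_allele <- !(df$effect_allele %in% bases) | !(df$other_allele %in% bases)
  reason[bad_allele] <- "non-ACGT allele (indel or multiallelic)"
  same <- !bad_allele & df$effect_allele == df$other_allele
  reason[same] <- "effect allele equals other allele"
  reason[is.na(reason) & (!is.finite(df$se) | df$se <= 0)] <- "nonpositive SE"
  reason[is.na(reason) & (!is.finite(df$beta))] <- "missing beta"
  reason[is.na(reason) &
           (!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1)] <- "p-value outside (0,1]"
  bad_eaf <- is.na(reason) & !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)
  reason[bad_eaf] <- "EAF outside [0,1]"

  keep <- is.na(reason)
  dropped <- data.frame(variant_id = df$variant_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  if (nrow(dropped) > 0)
    message(sprintf("dropped %d record(s) at validation: %s", nrow(dropped),
                    paste(sprintf("%s (%s)", dropped$variant_id, dropped$reason),
                          collapse = "; ")))
  df <- df[keep, , drop = FALSE]

  # Public summary stats often carry truncated p-values, so a p/z mismatch up
  # to a factor of 2 warns rather than invalidates the record.
  if (warn_pz && nrow(df) > 0) {
    p_recomp <- 2 * stats::pnorm(-abs(df$beta / df$se))
    ratio <- pmax(df$pvalue, p_recomp) / pmax(pmin(df$pvalue, p_recomp), 1e-300)
    off <- which(is.finite(ratio) & ratio > 2)
    if (length(off) > 0)
      warning(sprintf("p-value inconsistent with beta/se (z-test, factor > 2) for %d record(s), e.g. %s",
                      length(off), df$variant_id[off[1]]), call. = FALSE)
  }
  rownames(df) <- NULL
  list(data = df, dropped = dropped)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-separated file with a header row into a validated
#' `sumstats_table`. Rows violating record invariants (non-ACGT or identical
#' alleles, nonpositive SE, p-value outside (0,1], EAF outside \[0,1\]) are
#' dropped and logged with a reason; a duplicated variant ID is an error.
#' Positions are 1-based base pairs. Missing EAF is permitted (palindromic
#' SNPs with missing EAF are dropped later at harmonization).
#'
#' @param path Path to the file.
#' @param metadata A [study_metadata()] object for the trait.
#' @param column_map Named character vector mapping canonical field names
#'   (`variant_id`, `chr`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`) to the file's column names. Defaults to the
#'   canonical names themselves.
#' @param sep Field separator; `""` (default) auto-detects tab vs comma from
#'   the header line.
#'
#' @return A `sumstats_table`: list with `data` (validated data.frame in
#'   canonical column order), `metadata`, and `dropped` (variant_id/reason log).
#' @seealso [write_sumstats()], [read_exclusion_list()], [read_ld_table()]
#' @export
read_sumstats <- function(path, metadata, column_map = NULL, sep = "") {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  if (sep == "") {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"",
                           na.strings = c("NA", "", "."))
  cmap <- stats::setNames(SUMSTATS_COLS, SUMSTATS_COLS)
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  missing_cols <- cmap[!(cmap %in% names(raw))]
  if (length(missing_cols) > 0)
    stop(sprintf("missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)

  df <- data.frame(variant_id = as.character(raw[[cmap["variant_id"]]]),
                   chr = as.character(raw[[cmap["chr"]]]),
                   pos = as.integer(raw[[cmap["pos"]]]),
                   effect_allele = as.character(raw[[cmap["effect_allele"]]]),
                   other_allele = as.character(raw[[cmap["other_allele"]]]),
                   eaf = as.numeric(raw[[cmap["eaf"]]]),
                   beta = as.numeric(raw[[cmap["beta"]]]),
                   se = as.numeric(raw[[cmap["se"]]]),
                   pvalue = as.numeric(raw[[cmap["pvalue"]]]),
                   stringsAsFactors = FALSE)
  v <- validate_sumstats(df)
  if (nrow(v$data) == 0)
    stop("no valid records remain after validation", call. = FALSE)
  new_sumstats_table(v$data, metadata, v$dropped)
}

#' Write a summary-statistics table to TSV
#'
#' Writes the canonical nine columns at full precision, so that a read/write
#' round trip preserves every validated record exactly.
#'
#' @param table A `sumstats_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats_table"))
  df <- table$data[, SUMSTATS_COLS]
  for (col in c("eaf", "beta", "se", "pvalue"))
    df[[col]] <- formatC(df[[col]], digits = 17, format = "g")
  df$eaf[is.na(table$data$eaf)] <- "NA"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant exclusion list
#'
#' One variant ID per line; `#` starts a comment; blank lines ignored;
#' duplicates collapsed. Used for instruments flagged as pleiotropic by
#' upstream curation (e.g. phenotype/eQTL lookup) that must be removed from
#' the instrument set.
#'
#' @param path Path to the text file.
#' @return Character vector of unique variant IDs (possibly empty).
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Read a pairwise LD table
#'
#' Three whitespace/tab-separated columns: variant ID A, variant ID B, and
#' their squared correlation r2 in \[0, 1\]. Lookups are symmetric in the two
#' IDs; an absent pair has r2 = 0 and r2(v, v) = 1 implicitly.
#'
#' @param path Path to the file (no header).
#' @return An object of class `ld_table`.
#' @seealso [ld_lookup()]
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[\t ]+")
  nfield <- vapply(parts, length, integer(1))
  if (any(nfield != 3L))
    stop(sprintf("malformed LD table row at line %d (expected 3 fields)",
                 which(nfield != 3L)[1]), call. = FALSE)
  id_a <- vapply(parts, `[[`, character(1), 1L)
  id_b <- vapply(parts, `[[`, character(1), 2L)
  r2 <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  if (anyNA(r2))
    stop(sprintf("malformed LD table row at line %d (non-numeric r2)",
                 which(is.na(r2))[1]), call. = FALSE)
  ld_table(id_a, id_b, r2)
}

#' Construct an LD table from vectors
#'
#' @param id_a,id_b Variant ID vectors of equal length.
#' @param r2 Squared-correlation vector in \[0, 1\].
#' @return An `ld_table` supporting symmetric [ld_lookup()].
#' @export
ld_table <- function(id_a = character(), id_b = character(), r2 = numeric()) {
  stopifnot(length(id_a) == length(id_b), length(id_a) == length(r2))
  if (any(!is.finite(r2) | r2 < 0 | r2 > 1))
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  env <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(id_a)) {
    key <- paste(sort(c(id_a[i], id_b[i])), collapse = "\r")
    assign(key, r2[i], envir = env)
  }
  structure(list(env = env,
                 entries = data.frame(id_a = id_a, id_b = id_b, r2 = r2,
                                      stringsAsFactors = FALSE)),
            class = "ld_table")
}

#' Look up pairwise LD
#'
#' @param ld An `ld_table`.
#' @param a,b Variant IDs. The lookup is symmetric; `a == b` returns 1 and an
#'   absent pair returns 0.
#' @return r2 as a single numeric.
#' @export
ld_lookup <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"))
  if (a == b) return(1)
  key <- paste(sort(c(a, b)), collapse = "\r")
  if (exists(key, envir = ld$env, inherits = FALSE))
    get(key, envir = ld$env, inherits = FALSE)
  else 0
}

#' @export
print.ld_table <- function(x, ...) {
  cat(sprintf("LD table with %d pair(s)\n", nrow(x$entries)))
  invisible(x)
}
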