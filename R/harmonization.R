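BASE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Is an allele pair palindromic?
#'
#' A SNP is palindromic when its two alleles are base complements (A/T or
#' C/G), so the strand cannot be inferred from the allele labels alone.
#'
#' @param effect_allele,other_allele Single-base alleles (A/C/G/T).
#' @return Logical (vectorized).
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  unname(BASE_COMPLEMENT[toupper(effect_allele)] == toupper(other_allele))
}

#' Harmonize one exposure/outcome record pair
#'
#' Aligns the outcome association to the exposure's effect allele. Cases are
#' resolved in a fixed order:
#' \enumerate{
#'   \item alleles identical in the same order: keep (`action = "none"`);
#'   \item outcome alleles are the exposure pair in swapped order: negate
#'     the outcome effect and flip its EAF (`"swapped"`);
#'   \item outcome alleles are strand complements of case 1 or 2 and the SNP
#'     is not palindromic: relabel, applying the swap correction when needed
#'     (`"strand_flipped"` / `"swapped_and_flipped"`);
#'   \item palindromic SNP: drop (`palindromic_intermediate`) when either
#'     EAF is missing or inside `intermediate_band`; otherwise align the
#'     labels as in case 1/2, then compare EAFs — if they fall on opposite
#'     sides of 0.5 the outcome record is on the other strand, so negate its
#'     effect and flip its EAF once more;
#'   \item anything else: drop (`allele_mismatch`).
#' }
#' With `strict_palindromic = TRUE` every palindromic SNP is dropped
#' regardless of frequency (reason `palindromic_strict`).
#'
#' @param exposure,outcome Single-row data.frames (or lists) with the
#'   canonical summary-statistic fields; must share `variant_id`.
#' @param intermediate_band Length-2 EAF interval treated as uninformative
#'   for strand inference (default \[0.42, 0.58\]).
#' @param strict_palindromic Drop all palindromic SNPs when `TRUE`.
#' @return A one-row data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta_x`, `se_x`, `beta_y`, `se_y`, `eaf_x`, `eaf_y`,
#'   `action`, `palindromic`; or a drop marker list with `variant_id` and
#'   `reason`.
#' @export
harmonize_pair <- function(exposure, outcome,
                           intermediate_band = c(0.42, 0.58),
                           strict_palindromic = FALSE) {
  if (exposure$variant_id != outcome$variant_id)
    stop("harmonize_pair called on different variants", call. = FALSE)
  drop <- function(reason) list(variant_id = exposure$variant_id, reason = reason)

  ea_x <- exposure$effect_allele; oa_x <- exposure$other_allele
  ea_y <- outcome$effect_allele; oa_y <- outcome$other_allele
  pal <- is_palindromic(ea_x, oa_x)

  beta_y <- outcome$beta; eaf_y <- outcome$eaf
  flip_y <- function() {
    beta_y <<- -beta_y
    if (!is.na(eaf_y)) eaf_y <<- 1 - eaf_y
  }

  if (pal) {
    if (strict_palindromic) return(drop("palindromic_strict"))
    # For A/T and C/G the strand complement of the pair is the pair itself,
    # so the only label-level information is the order.
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) return(drop("allele_mismatch"))
    in_band <- function(f) !is.na(f) && f >= intermediate_band[1] && f <= intermediate_band[2]
    if (is.na(exposure$eaf) || is.na(eaf_y) ||
        in_band(exposure$eaf) || in_band(eaf_y))
      return(drop("palindromic_intermediate"))
    action <- "none"
    if (ea_y == oa_x && oa_y == ea_x) {  # swapped label order
      flip_y(); action <- "swapped"
    }
    if ((exposure$eaf < 0.5) != (eaf_y < 0.5)) {  # opposite strands
      flip_y()
      action <- switch(action, none = "strand_flipped",
                       swapped = "swapped_and_flipped")
    }
    return(data.frame(variant_id = exposure$variant_id,
                      effect_allele = ea_x, other_allele = oa_x,
                      beta_x = exposure$beta, se_x = exposure$se,
                      beta_y = beta_y, se_y = outcome$se,
                      eaf_x = exposure$eaf, eaf_y = eaf_y,
                      action = action, palindromic = TRUE,
                      stringsAsFactors = FALSE))
  }

  if (ea_y == ea_x && oa_y == oa_x) {
    action <- "none"
  } else if (ea_y == oa_x && oa_y == ea_x) {
    flip_y(); action <- "swapped"
  } else if (identical(unname(BASE_COMPLEMENT[ea_y]), ea_x) &&
             identical(unname(BASE_COMPLEMENT[oa_y]), oa_x)) {
    action <- "strand_flipped"
  } else if (identical(unname(BASE_COMPLEMENT[ea_y]), oa_x) &&
             identical(unname(BASE_COMPLEMENT[oa_y]), ea_x)) {
    flip_y(); action <- "swapped_and_flipped"
  } else {
    return(drop("allele_mismatch"))
  }
  data.frame(variant_id = exposure$variant_id,
             effect_allele = ea_x, other_allele = oa_x,
             beta_x = exposure$beta, se_x = exposure$se,
             beta_y = beta_y, se_y = outcome$se,
             eaf_x = exposure$eaf, eaf_y = eaf_y,
             action = action, palindromic = FALSE,
             stringsAsFactors = FALSE)
}

#' Harmonize instrument records across the exposure and outcome tables
#'
#' Applies [harmonize_pair()] to every selected instrument. Instruments
#' absent from the outcome table are dropped with reason
#' `missing_in_outcome`. The retained pairs and the drop log together cover
#' the instrument set exactly.
#'
#' @param instruments An `instrument_set` or character vector of variant IDs.
#' @param exposure,outcome `sumstats_table`s.
#' @inheritParams harmonize_pair
#' @return A `harmonized_dataset`: list with `pairs` (data.frame of
#'   harmonized records) and `dropped` (variant_id/reason data.frame).
#' @export
harmonize_tables <- function(instruments, exposure, outcome,
                             intermediate_band = c(0.42, 0.58),
                             strict_palindromic = FALSE) {
  ids <- if (inherits(instruments, "instrument_set")) instruments$selected else instruments
  stopifnot(inherits(exposure, "sumstats_table"), inherits(outcome, "sumstats_table"))
  ex_idx <- match(ids, exposure$data$variant_id)
  if (anyNA(ex_idx))
    stop(sprintf("instrument(s) absent from exposure table: %s",
                 paste(ids[is.na(ex_idx)], collapse = ", ")), call. = FALSE)
  out_idx <- match(ids, outcome$data$variant_id)

  pairs <- list(); dropped <- list()
  for (k in seq_along(ids)) {
    if (is.na(out_idx[k])) {
      dropped[[length(dropped) + 1L]] <-
        list(variant_id = ids[k], reason = "missing_in_outcome")
      next
    }
    h <- harmonize_pair(exposure$data[ex_idx[k], ], outcome$data[out_idx[k], ],
                        intermediate_band, strict_palindromic)
    if (is.data.frame(h)) pairs[[length(pairs) + 1L]] <- h
    else dropped[[length(dropped) + 1L]] <- h
  }
  pairs_df <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(variant_id = character(), effect_allele = character(),
               other_allele = character(), beta_x = numeric(), se_x = numeric(),
               beta_y = numeric(), se_y = numeric(), eaf_x = numeric(),
               eaf_y = numeric(), action = character(), palindromic = logical(),
               stringsAsFactors = FALSE)
  dropped_df <- if (length(dropped) > 0)
    data.frame(variant_id = vapply(dropped, `[[`, character(1), "variant_id"),
               reason = vapply(dropped, `[[`, character(1), "reason"),
               stringsAsFactors = FALSE)
  else data.frame(variant_id = character(), reason = character(),
                  stringsAsFactors = FALSE)
  if (nrow(dropped_df) > 0)
    message(sprintf("harmonization dropped %d variant(s): %s", nrow(dropped_df),
                    paste(sprintf("%s (%s)", dropped_df$variant_id,
                                  dropped_df$reason), collapse = "; ")))
  if (nrow(pairs_df) == 0)
    stop("no harmonizable instruments", call. = FALSE)
  rownames(pairs_df) <- NULL
  structure(list(pairs = pairs_df, dropped = dropped_df),
            class = "harmonized_dataset")
}

#' @export
print.harmonized_dataset <- function(x, ...) {
  cat(sprintf("Harmonized dataset: %d pair(s), %d dropped\n",
              nrow(x$pairs), nrow(x$dropped)))
  print(table(x$pairs$action))
  invisible(x)
}
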