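# Harmonize, merge, filter and characterize somatic variant calls from
# multiple callers/pipelines, and compare callsets against a baseline
# (e.g. a prior consortium multi-caller callset).

.variant_key_cols <- c("sample_id", "chrom", "start", "ref_allele",
                       "alt_allele")

.variant_key <- function(df) {
  do.call(paste, c(df[.variant_key_cols], sep = "\r"))
}

#' Indel length of a MAF-normalized allele pair
#'
#' Absolute difference in allele lengths, with the MAF placeholder `"-"`
#' counting as length zero: substitutions return 0, a pure deletion returns
#' the deleted length, a pure insertion the inserted length.
#'
#' @param ref_allele,alt_allele Character vectors of MAF-normalized alleles
#'   (`"-"` for the absent side of a pure indel).
#' @return Integer vector of indel lengths in bp.
#' @examples
#' indel_length("A", "G")    # 0
#' indel_length("-", "ACGT") # 4
#' @export
indel_length <- function(ref_allele, alt_allele) {
  len <- function(a) ifelse(a == "-", 0L, nchar(a))
  abs(len(ref_allele) - len(alt_allele))
}

#' Merge variant calls from multiple callers
#'
#' Deduplicates calls across callers into one consensus record per distinct
#' `(sample_id, chrom, start, ref_allele, alt_allele)` key. The `callers`
#' field collects every contributing caller label; consensus read-support
#' metrics (`t_alt_count`, `t_depth`) and the classification are taken from
#' the highest-priority caller that reported the variant (priority defaults
#' to first-appearance order of the caller labels). `filter_pass_any` is TRUE
#' when at least one caller flagged the variant `PASS`. Contradictory
#' somatic/germline flags for the same key resolve to somatic with a warning;
#' the conflicting keys are recorded in `attr(, "conflicts")`.
#'
#' @param tables A list of MAF tables (see [read_maf()]), or a single table.
#' @param caller_priority Optional character vector giving the consensus
#'   priority order of caller labels; defaults to input order.
#' @param long_indel_min Minimum allele-length difference (bp) for a variant
#'   to be flagged as a long indel (default 40).
#' @return A `data.frame` of merged variants ordered by sample, chromosome,
#'   start, ref and alt allele, with columns `sample_id`, `chrom`, `start`,
#'   `ref_allele`, `alt_allele`, `callers` (`;`-separated), `n_callers`,
#'   `variant_classification`, `filter_pass_any`, `t_alt_count`, `t_depth`,
#'   `vaf`, `indel_length`, `is_long_indel`, `is_somatic`.
#' @export
merge_callers <- function(tables, caller_priority = NULL,
                          long_indel_min = 40L) {
  if (is.data.frame(tables)) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  for (tb in tables) validate_maf(tb)
  all <- do.call(rbind, tables)
  if (is.null(caller_priority)) caller_priority <- unique(all$caller)
  if (!all(all$caller %in% caller_priority)) {
    stop("caller_priority does not cover all caller labels", call. = FALSE)
  }
  dt <- data.table::as.data.table(all)
  dt[, `:=`(.pri = match(caller, caller_priority))]
  data.table::setorderv(dt, c(.variant_key_cols, ".pri"))
  sample_id <- chrom <- ref_allele <- alt_allele <- caller <- NULL
  filter_status <- t_alt_count <- t_depth <- is_somatic <- NULL
  variant_classification <- .pri <- NULL
  merged <- dt[, list(
    callers = paste(unique(caller), collapse = ";"),
    n_callers = length(unique(caller)),
    variant_classification = variant_classification[1L],
    filter_pass_any = any(filter_status == "PASS"),
    t_alt_count = t_alt_count[1L],
    t_depth = t_depth[1L],
    somatic_conflict = length(unique(is_somatic)) > 1L,
    is_somatic = any(is_somatic)
  ), by = c(.variant_key_cols)]
  conflicts <- merged[merged$somatic_conflict, .variant_key_cols,
                      with = FALSE]
  if (nrow(conflicts)) {
    warning(sprintf(
      "%d variant key(s) had contradictory somatic/germline flags; somatic wins",
      nrow(conflicts)), call. = FALSE)
  }
  merged[, `:=`(somatic_conflict = NULL)]
  out <- as.data.frame(merged)
  out$vaf <- out$t_alt_count / out$t_depth
  out$indel_length <- indel_length(out$ref_allele, out$alt_allele)
  out$is_long_indel <- out$indel_length >= long_indel_min
  data.table::setorderv(out, .variant_key_cols)
  rownames(out) <- NULL
  attr(out, "conflicts") <- as.data.frame(conflicts)
  out
}

#' Build a variant filter configuration
#'
#' Read-support filter settings for merged variants: minimum variant allele
#' frequency, minimum alternate read count, PASS requirement, and a
#' machine-readable exclusion list standing in for manual review of read
#' alignments (e.g. in IGV).
#'
#' @param min_vaf Minimum variant allele frequency retained (default 0.2).
#' @param min_alt_count Minimum alternate-allele read count (default 2).
#' @param pass_only Require a PASS filter flag from at least one caller
#'   (default TRUE).
#' @param exclusion_list Optional `data.frame` with columns `sample_id`,
#'   `chrom`, `start`, `ref_allele`, `alt_allele` of variants to drop.
#' @param long_indel_min Long-indel threshold in bp (default 40), carried for
#'   provenance.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_vaf = 0.2, min_alt_count = 2L,
                          pass_only = TRUE, exclusion_list = NULL,
                          long_indel_min = 40L) {
  stopifnot(min_vaf >= 0, min_vaf <= 1, min_alt_count >= 0)
  if (!is.null(exclusion_list)) {
    stopifnot(all(.variant_key_cols %in% names(exclusion_list)))
  }
  structure(list(min_vaf = min_vaf, min_alt_count = as.integer(min_alt_count),
                 pass_only = pass_only, exclusion_list = exclusion_list,
                 long_indel_min = as.integer(long_indel_min)),
            class = "filter_config")
}

#' Filter merged variants by read support
#'
#' Partitions merged variants into retained and rejected sets under a
#' [filter_config()]: retained variants pass the caller filter flag in at
#' least one caller (if `pass_only`), have `vaf >= min_vaf` and
#' `t_alt_count >= min_alt_count`, and are not on the exclusion list. Each
#' rejected variant carries its first failing reason (checked in the order
#' `not_pass`, `low_vaf`, `low_alt_count`, `excluded`).
#'
#' @param merged A merged variant table from [merge_callers()].
#' @param cfg A [filter_config()].
#' @return A list with elements `retained` (a merged-variant table) and
#'   `rejected` (the complement, with an extra `reason` column). The two
#'   partition the input.
#' @export
filter_variants <- function(merged, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  n <- nrow(merged)
  reason <- rep(NA_character_, n)
  if (n) {
    if (cfg$pass_only) {
      reason[is.na(reason) & !merged$filter_pass_any] <- "not_pass"
    }
    reason[is.na(reason) & merged$vaf < cfg$min_vaf] <- "low_vaf"
    reason[is.na(reason) & merged$t_alt_count < cfg$min_alt_count] <-
      "low_alt_count"
    if (!is.null(cfg$exclusion_list) && nrow(cfg$exclusion_list)) {
      excl <- .variant_key(cfg$exclusion_list)
      reason[is.na(reason) & .variant_key(merged) %in% excl] <- "excluded"
    }
  }
  keep <- is.na(reason)
  rejected <- merged[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  retained <- merged[keep, , drop = FALSE]
  rownames(retained) <- rownames(rejected) <- NULL
  list(retained = retained, rejected = rejected)
}

#' Summarize retained variants by classification
#'
#' Counts and fractions per variant classification token over the somatic
#' retained variants (germline records are excluded from the summary by
#' default, mirroring somatic-only reporting), plus a combined deleterious
#' class pooling nonsense and frameshift events
#' (`Nonsense_Mutation + Frame_Shift_Del + Frame_Shift_Ins`). Fractions over
#' the base classes sum to 1; the combined row is marked with
#' `is_combined = TRUE` and excluded from that sum.
#'
#' @param retained A merged-variant table (typically `filter_variants()$retained`).
#' @param somatic_only Drop germline records before summarizing (default TRUE).
#' @return A `data.frame` with columns `class`, `n`, `fraction`,
#'   `is_combined`; zero rows on empty input.
#' @export
classify_variant_summary <- function(retained, somatic_only = TRUE) {
  df <- retained
  if (somatic_only && nrow(df)) df <- df[df$is_somatic, , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(class = character(0), n = integer(0),
                      fraction = numeric(0), is_combined = logical(0)))
  }
  tab <- table(df$variant_classification)
  out <- data.frame(class = names(tab), n = as.integer(tab),
                    fraction = as.numeric(tab) / nrow(df),
                    is_combined = FALSE, stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$class), , drop = FALSE]
  combined_classes <- c("Nonsense_Mutation", "Frame_Shift_Del",
                        "Frame_Shift_Ins")
  n_comb <- sum(df$variant_classification %in% combined_classes)
  out <- rbind(out, data.frame(class = "Nonsense_or_Frameshift",
                               n = n_comb, fraction = n_comb / nrow(df),
                               is_combined = TRUE))
  rownames(out) <- NULL
  out
}

#' Assign protein-level domain annotations to variants
#'
#' Maps each variant's 1-based amino-acid position onto a priority-ordered
#' list of protein domains (e.g. UCH, HBM, BRCA1/BARD1 binding, NLS); the
#' first domain whose `[aa_start, aa_end]` interval contains the position
#' wins. Variants with missing positions are counted as unassigned and
#' flagged in the summary.
#'
#' @param variants A variant table (one row per variant).
#' @param domains A `data.frame` with columns `domain_name`, `aa_start`,
#'   `aa_end` (1-based inclusive), in priority order.
#' @param protein_pos Numeric vector of 1-based amino-acid positions aligned
#'   to `variants` rows; defaults to a `protein_position` column.
#' @return A list with `assignments` (character vector, `NA` when no domain
#'   contains the position) and `summary` (`n_total`, `n_assigned`,
#'   `fraction_in_domain`, `n_missing_position`).
#' @export
annotate_domains <- function(variants, domains,
                             protein_pos = variants$protein_position) {
  stopifnot(all(c("domain_name", "aa_start", "aa_end") %in% names(domains)),
            all(domains$aa_end >= domains$aa_start))
  if (is.null(protein_pos)) {
    stop("protein positions are required (protein_pos or a protein_position column)",
         call. = FALSE)
  }
  stopifnot(length(protein_pos) == nrow(variants))
  assignments <- rep(NA_character_, nrow(variants))
  for (i in seq_len(nrow(domains))) {
    hit <- is.na(assignments) & !is.na(protein_pos) &
      protein_pos >= domains$aa_start[i] & protein_pos <= domains$aa_end[i]
    assignments[hit] <- domains$domain_name[i]
  }
  n_total <- nrow(variants)
  n_assigned <- sum(!is.na(assignments))
  list(assignments = assignments,
       summary = list(n_total = n_total, n_assigned = n_assigned,
                      fraction_in_domain = if (n_total) n_assigned / n_total
                                           else NA_real_,
                      n_missing_position = sum(is.na(protein_pos))))
}

#' Compare two callsets
#'
#' Partitions a new callset against an old baseline into shared, gained (new
#' only) and lost (old only) variants. In `exact_key` mode variants match on
#' the full `(sample_id, chrom, start, ref_allele, alt_allele)` key. In
#' `window` mode variants match within a sample and chromosome when their
#' start positions differ by at most `window` bp (alleles are not compared;
#' intended for cross-genome-build near-matches); many-to-many candidates are
#' resolved greedily to the nearest position, ties to the lower coordinate,
#' and resolved pairs are recorded in `window_matches`.
#'
#' The percent increase is computed over somatic records only, exposing all
#' set sizes rather than a single canonical baseline.
#'
#' @param new,old Merged-variant tables ([merge_callers()]).
#' @param match_mode `"exact_key"` (default) or `"window"`.
#' @param window Position window in bp for `window` mode (default 10).
#' @return A list of class `callset_comparison` with `shared`, `gained`,
#'   `lost`, `n_new`, `n_old`, `n_new_somatic`, `n_old_somatic`,
#'   `percent_increase` (100 * (somatic new - somatic old) / somatic old) and,
#'   in window mode, `window_matches`.
#' @export
compare_callsets <- function(new, old,
                             match_mode = c("exact_key", "window"),
                             window = 10L) {
  match_mode <- match.arg(match_mode)
  n_new <- nrow(new); n_old <- nrow(old)
  window_matches <- NULL
  if (match_mode == "exact_key") {
    kn <- .variant_key(new); ko <- .variant_key(old)
    shared <- sum(kn %in% ko)
    gained <- n_new - shared
    lost <- n_old - sum(ko %in% kn)
  } else {
    matched_old <- rep(FALSE, n_old)
    matched_new <- rep(FALSE, n_new)
    pairs <- list()
    ord <- order(new$sample_id, new$chrom, new$start)
    for (i in ord) {
      cand <- which(!matched_old & old$sample_id == new$sample_id[i] &
                      old$chrom == new$chrom[i] &
                      abs(old$start - new$start[i]) <= window)
      if (length(cand)) {
        d <- abs(old$start[cand] - new$start[i])
        best <- cand[order(d, old$start[cand])][1L]
        matched_old[best] <- TRUE
        matched_new[i] <- TRUE
        pairs[[length(pairs) + 1L]] <-
          data.frame(new_row = i, old_row = best,
                     distance = abs(old$start[best] - new$start[i]))
      }
    }
    shared <- sum(matched_new)
    gained <- n_new - shared
    lost <- n_old - sum(matched_old)
    window_matches <- if (length(pairs)) do.call(rbind, pairs) else
      data.frame(new_row = integer(0), old_row = integer(0),
                 distance = integer(0))
  }
  n_new_somatic <- if (n_new) sum(new$is_somatic) else 0L
  n_old_somatic <- if (n_old) sum(old$is_somatic) else 0L
  structure(list(
    shared = shared, gained = gained, lost = lost,
    n_new = n_new, n_old = n_old,
    n_new_somatic = n_new_somatic, n_old_somatic = n_old_somatic,
    percent_increase = if (n_old_somatic > 0)
      100 * (n_new_somatic - n_old_somatic) / n_old_somatic else NA_real_,
    match_mode = match_mode, window_matches = window_matches
  ), class = "callset_comparison")
}

#' @export
print.callset_comparison <- function(x, ...) {
  cat(sprintf("Callset comparison (%s): shared %d, gained %d, lost %d\n",
              x$match_mode, x$shared, x$gained, x$lost))
  cat(sprintf("  new: %d (%d somatic); old: %d (%d somatic); somatic increase %.1f%%\n",
              x$n_new, x$n_new_somatic, x$n_old, x$n_old_somatic,
              x$percent_increase))
  invisible(x)
}
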