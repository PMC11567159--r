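# Gene-level copy-number loss calls, loss-segment width summaries, and
# per-sample alteration categories combining mutation and CN status.

#' Call gene-level copy-number loss
#'
#' A sample has loss when its integer gene-level copy number is below the
#' threshold (default 2, i.e. any deviation below diploid). Loss depth is
#' `"single"` for copy number 1 and `"deep"` for 0.
#'
#' @param cn A gene-level copy-number table ([read_gene_cn()]).
#' @param gene Gene symbol to call loss for; must be present in `cn`.
#' @param threshold Copy numbers strictly below this are loss (default 2).
#' @return A `data.frame` with one row per sample carrying the gene: columns
#'   `sample_id`, `copy_number`, `loss` (logical), `loss_depth`
#'   (`"single"`, `"deep"`, or `NA` for non-loss / loss at higher thresholds).
#' @export
call_cn_loss <- function(cn, gene, threshold = 2L) {
  sub <- cn[cn$gene_symbol == gene, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("gene '%s' not present in copy-number table", gene),
         call. = FALSE)
  }
  out <- data.frame(sample_id = sub$sample_id,
                    copy_number = sub$copy_number,
                    loss = sub$copy_number < threshold,
                    stringsAsFactors = FALSE)
  out$loss_depth <- ifelse(!out$loss, NA_character_,
                           ifelse(out$copy_number == 0L, "deep",
                                  ifelse(out$copy_number == 1L, "single",
                                         NA_character_)))
  rownames(out) <- NULL
  out
}

#' Summarize copy-number loss segment widths around a gene locus
#'
#' For each loss sample, finds the copy-number segment overlapping the gene
#' locus (any shared bp; if several overlap, the one with maximal overlap,
#' ties to the wider segment) and takes its width
#' `seg_end - seg_start + 1`. Widths are summarized per cohort as median and
#' interquartile range using type-7 (linear-interpolation) quantiles. Loss
#' samples with no overlapping segment are excluded from the summary and
#' counted in a `no_segment` tally.
#'
#' @param segs A segment table ([read_seg()]).
#' @param gene_locus List or vector with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param loss_samples Character vector of sample ids with copy-number loss.
#' @param cohorts Optional named character vector mapping sample id to a
#'   cohort label; unmapped samples fall into `"all"`.
#' @return A list with `summary` (a `data.frame` with `cohort`, `n`,
#'   `median_bp`, `q1_bp`, `q3_bp`), `widths` (per-sample `data.frame`
#'   with `sample_id`, `cohort`, `width_bp`), and `no_segment` (tally of loss
#'   samples without an overlapping segment).
#' @export
loss_segment_widths <- function(segs, gene_locus, loss_samples,
                                cohorts = NULL) {
  locus_chrom <- as.character(gene_locus[["chrom"]])
  locus_start <- as.numeric(gene_locus[["start"]])
  locus_end <- as.numeric(gene_locus[["end"]])
  stopifnot(locus_end >= locus_start)
  widths <- data.frame(sample_id = character(0), cohort = character(0),
                       width_bp = numeric(0), stringsAsFactors = FALSE)
  no_segment <- 0L
  for (s in unique(loss_samples)) {
    ss <- segs[segs$sample_id == s & segs$chrom == locus_chrom, ,
               drop = FALSE]
    ov <- pmin(ss$seg_end, locus_end) - pmax(ss$seg_start, locus_start) + 1
    hit <- which(ov > 0)
    if (length(hit) == 0L) {
      no_segment <- no_segment + 1L
      next
    }
    w <- ss$seg_end[hit] - ss$seg_start[hit] + 1
    best <- hit[order(-ov[hit], -w)][1L]
    cohort <- if (!is.null(cohorts) && s %in% names(cohorts)) cohorts[[s]]
              else "all"
    widths <- rbind(widths, data.frame(
      sample_id = s, cohort = cohort,
      width_bp = ss$seg_end[best] - ss$seg_start[best] + 1,
      stringsAsFactors = FALSE))
  }
  if (nrow(widths)) {
    summary <- do.call(rbind, lapply(split(widths, widths$cohort), function(d) {
      q <- stats::quantile(d$width_bp, probs = c(0.25, 0.5, 0.75), type = 7,
                           names = FALSE)
      data.frame(cohort = d$cohort[1L], n = nrow(d), median_bp = q[2L],
                 q1_bp = q[1L], q3_bp = q[3L], stringsAsFactors = FALSE)
    }))
    rownames(summary) <- NULL
  } else {
    summary <- data.frame(cohort = character(0), n = integer(0),
                          median_bp = numeric(0), q1_bp = numeric(0),
                          q3_bp = numeric(0))
  }
  list(summary = summary, widths = widths, no_segment = no_segment)
}

#' Parse a "chrom:start-end" locus string
#'
#' @param locus A string such as `"chr3:52300003-52511030"` (1-based
#'   inclusive).
#' @return A list with `chrom`, `start`, `end`.
#' @export
parse_locus <- function(locus) {
  m <- regmatches(locus, regexec("^([^:]+):([0-9]+)-([0-9]+)$", locus))[[1L]]
  if (length(m) != 4L) {
    stop("locus must be of the form chrom:start-end, got: ", locus,
         call. = FALSE)
  }
  out <- list(chrom = m[2L], start = as.numeric(m[3L]), end = as.numeric(m[4L]))
  if (out$end < out$start) stop("locus end < start", call. = FALSE)
  out
}

#' Assign per-sample alteration categories
#'
#' Combines mutation status and gene-level copy-number loss into the four
#' disjoint categories `MutPlusCN` (both), `MutOnly`, `CNOnly` and
#' `Unaltered`. Category counts always conserve the sample universe.
#'
#' @param mut_samples Character vector of samples with a retained mutation.
#' @param cn_loss_samples Character vector of samples with copy-number loss.
#' @param all_samples Character vector of the full sample universe; both
#'   other sets must be subsets of it.
#' @return A list with `calls` (a `data.frame` of `sample_id`, `category`)
#'   and `summary` (per-category `n` and `percent` of all samples, plus
#'   `n_altered` and `percent_cn_involved` = share of altered samples whose
#'   alteration involves copy-number loss).
#' @export
assign_alteration_categories <- function(mut_samples, cn_loss_samples,
                                         all_samples) {
  mut_samples <- unique(mut_samples)
  cn_loss_samples <- unique(cn_loss_samples)
  all_samples <- unique(all_samples)
  extra <- setdiff(union(mut_samples, cn_loss_samples), all_samples)
  if (length(extra)) {
    stop("sample(s) in mutation/CN sets but not in sample universe: ",
         paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  category <- rep("Unaltered", length(all_samples))
  names(category) <- all_samples
  category[intersect(mut_samples, cn_loss_samples)] <- "MutPlusCN"
  category[setdiff(mut_samples, cn_loss_samples)] <- "MutOnly"
  category[setdiff(cn_loss_samples, mut_samples)] <- "CNOnly"
  calls <- data.frame(sample_id = all_samples,
                      category = unname(category[all_samples]),
                      stringsAsFactors = FALSE)
  levels <- c("Unaltered", "MutOnly", "CNOnly", "MutPlusCN")
  n <- vapply(levels, function(l) sum(calls$category == l), integer(1))
  n_altered <- sum(n[c("MutOnly", "CNOnly", "MutPlusCN")])
  n_cn_involved <- sum(n[c("CNOnly", "MutPlusCN")])
  summary <- data.frame(
    category = levels, n = as.integer(n),
    percent = 100 * as.numeric(n) / length(all_samples),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(calls = calls,
       summary = summary,
       n_altered = n_altered,
       percent_cn_involved = if (n_altered > 0)
         100 * n_cn_involved / n_altered else NA_real_)
}
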