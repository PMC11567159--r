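# One-shot pipeline driver: merge -> filter -> copy-number integration ->
# (internal or external) differential expression -> signature -> scores ->
# mixture classification, with a manifest recording inputs, parameters and
# per-stage row counts for exact reruns.

# small polynomial rolling hash (mod 2^31 - 1); enough to fingerprint a
# parameter set in the manifest
.hash_string <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Build and validate a pipeline configuration
#'
#' Collects every path and parameter of the end-to-end run. All referenced
#' input paths must exist at validation time.
#'
#' @param maf_paths Named character vector of MAF paths; names are caller
#'   labels.
#' @param gene_cn_path,seg_path,counts_path Input tables (see [read_gene_cn()],
#'   [read_seg()], [read_counts()]).
#' @param out_dir Output directory (created if needed).
#' @param gene Target gene symbol (default `"BAP1"`).
#' @param locus Locus string `chrom:start-end` (default the BAP1 hg38 locus).
#' @param exclusion_path Optional exclusion-list TSV (columns `sample_id`,
#'   `chrom`, `start`, `ref_allele`, `alt_allele`).
#' @param de_path Optional externally produced DE table (TSV with `gene`,
#'   `log2fc`, `p`, `padj`); when absent, [simple_de()] is used.
#' @param min_vaf,min_alt_count,pass_only,long_indel_min Variant filter
#'   settings (see [filter_config()]).
#' @param cn_threshold Copy-number loss threshold (default 2).
#' @param padj_max,min_abs_lfc Signature thresholds (see [build_signature()]).
#' @param score_method `"weighted"` or `"rank"`.
#' @param aggregate `"sum"` or `"mean"` for the weighted score.
#' @param seed Classifier seed (default 17).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(maf_paths, gene_cn_path, seg_path, counts_path,
                            out_dir, gene = "BAP1",
                            locus = "chr3:52300003-52511030",
                            exclusion_path = NULL, de_path = NULL,
                            min_vaf = 0.2, min_alt_count = 2L,
                            pass_only = TRUE, long_indel_min = 40L,
                            cn_threshold = 2L, padj_max = 0.05,
                            min_abs_lfc = 0,
                            score_method = c("weighted", "rank"),
                            aggregate = c("sum", "mean"), seed = 17L) {
  score_method <- match.arg(score_method)
  aggregate <- match.arg(aggregate)
  if (is.null(names(maf_paths)) || any(!nzchar(names(maf_paths)))) {
    stop("maf_paths must be named by caller label", call. = FALSE)
  }
  paths <- c(maf_paths, gene_cn_path, seg_path, counts_path,
             exclusion_path, de_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input path(s) do not exist: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  parse_locus(locus)  # validates the format
  structure(list(
    maf_paths = maf_paths, gene_cn_path = gene_cn_path, seg_path = seg_path,
    counts_path = counts_path, out_dir = out_dir, gene = gene,
    locus = locus, exclusion_path = exclusion_path, de_path = de_path,
    min_vaf = min_vaf, min_alt_count = as.integer(min_alt_count),
    pass_only = pass_only, long_indel_min = as.integer(long_indel_min),
    cn_threshold = as.integer(cn_threshold), padj_max = padj_max,
    min_abs_lfc = min_abs_lfc, score_method = score_method,
    aggregate = aggregate, seed = as.integer(seed)), class = "pipeline_config")
}

#' Run the full alteration-and-scoring pipeline
#'
#' Executes merge -> filter -> copy-number loss -> alteration categories ->
#' differential expression (internal substitute or external table) ->
#' signature -> activity scores -> mixture classification, writing each
#' stage's table under `config$out_dir` and a `manifest.json` capturing
#' inputs, a parameter hash and per-stage row counts. Any stage error aborts
#' with the stage name while preserving completed outputs.
#'
#' Differential expression compares samples carrying a retained mutation
#' (mutation with or without copy-number loss) against unaltered samples,
#' restricted to samples present in the counts matrix.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-stage results (`merged`,
#'   `retained`, `alterations`, `de`, `signature`, `scores`, `fit`,
#'   `classes`) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts_per_stage <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  mafs <- stage("read_maf", lapply(seq_along(config$maf_paths), function(i) {
    read_maf(config$maf_paths[[i]], names(config$maf_paths)[i])
  }))
  merged <- stage("merge", merge_callers(mafs,
                                         long_indel_min = config$long_indel_min))
  counts_per_stage$variants_merged <- nrow(merged)
  write_merged <- merged
  data.table::fwrite(write_merged, file.path(config$out_dir, "merged.tsv"),
                     sep = "\t", quote = FALSE)

  excl <- NULL
  if (!is.null(config$exclusion_path)) {
    excl <- stage("read_exclusions",
                  data.table::fread(config$exclusion_path, sep = "\t",
                                    data.table = FALSE))
  }
  cfg <- filter_config(min_vaf = config$min_vaf,
                       min_alt_count = config$min_alt_count,
                       pass_only = config$pass_only, exclusion_list = excl,
                       long_indel_min = config$long_indel_min)
  flt <- stage("filter", filter_variants(merged, cfg))
  counts_per_stage$variants_retained <- nrow(flt$retained)
  counts_per_stage$variants_rejected <- nrow(flt$rejected)
  data.table::fwrite(flt$retained, file.path(config$out_dir, "retained.tsv"),
                     sep = "\t", quote = FALSE)

  cn <- stage("read_gene_cn", read_gene_cn(config$gene_cn_path))
  loss <- stage("cn_loss", call_cn_loss(cn, config$gene,
                                        threshold = config$cn_threshold))
  segs <- stage("read_seg", read_seg(config$seg_path))
  widths <- stage("segment_widths",
                  loss_segment_widths(segs, parse_locus(config$locus),
                                      loss$sample_id[loss$loss]))
  all_samples <- unique(cn$sample_id)
  mut_samples <- intersect(unique(flt$retained$sample_id[
    flt$retained$is_somatic]), all_samples)
  alt <- stage("alteration_categories",
               assign_alteration_categories(
                 mut_samples, loss$sample_id[loss$loss], all_samples))
  counts_per_stage$samples_per_category <-
    stats::setNames(as.list(alt$summary$n), alt$summary$category)
  data.table::fwrite(alt$calls, file.path(config$out_dir, "alterations.tsv"),
                     sep = "\t", quote = FALSE)

  counts <- stage("read_counts", read_counts(config$counts_path))
  if (is.null(config$de_path)) {
    expr_samples <- colnames(counts)
    cats <- stats::setNames(alt$calls$category, alt$calls$sample_id)
    group <- rep(NA_character_, length(expr_samples))
    group[cats[expr_samples] %in% c("MutOnly", "MutPlusCN")] <- "mutant"
    group[cats[expr_samples] == "Unaltered"] <- "unaltered"
    use <- !is.na(group)
    de <- stage("simple_de", simple_de(counts[, use, drop = FALSE],
                                       group[use]))
  } else {
    de <- stage("read_de", {
      d <- data.table::fread(config$de_path, sep = "\t", data.table = FALSE)
      stopifnot(all(c("gene", "log2fc", "padj") %in% names(d)))
      d
    })
  }
  data.table::fwrite(de, file.path(config$out_dir, "de.tsv"), sep = "\t",
                     quote = FALSE)

  sig <- stage("signature", build_signature(de, padj_max = config$padj_max,
                                            min_abs_lfc = config$min_abs_lfc))
  counts_per_stage$signature_genes <- nrow(sig)
  write_signature(sig, file.path(config$out_dir, "signature.tsv"))

  norm <- stage("normalize", normalize_counts(counts))
  scores <- stage("score", if (config$score_method == "weighted") {
    weighted_score(norm, sig, aggregate = config$aggregate)
  } else {
    rank_score(norm, sig)
  })
  data.table::fwrite(scores, file.path(config$out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE)

  fit <- stage("mixture_fit", fit_score_mixture(scores, seed = config$seed))
  write_mixture_fit(fit, file.path(config$out_dir, "fit.json"))
  cls <- stage("classify", classify_scores(scores, fit))
  counts_per_stage$samples_classified <- nrow(cls$classes)
  counts_per_stage$fraction_mutant_like <- cls$summary$fraction_mutant_like
  data.table::fwrite(cls$classes, file.path(config$out_dir, "classes.tsv"),
                     sep = "\t", quote = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("bap1tools")),
    parameters = unclass(config),
    parameter_hash = .hash_string(paste(deparse(unclass(config)),
                                        collapse = "")),
    stage_counts = counts_per_stage,
    segment_width_summary = widths$summary)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(merged = merged, retained = flt$retained,
                 rejected = flt$rejected, alterations = alt, widths = widths,
                 de = de, signature = sig, scores = scores, fit = fit,
                 classes = cls$classes, manifest = manifest))
}
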