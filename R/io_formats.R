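# Readers and writers for the on-disk formats the pipeline consumes:
# MAF-style variant tables, SEG copy-number segments, gene-level integer
# copy-number tables, counts matrices (TSV) and GMT gene sets. All readers
# validate their invariants and report located errors; write/read round-trips
# are exact on valid tables.

# Canonical column names and their accepted header variants (case-insensitive).
# The alias table covers GDC- and MC3-style MAF headers as well as the plain
# snake_case names this package writes.
.maf_aliases <- list(
  sample_id              = c("tumor_sample_barcode", "sample", "sample_id"),
  chrom                  = c("chromosome", "chrom", "chr"),
  start                  = c("start_position", "start", "pos", "position"),
  ref_allele             = c("reference_allele", "ref", "ref_allele"),
  alt_allele             = c("tumor_seq_allele2", "alt", "alt_allele",
                             "tumor_seq_allele_2"),
  variant_classification = c("variant_classification", "classification"),
  filter_status          = c("filter", "filter_status"),
  t_alt_count            = c("t_alt_count", "tumor_alt_count"),
  t_depth                = c("t_depth", "tumor_depth"),
  mutation_status        = c("mutation_status", "somatic_status")
)

.seg_aliases <- list(
  sample_id = c("id", "sample", "sample_id"),
  chrom     = c("chrom", "chromosome", "chr"),
  seg_start = c("loc.start", "start", "seg_start"),
  seg_end   = c("loc.end", "end", "seg_end"),
  seg_mean  = c("seg.mean", "seg_mean", "segment_mean")
)

.gene_cn_aliases <- list(
  sample_id   = c("sample_id", "sample", "tumor_sample_barcode"),
  gene_symbol = c("gene_symbol", "gene", "gene symbol", "hugo_symbol"),
  copy_number = c("copy_number", "cn", "value", "copy number")
)

# Map canonical names onto the columns present in `nms`; error (naming the
# missing canonical column) unless it is listed in `optional`.
.resolve_columns <- function(nms, aliases, optional = character(0),
                             context = "table") {
  lower <- tolower(nms)
  out <- list()
  for (canon in names(aliases)) {
    hit <- which(lower %in% aliases[[canon]])
    if (length(hit) == 0L) {
      if (canon %in% optional) next
      stop(sprintf("%s is missing required column '%s'", context, canon),
           call. = FALSE)
    }
    out[[canon]] <- nms[hit[1L]]
  }
  out
}

.read_table <- function(path, context) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("%s file not found: %s", context, path), call. = FALSE)
  }
  # tolerate leading '#'-comment lines (e.g. "#version 2.4" in MAF files)
  head_lines <- readLines(path, n = 100L)
  skip <- which(!startsWith(head_lines, "#"))[1L]
  if (is.na(skip)) stop(sprintf("%s has no header line: %s", context, path),
                        call. = FALSE)
  data.table::fread(path, sep = "\t", header = TRUE, skip = skip - 1L,
                    data.table = FALSE, colClasses = "character",
                    na.strings = NULL)
}

.as_int <- function(x, col, context) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) | v != round(v))
  if (length(bad)) {
    stop(sprintf("%s: column '%s' is not integer at row(s) %s", context, col,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  as.integer(round(v))
}

.row_errors <- function(bad, msg, context) {
  if (length(bad)) {
    stop(sprintf("%s: %s at row(s) %s", context, msg,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(NULL)
}

#' Read a MAF-style variant table
#'
#' Reads a tab-delimited mutation annotation format (MAF) table for a single
#' caller or pipeline and returns it in the package's canonical column layout.
#' Required columns are resolved case-insensitively through an alias table
#' covering GDC/MC3 header variants (e.g. `Tumor_Sample_Barcode` vs `sample`).
#' Coordinates are 1-based inclusive; a pure insertion carries `ref_allele`
#' `"-"` and a pure deletion carries `alt_allele` `"-"`.
#'
#' Rows violating the MAF invariants (`t_alt_count <= t_depth`, `start >= 1`,
#' `ref_allele != alt_allele`, non-empty chromosome) are rejected with a
#' row-indexed error. A `Mutation_Status`-like column, when present, sets
#' `is_somatic` (`FALSE` only for `Germline`); otherwise all rows are assumed
#' somatic.
#'
#' @param path Path to a tab-delimited MAF file with a header row. Leading
#'   `#` comment lines are skipped.
#' @param caller_label Character scalar recorded in the `caller` column of
#'   every row, identifying the caller/pipeline the file came from.
#' @return A `data.frame` with columns `sample_id`, `caller`, `chrom`,
#'   `start`, `ref_allele`, `alt_allele`, `variant_classification`,
#'   `filter_status`, `t_alt_count`, `t_depth`, `is_somatic`.
#' @seealso [write_maf()], [merge_callers()]
#' @export
read_maf <- function(path, caller_label) {
  stopifnot(is.character(caller_label), length(caller_label) == 1L,
            nzchar(caller_label))
  context <- sprintf("MAF '%s'", path)
  raw <- .read_table(path, context)
  cols <- .resolve_columns(names(raw), .maf_aliases,
                           optional = "mutation_status", context = context)
  df <- data.frame(
    sample_id              = raw[[cols$sample_id]],
    caller                 = caller_label,
    chrom                  = raw[[cols$chrom]],
    start                  = .as_int(raw[[cols$start]], "start", context),
    ref_allele             = raw[[cols$ref_allele]],
    alt_allele             = raw[[cols$alt_allele]],
    variant_classification = raw[[cols$variant_classification]],
    filter_status          = raw[[cols$filter_status]],
    t_alt_count            = .as_int(raw[[cols$t_alt_count]], "t_alt_count",
                                     context),
    t_depth                = .as_int(raw[[cols$t_depth]], "t_depth", context),
    stringsAsFactors = FALSE
  )
  df$is_somatic <- if (!is.null(cols$mutation_status)) {
    tolower(raw[[cols$mutation_status]]) != "germline"
  } else TRUE
  validate_maf(df, context = context)
  df
}

#' Validate a MAF table's invariants
#'
#' Checks the canonical MAF invariants and throws a row-indexed error on the
#' first violated class: alt read count bounded by depth, positive 1-based
#' start, differing alleles, non-empty chromosome, non-negative counts.
#'
#' @param maf A data.frame in the layout produced by [read_maf()].
#' @param context Label used in error messages.
#' @return The validated table, invisibly.
#' @export
validate_maf <- function(maf, context = "MAF table") {
  need <- c("sample_id", "chrom", "start", "ref_allele", "alt_allele",
            "variant_classification", "filter_status", "t_alt_count",
            "t_depth")
  miss <- setdiff(need, names(maf))
  if (length(miss)) {
    stop(sprintf("%s is missing required column '%s'", context, miss[1L]),
         call. = FALSE)
  }
  .row_errors(which(maf$t_alt_count > maf$t_depth),
              "t_alt_count exceeds t_depth", context)
  .row_errors(which(maf$t_alt_count < 0L), "negative t_alt_count", context)
  .row_errors(which(maf$t_depth <= 0L), "non-positive t_depth", context)
  .row_errors(which(maf$start < 1L), "start < 1", context)
  .row_errors(which(maf$ref_allele == maf$alt_allele),
              "ref_allele equals alt_allele", context)
  .row_errors(which(!nzchar(maf$chrom)), "empty chromosome", context)
  invisible(maf)
}

#' Write a MAF table
#'
#' Writes a canonical MAF table back to disk using standard MAF header names
#' (`Tumor_Sample_Barcode`, `Chromosome`, ...). `is_somatic` is serialized as
#' a `Mutation_Status` column (`Somatic`/`Germline`) so that
#' `read_maf(write_maf(x))` is an exact round trip. The per-row `caller`
#' column is provenance of the reading step and is not written.
#'
#' @param maf A table in the layout produced by [read_maf()].
#' @param path Output path; tab-delimited UTF-8 with header.
#' @return `path`, invisibly.
#' @export
write_maf <- function(maf, path) {
  out <- data.frame(
    Tumor_Sample_Barcode   = maf$sample_id,
    Chromosome             = maf$chrom,
    Start_Position         = maf$start,
    Reference_Allele       = maf$ref_allele,
    Tumor_Seq_Allele2      = maf$alt_allele,
    Variant_Classification = maf$variant_classification,
    FILTER                 = maf$filter_status,
    t_alt_count            = maf$t_alt_count,
    t_depth                = maf$t_depth,
    Mutation_Status        = ifelse(maf$is_somatic, "Somatic", "Germline"),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a SEG copy-number segment file
#'
#' Parses the tab-delimited SEG dialect (`ID`, `chrom`, `loc.start`,
#' `loc.end`, `seg.mean`; `num.mark` tolerated and ignored) into the
#' canonical segment layout. Coordinates are 1-based inclusive and each
#' segment must satisfy `seg_end >= seg_start`.
#'
#' @param path Path to a SEG file.
#' @return A `data.frame` with columns `sample_id`, `chrom`, `seg_start`,
#'   `seg_end`, `seg_mean`.
#' @export
read_seg <- function(path) {
  context <- sprintf("SEG '%s'", path)
  raw <- .read_table(path, context)
  cols <- .resolve_columns(names(raw), .seg_aliases, context = context)
  df <- data.frame(
    sample_id = raw[[cols$sample_id]],
    chrom     = raw[[cols$chrom]],
    seg_start = .as_int(raw[[cols$seg_start]], "seg_start", context),
    seg_end   = .as_int(raw[[cols$seg_end]], "seg_end", context),
    seg_mean  = as.numeric(raw[[cols$seg_mean]]),
    stringsAsFactors = FALSE
  )
  .row_errors(which(df$seg_end < df$seg_start), "seg_end < seg_start", context)
  .row_errors(which(df$seg_start < 1L), "seg_start < 1", context)
  .row_errors(which(is.na(df$seg_mean)), "non-numeric seg.mean", context)
  df
}

#' Write a SEG segment table
#' @param seg A table in the layout produced by [read_seg()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(seg, path) {
  out <- data.frame(ID = seg$sample_id, chrom = seg$chrom,
                    loc.start = seg$seg_start, loc.end = seg$seg_end,
                    seg.mean = seg$seg_mean, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a gene-level integer copy-number table
#'
#' @param path Path to a tab-delimited table with sample, gene symbol and
#'   non-negative integer copy-number columns (header variants such as
#'   `Hugo_Symbol`/`gene` are accepted).
#' @return A `data.frame` with columns `sample_id`, `gene_symbol`,
#'   `copy_number`.
#' @export
read_gene_cn <- function(path) {
  context <- sprintf("gene CN '%s'", path)
  raw <- .read_table(path, context)
  cols <- .resolve_columns(names(raw), .gene_cn_aliases, context = context)
  df <- data.frame(
    sample_id   = raw[[cols$sample_id]],
    gene_symbol = raw[[cols$gene_symbol]],
    copy_number = .as_int(raw[[cols$copy_number]], "copy_number", context),
    stringsAsFactors = FALSE
  )
  .row_errors(which(df$copy_number < 0L), "negative copy_number", context)
  df
}

#' Write a gene-level copy-number table
#' @param cn A table in the layout produced by [read_gene_cn()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_cn <- function(cn, path) {
  data.table::fwrite(cn[, c("sample_id", "gene_symbol", "copy_number")],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a genes-by-samples counts matrix from TSV
#'
#' The first column holds unique gene identifiers; the remaining columns are
#' unique sample identifiers with non-negative integer counts.
#'
#' @param path Path to the tab-delimited counts file.
#' @return An integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  context <- sprintf("counts '%s'", path)
  raw <- .read_table(path, context)
  if (ncol(raw) < 2L) stop(sprintf("%s has no sample columns", context),
                           call. = FALSE)
  genes <- raw[[1L]]
  if (anyDuplicated(genes)) {
    stop(sprintf("%s: duplicated gene identifiers", context), call. = FALSE)
  }
  samples <- names(raw)[-1L]
  if (anyDuplicated(samples)) {
    stop(sprintf("%s: duplicated sample identifiers", context), call. = FALSE)
  }
  mat <- vapply(raw[-1L], function(col) .as_int(col, "counts", context),
                integer(nrow(raw)))
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, samples))
  if (any(mat < 0L)) {
    bad <- which(rowSums(mat < 0L) > 0L)
    stop(sprintf("%s: negative count at gene(s) %s", context,
                 paste(utils::head(genes[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  mat
}

#' Write a counts matrix to TSV
#' @param counts Integer matrix with gene rownames and sample colnames.
#' @param path Output path; first column is named `gene_id`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  out <- data.table::data.table(gene_id = rownames(counts))
  for (s in colnames(counts)) out[[s]] <- counts[, s]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One gene set per line: name, description, then one gene symbol per field.
#' Sets must be non-empty and contain no duplicate genes.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (one per gene set), with the
#'   per-set descriptions in `attr(, "descriptions")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT '%s': malformed line %d (need name, description and >= 1 gene)",
                   path, i), call. = FALSE)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      stop(sprintf("GMT '%s': empty gene set at line %d", path, i),
           call. = FALSE)
    }
    if (anyDuplicated(genes)) {
      stop(sprintf("GMT '%s': duplicate genes in set '%s' at line %d",
                   path, fields[1L], i), call. = FALSE)
    }
    sets[[fields[1L]]] <- genes
    descs[fields[1L]] <- fields[2L]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors; descriptions are taken from
#'   `attr(sets, "descriptions")` (default `"na"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descs) && !is.na(descs[nm])) descs[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
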