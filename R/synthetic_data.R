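# Synthetic-data generators emitting every input type with known ground
# truth: negative-binomial expression cohorts with a planted mutant
# signature, multi-caller variant tables with shared/unique calls and long
# indels, gene-level copy number with loss segments, and a differentiation
# time course whose signature strength varies monotonically with latent time.
# Every generator is a pure function of its parameters and seed.

.nb_counts <- function(log2_mu, dispersion) {
  # NB parameterized by mean and dispersion alpha: var = mu + alpha * mu^2
  mu <- 2^log2_mu
  matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
         nrow = nrow(log2_mu), dimnames = dimnames(log2_mu))
}

#' Simulate an expression cohort with a planted mutant signature
#'
#' Genes-by-samples negative-binomial counts (variance `mu + alpha mu^2`)
#' with log-normal gene baselines. A random subset of samples is "mutant";
#' in those samples, the planted up-genes are shifted `+effect_log2` and the
#' down-genes `-effect_log2` on the log2-mean scale. Defaults emulate a
#' moderately sized tumor cohort with a minority of mutant samples and a
#' 100-gene signature of 1 log2-unit effects.
#'
#' @param n_samples Number of samples (default 200).
#' @param frac_mutant Fraction of mutant samples, strictly in (0, 1)
#'   (default 0.15).
#' @param n_genes Number of genes (default 2000).
#' @param n_signature_genes Number of planted signature genes, half up and
#'   half down (default 100); at most `n_genes`.
#' @param effect_log2 Planted absolute effect on the log2-mean scale
#'   (default 1.0).
#' @param dispersion NB dispersion alpha (default 0.1).
#' @param seed Integer seed; regeneration with the same seed is
#'   bit-identical.
#' @return A list with `counts` (integer matrix) and `truth` (sample ids,
#'   `true_status` in mutant/wildtype, the planted `signature` data.frame
#'   with `gene`, `direction`, `weight`, `effect_log2`, plus `dispersion`,
#'   `baseline_log2_mean`, `seed`).
#' @export
gen_expression_cohort <- function(n_samples = 200L, frac_mutant = 0.15,
                                  n_genes = 2000L, n_signature_genes = 100L,
                                  effect_log2 = 1.0, dispersion = 0.1,
                                  seed = 1L) {
  if (frac_mutant <= 0 || frac_mutant >= 1) {
    stop("frac_mutant must be strictly between 0 and 1", call. = FALSE)
  }
  stopifnot(n_signature_genes <= n_genes, n_signature_genes >= 2L)
  withr::with_seed(seed, {
    samples <- sprintf("S%04d", seq_len(n_samples))
    genes <- sprintf("G%05d", seq_len(n_genes))
    n_mut <- max(1L, round(n_samples * frac_mutant))
    status <- rep("wildtype", n_samples)
    status[sample.int(n_samples, n_mut)] <- "mutant"
    baseline <- stats::rnorm(n_genes, mean = 5, sd = 2)  # log2 scale
    sig_idx <- sample.int(n_genes, n_signature_genes)
    n_up <- floor(n_signature_genes / 2)
    up_idx <- sig_idx[seq_len(n_up)]
    down_idx <- sig_idx[-seq_len(n_up)]
    log2_mu <- matrix(baseline, nrow = n_genes, ncol = n_samples,
                      dimnames = list(genes, samples))
    mut <- status == "mutant"
    log2_mu[up_idx, mut] <- log2_mu[up_idx, mut] + effect_log2
    log2_mu[down_idx, mut] <- log2_mu[down_idx, mut] - effect_log2
    counts <- .nb_counts(log2_mu, dispersion)
    signature <- data.frame(
      gene = genes[c(up_idx, down_idx)],
      direction = rep(c("up", "down"), c(length(up_idx), length(down_idx))),
      stringsAsFactors = FALSE)
    signature$weight <- ifelse(signature$direction == "up", -1, 1)
    signature$effect_log2 <- effect_log2
    list(counts = counts,
         truth = list(sample_id = samples, true_status = status,
                      signature = signature, dispersion = dispersion,
                      baseline_log2_mean = baseline, seed = seed))
  })
}

#' Simulate ground-truth somatic variants for one locus
#'
#' True variant records for a caller simulation: VAFs drawn Beta(8, 8)
#' (centered near 0.5, the clonal-heterozygous regime), depths Poisson
#' around `mean_depth`, a configurable fraction of long deletions (40-80 bp)
#' among the variants, and classification tokens drawn from the standard
#' MAF vocabulary.
#'
#' @param n_samples Number of samples in the cohort (ids `S0001`...);
#'   ignored when `sample_ids` is given.
#' @param n_variants Number of true variants (one per carrier sample, drawn
#'   without replacement, so `n_variants <=` the number of samples).
#' @param sample_ids Optional explicit pool of sample ids to draw carriers
#'   from (e.g. the mutant samples of an expression cohort).
#' @param locus Locus list/vector with `chrom`, `start`, `end` positions to
#'   draw from (defaults to the BAP1 hg38 locus).
#' @param mean_depth Mean sequencing depth (default 60).
#' @param long_indel_frac Fraction of variants that are long (>= 40 bp)
#'   deletions (default 0.1).
#' @param vaf_shape1,vaf_shape2 Beta parameters for true VAFs (default 8, 8).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `sample_id`, `chrom`, `start`,
#'   `ref_allele`, `alt_allele`, `variant_classification`, `vaf`, `depth`,
#'   `indel_length`.
#' @export
gen_variant_truth <- function(n_samples = 50L, n_variants = 20L,
                              locus = list(chrom = "chr3", start = 52300003,
                                           end = 52511030),
                              mean_depth = 60, long_indel_frac = 0.1,
                              vaf_shape1 = 8, vaf_shape2 = 8,
                              sample_ids = NULL, seed = 1L) {
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n_samples))
  stopifnot(n_variants <= length(sample_ids))
  withr::with_seed(seed, {
    samples <- sort(sample(sample_ids, n_variants))
    pos <- sort(sample(seq(locus$start, locus$end), n_variants))
    bases <- c("A", "C", "G", "T")
    n_long <- round(n_variants * long_indel_frac)
    is_long <- seq_len(n_variants) %in% sample.int(n_variants, n_long)
    ref <- alt <- character(n_variants)
    classification <- character(n_variants)
    snv_classes <- c("Missense_Mutation", "Nonsense_Mutation", "Silent",
                     "Splice_Site")
    for (i in seq_len(n_variants)) {
      if (is_long[i]) {
        len <- sample(40:80, 1L)
        ref[i] <- paste(sample(bases, len, replace = TRUE), collapse = "")
        alt[i] <- "-"
        classification[i] <- "Frame_Shift_Del"
      } else {
        ref[i] <- sample(bases, 1L)
        alt[i] <- sample(setdiff(bases, ref[i]), 1L)
        classification[i] <- sample(snv_classes, 1L,
                                    prob = c(0.45, 0.2, 0.15, 0.2))
      }
    }
    data.frame(sample_id = samples, chrom = locus$chrom, start = pos,
               ref_allele = ref, alt_allele = alt,
               variant_classification = classification,
               vaf = stats::rbeta(n_variants, vaf_shape1, vaf_shape2),
               depth = stats::rpois(n_variants, mean_depth) + 1L,
               indel_length = indel_length(ref, alt),
               stringsAsFactors = FALSE)
  })
}

#' Simulate per-caller MAF tables from variant truth
#'
#' Each caller detects each true variant with its sensitivity (long indels
#' only for the indel-capable callers), reports read support jittered around
#' truth (depth Poisson around the true depth; alt reads Binomial(depth,
#' VAF), floored at 1 since a caller never reports zero supporting reads),
#' and adds Poisson-many false-positive calls at novel positions with low
#' VAFs. All emitted calls carry `FILTER == "PASS"`.
#'
#' @param variant_truth Truth table from [gen_variant_truth()].
#' @param n_callers Number of callers (default 2).
#' @param sensitivities Per-caller detection probabilities (default 0.9).
#' @param fp_rates Per-caller expected false-positive call counts
#'   (default 0).
#' @param long_indel_callers Indices of callers able to call long (>= 40 bp)
#'   indels (default: caller 1 only).
#' @param seed Integer seed.
#' @return A list of MAF tables (callers `caller1`, `caller2`, ...), each in
#'   [read_maf()] layout, with `attr(, "detected")` a callers-by-variants
#'   logical matrix of the detection draws.
#' @export
gen_caller_tables <- function(variant_truth, n_callers = 2L,
                              sensitivities = rep(0.9, n_callers),
                              fp_rates = rep(0, n_callers),
                              long_indel_callers = 1L, seed = 1L) {
  stopifnot(n_callers >= 1L, length(sensitivities) == n_callers,
            length(fp_rates) == n_callers)
  nv <- nrow(variant_truth)
  withr::with_seed(seed, {
    detected <- matrix(FALSE, n_callers, nv)
    tables <- vector("list", n_callers)
    names(tables) <- sprintf("caller%d", seq_len(n_callers))
    for (c_idx in seq_len(n_callers)) {
      can_long <- c_idx %in% long_indel_callers
      det <- stats::runif(nv) < sensitivities[c_idx]
      det[variant_truth$indel_length >= 40 & !can_long] <- FALSE
      detected[c_idx, ] <- det
      tv <- variant_truth[det, , drop = FALSE]
      depth <- pmax(1L, stats::rpois(nrow(tv), tv$depth))
      alt <- pmax(1L, stats::rbinom(nrow(tv), depth, tv$vaf))
      alt <- pmin(alt, depth)
      n_det <- nrow(tv)
      calls <- data.frame(
        sample_id = tv$sample_id, caller = rep(names(tables)[c_idx], n_det),
        chrom = tv$chrom, start = tv$start, ref_allele = tv$ref_allele,
        alt_allele = tv$alt_allele,
        variant_classification = tv$variant_classification,
        filter_status = rep("PASS", n_det), t_alt_count = alt,
        t_depth = depth, is_somatic = rep(TRUE, n_det),
        stringsAsFactors = FALSE)
      n_fp <- stats::rpois(1L, fp_rates[c_idx])
      if (n_fp > 0L) {
        fp_pos <- sample(setdiff(
          seq(min(variant_truth$start), max(variant_truth$start)),
          variant_truth$start), n_fp)
        fp_depth <- stats::rpois(n_fp, 60) + 1L
        fp_alt <- pmax(1L, stats::rbinom(n_fp, fp_depth,
                                         stats::rbeta(n_fp, 2, 18)))
        bases <- c("A", "C", "G", "T")
        fp_ref <- sample(bases, n_fp, replace = TRUE)
        fp_alt_allele <- vapply(fp_ref, function(b)
          sample(setdiff(bases, b), 1L), character(1))
        calls <- rbind(calls, data.frame(
          sample_id = sample(unique(variant_truth$sample_id), n_fp,
                             replace = TRUE),
          caller = names(tables)[c_idx],
          chrom = variant_truth$chrom[1L], start = fp_pos,
          ref_allele = fp_ref, alt_allele = unname(fp_alt_allele),
          variant_classification = "Missense_Mutation",
          filter_status = "PASS", t_alt_count = fp_alt, t_depth = fp_depth,
          is_somatic = TRUE, stringsAsFactors = FALSE))
      }
      rownames(calls) <- NULL
      tables[[c_idx]] <- calls
    }
    attr(tables, "detected") <- detected
    tables
  })
}

#' Simulate gene-level copy number and loss segments
#'
#' Loss samples receive gene-level copy number 1 (0 with probability
#' `deep_prob`, echoing the predominance of single-copy loss) and one
#' segment overlapping the gene locus whose width is drawn from the stated
#' distribution; non-loss samples receive copy number 2 and a copy-neutral
#' segment covering the locus. The default width distribution is a mixture
#' of focal (log-uniform 0.1-30 Mb) and arm-level (uniform 60-90 Mb) events,
#' echoing the focal-vs-arm contrast seen across tumor types.
#'
#' @param sample_ids Character vector of sample ids.
#' @param frac_loss Fraction of samples with loss in [0, 1] (default 0.3).
#' @param gene Gene symbol for the gene-level table (default "BAP1").
#' @param locus Locus list with `chrom`, `start`, `end` (default BAP1 hg38).
#' @param width_distribution `"mixture"` (default), `"focal"`, `"arm"`, or a
#'   function(n) returning n widths in bp.
#' @param arm_frac Probability an event is arm-level under `"mixture"`
#'   (default 0.5).
#' @param deep_prob Probability a loss is deep (copy number 0; default 0.01).
#' @param seed Integer seed.
#' @return A list with `gene_cn` ([read_gene_cn()] layout), `segs`
#'   ([read_seg()] layout) and `truth` (`sample_id`, `loss`, `copy_number`,
#'   `seg_width`).
#' @export
gen_cn_tables <- function(sample_ids, frac_loss = 0.3, gene = "BAP1",
                          locus = list(chrom = "chr3", start = 52300003,
                                       end = 52511030),
                          width_distribution = c("mixture", "focal", "arm"),
                          arm_frac = 0.5, deep_prob = 0.01, seed = 1L) {
  stopifnot(frac_loss >= 0, frac_loss <= 1)
  if (!is.function(width_distribution)) {
    width_distribution <- match.arg(width_distribution)
  }
  n <- length(sample_ids)
  withr::with_seed(seed, {
    draw_width <- function(m) {
      if (is.function(width_distribution)) return(width_distribution(m))
      focal <- function(k) round(10^stats::runif(k, log10(0.1e6),
                                                 log10(30e6)))
      arm <- function(k) round(stats::runif(k, 60e6, 90e6))
      switch(width_distribution,
             focal = focal(m),
             arm = arm(m),
             mixture = {
               is_arm <- stats::runif(m) < arm_frac
               w <- numeric(m)
               w[is_arm] <- arm(sum(is_arm))
               w[!is_arm] <- focal(sum(!is_arm))
               w
             })
    }
    n_loss <- round(n * frac_loss)
    loss <- rep(FALSE, n)
    if (n_loss > 0L) loss[sample.int(n, n_loss)] <- TRUE
    cn <- ifelse(loss,
                 ifelse(stats::runif(n) < deep_prob, 0L, 1L), 2L)
    gene_len <- locus$end - locus$start + 1
    chrom_len <- 198e6  # approx. chr3
    seg_width <- rep(NA_real_, n)
    segs <- vector("list", n)
    for (i in seq_len(n)) {
      if (loss[i]) {
        w <- max(draw_width(1L), gene_len)
        # place the segment so it overlaps the locus
        lo <- round(stats::runif(1L, max(1, locus$end - w + 1),
                                 min(locus$start, chrom_len - w + 1)))
        seg_width[i] <- w
        segs[[i]] <- data.frame(
          sample_id = sample_ids[i], chrom = locus$chrom, seg_start = lo,
          seg_end = lo + w - 1,
          seg_mean = log2(max(cn[i], 0.5) / 2) + stats::rnorm(1L, 0, 0.05),
          stringsAsFactors = FALSE)
      } else {
        segs[[i]] <- data.frame(
          sample_id = sample_ids[i], chrom = locus$chrom, seg_start = 1,
          seg_end = chrom_len,
          seg_mean = stats::rnorm(1L, 0, 0.05), stringsAsFactors = FALSE)
      }
    }
    seg_tab <- do.call(rbind, segs)
    seg_tab$seg_start <- as.integer(seg_tab$seg_start)
    seg_tab$seg_end <- as.integer(seg_tab$seg_end)
    list(
      gene_cn = data.frame(sample_id = sample_ids, gene_symbol = gene,
                           copy_number = as.integer(cn),
                           stringsAsFactors = FALSE),
      segs = seg_tab,
      truth = data.frame(sample_id = sample_ids, loss = loss,
                         copy_number = as.integer(cn), seg_width = seg_width,
                         stringsAsFactors = FALSE))
  })
}

#' Simulate a differentiation time course
#'
#' Cells are assigned latent times on a uniform grid in [0, 1] across the
#' timepoints. The planted mutant-associated up-genes have log2-means
#' decreasing in time and the down-genes increasing, so the computed
#' activity score increases monotonically with time (emulating a
#' developmental gradient in which the disrupted-gene activity rises as
#' cells differentiate). Gaussian noise is added on the log2-means, then
#' negative-binomial counts are drawn.
#'
#' @param n_cells Number of cells (default 300).
#' @param timepoints Number of distinct timepoints (default 8).
#' @param n_genes Number of genes (default 2000).
#' @param signature Optional signature `data.frame` (`gene`, `direction`);
#'   by default 100 genes (half up, half down) are planted and returned.
#' @param slope Total log2-mean change of each signature gene across the
#'   time course; must be > 0 (default 2).
#' @param noise_sd Gaussian noise sd on the log2-means (default 0.3).
#' @param dispersion NB dispersion alpha (default 0.1).
#' @param seed Integer seed.
#' @return A list with `counts`, `time` (latent time per cell), and
#'   `signature` (with `weight` column).
#' @export
gen_timecourse <- function(n_cells = 300L, timepoints = 8L, n_genes = 2000L,
                           signature = NULL, slope = 2, noise_sd = 0.3,
                           dispersion = 0.1, seed = 1L) {
  if (slope < 0) stop("slope must be >= 0", call. = FALSE)
  withr::with_seed(seed, {
    cells <- sprintf("C%04d", seq_len(n_cells))
    genes <- sprintf("G%05d", seq_len(n_genes))
    tgrid <- seq(0, 1, length.out = timepoints)
    t_lat <- tgrid[1L + (seq_len(n_cells) - 1L) %% timepoints]
    baseline <- stats::rnorm(n_genes, mean = 5, sd = 2)
    if (is.null(signature)) {
      n_sig <- min(100L, n_genes)
      n_up <- n_sig %/% 2L
      sig_idx <- sample.int(n_genes, n_sig)
      signature <- data.frame(
        gene = genes[sig_idx],
        direction = rep(c("up", "down"), c(n_up, n_sig - n_up)),
        stringsAsFactors = FALSE)
    }
    signature$weight <- ifelse(signature$direction == "up", -1, 1)
    log2_mu <- matrix(baseline, nrow = n_genes, ncol = n_cells,
                      dimnames = list(genes, cells))
    up <- match(signature$gene[signature$direction == "up"], genes)
    down <- match(signature$gene[signature$direction == "down"], genes)
    # up-in-mutant genes are high early (low activity) and fall with time
    log2_mu[up, ] <- log2_mu[up, ] +
      slope * rep(0.5 - t_lat, each = length(up))
    log2_mu[down, ] <- log2_mu[down, ] +
      slope * rep(t_lat - 0.5, each = length(down))
    if (noise_sd > 0) {
      log2_mu <- log2_mu + stats::rnorm(length(log2_mu), 0, noise_sd)
    }
    counts <- .nb_counts(log2_mu, dispersion)
    list(counts = counts, time = t_lat, signature = signature)
  })
}
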