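test_that("all generators are bit-reproducible given their seed", {
  c1 <- gen_expression_cohort(n_samples = 20, n_genes = 50,
                              n_signature_genes = 10, seed = 5)
  c2 <- gen_expression_cohort(n_samples = 20, n_genes = 50,
                              n_signature_genes = 10, seed = 5)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$truth$true_status, c2$truth$true_status)

  vt <- gen_variant_truth(seed = 3)
  expect_identical(vt, gen_variant_truth(seed = 3))
  expect_identical(gen_caller_tables(vt, seed = 4),
                   gen_caller_tables(vt, seed = 4))
  ids <- sprintf("S%02d", 1:30)
  expect_identical(gen_cn_tables(ids, seed = 6), gen_cn_tables(ids, seed = 6))
  t1 <- gen_timecourse(n_cells = 24, timepoints = 4, n_genes = 60, seed = 7)
  t2 <- gen_timecourse(n_cells = 24, timepoints = 4, n_genes = 60, seed = 7)
  expect_identical(t1$counts, t2$counts)
})

test_that("expression cohort validates parameters and plants the effect", {
  expect_error(gen_expression_cohort(frac_mutant = 0), "strictly between")
  expect_error(gen_expression_cohort(frac_mutant = 1.2), "strictly between")

  cohort <- gen_expression_cohort(n_samples = 60, frac_mutant = 0.5,
                                  n_genes = 300, n_signature_genes = 40,
                                  effect_log2 = 2, dispersion = 0.05,
                                  seed = 11)
  mut <- cohort$truth$true_status == "mutant"
  sig <- cohort$truth$signature
  lc <- log2_cpm(cohort$counts)
  up_genes <- sig$gene[sig$direction == "up"]
  delta <- rowMeans(lc[up_genes, mut]) - rowMeans(lc[up_genes, !mut])
  expect_gt(mean(delta), 1.5)  # ~2 log2 units planted
  down_genes <- sig$gene[sig$direction == "down"]
  delta_d <- rowMeans(lc[down_genes, mut]) - rowMeans(lc[down_genes, !mut])
  expect_lt(mean(delta_d), -1.5)
})

test_that("null cohort (zero effect) yields ~5% small p-values", {
  cohort <- gen_expression_cohort(n_samples = 40, frac_mutant = 0.5,
                                  n_genes = 800, n_signature_genes = 10,
                                  effect_log2 = 0, seed = 13)
  de <- simple_de(cohort$counts,
                  ifelse(cohort$truth$true_status == "mutant", "mutant",
                         "unaltered"))
  frac <- mean(de$p < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("noiseless callers reproduce truth exactly after filtering", {
  vt <- gen_variant_truth(n_samples = 40, n_variants = 15, seed = 2)
  tabs <- gen_caller_tables(vt, n_callers = 2, sensitivities = c(1, 1),
                            fp_rates = c(0, 0),
                            long_indel_callers = 1:2, seed = 2)
  merged <- merge_callers(unname(tabs))
  res <- filter_variants(merged, filter_config(min_vaf = 0, min_alt_count = 1))
  expect_equal(nrow(res$retained), nrow(vt))
  expect_setequal(variant_key_of(res$retained), variant_key_of(vt))
})

test_that("a zero-sensitivity caller does not change the merge", {
  vt <- gen_variant_truth(seed = 8)
  tabs <- gen_caller_tables(vt, n_callers = 2, sensitivities = c(0.8, 0),
                            seed = 9)
  expect_equal(nrow(tabs[[2]]), 0L)
  m_both <- merge_callers(unname(tabs))
  m_one <- merge_callers(list(tabs[[1]]))
  expect_identical(variant_key_of(m_both), variant_key_of(m_one))
})

test_that("detection bookkeeping matches the drawn indicators", {
  vt <- gen_variant_truth(n_samples = 60, n_variants = 20,
                          long_indel_frac = 0, seed = 4)
  tabs <- gen_caller_tables(vt, n_callers = 2, sensitivities = c(0.8, 0.7),
                            seed = 4)
  det <- attr(tabs, "detected")
  union_detected <- vt[det[1, ] | det[2, ], ]
  merged <- merge_callers(unname(tabs))
  expect_equal(nrow(merged), nrow(union_detected))
  expect_setequal(variant_key_of(merged), variant_key_of(union_detected))
})

test_that("long indels only appear in indel-capable callers", {
  vt <- gen_variant_truth(n_samples = 50, n_variants = 25,
                          long_indel_frac = 0.4, seed = 10)
  tabs <- gen_caller_tables(vt, n_callers = 2, sensitivities = c(1, 1),
                            long_indel_callers = 1L, seed = 10)
  expect_true(any(indel_length(tabs[[1]]$ref_allele,
                               tabs[[1]]$alt_allele) >= 40))
  expect_true(all(indel_length(tabs[[2]]$ref_allele,
                               tabs[[2]]$alt_allele) < 40))
})

test_that("CN generator respects frac_loss and the width distribution", {
  ids <- sprintf("S%03d", 1:100)
  none <- gen_cn_tables(ids, frac_loss = 0, seed = 1)
  expect_false(any(call_cn_loss(none$gene_cn, "BAP1")$loss))

  fixed <- gen_cn_tables(ids, frac_loss = 0.4,
                         width_distribution = function(n) rep(10e6, n),
                         seed = 2)
  loss <- call_cn_loss(fixed$gene_cn, "BAP1")
  w <- loss_segment_widths(fixed$segs,
                           list(chrom = "chr3", start = 52300003,
                                end = 52511030),
                           loss$sample_id[loss$loss])
  expect_equal(w$summary$median_bp, 10e6)
  expect_equal(w$summary$q3_bp - w$summary$q1_bp, 0)
  expect_equal(w$no_segment, 0L)

  # category counts match truth bookkeeping
  tabs <- gen_cn_tables(ids, frac_loss = 0.3, seed = 3)
  truth_loss <- tabs$truth$sample_id[tabs$truth$loss]
  mut <- sample(ids, 10)
  res <- assign_alteration_categories(mut, truth_loss, ids)
  expect_equal(res$summary$n[res$summary$category == "CNOnly"],
               length(setdiff(truth_loss, mut)))
  expect_equal(res$n_altered, length(union(mut, truth_loss)))
})

test_that("timecourse limits: noiseless monotone and null slopes", {
  tc0 <- gen_timecourse(n_cells = 60, timepoints = 6, n_genes = 300,
                        slope = 6, noise_sd = 0, dispersion = 0.01, seed = 1)
  sc0 <- weighted_score(normalize_counts(tc0$counts), tc0$signature)
  rho <- spearman(sc0$score, tc0$time)$statistic
  expect_gt(rho, 0.98)

  tc_null <- gen_timecourse(n_cells = 60, timepoints = 6, n_genes = 300,
                            slope = 0, noise_sd = 0.3, seed = 1)
  sc_null <- weighted_score(normalize_counts(tc_null$counts),
                            tc_null$signature)
  expect_lt(abs(spearman(sc_null$score, tc_null$time)$statistic), 0.3)
})
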