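test_that("indel_length follows the MAF allele-length convention", {
  expect_identical(indel_length("A", "G"), 0L)
  expect_identical(indel_length("-", "ACGT"), 4L)
  long_ref <- paste(rep("A", 63), collapse = "")
  expect_identical(indel_length(long_ref, "-"), 63L)
  # vectorized
  expect_identical(indel_length(c("A", "-"), c("G", "AC")), c(0L, 2L))
})

test_that("merge_callers deduplicates by key and records caller provenance", {
  a <- make_maf(caller = "A", t_alt = 10L, t_depth = 20L)
  b <- make_maf(caller = "B", t_alt = 12L, t_depth = 40L)
  m <- merge_callers(list(a, b))
  expect_equal(nrow(m), 1L)
  expect_equal(m$callers, "A;B")
  expect_equal(m$n_callers, 2L)
  # consensus metrics come from the highest-priority caller (input order)
  expect_equal(m$t_alt_count, 10L)
  expect_equal(m$vaf, 0.5)
  # explicit priority flips the consensus source
  m2 <- merge_callers(list(a, b), caller_priority = c("B", "A"))
  expect_equal(m2$t_alt_count, 12L)
  expect_equal(m2$vaf, 0.3)
})

test_that("merge_callers is idempotent and order-invariant", {
  set.seed(11)
  a <- random_callset(15, "A")
  b <- random_callset(12, "B")
  m1 <- merge_callers(list(a, b))
  expect_identical(merge_callers(list(a, a))[, c("sample_id", "start")],
                   merge_callers(list(a))[, c("sample_id", "start")])
  m_rev <- merge_callers(list(b, a), caller_priority = c("A", "B"))
  expect_identical(variant_key_of(m1), variant_key_of(m_rev))
  expect_identical(m1$t_alt_count, m_rev$t_alt_count)
})

test_that("merged key set equals the brute-force union (3 callers, shared loci)", {
  mk <- function(caller, starts) {
    make_maf(caller = caller, sample_id = "S1", start = starts,
             ref = "A", alt = "G")
  }
  tables <- list(mk("A", c(100L, 200L)), mk("B", c(200L, 300L, 400L)),
                 mk("C", c(400L, 500L)))
  m <- merge_callers(tables)
  expect_equal(nrow(m), 5L)
  brute <- unique(unlist(lapply(tables, variant_key_of)))
  expect_setequal(variant_key_of(m), brute)
  expect_equal(sum(m$n_callers == 2L), 2L)
})

test_that("somatic conflicts warn and resolve to somatic", {
  a <- make_maf(caller = "A", somatic = TRUE)
  b <- make_maf(caller = "B", somatic = FALSE)
  expect_warning(m <- merge_callers(list(a, b)), "contradictory")
  expect_true(m$is_somatic)
  expect_equal(nrow(attr(m, "conflicts")), 1L)
})

test_that("filter_variants evaluates the retention predicate", {
  merged <- merge_callers(list(make_maf(
    caller = "A", sample_id = sprintf("S%d", 1:5),
    start = 101:105,
    filter = c("PASS", "PASS", "PASS", "lowq", "PASS"),
    t_alt = c(5L, 1L, 3L, 2L, 2L),
    t_depth = c(50L, 5L, 12L, 4L, 5L))))
  # VAFs: 0.10, 0.20, 0.25, 0.50, 0.40 -> row1 fails vaf, row2 fails alt,
  # row4 fails PASS
  merged$t_depth[5] <- 5L  # vaf 0.4 >= 0.2, alt 2 >= 2, PASS -> retained
  res <- filter_variants(merged, filter_config())
  expect_equal(nrow(res$retained), 2L)
  expect_setequal(res$rejected$reason, c("low_vaf", "low_alt_count",
                                         "not_pass"))
  # partition property
  expect_equal(nrow(res$retained) + nrow(res$rejected), nrow(merged))
  # empty input
  empty <- filter_variants(merged[0, ], filter_config())
  expect_equal(nrow(empty$retained), 0L)
  expect_equal(nrow(empty$rejected), 0L)
})

test_that("exclusion list removes variants with reason 'excluded'", {
  merged <- merge_callers(list(make_maf(sample_id = c("S1", "S2"),
                                        start = c(100L, 200L))))
  excl <- merged[1, c("sample_id", "chrom", "start", "ref_allele",
                      "alt_allele")]
  res <- filter_variants(merged, filter_config(exclusion_list = excl))
  expect_equal(nrow(res$retained), 1L)
  expect_equal(res$rejected$reason, "excluded")
  expect_equal(res$rejected$sample_id, "S1")
})

test_that("raising thresholds never increases the retained set", {
  for (seed in 1:25) {
    set.seed(seed)
    merged <- merge_callers(list(random_callset(30, "A"),
                                 random_callset(25, "B")))
    base <- filter_variants(merged, filter_config(min_vaf = 0.1,
                                                  min_alt_count = 1L))
    for (vaf in c(0.2, 0.4)) {
      tighter <- filter_variants(merged, filter_config(min_vaf = vaf,
                                                       min_alt_count = 1L))
      expect_true(all(variant_key_of(tighter$retained) %in%
                        variant_key_of(base$retained)))
    }
    tighter <- filter_variants(merged, filter_config(min_vaf = 0.1,
                                                     min_alt_count = 5L))
    expect_lte(nrow(tighter$retained), nrow(base$retained))
  }
})

test_that("classification summary counts, fractions and the combined class", {
  retained <- make_maf(
    sample_id = sprintf("S%d", 1:4), start = 101:104,
    classification = c("Missense_Mutation", "Missense_Mutation",
                       "Nonsense_Mutation", "Frame_Shift_Del"))
  retained <- merge_callers(list(retained))
  s <- classify_variant_summary(retained)
  expect_equal(s$fraction[s$class == "Missense_Mutation"], 0.5)
  expect_equal(s$fraction[s$is_combined], 0.5)
  expect_equal(sum(s$fraction[!s$is_combined]), 1)
  # single record -> 100%
  s1 <- classify_variant_summary(retained[1, ])
  expect_equal(s1$fraction[s1$class == "Missense_Mutation"], 1)
  # empty -> empty summary, no division by zero
  s0 <- classify_variant_summary(retained[0, ])
  expect_equal(nrow(s0), 0L)
  # germline records are excluded from the somatic summary
  retained$is_somatic[1] <- FALSE
  s2 <- classify_variant_summary(retained)
  expect_equal(sum(s2$n[!s2$is_combined]), 3L)
})

test_that("domain annotation assigns first containing interval", {
  domains <- data.frame(domain_name = c("UCH", "HBM", "NLS"),
                        aa_start = c(1L, 596L, 717L),
                        aa_end = c(240L, 600L, 722L))
  v <- make_maf(sample_id = sprintf("S%d", 1:4), start = 101:104)
  res <- annotate_domains(v, domains, protein_pos = c(10, 300, 500, 700))
  expect_equal(res$assignments, c("UCH", NA, NA, NA))
  expect_equal(res$summary$fraction_in_domain, 0.25)
  res2 <- annotate_domains(v, domains, protein_pos = c(50, 598, 720, NA))
  expect_equal(res2$assignments, c("UCH", "HBM", "NLS", NA))
  expect_equal(res2$summary$n_missing_position, 1L)
  expect_equal(res2$summary$fraction_in_domain, 0.75)
})

test_that("compare_callsets set arithmetic and conservation", {
  mk <- function(starts) merge_callers(list(make_maf(
    sample_id = "S1", start = starts)))
  old <- mk(c(100L, 200L))
  new <- mk(c(200L, 300L, 400L))
  cmp <- compare_callsets(new, old)
  expect_equal(cmp$shared, 1L)
  expect_equal(cmp$gained, 2L)
  expect_equal(cmp$lost, 1L)
  expect_equal(cmp$percent_increase, 50)
  # identical callsets
  cmp2 <- compare_callsets(old, old)
  expect_equal(cmp2$shared, 2L)
  expect_equal(cmp2$gained + cmp2$lost, 0L)
  expect_equal(cmp2$percent_increase, 0)
  # conservation invariants
  expect_equal(cmp$shared + cmp$gained, cmp$n_new)
  expect_equal(cmp$shared + cmp$lost, cmp$n_old)
})

test_that("window mode matches nearest position, ties to lower coordinate", {
  mk <- function(starts) merge_callers(list(make_maf(
    sample_id = "S1", start = starts, ref = "A", alt = "G")))
  new <- mk(105L)
  old <- mk(c(100L, 103L, 112L))
  cmp <- compare_callsets(new, old, match_mode = "window", window = 10L)
  expect_equal(cmp$shared, 1L)
  expect_equal(cmp$window_matches$old_row, 2L)  # distance 2 beats 5 and 7
  # tie at equal distance resolves to the lower coordinate
  old2 <- mk(c(103L, 107L))
  cmp2 <- compare_callsets(new, old2, match_mode = "window", window = 10L)
  expect_equal(old2$start[cmp2$window_matches$old_row], 103L)
  # beyond the window nothing matches
  cmp3 <- compare_callsets(new, mk(300L), match_mode = "window", window = 10L)
  expect_equal(cmp3$shared, 0L)
})
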