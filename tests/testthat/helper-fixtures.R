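# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately written from first principles (enumeration,
# sort-based quantiles, set arithmetic) so they stay independent of the
# implementation paths they check.

# toy MAF table in the canonical layout
make_maf <- function(sample_id = "S1", caller = "A", chrom = "chr3",
                     start = 100L, ref = "A", alt = "G",
                     classification = "Missense_Mutation",
                     filter = "PASS", t_alt = 10L, t_depth = 30L,
                     somatic = TRUE) {
  data.frame(sample_id = sample_id, caller = caller, chrom = chrom,
             start = as.integer(start), ref_allele = ref, alt_allele = alt,
             variant_classification = classification, filter_status = filter,
             t_alt_count = as.integer(t_alt), t_depth = as.integer(t_depth),
             is_somatic = somatic, stringsAsFactors = FALSE)
}

# random toy callset over a small universe; used by the oracle-equivalence
# suites
random_callset <- function(n, caller, n_samples = 5L, n_pos = 20L) {
  idx <- sample.int(n_samples * n_pos, n)
  make_maf(
    sample_id = sprintf("S%d", 1L + (idx - 1L) %/% n_pos),
    caller = caller,
    start = 100L + (idx - 1L) %% n_pos,
    ref = sample(c("A", "C"), n, replace = TRUE),
    alt = sample(c("G", "T"), n, replace = TRUE),
    filter = sample(c("PASS", "lowq"), n, replace = TRUE, prob = c(0.8, 0.2)),
    t_alt = sample(1:20, n, replace = TRUE),
    t_depth = sample(20:60, n, replace = TRUE))
}

variant_key_of <- function(df) {
  paste(df$sample_id, df$chrom, df$start, df$ref_allele, df$alt_allele,
        sep = "\r")
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combos <- utils::combn(N, n1)
  us <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# two-sided Fisher p by direct summation of hypergeometric probabilities,
# written with choose() rather than dhyper()
oracle_fisher <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  prob_a <- function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, prob_a, numeric(1))
  p_obs <- prob_a(m[1, 1])
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# sort-based type-7 quantile, written out from the interpolation formula
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# AUROC of "low score predicts positive class" via the rank formula
auroc_low_positive <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  u <- sum(r[positive]) - n1 * (n1 + 1) / 2
  1 - u / (n1 * n0)
}
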