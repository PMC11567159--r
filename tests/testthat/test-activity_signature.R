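toy_counts <- function() {
  matrix(c(0L, 3L, 15L,
           5L, 5L, 5L,
           8L, 1L, 30L), nrow = 3, byrow = TRUE,
         dimnames = list(c("G1", "G2", "G3"), c("S1", "S2", "S3")))
}

test_that("normalize_counts matches the hand-computed z of log2 counts", {
  z <- normalize_counts(toy_counts())
  # G1: log2(0,3,15)+1 -> (0,2,4); centered (-2,0,2); sample sd 2 -> (-1,0,1)
  expect_equal(unname(z["G1", ]), c(-1, 0, 1))
  # constant gene flagged and zeroed
  expect_equal(unname(z["G2", ]), c(0, 0, 0))
  expect_equal(attr(z, "constant_genes"), "G2")
  expect_error(normalize_counts(toy_counts()[, 1, drop = FALSE]),
               ">= 2 samples")
})

test_that("scaling one gene's counts leaves its z row unchanged", {
  counts <- toy_counts()
  z1 <- normalize_counts(counts, pseudocount = 0)
  counts2 <- counts
  counts2["G3", ] <- counts2["G3", ] * 8L  # log2 shift by 3
  z2 <- normalize_counts(counts2, pseudocount = 0)
  expect_equal(z1["G3", ], z2["G3", ])
})

test_that("simple_de: null labels give zero log2fc, planted effect is found", {
  set.seed(9)
  counts <- matrix(rnbinom(200 * 40, mu = 100, size = 10), nrow = 200,
                   dimnames = list(sprintf("G%d", 1:200),
                                   sprintf("S%d", 1:40)))
  # identical groups by label permutation of equal library columns
  cs <- counts
  cs[, 21:40] <- cs[, 1:20]
  de0 <- simple_de(cs, rep(c("unaltered", "mutant"), each = 20))
  expect_true(all(abs(de0$log2fc) < 1e-12))

  # a planted 4-fold increase
  counts2 <- counts
  counts2["G1", 21:40] <- rnbinom(20, mu = 400, size = 50)
  de <- simple_de(counts2, rep(c("unaltered", "mutant"), each = 20))
  g1 <- de[de$gene == "G1", ]
  expect_lt(g1$padj, 0.05)
  expect_gt(g1$log2fc, 1.5)
  expect_lt(g1$log2fc, 2.5)
  # direct test computation agrees
  lc <- log2_cpm(counts2)
  expect_equal(g1$p, mann_whitney_cc(lc["G1", 21:40], lc["G1", 1:20])$p)

  expect_error(simple_de(counts, c("mutant", rep("unaltered", 39))),
               "at least 2")
})

test_that("build_signature applies thresholds and the weight convention", {
  de <- data.frame(gene = c("A", "B", "C", "D"),
                   log2fc = c(2, -2, 1.5, 0),
                   p = c(0.001, 0.001, 0.1, 0.001),
                   padj = c(0.01, 0.01, 0.2, 0.01))
  sig <- build_signature(de)
  expect_setequal(sig$gene, c("A", "B"))  # C fails padj, D has zero lfc
  expect_equal(sig$weight[sig$gene == "A"], -1)  # up in mutant
  expect_equal(sig$direction[sig$gene == "A"], "up")
  expect_equal(sig$weight[sig$gene == "B"], 1)   # down in mutant
  expect_error(build_signature(de, padj_max = 1e-6), "relax")
  # fold-change threshold
  sig2 <- build_signature(transform(de, padj = 0.01), min_abs_lfc = 1.6)
  expect_setequal(sig2$gene, c("A", "B"))
})

test_that("weighted_score implements the signed sum", {
  z <- matrix(0, nrow = 3, ncol = 2,
              dimnames = list(c("A", "B", "C"), c("S1", "S2")))
  sig <- data.frame(gene = c("A", "B", "C"),
                    direction = c("up", "up", "down"),
                    weight = c(-1, -1, 1))
  expect_equal(weighted_score(z, sig)$score, c(0, 0))
  z[, 1] <- c(1, 2, 3)   # -1 - 2 + 3 = 0
  z[, 2] <- c(1, 0, 0)   # single up gene with z = +1 -> -1
  sc <- weighted_score(z, sig)
  expect_equal(sc$score, c(0, -1))
  # mean aggregate divides by signature size; duplicating the signature is
  # then a no-op
  sc_mean <- weighted_score(z, sig, aggregate = "mean")
  expect_equal(sc_mean$score, sc$score / 3)
  expect_equal(weighted_score(z, rbind(sig, sig), aggregate = "mean")$score,
               sc_mean$score)
  # zero overlap errors with the missing genes
  expect_error(weighted_score(z, data.frame(gene = "X", direction = "up",
                                            weight = -1)), "X")
})

test_that("flipping every signature direction negates the weighted score", {
  for (seed in 1:10) {
    set.seed(seed)
    z <- matrix(rnorm(30 * 8), nrow = 30,
                dimnames = list(sprintf("G%d", 1:30), sprintf("S%d", 1:8)))
    dirs <- sample(c("up", "down"), 10, replace = TRUE)
    sig <- data.frame(gene = sprintf("G%d", 1:10), direction = dirs,
                      weight = ifelse(dirs == "up", -1, 1))
    flipped <- sig
    flipped$direction <- ifelse(sig$direction == "up", "down", "up")
    flipped$weight <- -sig$weight
    expect_equal(weighted_score(z, flipped)$score,
                 -weighted_score(z, sig)$score)
  }
})

test_that("per-gene count scaling leaves weighted and rank scores unchanged", {
  set.seed(21)
  counts <- matrix(rnbinom(50 * 10, mu = 200, size = 5) + 1L, nrow = 50,
                   dimnames = list(sprintf("G%d", 1:50), sprintf("S%d", 1:10)))
  dirs <- rep(c("up", "down"), each = 5)
  sig <- data.frame(gene = sprintf("G%d", 1:10), direction = dirs,
                    weight = ifelse(dirs == "up", -1, 1))
  w1 <- weighted_score(normalize_counts(counts, pseudocount = 0), sig)$score
  counts2 <- counts
  counts2["G3", ] <- counts2["G3", ] * 16L
  w2 <- weighted_score(normalize_counts(counts2, pseudocount = 0), sig)$score
  expect_equal(w1, w2)
})

test_that("rank_score hits its extremes and sign convention", {
  n_genes <- 40
  mat <- matrix(rep(seq_len(n_genes), 2), ncol = 2,
                dimnames = list(sprintf("G%d", 1:n_genes), c("S1", "S2")))
  # up-genes are the top-expressed, down-genes the bottom -> strongly negative
  sig <- data.frame(gene = sprintf("G%d", c(37:40, 1:4)),
                    direction = rep(c("up", "down"), each = 4),
                    weight = rep(c(-1, 1), each = 4))
  sc <- rank_score(mat, sig)
  expect_lt(sc$score[1], -0.8)
  # interleaved uniformly -> near zero
  sig2 <- data.frame(gene = sprintf("G%d", 1:40),
                     direction = rep(c("up", "down"), 20),
                     weight = rep(c(-1, 1), 20))
  expect_lt(abs(rank_score(mat, sig2)$score[1]), 0.05)
})

test_that("geneset_score averages per-gene z rows", {
  counts <- toy_counts()
  # constant-gene set -> zeros
  expect_equal(geneset_score(counts, "G2")$score, c(0, 0, 0))
  # two-gene set equals the hand mean of the z rows
  z <- normalize_counts(counts)
  expect_equal(geneset_score(counts, c("G1", "G3"))$score,
               unname((z["G1", ] + z["G3", ]) / 2))
  expect_error(geneset_score(counts, "NOPE"), "no gene-set gene")
  # all-equal matrix -> all scores 0
  flat <- matrix(7L, 3, 3, dimnames = list(paste0("G", 1:3), paste0("S", 1:3)))
  expect_equal(geneset_score(flat, paste0("G", 1:3))$score, c(0, 0, 0))
})
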