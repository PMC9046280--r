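sig_matrix <- function(seed = 1, n_genes = 60, n_samples = 8) {
  set.seed(seed)
  v <- matrix(rlnorm(n_genes * n_samples, 3, 0.8), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%d", seq_len(n_samples))))
  expr_matrix(v, "fpkm")
}

test_that("z-score-sum over all genes conserves zero across samples", {
  m <- sig_matrix()
  sc <- signature_score(m, gene_signature("all", rownames(m)), "zscore_sum")
  expect_equal(sum(sc$score), 0, tolerance = 1e-9)
  expect_identical(attr(sc, "n_genes_found"), nrow(m))
})

test_that("log2-sum score is the sum of pseudocounted log2 abundances", {
  v <- matrix(c(3, 1), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  m <- expr_matrix(v, "fpkm")
  sc <- signature_score(m, gene_signature("s", c("g1", "g2")), "log2_sum")
  expect_equal(sc$score, 3)     # log2(4) + log2(2)
  expect_error(signature_score(zscore_genes(sig_matrix()),
                               gene_signature("s", "g001"), "log2_sum"),
               "z-scored")
})

test_that("missing signature genes are skipped and counted, all-missing errors", {
  m <- sig_matrix()
  sig <- gene_signature("s", c("g001", "g002", "ghost1", "ghost2"))
  sc <- signature_score(m, sig, "zscore_sum")
  expect_identical(attr(sc, "n_genes_found"), 2L)
  expect_identical(attr(sc, "n_genes_missing"), 2L)
  expect_error(signature_score(m, gene_signature("s", c("x", "y"))),
               "none of the 2")
})

test_that("scores are invariant to location shifts and consistent relabeling", {
  m <- sig_matrix(2)
  sig <- gene_signature("s", rownames(m)[1:10])
  base <- signature_score(m, sig, "zscore_sum")
  shifted <- unclass(m)
  shifted["g001", ] <- shifted["g001", ] + 100  # location removed by z
  s2 <- signature_score(expr_matrix(shifted, "fpkm"), sig, "zscore_sum")
  expect_equal(base$score, s2$score, tolerance = 1e-9)
  # permuting rows (labels travel with values) leaves scores unchanged
  perm <- sample(nrow(m))
  s3 <- signature_score(expr_matrix(unclass(m)[perm, ], "fpkm"), sig,
                        "zscore_sum")
  expect_equal(base$score, s3$score, tolerance = 1e-9)
})

test_that("planted signature-positive samples take the top score ranks", {
  cfg <- sim_config(seed = 21, n_samples = c(10, 10),
                    n_activated = 0, n_repressed = 0)
  sim <- simulate_study(cfg, with_sequence = FALSE)
  sig <- gene_signature("planted", sim$truth$signature_genes)
  sc <- signature_score(sim$counts, sig, "zscore_sum")
  top <- sc$sample_id[order(-sc$score)][seq_along(sim$truth$positive_samples)]
  expect_setequal(top, sim$truth$positive_samples)
})

test_that("signature derivation is intersection then strict fold filter", {
  sets <- list(c("A", "B", "C"), c("B", "C", "D"), c("B", "C", "E"),
               c("B", "C"))
  fc <- c(A = 5, B = 2.5, C = 1.9, D = 4, E = 4)
  sig <- derive_signature(sets, fc, fc_thresh = 2)
  expect_identical(sig$gene_ids, "B")
  # threshold below every value: the full consensus comes back
  all_in <- derive_signature(sets, fc, fc_thresh = -1e9)
  expect_setequal(all_in$gene_ids, c("B", "C"))
  expect_error(derive_signature(list(c("A"), c("B")), fc), "empty consensus")
  expect_error(derive_signature(list(c("A")), fc), "at least 2")
})

test_that("derivation is order-independent and matches a loop oracle", {
  set.seed(33)
  pool <- sprintf("g%03d", 1:120)
  for (i in 1:40) {
    sets <- replicate(sample(2:5, 1),
                      sample(pool, sample(30:80, 1)), simplify = FALSE)
    fc <- stats::setNames(round(rnorm(120, 1, 1.5), 3), pool)
    shared <- sample(pool, 1)
    sets <- lapply(sets, function(s) union(s, shared))
    fc[shared] <- 3.5
    # loop oracle: count membership per gene, then filter
    tally <- table(unlist(lapply(sets, unique)))
    consensus <- names(tally)[tally == length(sets)]
    expected <- sort(consensus[fc[consensus] > 2])
    sig <- derive_signature(sets, fc, 2)
    expect_identical(sort(sig$gene_ids), expected)
    sig_rev <- derive_signature(rev(sets), fc, 2)
    expect_identical(sort(sig_rev$gene_ids), expected)
  }
})

test_that("over-representation reproduces the worked combinatorial example", {
  universe <- sprintf("u%03d", 1:100)
  pw <- list(path10 = universe[1:10])
  query <- c(universe[1:3], universe[50:51])   # k=3 of K=10, n=5
  res <- ora(query, universe, pw)
  expect_equal(res$p_value, 499752 / 75287520, tolerance = 1e-12)
  expect_equal(res$p_value,
               brute_hyper_upper(3, 10, 5, 100), tolerance = 1e-12)
  # k = 0 gives p = 1
  res0 <- ora(universe[90:94], universe, pw)
  expect_equal(res0$p_value, 1)
  expect_error(ora(c("u001", "alien"), universe, pw), "alien")
})

test_that("BH adjustment uses the step-up minimum and shares the kernel", {
  universe <- sprintf("u%03d", 1:60)
  # three pathways engineered to give increasing raw p
  pws <- list(a = universe[1:12], b = universe[c(1:6, 31:36)],
              c = universe[31:42])
  query <- universe[1:10]
  res <- ora(query, universe, pws)
  # step-up oracle: adjusted_i = min_{j >= i} p_(j) * m / j on sorted p
  p <- res$p_value
  m_ <- length(p)
  manual <- vapply(seq_len(m_), function(i)
    min(1, min(p[i:m_] * m_ / (i:m_))), numeric(1))
  expect_equal(res$padj, manual)
  expect_true(all(res$padj >= res$p_value))
  # identical kernel as the motif enrichment tail
  expect_equal(res$p_value[1],
               hyper_upper_tail(res$k[1], res$K[1], res$n[1], res$N[1]))
})

test_that("GMT and signature files round-trip", {
  sets <- list(pathA = c("g1", "g2", "g3"), pathB = c("g2", "g9"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_identical(back$pathA, sets$pathA)
  f2 <- withr::local_tempfile()
  write_gmt(back, f2)
  expect_identical(readLines(f), readLines(f2))
  sig <- gene_signature("mysig", c("g1", "g5"))
  fs <- withr::local_tempfile()
  write_signature(sig, fs)
  expect_identical(read_signatures(fs)$mysig$gene_ids, sig$gene_ids)
})
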