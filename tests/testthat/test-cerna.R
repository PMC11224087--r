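test_that("pearson reproduces the closed-form df = 2 case and the exact limits", {
  expect_equal(pearson(c(1, 2, 3, 4), c(2, 4, 6, 8)), list(r = 1, p = 0, n = 4L),
               tolerance = 1e-15)
  expect_equal(pearson(c(1, 2, 3, 4), c(8, 6, 4, 2))$r, -1)
  # r = 0.8 at n = 4: F(t) = 1/2 + t / (2 sqrt(t^2 + 2)) gives exactly 0.9 => p = 0.2
  res <- pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  expect_equal(res$p, 0.2, tolerance = 1e-12)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("pearson agrees with cor.test across random vectors", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    res <- pearson(x, y)
    ct <- cor.test(x, y, method = "pearson")
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("hypergeometric tail matches exhaustive enumeration for all N <= 12", {
  for (N in c(4, 7, 10, 12)) {
    for (K in 1:N) for (n in 1:N) for (x in 0:min(K, n)) {
      expect_equal(cernet:::hyper_upper_tail(x, K, n, N), hyper_enum(x, K, n, N),
                   tolerance = 1e-12,
                   info = sprintf("N=%d K=%d n=%d x=%d", N, K, n, x))
    }
  }
})

test_that("worked pair-score cases: N=10 K=4 n=3 x=2 gives exactly 1/3", {
  ps <- cerna_pair_score(sponge_targets = c("a", "b", "c", "d"),
                         mrna_targets = c("a", "b", "e"), universe_size = 10)
  expect_equal(ps$x, 2)
  expect_equal(ps$hyper_p, 1 / 3, tolerance = 1e-12)
  expect_equal(ps$score, -log10(1 / 3), tolerance = 1e-12)
  # empty overlap: p = 1, never a division error
  ps0 <- cerna_pair_score(c("a", "b"), c("c", "d"), 10)
  expect_equal(ps0$hyper_p, 1)
  expect_equal(ps0$x, 0)
  # saturated universe
  u <- sprintf("mi%d", 1:6)
  ps1 <- cerna_pair_score(u, u, 6)
  expect_equal(ps1$hyper_p, 1)
  expect_equal(ps1$x, 6)
  expect_error(cerna_pair_score(u, u, 3), "universe_size")
})

test_that("log-space tail stays finite and consistent with phyper at large N", {
  for (case in list(c(50, 40, 12, 1e3), c(400, 300, 150, 1e5), c(30, 20, 18, 5e4))) {
    K <- case[1]; n <- case[2]; x <- case[3]; N <- case[4]
    expect_equal(cernet:::hyper_upper_tail(x, K, n, N),
                 phyper(x - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("screening with no DE miRNAs yields no triplets", {
  sc <- run_screen(sim_config(n_features = c(lncRNA = 20, circRNA = 10, miRNA = 30,
                                             mRNA = 40),
                              n_triplets = 2, target_length = 120, rng_seed = 3))
  de_no_mirna <- sc$de
  de_no_mirna$direction[de_no_mirna$class == "miRNA"] <- "ns"
  out <- screen_triplets(de_no_mirna, sc$hits, sc$cerna_norm, sc$mirna_norm)
  expect_equal(nrow(out$triplets), 0)
  expect_equal(nrow(out$pairs), 0)
})

test_that("emitted triplets satisfy every screening invariant", {
  sc <- run_screen(sim_config(rng_seed = 2))
  tr <- sc$screen$triplets
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$r_sponge_mirna < -0.8 & tr$p_sponge_mirna < 0.05))
  expect_true(all(tr$r_mirna_mrna < -0.8 & tr$p_mirna_mrna < 0.05))
  expect_true(all(tr$r_sponge_mrna > 0.8 & tr$p_sponge_mrna < 0.05))
  expect_true(all(tr$pair_hyper_p < 0.05))
  expect_true(all(tr$x == lengths(lapply(strsplit(
    sc$screen$pairs$shared_mirna_ids[match(paste(tr$sponge_id, tr$mrna_id),
      paste(sc$screen$pairs$sponge_id, sc$screen$pairs$mrna_id))], ","), identity))))
  # both targeting relations exist in the hits table
  hk <- paste(sc$hits$mirna_id, sc$hits$target_id)
  expect_true(all(paste(tr$mirna_id, tr$sponge_id) %in% hk))
  expect_true(all(paste(tr$mirna_id, tr$mrna_id) %in% hk))
  # every member is differentially expressed
  de_ids <- sc$de$feature_id[sc$de$direction != "ns"]
  expect_true(all(c(tr$sponge_id, tr$mirna_id, tr$mrna_id) %in% de_ids))
  # deterministic ordering by score
  expect_true(all(diff(tr$pair_score) <= 1e-12))
})

test_that("relaxing the correlation thresholds only enlarges the output", {
  sc <- run_screen(sim_config(rng_seed = 5))
  strict <- sc$screen$triplets
  relaxed <- screen_triplets(sc$de, sc$hits, sc$cerna_norm, sc$mirna_norm,
                             r_neg = -1e-9, r_pos = 1e-9)$triplets
  expect_true(all(triplet_key(strict) %in% triplet_key(relaxed)))
  expect_gte(nrow(relaxed), nrow(strict))
})

test_that("consistent sample permutation leaves the screen unchanged", {
  sc <- run_screen(sim_config(rng_seed = 6))
  perm <- rev(sc$cerna_norm$samples$sample_id)
  cn_p <- subset_expression(sc$cerna_norm, samples = perm)
  mn_p <- subset_expression(sc$mirna_norm, samples = perm)
  out_p <- screen_triplets(sc$de, sc$hits, cn_p, mn_p)
  expect_equal(out_p$triplets, sc$screen$triplets, tolerance = 1e-12)
})

test_that("mismatched platform samples raise an error naming the missing ids", {
  sc <- run_screen(sim_config(n_features = c(lncRNA = 20, circRNA = 10, miRNA = 30,
                                             mRNA = 40),
                              n_triplets = 2, target_length = 120, rng_seed = 3))
  mn_cut <- subset_expression(sc$mirna_norm,
                              samples = sc$mirna_norm$samples$sample_id[-1])
  expect_error(screen_triplets(sc$de, sc$hits, sc$cerna_norm, mn_cut),
               "unmatched.*TULP_1")
})

test_that("top_k_pairs ranks by score with a stable lexicographic tie-break", {
  pairs <- data.frame(sponge_id = c("s2", "s1", "s3", "s1"),
                      mrna_id = c("m1", "m2", "m1", "m1"),
                      x = c(2L, 2L, 1L, 3L),
                      hyper_p = c(0.01, 0.01, 0.2, 0.001),
                      score = c(2, 2, log10(5), 3))
  expect_equal(nrow(top_k_pairs(pairs, k = 100)), 4)   # underfull returns all
  expect_identical(top_k_pairs(pairs, k = 1)$sponge_id, "s1")
  top2 <- top_k_pairs(pairs, k = 3)
  expect_identical(top2$sponge_id[2:3], c("s1", "s2"))  # tie at score 2 -> id order
  expect_identical(top_k_pairs(pairs, 3), top_k_pairs(pairs, 3))
  expect_error(top_k_pairs(pairs, k = 0), "k must be")
})
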