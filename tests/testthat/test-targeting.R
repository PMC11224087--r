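test_that("scanner finds the definitional seed match with correct coordinates", {
  mir <- c(mirX = "UAAGGCACGCGGUGAAUGCC")  # seed 2-8 = AAGGCAC, rev comp GUGCCUU
  tgt <- c(m_gene = paste0("CCCCCCCCCC", "GUGCCUUA", "CCCCCCCCCC"))
  hits <- scan_targets(mir, tgt)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$mirna_id, "mirX")
  expect_true(hits$site_type %in% c("7mer-m8", "8mer"))  # has m8 match + A1 anchor
  expect_identical(hits$site_type, "8mer")
  expect_equal(hits$site_start, 11L)
  # the matched substring is the reverse complement of the seed
  expect_identical(unname(substr(tgt, hits$site_start, hits$site_start + 6)), "GUGCCUU")
  # T treated as U
  hits_dna <- scan_targets(mir, c(m_gene = "CCCCCCCCCCGTGCCTTACCCCCCCCCC"))
  expect_identical(hits_dna$site_type, "8mer")
})

test_that("full reverse complement of a miRNA contains a seed site", {
  mir <- c(mirY = "UAAGGCACGCGGUGAAUGCC")
  rc <- cernet:::revcomp_rna("UAAGGCACGCGGUGAAUGCC", u = "U")
  hits <- scan_targets(mir, c(m_t = rc), min_site_type = "7mer-m8")
  expect_gte(nrow(hits), 1)
  # position 1 of this miRNA is U, so the opposing base is A: 8mer
  expect_true("8mer" %in% hits$site_type)
})

test_that("site classes degrade as flanking matches are removed", {
  mir <- c(mirZ = "UAAGGCACGCGGUGAAUGCC")
  core <- "UGCCUU"  # rev comp of seed positions 2-7
  mk <- function(before, after) c(t = paste0("CCCCC", before, core, after, "CCCCC"))
  expect_identical(scan_targets(mir, mk("G", "A"), "6mer")$site_type, "8mer")
  expect_identical(scan_targets(mir, mk("G", "C"), "6mer")$site_type, "7mer-m8")
  expect_identical(scan_targets(mir, mk("C", "A"), "6mer")$site_type, "7mer-A1")
  expect_identical(scan_targets(mir, mk("C", "C"), "6mer")$site_type, "6mer")
  # default min_site_type drops the weak classes
  expect_equal(nrow(scan_targets(mir, mk("C", "A"))), 0)
  expect_equal(nrow(scan_targets(mir, mk("C", "C"))), 0)
})

test_that("scanner reads the given sense strand only", {
  cfg <- sim_config(n_features = c(lncRNA = 5, circRNA = 5, miRNA = 10, mRNA = 10),
                    n_triplets = 2, target_length = 200, rng_seed = 8)
  d <- generate_expression(cfg)
  seqs <- generate_sequences(cfg, d$truth)
  pair <- d$truth$true_target_pairs[1, ]
  fwd <- scan_targets(seqs$mirna_seqs[pair$mirna_id], seqs$target_seqs[pair$target_id])
  expect_gte(nrow(fwd), 1)
  rc <- cernet:::revcomp_rna(seqs$target_seqs[[pair$target_id]], u = "T")
  rev_hits <- scan_targets(seqs$mirna_seqs[pair$mirna_id],
                           stats::setNames(rc, pair$target_id))
  # the planted site does not survive reverse complementation
  expect_false(any(rev_hits$site_start %in% fwd$site_start))
})

test_that("scanner recall on planted sites is 100% at the default stringency", {
  cfg <- sim_config(n_features = c(lncRNA = 10, circRNA = 5, miRNA = 20, mRNA = 20),
                    n_triplets = 3, target_length = 300, rng_seed = 4)
  d <- generate_expression(cfg)
  seqs <- generate_sequences(cfg, d$truth)
  hits <- scan_targets(seqs$mirna_seqs, seqs$target_seqs)
  hk <- paste(hits$mirna_id, hits$target_id)
  pk <- paste(d$truth$true_target_pairs$mirna_id, d$truth$true_target_pairs$target_id)
  expect_true(all(pk %in% hk))
  # and each planted site is reported at its recorded coordinate
  sk <- paste(hits$mirna_id, hits$target_id, hits$site_start)
  expect_true(all(paste(seqs$sites$mirna_id, seqs$sites$target_id,
                        seqs$sites$site_start) %in% sk))
})

test_that("chance hit frequency matches the analytic site-occurrence rate", {
  # P(specific 7mer occurs in an iid uniform L-mer) ~ 1 - (1 - 4^-7)^(L-6)
  set.seed(77)
  L <- 500
  n_draws <- 1500
  mir <- c(mir1 = "UAAGGCACGCGGUGAAUGCC")
  targets <- vapply(seq_len(n_draws), function(i)
    paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = ""), character(1))
  names(targets) <- sprintf("m_%04d", seq_len(n_draws))
  hits <- scan_targets(mir, targets, min_site_type = "7mer-m8")
  observed <- length(unique(hits$target_id)) / n_draws
  p_site <- 1 - (1 - 4^-7)^(L - 6)
  mc_se <- sqrt(p_site * (1 - p_site) / n_draws)
  expect_lt(abs(observed - p_site), 3 * mc_se + 0.002)
})

test_that("sequence validation rejects empty and ambiguous input", {
  expect_error(scan_targets(c(m = ""), c(t = "ACGU")), "empty")
  expect_error(scan_targets(c(m = "ACGUACGUAC"), c(t = "ACGNN")), "ambiguity")
  expect_error(scan_targets(c(m = "ACGUACG"), c(t = "ACGU")), ">= 8 nt")
})

test_that("importer round-trips well-formed tables and excludes unknown ids", {
  d <- withr::local_tempdir()
  p <- file.path(d, "hits.tsv")
  writeLines(c("mirna_id\ttarget_id\tscore",
               "mi_1\tm_1\t150", "mi_1\tlnc_1\t140", "mi_2\tm_2\t120"), p)
  h <- import_target_table(p)
  expect_equal(nrow(h), 3)
  expect_identical(unique(h$source), "imported")
  expect_identical(h$target_class[h$target_id == "lnc_1"], "lncRNA")
  expect_warning(h2 <- import_target_table(p, known_ids = c("mi_1", "m_1", "lnc_1")),
                 "1 imported hit")
  expect_equal(nrow(h2), 2)
  writeLines(c("mirna_id\ttarget_id\tscore", "mi_1\tm_1"), p)
  expect_error(import_target_table(p), "malformed line 2")
  writeLines(character(0), p)
  expect_warning(h3 <- import_target_table(p), "empty")
  expect_equal(nrow(h3), 0)
})

test_that("target sets collapse multiple sites and stay mutually consistent", {
  hits <- data.frame(mirna_id = c("mi_1", "mi_1", "mi_2"),
                     target_id = c("g1", "g1", "g1"),
                     site_start = c(5L, 50L, 9L))
  ts <- target_sets(hits)
  expect_identical(ts$by_mirna$mi_1, "g1")
  expect_identical(sort(ts$by_target$g1), c("mi_1", "mi_2"))
  # rebuild each map from the other: identical memberships
  rebuilt <- do.call(rbind, lapply(names(ts$by_target), function(t)
    data.frame(mirna_id = ts$by_target[[t]], target_id = t)))
  ts2 <- target_sets(rebuilt)
  expect_identical(ts2$by_mirna, ts$by_mirna)
  expect_identical(target_sets(hits[0, ]), list(by_mirna = list(), by_target = list()))
})
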