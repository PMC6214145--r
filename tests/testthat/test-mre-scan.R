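test_that("the worked 8mer example is found at the expected span", {
  sites <- find_seed_sites("UAUGCAUGCAUGCAUGCAUG", "GGGCAUGCAUAGGG")
  expect_equal(nrow(sites), 1)
  expect_equal(sites$start, 3)
  expect_equal(sites$end, 11)
  expect_equal(sites$site_type, "8mer")
})

test_that("impossible seed matches yield no sites", {
  mir <- "UACGCAUGCAUGCAUGCAUG"   # seed complement contains G/C
  expect_equal(nrow(find_seed_sites(mir, strrep("A", 40))), 0)
})

test_that("two disjoint planted copies give exactly two sites", {
  mir <- "UAUGCAUGCAUGCAUGCAUG"
  block <- "CAUGCAUA"             # rc(mir 2-8) + A
  tgt <- paste0("GGGG", block, "GGGGGGG", block, "GG")
  sites <- find_seed_sites(mir, tgt)
  expect_equal(nrow(sites), 2)
  expect_equal(sites$site_type, c("8mer", "8mer"))
})

test_that("scanner equals the whole-site string-comparison oracle", {
  withr::with_seed(99, {
    for (i in 1:150) {
      mir <- random_rna_str(sample(19:24, 1))
      tgt <- random_rna_str(sample(40:80, 1))
      expect_equal(as.data.frame(find_seed_sites(mir, tgt)),
                   as.data.frame(seed_scan_oracle(mir, tgt)))
    }
  })
})

test_that("input validation catches non-RNA and short sequences", {
  expect_error(find_seed_sites("UAUGCXUG", strrep("A", 20)), "non-RNA")
  expect_error(find_seed_sites("UAUGCAU", strrep("A", 20)), "at least 8")
  expect_error(find_seed_sites("UAUGCAUG", "ACGU"), "at least 6")
  # T is accepted and treated as U
  expect_equal(find_seed_sites("TATGCATGCATGCATGCATG", "GGGCATGCATAGGG")$site_type,
               "8mer")
})

test_that("a perfect 20-nt duplex scores 100 and empty complementarity floors at 0", {
  mir <- random_rna_str(20)
  tgt <- rc_chr(mir)
  site <- list(start = 0L, end = nchar(tgt))
  expect_equal(pair_score(mir, tgt, site, window = nchar(tgt)), 100)
  # poly-A vs poly-A: every pairing is a mismatch, local floor is 0
  expect_equal(pair_score(strrep("A", 20), strrep("A", 20),
                          list(start = 0L, end = 20L), window = 20), 0)
})

test_that("pair score equals the exhaustive alignment oracle on short pairs", {
  withr::with_seed(7, {
    for (i in 1:60) {
      mir <- random_rna_str(sample(8:20, 1))
      tgt <- random_rna_str(sample(8:20, 1))
      site <- list(start = 0L, end = nchar(tgt))
      expect_equal(pair_score(mir, tgt, site, window = nchar(tgt)),
                   pair_score_oracle(mir, tgt))
    }
  })
})

test_that("duplex energy is the additive per-pair sum", {
  expect_equal(duplex_energy(tibble::tibble(target_base = character(),
                                            mirna_base = character())), 0)
  # CAUGCAU paired with AUGCAUG: 4 A:U + 3 G:C
  pairs <- tibble::tibble(target_base = strsplit("CAUGCAU", "")[[1]],
                          mirna_base = strsplit("GUACGUA", "")[[1]])
  expect_equal(duplex_energy(pairs), -17)
  expect_equal(duplex_energy(c("GC", "AU", "GU")), -6)
  # one extra G:U wobble lowers energy by exactly 1
  expect_equal(duplex_energy(c("GC", "GU")) - duplex_energy("GC"), -1)
  expect_error(duplex_energy("GX"), "invalid")
})

test_that("site scores are invariant under translation of the site", {
  mir <- random_rna_str(22)
  block <- paste0(rc_chr(substr(mir, 2, 22)), "A")
  for (pad in c(0, 15, 40)) {
    tgt <- paste0(strrep("G", pad + 30), block, strrep("G", 60 - pad))
    sites <- find_seed_sites(mir, tgt)
    hit <- sites[sites$site_type == "8mer", ][1, ]
    sc <- score_site(mir, tgt, hit, window = 30)
    if (pad == 0) base <- sc
    expect_equal(sc$pair_score, base$pair_score)
    expect_equal(sc$energy, base$energy)
  }
})

test_that("predict_targets applies the intersection-of-evidence rule", {
  mir <- "UAUGCAUGCAUGCAUGCAUG"
  strong <- paste0(strrep("G", 20), rc_chr(substr(mir, 2, 20)), "A",
                   strrep("G", 10))
  weak <- paste0(strrep("G", 20), "CAUGCAUA", strrep("G", 22))  # seed only
  preds <- predict_targets(c(m1 = mir), c(strong = strong, weak = weak))
  expect_equal(nrow(preds), 2)
  expect_true(preds$passed[preds$target_id == "strong"])
  expect_false(preds$passed[preds$target_id == "weak"])
  expect_gte(preds$best_pair_score[preds$target_id == "strong"], 80)
  expect_lte(preds$best_energy[preds$target_id == "strong"], -14)
  # no seed site anywhere -> empty prediction table
  none <- predict_targets(c(m1 = "UACGCAUGCAUGCAUGCAUG"),
                          c(t1 = strrep("A", 50)))
  expect_equal(nrow(none), 0)
  # id collisions between the two files are rejected
  expect_error(predict_targets(c(x = mir), c(x = strong)), "collision")
})

test_that("scanner recall on planted full-complement sites is 1", {
  cfg <- triplet_recovery_config(17, n_triplets = 8)
  sim <- simulate_sequences(cfg, simulate_expression(cfg))
  st <- sim$truth$site_truth
  hosts <- c(sim$sequences$lncrna, sim$sequences$utr3)
  preds <- predict_targets(sim$sequences$mirna[unique(st$mirna_id)],
                           hosts[unique(st$target_id)])
  found <- dplyr::semi_join(st, dplyr::filter(preds, passed),
                            by = c("mirna_id", "target_id"))
  expect_equal(nrow(found), nrow(st))
})
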