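test_that("zero-noise simulation with no planted effects is constant per gene", {
  cfg <- sim_config(n_per_group = 3, n_mirna = 5, n_lncrna = 5, n_mrna = 5,
                    noise_sd = 0, seed = 11)
  sim <- simulate_expression(cfg)
  for (cl in c("mirna", "lncrna", "mrna")) {
    m <- as.matrix(sim[[cl]][, -1])
    expect_true(all(apply(m, 1, function(v) diff(range(v)) == 0)))
    expect_true(all(m > 0))
  }
})

test_that("a planted effect at zero noise forces the exact linear fold change", {
  de <- tibble::tibble(class = "mrna", gene_id = "mrna_0003", contrast = "B",
                       direction = "up", log2fc = 2)
  cfg <- sim_config(n_per_group = 4, n_mirna = 4, n_lncrna = 4, n_mrna = 8,
                    noise_sd = 0, de_spec = de, seed = 5)
  sim <- simulate_expression(cfg)
  m <- as.matrix(sim$mrna[, -1])
  rownames(m) <- sim$mrna$gene_id
  grp <- sim$sample_info$group
  ratio <- mean(m["mrna_0003", grp == "B"]) / mean(m["mrna_0003", grp == "A"])
  expect_equal(ratio, 4)
  # remission group untouched by a B-contrast effect
  expect_equal(mean(m["mrna_0003", grp == "C"]),
               mean(m["mrna_0003", grp == "A"]))
})

test_that("the seed fully determines matrices and sequences", {
  cfg <- triplet_recovery_config(3, n_triplets = 2)
  s1 <- simulate_sequences(cfg, simulate_expression(cfg))
  s2 <- simulate_sequences(cfg, simulate_expression(cfg))
  expect_identical(s1$mrna, s2$mrna)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$truth, s2$truth)
})

test_that("planted 8mer block matches the reverse complement of miRNA 2-8 plus A", {
  mir <- paste(c("U", sample(c("A", "C", "G", "U"), 19, replace = TRUE)),
               collapse = "")
  host <- strrep("C", 50)
  planted <- plant_mre_site(host, mir, offset = 10, extent = "8mer")
  expect_equal(planted$site_start, 10)
  expect_equal(planted$site_end, 18)
  written <- substr(planted$seq, 11, 18)
  expect_equal(written, paste0(rc_chr(substr(mir, 2, 8)), "A"))
  expect_equal(nchar(planted$seq), 50)
})

test_that("full-extent planting embeds an 8mer recoverable by the scanner", {
  cfg <- triplet_recovery_config(21, n_triplets = 5)
  sim <- simulate_sequences(cfg, simulate_expression(cfg))
  st <- sim$truth$site_truth
  expect_equal(nrow(st), 10)  # lncRNA + mRNA site per triplet
  for (i in seq_len(nrow(st))) {
    host <- c(sim$sequences$lncrna, sim$sequences$utr3)[[st$target_id[i]]]
    sites <- find_seed_sites(sim$sequences$mirna[[st$mirna_id[i]]], host)
    hit <- sites[sites$start == st$start[i] & sites$end == st$end[i], ]
    expect_equal(hit$site_type, "8mer")
  }
})

test_that("planting a site longer than the host errors", {
  expect_error(plant_mre_site(strrep("A", 10), strrep("U", 22)),
               "longer than the host")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_per_group = 0), "positive")
  expect_error(sim_config(mirna_len = 30), "19-24")
  expect_error(sim_config(de_spec = tibble::tibble(
    class = "mrna", gene_id = "nope", contrast = "B",
    direction = "up", log2fc = 1)), "unknown")
})

test_that("detection flags mark sub-floor intensities Absent", {
  cfg <- sim_config(n_per_group = 2, n_mirna = 3, n_lncrna = 3, n_mrna = 30,
                    baseline_mean = 5, baseline_sd = 2, noise_sd = 0.2,
                    detection_floor = 30, seed = 2)
  sim <- simulate_expression(cfg)
  vals <- as.matrix(sim$mrna[, -1])
  flags <- as.matrix(detection_flags(sim$mrna)[, -1])
  expect_identical(unname(flags == "Absent"), unname(vals < 30))
})

test_that("simulation round-trips through the TSV/FASTA writers", {
  dir <- withr::local_tempdir()
  cfg <- triplet_recovery_config(9, n_triplets = 2)
  sim <- simulate_sequences(cfg, simulate_expression(cfg))
  write_simulation(sim, dir)
  back <- read_expression_table(file.path(dir, "mrna_expression.tsv"),
                                file.path(dir, "mrna_flags.tsv"))
  expect_equal(as.data.frame(back), as.data.frame(sim$mrna), tolerance = 1e-12)
  expect_identical(sample_groups(back), sim$sample_info)
  fa <- read_fasta(file.path(dir, "mirna.fa"))
  expect_identical(fa, sim$sequences$mirna)
})
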