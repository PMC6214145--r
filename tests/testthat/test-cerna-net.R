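# hand-built DE tables / predictions / edges for the join logic
mk_de <- function(ids, dirs, sig = TRUE, fc = NULL, p = 1e-4) {
  if (is.null(fc)) fc <- ifelse(dirs == "up", 4, 0.25)
  structure(tibble::tibble(gene_id = ids, fc = fc, log2fc = log2(fc),
                           direction = dirs, p = p, q = p,
                           significant = sig),
            class = c("cernet_de", "tbl_df", "tbl", "data.frame"))
}
mk_pred <- function(mir, tgt, passed = TRUE) {
  tibble::tibble(mirna_id = mir, target_id = tgt, n_sites = 1L,
                 best_pair_score = 100, best_energy = -40, passed = passed)
}

test_that("regulatory edges require passed prediction, significance, anti-direction", {
  mir_de <- mk_de(c("m1", "m2", "m3"), c("up", "up", "down"),
                  sig = c(TRUE, TRUE, FALSE))
  mrna_de <- mk_de(c("t1", "t2", "t3"), c("down", "up", "down"))
  preds <- mk_pred(c("m1", "m2", "m3"), c("t1", "t2", "t3"))
  edges <- mirna_mrna_network(mir_de, mrna_de, preds)
  # m1(up)->t1(down) kept; m2(up)->t2(up) same direction; m3 not significant
  expect_equal(nrow(edges), 1)
  expect_equal(edges$mirna_id, "m1")
  expect_equal(edges$target_id, "t1")
  # a failed prediction never becomes an edge
  edges2 <- mirna_mrna_network(mir_de, mrna_de,
                               mk_pred("m1", "t1", passed = FALSE))
  expect_equal(nrow(edges2), 0)
  # predictions naming unknown genes are skipped with a message
  expect_message(
    mirna_mrna_network(mir_de, mrna_de, mk_pred("m9", "t9")), "skipping")
})

test_that("triplet assembly enforces all five criteria on a hand fixture", {
  # mirrors the elicitation sponge example: miRNA up, lncRNA and mRNA down,
  # shared MRE, positive lncRNA-mRNA co-expression
  mir_de <- mk_de("mir155", "up")
  mrna_de <- mk_de("pkia", "down")
  lnc_de <- mk_de("linc0490", "down")
  mrna_pred <- mk_pred("mir155", "pkia")
  lnc_pred <- mk_pred("mir155", "linc0490")
  cnc <- tibble::tibble(ncrna_id = "linc0490", coding_id = "pkia",
                        r = 0.999, p = 1e-9, q = 1e-8)
  trip <- assemble_cerna_triplets(lnc_de, mir_de, mrna_de,
                                  lnc_pred, mrna_pred, cnc)
  expect_equal(nrow(trip), 1)
  expect_equal(trip$lncrna_id, "linc0490")
  expect_equal(trip$mirna_id, "mir155")
  expect_equal(trip$mrna_id, "pkia")

  # knocking out any single criterion suppresses the triplet
  no_mre <- assemble_cerna_triplets(lnc_de, mir_de, mrna_de,
                                    mk_pred("mir155", "linc0490", FALSE),
                                    mrna_pred, cnc)
  expect_equal(nrow(no_mre), 0)
  neg_cnc <- assemble_cerna_triplets(lnc_de, mir_de, mrna_de, lnc_pred,
                                     mrna_pred, dplyr::mutate(cnc, r = -0.999))
  expect_equal(nrow(neg_cnc), 0)
  weak_lnc <- assemble_cerna_triplets(
    mk_de("linc0490", "down", fc = 0.6), mir_de, mrna_de,
    lnc_pred, mrna_pred, cnc)
  expect_equal(nrow(weak_lnc), 0)
  same_dir <- assemble_cerna_triplets(
    mk_de("linc0490", "up"), mir_de, mrna_de, lnc_pred, mrna_pred, cnc)
  expect_equal(nrow(same_dir), 0)
  # ... unless the direction rule is relaxed
  relaxed <- assemble_cerna_triplets(
    mk_de("linc0490", "up"), mir_de, mrna_de, lnc_pred, mrna_pred, cnc,
    require_direction = FALSE)
  expect_equal(nrow(relaxed), 1)
})

test_that("lncRNA stage uses the inclusive fc >= 2 boundary", {
  mir_de <- mk_de("m", "up")
  mrna_de <- mk_de("t", "down")
  lnc_exact <- mk_de("l", "down", fc = 0.5)  # exactly 2-fold down
  trip <- assemble_cerna_triplets(lnc_exact, mir_de, mrna_de,
                                  mk_pred("m", "l"), mk_pred("m", "t"),
                                  tibble::tibble(ncrna_id = "l", coding_id = "t",
                                                 r = 0.99, p = 0, q = 0))
  expect_equal(nrow(trip), 1)
})

test_that("planted triplets are recovered exactly and the audit re-confirms them", {
  cfg <- triplet_recovery_config(41, n_triplets = 6)
  run <- run_pipeline(run_config(sim = cfg, normalize = FALSE, seed = 41),
                      quiet = TRUE)
  trip <- run$networks$elicitation$triplets
  tt <- run$truth$triplet_truth
  expect_setequal(triplet_key(trip), triplet_key(tt))
  ph <- run$de$elicitation
  audit <- verify_triplets(trip, ph$lncrna, ph$mirna, ph$mrna,
                           run$predictions$lncrna, run$predictions$mrna,
                           run$cnc)
  expect_true(all(audit$ok))
})

test_that("network export round-trips nodes and edges through GraphML", {
  cfg <- triplet_recovery_config(43, n_triplets = 3)
  run <- run_pipeline(run_config(sim = cfg, normalize = FALSE, seed = 43),
                      quiet = TRUE)
  trip <- run$networks$elicitation$triplets
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(trip, path)
  g <- read_network(path)
  expect_setequal(igraph::V(g)$name,
                  unique(c(trip$lncrna_id, trip$mirna_id, trip$mrna_id)))
  expect_equal(igraph::gsize(g), 3 * nrow(trip))
  expect_setequal(unique(igraph::V(g)$rna_class), c("miRNA", "lncRNA", "mRNA"))
  # one triplet -> 3 nodes, 3 edges
  one <- trip[1, ]
  class(one) <- class(trip)
  export_network(one, path)
  g1 <- read_network(path)
  expect_equal(igraph::gorder(g1), 3)
  expect_equal(igraph::gsize(g1), 3)
  # empty network still writes a valid zero-node file
  empty <- trip[0, ]
  class(empty) <- class(trip)
  export_network(empty, path)
  expect_equal(igraph::gorder(read_network(path)), 0)
  # TSV export carries the same edges
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(trip, tsv, format = "tsv")
  el <- read.delim(tsv)
  expect_equal(nrow(el), 3 * nrow(trip))
})
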