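# Network assembly: the directional miRNA-mRNA anti-regulation network and
# the ceRNA (sponge) lncRNA-miRNA-mRNA triplet network, plus GraphML/TSV
# export and an independent post-hoc audit of every emitted triplet.

#' Directional miRNA-mRNA regulatory network
#'
#' An edge miRNA -> mRNA is drawn when the mRNA is a passed target
#' prediction of the miRNA, both genes are significantly differentially
#' expressed in the contrast, and their directions are opposite
#' (up-regulated miRNAs intersected with down-regulated mRNAs and vice
#' versa). Predictions naming genes absent from the DE tables are skipped
#' with a message.
#'
#' @param mir_de,mrna_de DE tables ([call_differential()]) from the same
#'   contrast.
#' @param predictions Target predictions ([predict_targets()]) of miRNAs
#'   against mRNA 3'UTRs.
#' @return A tibble of edges: `mirna_id`, `target_id`, `mirna_direction`,
#'   `target_direction`, `best_pair_score`, `best_energy`.
#' @export
mirna_mrna_network <- function(mir_de, mrna_de, predictions) {
  pred <- filter(predictions, .data$passed)
  missing <- union(setdiff(pred$mirna_id, mir_de$gene_id),
                   setdiff(pred$target_id, mrna_de$gene_id))
  if (length(missing)) {
    inform(sprintf("skipping %d prediction gene(s) absent from the DE tables",
                   length(missing)))
  }
  mir_sig <- filter(mir_de, .data$significant) |>
    select(mirna_id = "gene_id", mirna_direction = "direction")
  mrna_sig <- filter(mrna_de, .data$significant) |>
    select(target_id = "gene_id", target_direction = "direction")
  pred |>
    select("mirna_id", "target_id", "best_pair_score", "best_energy") |>
    inner_join(mir_sig, by = "mirna_id") |>
    inner_join(mrna_sig, by = "target_id") |>
    filter(.data$mirna_direction != .data$target_direction) |>
    select("mirna_id", "target_id", "mirna_direction", "target_direction",
           "best_pair_score", "best_energy") |>
    arrange(.data$mirna_id, .data$target_id)
}

#' Assemble ceRNA (sponge) triplets
#'
#' Emits a (lncRNA, miRNA, mRNA) triplet when all of the following hold:
#' (1) the lncRNA is dysregulated at fold change >= `lnc_fc_min` with
#' p < `lnc_p_max`; (2) the mRNA is a passed target prediction of the miRNA
#' and forms a directional regulatory edge with it (opposite DE
#' directions); (3) the lncRNA itself carries a passed binding site (MRE)
#' for the same miRNA; (4) the lncRNA-mRNA pair is a retained co-expression
#' edge with r > 0; (5) optionally, the lncRNA and mRNA share the same DE
#' direction, both opposite the miRNA. Duplicate triples are collapsed.
#'
#' @param lnc_de,mir_de,mrna_de DE tables from the same contrast.
#' @param lnc_predictions Passed/failed MRE predictions of miRNAs on
#'   lncRNAs.
#' @param mrna_predictions Predictions of miRNAs on mRNA 3'UTRs.
#' @param cnc_edges Retained co-expression edges ([cnc_network()]) between
#'   lncRNAs (`ncrna_id`) and mRNAs (`coding_id`).
#' @param lnc_fc_min lncRNA fold-change cutoff, inclusive (default 2.0).
#' @param lnc_p_max lncRNA p cutoff, strict (default 0.05).
#' @param require_direction Enforce criterion (5) (default TRUE).
#' @param phase Optional label ("elicitation"/"remission") stamped on rows.
#' @return A tibble of class `cerna_triplets`: identities, the three DE
#'   directions, lncRNA fc and p, co-expression r and q, and `phase`.
#' @export
assemble_cerna_triplets <- function(lnc_de, mir_de, mrna_de,
                                    lnc_predictions, mrna_predictions,
                                    cnc_edges,
                                    lnc_fc_min = 2.0, lnc_p_max = 0.05,
                                    require_direction = TRUE,
                                    phase = NA_character_) {
  reg <- mirna_mrna_network(mir_de, mrna_de, mrna_predictions)
  lnc_ok <- lnc_de |>
    filter((.data$fc >= lnc_fc_min | .data$fc <= 1 / lnc_fc_min),
           .data$p < lnc_p_max) |>
    select(lncrna_id = "gene_id", lnc_direction = "direction",
           lnc_fc = "fc", lnc_p = "p")
  lnc_mre <- lnc_predictions |>
    filter(.data$passed) |>
    select(mirna_id = "mirna_id", lncrna_id = "target_id")
  pos_cnc <- cnc_edges |>
    filter(.data$r > 0) |>
    select(lncrna_id = "ncrna_id", mrna_id = "coding_id",
           coexpr_r = "r", coexpr_q = "q")
  out <- reg |>
    rename(mrna_id = "target_id", mrna_direction = "target_direction") |>
    inner_join(lnc_mre, by = "mirna_id", relationship = "many-to-many") |>
    inner_join(lnc_ok, by = "lncrna_id") |>
    inner_join(pos_cnc, by = c("lncrna_id", "mrna_id"))
  if (require_direction) {
    out <- filter(out, .data$lnc_direction == .data$mrna_direction,
                  .data$lnc_direction != .data$mirna_direction)
  }
  out <- out |>
    distinct(.data$lncrna_id, .data$mirna_id, .data$mrna_id, .keep_all = TRUE) |>
    mutate(phase = phase) |>
    select("lncrna_id", "mirna_id", "mrna_id",
           "lnc_direction", "mirna_direction", "mrna_direction",
           "lnc_fc", "lnc_p", "coexpr_r", "coexpr_q",
           "best_pair_score", "best_energy", "phase") |>
    arrange(.data$lncrna_id, .data$mirna_id, .data$mrna_id)
  structure(out, class = c("cerna_triplets", class(out)))
}

#' Re-verify emitted triplets against the raw evidence
#'
#' Independent post-hoc audit: re-checks, for every emitted triplet and
#' directly from the raw input tables, each of the five assembly criteria.
#'
#' @inheritParams assemble_cerna_triplets
#' @param triplets Result of [assemble_cerna_triplets()].
#' @return A tibble with one row per triplet and one logical column per
#'   criterion (`lnc_dysregulated`, `mrna_antiregulated`, `lnc_has_mre`,
#'   `positive_coexpression`, `direction_consistent`) plus `ok` (all five).
#' @export
verify_triplets <- function(triplets, lnc_de, mir_de, mrna_de,
                            lnc_predictions, mrna_predictions, cnc_edges,
                            lnc_fc_min = 2.0, lnc_p_max = 0.05) {
  check_row <- function(l, m, r) {
    ld <- lnc_de[lnc_de$gene_id == l, ]
    md <- mir_de[mir_de$gene_id == m, ]
    rd <- mrna_de[mrna_de$gene_id == r, ]
    c1 <- nrow(ld) == 1 &&
      (ld$fc >= lnc_fc_min || ld$fc <= 1 / lnc_fc_min) && ld$p < lnc_p_max
    pr <- mrna_predictions[mrna_predictions$mirna_id == m &
                             mrna_predictions$target_id == r, ]
    c2 <- nrow(pr) == 1 && pr$passed && nrow(md) == 1 && nrow(rd) == 1 &&
      md$significant && rd$significant && md$direction != rd$direction
    pl <- lnc_predictions[lnc_predictions$mirna_id == m &
                            lnc_predictions$target_id == l, ]
    c3 <- nrow(pl) == 1 && pl$passed
    ce <- cnc_edges[cnc_edges$ncrna_id == l & cnc_edges$coding_id == r, ]
    c4 <- nrow(ce) == 1 && ce$r > 0
    c5 <- nrow(ld) == 1 && nrow(rd) == 1 && nrow(md) == 1 &&
      ld$direction == rd$direction && ld$direction != md$direction
    tibble(lnc_dysregulated = c1, mrna_antiregulated = c2, lnc_has_mre = c3,
           positive_coexpression = c4, direction_consistent = c5)
  }
  out <- list_rbind(pmap(list(triplets$lncrna_id, triplets$mirna_id,
                              triplets$mrna_id), check_row))
  out$ok <- out$lnc_dysregulated & out$mrna_antiregulated & out$lnc_has_mre &
    out$positive_coexpression & out$direction_consistent
  bind_cols(triplets[c("lncrna_id", "mirna_id", "mrna_id")], out)
}

#' @method glance cerna_triplets
#' @export
glance.cerna_triplets <- function(x, ...) {
  tibble(n_triplets = nrow(x),
         n_lncrna = dplyr::n_distinct(x$lncrna_id),
         n_mirna = dplyr::n_distinct(x$mirna_id),
         n_mrna = dplyr::n_distinct(x$mrna_id))
}

#' @method tidy cerna_triplets
#' @export
tidy.cerna_triplets <- function(x, ...) as_tibble(x)

triplets_to_igraph <- function(triplets) {
  nodes <- bind_rows(
    tibble(name = triplets$lncrna_id, rna_class = "lncRNA",
           direction = triplets$lnc_direction),
    tibble(name = triplets$mirna_id, rna_class = "miRNA",
           direction = triplets$mirna_direction),
    tibble(name = triplets$mrna_id, rna_class = "mRNA",
           direction = triplets$mrna_direction)) |>
    distinct(.data$name, .keep_all = TRUE)
  edges <- bind_rows(
    tibble(from = triplets$mirna_id, to = triplets$lncrna_id,
           evidence = "mre", score = triplets$best_pair_score),
    tibble(from = triplets$mirna_id, to = triplets$mrna_id,
           evidence = "regulation", score = triplets$best_pair_score),
    tibble(from = triplets$lncrna_id, to = triplets$mrna_id,
           evidence = "coexpression", score = triplets$coexpr_r)) |>
    distinct(.data$from, .data$to, .data$evidence, .keep_all = TRUE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

edges_to_igraph <- function(edges) {
  nodes <- bind_rows(
    tibble(name = edges$mirna_id, rna_class = "miRNA",
           direction = edges$mirna_direction),
    tibble(name = edges$target_id, rna_class = "mRNA",
           direction = edges$target_direction)) |>
    distinct(.data$name, .keep_all = TRUE)
  el <- tibble(from = edges$mirna_id, to = edges$target_id,
               evidence = "regulation", score = edges$best_pair_score)
  igraph::graph_from_data_frame(el, directed = TRUE, vertices = nodes)
}

#' Export a network as GraphML or a TSV edge list
#'
#' Nodes carry `rna_class` and `direction` attributes; edges carry the
#' evidence type and score. An empty network writes a valid file with zero
#' nodes.
#'
#' @param x A `cerna_triplets` table or a miRNA-mRNA edge table.
#' @param path Output path.
#' @param format `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(x, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  g <- if (inherits(x, "cerna_triplets")) triplets_to_igraph(x) else {
    if (!all(c("mirna_id", "target_id") %in% names(x))) {
      abort("x must be a cerna_triplets table or a miRNA-mRNA edge table")
    }
    edges_to_igraph(x)
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GraphML network back
#' @param path GraphML file path.
#' @return An igraph object.
#' @export
read_network <- function(path) igraph::read_graph(path, format = "graphml")
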