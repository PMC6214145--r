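# End-to-end orchestration: simulate or ingest -> normalize & filter ->
# differential expression per class and contrast -> MRE scanning -> CNC ->
# directional and ceRNA networks -> optional enrichment, with a JSON run
# manifest of parameters and per-stage counts.

#' Pipeline run configuration
#'
#' @param sim A [sim_config()] describing the synthetic study, or `NULL`
#'   when `inputs` is given.
#' @param inputs Optional named list of file paths for a pre-existing study:
#'   `mirna`, `lncrna`, `mrna` expression TSVs (layout of
#'   [write_expression_table()]), optional `*_flags` TSVs, and FASTA paths
#'   `mirna_fa`, `lncrna_fa`, `utr_fa`.
#' @param thresholds Named list of [de_thresholds()] per class; defaults to
#'   the canonical per-class cutoffs.
#' @param scan List of scanner parameters: `s_min`, `e_max`, `window`, plus
#'   optional `lnc_s_min`/`lnc_e_max` overrides for lncRNA MRE prediction.
#' @param cnc List with `pcc_min` and `fdr_max`.
#' @param lnc_fc_min,lnc_p_max lncRNA cutoffs for triplet assembly
#'   (fold change inclusive >= 2, p strict < 0.05).
#' @param contrasts Named list of `c(ref=, test=)` pairs; defaults to
#'   elicitation (B vs A) and remission (C vs A).
#' @param min_flagged_samples Detection-filter threshold.
#' @param mirna_ref_min Intensity floor defining the median-normalization
#'   reference set.
#' @param normalize Apply the per-class normalization stage (median scaling
#'   for miRNAs, quantile for lncRNAs/mRNAs). Set to `FALSE` for inputs
#'   already on a common intensity scale, e.g. simulated matrices: quantile
#'   normalization under strong one-sided differential expression compresses
#'   tail intensities and can attenuate extreme co-expression.
#' @param scan_de_only Scan only miRNAs significant in some contrast
#'   (default TRUE).
#' @param require_direction Direction-consistency rule for triplets.
#' @param gene_sets Optional GMT path or gene-set tibble for enrichment of
#'   per-phase significant mRNAs.
#' @param out_dir Optional output directory for all intermediate tables,
#'   networks and the manifest.
#' @param seed Integer seed; overrides the simulation seed so one number
#'   drives the whole run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = NULL, inputs = NULL,
                       thresholds = list(mirna = de_thresholds("mirna"),
                                         lncrna = de_thresholds("lncrna"),
                                         mrna = de_thresholds("mrna")),
                       scan = list(s_min = 80, e_max = -14, window = 30),
                       cnc = list(pcc_min = 0.995, fdr_max = 0.05),
                       lnc_fc_min = 2.0, lnc_p_max = 0.05,
                       contrasts = list(elicitation = c(ref = "A", test = "B"),
                                        remission = c(ref = "A", test = "C")),
                       min_flagged_samples = 3,
                       mirna_ref_min = 30,
                       normalize = TRUE,
                       scan_de_only = TRUE,
                       require_direction = TRUE,
                       gene_sets = NULL,
                       out_dir = NULL,
                       seed = NULL) {
  if (is.null(sim) && is.null(inputs)) sim <- demo_config(seed %||% 1L)
  if (!is.null(sim) && !is.null(seed)) sim$seed <- as.integer(seed)
  scan <- utils::modifyList(list(s_min = 80, e_max = -14, window = 30), scan)
  cnc <- utils::modifyList(list(pcc_min = 0.995, fdr_max = 0.05), cnc)
  stopifnot(cnc$pcc_min >= 0, cnc$pcc_min <= 1, cnc$fdr_max > 0)
  cfg <- list(sim = sim, inputs = inputs, thresholds = thresholds,
              scan = scan, cnc = cnc,
              lnc_fc_min = lnc_fc_min, lnc_p_max = lnc_p_max,
              contrasts = contrasts,
              min_flagged_samples = min_flagged_samples,
              mirna_ref_min = mirna_ref_min,
              normalize = normalize,
              scan_de_only = scan_de_only,
              require_direction = require_direction,
              gene_sets = gene_sets, out_dir = out_dir,
              seed = seed %||% (if (!is.null(sim)) sim$seed else 1L))
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Recognizes the top-level keys of [run_config()]; the `sim` block is
#' passed to [sim_config()] (its `de_spec`/`triplet_spec` sub-blocks become
#' tibbles), and per-class `thresholds` blocks to [de_thresholds()].
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    for (fld in c("de_spec", "triplet_spec")) {
      if (!is.null(y$sim[[fld]])) {
        y$sim[[fld]] <- as_tibble(do.call(rbind.data.frame, y$sim[[fld]]))
      }
    }
    y$sim <- do.call(sim_config, y$sim)
  }
  if (!is.null(y$thresholds)) {
    y$thresholds <- imap(y$thresholds, function(th, cl) {
      do.call(de_thresholds, c(list(class = cl), th))
    })
  }
  if (!is.null(y$contrasts)) y$contrasts <- map(y$contrasts, unlist)
  do.call(run_config, y)
}

stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full ceRNA pipeline
#'
#' Executes every stage in dependency order, writing intermediates and a
#' JSON manifest when `out_dir` is set. The manifest records package
#' version, parameters, and per-stage counts; identical config and seed
#' yield identical manifests.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `cernet_run`: `normalized` (per-class expression
#'   tables), `de` (per phase per class), `predictions` (mRNA and lncRNA),
#'   `cnc`, `networks` (per-phase regulatory edges and triplets),
#'   `enrichment` (or NULL), `truth` (when simulated), and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))

  # --- ingest / simulate ------------------------------------------------
  dat <- stage("input", {
    if (!is.null(config$inputs)) read_study_inputs(config$inputs) else {
      sim <- simulate_expression(config$sim)
      simulate_sequences(config$sim, sim)
    }
  })
  say("input: %d miRNAs, %d lncRNAs, %d mRNAs, %d samples",
      nrow(dat$mirna), nrow(dat$lncrna), nrow(dat$mrna), nrow(dat$sample_info))

  # --- normalization + detection filtering ------------------------------
  norm <- stage("normalize", {
    if (config$normalize) {
      list(mirna = median_normalize(dat$mirna, config$mirna_ref_min),
           lncrna = quantile_normalize(dat$lncrna),
           mrna = quantile_normalize(dat$mrna))
    } else {
      list(mirna = dat$mirna, lncrna = dat$lncrna, mrna = dat$mrna)
    }
  })
  norm <- stage("detection_filter", {
    map(norm, function(m) {
      if (is.null(detection_flags(m))) m else
        filter_detected(m, config$min_flagged_samples)
    })
  })
  say("retained after detection filter: %d/%d/%d (miRNA/lncRNA/mRNA)",
      nrow(norm$mirna), nrow(norm$lncrna), nrow(norm$mrna))

  # --- differential expression ------------------------------------------
  de <- stage("differential_expression", {
    imap(config$contrasts, function(ct, phase) {
      imap(norm, function(m, cl) {
        call_differential(m, ref = ct[["ref"]], test = ct[["test"]],
                          thresholds = config$thresholds[[cl]])
      })
    })
  })

  # --- MRE scanning ------------------------------------------------------
  preds <- stage("mre_scan", {
    mir_seqs <- dat$sequences$mirna
    if (config$scan_de_only) {
      sig <- unique(unlist(map(de, function(ph) {
        ph$mirna$gene_id[ph$mirna$significant]
      })))
      mir_seqs <- mir_seqs[intersect(names(mir_seqs), sig)]
    }
    sc <- config$scan
    list(
      mrna = predict_targets(mir_seqs, dat$sequences$utr3,
                             s_min = sc$s_min, e_max = sc$e_max,
                             window = sc$window),
      lncrna = predict_targets(mir_seqs, dat$sequences$lncrna,
                               s_min = sc$lnc_s_min %||% sc$s_min,
                               e_max = sc$lnc_e_max %||% sc$e_max,
                               window = sc$window))
  })
  say("scan: %d miRNA-mRNA and %d miRNA-lncRNA seed pairs (%d / %d passed)",
      nrow(preds$mrna), nrow(preds$lncrna),
      sum(preds$mrna$passed), sum(preds$lncrna$passed))

  # --- CNC ---------------------------------------------------------------
  cnc <- stage("cnc", {
    cnc_network(norm$lncrna, norm$mrna,
                pcc_min = config$cnc$pcc_min, fdr_max = config$cnc$fdr_max)
  })
  say("cnc: %d retained edges of %d tested pairs",
      nrow(cnc), attr(cnc, "n_tested") %||% NA_integer_)

  # --- networks ----------------------------------------------------------
  networks <- stage("cerna_network", {
    imap(de, function(ph, phase) {
      edges <- mirna_mrna_network(ph$mirna, ph$mrna, preds$mrna)
      trip <- assemble_cerna_triplets(
        ph$lncrna, ph$mirna, ph$mrna,
        lnc_predictions = preds$lncrna, mrna_predictions = preds$mrna,
        cnc_edges = cnc,
        lnc_fc_min = config$lnc_fc_min, lnc_p_max = config$lnc_p_max,
        require_direction = config$require_direction, phase = phase)
      list(edges = edges, triplets = trip)
    })
  })

  # --- enrichment (optional) --------------------------------------------
  enr <- NULL
  if (!is.null(config$gene_sets)) {
    enr <- stage("enrichment", {
      sets <- if (is.character(config$gene_sets)) read_gmt(config$gene_sets)
              else config$gene_sets
      universe <- norm$mrna$gene_id
      imap(de, function(ph, phase) {
        q <- intersect(ph$mrna$gene_id[ph$mrna$significant], universe)
        if (!length(q)) return(NULL)
        hypergeometric_enrichment(q, universe, sets)
      })
    })
  }

  manifest <- build_manifest(config, norm, de, preds, cnc, networks)
  out <- structure(list(config = config, input = dat, normalized = norm,
                        de = de, predictions = preds, cnc = cnc,
                        networks = networks, enrichment = enr,
                        truth = dat$truth, manifest = manifest),
                   class = "cernet_run")
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

build_manifest <- function(config, norm, de, preds, cnc, networks) {
  de_counts <- imap(de, function(ph, phase) {
    imap(ph, function(tab, cl) {
      g <- glance(tab)
      list(n_genes = g$n_genes, n_significant = g$n_significant,
           n_up = g$n_up, n_down = g$n_down)
    })
  })
  list(
    package = "cernet",
    version = as.character(utils::packageVersion("cernet")),
    seed = config$seed,
    parameters = list(
      thresholds = map(config$thresholds, unclass),
      scan = config$scan, cnc = config$cnc,
      lnc_fc_min = config$lnc_fc_min, lnc_p_max = config$lnc_p_max,
      min_flagged_samples = config$min_flagged_samples,
      mirna_ref_min = config$mirna_ref_min,
      require_direction = config$require_direction),
    counts = list(
      genes_retained = map(norm, nrow),
      de = de_counts,
      predictions = list(mrna_pairs = nrow(preds$mrna),
                         mrna_passed = sum(preds$mrna$passed),
                         lncrna_pairs = nrow(preds$lncrna),
                         lncrna_passed = sum(preds$lncrna$passed)),
      cnc_edges = nrow(cnc),
      networks = imap(networks, function(nw, phase) {
        list(regulatory_edges = nrow(nw$edges), triplets = nrow(nw$triplets))
      })))
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(run$normalized)) {
    write_expression_table(run$normalized[[cl]],
                           file.path(dir, paste0(cl, "_normalized.tsv")))
  }
  tw <- function(x, f) write.table(as.data.frame(x), file.path(dir, f),
                                   sep = "\t", quote = FALSE, row.names = FALSE)
  for (phase in names(run$de)) {
    for (cl in names(run$de[[phase]])) {
      tw(run$de[[phase]][[cl]], sprintf("de_%s_%s.tsv", phase, cl))
    }
    tw(run$networks[[phase]]$edges, sprintf("edges_%s.tsv", phase))
    tw(run$networks[[phase]]$triplets, sprintf("triplets_%s.tsv", phase))
    if (nrow(run$networks[[phase]]$triplets)) {
      export_network(run$networks[[phase]]$triplets,
                     file.path(dir, sprintf("cerna_%s.graphml", phase)))
    }
  }
  tw(select(run$predictions$mrna, -"sites"), "predictions_mrna.tsv")
  tw(select(run$predictions$lncrna, -"sites"), "predictions_lncrna.tsv")
  tw(run$cnc, "cnc_edges.tsv")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

read_study_inputs <- function(inputs) {
  need <- c("mirna", "lncrna", "mrna")
  if (!all(need %in% names(inputs))) {
    abort("inputs must name mirna, lncrna and mrna expression TSVs")
  }
  tabs <- map(need, function(cl) {
    read_expression_table(inputs[[cl]], inputs[[paste0(cl, "_flags")]])
  })
  names(tabs) <- need
  seqs <- list(
    mirna = if (!is.null(inputs$mirna_fa)) read_fasta(inputs$mirna_fa),
    lncrna = if (!is.null(inputs$lncrna_fa)) read_fasta(inputs$lncrna_fa),
    utr3 = if (!is.null(inputs$utr_fa)) read_fasta(inputs$utr_fa))
  c(tabs, list(sample_info = sample_groups(tabs$mirna),
               sequences = seqs, truth = NULL))
}

#' @export
print.cernet_run <- function(x, ...) {
  cat("ceRNA pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @method glance cernet_run
#' @export
glance.cernet_run <- function(x, ...) {
  cnt <- x$manifest$counts
  phases <- names(cnt$networks)
  tibble(
    seed = x$manifest$seed,
    n_cnc_edges = cnt$cnc_edges,
    !!!setNames(map_int(phases, ~ cnt$networks[[.x]]$triplets),
                paste0("triplets_", phases)),
    !!!setNames(map_int(phases, ~ cnt$networks[[.x]]$regulatory_edges),
                paste0("edges_", phases)))
}

#' @method tidy cernet_run
#' @export
tidy.cernet_run <- function(x, ...) {
  cnt <- x$manifest$counts$de
  rows <- list()
  for (phase in names(cnt)) {
    for (cl in names(cnt[[phase]])) {
      rows[[length(rows) + 1L]] <- tibble(
        phase = phase, class = cl,
        n_genes = cnt[[phase]][[cl]]$n_genes,
        n_significant = cnt[[phase]][[cl]]$n_significant,
        n_up = cnt[[phase]][[cl]]$n_up,
        n_down = cnt[[phase]][[cl]]$n_down)
    }
  }
  list_rbind(rows)
}
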