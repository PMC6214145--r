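# Synthetic three-group expression study with planted ground truth:
# differential effects per RNA class, miRNA response elements written into
# transcript sequences, and sponge (ceRNA) triplets coupling a miRNA
# negatively to a lncRNA and an mRNA that are positively co-expressed.

#' Simulation configuration
#'
#' Defines a three-group (A = control, B = elicitation, C = remission)
#' expression study. Intensities are generated on the log2 scale as
#' baseline + planted effect + triplet coupling + Normal noise, then
#' exponentiated, so fold changes of planted effects are exact on the linear
#' scale.
#'
#' Planted sponge triplets contribute (i) opposite differential shifts to the
#' miRNA versus the lncRNA and mRNA in the triplet's phase and (ii) a shared
#' latent Normal factor with loadings (-k, +k, +k) on (miRNA, lncRNA, mRNA),
#' so the miRNA is anti-correlated with both partners while the lncRNA and
#' mRNA are positively co-expressed.
#'
#' @param n_per_group Replicates per group (default 4, a 12-array design).
#' @param n_mirna,n_lncrna,n_mrna Gene counts per RNA class.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 intensity
#'   distribution (defaults 8 and 1.5, typical array scale).
#' @param noise_sd Residual log2 standard deviation per cell.
#' @param de_spec Tibble of planted differential effects with columns
#'   `class` (mirna/lncrna/mrna), `gene_id`, `contrast` ("B" or "C"),
#'   `direction` ("up"/"down"), `log2fc` (positive magnitude). `NULL` = none.
#' @param triplet_spec Tibble of planted sponge triplets with columns
#'   `lncrna_id`, `mirna_id`, `mrna_id`, `phase` ("B"/"C"), `mir_direction`
#'   ("up"/"down"), `log2fc` (shift magnitude, default 3) and `k` (latent
#'   coupling loading, default 0.5). `NULL` = none.
#' @param mirna_len miRNA length in nt (19-24).
#' @param lnc_len,utr_len lncRNA and mRNA 3'UTR lengths in nt.
#' @param site_extent `"full"` plants the full reverse complement of the
#'   miRNA (site passes default pair-score/energy thresholds); `"8mer"`
#'   plants only the 8-nt seed site.
#' @param detection_floor Intensity below which a cell is flagged Absent.
#' @param seed Integer seed; fully determines all outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 4,
                       n_mirna = 50, n_lncrna = 150, n_mrna = 300,
                       baseline_mean = 8, baseline_sd = 1.5,
                       noise_sd = 0.25,
                       de_spec = NULL, triplet_spec = NULL,
                       mirna_len = 22, lnc_len = 400, utr_len = 300,
                       site_extent = c("full", "8mer"),
                       detection_floor = 30,
                       seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    n_mirna = as.integer(n_mirna), n_lncrna = as.integer(n_lncrna),
    n_mrna = as.integer(n_mrna),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    noise_sd = noise_sd,
    de_spec = if (!is.null(de_spec)) as_tibble(de_spec),
    triplet_spec = if (!is.null(triplet_spec)) as_tibble(triplet_spec),
    mirna_len = as.integer(mirna_len),
    lnc_len = as.integer(lnc_len), utr_len = as.integer(utr_len),
    site_extent = match.arg(site_extent),
    detection_floor = detection_floor,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

sim_gene_ids <- function(cfg) {
  list(mirna  = sprintf("mir_%04d", seq_len(cfg$n_mirna)),
       lncrna = sprintf("lnc_%04d", seq_len(cfg$n_lncrna)),
       mrna   = sprintf("mrna_%04d", seq_len(cfg$n_mrna)))
}

validate_sim_config <- function(cfg) {
  if (cfg$n_per_group <= 0) abort("n_per_group must be positive")
  if (any(c(cfg$n_mirna, cfg$n_lncrna, cfg$n_mrna) < 0)) {
    abort("gene counts must be non-negative")
  }
  if (cfg$noise_sd < 0 || cfg$baseline_sd < 0) abort("standard deviations must be >= 0")
  if (cfg$mirna_len < 19 || cfg$mirna_len > 24) abort("mirna_len must be 19-24 nt")
  if (cfg$lnc_len < 30 || cfg$utr_len < 30) abort("transcript lengths must be >= 30 nt")
  ids <- sim_gene_ids(cfg)
  ds <- cfg$de_spec
  if (!is.null(ds)) {
    stopifnot(all(c("class", "gene_id", "contrast", "direction", "log2fc") %in% names(ds)))
    for (cl in unique(ds$class)) {
      bad <- setdiff(ds$gene_id[ds$class == cl], ids[[cl]])
      if (length(bad)) abort(sprintf("de_spec: unknown %s gene id(s): %s",
                                     cl, paste(head(bad, 3), collapse = ", ")))
    }
    stopifnot(all(ds$contrast %in% c("B", "C")),
              all(ds$direction %in% c("up", "down")),
              all(ds$log2fc > 0))
  }
  ts <- cfg$triplet_spec
  if (!is.null(ts)) {
    stopifnot(all(c("lncrna_id", "mirna_id", "mrna_id") %in% names(ts)))
    bad <- c(setdiff(ts$lncrna_id, ids$lncrna), setdiff(ts$mirna_id, ids$mirna),
             setdiff(ts$mrna_id, ids$mrna))
    if (length(bad)) abort(sprintf("triplet_spec: unknown gene id(s): %s",
                                   paste(head(bad, 3), collapse = ", ")))
  }
  invisible(cfg)
}

# triplet_spec with defaults filled in
triplet_spec_full <- function(cfg) {
  ts <- cfg$triplet_spec
  if (is.null(ts) || nrow(ts) == 0) {
    return(tibble(lncrna_id = character(), mirna_id = character(),
                  mrna_id = character(), phase = character(),
                  mir_direction = character(), log2fc = numeric(),
                  k = numeric()))
  }
  if (!"phase" %in% names(ts)) ts$phase <- "B"
  if (!"mir_direction" %in% names(ts)) ts$mir_direction <- "up"
  if (!"log2fc" %in% names(ts)) ts$log2fc <- 3
  if (!"k" %in% names(ts)) ts$k <- 0.5
  ts
}

#' Simulate three-class expression matrices with planted truth
#'
#' Generates miRNA, lncRNA and mRNA expression tables for groups A/B/C along
#' with the ground truth of every planted differential effect and sponge
#' triplet. Detection flags mark a cell Absent when its intensity falls below
#' `detection_floor`.
#'
#' @param config A [sim_config()].
#' @return A list of class `cernet_sim` with elements `mirna`, `lncrna`,
#'   `mrna` (expression tables), `sample_info`, and `truth` (a list with
#'   `de_truth` and `triplet_truth` tibbles; `site_truth` is added by
#'   [simulate_sequences()]).
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_expression_impl(config))
}

simulate_expression_impl <- function(cfg) {
  n <- cfg$n_per_group
  groups <- rep(c("A", "B", "C"), each = n)
  sample_ids <- paste0(groups, rep(seq_len(n), times = 3))
  si <- tibble(sample_id = sample_ids, group = groups)
  ids <- sim_gene_ids(cfg)
  ts <- triplet_spec_full(cfg)

  # effect matrix per class: planted de_spec plus triplet-implied shifts
  de_truth <- cfg$de_spec %||%
    tibble(class = character(), gene_id = character(), contrast = character(),
           direction = character(), log2fc = numeric())
  if (nrow(ts)) {
    flip <- function(d) ifelse(d == "up", "down", "up")
    de_truth <- bind_rows(
      de_truth,
      tibble(class = "mirna", gene_id = ts$mirna_id, contrast = ts$phase,
             direction = ts$mir_direction, log2fc = ts$log2fc),
      tibble(class = "lncrna", gene_id = ts$lncrna_id, contrast = ts$phase,
             direction = flip(ts$mir_direction), log2fc = ts$log2fc),
      tibble(class = "mrna", gene_id = ts$mrna_id, contrast = ts$phase,
             direction = flip(ts$mir_direction), log2fc = ts$log2fc)
    )
  }
  de_truth <- distinct(de_truth, .data$class, .data$gene_id, .data$contrast,
                       .keep_all = TRUE)

  # latent factors: one N(0,1) draw per triplet per sample
  latent <- if (nrow(ts)) matrix(rnorm(nrow(ts) * length(sample_ids)),
                                 nrow = nrow(ts)) else NULL

  make_class <- function(cl) {
    g <- ids[[cl]]
    ng <- length(g)
    base <- rnorm(ng, cfg$baseline_mean, cfg$baseline_sd)
    log2m <- matrix(base, nrow = ng, ncol = length(sample_ids))
    dimnames(log2m) <- list(g, sample_ids)
    dt <- de_truth[de_truth$class == cl, ]
    if (nrow(dt)) {
      for (i in seq_len(nrow(dt))) {
        eff <- dt$log2fc[i] * ifelse(dt$direction[i] == "up", 1, -1)
        log2m[dt$gene_id[i], groups == dt$contrast[i]] <-
          log2m[dt$gene_id[i], groups == dt$contrast[i]] + eff
      }
    }
    if (nrow(ts)) {
      id_col <- switch(cl, mirna = "mirna_id", lncrna = "lncrna_id", mrna = "mrna_id")
      load_sign <- if (cl == "mirna") -1 else 1
      for (i in seq_len(nrow(ts))) {
        gid <- ts[[id_col]][i]
        log2m[gid, ] <- log2m[gid, ] + load_sign * ts$k[i] * latent[i, ]
      }
    }
    if (cfg$noise_sd > 0) {
      log2m <- log2m + matrix(rnorm(length(log2m), 0, cfg$noise_sd), nrow = ng)
    }
    vals <- 2^log2m
    flags <- ifelse(vals < cfg$detection_floor, "Absent", "Present")
    flag_tbl <- tibble(gene_id = g,
                       as_tibble(flags, .name_repair = "minimal"))
    expression_table(vals, gene_ids = g, sample_info = si, flags = flag_tbl)
  }

  out <- list(mirna = make_class("mirna"),
              lncrna = make_class("lncrna"),
              mrna = make_class("mrna"),
              sample_info = si,
              truth = list(de_truth = de_truth, triplet_truth = ts),
              config = cfg)
  class(out) <- "cernet_sim"
  out
}

#' Simulate RNA sequences and plant miRNA response elements
#'
#' Draws random RNA sequences (miRNAs start with U, the most common 5'
#' nucleotide) and, for every planted triplet, writes a binding site for the
#' triplet's miRNA into both the lncRNA and the mRNA 3'UTR at a recorded
#' position. With `site_extent = "full"` (the default) the written site is
#' the reverse complement of miRNA positions 2..L followed by an A facing
#' position 1, so the site carries full-length complementarity; `"8mer"`
#' writes only the canonical 8-nt seed site. `site_truth` always records the
#' 0-based half-open span of the 8mer seed site.
#'
#' @param config A [sim_config()].
#' @param sim Optionally, the result of [simulate_expression()]; its truth
#'   table is extended in place.
#' @return A list with named character vectors `mirna`, `lncrna`, `utr3` and
#'   the `site_truth` tibble (columns `mirna_id`, `target_id`, `start`,
#'   `end`, `site_seq`). If `sim` is given, it is returned with `$sequences`
#'   and `$truth$site_truth` filled in.
#' @export
simulate_sequences <- function(config, sim = NULL) {
  validate_sim_config(config)
  res <- withr::with_seed(config$seed + 104729L, simulate_sequences_impl(config))
  if (is.null(sim)) return(res)
  sim$sequences <- res[c("mirna", "lncrna", "utr3")]
  sim$truth$site_truth <- res$site_truth
  sim
}

random_rna <- function(n, len, prefix = NULL) {
  out <- vapply(seq_len(n), function(i) {
    body <- paste(sample(c("A", "C", "G", "U"), len - length(prefix),
                         replace = TRUE), collapse = "")
    paste0(paste(prefix, collapse = ""), body)
  }, character(1))
  out
}

simulate_sequences_impl <- function(cfg) {
  ids <- sim_gene_ids(cfg)
  mir <- setNames(random_rna(cfg$n_mirna, cfg$mirna_len, prefix = "U"), ids$mirna)
  lnc <- setNames(random_rna(cfg$n_lncrna, cfg$lnc_len), ids$lncrna)
  utr <- setNames(random_rna(cfg$n_mrna, cfg$utr_len), ids$mrna)
  ts <- triplet_spec_full(cfg)
  site_truth <- tibble(mirna_id = character(), target_id = character(),
                       start = integer(), end = integer(), site_seq = character())
  if (nrow(ts)) {
    used <- list()  # occupied spans per host, to keep planted sites disjoint
    for (i in seq_len(nrow(ts))) {
      for (host in c("lncrna", "mrna")) {
        tid <- if (host == "lncrna") ts$lncrna_id[i] else ts$mrna_id[i]
        seqs <- if (host == "lncrna") lnc else utr
        planted <- plant_mre_site(seqs[[tid]], mir[[ts$mirna_id[i]]],
                                  extent = cfg$site_extent,
                                  avoid = used[[tid]])
        if (host == "lncrna") lnc[[tid]] <- planted$seq else utr[[tid]] <- planted$seq
        used[[tid]] <- rbind(used[[tid]], planted$span)
        site_truth <- bind_rows(site_truth, tibble(
          mirna_id = ts$mirna_id[i], target_id = tid,
          start = planted$site_start, end = planted$site_end,
          site_seq = substr(planted$seq, planted$site_start + 1L, planted$site_end)))
      }
    }
  }
  list(mirna = mir, lncrna = lnc, utr3 = utr, site_truth = site_truth)
}

#' Write an 8mer binding site for a miRNA into a host transcript
#'
#' @param target_seq Host RNA sequence (5'->3').
#' @param mirna_seq miRNA sequence (5'->3').
#' @param offset 0-based position at which the written block starts; random
#'   if `NULL`.
#' @param extent `"full"` writes the reverse complement of miRNA positions
#'   2..L plus a 3' A (block length = miRNA length); `"8mer"` writes the
#'   8-nt seed site only (reverse complement of positions 2-8 plus a 3' A).
#' @param avoid Optional matrix of occupied (start, end) spans to avoid when
#'   choosing a random offset.
#' @return A list: `seq` (modified host), `site_start`/`site_end` (0-based
#'   half-open span of the 8mer site), `span` (the written block).
#' @export
plant_mre_site <- function(target_seq, mirna_seq, offset = NULL,
                           extent = c("full", "8mer"), avoid = NULL) {
  extent <- match.arg(extent)
  mirna_seq <- clean_rna(mirna_seq, "mirna")
  target_seq <- clean_rna(target_seq, "target")
  L <- nchar(mirna_seq)
  block <- if (extent == "8mer") {
    paste0(rc_rna(substr(mirna_seq, 2, 8)), "A")
  } else {
    paste0(rc_rna(substr(mirna_seq, 2, L)), "A")
  }
  blen <- nchar(block)
  tlen <- nchar(target_seq)
  if (blen > tlen) abort("planted site is longer than the host sequence")
  if (is.null(offset)) {
    starts <- 0:(tlen - blen)
    if (!is.null(avoid) && nrow(avoid)) {
      ok <- vapply(starts, function(s) all(s + blen <= avoid[, 1] | s >= avoid[, 2]),
                   logical(1))
      starts <- starts[ok]
      if (!length(starts)) abort("no room left to plant a disjoint site")
    }
    offset <- if (length(starts) == 1) starts else sample(starts, 1)
  }
  if (offset < 0 || offset + blen > tlen) {
    abort("planted site does not fit in the host sequence at this offset")
  }
  seq_out <- paste0(substr(target_seq, 1, offset), block,
                    substr(target_seq, offset + blen + 1L, tlen))
  # 8mer seed site = last 8 nt of the written block
  list(seq = seq_out,
       site_start = offset + blen - 8L,
       site_end = offset + blen,
       span = matrix(c(offset, offset + blen), nrow = 1))
}

#' Write a named set of RNA sequences as FASTA
#' @param seqs Named character vector of RNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector of RNA (T mapped to U)
#' @param path FASTA path.
#' @return Named character vector, upper case, RNA alphabet.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- chartr("Tt", "Uu", toupper(as.character(ss)))
  setNames(out, names(ss))
}

#' Write all simulation outputs to a directory
#'
#' Writes the three expression tables (with flag tables), FASTA sequence
#' sets, and the truth tables as TSV.
#'
#' @param sim Result of [simulate_expression()] (after
#'   [simulate_sequences()] if sequences are wanted).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in c("mirna", "lncrna", "mrna")) {
    write_expression_table(sim[[cl]],
                           file.path(dir, paste0(cl, "_expression.tsv")),
                           file.path(dir, paste0(cl, "_flags.tsv")))
  }
  tw <- function(x, f) write.table(as.data.frame(x), file.path(dir, f),
                                   sep = "\t", quote = FALSE, row.names = FALSE)
  tw(sim$truth$de_truth, "de_truth.tsv")
  tw(sim$truth$triplet_truth, "triplet_truth.tsv")
  if (!is.null(sim$sequences)) {
    write_fasta(sim$sequences$mirna, file.path(dir, "mirna.fa"))
    write_fasta(sim$sequences$lncrna, file.path(dir, "lncrna.fa"))
    write_fasta(sim$sequences$utr3, file.path(dir, "mrna_3utr.fa"))
    tw(sim$truth$site_truth, "site_truth.tsv")
  }
  invisible(dir)
}

#' A scaled-down three-phase study design with planted sponge triplets
#'
#' Convenience configuration emulating an atopic-dermatitis-like recurrence
#' design at desk scale: a massive elicitation (B vs A) response, a sparse
#' remission (C vs A) response, and a handful of planted ceRNA triplets in
#' each phase.
#'
#' @param seed Integer seed.
#' @param n_per_group Replicates per group.
#' @param n_triplets_elicitation,n_triplets_remission Planted triplet counts.
#' @param noise_sd Residual log2 SD.
#' @param k Latent coupling loading.
#' @param triplet_log2fc Shift magnitude for triplet members.
#' @return A [sim_config()].
#' @export
demo_config <- function(seed = 1L, n_per_group = 4,
                        n_triplets_elicitation = 5, n_triplets_remission = 3,
                        noise_sd = 0.25, k = 0.5, triplet_log2fc = 3) {
  n_mirna <- 50; n_lncrna <- 150; n_mrna <- 300
  ids <- list(mirna = sprintf("mir_%04d", 1:n_mirna),
              lncrna = sprintf("lnc_%04d", 1:n_lncrna),
              mrna = sprintf("mrna_%04d", 1:n_mrna))
  nt <- n_triplets_elicitation + n_triplets_remission
  ts <- tibble(
    lncrna_id = ids$lncrna[seq_len(nt)],
    mirna_id = ids$mirna[seq_len(nt)],
    mrna_id = ids$mrna[seq_len(nt)],
    phase = rep(c("B", "C"), c(n_triplets_elicitation, n_triplets_remission)),
    mir_direction = "up", log2fc = triplet_log2fc, k = k)
  # phase asymmetry: many B-phase effects, few C-phase, outside triplet genes
  de_rows <- function(class, pool, n_b, n_c) {
    pool_b <- pool[nt + seq_len(n_b)]
    pool_c <- pool[nt + n_b + seq_len(n_c)]
    bind_rows(
      tibble(class = class, gene_id = pool_b, contrast = "B",
             direction = rep(c("up", "down"), length.out = n_b), log2fc = 2),
      tibble(class = class, gene_id = pool_c, contrast = "C",
             direction = rep(c("up", "down"), length.out = n_c), log2fc = 2))
  }
  de <- bind_rows(de_rows("mirna", ids$mirna, 10, 2),
                  de_rows("lncrna", ids$lncrna, 40, 6),
                  de_rows("mrna", ids$mrna, 80, 10))
  sim_config(n_per_group = n_per_group, n_mirna = n_mirna,
             n_lncrna = n_lncrna, n_mrna = n_mrna,
             noise_sd = noise_sd, de_spec = de, triplet_spec = ts,
             seed = seed)
}
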