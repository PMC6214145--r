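# Independent reference implementations used as oracles, plus small fixture
# builders. These deliberately use different constructions than the package
# code they check.

rc_chr <- function(s) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

random_rna_str <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# direct Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  q_sorted <- rev(cummin(rev(sp * m / seq_len(m))))
  q_sorted <- pmin(1, q_sorted)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# whole-site string comparison scan: builds the four expected site strings
# from the miRNA and compares complete target substrings, then keeps the
# top-ranked type per anchor
seed_scan_oracle <- function(mir, tgt) {
  s6 <- rc_chr(substr(mir, 2, 7))
  s7m8 <- rc_chr(substr(mir, 2, 8))
  s7a1 <- paste0(s6, "A")
  s8 <- paste0(s7m8, "A")
  L <- nchar(tgt)
  rows <- list()
  for (a in 0:(L - 6)) {                      # 0-based anchor of the 6mer core
    row <- if (a >= 1 && a + 7 <= L && substr(tgt, a, a + 7) == s8) {
      tibble::tibble(start = a - 1L, end = a + 7L, site_type = "8mer")
    } else if (a >= 1 && substr(tgt, a, a + 6) == s7m8) {
      tibble::tibble(start = a - 1L, end = a + 6L, site_type = "7mer-m8")
    } else if (a + 7 <= L && substr(tgt, a + 1, a + 7) == s7a1) {
      tibble::tibble(start = a, end = a + 7L, site_type = "7mer-A1")
    } else if (substr(tgt, a + 1, a + 6) == s6) {
      tibble::tibble(start = a, end = a + 6L, site_type = "6mer")
    }
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          site_type = character()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), start, end)
}

# local complementarity alignment via Biostrings with the same scoring
# scheme (WC +5, G:U wobble +2, mismatch -3, linear gap -8), floored at 0
pair_score_oracle <- function(mir, tgt) {
  bases <- c("A", "C", "G", "T")            # U mapped to T for Biostrings
  mat <- matrix(-3, 4, 4, dimnames = list(bases, bases))
  wc <- list(c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G"))
  for (p in wc) mat[p[1], p[2]] <- 5
  mat["G", "T"] <- 2                         # target G : miRNA U
  mat["T", "G"] <- 2
  tgt_dna <- chartr("U", "T", tgt)
  mir_rev_dna <- chartr("U", "T",
                        paste(rev(strsplit(mir, "")[[1]]), collapse = ""))
  aln <- Biostrings::pairwiseAlignment(
    pattern = tgt_dna, subject = mir_rev_dna, type = "local",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 8)
  max(0, Biostrings::score(aln))
}

# tiny expression table from a matrix, with A/B/... groups
expr_fixture <- function(m, groups = NULL, flags = NULL) {
  if (is.null(rownames(m)) && nrow(m) > 0) {
    rownames(m) <- paste0("g", seq_len(nrow(m)))
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  si <- if (!is.null(groups)) {
    tibble::tibble(sample_id = colnames(m), group = groups)
  }
  fl <- if (!is.null(flags)) {
    colnames(flags) <- colnames(m)
    tibble::tibble(gene_id = rownames(m),
                   tibble::as_tibble(flags, .name_repair = "minimal"))
  }
  expression_table(m, sample_info = si, flags = fl)
}

`%iff%` <- function(a, b) if (is.null(a)) b else a

triplet_recovery_config <- function(seed, n_triplets = 10, k = 1,
                                    log2fc = 4, noise_sd = 0.05) {
  ids <- function(p, n) sprintf("%s_%04d", p, seq_len(n))
  ts <- tibble::tibble(
    lncrna_id = ids("lnc", 100)[seq_len(n_triplets)],
    mirna_id = ids("mir", 30)[seq_len(n_triplets)],
    mrna_id = ids("mrna", 300)[seq_len(n_triplets)],
    phase = "B",
    mir_direction = rep(c("up", "down"), length.out = n_triplets),
    log2fc = log2fc, k = k)
  sim_config(n_mirna = 30, n_lncrna = 100, n_mrna = 300,
             noise_sd = noise_sd, triplet_spec = ts, seed = seed)
}

triplet_key <- function(x) paste(x$lncrna_id, x$mirna_id, x$mrna_id)
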