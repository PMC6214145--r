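# miRNA response element (MRE) prediction: canonical seed-site scanning
# (8mer / 7mer-m8 / 7mer-A1 / 6mer taxonomy) combined with an alignment
# "pair score" over the full miRNA and an additive per-base-pair duplex
# energy proxy. A site passes only when the seed match, the pair score and
# the energy criterion all hold (intersection-of-evidence rule).

RNA_ALPHABET <- c("A", "C", "G", "U")

clean_rna <- function(seq, what = "sequence") {
  if (length(seq) != 1 || is.na(seq)) abort(sprintf("%s must be a single string", what))
  s <- chartr("Tt", "Uu", toupper(seq))
  if (grepl("[^ACGU]", s)) {
    abort(sprintf("%s contains non-RNA characters: %s", what,
                  gsub("[ACGU]", "", s)))
  }
  s
}

rc_rna <- function(seq) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

comp_rna <- function(base) chartr("ACGU", "UGCA", base)

#' Scan a transcript for canonical miRNA seed sites
#'
#' Reports every target window whose sequence is the reverse complement of
#' miRNA positions 2-7 (the 6mer seed core), classified by the canonical
#' site taxonomy: extended by a match to miRNA position 8 (7mer-m8), by an A
#' opposite miRNA position 1 (7mer-A1), or both (8mer). For each anchor
#' position only the highest-ranking type is reported
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer); sites at distinct anchors are all kept.
#'
#' @param mirna_seq miRNA sequence, 5'->3', >= 8 nt (T accepted for U).
#' @param target_seq Transcript sequence, 5'->3', >= 6 nt.
#' @return A tibble with one row per site: `start`, `end` (0-based half-open
#'   span on the target), `site_type`.
#' @export
find_seed_sites <- function(mirna_seq, target_seq) {
  mir <- clean_rna(mirna_seq, "mirna_seq")
  tgt <- clean_rna(target_seq, "target_seq")
  if (nchar(mir) < 8) abort("miRNA must be at least 8 nt")
  if (nchar(tgt) < 6) abort("target must be at least 6 nt")
  core <- rc_rna(substr(mir, 2, 7))
  m8c <- comp_rna(substr(mir, 8, 8))
  L <- nchar(tgt)
  starts <- seq_len(L - 5L)                       # 1-based anchor candidates
  windows <- substring(tgt, starts, starts + 5L)
  anchors <- starts[windows == core]
  if (!length(anchors)) {
    return(tibble(start = integer(), end = integer(), site_type = character()))
  }
  tchar <- strsplit(tgt, "")[[1]]
  rows <- lapply(anchors, function(i) {
    a <- i - 1L                                   # 0-based start of the core
    has_m8 <- i > 1L && tchar[i - 1L] == m8c
    has_a1 <- (i + 6L) <= L && tchar[i + 6L] == "A"
    if (has_m8 && has_a1) {
      tibble(start = a - 1L, end = a + 7L, site_type = "8mer")
    } else if (has_m8) {
      tibble(start = a - 1L, end = a + 6L, site_type = "7mer-m8")
    } else if (has_a1) {
      tibble(start = a, end = a + 7L, site_type = "7mer-A1")
    } else {
      tibble(start = a, end = a + 6L, site_type = "6mer")
    }
  })
  arrange(list_rbind(rows), .data$start, .data$end)
}

# complementarity score between a target base and a miRNA base:
# Watson-Crick +5, G:U wobble +2, otherwise -3
pair_match_score <- function(t, m, match = 5, wobble = 2, mismatch = -3) {
  wc <- (t == "A" & m == "U") | (t == "U" & m == "A") |
        (t == "G" & m == "C") | (t == "C" & m == "G")
  gu <- (t == "G" & m == "U") | (t == "U" & m == "G")
  ifelse(wc, match, ifelse(gu, wobble, mismatch))
}

# Smith-Waterman local alignment of a target window (5'->3') against the
# reversed miRNA so that aligned positions are antiparallel base pairs.
# Linear gap penalty; returns best score (floored at 0) and the aligned
# base pairs from the traceback.
sw_complementarity <- function(window_chars, mir_rev_chars,
                               match = 5, wobble = 2, mismatch = -3, gap = -8) {
  n <- length(window_chars); m <- length(mir_rev_chars)
  H <- matrix(0, n + 1L, m + 1L)
  P <- matrix(0L, n + 1L, m + 1L)  # 0 stop, 1 diag, 2 up(gap in mirna), 3 left
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    ti <- window_chars[i]
    for (j in seq_len(m)) {
      s <- pair_match_score(ti, mir_rev_chars[j], match, wobble, mismatch)
      diag <- H[i, j] + s
      up <- H[i, j + 1L] + gap
      left <- H[i + 1L, j] + gap
      v <- max(0, diag, up, left)
      H[i + 1L, j + 1L] <- v
      P[i + 1L, j + 1L] <- if (v == 0) 0L else if (v == diag) 1L else if (v == up) 2L else 3L
      if (v > best) { best <- v; bi <- i; bj <- j }
    }
  }
  pairs <- tibble(target_pos = integer(), mirna_pos = integer(),
                  target_base = character(), mirna_base = character())
  if (best > 0) {
    i <- bi; j <- bj; tp <- integer(); mp <- integer()
    while (i > 0 && j > 0 && P[i + 1L, j + 1L] != 0L) {
      d <- P[i + 1L, j + 1L]
      if (d == 1L) { tp <- c(i, tp); mp <- c(j, mp); i <- i - 1L; j <- j - 1L }
      else if (d == 2L) i <- i - 1L
      else j <- j - 1L
    }
    pairs <- tibble(target_pos = tp, mirna_pos = mp,
                    target_base = window_chars[tp], mirna_base = mir_rev_chars[mp])
  }
  list(score = best, pairs = pairs)
}

site_window <- function(target, site_end, window) {
  w_start <- max(0L, site_end - window)           # 0-based half-open
  substr(target, w_start + 1L, site_end)
}

#' Alignment pair score of a predicted site
#'
#' Scores the antiparallel complementarity between the full miRNA and the
#' target window of `window` nt ending at the site's 3' edge, by local
#' alignment with Watson-Crick match +5, G:U wobble +2, mismatch -3 and a
#' linear gap penalty of -8. The local-alignment floor is 0.
#'
#' @param mirna_seq miRNA sequence 5'->3'.
#' @param target_seq Target sequence 5'->3'.
#' @param site A one-row tibble or list with `start` and `end` (0-based
#'   half-open), as returned by [find_seed_sites()].
#' @param window Window length in nt (default 30).
#' @return The alignment score (numeric scalar).
#' @export
pair_score <- function(mirna_seq, target_seq, site, window = 30) {
  score_site(mirna_seq, target_seq, site, window)$pair_score
}

#' Pair score and duplex energy of one site
#'
#' @inheritParams pair_score
#' @return A list with `pair_score`, `energy`, and the aligned base `pairs`.
#' @export
score_site <- function(mirna_seq, target_seq, site, window = 30) {
  mir <- clean_rna(mirna_seq, "mirna_seq")
  tgt <- clean_rna(target_seq, "target_seq")
  if (site$end > nchar(tgt) || site$start < 0) abort("site span outside target")
  if (window < 6) abort("window shorter than the seed region")
  win <- site_window(tgt, site$end, window)
  aln <- sw_complementarity(strsplit(win, "")[[1]],
                            rev(strsplit(mir, "")[[1]]))
  list(pair_score = aln$score,
       energy = duplex_energy(aln$pairs),
       pairs = aln$pairs)
}

#' Additive duplex energy proxy
#'
#' Sums a per-base-pair stability proxy over the aligned pairs of a duplex:
#' G:C -3.0, A:U -2.0, G:U -1.0 kcal/mol; aligned mismatches and unpaired
#' positions contribute 0. This is a deliberately simple additive stand-in
#' for a thermodynamic folding energy, chosen so the stage is exactly
#' testable.
#'
#' @param pairs Either a data frame with columns `target_base` and
#'   `mirna_base`, or a character vector of two-letter pairs (e.g. `"GC"`).
#' @return Total energy in kcal/mol (<= 0).
#' @export
duplex_energy <- function(pairs) {
  if (is.data.frame(pairs)) {
    if (nrow(pairs) == 0) return(0)
    a <- pairs$target_base; b <- pairs$mirna_base
  } else {
    if (length(pairs) == 0) return(0)
    if (any(nchar(pairs) != 2)) abort("pairs must be two-letter base pairs")
    a <- substr(pairs, 1, 1); b <- substr(pairs, 2, 2)
  }
  if (!all(c(a, b) %in% RNA_ALPHABET)) abort("invalid base symbol in pairs")
  key <- paste0(pmin(a, b), pmax(a, b))
  e <- c("CG" = -3, "AU" = -2, "GU" = -1)
  sum(e[key], na.rm = TRUE)
}

#' Predict miRNA targets by seed match plus alignment scoring
#'
#' For every (miRNA, transcript) pair, finds canonical seed sites and scores
#' each with [pair_score()] and [duplex_energy()]. A prediction passes when
#' at least one of its sites both scores `>= s_min` and has energy
#' `<= e_max` — seed evidence and score evidence must agree on the same
#' site.
#'
#' @param mirnas Named character vector of miRNA sequences, or a FASTA path.
#' @param transcripts Named character vector of target sequences, or a FASTA
#'   path.
#' @param s_min Minimum pair score (default 80).
#' @param e_max Maximum (most positive) energy in kcal/mol (default -14).
#' @param window Alignment window length (default 30).
#' @return A tibble with one row per (miRNA, target) pair that has at least
#'   one seed site: `mirna_id`, `target_id`, `n_sites`, `best_pair_score`,
#'   `best_energy`, `passed`, and a `sites` list-column of per-site tibbles
#'   (`start`, `end`, `site_type`, `pair_score`, `energy`, `site_passed`).
#' @export
predict_targets <- function(mirnas, transcripts, s_min = 80, e_max = -14,
                            window = 30) {
  mirnas <- as_seq_set(mirnas, "mirnas")
  transcripts <- as_seq_set(transcripts, "transcripts")
  clash <- intersect(names(mirnas), names(transcripts))
  if (length(clash)) {
    abort(sprintf("id collision between miRNA and transcript sets: %s",
                  paste(head(clash, 3), collapse = ", ")))
  }
  # precompute 6mer windows per transcript once; anchor lookup per miRNA
  tchars <- lapply(transcripts, function(s) strsplit(s, "")[[1]])
  twins <- lapply(transcripts, function(s) {
    L <- nchar(s)
    if (L < 6) return(character())
    substring(s, seq_len(L - 5L), seq_len(L - 5L) + 5L)
  })
  out <- list()
  for (mid in names(mirnas)) {
    mir <- mirnas[[mid]]
    core <- rc_rna(substr(mir, 2, 7))
    m8c <- comp_rna(substr(mir, 8, 8))
    mir_rev <- rev(strsplit(mir, "")[[1]])
    for (tid in names(transcripts)) {
      anchors <- which(twins[[tid]] == core)
      if (!length(anchors)) next
      tgt <- transcripts[[tid]]
      tc <- tchars[[tid]]
      L <- length(tc)
      sites <- list_rbind(lapply(anchors, function(i) {
        a <- i - 1L
        has_m8 <- i > 1L && tc[i - 1L] == m8c
        has_a1 <- (i + 6L) <= L && tc[i + 6L] == "A"
        if (has_m8 && has_a1) tibble(start = a - 1L, end = a + 7L, site_type = "8mer")
        else if (has_m8) tibble(start = a - 1L, end = a + 6L, site_type = "7mer-m8")
        else if (has_a1) tibble(start = a, end = a + 7L, site_type = "7mer-A1")
        else tibble(start = a, end = a + 6L, site_type = "6mer")
      }))
      scored <- lapply(seq_len(nrow(sites)), function(r) {
        win <- site_window(tgt, sites$end[r], window)
        aln <- sw_complementarity(strsplit(win, "")[[1]], mir_rev)
        c(pair_score = aln$score, energy = duplex_energy(aln$pairs))
      })
      sites$pair_score <- vapply(scored, `[[`, numeric(1), "pair_score")
      sites$energy <- vapply(scored, `[[`, numeric(1), "energy")
      sites$site_passed <- sites$pair_score >= s_min & sites$energy <= e_max
      out[[length(out) + 1L]] <- tibble(
        mirna_id = mid, target_id = tid, n_sites = nrow(sites),
        best_pair_score = max(sites$pair_score),
        best_energy = min(sites$energy),
        passed = any(sites$site_passed),
        sites = list(sites))
    }
  }
  if (!length(out)) {
    return(tibble(mirna_id = character(), target_id = character(),
                  n_sites = integer(), best_pair_score = numeric(),
                  best_energy = numeric(), passed = logical(),
                  sites = list()))
  }
  list_rbind(out)
}

as_seq_set <- function(x, what) {
  if (is.character(x) && length(x) == 1 && is.null(names(x)) && file.exists(x)) {
    x <- read_fasta(x)
  }
  if (length(x) == 0) return(setNames(character(), character()))
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    abort(sprintf("%s must be uniquely named sequences or a FASTA path", what))
  }
  vapply(x, clean_rna, character(1), what = what)
}
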