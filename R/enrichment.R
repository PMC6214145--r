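# Gene-set over-representation with the hypergeometric upper tail, for
# GO/KEGG-style term collections supplied as GMT files.

#' Read gene sets from a GMT file
#'
#' @param path GMT path (term, description, member genes per line).
#' @return A tibble: `term_id`, `term_name`, `members` (list-column).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  desc <- vapply(strsplit(readLines(path), "\t", fixed = TRUE),
                 function(f) f[2], character(1))
  tibble(term_id = names(sets), term_name = unname(desc),
         members = unname(sets))
}

#' Write gene sets to a GMT file
#'
#' @param sets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$term_id[i], sets$term_name[i], sets$members[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation
#'
#' Per term, the upper-tail hypergeometric probability of drawing at least
#' the observed overlap: population = universe, successes = term members in
#' the universe, draws = query size. Terms are BH-adjusted across the
#' collection; the enrichment score is -log10(p). Output is ordered by p
#' then term id for determinism.
#'
#' @param query Character vector of genes of interest (must lie in
#'   `universe`).
#' @param universe Character vector of background genes.
#' @param sets A tibble as from [read_gmt()], or a named list of member
#'   vectors.
#' @param p_max Significance cutoff on the raw p (default 0.05).
#' @return A tibble: `term_id`, `term_name`, `set_size`, `overlap`, `p`,
#'   `q`, `score`, `significant`.
#' @export
hypergeometric_enrichment <- function(query, universe, sets, p_max = 0.05) {
  query <- unique(query); universe <- unique(universe)
  stray <- setdiff(query, universe)
  if (length(stray)) {
    abort(sprintf("query gene(s) absent from the universe: %s",
                  paste(head(stray, 5), collapse = ", ")))
  }
  if (!is.data.frame(sets)) {
    sets <- tibble(term_id = names(sets), term_name = names(sets),
                   members = unname(sets))
  }
  N <- length(universe); n_draw <- length(query)
  rows <- lapply(seq_len(nrow(sets)), function(i) {
    memb <- intersect(sets$members[[i]], universe)
    K <- length(memb)
    k <- length(intersect(query, memb))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE)
    tibble(term_id = sets$term_id[i], term_name = sets$term_name[i],
           set_size = K, overlap = k, p = p)
  })
  out <- list_rbind(rows) |>
    mutate(q = bh_fdr(.data$p), score = -log10(.data$p),
           significant = .data$p <= p_max) |>
    arrange(.data$p, .data$term_id)
  structure(out, class = c("cernet_enrichment", class(out)))
}
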