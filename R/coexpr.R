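# Coding--non-coding co-expression (CNC): Pearson correlation between every
# (non-coding, coding) gene pair over shared samples, with a t-approximation
# p-value and BH FDR over the full family of tested pairs.

#' Pearson correlation coefficient between two profiles
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return The product-moment correlation r.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("zero variance input")
  cor(x, y)
}

#' Two-sided p-value for a correlation coefficient
#'
#' Uses the t transformation t = r * sqrt(n-2) / sqrt(1-r^2) with n-2
#' degrees of freedom; |r| = 1 maps to p = 0.
#'
#' @param r Correlation coefficient in [-1, 1].
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p-value.
#' @export
correlation_test <- function(r, n) {
  if (any(n < 3)) abort("n must be at least 3")
  if (any(abs(r) > 1 + 1e-12)) abort("|r| cannot exceed 1")
  dm <- dim(r)
  r <- pmin(1, pmax(-1, as.vector(r)))
  p <- ifelse(abs(r) >= 1, 0, {
    t <- r * sqrt(n - 2) / sqrt(pmax(0, 1 - r^2))
    2 * pt(-abs(t), n - 2)
  })
  if (!is.null(dm)) dim(p) <- dm
  p
}

#' Coding--non-coding co-expression network
#'
#' Correlates every non-coding gene against every coding gene over their
#' shared samples (log2 intensities), adjusts the p-values across all tested
#' pairs by Benjamini-Hochberg, and retains pairs with `|r| >= pcc_min` and
#' `q < fdr_max`. Defaults follow the stringent array-CNC convention:
#' |PCC| >= 0.995 and FDR < 0.05. The sign of r is kept on each edge for
#' downstream direction rules. Constant genes are skipped with a warning.
#'
#' @param nc An expression table of non-coding genes (e.g. lncRNAs).
#' @param coding An expression table of coding genes, same samples in the
#'   same order.
#' @param pcc_min Minimum |r|.
#' @param fdr_max FDR cutoff (strict `<`).
#' @param groups Optional character vector of group labels; when given, only
#'   samples in those groups are used (requires sample metadata).
#' @param log2_values Correlate log2 intensities (default TRUE).
#' @return A tibble of retained edges: `ncrna_id`, `coding_id`, `r`, `p`,
#'   `q`, sorted by q then |r| descending; the number of tested pairs is in
#'   the `n_tested` attribute and the sample count in `n_samples`.
#' @export
cnc_network <- function(nc, coding, pcc_min = 0.995, fdr_max = 0.05,
                        groups = NULL, log2_values = TRUE) {
  validate_expression(nc)
  validate_expression(coding)
  m1 <- expr_matrix(nc); m2 <- expr_matrix(coding)
  if (!identical(colnames(m1), colnames(m2))) {
    abort("the two matrices must share the same samples in the same order")
  }
  if (!is.null(groups)) {
    si <- sample_groups(nc) %||% sample_groups(coding)
    if (is.null(si)) abort("group filtering needs sample metadata")
    keep <- si$sample_id[si$group %in% groups]
    m1 <- m1[, keep, drop = FALSE]; m2 <- m2[, keep, drop = FALSE]
  }
  n <- ncol(m1)
  if (n < 3) abort("need at least 3 shared samples")
  if (log2_values) { m1 <- log2(m1); m2 <- log2(m2) }
  const1 <- apply(m1, 1, stats::sd) == 0
  const2 <- apply(m2, 1, stats::sd) == 0
  if (any(const1) || any(const2)) {
    warn(sprintf("skipping %d constant gene(s) with undefined correlation",
                 sum(const1) + sum(const2)))
    m1 <- m1[!const1, , drop = FALSE]; m2 <- m2[!const2, , drop = FALSE]
  }
  if (nrow(m1) == 0 || nrow(m2) == 0) {
    out <- tibble(ncrna_id = character(), coding_id = character(),
                  r = numeric(), p = numeric(), q = numeric())
    attr(out, "n_tested") <- 0L
    return(out)
  }
  R <- cor(t(m1), t(m2))                  # nc x coding
  P <- correlation_test(R, n)
  Q <- matrix(bh_fdr(as.vector(P)), nrow = nrow(P))
  keep <- abs(R) >= pcc_min & Q < fdr_max
  idx <- which(keep, arr.ind = TRUE)
  out <- tibble(ncrna_id = rownames(R)[idx[, 1]],
                coding_id = colnames(R)[idx[, 2]],
                r = R[keep], p = P[keep], q = Q[keep]) |>
    arrange(.data$q, dplyr::desc(abs(.data$r)), .data$ncrna_id, .data$coding_id)
  attr(out, "n_tested") <- length(R)
  attr(out, "n_samples") <- n
  out
}
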