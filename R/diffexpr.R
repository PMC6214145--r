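# Per-gene two-group testing and fold-change calling. Fold change is the
# ratio of linear-scale group means (array convention); the test is a Welch
# unequal-variance t on log2 intensities with a small variance floor so
# degenerate zero-variance fixtures stay defined.

#' Differential-expression thresholds per RNA class
#'
#' Canonical cutoffs: fold change > 1.5 with p <= 0.05 for miRNAs, fold
#' change > 2.0 with p <= 0.05 for lncRNAs and mRNAs. `strict_fc` controls
#' whether the fold-change comparison is strict (`>`) or inclusive (`>=`);
#' `strict_p` likewise for the p-value cutoff (default inclusive, `<=`).
#'
#' @param class One of `"mirna"`, `"lncrna"`, `"mrna"`.
#' @param fc_min Linear fold-change cutoff (> 1).
#' @param p_max p-value cutoff.
#' @param strict_fc,strict_p Strictness of the two comparisons.
#' @return A list of class `de_thresholds`.
#' @export
de_thresholds <- function(class = c("mrna", "lncrna", "mirna"),
                          fc_min = NULL, p_max = 0.05,
                          strict_fc = TRUE, strict_p = FALSE) {
  class <- match.arg(class)
  fc_min <- fc_min %||% if (class == "mirna") 1.5 else 2.0
  if (fc_min <= 1) abort("fc_min must exceed 1")
  if (p_max <= 0 || p_max > 1) abort("p_max must be in (0, 1]")
  structure(list(class = class, fc_min = fc_min, p_max = p_max,
                 strict_fc = strict_fc, strict_p = strict_p),
            class = "de_thresholds")
}

#' Linear-scale fold change between two groups
#'
#' @param ref_values,test_values Strictly positive intensities.
#' @return A one-row tibble: `fc` (mean(test)/mean(ref)), `log2fc`,
#'   `direction` (`up`/`down`/`none`), and `n_fold` (the magnitude,
#'   1/fc for down-regulation, so "4-fold down" reads as 4).
#' @export
fold_change <- function(ref_values, test_values) {
  if (!length(ref_values) || !length(test_values)) abort("empty group")
  if (any(c(ref_values, test_values) <= 0)) abort("intensities must be positive")
  fc <- mean(test_values) / mean(ref_values)
  tibble(fc = fc, log2fc = log2(fc),
         direction = if (fc > 1) "up" else if (fc < 1) "down" else "none",
         n_fold = if (fc < 1) 1 / fc else fc)
}

#' Welch two-sample t-test with a variance floor
#'
#' Unequal-variance t statistic between two groups (intended for log2
#' intensities), two-sided p from the t distribution with
#' Welch-Satterthwaite degrees of freedom. A floor of `var_floor` is added
#' to each group variance so that identical or constant groups yield t = 0,
#' p = 1 rather than 0/0.
#'
#' @param ref_values,test_values Numeric vectors, >= 2 values each.
#' @param var_floor Variance floor (log2 scale), default 1e-8.
#' @return A one-row tibble with `t` (sign: test minus ref), `df`, `p`.
#' @export
two_group_test <- function(ref_values, test_values, var_floor = 1e-8) {
  n1 <- length(ref_values); n2 <- length(test_values)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 values")
  v1 <- stats::var(ref_values) + var_floor
  v2 <- stats::var(test_values) + var_floor
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(test_values) - mean(ref_values)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input
#' and clipped at 1.
#'
#' @param pvalues Numeric vector in [0, 1].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Call differential expression for one contrast
#'
#' Computes, per gene, linear fold change, the Welch test on log2
#' intensities, BH-adjusted q, and the significance call at the class
#' thresholds: significant iff the fold change exceeds `fc_min` in either
#' direction and p passes `p_max`. Significance uses the raw p-value (q is
#' reported alongside).
#'
#' @param x An expression table.
#' @param ref,test Group labels of the reference and test group.
#' @param thresholds A [de_thresholds()] object.
#' @param sample_info Sample metadata; defaults to the table's attribute.
#' @return A tibble of class `cernet_de`, one row per gene: `gene_id`,
#'   `mean_ref`, `mean_test`, `fc`, `log2fc`, `direction`, `t`, `df`, `p`,
#'   `q`, `neg_log10_p`, `significant`; sorted as the input. The contrast
#'   and thresholds are attached as attributes.
#' @export
call_differential <- function(x, ref = "A", test = "B",
                              thresholds = de_thresholds("mrna"),
                              sample_info = NULL) {
  validate_expression(x)
  si <- sample_info %||% sample_groups(x)
  if (is.null(si)) abort("no sample group labels available")
  m <- expr_matrix(x)
  ref_ids <- si$sample_id[si$group == ref]
  test_ids <- si$sample_id[si$group == test]
  if (!length(ref_ids)) abort(sprintf("unknown or empty group '%s'", ref))
  if (!length(test_ids)) abort(sprintf("unknown or empty group '%s'", test))
  mr <- m[, ref_ids, drop = FALSE]
  mt <- m[, test_ids, drop = FALSE]
  if (nrow(m) == 0) {
    out <- tibble(gene_id = character(), mean_ref = numeric(),
                  mean_test = numeric(), fc = numeric(), log2fc = numeric(),
                  direction = character(), t = numeric(), df = numeric(),
                  p = numeric(), q = numeric(), neg_log10_p = numeric(),
                  significant = logical())
    return(structure(out, class = c("cernet_de", class(out)),
                     contrast = c(ref = ref, test = test),
                     thresholds = thresholds))
  }
  mean_ref <- rowMeans(mr)
  mean_test <- rowMeans(mt)
  fc <- mean_test / mean_ref
  # vectorized Welch on log2 values
  l_r <- log2(mr); l_t <- log2(mt)
  n1 <- ncol(l_r); n2 <- ncol(l_t)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 samples")
  v1 <- apply(l_r, 1, stats::var) + 1e-8
  v2 <- apply(l_t, 1, stats::var) + 1e-8
  se2 <- v1 / n1 + v2 / n2
  tstat <- (rowMeans(l_t) - rowMeans(l_r)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  q <- bh_fdr(p)
  pass_fc <- if (thresholds$strict_fc) {
    fc > thresholds$fc_min | fc < 1 / thresholds$fc_min
  } else {
    fc >= thresholds$fc_min | fc <= 1 / thresholds$fc_min
  }
  pass_p <- if (thresholds$strict_p) p < thresholds$p_max else p <= thresholds$p_max
  out <- tibble(
    gene_id = rownames(m),
    mean_ref = unname(mean_ref), mean_test = unname(mean_test),
    fc = unname(fc), log2fc = unname(log2(fc)),
    direction = unname(ifelse(fc > 1, "up", ifelse(fc < 1, "down", "none"))),
    t = unname(tstat), df = unname(df), p = unname(p), q = unname(q),
    neg_log10_p = unname(-log10(p)),
    significant = unname(pass_fc & pass_p))
  structure(out, class = c("cernet_de", class(out)),
            contrast = c(ref = ref, test = test), thresholds = thresholds)
}

#' @method glance cernet_de
#' @export
glance.cernet_de <- function(x, ...) {
  ct <- attr(x, "contrast")
  tibble(ref = unname(ct["ref"]), test = unname(ct["test"]),
         n_genes = nrow(x),
         n_significant = sum(x$significant),
         n_up = sum(x$significant & x$direction == "up"),
         n_down = sum(x$significant & x$direction == "down"))
}

#' @method tidy cernet_de
#' @export
tidy.cernet_de <- function(x, ...) as_tibble(x)

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Agglomerative clustering of genes or samples with distance
#' 1 - Pearson r on log2 intensities and average linkage; deterministic for
#' a given input order.
#'
#' @param x An expression table.
#' @param axis `"genes"` or `"samples"`.
#' @return An [stats::hclust] object.
#' @export
hierarchical_cluster <- function(x, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  validate_expression(x)
  m <- log2(expr_matrix(x))
  if (axis == "samples") m <- t(m)
  if (nrow(m) < 2) abort("need at least 2 items to cluster")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance item(s): correlation distance undefined (%s)",
                  paste(head(rownames(m)[sds == 0], 3), collapse = ", ")))
  }
  d <- as.dist(1 - cor(t(m)))
  hclust(d, method = "average")
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes delta-Ct (target minus reference Ct) per condition, delta-delta
#' Ct (treated minus control), and returns 2^-ddCt. Replicate Ct values are
#' averaged within each condition before differencing.
#'
#' @param treated,control Each a list or data frame with elements/columns
#'   `ct_target` and `ct_reference` (threshold cycles).
#' @return Relative expression (positive scalar). Swapping treated and
#'   control inverts the result.
#' @export
ddct_fold_change <- function(treated, control) {
  dct <- function(x) {
    ct_t <- x$ct_target; ct_r <- x$ct_reference
    if (any(!is.finite(c(ct_t, ct_r))) || any(c(ct_t, ct_r) <= 0)) {
      abort("Ct values must be finite and positive")
    }
    mean(ct_t) - mean(ct_r)
  }
  ddct <- dct(treated) - dct(control)
  2^(-ddct)
}
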